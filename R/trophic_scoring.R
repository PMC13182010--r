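# Copiotroph/oligotroph classification against reference landmarks and the
# Sugar-Acid Preference (SAP) index.
#
# Each of 33 COG (sub)categories carries a reference value for an "average
# copiotroph" and an "average oligotroph" plus a direction: "+" means higher
# normalized gene counts indicate copiotrophy, "-" the opposite. A genome's
# normalized count is compared to the two landmarks per category; categories
# falling between them are indeterminate.

#' Read a trophic landmark set from YAML
#'
#' The file holds one entry per scored category: `category` (a COG letter or
#' a specific id like `COG1263`), `direction` (`"+"` or `"-"`),
#' `oligotroph_value`, `copiotroph_value` (may be null placeholders to be
#' filled by the user) and `unit` (`per_mb` or `per_orf`).
#'
#' @param path YAML file; defaults to the packaged landmark skeleton.
#' @return tibble of class `trophic_landmarks` with columns `category`,
#'   `direction`, `oligotroph_value`, `copiotroph_value`, `unit`.
#' @export
read_landmarks <- function(path = genotroph_extdata("landmarks.yaml")) {
  raw <- yaml::read_yaml(path)
  entries <- raw$landmarks %||% raw
  df <- dplyr::bind_rows(lapply(entries, function(e) {
    tibble(
      category = normalize_category_id(e$category),
      direction = as.character(e$direction),
      oligotroph_value = as.numeric(e$oligotroph_value %||% NA_real_),
      copiotroph_value = as.numeric(e$copiotroph_value %||% NA_real_),
      unit = as.character(e$unit %||% raw$unit %||% "per_mb")
    )
  }))
  validate_landmarks(df)
}

validate_landmarks <- function(df) {
  if (!all(df$direction %in% c("+", "-"))) {
    stop("landmark direction must be '+' or '-'", call. = FALSE)
  }
  if (!all(df$unit %in% c("per_mb", "per_orf"))) {
    stop("landmark unit must be 'per_mb' or 'per_orf'", call. = FALSE)
  }
  if (anyDuplicated(df$category)) {
    stop("duplicate landmark categories", call. = FALSE)
  }
  defined <- !is.na(df$oligotroph_value) & !is.na(df$copiotroph_value)
  if (any(defined & df$oligotroph_value == df$copiotroph_value)) {
    stop("oligotroph and copiotroph landmark values must differ", call. = FALSE)
  }
  class(df) <- c("trophic_landmarks", class(df))
  df
}

# "COG_1263", "COG1263" and "cog 1263" all normalize to "COG1263";
# single letters are upper-cased.
normalize_category_id <- function(x) {
  x <- toupper(gsub("[ _]", "", as.character(x)))
  is_cog <- grepl("^COG[0-9]+$", x)
  x[is_cog] <- sprintf("COG%04d", as.integer(sub("^COG", "", x[is_cog])))
  x
}

#' Count genes per landmark category
#'
#' General single-letter categories are counted from each gene's COG-category
#' letters (one increment per gene carrying the letter); specific `COGnnnn`
#' categories from each gene's COG ids.
#'
#' @param tables list of `annotation_table`s.
#' @param landmarks a `trophic_landmarks` table.
#' @return integer matrix genome x landmark category.
#' @export
landmark_counts <- function(tables, landmarks) {
  cats <- landmarks$category
  letters <- cats[nchar(cats) == 1]
  cogids <- cats[grepl("^COG[0-9]{4}$", cats)]
  other <- setdiff(cats, c(letters, cogids))
  if (length(other)) {
    stop("unrecognized landmark category id(s): ", paste(other, collapse = ", "),
      call. = FALSE
    )
  }
  gids <- vapply(tables, genome_id, character(1))
  out <- matrix(0L, nrow = length(gids), ncol = length(cats),
    dimnames = list(gids, cats))
  if (length(letters)) {
    lc <- count_cog_categories(tables)
    out[, letters] <- unclass(lc)[, letters, drop = FALSE]
  }
  if (length(cogids)) {
    out[, cogids] <- count_cog_ids(tables, cogids)
  }
  out
}

#' Normalize per-category counts by genome size or ORF total
#'
#' @param counts genome x category count matrix.
#' @param genomes tibble of genome records (one row per genome; must cover
#'   every row of `counts`).
#' @param unit `"per_mb"` (count / genome size in Mb, the default used for
#'   landmark scoring) or `"per_orf"` (count / total annotated ORFs).
#' @return numeric matrix of the same shape, with attribute `unit`.
#' @export
normalize_category_counts <- function(counts, genomes, unit = c("per_mb", "per_orf")) {
  unit <- match.arg(unit)
  idx <- match(rownames(counts), genomes$genome_id)
  if (anyNA(idx)) {
    stop(
      "missing genome metadata for: ",
      paste(rownames(counts)[is.na(idx)], collapse = ", "),
      call. = FALSE
    )
  }
  denom <- if (unit == "per_mb") {
    genomes$size_mb[idx]
  } else {
    as.numeric(genomes$total_orfs[idx])
  }
  if (any(is.na(denom)) || any(denom <= 0)) {
    stop("normalization denominator missing or nonpositive", call. = FALSE)
  }
  out <- sweep(unclass(counts) * 1.0, 1, denom, "/")
  attr(out, "unit") <- unit
  out
}

#' Call trophic strategy for one category value
#'
#' Direction `"+"`: value above the copiotroph landmark is a copiotroph
#' call, below the oligotroph landmark an oligotroph call, in between
#' (ties inclusive) indeterminate. Direction `"-"` mirrors the comparisons.
#'
#' @param value normalized count(s); vectorized.
#' @param direction `"+"` or `"-"` (recycled).
#' @param oligotroph_value,copiotroph_value landmark references (recycled).
#' @return character vector in
#'   `c("copiotroph", "oligotroph", "indeterminate")`.
#' @export
call_trophic_category <- function(value, direction, oligotroph_value,
                                  copiotroph_value) {
  n <- max(length(value), length(direction), length(oligotroph_value),
    length(copiotroph_value))
  value <- rep_len(value, n)
  direction <- rep_len(direction, n)
  olig <- rep_len(oligotroph_value, n)
  copi <- rep_len(copiotroph_value, n)
  out <- rep("indeterminate", n)
  plus <- direction == "+"
  out[plus & value > copi] <- "copiotroph"
  out[plus & value < olig] <- "oligotroph"
  out[!plus & value < copi] <- "copiotroph"
  out[!plus & value > olig] <- "oligotroph"
  out[is.na(value) | is.na(olig) | is.na(copi)] <- NA_character_
  out
}

#' Score genomes against a landmark set
#'
#' @param normalized genome x category matrix from
#'   [normalize_category_counts()] (columns must cover the landmark
#'   categories).
#' @param landmarks a `trophic_landmarks` table with values filled in.
#' @param include_mean also score the across-genome mean profile as a
#'   pseudo-genome `"mean-of-genomes"`.
#' @return tibble with columns `genome_id`, `category`, `normalized_value`,
#'   `direction`, `call`.
#' @export
score_trophic <- function(normalized, landmarks, include_mean = TRUE) {
  missing_cats <- setdiff(landmarks$category, colnames(normalized))
  if (length(missing_cats)) {
    stop("normalized matrix lacks landmark categories: ",
      paste(missing_cats, collapse = ", "),
      call. = FALSE
    )
  }
  m <- normalized[, landmarks$category, drop = FALSE]
  if (include_mean && nrow(m) > 1) {
    m <- rbind(m, "mean-of-genomes" = colMeans(m))
  }
  rows <- lapply(seq_len(nrow(m)), function(i) {
    tibble(
      genome_id = rownames(m)[i],
      category = landmarks$category,
      normalized_value = unname(m[i, ]),
      direction = landmarks$direction,
      call = call_trophic_category(
        m[i, ], landmarks$direction,
        landmarks$oligotroph_value, landmarks$copiotroph_value
      )
    )
  })
  dplyr::bind_rows(rows)
}

#' Summarize trophic calls into an overall label
#'
#' With c = copiotroph, o = oligotroph and i = indeterminate category
#' tallies: unanimity gives `"copiotroph"`/`"oligotroph"`; a strict
#' majority side (c > o, or o > c) without unanimity gives
#' `"moderate copiotroph"`/`"moderate oligotroph"`; otherwise
#' `"indeterminate"`.
#'
#' @param calls either a tibble of per-category calls (from
#'   [score_trophic()], one genome or the mean profile) or a named tally
#'   vector/list with elements `copiotroph`, `oligotroph`, `indeterminate`.
#' @return a one-row tibble with the tallies and `overall_label`.
#' @export
summarize_trophic <- function(calls) {
  if (is.data.frame(calls)) {
    if (length(unique(calls$genome_id)) != 1) {
      stop("summarize one genome (or the mean profile) at a time; see ",
        "summarize_trophic_all()",
        call. = FALSE
      )
    }
    tab <- table(factor(calls$call,
      levels = c("copiotroph", "oligotroph", "indeterminate")))
    n_cop <- unname(tab["copiotroph"])
    n_oli <- unname(tab["oligotroph"])
    n_ind <- unname(tab["indeterminate"])
    gid <- unique(calls$genome_id)
  } else {
    n_cop <- as.integer(calls[["copiotroph"]])
    n_oli <- as.integer(calls[["oligotroph"]])
    n_ind <- as.integer(calls[["indeterminate"]])
    gid <- NA_character_
  }
  total <- n_cop + n_oli + n_ind
  label <- if (total == 0) {
    "indeterminate"
  } else if (n_cop == total) {
    "copiotroph"
  } else if (n_oli == total) {
    "oligotroph"
  } else if (n_cop > n_oli) {
    "moderate copiotroph"
  } else if (n_oli > n_cop) {
    "moderate oligotroph"
  } else {
    "indeterminate"
  }
  tibble(
    genome_id = gid, n_copiotroph = as.integer(n_cop),
    n_oligotroph = as.integer(n_oli), n_indeterminate = as.integer(n_ind),
    overall_label = label
  )
}

#' Summaries for every genome in a call table
#'
#' @param calls tibble from [score_trophic()].
#' @return tibble with one summary row per genome id present.
#' @export
summarize_trophic_all <- function(calls) {
  dplyr::bind_rows(lapply(
    split(calls, calls$genome_id),
    summarize_trophic
  ))
}

#' Read a Sugar-Acid Preference configuration
#'
#' @param path YAML with `sugar_kos`, `acid_kos`, coefficients `s` and `a`.
#' @return list of class `sap_config`.
#' @export
read_sap_config <- function(path = genotroph_extdata("sap_config.yaml")) {
  raw <- yaml::read_yaml(path)
  cfg <- list(
    sugar_kos = as.character(raw$sugar_kos),
    acid_kos = as.character(raw$acid_kos),
    s = as.numeric(raw$s %||% 60.76),
    a = as.numeric(raw$a %||% -20.21)
  )
  if (!length(cfg$sugar_kos) || !length(cfg$acid_kos)) {
    stop("SAP config must define non-empty sugar and acid KO sets", call. = FALSE)
  }
  if (length(intersect(cfg$sugar_kos, cfg$acid_kos))) {
    stop("sugar and acid KO sets must be disjoint", call. = FALSE)
  }
  class(cfg) <- "sap_config"
  cfg
}

#' SAP index from relative abundances
#'
#' `SAP = tanh(s*S + a*A)` where S and A are the relative abundances
#' (fractions of annotated ORFs) of sugar- and acid-metabolism genes.
#' With the default coefficients (s = 60.76, a = -20.21) the index lies
#' strictly within (-1, 1); values near +1 indicate a sugar-metabolic
#' orientation, near -1 an acid orientation.
#'
#' The index is strictly inside (-1, 1); arguments extreme enough for
#' `tanh` to saturate to +/-1 in double precision are nudged to the nearest
#' representable value inside the open interval.
#'
#' @param S,A relative abundances in \[0, 1\].
#' @param s,a coefficients.
#' @return numeric SAP value(s).
#' @export
sap_index <- function(S, A, s = 60.76, a = -20.21) {
  bound <- 1 - .Machine$double.eps / 2
  pmin(pmax(tanh(s * S + a * A), -bound), bound)
}

#' Compute the SAP index for a genome
#'
#' @param annotation an `annotation_table` carrying KO assignments.
#' @param genome a genome record with `total_orfs` (> 0); if `NULL`, the
#'   number of annotated genes is used as the ORF total.
#' @param cfg a `sap_config`.
#' @return one-row tibble with `genome_id`, `S`, `A`, `sap`.
#' @export
compute_sap <- function(annotation, genome = NULL, cfg = read_sap_config()) {
  total_orfs <- if (is.null(genome)) {
    nrow(annotation)
  } else {
    genome$total_orfs
  }
  if (is.na(total_orfs) || total_orfs <= 0) {
    stop("total_orfs must be positive to compute relative abundances",
      call. = FALSE
    )
  }
  ko <- annotation$ko_id
  S <- sum(ko %in% cfg$sugar_kos) / total_orfs
  A <- sum(ko %in% cfg$acid_kos) / total_orfs
  tibble(
    genome_id = genome_id(annotation),
    S = S, A = A, sap = sap_index(S, A, cfg$s, cfg$a)
  )
}
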