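# ABC / PTS sugar-transporter completeness and transporter gene density.
#
# A transporter system is a set of named roles, each satisfied by any of a
# set of KO ids. An ABC importer needs a substrate-binding protein (SBP),
# transmembrane domain(s) (TMD) and a nucleotide-binding domain (NBD); a
# PTS needs enzyme I (EI), the phosphocarrier HPr and a substrate-specific
# enzyme II complex (EII). Only systems with every role matched count as
# evidence that the genome can transport the substrate.

ABC_ROLES <- c("SBP", "TMD", "NBD")
PTS_ROLES <- c("EI", "HPr", "EII")

#' Read transporter system definitions from YAML
#'
#' Each entry defines `system_id`, `kind` (`ABC`/`PTS`), `substrate` and a
#' `roles` mapping role name -> acceptable KO ids. For PTS systems the
#' general EI/HPr roles may be declared once at the top level (`pts_common`)
#' and are merged into every PTS system (a single EI/HPr copy serves all
#' EII complexes).
#'
#' @param path YAML file; defaults to the packaged sugar transporter set.
#' @return list of transporter definitions, class `transporter_defs`.
#' @export
read_transporter_defs <- function(path = genotroph_extdata("transporter_defs.yaml")) {
  raw <- yaml::read_yaml(path)
  common <- raw$pts_common %||% list()
  defs <- lapply(raw$systems, function(e) {
    roles <- lapply(e$roles, as.character)
    if (identical(e$kind, "PTS")) {
      for (r in names(common)) {
        if (is.null(roles[[r]])) roles[[r]] <- as.character(common[[r]])
      }
    }
    def <- list(
      system_id = e$system_id, kind = e$kind,
      substrate = e$substrate, roles = roles
    )
    validate_transporter_def(def)
    def
  })
  names(defs) <- vapply(defs, `[[`, character(1), "system_id")
  class(defs) <- "transporter_defs"
  defs
}

validate_transporter_def <- function(def) {
  expected <- switch(def$kind,
    ABC = ABC_ROLES,
    PTS = PTS_ROLES,
    stop("transporter kind must be ABC or PTS", call. = FALSE)
  )
  if (!setequal(names(def$roles), expected)) {
    stop(
      "system ", def$system_id, " must define exactly roles ",
      paste(expected, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(!vapply(def$roles, length, integer(1)))) {
    stop("every role of ", def$system_id, " needs >= 1 acceptable KO",
      call. = FALSE
    )
  }
  if (is.null(def$substrate) || !nzchar(def$substrate)) {
    stop("system ", def$system_id, " needs a substrate", call. = FALSE)
  }
  invisible(def)
}

#' Adjudicate completeness of one transporter system in one genome
#'
#' A role is present iff at least one gene's KO id falls in the role's
#' acceptable set; the system is complete iff every role is present.
#'
#' @param annotation an `annotation_table` with KO assignments.
#' @param sysdef one transporter definition (element of
#'   [read_transporter_defs()]).
#' @return a list of class `system_completeness` with `genome_id`,
#'   `system_id`, `kind`, `substrate`, `status` (`complete`/`incomplete`),
#'   `present_roles`, `missing_roles`, `supporting_genes` (gene ids per
#'   role).
#' @export
assess_system <- function(annotation, sysdef) {
  validate_transporter_def(sysdef)
  ko <- annotation$ko_id
  supporting <- lapply(sysdef$roles, function(accepted) {
    annotation$gene_id[!is.na(ko) & ko %in% accepted]
  })
  present <- names(supporting)[vapply(supporting, length, integer(1)) > 0]
  missing <- setdiff(names(sysdef$roles), present)
  structure(
    list(
      genome_id = genome_id(annotation),
      system_id = sysdef$system_id,
      kind = sysdef$kind,
      substrate = sysdef$substrate,
      status = if (length(missing)) "incomplete" else "complete",
      present_roles = present,
      missing_roles = missing,
      supporting_genes = supporting
    ),
    class = "system_completeness"
  )
}

#' Assess every system of a definition set against one genome
#'
#' @inheritParams assess_system
#' @param defs a `transporter_defs` list.
#' @return list of `system_completeness` results, one per system.
#' @export
assess_all_systems <- function(annotation, defs) {
  lapply(unclass(defs), function(d) assess_system(annotation, d))
}

#' Transportable substrates implied by complete systems
#'
#' A substrate is transportable by a pathway kind iff at least one system of
#' that kind for the substrate is complete; ABC and PTS capabilities are
#' reported separately.
#'
#' @param completeness list of `system_completeness` results (possibly for
#'   several genomes).
#' @return tibble with columns `genome_id`, `kind`, `substrates` (list
#'   column of sorted unique substrate names).
#' @export
infer_sugar_capabilities <- function(completeness) {
  df <- dplyr::bind_rows(lapply(completeness, function(x) {
    tibble(
      genome_id = x$genome_id, kind = x$kind,
      substrate = x$substrate, status = x$status
    )
  }))
  grid <- tidyr::expand_grid(
    genome_id = unique(df$genome_id), kind = c("ABC", "PTS")
  )
  caps <- lapply(seq_len(nrow(grid)), function(i) {
    sub <- df[df$genome_id == grid$genome_id[i] & df$kind == grid$kind[i] &
      df$status == "complete", ]
    sort(unique(sub$substrate))
  })
  grid$substrates <- caps
  grid
}

#' Transporter gene density per megabase
#'
#' @param n_genes total number of transporter-coding genes (>= 0).
#' @param size_mb genome size in megabases (> 0).
#' @param genome_id optional identifier carried into the report.
#' @return one-row tibble with `n_transporter_genes`, `size_mb`,
#'   `density_per_mb` (raw) and `density_display` (rounded half-up to one
#'   decimal, the conventional presentation).
#' @export
transporter_density <- function(n_genes, size_mb, genome_id = NA_character_) {
  if (any(n_genes < 0)) stop("n_genes must be nonnegative", call. = FALSE)
  if (any(size_mb <= 0)) stop("size_mb must be positive", call. = FALSE)
  density <- n_genes / size_mb
  tibble(
    genome_id = genome_id,
    n_transporter_genes = as.integer(n_genes),
    size_mb = size_mb,
    density_per_mb = density,
    density_display = round_half_up(density, 1)
  )
}

#' Rank a density against a reference distribution
#'
#' The percentile is the fraction of reference genomes with density strictly
#' below the query. Histogram bins of the stated width (default 5 per Mb,
#' edges 0-4, 5-9, ...) are returned for distribution plots.
#'
#' @param density query density (transporter genes per Mb).
#' @param reference numeric vector of reference densities (non-empty).
#' @param bin_width histogram bin width.
#' @return list with `percentile`, `top_fraction`
#'   (fraction of reference at or above the query), `median_reference` and
#'   `bins` (tibble `bin_start`, `bin_end`, `label`, `n`).
#' @export
rank_against_reference <- function(density, reference, bin_width = 5) {
  if (!length(reference)) stop("reference must be non-empty", call. = FALSE)
  perc <- mean(reference < density)
  upper <- max(c(reference, density))
  starts <- seq(0, floor(upper / bin_width) * bin_width, by = bin_width)
  bins <- tibble(
    bin_start = starts,
    bin_end = starts + bin_width - 1,
    label = sprintf("%d-%d", starts, starts + bin_width - 1),
    n = vapply(starts, function(s) {
      sum(reference >= s & reference < s + bin_width)
    }, numeric(1))
  )
  list(
    percentile = perc,
    top_fraction = mean(reference >= density),
    median_reference = stats::median(reference),
    bins = bins
  )
}
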