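# CAZyme family counts (dbCAN dialect) and glycoside-hydrolase polymer
# capability profiles (agar, cellulose, chitin, pectin, xylan).

#' Read a dbCAN overview table into family counts
#'
#' Accepts the dbCAN `overview.txt` dialect: one row per gene, with family
#' assignments in an `HMMER` column (tokens like `GH18(150-400)`, several
#' joined by `+`) or, failing that, in the second column. Subfamily
#' suffixes (`GH5_25`) collapse to the family (`GH5`). Unparseable family
#' tokens are skipped with a warning.
#'
#' @param path TSV file path.
#' @param genome_id genome identifier.
#' @return list of class `cazyme_counts`: `genome_id`, `counts` (named
#'   integer vector family -> count).
#' @export
read_dbcan_overview <- function(path, genome_id) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  col <- if ("HMMER" %in% names(df)) {
    df$HMMER
  } else if (ncol(df) >= 2) {
    df[[2]]
  } else {
    stop("dbCAN table needs an HMMER column or at least two columns",
      call. = FALSE
    )
  }
  tokens <- unlist(lapply(col, function(s) {
    if (is.na(s) || s %in% c("", "-")) {
      return(character(0))
    }
    strsplit(s, "+", fixed = TRUE)[[1]]
  }))
  tokens <- sub("\\(.*\\)$", "", tokens)
  fams <- sub("_[0-9]+$", "", tokens)
  ok <- grepl("^(GH|GT|PL|CE|AA|CBM)[0-9]+$", fams)
  if (any(!ok)) {
    warning(
      "skipping unparseable CAZyme family token(s) in ", basename(path),
      ": ", paste(unique(tokens[!ok]), collapse = ", "),
      call. = FALSE
    )
  }
  counts <- table(fams[ok])
  cazyme_counts(genome_id, setNames(as.integer(counts), names(counts)))
}

#' Construct a CAZyme count object
#'
#' @param genome_id genome identifier.
#' @param counts named integer vector family -> count (all >= 0).
#' @return list of class `cazyme_counts`.
#' @export
cazyme_counts <- function(genome_id, counts) {
  if (length(counts) && (is.null(names(counts)) || any(counts < 0))) {
    stop("counts must be a named nonnegative vector", call. = FALSE)
  }
  structure(
    list(genome_id = genome_id, counts = counts),
    class = "cazyme_counts"
  )
}

#' Read a polymer -> GH family map
#'
#' @param path YAML mapping polymer names to GH family lists; defaults to
#'   the packaged map.
#' @return named list polymer -> character vector of families.
#' @export
read_polymer_map <- function(path = genotroph_extdata("polymer_map.yaml")) {
  raw <- yaml::read_yaml(path)
  map <- lapply(raw$polymers %||% raw, as.character)
  if (!length(map)) stop("empty polymer map", call. = FALSE)
  map
}

#' Polymer degradation profile from family counts
#'
#' Sums gene counts over the families mapped to each polymer. Polymers with
#' no mapped gene are retained with count 0 (explicit absence). Families
#' present in the input but absent from the map are reported under
#' `unmapped`, never silently dropped.
#'
#' @param counts a `cazyme_counts` object.
#' @param map polymer map from [read_polymer_map()].
#' @return list with `profile` (tibble `genome_id`, `polymer`, `n_genes`),
#'   `by_family` (tibble `genome_id`, `family`, `polymer`, `count`) and
#'   `unmapped` (named vector of unmapped family counts).
#' @export
polymer_profile <- function(counts, map) {
  fams <- names(counts$counts)
  profile <- tibble(
    genome_id = counts$genome_id,
    polymer = names(map),
    n_genes = vapply(names(map), function(p) {
      sum(counts$counts[intersect(map[[p]], fams)])
    }, numeric(1), USE.NAMES = FALSE)
  )
  by_family <- dplyr::bind_rows(lapply(names(map), function(p) {
    tibble(
      genome_id = counts$genome_id,
      family = map[[p]],
      polymer = p,
      count = as.integer(ifelse(map[[p]] %in% fams,
        counts$counts[map[[p]]], 0L
      ))
    )
  }))
  mapped <- unique(unlist(map))
  unmapped <- counts$counts[setdiff(fams, mapped)]
  list(profile = profile, by_family = by_family, unmapped = unmapped)
}

#' Merge CAZyme counts across genomes (sums shared families)
#'
#' @param x,y `cazyme_counts` objects.
#' @param genome_id identifier for the merged object.
#' @return a `cazyme_counts` with element-wise summed counts.
#' @export
merge_cazyme_counts <- function(x, y, genome_id = paste(x$genome_id, y$genome_id, sep = "+")) {
  fams <- sort(union(names(x$counts), names(y$counts)))
  get0i <- function(v, f) ifelse(f %in% names(v), v[f], 0L)
  merged <- setNames(
    as.integer(get0i(x$counts, fams) + get0i(y$counts, fams)),
    fams
  )
  cazyme_counts(genome_id, merged)
}
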