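# Genome x COG-category count matrix, per-category Z-scores and CV banding.
# A gene with k category letters increments k cells (the eggNOG convention);
# a gene with no letter increments the "unknown" sentinel column.

#' Count genes per COG category per genome
#'
#' @param tables list of `annotation_table`s with distinct genome ids.
#' @param policy `"per_letter"` (a gene with k category letters increments k
#'   cells) or `"first_letter"` (only the first letter counts).
#' @return an integer matrix of class `cog_count_matrix` (genome x category)
#'   whose columns are the prokaryotic COG alphabet plus `"unknown"`.
#' @export
count_cog_categories <- function(tables, policy = c("per_letter", "first_letter")) {
  policy <- match.arg(policy)
  if (!length(tables)) stop("need at least one annotation table", call. = FALSE)
  ids <- vapply(tables, genome_id, character(1))
  if (anyDuplicated(ids)) stop("genome ids must be distinct", call. = FALSE)
  cats <- c(COG_ALPHABET, UNKNOWN_CATEGORY)
  counts <- matrix(0L, nrow = length(ids), ncol = length(cats),
    dimnames = list(ids, cats))
  for (i in seq_along(tables)) {
    for (letters in tables[[i]]$cog_categories) {
      if (!length(letters)) {
        counts[i, UNKNOWN_CATEGORY] <- counts[i, UNKNOWN_CATEGORY] + 1L
      } else {
        use <- if (policy == "first_letter") letters[1] else letters
        counts[i, use] <- counts[i, use] + 1L
      }
    }
  }
  class(counts) <- c("cog_count_matrix", class(counts))
  counts
}

#' Count genes carrying specific COG ids
#'
#' @param tables list of `annotation_table`s.
#' @param ids character vector of COG ids (e.g. `"COG1263"`).
#' @return integer matrix genome x COG id; a gene carrying an id increments
#'   that id's cell once.
#' @export
count_cog_ids <- function(tables, ids) {
  gids <- vapply(tables, genome_id, character(1))
  counts <- matrix(0L, nrow = length(gids), ncol = length(ids),
    dimnames = list(gids, ids))
  for (i in seq_along(tables)) {
    gene_ids <- tables[[i]]$cog_ids
    for (g in gene_ids) {
      hit <- intersect(g, ids)
      if (length(hit)) counts[i, hit] <- counts[i, hit] + 1L
    }
  }
  counts
}

#' Per-category Z-scores across genomes
#'
#' For each category, z = (x - mu) / sigma where mu and sigma are the mean
#' and standard deviation of the category's count across all genomes. If a
#' category's sigma is 0 all its z-values are 0.
#'
#' @param counts a `cog_count_matrix` (or any genome x category matrix) with
#'   at least two genomes.
#' @param sd_type `"population"` (divide by n) or `"sample"` (divide by
#'   n - 1).
#' @return a numeric matrix of the same shape.
#' @export
zscore_matrix <- function(counts, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (nrow(counts) < 2) {
    stop("Z-scores require at least two genomes (sigma undefined for one)",
      call. = FALSE
    )
  }
  x <- unclass(counts)
  storage.mode(x) <- "double"
  mu <- colMeans(x)
  n <- nrow(x)
  sigma <- apply(x, 2, function(col) {
    s2 <- sum((col - mean(col))^2)
    sqrt(s2 / if (sd_type == "population") n else n - 1)
  })
  z <- sweep(x, 2, mu, "-")
  nonzero <- sigma > 0
  z[, nonzero] <- sweep(z[, nonzero, drop = FALSE], 2, sigma[nonzero], "/")
  z[, !nonzero] <- 0
  z
}

#' Coefficient-of-variation banding per COG category
#'
#' CV = 100 * sigma / mu per category (population sigma). Categories with
#' CV <= `low_max` are banded `"low"`, CV >= `high_min` `"high"`, otherwise
#' `"intermediate"` (both boundaries inclusive toward the outer bands).
#' Categories with zero mean get band `"undefined"`.
#'
#' @inheritParams zscore_matrix
#' @param low_max upper bound (percent) of the low-variability band.
#' @param high_min lower bound (percent) of the high-variability band.
#' @return a tibble with columns `category`, `cv` (percent), `band`.
#' @export
cv_banding <- function(counts, low_max = 5, high_min = 10) {
  if (nrow(counts) < 2) stop("CV requires at least two genomes", call. = FALSE)
  if (low_max >= high_min) stop("low_max must be below high_min", call. = FALSE)
  x <- unclass(counts)
  storage.mode(x) <- "double"
  mu <- colMeans(x)
  n <- nrow(x)
  sigma <- apply(x, 2, function(col) sqrt(sum((col - mean(col))^2) / n))
  cv <- ifelse(mu > 0, 100 * sigma / mu, NA_real_)
  band <- ifelse(is.na(cv), "undefined",
    ifelse(cv <= low_max, "low", ifelse(cv >= high_min, "high", "intermediate"))
  )
  tibble(category = colnames(x), cv = unname(cv), band = unname(band))
}

#' Long-format export of counts, Z-scores and CV bands
#'
#' Heatmap-ready table with one row per genome x category.
#'
#' @inheritParams zscore_matrix
#' @param low_max,high_min CV band thresholds in percent.
#' @return tibble with columns `genome_id`, `category`, `count`, `z`,
#'   `cv_band`.
#' @export
cog_profile_long <- function(counts, low_max = 5, high_min = 10) {
  z <- zscore_matrix(counts)
  bands <- cv_banding(counts, low_max, high_min)
  long <- as_tibble(as.data.frame.table(unclass(counts), stringsAsFactors = FALSE))
  names(long) <- c("genome_id", "category", "count")
  long$z <- as.vector(z)
  long$count <- as.integer(long$count)
  dplyr::left_join(long, setNames(bands[c("category", "band")],
    c("category", "cv_band")), by = "category")
}
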