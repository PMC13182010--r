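#' @importFrom rlang %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join distinct n
#' @importFrom stats rpois rnorm sd median setNames
#' @importFrom utils head tail
NULL

# Prokaryotic COG functional category alphabet, in the conventional display
# order. Letters B (chromatin), Y (nuclear structure) and Z (cytoskeleton)
# describe eukaryote-specific machinery and are excluded from the recognized
# set; annotations carrying them are dropped at parse time with a warning.
COG_ALPHABET <- c(
  "J", "A", "K", "L", "D", "V", "T", "M", "N", "U", "O", "X",
  "C", "G", "E", "F", "H", "I", "P", "Q", "R", "S", "W"
)

EUKARYOTIC_COG_LETTERS <- c("B", "Y", "Z")

# Sentinel column for genes with no COG category assignment.
UNKNOWN_CATEGORY <- "unknown"

#' Round half away from zero at a fixed number of decimals
#'
#' Base R `round()` rounds half to even; per-megabase transporter densities
#' are presented with conventional half-up rounding at one decimal (e.g.
#' 294/4.8 = 61.25 is shown as 61.3).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 1) {
  mult <- 10^digits
  sign(x) * floor(abs(x) * mult + 0.5) / mult
}

#' Locate a packaged configuration or fixture file
#'
#' @param ... path components under `inst/extdata`.
#' @return absolute path to the file.
#' @export
genotroph_extdata <- function(...) {
  path <- system.file("extdata", ..., package = "genotroph", mustWork = FALSE)
  if (!nzchar(path)) {
    stop("packaged file not found: ", file.path(...), call. = FALSE)
  }
  path
}

# Deterministic 32-bit seed derived from an integer seed and a string key,
# so each synthetic genome gets its own reproducible RNG stream and adding
# a genome to a cohort does not perturb the others.
derive_seed <- function(seed, key) {
  h <- 0
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% 2147480009
  }
  as.integer((as.numeric(seed) * 7919 + h) %% 2147480009)
}

# Evaluate `expr` under a local RNG seed without touching the caller's
# .Random.seed.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
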