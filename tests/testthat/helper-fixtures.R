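# In-code fixture builders shared across the suite.

# Compact annotation_table builder: cats is a list of character vectors
# (COG letters per gene), kos/cogids/products optional parallel vectors.
ann_fixture <- function(genome_id, cats, kos = NULL, cogids = NULL,
                        products = NULL) {
  n <- length(cats)
  genotroph:::new_annotation_table(genome_id, tibble::tibble(
    gene_id = sprintf("%s_g%03d", genome_id, seq_len(n)),
    cog_categories = lapply(cats, as.character),
    cog_ids = if (is.null(cogids)) {
      replicate(n, character(0), simplify = FALSE)
    } else {
      lapply(cogids, as.character)
    },
    ko_id = if (is.null(kos)) rep(NA_character_, n) else as.character(kos),
    product = if (is.null(products)) rep(NA_character_, n) else products,
    rank = seq_len(n) - 1L
  ))
}

# Annotation table whose genes carry only KO ids (one gene per KO, with
# optional repeats).
ko_ann <- function(genome_id, kos) {
  ann_fixture(genome_id,
    cats = replicate(length(kos), character(0), simplify = FALSE),
    kos = kos
  )
}

# Labeled square similarity matrix from a vector of upper-triangle values.
sim_matrix <- function(ids, upper, diag_val = 100) {
  n <- length(ids)
  m <- matrix(diag_val, n, n, dimnames = list(ids, ids))
  k <- 1
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- upper[k]
      k <- k + 1
    }
  }
  m
}

# Write lines to a temp file and return its path.
tmp_lines <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# A detection record list for adjudicate() with less typing.
mk_det <- function(roles, source = "txsscan", genome = "g1", model = "toy") {
  detection_record(genome, model, roles, source = source)
}

# A toy machinery model with n mandatory roles r1..rn.
toy_model <- function(n, threshold = 1 / 3, model_id = "toy") {
  list(
    model_id = model_id,
    mandatory_genes = paste0("r", seq_len(n)),
    accessory_genes = character(0),
    highly_incomplete_fraction = threshold
  )
}
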