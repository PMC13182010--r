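# Packaged reference metadata for the seven Motilimonas genomes the
# pipeline was developed around (strain labels, NCBI accessions, genome
# sizes, CDS totals and printed transporter gene counts). These are inputs
# for worked examples and density calculations, not computed results.

#' Motilimonas genome metadata table
#'
#' Genome size (Mb), assembly level, CDS totals and total/sugar transporter
#' gene counts for the seven publicly available Motilimonas genomes.
#'
#' @return tibble with one row per genome.
#' @export
motilimonas_genomes <- function() {
  readr::read_tsv(
    genotroph_extdata("motilimonas_genomes.tsv"),
    col_types = readr::cols(
      genome_id = readr::col_character(),
      label = readr::col_character(),
      accession = readr::col_character(),
      assembly_level = readr::col_character(),
      size_mb = readr::col_double(),
      cds = readr::col_integer(),
      n_transporter_genes = readr::col_integer(),
      abc_sugar_genes = readr::col_integer(),
      pts_sugar_genes = readr::col_integer()
    ),
    progress = FALSE
  )
}
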