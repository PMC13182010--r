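#!/usr/bin/env Rscript
# Build the synthetic seven-genome cohort used by the downstream analysis
# scripts: annotation tables in the eggNOG dialect, ANI/dDDH matrices with
# a planted three-genome species block, and a pipeline config. Bulky
# intermediates go under scratch/cohort; later scripts read from there.

suppressPackageStartupMessages(library(genotroph))

dir.create("scratch/cohort", recursive = TRUE, showWarnings = FALSE)
seed <- 2026L

ids <- c("simA", "simB", "simC", "simD", "simE", "simF", "simG")
# simA-simC form a planted conspecific block (mirroring a three-genome
# clade); all genomes are "moderate" archetypes except one copiotroph and
# one oligotroph control at the ends of the spectrum.
archetypes <- c("moderate", "moderate", "moderate", "moderate",
  "moderate", "copiotroph", "oligotroph")
sizes <- c(4.8, 4.6, 4.8, 4.8, 4.6, 4.2, 4.5)

panel_on <- list(
  napA = 1, napB = 1, nirB = 1, nirD = 1, # nitrate reduction
  proV = 1, proW = 1, proX = 1, # proU osmoprotectant transport
  cheA = 1, cheW = 1, cheV = 1, cheB = 1, cheR = 1, cheD = 1,
  cheY = 1, cheZ = 1, cheX = 1, fliG = 1, fliM = 1, fliN = 1,
  motA = 1, motB = 1 # chemotaxis signalling
)

specs <- lapply(seq_along(ids), function(i) {
  synthetic_genome_spec(ids[i],
    size_mb = sizes[i], archetype = archetypes[i],
    seed = seed + i, n_background_genes = 1500L,
    sugar_genes = 25, acid_genes = 8,
    panel_toggles = panel_on,
    cazyme_profile = c(GH18 = 12, GH5 = 1, GH2 = 1)
  )
})

genome_entries <- lapply(specs, function(spec) {
  ann <- generate_annotation(spec)
  path <- file.path("scratch/cohort", paste0(spec$genome_id, ".annotations.tsv"))
  write_eggnog_table(ann, path)
  cat(sprintf("  %s: %d genes (%s archetype)\n",
    spec$genome_id, nrow(ann), spec$archetype))
  list(id = spec$genome_id, size_mb = spec$size_mb, eggnog = path,
    assembly_level = "contig")
})

cohort <- synthetic_cohort_spec(
  blocks = list(ids[1:3], ids[4], ids[5], ids[6], ids[7]),
  seed = seed
)
sm <- generate_similarity(cohort)
write_similarity_tsv(sm, "scratch/cohort/ani.tsv", "scratch/cohort/dddh.tsv")

yaml::write_yaml(
  list(genomes = genome_entries, ani = "scratch/cohort/ani.tsv",
    dddh = "scratch/cohort/dddh.tsv"),
  "scratch/cohort/config.yaml"
)

cat("Simulated", length(ids), "genomes;",
  "planted species block:", paste(ids[1:3], collapse = ", "), "\n")
cat("Cohort config written to scratch/cohort/config.yaml\n")
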