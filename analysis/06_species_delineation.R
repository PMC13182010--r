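#!/usr/bin/env Rscript
# Species delineation: (i) of the simulated cohort from its generated
# ANI/dDDH matrices (planted three-genome block), and (ii) of the seven
# reference genomes from matrices constructed to the printed pairwise
# summary ranges.

suppressPackageStartupMessages(library(genotroph))

sm <- read_similarity_matrices("scratch/cohort/ani.tsv", "scratch/cohort/dddh.tsv")
dl <- delineate(sm)

cat("Simulated cohort clusters:\n")
print(as.data.frame(dl$clusters))
cat("Planted block recovered:",
  identical(cluster_members(dl, "simA"), c("simA", "simB", "simC")), "\n")

# Reference cohort: clade pairs at ANI 98.32-98.72 / dDDH 87.8-90.2, the
# nearest neighbour elevated but below both thresholds, all else low.
ids <- c("Spo1_1", "E26", "G1M02", "MKS20", "YH6", "KMU-193", "PLHSC7-2")
n <- length(ids)
ani <- matrix(85, n, n, dimnames = list(ids, ids))
dddh <- matrix(30, n, n, dimnames = list(ids, ids))
clade <- ids[1:3]
ani[clade, clade] <- 98.52
dddh[clade, clade] <- 89
ani["Spo1_1", "E26"] <- ani["E26", "Spo1_1"] <- 98.32
ani["E26", "G1M02"] <- ani["G1M02", "E26"] <- 98.72
dddh["Spo1_1", "E26"] <- dddh["E26", "Spo1_1"] <- 87.8
dddh["E26", "G1M02"] <- dddh["G1M02", "E26"] <- 90.2
ani["MKS20", clade] <- ani[clade, "MKS20"] <- 92
dddh["MKS20", clade] <- dddh[clade, "MKS20"] <- 48
diag(ani) <- diag(dddh) <- 100
ref <- delineate(similarity_matrices(ani, dddh))

dir.create("results", showWarnings = FALSE)
readr::write_tsv(dl$clusters, "results/sim_species_clusters.tsv", progress = FALSE)
readr::write_tsv(ref$clusters, "results/reference_species_clusters.tsv",
  progress = FALSE)
readr::write_tsv(ref$pairs, "results/reference_species_pairs.tsv",
  progress = FALSE)

cat("Reference cohort: cluster containing Spo1_1 =",
  paste(cluster_members(ref, "Spo1_1"), collapse = ", "), "\n")
cat("Total putative species among the reference genomes:",
  length(unique(ref$clusters$cluster)), "\n")
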