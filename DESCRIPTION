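Package: genotroph
Title: Genome Ecophysiological Profiling of Heterotrophic Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Profiles bacterial genomes along the copiotroph-oligotroph
    continuum from per-gene functional annotation tables. Parses
    eggNOG-mapper and BlastKOALA output dialects, counts genes per COG
    category with Z-scores and coefficient-of-variation banding, scores
    trophic strategy against copiotroph/oligotroph reference landmarks,
    computes the Sugar-Acid Preference (SAP) index, adjudicates ABC/PTS
    sugar-transporter and secretion-system/pilus/flagellum completeness
    (with gene-neighborhood rescue), screens ecological gene panels
    (osmoadaptation, oxidative stress, nitrate reduction, chemotaxis),
    builds CAZyme glycoside-hydrolase polymer profiles, and delineates
    species from ANI and dDDH matrices under dual thresholds. Includes a
    seeded synthetic-annotation generator so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
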