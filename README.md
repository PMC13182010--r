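# genotroph

Genome ecophysiological profiling of heterotrophic bacteria from
functional annotation tables.

Marine bacteria spread along a copiotroph–oligotroph continuum:
copiotrophs boom on transient nutrient patches (large genomes, many
phosphotransferase sugar-uptake systems, motility, chemotaxis,
chitinases), oligotrophs grow steadily on dilute nutrients (streamlined
genomes, high-affinity ABC transporters). `genotroph` infers where a
genome sits on that continuum — and profiles the ecological traits
around it — starting from the tables that standard annotation tools
emit (eggNOG-mapper, BlastKOALA, dbCAN, MacSyFinder-style scanners),
without running any of those tools itself. It was built around the seven
publicly available *Motilimonas* genomes (family *Psychromonadaceae*)
but every stage is generic.

What it computes:

- **COG profile** — genes per COG category per genome, Z-scores
  *z = (x − µ)/σ* per category across the cohort, and
  coefficient-of-variation bands (low ≤ 5%, high ≥ 10%).
- **Trophic scoring** — per-Mb (or per-ORF) category counts compared to
  "average copiotroph" / "average oligotroph" reference landmarks over
  33 COG (sub)categories with per-category direction, plus an overall
  label (copiotroph / moderate copiotroph / indeterminate / …).
- **SAP index** — Sugar-Acid Preference, `SAP = tanh(sS + aA)` with
  s = 60.76, a = −20.21, of sugar- and acid-gene ORF fractions
  (+1 sugar-oriented, −1 acid-oriented).
- **Transporters** — ABC (SBP + TMD + NBD) and PTS (EI + HPr + EII)
  completeness, transportable-sugar inference, genes-per-Mb density with
  reference-distribution ranking.
- **Trait panels** — osmoadaptation (compatible solutes), oxidative
  stress / high-affinity oxidases (microaerobe flag), nitrate reduction
  to ammonia, fermentation end products, chemotaxis, MCP/Aer counts.
- **Machinery adjudication** — secretion systems T1SS–T6SS (incl. T4SS
  subtypes), flagellum, Tad/MSH/T4aP pili: completeness with provenance
  codes (scanner-confirmed, BRITE-only, homology-rescued, highly
  incomplete) and a ±10-gene neighborhood window for rescue candidates.
- **CAZyme profiles** — GH-family counts mapped to polymer capabilities
  (agar, cellulose, chitin, pectin, xylan).
- **Species delineation** — connected components of genome pairs
  exceeding 95% ANI **and** 70% dDDH, with non-clique components
  flagged.
- **Synthetic data** — seeded generators for every input above, so the
  whole pipeline is testable without downloads.

## Worked example

Transporter densities from the packaged *Motilimonas* metadata
(counts and genome sizes are the published inputs):

```r
library(genotroph)
meta <- motilimonas_genomes()
transporter_density(meta$n_transporter_genes, meta$size_mb, meta$genome_id)
#> # A tibble: 7 × 5
#>   genome_id n_transporter_genes size_mb density_per_mb density_display
#>   <chr>                   <int>   <dbl>          <dbl>           <dbl>
#> 1 Spo1_1                    280     4.8           58.3            58.3
#> 2 E26                       282     4.6           61.3            61.3
#> 3 G1M02                     289     4.8           60.2            60.2
#> 4 MKS20                     294     4.8           61.2            61.3
#> 5 YH6                       263     4.6           57.2            57.2
#> 6 KMU-193                   268     4.2           63.8            63.8
#> 7 PLHSC7-2                  256     4.5           56.9            56.9
```

`density_display` is the half-up 1-decimal presentation: all seven
genomes carry 57–64 transporter genes per Mb. A category outcome of
21 copiotroph / 4 oligotroph / 8 indeterminate landmark categories maps
to the genus-level label:

```r
summarize_trophic(c(copiotroph = 21, oligotroph = 4, indeterminate = 8))
#> # A tibble: 1 × 5
#>   genome_id n_copiotroph n_oligotroph n_indeterminate overall_label
#>   <chr>            <int>        <int>           <int> <chr>
#> 1 <NA>                21            4               8 moderate copiotroph
```

End to end on synthetic data — generate a copiotroph-archetype genome,
score it, and compute its SAP index:

```r
lm   <- synthetic_landmarks()
spec <- synthetic_genome_spec("demo", archetype = "copiotroph", seed = 1,
                              sugar_genes = 25, acid_genes = 8)
ann  <- generate_annotation(spec, lm)
norm <- normalize_category_counts(landmark_counts(list(ann), lm),
                                  synthetic_genome_record(spec, ann))
summarize_trophic(score_trophic(norm, lm, include_mean = FALSE))$overall_label
#> [1] "copiotroph"
compute_sap(ann)$sap
#> [1] 0.3715833
```

## Analysis workflow

The `analysis/` scripts run the published-style analysis sequence over a
simulated seven-genome cohort (bulky intermediates under `scratch/`,
summary tables under `results/`):

```sh
Rscript analysis/01_simulate_cohort.R      # cohort + ANI/dDDH matrices
Rscript analysis/02_cog_profile.R          # counts, Z-scores, CV bands
Rscript analysis/03_trophic_sap.R          # landmark scoring + SAP
Rscript analysis/04_transporters_panels.R  # completeness, panels, densities
Rscript analysis/05_machineries_cazymes.R  # secretion/pili adjudication, CAZymes
Rscript analysis/06_species_delineation.R  # dual-threshold clustering
```

`run_profile()` wraps the same stages behind one config (see
`?run_profile`) and writes per-genome JSON profiles.

## Notes on shipped configuration

The landmark reference values and the SAP KO curation are not
redistributed (`landmarks.yaml` ships ids/directions with placeholder
values; `sap_config.yaml` ships a compact stand-in KO curation) — see
the methods vignette (`vignettes/genome-ecophysiological-profiling.Rmd`)
for why, and for the full account of models, parameters, numerical
choices and limitations.
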