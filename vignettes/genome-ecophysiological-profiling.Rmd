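---
title: "Genome ecophysiological profiling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome ecophysiological profiling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genotroph)
```

`genotroph` profiles heterotrophic bacterial genomes along the
copiotroph–oligotroph continuum starting from per-gene functional
annotation tables — the output of tools like eggNOG-mapper (COG
categories and ids), BlastKOALA (KEGG KOs), dbCAN (CAZyme families) and
MacSyFinder-style system scanners. It never runs those tools; it parses
their table dialects and does the comparative arithmetic and rule-based
adjudication on top. This vignette explains the models behind each stage,
the parameters that matter, and the choices made where the design was
genuinely open.

## The data model

Everything hangs off the `annotation_table`: one row per gene with a set
of COG category letters (possibly empty), a set of specific COG ids, an
optional KO id, free-text product, and a 0-based `rank` giving gene order
along the replicon. Rank stands in for coordinates — the pipeline never
parses GFF/GenBank, and ten-genes-either-side neighborhood logic only
needs order, not base pairs. COG letters outside the prokaryotic
alphabet are dropped at parse time with a warning; the eukaryote-specific
chromatin/nuclear/cytoskeleton letters (B, Y, Z) have no meaning for
bacterial genomes, while A (RNA processing) is retained because it does
occur in prokaryotic annotations. Genes with no category letter are
tallied under an explicit `"unknown"` sentinel rather than silently
ignored, so the uncharacterized fraction of a genome stays visible.

Merging KO assignments onto a COG table (`merge_annotations()`) is
commutative by construction: per gene, category sets and COG-id sets are
unioned, the KO is the unique non-missing value, and a conflict is an
error rather than a silent overwrite. The order in which annotation
layers arrive therefore cannot change the result.

## COG counts, Z-scores and CV bands

`count_cog_categories()` counts one increment per category letter per
gene (the eggNOG convention for multi-letter assignments;
`policy = "first_letter"` is available for the stricter one-gene-one-vote
convention). Z-scores are the plain standardization
$z = (x - \mu)/\sigma$ per category across genomes. The formula does not
specify the variance estimator; we default to the population
$\sigma$ (divide by $n$) because the genomes at hand are the entire
cohort being compared, not a sample from a larger one — and expose
`sd_type = "sample"` for users who disagree. A category with
$\sigma = 0$ gets $z = 0$ everywhere, which keeps heatmaps neutral
instead of propagating NaN. Coefficients of variation are
$100\,\sigma/\mu$; the banding boundaries (low $\le$ 5%, high $\ge$ 10%)
are both inclusive toward the outer bands, and both are configurable.

## Trophic-strategy scoring against landmarks

The classifier compares each genome's normalized gene count in 33 COG
(sub)categories against two reference values per category — an "average
copiotroph" and an "average oligotroph" — with a direction flag: for
`"+"` categories, higher counts indicate copiotrophy; for `"-"`
categories the comparisons are mirrored. A value beyond the copiotroph
landmark is a copiotroph call, beyond the oligotroph landmark an
oligotroph call, and anything in between — including exact ties — is
indeterminate. Ties are genuinely ambiguous and we resolve them
conservatively rather than inventing a tie-break the reference scheme
never states.

Two normalizations circulate for this analysis: counts per Mb of genome
and counts per annotated ORF. Both are implemented
(`normalize_category_counts()`); per-Mb is the default because the
headline landmark comparison is conventionally drawn on that scale, and
the chosen unit is recorded in the output metadata so the provenance is
never ambiguous.

The packaged `landmarks.yaml` ships the 33 category ids and the 14/19
direction split with the numeric reference values left as explicit
placeholders: those values belong to the published reference scheme's
supplementary material and are not redistributed. The package is fully
exercisable without them through `synthetic_landmarks()`, which fills
the skeleton with stand-in values (oligotroph 5 / copiotroph 15 genes
per Mb, mirrored for `"-"` categories). All tests use synthetic
landmarks; nothing in the test suite depends on the unpublished numbers.

The per-genome summary maps category tallies to an overall label:
unanimity gives `copiotroph`/`oligotroph`; a strict majority side without
unanimity gives the `moderate` variant; anything else (including tied
tallies) is `indeterminate`. The summary is computed both per genome and
on the across-genome mean profile, since a genus-level statement is
naturally made about the mean.

## The SAP index

The Sugar-Acid Preference index is
$\mathrm{SAP} = \tanh(sS + aA)$ with $s = 60.76$, $a = -20.21$, where
$S$ and $A$ are the fractions of annotated ORFs assigned to
sugar-metabolism and acid-metabolism KOs. Values near $+1$ indicate a
sugar-metabolic orientation, near $-1$ an acid orientation. The KO sets
are configuration, not code: the published curation they derive from is
not redistributed, so `sap_config.yaml` ships a compact, documented
stand-in curation that users should replace for production analyses.
One numerical note: $\tanh$ saturates to exactly 1.0 in double precision
around argument 19, so `sap_index()` nudges saturated values to the
nearest representable number inside $(-1, 1)$, preserving the index's
open-interval range at a deviation below $3 \times 10^{-16}$.

## Transporter completeness and density

An ABC importer is complete iff all three roles — substrate-binding
protein, transmembrane domain, nucleotide-binding domain — are matched
by at least one gene KO; a PTS system iff enzyme I, HPr and the
substrate-specific EII complex are matched. EI and HPr are genome-global
(one copy phosphorylates every EII), so they are declared once and
merged into every PTS definition; a single match satisfies them for all
systems. Only complete systems count as evidence that the corresponding
sugar is transportable, and ABC- and PTS-derived capability lists are
kept separate.

Transporter density is genes per Mb, presented rounded half-up to one
decimal (`round_half_up()`), because conventional reporting of 61.25
is 61.3 while base R's round-half-even would print 61.2. The raw
quotient is always retained alongside. `rank_against_reference()` places
a density in a reference distribution as the fraction of reference
genomes strictly below it, with width-5 histogram bins for distribution
plots.

## Gene panels

Panels are YAML-declared marker lists with three matching modes (KO id,
COG id, gene-symbol regex against product text — the last is inherently
annotation-tool-dependent and used only where no stable KO exists, e.g.
carnitine dehydrogenase genes). Markers sharing a `subsystem` label are
jointly required: the proU transporter needs proV + proW + proX, and a
genome carrying only ectB + ectC has an incomplete ectoine pathway —
partial is reported, never promoted to complete. Multi-COG complexes
(cbb3-type oxidase, bd-type oxidase) use `match_all`: the complex copy
number is the minimum per-subunit count, so losing one subunit removes
the complex. The osmoadaptation verdict is true iff at least one
transport or biosynthesis subsystem is complete; nitrate reduction to
ammonia requires all of napA/napB/nirB/nirD; oxidative and fermentation
panels are report-only, with the microaerobe flag derived from the
presence of at least one complete high-affinity oxidase.

## Machinery adjudication and neighborhood rescue

Secretion systems, pili and the flagellum are multi-gene machineries
whose detections arrive from two routes (a MacSyFinder-family scanner
and KEGG BRITE screens) plus, optionally, a homology-rescue table for
roles recovered by manual inspection of the cluster neighborhood.
Because running BLASTp is out of scope, rescue hits are an *input*; what
the package computes is the neighborhood itself:
`neighborhood_window()` returns the gene ranks within ten positions
(configurable) upstream and downstream of the detected cluster,
truncating at replicon ends for linear topologies and wrapping for
circular ones — matching how scanner topology is parameterized by
assembly level (chromosome-level assemblies circular, others linear).

The adjudication rule table: scanner-complete is status
`complete_scan_confirmed` (code `a`); scanner-incomplete but completed
by the BRITE union is `complete_brite_only` (`f`); completed only by
rescue is `complete_after_rescue` (`e` for TXSScan detections, `c` for
ConjScan); an unrescued machinery missing more than a third of its
mandatory roles is `highly_incomplete` (`b`); any other incomplete state
is `d`. Two choices here were open. First, the highly-incomplete cutoff
is nowhere defined numerically; missing fraction $> 1/3$ is consistent
with every worked case we can check (6/13 missing labelled highly
incomplete) and is configurable per model. Second, codes `c` and `e`
differ only by the detecting scanner as far as can be determined, so
both map to the same status with the scanner recorded; and ConjScan
detections never escalate to `b`, mirroring how degraded conjugative
T4SS clusters (13/17 roles missing) are conventionally coded as plain
incomplete. Rescue can only improve a status — this monotonicity is
asserted property-style in the tests.

## CAZyme polymer profiles

dbCAN-style family assignments collapse subfamilies (GH5_25 → GH5) and
tally per family. The polymer map (agar, cellulose, chitin, pectin,
xylan → GH family sets) is configuration with a shipped default; GH18
for chitin and GH5/GH9/GH6, GH2 for cellulose/xylan are anchored by the
primary analysis, the remaining families follow a standard curation of
polymer-active GH classes. Families present in the input but absent
from the map land in an explicit `unmapped` bucket. Zero-count polymers
are retained: "no agarases found" is a result, not missing data.

## Species delineation

A genome pair is conspecific when ANI exceeds 95% *and* dDDH exceeds
70% (both thresholds and the AND/OR combination configurable; strict
`>` by default because the convention is that values must *exceed* the
thresholds). Putative species are connected components of the pass
graph. Transitivity is assumed rather than enforced: a chained
component whose members are not all pairwise linked is still one
cluster, but it is flagged in `non_clique_clusters` and the full
per-pair pass/fail table is returned, so a user can see exactly which
pair broke the clique. Matrices are symmetrized by the arithmetic mean
of reciprocal entries on ingestion (dDDH tools can emit asymmetric
estimates and no convention is stated for reconciling them) and the
diagonal is forced to 100.

## The synthetic-data generator

`generate_annotation()` draws per-category gene counts Poisson with mean
= target normalized value × genome size, where the target sits beyond
the copiotroph (or oligotroph) landmark by 60% of the landmark
separation in the archetype's direction. Poisson is the simplest count
model consistent with gene-count data; negative-binomial overdispersion
is available via a `dispersion` parameter, off by default. The
`moderate` archetype places a configurable 65% of categories on the
copiotroph side — approximating a 21-of-33 split, the canonical
moderate-copiotroph profile. Panel genes are injected by marker toggles,
sugar/acid KO genes by count, and background genes (≈10% of them
unassigned) fill in ordinary categories. Each genome draws from an RNG
stream derived from (seed, genome id), so a fixed seed gives
byte-identical output and adding a genome to a cohort does not perturb
the others; generators also restore the caller's RNG state.

`generate_similarity()` plants species blocks: within-block ANI/dDDH
draws (default N(98.5, 0.1) / N(89, 0.6)) versus between-block draws
(N(82, 1.5) / N(25, 2)), clipped to [0, 100]. With the defaults, block
separation from both thresholds exceeds three standard deviations, so
exact recovery of the planted partition is the expected behaviour and is
asserted across 20 seeds.

What the generator does *not* emulate: correlated category counts
(real genomes covary phylogenetically), annotation-tool error modes
(mis-assigned KOs, split genes), operon structure beyond contiguous
machinery clusters, and any sequence-level signal. Passing the recovery
tests therefore demonstrates that the scoring and clustering machinery
is correct on data matching its statistical assumptions — it does not
validate annotation quality on real genomes, and the per-category
landmark comparison on real data additionally depends on the annotation
database version used.

## Problem sizes and reproducibility

The analysis scripts under `analysis/` simulate a seven-genome cohort
(~1,500 background genes per genome plus category-driven counts,
matching the gene-count scale of 4–5 Mb genomes); the test suite uses
smaller cohorts (150–300 background genes) and 20-replicate recovery
experiments, which keep the full suite under a minute while leaving the
Poisson noise clearly visible to the assertions.
`scripts/acceptance.R --seed N --out path` reruns the headline
quantities from scratch; all randomness flows from the one seed.
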