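test_that("the packaged landmark skeleton has the expected structure", {
  lm <- read_landmarks()
  expect_equal(nrow(lm), 33)
  expect_equal(sum(lm$direction == "+"), 14)
  expect_equal(sum(lm$direction == "-"), 19)
  expect_true(all(c("Q", "I", "N", "T", "V", "K") %in% lm$category))
  expect_true(all(c("COG1263", "COG0625", "COG3325") %in% lm$category))
  # values ship as placeholders for the user to fill
  expect_true(all(is.na(lm$oligotroph_value)))
})

test_that("normalization divides by genome size or ORF total", {
  counts <- matrix(c(48L, 430L), 1, 2, dimnames = list("g1", c("G", "T")))
  genomes <- genome_record("g1", size_mb = 4.8, total_orfs = 4300)
  per_mb <- normalize_category_counts(counts, genomes, "per_mb")
  expect_equal(unname(per_mb["g1", "G"]), 10)
  per_orf <- normalize_category_counts(counts, genomes, "per_orf")
  expect_equal(unname(per_orf["g1", "T"]), 0.1)

  # element-wise division oracle on a random matrix
  set.seed(41)
  m <- matrix(sample(0:500, 12), 3, 4,
    dimnames = list(c("a", "b", "c"), c("G", "T", "V", "K")))
  gs <- dplyr::bind_rows(
    genome_record("a", 4.1), genome_record("b", 5.2), genome_record("c", 3.3)
  )
  norm <- normalize_category_counts(m, gs)
  for (i in 1:3) for (j in 1:4) {
    expect_equal(norm[i, j], m[i, j] / gs$size_mb[i])
  }
  expect_error(
    normalize_category_counts(m, gs, "per_orf"),
    "denominator"
  )
})

test_that("trophic calls respect direction and treat ties as indeterminate", {
  expect_equal(call_trophic_category(3.0, "+", 1.0, 3.0), "indeterminate")
  expect_equal(call_trophic_category(4.2, "+", 1.0, 3.0), "copiotroph")
  expect_equal(call_trophic_category(0.5, "+", 1.0, 3.0), "oligotroph")
  expect_equal(call_trophic_category(1.0, "-", 5.0, 2.0), "copiotroph")
  expect_equal(call_trophic_category(6.0, "-", 5.0, 2.0), "oligotroph")

  # dense grid vs an independent rule re-implementation, both directions
  brute <- function(v, dir, olig, copi) {
    if (dir == "+") {
      if (v > copi) return("copiotroph")
      if (v < olig) return("oligotroph")
      return("indeterminate")
    }
    if (v < copi) return("copiotroph")
    if (v > olig) return("oligotroph")
    "indeterminate"
  }
  grid <- seq(-1, 7, by = 0.05)
  for (dir in c("+", "-")) {
    olig <- if (dir == "+") 1.0 else 5.0
    copi <- if (dir == "+") 3.0 else 2.0
    got <- call_trophic_category(grid, dir, olig, copi)
    want <- vapply(grid, brute, character(1), dir = dir, olig = olig, copi = copi)
    expect_identical(got, want)
  }
})

test_that("trophic summary maps tallies to overall labels", {
  s <- summarize_trophic(c(copiotroph = 21, oligotroph = 4, indeterminate = 8))
  expect_equal(s$overall_label, "moderate copiotroph")
  expect_equal(
    summarize_trophic(c(copiotroph = 33, oligotroph = 0, indeterminate = 0))$overall_label,
    "copiotroph"
  )
  expect_equal(
    summarize_trophic(c(copiotroph = 10, oligotroph = 10, indeterminate = 13))$overall_label,
    "indeterminate"
  )
  expect_equal(
    summarize_trophic(c(copiotroph = 4, oligotroph = 21, indeterminate = 8))$overall_label,
    "moderate oligotroph"
  )
  expect_equal(
    summarize_trophic(c(copiotroph = 0, oligotroph = 33, indeterminate = 0))$overall_label,
    "oligotroph"
  )
})

test_that("scoring a matrix emits per-genome calls plus the mean profile", {
  lm <- synthetic_landmarks()
  m <- matrix(20, nrow = 2, ncol = nrow(lm),
    dimnames = list(c("g1", "g2"), lm$category))
  calls <- score_trophic(m, lm)
  expect_setequal(unique(calls$genome_id), c("g1", "g2", "mean-of-genomes"))
  # value 20/Mb is beyond the copiotroph landmark for "+" (15) and beyond
  # the oligotroph landmark for "-" (15), so calls split by direction
  g1 <- calls[calls$genome_id == "g1", ]
  expect_true(all(g1$call[g1$direction == "+"] == "copiotroph"))
  expect_true(all(g1$call[g1$direction == "-"] == "oligotroph"))
})

test_that("SAP follows tanh(sS + aA) with its published coefficients", {
  expect_equal(sap_index(0, 0), 0)

  # independent high-precision evaluation via the exponential form
  S <- 0.01
  A <- 0.01
  x <- 60.76 * S - 20.21 * A
  expected <- (exp(2 * x) - 1) / (exp(2 * x) + 1)
  expect_equal(sap_index(S, A), expected, tolerance = 1e-12)

  # saturation: S = 1, A = 0 approaches but never reaches 1
  top <- sap_index(1, 0)
  expect_gt(top, 0.999)
  expect_lt(top, 1)
})

test_that("SAP is monotone in S and -A and bounded on a grid", {
  S <- seq(0, 0.05, length.out = 60)
  A <- seq(0, 0.05, length.out = 60)
  grid <- outer(S, A, sap_index)
  expect_true(all(abs(grid) < 1))
  # increasing S (rows) strictly increases sap; increasing A decreases it
  expect_true(all(diff(grid) > 0))
  expect_true(all(t(diff(t(grid))) < 0))
})

test_that("compute_sap counts configured KOs relative to the ORF total", {
  cfg <- read_sap_config()
  kos <- c(cfg$sugar_kos[1], cfg$sugar_kos[2], cfg$acid_kos[1], NA, NA)
  tab <- ko_ann("gS", kos)
  res <- compute_sap(tab, cfg = cfg)
  expect_equal(res$S, 2 / 5)
  expect_equal(res$A, 1 / 5)
  expect_equal(res$sap, tanh(cfg$s * 2 / 5 + cfg$a * 1 / 5))
  # explicit genome record overrides the denominator
  rec <- genome_record("gS", 4, total_orfs = 10)
  expect_equal(compute_sap(tab, rec, cfg)$S, 0.2)
})

test_that("landmark counting handles general letters and specific COG ids", {
  lm <- synthetic_landmarks()
  tab <- ann_fixture("gL",
    cats = list("Q", "Q", "V", character(0)),
    cogids = list(character(0), character(0), character(0), "COG1263")
  )
  counts <- landmark_counts(list(tab), lm)
  expect_equal(unname(counts["gL", "Q"]), 2L)
  expect_equal(unname(counts["gL", "V"]), 1L)
  expect_equal(unname(counts["gL", "COG1263"]), 1L)
  expect_equal(unname(counts["gL", "COG3325"]), 0L)
})
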