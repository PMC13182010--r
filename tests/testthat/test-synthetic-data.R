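test_that("generators are deterministic under a fixed seed", {
  spec <- synthetic_genome_spec("det", archetype = "copiotroph", seed = 9,
    n_background_genes = 300L, sugar_genes = 5, acid_genes = 5,
    panel_toggles = list(napA = 0.5, proV = 1))
  a <- generate_annotation(spec)
  b <- generate_annotation(spec)
  expect_identical(a, b)

  cs <- synthetic_cohort_spec(blocks = list(c("x", "y"), "z"), seed = 3)
  expect_identical(generate_similarity(cs), generate_similarity(cs))

  cz <- synthetic_genome_spec("det", seed = 9,
    cazyme_profile = c(GH18 = 12, GH5 = 1))
  expect_identical(generate_cazyme_counts(cz), generate_cazyme_counts(cz))
})

test_that("generation does not disturb the caller's RNG state", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generate_annotation(
    synthetic_genome_spec("rng", seed = 5, n_background_genes = 50L)
  ))
  expect_identical(runif(1), before)
})

test_that("planted archetypes are recovered by the trophic scorer", {
  lm <- synthetic_landmarks()
  run <- function(archetype, seed) {
    spec <- synthetic_genome_spec(paste0("s", seed), archetype = archetype,
      seed = seed, n_background_genes = 200L)
    ann <- generate_annotation(spec, lm)
    norm <- normalize_category_counts(
      landmark_counts(list(ann), lm),
      synthetic_genome_record(spec, ann)
    )
    calls <- score_trophic(norm, lm, include_mean = FALSE)
    summarize_trophic(calls)
  }
  cop <- run("copiotroph", 1)
  expect_gte(cop$n_copiotroph / 33, 0.9)
  oli <- run("oligotroph", 2)
  expect_gte(oli$n_oligotroph / 33, 0.9)
  mod <- run("moderate", 3)
  expect_equal(mod$overall_label, "moderate copiotroph")
})

test_that("panel toggles control marker injection", {
  spec_off <- synthetic_genome_spec("off", seed = 4, n_background_genes = 150L)
  ann_off <- generate_annotation(spec_off)
  panels <- read_panels()
  for (p in panels[c("nitrate_reduction", "chemotaxis", "osmoadaptation")]) {
    v <- screen_panel(ann_off, p)$verdict
    expect_false(isTRUE(v))
  }
  spec_on <- synthetic_genome_spec("on", seed = 4, n_background_genes = 150L,
    panel_toggles = list(napA = 1, napB = 1, nirB = 1, nirD = 1))
  ann_on <- generate_annotation(spec_on)
  expect_true(screen_panel(ann_on, panels$nitrate_reduction)$verdict)
})

test_that("similarity blocks come out exactly under zero variance", {
  cs <- synthetic_cohort_spec(
    blocks = list(c("a", "b", "c"), c("d", "e")),
    within = list(ani_mean = 98.5, ani_sd = 0, dddh_mean = 89, dddh_sd = 0),
    between = list(ani_mean = 82, ani_sd = 0, dddh_mean = 25, dddh_sd = 0),
    seed = 7
  )
  sm <- generate_similarity(cs)
  expect_equal(sm$ani["a", "b"], 98.5)
  expect_equal(sm$ani["a", "d"], 82)
  expect_equal(sm$dddh["d", "e"], 89)
  expect_equal(unname(diag(sm$ani)), rep(100, 5))

  single <- generate_similarity(synthetic_cohort_spec(blocks = list("solo")))
  expect_equal(dim(single$ani), c(1, 1))
  expect_equal(single$ani[1, 1], 100)
})

test_that("planted species blocks are recovered by delineation", {
  cs <- synthetic_cohort_spec(blocks = list(c("a", "b", "c"), "d", "e"), seed = 11)
  dl <- delineate(generate_similarity(cs))
  expect_setequal(cluster_members(dl, "a"), c("a", "b", "c"))
  expect_equal(length(unique(dl$clusters$cluster)), 3)
})

test_that("machinery scenarios translate into the expected adjudications", {
  models <- read_machinery_models()
  # nothing missing -> complete (code a needs BRITE confirmation; scanner
  # alone is also complete_scan_confirmed)
  s0 <- synthetic_genome_spec("m0", machinery_scenarios = list(T2SS = character(0)))
  d0 <- generate_machinery_detections(s0, models)
  expect_equal(adjudicate(d0$detections, models$T2SS)$provenance_code, "a")

  # 6 of 13 roles missing, no rescue -> highly incomplete
  missing6 <- models$T2SS$mandatory_genes[1:6]
  s1 <- synthetic_genome_spec("m1", machinery_scenarios = list(T2SS = missing6))
  d1 <- generate_machinery_detections(s1, models)
  expect_equal(adjudicate(d1$detections, models$T2SS)$status, "highly_incomplete")

  # one missing role present in the rescue table -> complete_after_rescue
  s2 <- synthetic_genome_spec("m2",
    machinery_scenarios = list(T2SS = "gspC"))
  d2 <- generate_machinery_detections(s2, models, rescue = list(T2SS = "gspC"))
  st <- adjudicate(d2$detections, models$T2SS, rescue_hits = d2$rescue_hits$T2SS)
  expect_equal(st$status, "complete_after_rescue")

  expect_error(
    generate_machinery_detections(
      synthetic_genome_spec("m3", machinery_scenarios = list(NOPE = "x")), models
    ),
    "unknown model"
  )
})

test_that("adding a genome to a cohort leaves other genomes' draws unchanged", {
  mk <- function(id) {
    synthetic_genome_spec(id, archetype = "moderate", seed = 99,
      n_background_genes = 100L)
  }
  a_alone <- generate_annotation(mk("gA"))
  invisible(generate_annotation(mk("gB")))
  a_again <- generate_annotation(mk("gA"))
  expect_identical(a_alone, a_again)
})

test_that("spec validation rejects bad inputs", {
  expect_error(
    synthetic_genome_spec("x", archetype = "custom"),
    "custom_means"
  )
  expect_error(
    synthetic_genome_spec("x", panel_toggles = list(napA = 1.5)),
    "\\[0, 1\\]"
  )
  expect_error(
    synthetic_cohort_spec(blocks = list(c("a", "b"), "a")),
    "disjoint"
  )
  expect_error(
    synthetic_cohort_spec(
      blocks = list("a", "b"),
      within = list(ani_mean = 80, ani_sd = 1, dddh_mean = 80, dddh_sd = 1)
    ),
    "exceed"
  )
})
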