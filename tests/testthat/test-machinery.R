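models <- read_machinery_models()

test_that("packaged models anchor the printed role totals", {
  expect_equal(length(models$T2SS$mandatory_genes), 13)
  expect_equal(length(models$T4SS_G$mandatory_genes), 17)
  expect_equal(length(models$T6SS$mandatory_genes), 13)
})

test_that("neighborhood windows truncate on linear and wrap on circular replicons", {
  expect_equal(
    neighborhood_window(100:110, n_genes = 5000, window = 10),
    c(90:99, 111:120)
  )
  # cluster at the replicon start: upstream side empty
  expect_equal(
    neighborhood_window(0:5, n_genes = 5000, window = 10),
    6:15
  )
  # circular: wraps through rank 0
  got <- neighborhood_window(c(48, 49), n_genes = 50, window = 10,
    topology = "circular")
  want <- sort(setdiff(unique(c((48 - 10):(48 - 1), (49 + 1):(49 + 10)) %% 50),
    c(48, 49)))
  expect_equal(got, want)
  expect_true(all(0:9 %in% got))
  expect_equal(neighborhood_window(5, 10, window = 0), integer(0))
  expect_error(neighborhood_window(integer(0), 10), "empty cluster")
})

test_that("adjudication reproduces the provenance code scheme", {
  t2 <- models$T2SS
  all13 <- t2$mandatory_genes
  # scanner complete, BRITE confirms -> a
  st <- adjudicate(list(
    mk_det(all13, "txsscan", model = "T2SS"),
    mk_det(all13, "brite", model = "T2SS")
  ), t2)
  expect_equal(st$status, "complete_scan_confirmed")
  expect_equal(st$provenance_code, "a")

  # 6 of 13 missing, no rescue -> highly incomplete (b)
  st_b <- adjudicate(list(mk_det(all13[1:7], "txsscan", model = "T2SS")), t2)
  expect_equal(st_b$status, "highly_incomplete")
  expect_equal(st_b$provenance_code, "b")
  expect_equal(st_b$missing_fraction, 6 / 13)

  # scanner incomplete but BRITE complete -> f
  st_f <- adjudicate(list(
    mk_det(all13[1:10], "txsscan", model = "T2SS"),
    mk_det(all13, "brite", model = "T2SS")
  ), t2)
  expect_equal(st_f$status, "complete_brite_only")
  expect_equal(st_f$provenance_code, "f")

  # scanner incomplete, rescued -> e (TXSScan) / c (ConjScan)
  st_e <- adjudicate(list(mk_det(all13[-1], "txsscan", model = "T2SS")), t2,
    rescue_hits = all13[1])
  expect_equal(st_e$status, "complete_after_rescue")
  expect_equal(st_e$provenance_code, "e")
  t4 <- models$T4SS_G
  st_c <- adjudicate(
    list(mk_det(t4$mandatory_genes[-1], "conjscan", model = "T4SS_G")), t4,
    rescue_hits = t4$mandatory_genes[1]
  )
  expect_equal(st_c$provenance_code, "c")

  # ConjScan detection with most roles missing stays code d, not b
  st_d <- adjudicate(
    list(mk_det(t4$mandatory_genes[1:4], "conjscan", model = "T4SS_G")), t4
  )
  expect_equal(st_d$status, "incomplete")
  expect_equal(st_d$provenance_code, "d")

  expect_error(
    adjudicate(list(mk_det("r1", model = "T2SS")), t2),
    "not in model"
  )
  expect_error(
    adjudicate(list(mk_det(all13, model = "T2SS")), t2, rescue_hits = "bogus"),
    "rescue roles"
  )
})

test_that("adjudication equals an exhaustive rule-table oracle on toy models", {
  # independent transcription of the adjudication rule table
  oracle <- function(scan_roles, brite_roles, rescue, mandatory, thr, scanner) {
    scan_complete <- setequal(scan_roles, mandatory)
    brite_complete <- length(brite_roles) && setequal(brite_roles, mandatory)
    u <- union(scan_roles, brite_roles)
    missing_pre <- setdiff(mandatory, u)
    missing_post <- setdiff(missing_pre, rescue)
    frac <- length(missing_post) / length(mandatory)
    if (scan_complete) {
      c("complete_scan_confirmed", "a")
    } else if (!length(missing_pre) || brite_complete) {
      c("complete_brite_only", "f")
    } else if (!length(missing_post)) {
      c("complete_after_rescue", if (scanner == "conjscan") "c" else "e")
    } else if (frac > thr && scanner != "conjscan") {
      c("highly_incomplete", "b")
    } else {
      c("incomplete", "d")
    }
  }
  model <- toy_model(5)
  roles <- model$mandatory_genes
  for (scanner in c("txsscan", "conjscan")) {
    for (mask in 0:31) {
      scan_roles <- roles[bitwAnd(mask, 2^(0:4)) > 0]
      for (rescue_first_missing in c(FALSE, TRUE)) {
        missing <- setdiff(roles, scan_roles)
        rescue <- if (rescue_first_missing && length(missing)) missing[1] else character(0)
        st <- adjudicate(list(mk_det(scan_roles, scanner)), model,
          rescue_hits = rescue)
        want <- oracle(scan_roles, character(0), rescue, roles, 1 / 3, scanner)
        expect_equal(c(st$status, st$provenance_code), want,
          info = sprintf("scanner=%s mask=%d rescue=%s", scanner, mask,
            rescue_first_missing))
      }
    }
  }
})

test_that("rescue only ever improves a status", {
  model <- toy_model(6)
  roles <- model$mandatory_genes
  rank_of <- c(
    absent = 0, highly_incomplete = 1, incomplete = 2,
    complete_after_rescue = 3, complete_brite_only = 3,
    complete_scan_confirmed = 4
  )
  set.seed(71)
  for (i in 1:30) {
    scan_roles <- sample(roles, sample(0:6, 1))
    missing <- setdiff(roles, scan_roles)
    rescue <- if (length(missing)) sample(missing, sample(length(missing), 1)) else character(0)
    st0 <- adjudicate(list(mk_det(scan_roles)), model)
    st1 <- adjudicate(list(mk_det(scan_roles)), model, rescue_hits = rescue)
    expect_gte(rank_of[st1$status], rank_of[st0$status])
  }
})

test_that("adjudication is stable when re-fed its own detected roles", {
  model <- toy_model(4)
  st <- adjudicate(list(mk_det(model$mandatory_genes[-1]), mk_det(model$mandatory_genes[1], "brite")), model)
  again <- adjudicate(
    list(
      mk_det(st$present_roles[st$present_roles %in% model$mandatory_genes][1:3]),
      mk_det(st$present_roles, "brite")
    ),
    model
  )
  expect_equal(again$missing_roles, st$missing_roles)
  expect_true(startsWith(again$status, "complete"))
})

test_that("the machinery summary matrix mirrors copies and absences", {
  t1 <- models$T1SS
  mk_complete <- function(g, model) {
    adjudicate(list(
      mk_det(model$mandatory_genes, genome = g, model = model$model_id),
      mk_det(model$mandatory_genes, "brite", genome = g, model = model$model_id)
    ), model)
  }
  statuses <- c(
    lapply(c("gA", "gB", "gC", "gD"), mk_complete, model = models$T6SS),
    list(mk_complete("gA", t1), mk_complete("gA", t1)) # two T1SS copies
  )
  summ <- summarize_machineries(statuses)
  t6row <- summ$matrix[summ$matrix$model_id == "T6SS", -1]
  expect_equal(sum(t6row != "0"), 4)
  expect_equal(summ$matrix[["gA"]][summ$matrix$model_id == "T1SS"], "2aa")
  expect_equal(summ$matrix[["gB"]][summ$matrix$model_id == "T1SS"], "0")
})
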