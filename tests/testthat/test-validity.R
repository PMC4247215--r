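tab_ref <- confusionTable(tp = 23, fp = 32, fn = 5, tn = 81)

test_that("confusion counts cross-classify labels correctly", {
  act <- c(rep("poor", 3), rep("satisfactory", 2))
  prd <- c(rep("at_risk", 3), rep("not_at_risk", 2))
  expect_equal(as.integer(confusion(act, prd)), c(3, 0, 0, 2))
  none <- confusion(act, rep("not_at_risk", 5))
  expect_equal(unname(none["tp"] + none["fp"]), 0L)
  expect_error(confusion(act, prd[1:3]), "equal length")
  expect_error(confusionTable(-1, 0, 0, 5), "nonnegative")
})

test_that("wilson interval matches the score-test inversion in prop.test", {
  for (case in list(c(23, 28), c(81, 113), c(23, 55), c(81, 86), c(1, 10), c(10, 10))) {
    got <- wilsonCi(case[1], case[2])
    ref <- prop.test(case[1], case[2], correct = FALSE)$conf.int
    expect_equal(unname(got), as.numeric(ref), tolerance = 1e-10)
  }
  expect_equal(unname(wilsonCi(0, 20)["lo"]), 0)
  expect_equal(unname(wilsonCi(20, 20)["hi"]), 1)
  expect_error(wilsonCi(3, 0), "zero trials")
})

test_that("wilson intervals stay in [0,1] and tighten with n", {
  set.seed(8)
  prev_width <- Inf
  for (n in c(10, 40, 160, 640)) {
    ci <- wilsonCi(round(0.3 * n), n)
    expect_gte(ci["lo"], 0)
    expect_lte(ci["hi"], 1)
    width <- diff(ci)
    expect_lt(width, prev_width)
    prev_width <- width
  }
})

test_that("wilson coverage is near nominal at n = 28", {
  set.seed(123)
  p <- 0.8
  hits <- 0
  B <- 2000
  for (b in seq_len(B)) {
    x <- rbinom(1, 28, p)
    ci <- wilsonCi(x, 28)
    hits <- hits + (ci["lo"] <= p && p <= ci["hi"])
  }
  expect_gte(hits / B, 0.93)
})

test_that("clopper-pearson fallback matches binom.test", {
  for (case in list(c(23, 28), c(0, 15), c(7, 9))) {
    got <- clopperPearsonCi(case[1], case[2])
    ref <- binom.test(case[1], case[2])$conf.int
    expect_equal(unname(got), as.numeric(ref), tolerance = 1e-10)
  }
})

test_that("likelihood ratios and their log-method intervals are correct", {
  lr <- likelihoodRatios(tab_ref)
  expect_equal(lr$lr_pos$estimate, (23 / 28) / (1 - 81 / 113))
  expect_equal(round(lr$lr_pos$estimate, 2), 2.90)
  expect_equal(round(lr$lr_pos$lo, 2), 2.06)
  expect_equal(round(lr$lr_pos$hi, 2), 4.08)
  expect_equal(round(lr$lr_neg$estimate, 2), 0.25)
  expect_equal(round(lr$lr_neg$lo, 2), 0.11)
  # an uninformative test has both ratios at 1
  lr_flat <- likelihoodRatios(confusionTable(5, 5, 5, 5))
  expect_equal(lr_flat$lr_pos$estimate, 1)
  expect_equal(lr_flat$lr_neg$estimate, 1)
  # degenerate margins flag rather than fabricate intervals
  lr_deg <- likelihoodRatios(confusionTable(5, 0, 0, 5))
  expect_false(lr_deg$lr_pos$defined)
  expect_false(lr_deg$lr_neg$defined)
})

test_that("lr intervals widen as any supporting cell count shrinks", {
  base <- likelihoodRatios(confusionTable(40, 40, 10, 110))
  shrunk <- likelihoodRatios(confusionTable(8, 8, 2, 22)) # same rates, 1/5 n
  expect_gt(
    shrunk$lr_pos$hi / shrunk$lr_pos$lo,
    base$lr_pos$hi / base$lr_pos$lo
  )
  expect_gt(
    shrunk$lr_neg$hi / shrunk$lr_neg$lo,
    base$lr_neg$hi / base$lr_neg$lo
  )
})

test_that("validity report reproduces all panel identities", {
  rep <- validityReport(tab_ref)
  expect_equal(rep["sensitivity", "estimate"], 23 / 28)
  expect_equal(rep["specificity", "estimate"], 81 / 113)
  expect_equal(rep["ppv", "estimate"], 23 / 55)
  expect_equal(rep["npv", "estimate"], 81 / 86)
  expect_equal(
    rep["auc", "estimate"],
    (rep["sensitivity", "estimate"] + rep["specificity", "estimate"]) / 2
  )
  # algebraic identities hold for arbitrary tables
  set.seed(99)
  for (i in 1:10) {
    cells <- rmultinom(1, 200, c(0.15, 0.2, 0.05, 0.6))
    t <- confusionTable(cells[1], cells[2], cells[3], cells[4])
    r <- validityReport(t)
    se <- r["sensitivity", "estimate"]
    sp <- r["specificity", "estimate"]
    if (sp < 1 && sp > 0) {
      expect_equal(r["lr_pos", "estimate"], se / (1 - sp))
      expect_equal(r["lr_neg", "estimate"], (1 - se) / sp)
    }
    # prevalence identity: flagged fraction decomposes exactly
    prev <- (t["tp"] + t["fn"]) / sum(t)
    flagged <- (t["tp"] + t["fp"]) / sum(t)
    expect_equal(unname(se * prev + (1 - sp) * (1 - prev)), unname(flagged))
    # Bayes consistency for the PPV
    expect_equal(
      unname(r["ppv", "estimate"]),
      unname(se * prev / (se * prev + (1 - sp) * (1 - prev)))
    )
    expect_true(all(r$lo <= r$estimate + 1e-12 & r$estimate <= r$hi + 1e-12))
  }
})

test_that("perfect and degenerate tables are handled explicitly", {
  perfect <- validityReport(confusionTable(20, 0, 0, 80))
  expect_equal(perfect["sensitivity", "estimate"], 1)
  expect_equal(perfect["specificity", "estimate"], 1)
  expect_equal(perfect["auc", "estimate"], 1)
  no_pos <- validityReport(confusionTable(0, 10, 0, 90))
  expect_true(is.na(no_pos["sensitivity", "estimate"]))
  expect_false(no_pos["sensitivity", "defined"])
  expect_error(validityReport(confusionTable(0, 0, 0, 0)), "empty")
})

test_that("reports serialize to the JSON panel", {
  tmp <- withr::local_tempfile(fileext = ".json")
  writeReport(validityReport(tab_ref), tmp)
  doc <- jsonlite::read_json(tmp)
  expect_equal(doc$table$tp, 23)
  metrics <- vapply(doc$metrics, `[[`, character(1), "metric")
  expect_equal(
    metrics,
    c("sensitivity", "specificity", "ppv", "npv", "lr_pos", "lr_neg", "auc")
  )
})

test_that("cohort accounting reproduces the flow proportions", {
  acc <- cohortAccounting(
    assessed = 511, eligible = 220, interviewed = 197,
    unknown_eligibility = 77, excluded_post_interview = 44, completed = 141
  )
  expect_equal(round(acc$eligibility, 2), 0.43)
  expect_equal(round(100 * acc$participation, 1), 77.8)
  expect_equal(round(100 * acc$follow_up, 1), 92.2)
  zero <- cohortAccounting(0, 0, 0, 0, 0, 0)
  expect_false(any(zero$defined))
  expect_error(cohortAccounting(-1, 0, 0, 0, 0, 0), "nonnegative")
})
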