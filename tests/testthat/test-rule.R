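test_that("rule construction enforces totality and forward jumps", {
  q_ok <- list(
    list(item = "F1", branches = list(`0` = "q2", `1` = "q2", `2` = "at_risk", `3` = "at_risk", `4` = "at_risk")),
    list(item = "F2", branches = list(`0` = "not_at_risk", `1` = "not_at_risk", `2` = "not_at_risk", `3` = "at_risk", `4` = "at_risk"))
  )
  rule <- predictionRule(q_ok)
  expect_equal(nQuestions(rule), 2)
  expect_equal(ruleItems(rule), c("F1", "F2"))

  q_back <- q_ok
  q_back[[2]]$branches$`0` <- "q1" # backward jump
  expect_error(predictionRule(q_back), "later question")
  q_part <- q_ok
  q_part[[1]]$branches$`4` <- NULL
  expect_error(predictionRule(q_part), "every answer level")
  q_bad <- q_ok
  q_bad[[1]]$branches$`2` <- "maybe"
  expect_error(predictionRule(q_bad), "unknown action")
})

test_that("flattened trees classify exactly like the source tree", {
  # exhaustive sweep over all 5^d combinations of the tested items
  for (seed in c(31, 32, 33, 34)) {
    d <- random_labelled_data(80, n_pred = 3, seed = seed, noise = 0.25)
    tree <- growTree(
      d$data, d$outcome, names(d$data),
      treeControl(min_parent = 8, min_child = 4, max_depth = 3, min_decrease = 0)
    )
    rule <- flattenTree(tree)
    items <- treeItems(tree)
    grid <- expand.grid(rep(list(0:4), length(items)))
    names(grid) <- items
    # untested predictors can hold any value; fix them at 0
    for (p in setdiff(names(d$data), items)) grid[[p]] <- 0
    expect_identical(applyRule(rule, grid), predict(tree, grid))
  }
})

test_that("flattening a repeated-split tree asks about the item twice", {
  df <- data.frame(X = c(0, 1, 2, 3, 4, 4, 2, 1))
  y <- c("satisfactory", "satisfactory", "poor", "poor", "satisfactory", "satisfactory", "poor", "satisfactory")
  tree <- growTree(df, y, "X", treeControl(min_parent = 2, min_child = 1, max_depth = 2, min_decrease = 0))
  rule <- flattenTree(tree)
  if (!is.null(tree$root$split) && !is.null(tree$root$left$split)) {
    expect_gt(nQuestions(rule), length(ruleItems(rule)))
    expect_equal(ruleItems(rule), "X")
  }
  expect_identical(applyRule(rule, df), predict(tree, df))
})

test_that("single-leaf trees flatten to a constant rule", {
  df <- data.frame(X = c(1, 2, 3, 4))
  tree <- growTree(df, rep("satisfactory", 4), "X",
    treeControl(min_parent = 2, min_child = 1, max_depth = 2, min_decrease = 0))
  rule <- flattenTree(tree)
  expect_equal(as.character(applyRule(rule, df)), rep("not_at_risk", 4))
})

test_that("the bundled default rule honours its anchor patterns", {
  rule <- defaultRule()
  expect_equal(length(ruleItems(rule)), 5)
  expect_setequal(ruleItems(rule), c("F10", "F11", "F15", "F17", "S1"))
  # the toilet item is asked at two different points
  expect_gt(nQuestions(rule), 5)
  all_none <- as.data.frame(as.list(make_items(0)))
  all_extreme <- as.data.frame(as.list(make_items(4)))
  expect_equal(as.character(applyRule(rule, all_none)), "not_at_risk")
  expect_equal(as.character(applyRule(rule, all_extreme)), "at_risk")
})

test_that("applying a rule to incomplete answers is an error", {
  rule <- defaultRule()
  probe <- as.data.frame(as.list(make_items(1)))
  probe$F11 <- NA
  expect_error(applyRule(rule, probe), "missing")
  probe$F11 <- 7
  expect_error(applyRule(rule, probe), "0..4")
})

test_that("rule selection is sensitivity-first above the specificity floor", {
  mk <- function(nq, se, sp) {
    qs <- lapply(seq_len(nq), function(k) {
      acts <- if (k == nq) {
        list(`0` = "not_at_risk", `1` = "not_at_risk", `2` = "at_risk", `3` = "at_risk", `4` = "at_risk")
      } else {
        list(`0` = paste0("q", k + 1), `1` = paste0("q", k + 1), `2` = paste0("q", k + 1), `3` = "at_risk", `4` = "at_risk")
      }
      list(item = paste0("F", k), branches = acts)
    })
    list(rule = predictionRule(qs), report = list(sensitivity = se, specificity = sp))
  }
  # high-sensitivity candidate below the floor loses to the balanced one
  sel <- selectRule(list(mk(3, 0.90, 0.50), mk(5, 0.82, 0.72)), min_specificity = 0.70)
  expect_equal(attr(sel, "candidate"), 2)
  # simplicity tie-break: identical validity, fewer questions wins
  sel2 <- selectRule(list(mk(4, 0.8, 0.75), mk(2, 0.8, 0.75)), min_specificity = 0.70)
  expect_equal(attr(sel2, "candidate"), 2)
  # ordering invariance up to the documented final tie-break
  sel3 <- selectRule(list(mk(2, 0.8, 0.75), mk(4, 0.8, 0.75)), min_specificity = 0.70)
  expect_equal(nQuestions(sel3), nQuestions(sel2))
  expect_error(
    selectRule(list(mk(3, 0.9, 0.5)), min_specificity = 0.70),
    "specificity floor"
  )
  expect_error(selectRule(list()), "empty")
})

test_that("rules round-trip through the JSON schema", {
  rule <- defaultRule()
  tmp <- withr::local_tempfile(fileext = ".json")
  writeRule(rule, tmp)
  back <- readRule(tmp)
  expect_equal(back$questions, rule$questions)
  set.seed(5)
  probes <- make_item_df(50)
  for (col in names(probes)) probes[[col]] <- sample(0:4, 50, replace = TRUE)
  expect_identical(applyRule(back, probes), applyRule(rule, probes))
})

test_that("the questionnaire rendering lists every question", {
  txt <- format(defaultRule())
  expect_true(any(grepl("Q1\\.", txt)))
  expect_true(any(grepl("toilet", txt)))
  expect_true(any(grepl("AT RISK", txt)))
})
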