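eq_weights <- treeControl(
  min_parent = 2, min_child = 1, max_depth = 2, min_decrease = 0
)

test_that("gini impurity matches direct arithmetic", {
  expect_equal(gini(c(0, 113)), 0)
  expect_equal(gini(c(10, 10)), 0.5)
  expect_equal(gini(c(28, 113)), 1 - (28 / 141)^2 - (113 / 141)^2)
  expect_equal(round(gini(c(28, 113)), 4), 0.3183)
  expect_error(gini(c(0, 0)), "undefined")
  expect_error(gini(c(-1, 5)), "nonnegative")
})

test_that("bestSplit finds the perfect separator and respects purity", {
  df <- data.frame(X = c(0, 0, 4, 4))
  y <- c("satisfactory", "satisfactory", "poor", "poor")
  s <- bestSplit(df, y, "X", eq_weights)
  expect_equal(s$predictor, "X")
  expect_equal(s$threshold, 0)
  expect_equal(s$decrease, 0.5)
  # already pure -> no split
  expect_null(bestSplit(df, rep("poor", 4), "X", eq_weights))
  expect_error(bestSplit(df, y, character(0)), "empty predictor")
})

test_that("bestSplit agrees with brute-force enumeration over all pairs", {
  for (seed in 1:25) {
    d <- random_labelled_data(n = 6 + (seed %% 20), n_pred = 3, seed = seed, noise = 0.3)
    got <- bestSplit(d$data, d$outcome, names(d$data), eq_weights)
    want <- oracle_best_split(as.matrix(d$data), d$y01)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$predictor, names(d$data)[want$j])
      expect_equal(got$threshold, want$t)
      expect_equal(got$decrease, want$d, tolerance = 1e-10)
    }
  }
})

test_that("grow/predict reproduce the naive level-wise enumeration oracle", {
  for (seed in 1:40) {
    d <- random_labelled_data(n = 10 + (seed %% 21), n_pred = 3, seed = 100 + seed, noise = 0.15)
    tree <- growTree(d$data, d$outcome, names(d$data), eq_weights)
    got <- predict(tree, d$data) == "at_risk"
    want <- oracle_tree_predict(as.matrix(d$data), d$y01) == 1L
    expect_identical(unname(got), want)
  }
})

test_that("stopping rules produce the documented degenerate trees", {
  d <- random_labelled_data(30, seed = 5, noise = 0.2)
  # min_decrease above any achievable gain: single majority leaf
  ctl <- treeControl(min_parent = 2, min_child = 1, max_depth = 3, min_decrease = 0.6)
  tree <- growTree(d$data, d$outcome, names(d$data), ctl)
  expect_null(tree$root$split)
  expect_equal(
    tree$root$class,
    if (sum(d$y01) >= length(d$y01) - sum(d$y01)) "at_risk" else "not_at_risk"
  )
  # perfectly separable toy data: depth-1 tree with perfect training accuracy
  df <- data.frame(A = c(0, 1, 3, 4, 0, 4), B = c(2, 2, 2, 2, 2, 2))
  y <- ifelse(df$A <= 1, "satisfactory", "poor")
  t2 <- growTree(df, y, c("A", "B"), treeControl(min_parent = 2, min_child = 1, max_depth = 1, min_decrease = 0))
  expect_equal(unname(predict(t2, df) == "at_risk"), y == "poor")
})

test_that("counts are conserved at every split and decreases are nonnegative", {
  d <- random_labelled_data(120, seed = 9, noise = 0.25)
  tree <- growTree(d$data, d$outcome, names(d$data), treeControl(min_parent = 10, min_child = 5, max_depth = 4, min_decrease = 0))
  check <- function(node) {
    if (is.null(node$split)) {
      return(invisible())
    }
    expect_gte(node$split$decrease, 0)
    expect_equal(node$left$counts + node$right$counts, node$counts)
    check(node$left)
    check(node$right)
  }
  check(tree$root)
})

test_that("records at a boundary value route to the left child", {
  df <- data.frame(X = c(0, 0, 1, 4, 4, 4))
  y <- c("satisfactory", "satisfactory", "satisfactory", "poor", "poor", "poor")
  tree <- growTree(df, y, "X", treeControl(min_parent = 2, min_child = 1, max_depth = 1, min_decrease = 0))
  t <- tree$root$split$threshold
  at_boundary <- predict(tree, data.frame(X = t))
  expect_equal(as.character(at_boundary), tree$root$left$class)
})

test_that("missing tested predictors are unclassifiable, not guessed", {
  d <- random_labelled_data(40, seed = 3, noise = 0.1)
  tree <- growTree(d$data, d$outcome, names(d$data), treeControl(min_parent = 5, min_child = 2, max_depth = 2, min_decrease = 0))
  probe <- d$data[1, ]
  probe[[tree$root$split$predictor]] <- NA
  expect_error(predict(tree, probe), "cannot be classified")
})

test_that("invalid predictor values are rejected with row identification", {
  d <- random_labelled_data(20, seed = 4)
  d$data$X1[7] <- 9
  expect_error(
    growTree(d$data, d$outcome, names(d$data), eq_weights),
    "'X1'.*row\\(s\\) 7"
  )
})

test_that("raising the poor-class weight never decreases training sensitivity", {
  for (seed in c(21, 22, 23)) {
    d <- random_labelled_data(150, seed = seed, noise = 0.3)
    sens <- sapply(c(1, 2, 4, 8), function(w) {
      ctl <- treeControl(
        min_parent = 10, min_child = 5, max_depth = 3, min_decrease = 0,
        class_weights = c(poor = w, satisfactory = 1)
      )
      pred <- predict(growTree(d$data, d$outcome, names(d$data), ctl), d$data)
      tab <- confusion(d$outcome, pred)
      tab["tp"] / (tab["tp"] + tab["fn"])
    })
    expect_true(all(diff(sens) >= -1e-12))
  }
})

test_that("training predictions agree with rpart configured identically", {
  skip_if_not_installed("rpart")
  agree <- 0
  total <- 0
  for (seed in 1:10) {
    d <- random_labelled_data(200, n_pred = 3, seed = 300 + seed, noise = 0.2)
    ctl <- treeControl(min_parent = 20, min_child = 10, max_depth = 3, min_decrease = 1e-9)
    mine <- predict(growTree(d$data, d$outcome, names(d$data), ctl), d$data)
    rp <- rpart::rpart(
      outcome ~ ., data = cbind(d$data, outcome = d$outcome),
      method = "class",
      parms = list(split = "gini"),
      control = rpart::rpart.control(
        minsplit = 20, minbucket = 10, maxdepth = 3, cp = 0, xval = 0,
        maxsurrogate = 0, usesurrogate = 0
      )
    )
    theirs <- predict(rp, d$data, type = "class")
    agree <- agree + sum((mine == "at_risk") == (theirs == "poor"))
    total <- total + nrow(d$data)
  }
  expect_gte(agree / total, 0.95)
})

test_that("trees serialize to JSON and round-trip losslessly", {
  d <- random_labelled_data(60, seed = 13, noise = 0.2)
  tree <- growTree(d$data, d$outcome, names(d$data), treeControl(min_parent = 5, min_child = 2, max_depth = 3, min_decrease = 0))
  tmp <- withr::local_tempfile(fileext = ".json")
  writeTree(tree, tmp)
  back <- readTree(tmp)
  expect_identical(predict(back, d$data), predict(tree, d$data))
  expect_equal(back$root, tree$root, tolerance = 1e-12)
  expect_identical(treeItems(back), treeItems(tree))
})
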