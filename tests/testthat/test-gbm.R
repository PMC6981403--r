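make_xy <- function(n = 120, p = 6, seed = 1) {
  set.seed(seed)
  X <- random_design(n, p)
  logit <- 1.5 * X[, 1] - 1.0 * X[, 2] + 0.3
  y <- rbinom(n, 1, plogis(logit))
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  list(X = X, y = y)
}

test_that("base score is the log-odds of the training base rate", {
  d <- make_xy()
  m <- fit_gbm(d$X, d$y, gbm_config(n_trees = 1, max_depth = 1, min_leaf = 5))
  p <- mean(d$y)
  expect_equal(m$base_score, log(p / (1 - p)))
})

test_that("degenerate targets are rejected", {
  X <- random_design(20, 3)
  expect_error(fit_gbm(X, rep(1, 20)), "degenerate target")
  expect_error(fit_gbm(X, rep(0, 20)), "degenerate target")
})

test_that("a perfect predictor takes all the gain and separates training data", {
  set.seed(3)
  X <- random_design(80, 5)
  y <- X[, 3]
  m <- fit_gbm(X, y, gbm_config(n_trees = 1, max_depth = 1, min_leaf = 1))
  imp <- gain_importance(m, normalize = TRUE)
  expect_equal(unname(imp["f03"]), 1)
  expect_equal(sum(imp[setdiff(names(imp), "f03")]), 0)
  m2 <- fit_gbm(X, y, gbm_config(n_trees = 25, max_depth = 1, min_leaf = 1))
  expect_equal(auc(predict_proba(m2, X), y), 1.0)
})

test_that("split gain matches the hand-computed SSE identity", {
  # residuals (1,1,-1,-1) split by f=(1,1,0,0): gain (2*2/4)*(1-(-1))^2 = 4
  X <- cbind(f1 = c(1L, 1L, 0L, 0L), f2 = c(1L, 0L, 1L, 0L))
  s <- best_split(X, c(1, 1, -1, -1), min_leaf = 1)
  expect_identical(s$feature, "f1")
  expect_equal(s$gain, 4)
  # zero-variance residuals admit no split
  s0 <- best_split(X, rep(2, 4), min_leaf = 1)
  expect_identical(s0$feature, NA_character_)
})

test_that("split ties break towards the lowest column index", {
  X <- cbind(a = c(1L, 1L, 0L, 0L), b = c(1L, 1L, 0L, 0L))
  s <- best_split(X, c(2, 2, -1, -1), min_leaf = 1)
  expect_identical(s$feature, "a")
})

test_that("split choice and gain match exhaustive enumeration", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(20:200, 1)
    X <- random_design(n, 10)
    resid <- rnorm(n)
    ml <- sample(c(1L, 5L), 1)
    got <- best_split(X, resid, min_leaf = ml)
    want <- oracle_split(X, resid, min_leaf = ml)
    expect_identical(got$feature, want$feature)
    if (!is.na(want$gain)) expect_equal(got$gain, want$gain, tolerance = 1e-9)
  }
})

test_that("training deviance is non-increasing across boosting iterations", {
  for (seed in 1:3) {
    d <- make_xy(seed = seed)
    m <- fit_gbm(d$X, d$y, gbm_config(n_trees = 40, max_depth = 2))
    expect_true(all(diff(m$train_loss) <= 1e-9))
  }
})

test_that("trees respect max_depth and min_leaf", {
  d <- make_xy(n = 200, p = 8, seed = 5)
  cfg <- gbm_config(n_trees = 20, max_depth = 3, min_leaf = 15)
  m <- fit_gbm(d$X, d$y, cfg)
  depth_of <- function(tr, node = 1L) {
    if (tr$feature[node] < 0) return(0L)
    1L + max(depth_of(tr, tr$left[node] + 1L),
             depth_of(tr, tr$right[node] + 1L))
  }
  for (tr in m$trees) {
    expect_lte(depth_of(tr), cfg$max_depth)
    leaves <- tr$feature < 0
    expect_true(all(tr$n[leaves] >= cfg$min_leaf))
  }
})

test_that("gain importance equals an independent tree-walk aggregation", {
  d <- make_xy(n = 150, p = 7, seed = 8)
  m <- fit_gbm(d$X, d$y, gbm_config(n_trees = 3, max_depth = 3))
  expect_equal(m$importance, oracle_importance(m))
  norm <- gain_importance(m, normalize = TRUE)
  expect_equal(sum(norm), 1)
  expect_true(all(norm >= 0))
})

test_that("importance is invariant to row permutation", {
  d <- make_xy(n = 100, seed = 13)
  set.seed(99)
  perm <- sample(nrow(d$X))
  m1 <- fit_gbm(d$X, d$y, gbm_config(n_trees = 10, max_depth = 2))
  m2 <- fit_gbm(d$X[perm, ], d$y[perm], gbm_config(n_trees = 10, max_depth = 2))
  expect_equal(m1$importance, m2$importance)
})

test_that("identical inputs give bit-identical model dumps", {
  d <- make_xy(seed = 21)
  cfg <- gbm_config(n_trees = 15, max_depth = 2)
  j1 <- gbm_to_json(fit_gbm(d$X, d$y, cfg))
  j2 <- gbm_to_json(fit_gbm(d$X, d$y, cfg))
  expect_identical(as.character(j1), as.character(j2))
})

test_that("models survive a JSON round trip", {
  d <- make_xy(seed = 30)
  m <- fit_gbm(d$X, d$y, gbm_config(n_trees = 5, max_depth = 2))
  m2 <- gbm_from_json(gbm_to_json(m))
  expect_equal(m2$base_score, m$base_score)
  expect_equal(m2$importance, m$importance)
  expect_equal(predict_proba(m2, d$X), predict_proba(m, d$X))
})

test_that("predictions with no trees equal the base rate", {
  # a constructed 0-tree model: sigmoid(base) must recover the rate
  d <- make_xy(seed = 2)
  m <- fit_gbm(d$X, d$y, gbm_config(n_trees = 1, max_depth = 1))
  m$trees <- list()
  expect_equal(predict_proba(m, d$X), rep(mean(d$y), nrow(d$X)))
  expect_error(predict_proba(m, d$X[, 1:3]), "do not match")
})
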