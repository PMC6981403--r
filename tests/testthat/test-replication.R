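test_that("cross-stratum aggregation gives per-node mean and sample sd", {
  hm <- rbind(a = c(0.2, 0.4, 0.6), b = c(1, 1, 1), c = c(0.5, NA, 0.7))
  colnames(hm) <- c("s1", "s2", "s3")
  agg <- aggregate_strata(hm)
  expect_equal(unname(agg$mean_hub["a"]), 0.4)
  expect_equal(unname(agg$sd_hub["a"]), 0.2)
  expect_equal(unname(agg$sd_hub["b"]), 0)
  # NA entries are excluded, not propagated
  expect_equal(unname(agg$mean_hub["c"]), 0.6)

  one <- aggregate_strata(hm[, 1, drop = FALSE])
  expect_equal(unname(one$mean_hub), unname(hm[, 1]))
  expect_true(all(one$sd_hub == 0))
})

test_that("stratum correlations recover the textbook Pearson coefficient", {
  hm <- cbind(s1 = c(1, 2, 3, 4), s2 = c(2, 4, 5, 9), s3 = c(1, 2, 3, 4))
  rownames(hm) <- letters[1:4]
  r <- correlate_strata(hm)
  expect_equal(dim(r), c(3L, 3L))
  expect_equal(unname(diag(r)), rep(1, 3))
  expect_equal(r, t(r))
  expect_equal(r["s1", "s2"], oracle_pearson(hm[, "s1"], hm[, "s2"]))
  expect_equal(r["s1", "s3"], 1)
  neg <- cbind(s1 = c(1, 2, 3, 4), s2 = c(8, 6, 4, 2))
  expect_equal(correlate_strata(neg)["s1", "s2"], -1)
  flat <- cbind(s1 = c(1, 2, 3), s2 = c(5, 5, 5))
  expect_warning(rf <- correlate_strata(flat), "zero-variance")
  expect_true(is.na(rf["s1", "s2"]))
})

test_that("correlations ignore common positive affine rescaling", {
  set.seed(8)
  hm <- matrix(runif(30), 10, 3, dimnames = list(letters[1:10], c("x", "y", "z")))
  expect_equal(correlate_strata(0.3 + 2 * hm), correlate_strata(hm))
})

small_cfg <- gbm_config(n_trees = 15, max_depth = 2, min_leaf = 5)

test_that("a single-stratum run reports zero sd and no correlation matrix", {
  tab <- simulate_survey(sim_config(n_subjects = 250, n_strata = 1,
                                    n_dependent = 4, n_noise = 4, seed = 5))
  rep <- run_pipeline(tab, gbm = small_cfg, min_stratum_n = 10, seed = 5)
  expect_identical(rep$strata, "stratum_1")
  expect_true(all(rep$sd_hub == 0))
  expect_null(rep$corr)
  expect_equal(nrow(rep$top_k), 5L)
})

test_that("duplicated strata give identical hub vectors and r = 1", {
  tab <- simulate_survey(sim_config(n_subjects = 200, n_strata = 1,
                                    n_dependent = 4, n_noise = 3, seed = 9))
  v <- tab$values
  dup <- data.frame(rbind(v, v), stringsAsFactors = FALSE)
  dup$region <- rep(c("north", "south"), each = nrow(v))
  tab2 <- categorical_table(dup, stratum_col = "region")
  rep <- run_pipeline(tab2, gbm = small_cfg, min_stratum_n = 10, seed = 3)
  expect_equal(unname(rep$hub_matrix[, "north"]),
               unname(rep$hub_matrix[, "south"]))
  expect_equal(rep$corr["north", "south"], 1)
  expect_true(all(rep$sd_hub < 1e-12))
})

test_that("row order does not change the report", {
  cfg <- sim_config(n_subjects = 150, n_strata = 2, n_dependent = 3,
                    n_noise = 3, seed = 21)
  tab <- simulate_survey(cfg)
  set.seed(1)
  perm <- sample(nrow(tab$values))
  ptab <- structure(list(values = tab$values[perm, , drop = FALSE],
                         variables = tab$variables,
                         subject_ids = tab$subject_ids[perm],
                         stratum = tab$stratum[perm]),
                    class = "categorical_table")
  r1 <- run_pipeline(tab, gbm = small_cfg, min_stratum_n = 10, seed = 7)
  r2 <- run_pipeline(ptab, gbm = small_cfg, min_stratum_n = 10, seed = 7)
  # strata are analysed in canonical content order, so any row permutation
  # must leave hub vectors and rankings exactly unchanged
  expect_equal(r1$hub_matrix, r2$hub_matrix)
  expect_identical(r1$top_k, r2$top_k)
})

test_that("undersized strata are skipped with a warning", {
  df <- data.frame(q1 = sample(c("a", "b"), 120, replace = TRUE),
                   q2 = sample(c("x", "y"), 120, replace = TRUE),
                   q3 = sample(c("u", "v"), 120, replace = TRUE),
                   region = c(rep("big", 110), rep("tiny", 10)),
                   stringsAsFactors = FALSE)
  tab <- categorical_table(df, stratum_col = "region")
  expect_warning(rep <- run_pipeline(tab, gbm = small_cfg,
                                     min_stratum_n = 50, seed = 2),
                 "tiny")
  expect_identical(rep$strata, "big")
})

test_that("the log holds one terminal status per target per stratum", {
  tab <- simulate_survey(sim_config(n_subjects = 150, n_strata = 2,
                                    n_dependent = 3, n_noise = 2, seed = 4))
  rep <- run_pipeline(tab, gbm = small_cfg, min_stratum_n = 10, seed = 4)
  for (lab in rep$strata) {
    targets <- rep$auc_tables[[lab]]$target
    status <- grep(sprintf("^\\[%s\\] .*(fitted|skipped)", lab), rep$log,
                   value = TRUE)
    expect_length(status, length(targets))
  }
})
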