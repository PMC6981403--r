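#' Seeded train/test partition
#'
#' Draws `round(train_frac * n)` training indices by uniform sampling without
#' replacement; the remaining indices form the test set. One partition is
#' drawn per stratum and reused for every target fitted in that stratum, so
#' test AUCs are comparable across targets. The split is simple random, not
#' label-stratified; targets whose train or test slice ends up single-class
#' are skipped downstream.
#'
#' @param n number of subjects (>= 2).
#' @param train_frac training fraction in (0, 1); default 0.7 (a 70/30 split).
#' @param seed integer seed; the global RNG state is left untouched.
#' @return list with integer vectors `train` and `test` (disjoint, exhaustive).
#' @export
train_test_split <- function(n, train_frac = 0.7, seed = 1L) {
  if (n < 2L) stop("need at least 2 subjects to split")
  stopifnot(train_frac > 0, train_frac < 1)
  n_train <- round(train_frac * n)
  n_train <- max(1L, min(n - 1L, n_train))
  train <- with_seed(seed, sort(sample.int(n, n_train)))
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Area under the ROC curve (rank statistic, midrank ties)
#'
#' Mann-Whitney form: `(sum of positive ranks - n1 (n1 + 1) / 2) / (n1 n0)`,
#' with midranks for tied scores, i.e. the probability that a random positive
#' outscores a random negative, ties counting one half.
#'
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 labels; must contain both classes.
#' @return AUC in \[0, 1\], or `NA_real_` if `labels` is single-class.
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Fit + evaluate one target dummy within a stratum. Returns a record with the
# model (or NULL), test AUC, and a skip reason when the target is degenerate
# or single-class in either slice.
evaluate_target <- function(encoded, target, split, config = gbm_config()) {
  skip <- function(reason) {
    list(target = target, model = NULL, auc = NA_real_,
         n_train = length(split$train), n_test = length(split$test),
         skipped = TRUE, reason = reason)
  }
  if (target %in% encoded$degenerate) return(skip("degenerate (constant) dummy"))
  y <- encoded$data[, target]
  y_train <- y[split$train]
  y_test <- y[split$test]
  if (length(unique(y_train)) < 2L) return(skip("single-class training slice"))
  mask <- predictor_mask(encoded, target)
  model <- fit_gbm(encoded$data[split$train, , drop = FALSE], y_train,
                   config = config, features = mask)
  a <- if (length(unique(y_test)) < 2L) NA_real_ else {
    auc(predict_proba(model, encoded$data[split$test, , drop = FALSE]), y_test)
  }
  list(target = target, model = model, auc = a,
       n_train = length(split$train), n_test = length(split$test),
       skipped = FALSE,
       reason = if (is.na(a)) "single-class test slice (AUC undefined)" else "")
}
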