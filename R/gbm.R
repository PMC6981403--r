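#' Gradient boosting configuration
#'
#' Hyperparameters of the per-target boosted classifier. The ensemble size
#' and depth default to 100 trees of maximum depth 4, the setting used for
#' survey-scale predictive networks; learning rate 0.1 and a minimum of 10
#' observations per leaf are the customary defaults of production gradient
#' boosting implementations. There is no row or column subsampling, so a fit
#' is fully deterministic given the data.
#'
#' @param n_trees number of boosting iterations (>= 1).
#' @param max_depth maximum tree depth (>= 1; depth 1 is a stump).
#' @param learn_rate shrinkage applied to every leaf value, in (0, 1].
#' @param min_leaf minimum training samples per leaf (>= 1).
#' @return a `gbm_config` list.
#' @export
gbm_config <- function(n_trees = 100L, max_depth = 4L, learn_rate = 0.1,
                       min_leaf = 10L) {
  stopifnot(n_trees >= 1L, max_depth >= 1L,
            learn_rate > 0, learn_rate <= 1, min_leaf >= 1L)
  structure(list(n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth),
                 learn_rate = as.numeric(learn_rate),
                 min_leaf = as.integer(min_leaf)),
            class = "gbm_config")
}

#' Fit a gradient-boosted classifier on binary dummy predictors
#'
#' Bernoulli-deviance boosting of shallow regression trees. The model starts
#' from the log-odds of the training base rate; each iteration fits a tree to
#' the current residuals `y - p` by exhaustive single-feature search
#' maximising the squared-error reduction
#' `(nL * nR / n) * (meanL - meanR)^2`, with ties broken towards the lowest
#' column index, and takes a damped Newton step
#' `sum(residual) / sum(p (1 - p))` in each leaf. A node whose residuals have
#' zero variance (or that cannot satisfy `min_leaf`) becomes a leaf; boosting
#' stops early once the target is fitted exactly.
#'
#' @param X integer 0/1 matrix with named columns (subjects x dummies).
#' @param y binary (0/1) response vector; must contain both classes.
#' @param config a [gbm_config()].
#' @param features character vector of admissible predictor columns
#'   (defaults to all columns of `X`); use [predictor_mask()] to exclude the
#'   target's sibling dummies.
#' @return a `gbm_model`: `base_score` (initial log-odds), `trees` (flat node
#'   arrays), `importance` (named per-feature gain totals), `feature_names`,
#'   `train_loss` (per-iteration Bernoulli deviance), and the config.
#' @export
fit_gbm <- function(X, y, config = gbm_config(), features = colnames(X)) {
  stopifnot(is.matrix(X), !is.null(colnames(X)))
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X rows must match length of y")
  if (length(unique(y)) < 2L) stop("degenerate target")
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  idx <- match(features, colnames(X))
  if (anyNA(idx)) stop("unknown feature(s): ",
                       paste(features[is.na(idx)], collapse = ", "))
  storage.mode(X) <- "integer"
  fit <- gbm_fit_cpp(X, y, as.integer(idx - 1L), config$n_trees,
                     config$max_depth, config$learn_rate, config$min_leaf)
  importance <- as.numeric(fit$importance)
  names(importance) <- colnames(X)
  structure(list(base_score = fit$base_score, trees = fit$trees,
                 importance = importance, feature_names = colnames(X),
                 train_loss = as.numeric(fit$train_loss), config = config),
            class = "gbm_model")
}

#' @export
print.gbm_model <- function(x, ...) {
  cat(sprintf("gbm_model: %d trees (max depth %d), base score %.4f, %d features used\n",
              length(x$trees), x$config$max_depth, x$base_score,
              sum(x$importance > 0)))
  invisible(x)
}

#' Predicted class-1 probabilities from a boosted model
#'
#' @param model a [fit_gbm()] model.
#' @param X integer 0/1 matrix whose columns match `model$feature_names`.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "gbm_model"), is.matrix(X))
  if (!identical(colnames(X), model$feature_names))
    stop("feature columns do not match the fitted model")
  storage.mode(X) <- "integer"
  as.numeric(gbm_predict_cpp(model$trees, model$base_score,
                             model$config$learn_rate, X))
}

#' Gain importance of a boosted model
#'
#' Total squared-error reduction attributable to splits on each feature,
#' summed over all internal nodes of all trees. With `normalize = TRUE` the
#' vector is rescaled to sum to 1 (the relative importance used for network
#' edges); an all-zero vector stays all-zero.
#'
#' @param model a [fit_gbm()] model.
#' @param normalize rescale to unit sum?
#' @return named nonnegative numeric vector over `model$feature_names`.
#' @export
gain_importance <- function(model, normalize = FALSE) {
  stopifnot(inherits(model, "gbm_model"))
  imp <- model$importance
  if (normalize) {
    tot <- sum(imp)
    if (tot > 0) imp <- imp / tot
  }
  imp
}

#' Best single-feature split by residual sum-of-squares reduction
#'
#' Exposes the split search used inside [fit_gbm()]: over the admissible
#' binary features, the gain of splitting `rows` on feature `f` is
#' `(nL * nR / n) * (meanL - meanR)^2` of the residuals (identically
#' `SSE_parent - SSE_left - SSE_right`); both children must keep at least
#' `min_leaf` rows. Ties go to the lowest column index.
#'
#' @param X integer 0/1 matrix with named columns.
#' @param residuals numeric residual vector (one per row of `X`).
#' @param rows integer row indices defining the node (default all rows).
#' @param features admissible feature names (default all columns).
#' @param min_leaf minimum child size.
#' @return list with `feature` (name, or `NA` if no admissible positive-gain
#'   split exists) and `gain`.
#' @export
best_split <- function(X, residuals, rows = seq_len(nrow(X)),
                       features = colnames(X), min_leaf = 1L) {
  stopifnot(is.matrix(X), length(residuals) == nrow(X))
  idx <- match(features, colnames(X))
  if (anyNA(idx)) stop("unknown feature(s)")
  storage.mode(X) <- "integer"
  res <- best_split_cpp(X, as.numeric(residuals), as.integer(rows - 1L),
                        as.integer(idx - 1L), as.integer(min_leaf))
  if (is.na(res$feature)) return(list(feature = NA_character_, gain = NA_real_))
  list(feature = colnames(X)[res$feature], gain = res$gain)
}

#' Serialize a boosted model to a JSON string
#'
#' Dumps base score, per-tree node arrays and the importance table in a
#' stable, human-inspectable layout; [gbm_from_json()] restores an
#' equivalent model object.
#'
#' @param model a [fit_gbm()] model.
#' @return a JSON character scalar.
#' @export
gbm_to_json <- function(model) {
  stopifnot(inherits(model, "gbm_model"))
  jsonlite::toJSON(list(
    base_score = model$base_score,
    config = unclass(model$config),
    feature_names = model$feature_names,
    importance = model$importance,
    train_loss = model$train_loss,
    trees = model$trees
  ), digits = NA, auto_unbox = TRUE)
}

#' Restore a boosted model from its JSON dump
#'
#' @param json a string produced by [gbm_to_json()].
#' @return a `gbm_model`.
#' @export
gbm_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE)
  cfg <- gbm_config(x$config$n_trees, x$config$max_depth,
                    x$config$learn_rate, x$config$min_leaf)
  trees <- lapply(seq_along(x$trees), function(i) {
    tr <- x$trees[[i]]
    list(feature = as.integer(tr$feature), left = as.integer(tr$left),
         right = as.integer(tr$right), value = as.numeric(tr$value),
         gain = as.numeric(tr$gain), n = as.integer(tr$n))
  })
  imp <- as.numeric(x$importance)
  names(imp) <- x$feature_names
  structure(list(base_score = x$base_score, trees = trees, importance = imp,
                 feature_names = x$feature_names,
                 train_loss = as.numeric(x$train_loss), config = cfg),
            class = "gbm_model")
}
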