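# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately use different formulas/arithmetic than the package.

# AUC by brute-force counting over all positive-negative pairs
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# exhaustive single-feature split search by explicit SSE decomposition
# (SSE_parent - SSE_left - SSE_right), lowest column index wins ties
oracle_split <- function(X, resid, rows = seq_len(nrow(X)), min_leaf = 1L) {
  sse <- function(r) if (length(r) == 0) 0 else sum((r - mean(r))^2)
  r <- resid[rows]
  parent <- sse(r)
  best <- list(feature = NA_character_, gain = NA_real_)
  for (j in seq_len(ncol(X))) {
    right <- X[rows, j] == 1
    if (sum(right) < min_leaf || sum(!right) < min_leaf) next
    g <- parent - sse(r[right]) - sse(r[!right])
    if (!is.na(g) && g > 0 &&
        (is.na(best$gain) || g > best$gain + 1e-9)) {
      best <- list(feature = colnames(X)[j], gain = g)
    }
  }
  best
}

# all per-feature split gains by the same SSE decomposition (NA where the
# min_leaf constraint rules the split out)
oracle_gains <- function(X, resid, rows = seq_len(nrow(X)), min_leaf = 1L) {
  sse <- function(r) if (length(r) == 0) 0 else sum((r - mean(r))^2)
  r <- resid[rows]
  parent <- sse(r)
  vapply(seq_len(ncol(X)), function(j) {
    right <- X[rows, j] == 1
    if (sum(right) < min_leaf || sum(!right) < min_leaf) return(NA_real_)
    parent - sse(r[right]) - sse(r[!right])
  }, 0)
}

# collect per-feature gain sums by walking a model's trees node by node
oracle_importance <- function(model) {
  imp <- numeric(length(model$feature_names))
  names(imp) <- model$feature_names
  for (tr in model$trees) {
    for (k in seq_along(tr$feature)) {
      f <- tr$feature[k]
      if (f >= 0) imp[f + 1L] <- imp[f + 1L] + tr$gain[k]
    }
  }
  imp
}

# dominant eigenvector of A A' from a dense symmetric eigendecomposition
oracle_hubs <- function(A) {
  M <- A %*% t(A)
  v <- eigen(M, symmetric = TRUE)$vectors[, 1]
  if (sum(v) < 0) v <- -v
  v <- pmax(v, 0)
  if (max(v) > 0) v / max(v) else v
}

# two-pass textbook Pearson correlation
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# random binary design matrix with distinct, non-complementary columns so
# that the split argmax is unique with probability one
random_design <- function(n, p) {
  repeat {
    X <- matrix(rbinom(n * p, 1L, runif(p, 0.25, 0.75)[rep(seq_len(p),
                                                           each = n)]),
                n, p)
    colnames(X) <- sprintf("f%02d", seq_len(p))
    key <- apply(X, 2, paste, collapse = "")
    keyc <- apply(1L - X, 2, paste, collapse = "")
    if (anyDuplicated(c(key)) == 0 && !any(key %in% keyc) &&
        all(colSums(X) > 0) && all(colSums(X) < n)) return(X)
  }
}

# small random categorical survey data.frame
random_survey <- function(n = 60, vars = 4, levels = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  df <- as.data.frame(lapply(seq_len(vars), function(j) {
    sample(LETTERS[seq_len(levels)], n, replace = TRUE)
  }))
  names(df) <- sprintf("q%d", seq_len(vars))
  df
}
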