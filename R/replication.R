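#' Cross-stratum mean and standard deviation of hub scores
#'
#' Arithmetic mean and sample standard deviation per node across strata,
#' computed over the strata where the node has a score (`NA` entries --
#' nodes absent or skipped in a stratum -- are excluded pairwise). With a
#' single stratum every sd is 0.
#'
#' @param hub_matrix numeric matrix, nodes x strata (dimnames required).
#' @return list with named vectors `mean_hub` and `sd_hub`.
#' @export
aggregate_strata <- function(hub_matrix) {
  stopifnot(is.matrix(hub_matrix), ncol(hub_matrix) >= 1L)
  mean_hub <- apply(hub_matrix, 1, function(x) mean(x, na.rm = TRUE))
  sd_hub <- apply(hub_matrix, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) 0 else sd(x)
  })
  list(mean_hub = mean_hub, sd_hub = sd_hub)
}

#' Pairwise Pearson correlation of hub scores between strata
#'
#' For each pair of strata, Pearson r over the nodes scored in both
#' (pairwise-complete); the diagonal is 1. A zero-variance stratum vector
#' yields `NA` entries (flagged with a warning).
#'
#' @param hub_matrix numeric matrix, nodes x strata.
#' @return strata x strata symmetric correlation matrix.
#' @export
correlate_strata <- function(hub_matrix) {
  stopifnot(is.matrix(hub_matrix), ncol(hub_matrix) >= 2L,
            nrow(hub_matrix) >= 3L)
  suppressWarnings(r <- cor(hub_matrix, use = "pairwise.complete.obs",
                            method = "pearson"))
  diag(r) <- 1
  if (anyNA(r)) warning("zero-variance hub vector: undefined correlation entries")
  r
}

#' Run the full predictive-network pipeline, replicated over strata
#'
#' For each stratum: one-hot encode, draw one 70/30 train/test split, fit one
#' gradient-boosted classifier per non-degenerate dummy target (all dummies
#' from other variables as predictors), record its test AUC and gain
#' importances, assemble the directed weighted network, and compute hub
#' scores. Hub vectors are then aligned across strata on the union of nodes,
#' averaged, and correlated pairwise; the final ranking is by mean hub score.
#' Everything is deterministic given `seed`: per-stratum seeds are derived
#' with [derive_seed()] so strata never perturb each other.
#'
#' @param table a [categorical_table()]; without a stratum vector a single
#'   pseudo-stratum `"all"` is used.
#' @param gbm a [gbm_config()].
#' @param train_frac training fraction of the per-stratum split.
#' @param top_k size of the final hub ranking (default 5).
#' @param normalize_columns passed to [build_adjacency()].
#' @param min_stratum_n strata with fewer subjects are skipped with a warning.
#' @param seed master seed.
#' @param verbose print per-stratum progress?
#' @return a `replication_report`: `strata`; `hub_matrix` (nodes x strata,
#'   `NA` where a node is absent); `mean_hub`, `sd_hub`; `corr` (or `NULL`
#'   for one stratum); `top_k` ranking by mean hub; per-stratum `auc_tables`
#'   (data.frames: target, auc, n_train, n_test, skipped, reason),
#'   `auc_summaries` (five-number summaries), `networks`, `hubs`, and `log`
#'   (character vector, one terminal status line per target per stratum).
#' @export
run_pipeline <- function(table, gbm = gbm_config(), train_frac = 0.7,
                         top_k = 5L, normalize_columns = TRUE,
                         min_stratum_n = 50L, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(table, "categorical_table"))
  stratum <- table$stratum %||% rep("all", nrow(table$values))
  labels <- sort(unique(stratum), method = "radix")

  hubs <- list(); networks <- list(); auc_tables <- list(); log <- character(0)
  for (lab in labels) {
    rows <- which(stratum == lab)
    if (length(rows) < min_stratum_n) {
      warning(sprintf("stratum '%s' has %d subjects (< %d): skipped",
                      lab, length(rows), min_stratum_n))
      log <- c(log, sprintf("[%s] stratum skipped: %d subjects", lab,
                            length(rows)))
      next
    }
    # canonical content order: the analysis depends only on the multiset of
    # rows, so row permutations (and relabelled duplicate strata) are inert
    key <- do.call(paste, c(split(table$values[rows, , drop = FALSE],
                                  col(table$values[rows, , drop = FALSE])),
                            sep = "\x1f"))
    rows <- rows[order(key, method = "radix")]
    sub <- structure(list(values = table$values[rows, , drop = FALSE],
                          variables = table$variables,
                          subject_ids = table$subject_ids[rows],
                          stratum = NULL),
                     class = "categorical_table")
    encoded <- one_hot_encode(sub)
    content <- paste(sort(key, method = "radix"), collapse = "\n")
    split <- train_test_split(nrow(encoded$data), train_frac,
                              seed = derive_seed(seed, content))
    if (verbose)
      message(sprintf("stratum %s: %d subjects, %d dummy targets",
                      lab, length(rows), length(encoded$columns)))
    importances <- list()
    recs <- vector("list", length(encoded$columns))
    for (i in seq_along(encoded$columns)) {
      target <- encoded$columns[i]
      rec <- evaluate_target(encoded, target, split, config = gbm)
      recs[[i]] <- rec
      log <- c(log, sprintf("[%s] %s: %s", lab, target,
                            if (rec$skipped) paste("skipped -", rec$reason)
                            else sprintf("fitted, test AUC %s",
                                         formatC(rec$auc, digits = 4,
                                                 format = "f"))))
      if (!rec$skipped) {
        imp <- gain_importance(rec$model)
        mask <- predictor_mask(encoded, target)
        importances[[target]] <- imp[mask]
      }
    }
    auc_tables[[lab]] <- data.frame(
      target = vapply(recs, `[[`, "", "target"),
      auc = vapply(recs, `[[`, 0, "auc"),
      n_train = vapply(recs, `[[`, 0L, "n_train"),
      n_test = vapply(recs, `[[`, 0L, "n_test"),
      skipped = vapply(recs, `[[`, FALSE, "skipped"),
      reason = vapply(recs, `[[`, "", "reason"),
      stringsAsFactors = FALSE)
    net <- build_adjacency(importances, encoded,
                           normalize_columns = normalize_columns)
    networks[[lab]] <- net
    hs <- hub_scores(net)
    log <- c(log, sprintf("[%s] hub power iteration: %d iterations, %s", lab,
                          hs$iterations,
                          if (hs$converged) "converged" else "NOT converged"))
    hubs[[lab]] <- hs
  }
  if (length(hubs) == 0L) stop("no stratum large enough to analyse")

  strata <- names(hubs)
  all_nodes <- sort(unique(unlist(lapply(hubs, function(h) names(h$scores)))),
                    method = "radix")
  hub_matrix <- matrix(NA_real_, length(all_nodes), length(strata),
                       dimnames = list(all_nodes, strata))
  for (lab in strata) hub_matrix[names(hubs[[lab]]$scores), lab] <-
    hubs[[lab]]$scores
  agg <- aggregate_strata(hub_matrix)
  corr <- if (length(strata) >= 2L && length(all_nodes) >= 3L)
    correlate_strata(hub_matrix) else NULL
  ranking <- rank_hubs(agg$mean_hub, k = top_k)
  auc_summaries <- lapply(auc_tables, function(tab) {
    a <- tab$auc[!is.na(tab$auc)]
    if (length(a) == 0) rep(NA_real_, 5)
    else unname(quantile(a, c(0, 0.25, 0.5, 0.75, 1)))
  })
  structure(list(strata = strata, hub_matrix = hub_matrix,
                 mean_hub = agg$mean_hub, sd_hub = agg$sd_hub, corr = corr,
                 top_k = ranking, auc_tables = auc_tables,
                 auc_summaries = auc_summaries, networks = networks,
                 hubs = hubs, log = log,
                 config = list(gbm = gbm, train_frac = train_frac,
                               top_k = top_k,
                               normalize_columns = normalize_columns,
                               min_stratum_n = min_stratum_n, seed = seed)),
            class = "replication_report")
}

#' @export
print.replication_report <- function(x, ...) {
  cat(sprintf("replication_report: %d strata, %d nodes\n",
              length(x$strata), nrow(x$hub_matrix)))
  cat("top hubs by mean hub score:\n")
  print(x$top_k, row.names = FALSE)
  if (!is.null(x$corr)) {
    lo <- min(x$corr[lower.tri(x$corr)])
    cat(sprintf("cross-stratum Pearson r: min %.4f\n", lo))
  }
  invisible(x)
}
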