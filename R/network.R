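#' Assemble the directed weighted predictive network
#'
#' Builds the N x N adjacency matrix A over dummy variables with
#' `A[i, j]` = gain importance of predictor i in the model fitted for target
#' j: rows are outgoing links ("i helps predict others"), columns are
#' incoming links. Entries between dummies of the same source variable are
#' structurally zero (the anti-leakage exclusion), skipped targets keep an
#' all-zero column so node indexing is stable, and no edge thresholding of
#' any kind is applied.
#'
#' By default each non-zero column is rescaled to sum to 1, so every fitted
#' model contributes equal total edge mass regardless of its target's
#' base-rate variance; set `normalize_columns = FALSE` for raw gain sums.
#'
#' @param importances named list: for each non-skipped target dummy, a named
#'   importance vector over (a subset of) its admissible predictors.
#' @param encoded the [one_hot_encode()] result the models were fitted on.
#' @param normalize_columns rescale each non-zero column to unit sum?
#' @return a `predictive_network`: `nodes`, adjacency `A`, `groups`.
#' @export
build_adjacency <- function(importances, encoded, normalize_columns = TRUE) {
  stopifnot(inherits(encoded, "encoded_matrix"), is.list(importances))
  nodes <- encoded$columns
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  gmap <- group_map(encoded)
  for (target in names(importances)) {
    if (!target %in% nodes) stop("unknown target: ", target)
    imp <- importances[[target]]
    if (length(imp) == 0) next
    if (is.null(names(imp))) stop("importance vector must be named")
    bad <- names(imp)[gmap[names(imp)] == gmap[[target]]]
    if (length(bad) > 0)
      stop("leakage: importance for same-group predictor(s) of ", target,
           ": ", paste(bad, collapse = ", "))
    A[names(imp), target] <- imp
  }
  if (any(A < 0)) stop("importances must be nonnegative")
  if (normalize_columns) {
    cs <- colSums(A)
    nz <- cs > 0
    A[, nz] <- sweep(A[, nz, drop = FALSE], 2, cs[nz], "/")
  }
  structure(list(nodes = nodes, A = A, groups = encoded$groups),
            class = "predictive_network")
}

#' @export
print.predictive_network <- function(x, ...) {
  cat(sprintf("predictive_network: %d nodes, %d edges\n",
              length(x$nodes), sum(x$A > 0)))
  invisible(x)
}

#' Hub scores by power iteration on A A'
#'
#' The hub score vector is the principal eigenvector of `M = A %*% t(A)`
#' (Perron-Frobenius: nonnegative for nonnegative A), computed by power
#' iteration started from the uniform positive vector, with each iterate
#' max-normalized so the top hub scores 1. A node scores high when its
#' outgoing edges point at targets that are themselves pointed at by other
#' strong hubs -- here, variables carrying predictive information about many
#' other variables. The zero matrix yields all-zero scores.
#'
#' @param net a [build_adjacency()] network, or a plain nonnegative matrix.
#' @param tol convergence tolerance on the max-norm difference of successive
#'   max-normalized iterates.
#' @param max_iter iteration cap; non-convergence is flagged, not an error.
#' @return a `hub_scores` object: `scores` (named, in \[0, 1\], max 1),
#'   `eigenvalue` (Rayleigh quotient estimate of the dominant eigenvalue of
#'   `M`), `iterations`, `converged`.
#' @export
hub_scores <- function(net, tol = 1e-12, max_iter = 10000L) {
  A <- if (inherits(net, "predictive_network")) net$A else as.matrix(net)
  if (any(A < 0)) stop("adjacency must be nonnegative")
  n <- nrow(A)
  nodes <- rownames(A) %||% sprintf("n%d", seq_len(n))
  mul <- function(v) as.numeric(A %*% crossprod(A, v)) # M v without forming M
  v <- rep(1, n)
  zero <- function(s) structure(
    list(scores = s, eigenvalue = 0, iterations = 0L, converged = TRUE),
    class = "hub_scores")
  if (all(A == 0)) {
    s <- rep(0, n); names(s) <- nodes
    return(zero(s))
  }
  v <- v / max(v)
  converged <- FALSE
  it <- 0L
  lambda <- 0
  while (it < max_iter) {
    it <- it + 1L
    w <- mul(v)
    m <- max(w)
    if (m == 0) { # v fell entirely in the null space; scores are zero
      s <- rep(0, n); names(s) <- nodes
      return(zero(s))
    }
    w <- w / m
    if (max(abs(w - v)) < tol) {
      v <- w
      converged <- TRUE
      break
    }
    v <- w
  }
  lambda <- sum(v * mul(v)) / sum(v * v)
  names(v) <- nodes
  structure(list(scores = v, eigenvalue = lambda, iterations = it,
                 converged = converged),
            class = "hub_scores")
}

#' @export
print.hub_scores <- function(x, ...) {
  cat(sprintf("hub_scores: %d nodes, dominant eigenvalue %.6g (%s in %d iterations)\n",
              length(x$scores), x$eigenvalue,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Top-k hub ranking
#'
#' @param scores a [hub_scores()] object or a named numeric vector.
#' @param k number of top nodes to return (>= 1); capped at the node count.
#' @return data.frame with `node`, `score`, `rank`, sorted by score
#'   descending with ties broken by node name ascending.
#' @export
rank_hubs <- function(scores, k = 5L) {
  stopifnot(k >= 1L)
  s <- if (inherits(scores, "hub_scores")) scores$scores else scores
  ord <- order(-s, names(s), method = "radix")
  top <- head(ord, k)
  data.frame(node = names(s)[top], score = unname(s[top]),
             rank = seq_along(top), stringsAsFactors = FALSE)
}

#' Export the network as an edge list
#'
#' @param net a [build_adjacency()] network.
#' @return data.frame `(source, target, weight)` containing only non-zero
#'   edges, in column-major (target-major) order.
#' @export
edge_list <- function(net) {
  stopifnot(inherits(net, "predictive_network"))
  idx <- which(net$A > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
  data.frame(source = net$nodes[idx[, 1]], target = net$nodes[idx[, 2]],
             weight = net$A[idx], stringsAsFactors = FALSE)
}

#' Write a network to GraphML
#'
#' Converts the adjacency matrix to an igraph directed weighted graph and
#' writes GraphML with a `weight` edge attribute.
#'
#' @param net a [build_adjacency()] network.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "predictive_network"))
  g <- igraph::graph_from_adjacency_matrix(net$A, mode = "directed",
                                           weighted = TRUE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
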