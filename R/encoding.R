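#' Construct a categorical survey table
#'
#' Bundles a subjects-by-variables grid of category labels with optional
#' subject identifiers and an optional per-subject stratum label (for example
#' a geographic region). Every analysis variable is treated as categorical;
#' missing cells (`NA` or empty strings) are mapped to an explicit reserved
#' level so that no subject is ever dropped.
#'
#' @param data a data.frame of categorical columns (factors or character).
#' @param stratum_col name of the column holding stratum labels, or `NULL`
#'   for an unstratified table. The stratum column is removed from the set of
#'   analysis variables.
#' @param id_col optional name of a subject-identifier column (removed from
#'   the analysis variables).
#' @param missing_label reserved label substituted for `NA`/empty cells.
#'   Set to `NULL` to forbid missing values (an error is raised if any occur).
#' @return an object of class `categorical_table` with elements
#'   `values` (character matrix, subjects x variables), `variables`,
#'   `subject_ids`, and `stratum` (character vector or `NULL`).
#' @export
categorical_table <- function(data, stratum_col = NULL, id_col = NULL,
                              missing_label = "MISSING") {
  stopifnot(is.data.frame(data))
  if (nrow(data) < 2L || ncol(data) < 1L) stop("no data")
  nm <- names(data)
  if (anyDuplicated(nm)) stop("duplicate variable names")

  subject_ids <- if (!is.null(id_col)) {
    if (!id_col %in% nm) stop("id column not found: ", id_col)
    as.character(data[[id_col]])
  } else sprintf("s%d", seq_len(nrow(data)))

  stratum <- NULL
  if (!is.null(stratum_col)) {
    if (!stratum_col %in% nm) stop("stratum column not found: ", stratum_col)
    stratum <- as.character(data[[stratum_col]])
  }
  drop <- c(stratum_col, id_col)
  vars <- setdiff(nm, drop)
  if (length(vars) < 1L) stop("no data")

  values <- vapply(vars, function(v) as.character(data[[v]]),
                   character(nrow(data)))
  if (!is.matrix(values)) values <- matrix(values, nrow = nrow(data),
                                           dimnames = list(NULL, vars))
  miss <- is.na(values) | values == ""
  if (any(miss)) {
    if (is.null(missing_label)) stop("missing values present and missing_label is NULL")
    values[miss] <- missing_label
  }
  structure(list(values = values, variables = vars,
                 subject_ids = subject_ids, stratum = stratum),
            class = "categorical_table")
}

#' @export
print.categorical_table <- function(x, ...) {
  cat(sprintf("categorical_table: %d subjects x %d variables%s\n",
              nrow(x$values), length(x$variables),
              if (is.null(x$stratum)) ""
              else sprintf(", %d strata", length(unique(x$stratum)))))
  invisible(x)
}

#' One-hot encode a categorical table
#'
#' Expands every categorical variable into the full set of its observed
#' levels (all k indicator columns are kept, not k-1 reference coding), so
#' that every dummy can in turn serve as a two-class prediction target.
#' Dummy columns are named `<variable>=<level>`; column order is variable
#' order, then level order lexicographic, which makes the encoding fully
#' deterministic. Constant (all-0 or all-1) dummies are flagged as degenerate:
#' they stay in the matrix for stable indexing but are skipped as targets.
#'
#' @param table a [categorical_table()].
#' @return an object of class `encoded_matrix`: `data` (integer 0/1 matrix,
#'   subjects x dummies), `columns`, `groups` (named list mapping each source
#'   variable to its dummy columns), `degenerate` (character vector), and the
#'   inherited `stratum`/`subject_ids`.
#' @export
one_hot_encode <- function(table) {
  stopifnot(inherits(table, "categorical_table"))
  v <- table$values
  if (nrow(v) < 2L || ncol(v) < 1L) stop("no data")
  groups <- list()
  blocks <- vector("list", ncol(v))
  for (j in seq_len(ncol(v))) {
    var <- colnames(v)[j]
    lev <- sort(unique(v[, j]), method = "radix")
    cols <- paste0(var, "=", lev)
    block <- matrix(0L, nrow(v), length(lev), dimnames = list(NULL, cols))
    for (k in seq_along(lev)) block[, k] <- as.integer(v[, j] == lev[k])
    groups[[var]] <- cols
    blocks[[j]] <- block
  }
  data <- do.call(cbind, blocks)
  csum <- colSums(data)
  degenerate <- colnames(data)[csum == 0L | csum == nrow(data)]
  structure(list(data = data, columns = colnames(data), groups = groups,
                 degenerate = degenerate, stratum = table$stratum,
                 subject_ids = table$subject_ids),
            class = "encoded_matrix")
}

#' @export
print.encoded_matrix <- function(x, ...) {
  cat(sprintf("encoded_matrix: %d subjects x %d dummies (%d variables, %d degenerate)\n",
              nrow(x$data), length(x$columns), length(x$groups),
              length(x$degenerate)))
  invisible(x)
}

#' Admissible predictors for a target dummy
#'
#' Returns every dummy column except the members of the target's own group.
#' Sibling dummies of a one-hot block jointly determine the target (the block
#' row-sums are 1), so admitting them would leak the answer into the
#' predictor set; they are excluded wholesale, target included.
#'
#' @param encoded an [one_hot_encode()] result.
#' @param target a dummy column name.
#' @return character vector of admissible predictor dummy names, in column
#'   order.
#' @export
predictor_mask <- function(encoded, target) {
  stopifnot(inherits(encoded, "encoded_matrix"))
  if (!target %in% encoded.columns(encoded)) stop("unknown target: ", target)
  grp <- group_of(encoded, target)
  setdiff(encoded$columns, encoded$groups[[grp]])
}

encoded.columns <- function(encoded) encoded$columns

# source variable of a dummy column
group_of <- function(encoded, dummy) {
  for (g in names(encoded$groups))
    if (dummy %in% encoded$groups[[g]]) return(g)
  stop("unknown dummy: ", dummy)
}

# fast dummy -> variable lookup table
group_map <- function(encoded) {
  map <- rep(names(encoded$groups), lengths(encoded$groups))
  names(map) <- unlist(encoded$groups, use.names = FALSE)
  map[encoded$columns]
}

#' Decode a one-hot block back to its original column
#'
#' @param encoded an [one_hot_encode()] result.
#' @param variable a source variable name.
#' @return character vector of level labels, one per subject.
#' @export
decode_variable <- function(encoded, variable) {
  cols <- encoded$groups[[variable]]
  if (is.null(cols)) stop("unknown variable: ", variable)
  lev <- substring(cols, nchar(variable) + 2L)
  block <- encoded$data[, cols, drop = FALSE]
  lev[max.col(block, ties.method = "first")]
}
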