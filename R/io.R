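#' Read a categorical survey table from CSV/TSV
#'
#' The delimiter is inferred from the extension (`.tsv`/`.txt` = tab,
#' otherwise comma). All columns are read as character; empty cells and the
#' `na_label` sentinel become the reserved `MISSING` level.
#'
#' @param path input file with a header row.
#' @param stratum_col,id_col optional column designations, see
#'   [categorical_table()].
#' @param na_label cell value treated as missing, in addition to empty cells.
#' @return a [categorical_table()].
#' @export
read_survey <- function(path, stratum_col = NULL, id_col = NULL,
                        na_label = "") {
  if (!file.exists(path)) stop("input file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- data.table::fread(path, sep = sep, colClasses = "character",
                          na.strings = unique(c(na_label, "")),
                          data.table = FALSE, showProgress = FALSE)
  for (col in setdiff(c(stratum_col, id_col), character(0))) {
    if (!col %in% names(df))
      stop("designated column '", col, "' not found in ", path)
  }
  categorical_table(df, stratum_col = stratum_col, id_col = id_col)
}

#' Write an encoded matrix and its group map to TSV
#'
#' The matrix file has the dummy names as header and one 0/1 row per
#' subject; the group map is a two-column TSV `(dummy, variable)`.
#' [read_encoded()] restores the in-memory structure exactly.
#'
#' @param encoded an [one_hot_encode()] result.
#' @param path matrix TSV path.
#' @param groups_path group-map TSV path (default: `path` with a `.groups.tsv`
#'   suffix).
#' @return `path`, invisibly.
#' @export
write_encoded <- function(encoded, path,
                          groups_path = sub("(\\.tsv)?$", ".groups.tsv",
                                            path)[1]) {
  stopifnot(inherits(encoded, "encoded_matrix"))
  data.table::fwrite(as.data.frame(encoded$data), path, sep = "\t")
  gmap <- group_map(encoded)
  data.table::fwrite(data.frame(dummy = names(gmap), variable = unname(gmap)),
                     groups_path, sep = "\t")
  invisible(path)
}

#' Read an encoded matrix written by [write_encoded()]
#'
#' @param path matrix TSV path.
#' @param groups_path group-map TSV path.
#' @return an `encoded_matrix` (without stratum/subject metadata).
#' @export
read_encoded <- function(path, groups_path = sub("(\\.tsv)?$", ".groups.tsv",
                                                 path)[1]) {
  m <- as.matrix(data.table::fread(path, sep = "\t", data.table = FALSE))
  storage.mode(m) <- "integer"
  g <- data.table::fread(groups_path, sep = "\t", data.table = FALSE,
                         colClasses = "character")
  if (!identical(sort(g$dummy), sort(colnames(m))))
    stop("group map does not cover the matrix columns")
  groups <- split(g$dummy, g$variable)
  # restore column-order within groups and variable order of first appearance
  groups <- groups[unique(g$variable)]
  groups <- lapply(groups, function(cols) cols[order(match(cols, colnames(m)))])
  csum <- colSums(m)
  structure(list(data = m, columns = colnames(m), groups = groups,
                 degenerate = colnames(m)[csum == 0L | csum == nrow(m)],
                 stratum = NULL,
                 subject_ids = sprintf("s%d", seq_len(nrow(m)))),
            class = "encoded_matrix")
}

# hub table: node, variable, level, hub_score, rank
hub_table <- function(scores) {
  s <- if (inherits(scores, "hub_scores")) scores$scores else scores
  ord <- order(-s, names(s), method = "radix")
  node <- names(s)[ord]
  data.frame(node = node,
             variable = sub("=[^=]*$", "", node),
             level = sub("^.*=", "", node),
             hub_score = unname(s[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Write a replication report directory
#'
#' Writes, for each stratum, `hub_scores_<stratum>.tsv` (node, variable,
#' level, hub_score, rank) and `auc_<stratum>.tsv`; plus `mean_hub.tsv`
#' (node, mean, sd), `corr.tsv`, `top_k.tsv`, `run_log.txt`, and
#' `config_echo.json`.
#'
#' @param report a [run_pipeline()] report.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "replication_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(dir, ...)
  for (lab in report$strata) {
    data.table::fwrite(hub_table(report$hubs[[lab]]),
                       out(sprintf("hub_scores_%s.tsv", lab)), sep = "\t")
    data.table::fwrite(report$auc_tables[[lab]],
                       out(sprintf("auc_%s.tsv", lab)), sep = "\t")
  }
  data.table::fwrite(data.frame(node = rownames(report$hub_matrix),
                                mean_hub = unname(report$mean_hub),
                                sd_hub = unname(report$sd_hub)),
                     out("mean_hub.tsv"), sep = "\t")
  if (!is.null(report$corr)) {
    cd <- data.frame(stratum = rownames(report$corr), report$corr,
                     check.names = FALSE)
    data.table::fwrite(cd, out("corr.tsv"), sep = "\t")
  }
  data.table::fwrite(report$top_k, out("top_k.tsv"), sep = "\t")
  writeLines(report$log, out("run_log.txt"))
  jsonlite::write_json(report$config, out("config_echo.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
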