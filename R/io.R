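# All on-disk formats are tab-separated text with a header line (except the
# plain N x N adjacency), decimal point, no thousands separators.

#' Validate a node table
#'
#' A node table has one row per ROI: a 0-based contiguous integer id, a
#' short label, MNI-convention coordinates in mm, and a module label. It
#' defines the node order of every matrix in the pipeline.
#'
#' @param x data.frame with columns `roi_id`, `label`, `x`, `y`, `z`, `module`.
#' @return the validated data.frame, invisibly classed `node_table`.
#' @export
as_node_table <- function(x) {
  needed <- c("roi_id", "label", "x", "y", "z", "module")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols)) {
    stop_netreconfig("node table is missing columns: ",
                     paste(missing_cols, collapse = ", "))
  }
  x <- as.data.frame(x)[needed]
  if (anyDuplicated(x$roi_id)) {
    dup <- unique(x$roi_id[duplicated(x$roi_id)])
    stop_netreconfig("duplicate roi_id: ", paste(dup, collapse = ", "))
  }
  if (!is.numeric(x$roi_id) || !identical(as.integer(sort(x$roi_id)),
                                          seq_len(nrow(x)) - 1L)) {
    stop_netreconfig("roi_id must be contiguous integers starting at 0")
  }
  coords <- as.matrix(x[, c("x", "y", "z")])
  if (!is.numeric(coords) || !all(is.finite(coords))) {
    stop_netreconfig("non-numeric or non-finite coordinates in node table")
  }
  if (any(!nzchar(as.character(x$module)))) {
    stop_netreconfig("empty module labels in node table")
  }
  if (nrow(x) < 3) stop_netreconfig("node table needs at least 3 ROIs")
  x$roi_id <- as.integer(x$roi_id)
  x$label <- as.character(x$label)
  x$module <- as.character(x$module)
  class(x) <- c("node_table", "data.frame")
  x
}

#' Read / write a node table TSV
#'
#' @param path file with header columns `roi_id label x y z module`.
#' @return `read_node_table` returns a validated [as_node_table()] table
#'   with the file's row order preserved.
#' @export
read_node_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (all(c("x", "y", "z") %in% names(x))) {
    for (cc in c("x", "y", "z")) {
      v <- suppressWarnings(as.numeric(x[[cc]]))
      if (anyNA(v) && !anyNA(x[[cc]])) {
        stop_netreconfig("non-numeric coordinates in column ", cc)
      }
      x[[cc]] <- v
    }
  }
  as_node_table(x)
}

#' @rdname read_node_table
#' @param nodes a node table.
#' @export
write_node_table <- function(nodes, path) {
  utils::write.table(as.data.frame(nodes), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' ROI time-series container
#'
#' One scan: a T x N matrix of ROI signals (rows = time points, columns =
#' ROIs in node-table order) with its subject, condition, and sampling
#' interval.
#'
#' @param data numeric T x N matrix.
#' @param subject_id subject identifier.
#' @param condition condition label.
#' @param tr_seconds sampling interval in seconds (volume repetition time).
#' @return object of class `scan_series`.
#' @export
scan_series <- function(data, subject_id = "S01", condition = "RS",
                        tr_seconds = 2) {
  data <- as.matrix(data)
  if (nrow(data) < 3) stop_netreconfig("scan needs at least 3 time points")
  if (!all(is.finite(data))) stop_netreconfig("non-finite values in scan series")
  structure(list(subject_id = as.character(subject_id),
                 condition = as.character(condition),
                 data = data, tr_seconds = tr_seconds),
            class = "scan_series")
}

#' Read / write a scan-series TSV
#'
#' The file is T rows x N columns with a header of ROI labels. Column
#' count is validated against the node table: node order is the single
#' source of truth for all matrices.
#'
#' @param path file path.
#' @param nodes node table defining N and the column order.
#' @inheritParams scan_series
#' @return `read_series` returns a [scan_series()].
#' @export
read_series <- function(path, nodes, subject_id = "S01", condition = "RS",
                        tr_seconds = 2) {
  x <- as.matrix(utils::read.delim(path, check.names = FALSE))
  if (ncol(x) != nrow(nodes)) {
    stop_netreconfig("series has ", ncol(x), " columns but node table has ",
                     nrow(nodes), " ROIs")
  }
  if (!is.numeric(x) || !all(is.finite(x))) {
    stop_netreconfig("non-finite or non-numeric entries in series file")
  }
  scan_series(x, subject_id, condition, tr_seconds)
}

#' @rdname read_series
#' @param series a `scan_series`.
#' @export
write_series <- function(series, path, nodes = NULL) {
  m <- series$data
  colnames(m) <- if (!is.null(nodes)) nodes$label else
    colnames(m) %||% paste0("ROI_", seq_len(ncol(m)))
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an N x N adjacency matrix as plain TSV
#'
#' @param path file path.
#' @param nodes optional node table; if given, dimension is validated.
#' @return `read_adjacency` returns a numeric matrix.
#' @export
read_adjacency <- function(path, nodes = NULL) {
  m <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m)) stop_netreconfig("adjacency file is not square")
  if (!is.null(nodes) && nrow(m) != nrow(nodes)) {
    stop_netreconfig("adjacency dimension ", nrow(m),
                     " does not match node table N = ", nrow(nodes))
  }
  m
}

#' @rdname read_adjacency
#' @param adjacency numeric square matrix.
#' @export
write_adjacency <- function(adjacency, path) {
  utils::write.table(adjacency, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a confound matrix TSV
#'
#' T rows x C regressors (e.g. 6 motion parameters plus white-matter and
#' CSF signals) with a header of regressor names.
#'
#' @param path file path.
#' @return list with `data` (T x C matrix) and `names`.
#' @export
read_confounds <- function(path) {
  x <- as.matrix(utils::read.delim(path, check.names = FALSE))
  if (!all(is.finite(x))) stop_netreconfig("non-finite entries in confound file")
  list(data = x, names = colnames(x))
}

#' Write metric records and group statistics to report files
#'
#' Writes a long-format TSV (`subject condition metric value`), a summary
#' TSV with one row per metric (per-condition mean and SD, F, df, p), and
#' a JSON file holding both.
#'
#' @param records data.frame of metric records: columns `subject`,
#'   `condition`, then one column per metric.
#' @param summary data.frame as produced by [summarize_metrics()]; computed
#'   from `records` when omitted.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
write_report <- function(records, summary = NULL, dir = ".",
                         prefix = "metrics") {
  if (is.null(records) || nrow(records) == 0) {
    stop_netreconfig("empty record set")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  long <- metrics_long(records)
  if (is.null(summary)) summary <- summarize_metrics(records)
  p_long <- file.path(dir, paste0(prefix, "_long.tsv"))
  p_sum <- file.path(dir, paste0(prefix, "_summary.tsv"))
  p_json <- file.path(dir, paste0(prefix, ".json"))
  utils::write.table(long, p_long, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(summary, p_sum, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(long = long, summary = summary), p_json,
                       digits = NA, dataframe = "rows")
  invisible(c(long = p_long, summary = p_sum, json = p_json))
}

#' @rdname write_report
#' @param path path of a long-format report file.
#' @export
read_report_long <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Reshape wide metric records to long format
#' @param records wide metric records (`subject`, `condition`, metrics...).
#' @return data.frame with columns `subject`, `condition`, `metric`, `value`.
#' @export
metrics_long <- function(records) {
  metric_cols <- setdiff(names(records), c("subject", "condition"))
  out <- do.call(rbind, lapply(metric_cols, function(mc) {
    data.frame(subject = records$subject,
               condition = as.character(records$condition),
               metric = mc, value = records[[mc]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
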