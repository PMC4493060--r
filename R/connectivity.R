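# Functional-connectivity construction: full Pearson matrix with edgewise
# two-sided p-values, then Bonferroni thresholding over the N(N-1)/2
# unique ROI pairs.

#' Pearson correlation matrix with edgewise p-values
#'
#' Computes the sample Pearson correlation between every pair of ROI time
#' courses and the two-sided p-value of each coefficient from the
#' t-transform `t = r * sqrt((T-2) / (1-r^2))` on `T - 2` degrees of
#' freedom.
#'
#' @param series a [scan_series()] or T x N matrix.
#' @return list of class `correlation_result` with `r` (N x N, unit
#'   diagonal), `p` (N x N, diagonal 1), and `n_timepoints`.
#' @export
pearson_matrix <- function(series) {
  m <- series_data(series)
  n_time <- nrow(m)
  if (n_time < 3) stop_netreconfig("need at least 3 time points")
  sds <- apply(m, 2, stats::sd)
  if (any(sds < 1e-12)) {
    bad <- which(sds < 1e-12)
    lbl <- colnames(m)[bad] %||% as.character(bad)
    stop_netreconfig("zero-variance ROI column(s): ",
                     paste(lbl, collapse = ", "))
  }
  r <- stats::cor(m)
  r <- (r + t(r)) / 2
  r[r > 1] <- 1
  r[r < -1] <- -1
  df <- n_time - 2
  tval <- abs(r) * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(tval, df = df, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  diag(r) <- 1
  diag(p) <- 1
  dimnames(r) <- dimnames(p) <- NULL
  structure(list(r = r, p = p, n_timepoints = n_time),
            class = "correlation_result")
}

#' Bonferroni-corrected edgewise p-threshold
#'
#' The familywise level is divided by the number of unique ROI pairs,
#' `N (N - 1) / 2` (12720 for a 160-node network at alpha = 0.05).
#'
#' @param n_nodes number of network nodes N.
#' @param alpha familywise error level.
#' @return the per-edge p-value threshold.
#' @export
bonferroni_alpha <- function(n_nodes, alpha = 0.05) {
  alpha / (n_nodes * (n_nodes - 1) / 2)
}

#' Network container
#'
#' @param adjacency symmetric N x N matrix with zero diagonal; entries in
#'   \{0, 1\} for binary mode, non-negative for weighted mode.
#' @param mode `"binary"` or `"weighted"`.
#' @param node_table optional node table the adjacency refers to.
#' @return object of class `fc_network`.
#' @export
fc_network <- function(adjacency, mode = c("binary", "weighted"),
                       node_table = NULL) {
  mode <- match.arg(mode)
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency)) {
    stop_netreconfig("adjacency must be square")
  }
  if (max(abs(adjacency - t(adjacency))) > 1e-12) {
    stop_netreconfig("adjacency must be symmetric")
  }
  if (any(diag(adjacency) != 0)) stop_netreconfig("self-loops are not allowed")
  if (mode == "binary" && !all(adjacency %in% c(0, 1))) {
    stop_netreconfig("binary adjacency entries must be 0 or 1")
  }
  if (mode == "weighted" && any(adjacency < 0)) {
    stop_netreconfig("weighted adjacency entries must be non-negative")
  }
  if (!is.null(node_table) && nrow(node_table) != nrow(adjacency)) {
    stop_netreconfig("adjacency dimension ", nrow(adjacency),
                     " does not match node table N = ", nrow(node_table))
  }
  structure(list(adjacency = unname(adjacency), mode = mode,
                 node_table = node_table),
            class = "fc_network")
}

as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(
    net$adjacency, mode = "undirected",
    weighted = if (net$mode == "weighted") TRUE else NULL,
    diag = FALSE)
}

n_nodes <- function(net) nrow(net$adjacency)

n_edges <- function(net) sum(net$adjacency[upper.tri(net$adjacency)] > 0)

#' Binary network by Bonferroni thresholding
#'
#' Edge (i, j) is present iff `p_ij < alpha / (N (N-1) / 2)` (strict
#' inequality) and, when `positive_only`, `r_ij > 0`. Edge retention is
#' sign-agnostic by default.
#'
#' @param corr a [pearson_matrix()] result.
#' @param alpha familywise error level.
#' @param positive_only drop negatively correlated edges.
#' @param node_table optional node table.
#' @return binary [fc_network()].
#' @export
bonferroni_threshold <- function(corr, alpha = 0.05, positive_only = FALSE,
                                 node_table = NULL) {
  n <- nrow(corr$p)
  keep <- corr$p < bonferroni_alpha(n, alpha)
  if (positive_only) keep <- keep & (corr$r > 0)
  a <- keep * 1
  diag(a) <- 0
  fc_network(a, "binary", node_table)
}

#' Weighted network on the Bonferroni-surviving edge set
#'
#' Same edge set as [bonferroni_threshold()]; surviving edges carry weight
#' `|r_ij|` so that edge lengths `1/w` are well defined.
#'
#' @inheritParams bonferroni_threshold
#' @return weighted [fc_network()].
#' @export
weighted_network <- function(corr, alpha = 0.05, positive_only = FALSE,
                             node_table = NULL) {
  bin <- bonferroni_threshold(corr, alpha, positive_only, node_table)
  fc_network(bin$adjacency * abs(corr$r), "weighted", node_table)
}
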