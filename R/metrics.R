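# Global and nodal graph parameters. Binary definitions follow the
# standard complex-network conventions (Rubinov & Sporns): clustering of
# degree-<2 nodes is 0 and enters the mean; Lp averages finite distances
# only (the unreachable fraction is reported alongside); the efficiency
# family uses 1/Inf = 0. The weighted variant uses node strength, Onnela
# clustering, and shortest paths over edge lengths 1/w.

#' Degree statistics
#'
#' @param net an [fc_network()].
#' @return list with `K` (mean degree for binary networks, mean strength
#'   for weighted ones) and `degree` (the per-node vector).
#' @export
degree_stats <- function(net) {
  deg <- rowSums(net$adjacency)
  list(K = mean(deg), degree = deg)
}

binary_support <- function(net) (net$adjacency > 0) * 1

#' Clustering coefficient
#'
#' Binary: `C_i = 2 E_i / (k_i (k_i - 1))` with `E_i` the edges among the
#' neighbours of i, 0 when `k_i < 2`. Weighted: Onnela's geometric-mean
#' triangle intensity on weights rescaled by the maximum weight. `Cp` is
#' the mean over all N nodes.
#'
#' @param net an [fc_network()].
#' @return list with `Cp` and `per_node`.
#' @export
clustering_coef <- function(net) {
  A <- binary_support(net)
  k <- rowSums(A)
  H <- if (net$mode == "weighted") {
    mx <- max(net$adjacency)
    if (mx > 0) (net$adjacency / mx)^(1 / 3) else net$adjacency
  } else A
  tri2 <- diag(H %*% H %*% H) # twice the (intensity-weighted) triangle count
  per_node <- ifelse(k < 2, 0, tri2 / (k * (k - 1)))
  list(Cp = mean(per_node), per_node = per_node)
}

#' Shortest-path statistics
#'
#' Binary: breadth-first hop counts. Weighted: minimal sums of edge
#' lengths `1/w`. Unreachable pairs are `Inf`.
#'
#' @param net an [fc_network()].
#' @return list of class `path_stats` with `d` (N x N distance matrix) and
#'   `reachable_fraction` (share of distinct ordered pairs at finite
#'   distance).
#' @export
shortest_paths <- function(net) {
  g <- as_igraph(net)
  w <- if (net$mode == "weighted") 1 / igraph::E(g)$weight else NA
  d <- igraph::distances(g, weights = w)
  dimnames(d) <- NULL
  n <- nrow(d)
  off <- d[upper.tri(d)]
  structure(list(d = d,
                 reachable_fraction = if (n > 1) mean(is.finite(off)) else 1),
            class = "path_stats")
}

#' Characteristic path length
#'
#' Mean of `d_ij` over all unordered pairs at finite distance; errors when
#' the graph has no edges at all. The unreachable share is available from
#' the `path_stats` input.
#'
#' @param paths a [shortest_paths()] result.
#' @return Lp.
#' @export
char_path_length <- function(paths) {
  off <- paths$d[upper.tri(paths$d)]
  fin <- off[is.finite(off) & off > 0]
  if (!length(fin)) {
    stop_netreconfig("characteristic path length undefined: no connected pairs")
  }
  mean(fin)
}

#' Global efficiency
#'
#' Mean over all unordered pairs of `1 / d_ij`, with `1/Inf = 0`.
#'
#' @param paths a [shortest_paths()] result.
#' @return Eglob in `[0, 1]` for binary networks.
#' @export
global_efficiency <- function(paths) {
  n <- nrow(paths$d)
  if (n < 2) return(0)
  off <- paths$d[upper.tri(paths$d)]
  inv <- ifelse(is.finite(off) & off > 0, 1 / off, 0)
  mean(inv)
}

#' Nodal efficiency
#'
#' `Enod_i = (1 / (N-1)) * sum_{j != i} 1 / d_ij`, with unreachable terms 0.
#'
#' @param paths a [shortest_paths()] result.
#' @return list with `Enod` (per-node vector) .
#' @export
nodal_efficiency <- function(paths) {
  d <- paths$d
  inv <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
  diag(inv) <- 0
  list(Enod = rowSums(inv) / (nrow(d) - 1))
}

subgraph_efficiency <- function(net, idx) {
  sub <- fc_network(net$adjacency[idx, idx, drop = FALSE], net$mode)
  global_efficiency(shortest_paths(sub))
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced by
#' each node's neighbours (the node itself excluded); 0 for nodes with
#' fewer than 2 neighbours.
#'
#' @param net an [fc_network()].
#' @return list with `Eloc` and `per_node`.
#' @export
local_efficiency <- function(net) {
  A <- binary_support(net)
  n <- nrow(A)
  per_node <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) return(0)
    subgraph_efficiency(net, nb)
  }, numeric(1))
  list(Eloc = mean(per_node), per_node = per_node)
}

#' Average physical distance of existing connections
#'
#' Mean over present edges of the Euclidean distance in mm between the two
#' ROIs' coordinates — a wiring-cost proxy. Edge presence only; weights
#' are ignored.
#'
#' @param net an [fc_network()].
#' @param node_table node table with `x`, `y`, `z` in mm; defaults to the
#'   table attached to the network.
#' @return Dp in mm.
#' @export
physical_distance <- function(net, node_table = net$node_table) {
  if (is.null(node_table)) stop_netreconfig("node coordinates are required")
  A <- binary_support(net)
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    stop_netreconfig("physical distance undefined: network has no edges")
  }
  xyz <- as.matrix(node_table[, c("x", "y", "z")])
  mean(sqrt(rowSums((xyz[idx[, 1], , drop = FALSE] -
                       xyz[idx[, 2], , drop = FALSE])^2)))
}

#' Newman modularity of the best partition found
#'
#' Louvain-style greedy optimisation restarted under random node
#' permutations; the partition with the largest Q over all restarts (and
#' over the trivial one-community partition, which scores 0) is returned,
#' so the reported Q is never negative on a graph with edges.
#'
#' @param net an [fc_network()].
#' @param n_restarts optimiser restarts (default 100).
#' @param seed RNG seed for the restart permutations.
#' @return list with `Q` and `membership` (integer community labels).
#' @export
modularity_partition <- function(net, n_restarts = 100, seed = NULL) {
  if (n_edges(net) == 0) {
    stop_netreconfig("modularity undefined: network has no edges")
  }
  g <- as_igraph(net)
  w <- if (net$mode == "weighted") igraph::E(g)$weight else NULL
  n <- n_nodes(net)
  with_seed(seed, {
    best_q <- 0
    best_members <- rep(1L, n)
    for (r in seq_len(max(1, n_restarts))) {
      perm <- sample.int(n)
      gp <- igraph::permute(g, perm)
      wp <- if (is.null(w)) NULL else igraph::E(gp)$weight
      cl <- igraph::cluster_louvain(gp, weights = wp)
      memb <- igraph::membership(cl)[perm]
      q <- igraph::modularity(g, memb, weights = w)
      if (q > best_q) {
        best_q <- q
        best_members <- as.integer(memb)
      }
    }
    list(Q = best_q, membership = best_members)
  })
}

#' Full metric suite for one network
#'
#' Computes the global parameter set (K, Cp, Lp, Eloc, Eglob, Dp, Q), the
#' nodal efficiency vector, and optionally the small-worldness summary
#' (against a rewired null ensemble) and the targeted-attack robustness.
#'
#' @param net an [fc_network()].
#' @param node_table node table (coordinates for Dp).
#' @param n_nulls rewired nulls for sigma; 0 skips the null ensemble.
#' @param swaps_per_edge double-edge-swap attempts per edge in the nulls.
#' @param n_restarts modularity restarts.
#' @param robustness compute the targeted-attack curve and R.
#' @param seed RNG seed covering nulls and modularity restarts.
#' @return list with `global` (named numeric vector), `Enod`, `membership`,
#'   and, when requested, `null_summary` and `attack`.
#' @export
network_metrics <- function(net, node_table = net$node_table,
                            n_nulls = 0, swaps_per_edge = 10,
                            n_restarts = 100, robustness = TRUE,
                            seed = NULL) {
  seeds <- derive_seeds(seed %||% sample.int(2147483646L, 1),
                        c("modularity", "nulls"))
  paths <- shortest_paths(net)
  deg <- degree_stats(net)
  clus <- clustering_coef(net)
  eloc <- local_efficiency(net)
  enod <- nodal_efficiency(paths)$Enod
  mod <- modularity_partition(net, n_restarts, seed = seeds[["modularity"]])
  global <- c(K = deg$K, Cp = clus$Cp, Lp = char_path_length(paths),
              Eloc = eloc$Eloc, Eglob = global_efficiency(paths),
              Dp = physical_distance(net, node_table), Q = mod$Q)
  out <- list(global = global, Enod = enod, membership = mod$membership,
              reachable_fraction = paths$reachable_fraction)
  if (n_nulls > 0) {
    ns <- null_ensemble(net, n_nulls = n_nulls,
                        swaps_per_edge = swaps_per_edge,
                        seed = seeds[["nulls"]])
    out$null_summary <- ns
    out$global <- c(out$global, sigma = ns$sigma, gamma = ns$gamma,
                    lambda = ns$lambda)
  }
  if (isTRUE(robustness)) {
    att <- attack_curve(net, enod = enod)
    out$attack <- att
    out$global <- c(out$global, R = robustness_auc(att))
  }
  out
}
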