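# Degree-preserving null models (Maslov-Sneppen double-edge swaps) and
# targeted-attack robustness.

#' Degree-preserving rewiring
#'
#' Repeated double-edge swaps: two edges (a,b), (c,d) are replaced by
#' (a,d), (c,b) whenever no self-loop or duplicate edge would result.
#' `swaps_per_edge * E` swaps are attempted, leaving every node's degree
#' and the edge count exactly unchanged. Graphs with no legal swap (e.g. a
#' complete graph) are returned unchanged. For weighted networks the
#' binary support is rewired and the original weight multiset is randomly
#' permuted onto the new edge set.
#'
#' @param net an [fc_network()].
#' @param swaps_per_edge swap attempts per edge (default 10).
#' @param seed RNG seed.
#' @return rewired [fc_network()] of the same mode.
#' @export
maslov_rewire <- function(net, swaps_per_edge = 10, seed = NULL) {
  e <- n_edges(net)
  if (e < 2) return(net)
  with_seed(seed, {
    g <- igraph::graph_from_adjacency_matrix(binary_support(net),
                                             mode = "undirected", diag = FALSE)
    g2 <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                   niter = swaps_per_edge * e))
    a <- as.matrix(igraph::as_adjacency_matrix(g2, type = "both"))
    dimnames(a) <- NULL
    if (net$mode == "weighted") {
      w <- net$adjacency[upper.tri(net$adjacency) & net$adjacency > 0]
      up <- which(upper.tri(a) & a > 0)
      a[up] <- sample(w)
      a[lower.tri(a)] <- 0
      a <- a + t(a)
    }
    fc_network(a, net$mode, net$node_table)
  })
}

null_cp_lp <- function(net) {
  cl <- clustering_coef(net)
  paths <- shortest_paths(net)
  off <- paths$d[upper.tri(paths$d)]
  fin <- off[is.finite(off) & off > 0]
  c(Cp = cl$Cp, Lp = if (length(fin)) mean(fin) else NA_real_)
}

#' Small-worldness against a rewired null ensemble
#'
#' `Cp_rand` and `Lp_rand` are means over `n_nulls` independent
#' degree-preserving rewirings of the network; `gamma = Cp / Cp_rand`,
#' `lambda = Lp / Lp_rand`, `sigma = gamma / lambda`. A network is called
#' small-world when sigma > 1 (clustering above, path length near, the
#' degree-matched random expectation).
#'
#' @param net an [fc_network()] with at least one edge.
#' @param n_nulls ensemble size (default 100).
#' @param swaps_per_edge swap attempts per edge per null.
#' @param seed RNG seed.
#' @return list of class `null_summary` with `Cp_rand`, `Lp_rand`,
#'   `gamma`, `lambda`, `sigma`.
#' @export
null_ensemble <- function(net, n_nulls = 100, swaps_per_edge = 10,
                          seed = NULL) {
  if (n_edges(net) == 0) stop_netreconfig("null ensemble needs a non-empty network")
  real <- null_cp_lp(net)
  seeds <- with_seed(seed, sample.int(2147483646L, n_nulls))
  vals <- vapply(seq_len(n_nulls), function(i) {
    null_cp_lp(maslov_rewire(net, swaps_per_edge, seed = seeds[i]))
  }, numeric(2))
  cp_rand <- mean(vals["Cp", ])
  lp_rand <- mean(vals["Lp", ], na.rm = TRUE)
  if (!is.finite(cp_rand) || cp_rand <= 0) {
    stop_netreconfig("sigma undefined: null networks are triangle-free ",
                     "(Cp_rand = 0)")
  }
  if (!is.finite(lp_rand) || lp_rand <= 0) {
    stop_netreconfig("sigma undefined: null networks have no connected pairs")
  }
  gamma <- real[["Cp"]] / cp_rand
  lambda <- real[["Lp"]] / lp_rand
  structure(list(Cp_rand = cp_rand, Lp_rand = lp_rand,
                 gamma = gamma, lambda = lambda, sigma = gamma / lambda),
            class = "null_summary")
}

#' Targeted-attack curve
#'
#' Nodes are ranked once on the intact network by decreasing nodal
#' efficiency (ties broken by ascending node index) and removed
#' cumulatively; `s_k` is the size of the largest connected component
#' after the top-k removals, for k = 0..N-1.
#'
#' @param net an [fc_network()].
#' @param enod nodal-efficiency vector; computed from the network when
#'   omitted.
#' @return list of class `attack_result` with `attack_order` (1-based node
#'   indices in removal order) and `curve` (length N, `s_0` first).
#' @export
attack_curve <- function(net, enod = NULL) {
  n <- n_nodes(net)
  if (is.null(enod)) enod <- nodal_efficiency(shortest_paths(net))$Enod
  ord <- order(-enod, seq_len(n))
  g <- igraph::graph_from_adjacency_matrix(binary_support(net),
                                           mode = "undirected", diag = FALSE)
  igraph::V(g)$orig <- seq_len(n)
  curve <- numeric(n)
  curve[1] <- max(igraph::components(g)$csize)
  for (k in seq_len(n - 1)) {
    g <- igraph::delete_vertices(g, which(igraph::V(g)$orig == ord[k]))
    curve[k + 1] <- max(igraph::components(g)$csize)
  }
  structure(list(attack_order = ord, curve = curve), class = "attack_result")
}

#' Robustness: area under the attack curve
#'
#' `R = (1/N) * sum_{k=0}^{N-1} s_k`. The intact network contributes the
#' k = 0 term, so R is bounded by `(N+1)/2`, attained only by a complete
#' graph (80.5 for N = 160).
#'
#' @param result an [attack_curve()] result.
#' @return R.
#' @export
robustness_auc <- function(result) {
  sum(result$curve) / length(result$curve)
}
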