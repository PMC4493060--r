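# Independent brute-force oracles used against the package's graph
# metrics. Everything here is deliberately naive: Floyd-Warshall instead
# of BFS, explicit neighbour enumeration, exhaustive partition search.

adj_from_edges <- function(n, edges) {
  a <- matrix(0, n, n)
  for (e in edges) {
    a[e[1], e[2]] <- 1
    a[e[2], e[1]] <- 1
  }
  a
}

complete_adj <- function(n) {
  a <- matrix(1, n, n)
  diag(a) <- 0
  a
}

path_adj <- function(n) {
  adj_from_edges(n, lapply(seq_len(n - 1), function(i) c(i, i + 1)))
}

rand_adj <- function(n, p) {
  a <- matrix(0, n, n)
  up <- which(upper.tri(a))
  a[up] <- stats::rbinom(length(up), 1, p)
  a + t(a)
}

toy_nodes <- function(n, coords = NULL) {
  if (is.null(coords)) coords <- matrix(stats::rnorm(3 * n, sd = 20), ncol = 3)
  as_node_table(data.frame(roi_id = seq_len(n) - 1L,
                           label = paste0("N", seq_len(n)),
                           x = coords[, 1], y = coords[, 2], z = coords[, 3],
                           module = "M1"))
}

bf_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  d[a > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

bf_clustering <- function(a) {
  n <- nrow(a)
  per <- vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    e_i <- sum(a[nb, nb]) / 2
    2 * e_i / (k * (k - 1))
  }, numeric(1))
  list(per_node = per, Cp = mean(per))
}

bf_lp <- function(a) {
  d <- bf_distances(a)
  off <- d[upper.tri(d)]
  mean(off[is.finite(off)])
}

bf_global_eff <- function(a) {
  d <- bf_distances(a)
  off <- d[upper.tri(d)]
  if (!length(off)) return(0)
  mean(ifelse(is.finite(off), 1 / off, 0))
}

bf_nodal_eff <- function(a) {
  d <- bf_distances(a)
  n <- nrow(a)
  vapply(seq_len(n), function(i) {
    inv <- 1 / d[i, -i]
    sum(inv[is.finite(inv)]) / (n - 1)
  }, numeric(1))
}

bf_local_eff <- function(a) {
  n <- nrow(a)
  per <- vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] > 0)
    if (length(nb) < 2) return(0)
    bf_global_eff(a[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(per)
}

# Newman modularity of a given membership vector, straight from the
# definition Q = (1/2m) sum_ij (A_ij - k_i k_j / 2m) delta(c_i, c_j).
bf_modularity_score <- function(a, memb) {
  m2 <- sum(a)
  k <- rowSums(a)
  same <- outer(memb, memb, `==`)
  sum((a - outer(k, k) / m2)[same]) / m2
}

# All set partitions of n elements as restricted-growth membership vectors.
enumerate_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, mx) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(mx + 1L)) rec(c(prefix, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

bf_best_modularity <- function(a) {
  best <- -Inf
  for (memb in enumerate_partitions(nrow(a))) {
    q <- bf_modularity_score(a, memb)
    if (q > best) best <- q
  }
  best
}

# Repeated-measures ANOVA by explicit sums-of-squares partition.
rm_anova_oracle <- function(values) {
  s <- nrow(values)
  cc <- ncol(values)
  grand <- mean(values)
  ss_subj <- cc * sum((rowMeans(values) - grand)^2)
  ss_cond <- s * sum((colMeans(values) - grand)^2)
  ss_tot <- sum((values - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_cond
  df1 <- cc - 1
  df2 <- (cc - 1) * (s - 1)
  f <- (ss_cond / df1) / (ss_err / df2)
  list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# A small cohort with loadings strong enough that even the lowest
# condition produces clustered networks: used by pipeline-level tests
# that need every stage (including the null ensemble) to be defined.
strong_sim_cfg <- function(n_subjects = 6, n_rois = 48, n_timepoints = 150,
                          n_modules = 3, ...) {
  args <- list(n_subjects = n_subjects, n_rois = n_rois,
               n_timepoints = n_timepoints, n_modules = n_modules,
               lambda_within = c(0.62, 0.72, 0.82),
               lambda_global = c(0.20, 0.30, 0.40))
  do.call(sim_config, utils::modifyList(args, list(...)))
}
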