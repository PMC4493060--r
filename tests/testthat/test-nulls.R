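test_that("rewiring conserves the degree sequence exactly", {
  set.seed(40)
  for (rep in 1:100) {
    a <- rand_adj(sample(6:20, 1), runif(1, 0.15, 0.6))
    net <- fc_network(a)
    null <- maslov_rewire(net, swaps_per_edge = 10, seed = rep)
    expect_equal(rowSums(null$adjacency), rowSums(a))
    expect_equal(sum(null$adjacency), sum(a))
  }
})

test_that("graphs with no legal swap are returned unchanged", {
  k5 <- fc_network(complete_adj(5))
  out <- maslov_rewire(k5, swaps_per_edge = 50, seed = 1)
  expect_equal(out$adjacency, k5$adjacency)
})

test_that("rewiring a 6-cycle can reach the two-triangle configuration", {
  # the only 2-regular graphs on 6 nodes are the 6-cycle and two disjoint
  # triangles; with enough swap attempts both must occur across seeds
  ring6 <- fc_network(adj_from_edges(6, list(c(1, 2), c(2, 3), c(3, 4),
                                             c(4, 5), c(5, 6), c(6, 1))))
  hit <- 0
  for (seed in 1:40) {
    out <- maslov_rewire(ring6, swaps_per_edge = 30, seed = seed)
    n_tri <- sum(diag(out$adjacency %*% out$adjacency %*% out$adjacency)) / 6
    expect_true(n_tri %in% c(0, 2))
    if (n_tri == 2) hit <- hit + 1
  }
  expect_gt(hit, 0)
})

test_that("weighted rewiring preserves strengthless support and the weight multiset", {
  set.seed(41)
  a <- rand_adj(12, 0.4)
  w <- a * matrix(runif(144, 0.2, 0.9), 12)
  w <- pmax(w, t(w)) * ((a + t(a)) > 0)
  w <- (w + t(w)) / 2
  net <- fc_network(w, "weighted")
  null <- maslov_rewire(net, 10, seed = 3)
  expect_equal(rowSums(null$adjacency > 0), rowSums(w > 0))
  expect_equal(sort(null$adjacency[upper.tri(w) & null$adjacency > 0]),
               sort(w[upper.tri(w) & w > 0]))
})

test_that("the null ensemble recovers the small-world signature", {
  # complete graph: nulls are identical to the input
  k6 <- fc_network(complete_adj(6))
  ns <- null_ensemble(k6, n_nulls = 10, seed = 1)
  expect_equal(ns$gamma, 1)
  expect_equal(ns$lambda, 1)
  expect_equal(ns$sigma, 1)

  # ring lattice with 5% shortcuts: sigma > 1 for every seed
  ring_lattice <- function(n, k) {
    a <- matrix(0, n, n)
    for (i in seq_len(n)) {
      for (s in seq_len(k / 2)) {
        j <- ((i - 1 + s) %% n) + 1
        a[i, j] <- a[j, i] <- 1
      }
    }
    a
  }
  for (seed in 1:10) {
    a <- ring_lattice(100, 6)
    set.seed(seed)
    drop <- sample(which(upper.tri(a) & a > 0), 15)
    gain <- sample(which(upper.tri(a) & a == 0), 15)
    a[drop] <- 0
    a[gain] <- 1
    a[lower.tri(a)] <- 0
    a <- a + t(a)
    ws <- fc_network(a)
    expect_gt(null_ensemble(ws, n_nulls = 10, seed = 100 + seed)$sigma, 1)
  }

  # Erdos-Renyi is its own null up to fluctuation
  for (seed in 1:10) {
    set.seed(1000 + seed)
    er <- fc_network(rand_adj(100, 0.1))
    sg <- null_ensemble(er, n_nulls = 10, seed = 2000 + seed)$sigma
    expect_gt(sg, 0.7)
    expect_lt(sg, 1.4)
  }

  expect_error(null_ensemble(fc_network(matrix(0, 4, 4))), "non-empty")
  # triangle-free graphs whose nulls stay triangle-free: sigma undefined
  star <- fc_network(adj_from_edges(4, list(c(1, 2), c(1, 3), c(1, 4))))
  expect_error(null_ensemble(star, n_nulls = 5, seed = 1), "triangle-free")
})

test_that("targeted attack removes high-efficiency nodes first", {
  expect_equal(attack_curve(fc_network(complete_adj(4)))$curve, c(4, 3, 2, 1))
  star <- fc_network(adj_from_edges(4, list(c(1, 2), c(1, 3), c(1, 4))))
  res <- attack_curve(star)
  expect_equal(res$attack_order[1], 1) # hub has the highest nodal efficiency
  expect_equal(res$curve, c(4, 1, 1, 1))
  empty3 <- fc_network(matrix(0, 3, 3))
  expect_equal(attack_curve(empty3)$curve, c(1, 1, 1))
})

test_that("robustness is the normalized area under the attack curve", {
  expect_equal(robustness_auc(attack_curve(fc_network(complete_adj(4)))), 2.5)
  star <- fc_network(adj_from_edges(4, list(c(1, 2), c(1, 3), c(1, 4))))
  expect_equal(robustness_auc(attack_curve(star)), 1.75)
  # attack curves never dip below the singleton floor nor above N - k
  set.seed(42)
  for (rep in 1:10) {
    net <- fc_network(rand_adj(15, 0.2))
    curve <- attack_curve(net)$curve
    expect_true(all(diff(curve) <= 0))
    expect_true(all(curve <= 15 - (seq_along(curve) - 1)))
    expect_true(all(curve >= 1))
  }
})

test_that("targeted attack is at least as damaging as random removal", {
  set.seed(43)
  random_auc <- function(net, order) {
    g <- igraph::graph_from_adjacency_matrix(net$adjacency, "undirected")
    igraph::V(g)$orig <- seq_len(nrow(net$adjacency))
    curve <- max(igraph::components(g)$csize)
    for (k in seq_len(length(order) - 1)) {
      g <- igraph::delete_vertices(g, which(igraph::V(g)$orig == order[k]))
      curve <- c(curve, max(igraph::components(g)$csize))
    }
    sum(curve) / length(curve)
  }
  diffs <- replicate(20, {
    net <- fc_network(rand_adj(25, 0.15))
    r_targ <- robustness_auc(attack_curve(net))
    r_rand <- mean(replicate(10, random_auc(net, sample(25))))
    r_rand - r_targ
  })
  expect_gt(mean(diffs), 0)
})
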