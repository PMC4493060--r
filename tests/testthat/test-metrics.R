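k4 <- fc_network(complete_adj(4))
p4 <- fc_network(path_adj(4))
tri_pendant <- fc_network(adj_from_edges(4, list(c(1, 2), c(2, 3), c(1, 3),
                                                 c(1, 4))))

test_that("degree, clustering, and path metrics match hand-computed values", {
  expect_equal(degree_stats(k4)$K, 3)
  expect_equal(degree_stats(fc_network(matrix(0, 5, 5)))$K, 0)
  two_tri_bridge <- fc_network(adj_from_edges(6, list(
    c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6), c(3, 4))))
  expect_equal(degree_stats(two_tri_bridge)$K, 7 / 3)

  expect_equal(clustering_coef(k4)$Cp, 1)
  expect_equal(clustering_coef(p4)$Cp, 0)
  cl <- clustering_coef(tri_pendant)
  expect_equal(cl$per_node, c(1 / 3, 1, 1, 0))
  expect_equal(cl$Cp, 7 / 12)

  expect_true(all(shortest_paths(k4)$d[upper.tri(diag(4))] == 1))
  expect_equal(shortest_paths(p4)$d[1, 4], 3)

  expect_equal(char_path_length(shortest_paths(k4)), 1)
  expect_equal(char_path_length(shortest_paths(p4)), 10 / 6)
  two_edges <- fc_network(adj_from_edges(4, list(c(1, 2), c(3, 4))))
  paths <- shortest_paths(two_edges)
  expect_equal(char_path_length(paths), 1)
  expect_equal(paths$reachable_fraction, 2 / 6)
  expect_error(char_path_length(shortest_paths(fc_network(matrix(0, 3, 3)))),
               "no connected pairs")
})

test_that("efficiency family matches hand-computed values and conventions", {
  expect_equal(global_efficiency(shortest_paths(k4)), 1)
  expect_equal(global_efficiency(shortest_paths(p4)), 13 / 18)
  expect_equal(global_efficiency(shortest_paths(fc_network(matrix(0, 4, 4)))), 0)

  expect_equal(local_efficiency(k4)$Eloc, 1)
  star <- fc_network(adj_from_edges(4, list(c(1, 2), c(1, 3), c(1, 4))))
  expect_equal(local_efficiency(star)$Eloc, 0)
  expect_equal(local_efficiency(tri_pendant)$Eloc,
               bf_local_eff(tri_pendant$adjacency))

  expect_equal(nodal_efficiency(shortest_paths(k4))$Enod, rep(1, 4))
  expect_equal(nodal_efficiency(shortest_paths(p4))$Enod[1], 11 / 18)
  iso <- fc_network(adj_from_edges(3, list(c(1, 2))))
  expect_equal(nodal_efficiency(shortest_paths(iso))$Enod[3], 0)
})

test_that("physical distance averages Euclidean edge lengths in mm", {
  nodes3 <- toy_nodes(3, coords = rbind(c(0, 0, 0), c(3, 4, 0), c(0, 0, 9)))
  net <- fc_network(adj_from_edges(3, list(c(1, 2))))
  expect_equal(physical_distance(net, nodes3), 5)
  tri <- fc_network(complete_adj(3))
  nodes_line <- toy_nodes(3, coords = rbind(c(0, 0, 0), c(0, 0, 2),
                                            c(0, 0, 4)))
  expect_equal(physical_distance(tri, nodes_line), 8 / 3)
  dup <- toy_nodes(3, coords = matrix(1, 3, 3))
  expect_equal(physical_distance(tri, dup), 0)
  expect_error(physical_distance(fc_network(matrix(0, 3, 3)), nodes_line),
               "no edges")
})

test_that("modularity scores known partitions and finds small-graph optima", {
  two_tri <- fc_network(adj_from_edges(6, list(c(1, 2), c(2, 3), c(1, 3),
                                               c(4, 5), c(5, 6), c(4, 6))))
  # direct evaluation of the definition on the component partition
  expect_equal(bf_modularity_score(two_tri$adjacency, c(1, 1, 1, 2, 2, 2)),
               0.5)
  res <- modularity_partition(two_tri, n_restarts = 20, seed = 1)
  expect_equal(res$Q, 0.5)
  # all-in-one partition scores exactly 0
  expect_equal(bf_modularity_score(two_tri$adjacency, rep(1, 6)), 0)

  set.seed(30)
  for (rep in 1:15) {
    n <- sample(5:8, 1)
    a <- rand_adj(n, 0.4)
    if (sum(a) == 0) next
    found <- modularity_partition(fc_network(a), n_restarts = 50,
                                  seed = rep)$Q
    expect_equal(found, bf_best_modularity(a), tolerance = 1e-12)
  }
  expect_error(modularity_partition(fc_network(matrix(0, 4, 4))), "no edges")
})

test_that("binary metrics agree with brute-force oracles on random graphs", {
  set.seed(31)
  for (rep in 1:60) {
    n <- sample(4:12, 1)
    a <- rand_adj(n, runif(1, 0.15, 0.7))
    net <- fc_network(a)
    expect_equal(shortest_paths(net)$d, bf_distances(a))
    expect_equal(clustering_coef(net)$per_node, bf_clustering(a)$per_node,
                 tolerance = 1e-12)
    expect_equal(local_efficiency(net)$Eloc, bf_local_eff(a),
                 tolerance = 1e-12)
    expect_equal(nodal_efficiency(shortest_paths(net))$Enod, bf_nodal_eff(a),
                 tolerance = 1e-12)
  }
})

test_that("adding an edge never decreases global efficiency or increases distances", {
  set.seed(32)
  for (rep in 1:25) {
    a <- rand_adj(9, 0.25)
    absent <- which(upper.tri(a) & a == 0)
    if (!length(absent)) next
    pick <- sample(absent, 1)
    b <- a
    b[pick] <- 1
    b <- pmax(b, t(b))
    d_a <- shortest_paths(fc_network(a))$d
    d_b <- shortest_paths(fc_network(b))$d
    fin <- is.finite(d_a)
    expect_true(all(d_b[fin] <= d_a[fin]))
    expect_gte(global_efficiency(shortest_paths(fc_network(b))),
               global_efficiency(shortest_paths(fc_network(a))))
  }
})

test_that("weighted metrics reduce to binary on 0/1 weights and match hand values", {
  set.seed(33)
  a <- rand_adj(8, 0.4)
  bin <- fc_network(a, "binary")
  wt <- fc_network(a, "weighted")
  expect_equal(degree_stats(wt)$K, degree_stats(bin)$K)
  expect_equal(clustering_coef(wt)$Cp, clustering_coef(bin)$Cp,
               tolerance = 1e-12)
  expect_equal(shortest_paths(wt)$d, shortest_paths(bin)$d)
  expect_equal(local_efficiency(wt)$Eloc, local_efficiency(bin)$Eloc,
               tolerance = 1e-12)
  expect_equal(modularity_partition(wt, 20, seed = 2)$Q,
               modularity_partition(bin, 20, seed = 2)$Q, tolerance = 1e-12)

  # two nodes, one edge of weight 0.5: strength, distance, efficiency
  pair <- fc_network(matrix(c(0, 0.5, 0.5, 0), 2, 2), "weighted")
  expect_equal(degree_stats(pair)$degree, c(0.5, 0.5))
  expect_equal(shortest_paths(pair)$d[1, 2], 2)
  expect_equal(global_efficiency(shortest_paths(pair)), 0.5)

  # equal-weight triangle: Onnela clustering is 1 after max-rescaling
  w <- 0.4
  triw <- fc_network(complete_adj(3) * w, "weighted")
  expect_equal(clustering_coef(triw)$Cp, 1, tolerance = 1e-12)
})
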