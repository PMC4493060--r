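test_that("module assignment splits ROIs as evenly as possible", {
  nt <- make_node_table(sim_config(n_rois = 6, n_modules = 6), seed = 1)
  expect_equal(as.vector(table(nt$module)), rep(1, 6))
  nt160 <- make_node_table(sim_config(), seed = 1)
  expect_equal(sort(as.vector(table(nt160$module)), decreasing = TRUE),
               c(27, 27, 27, 27, 26, 26))
})

test_that("within-module ROI distances are smaller than between-module", {
  cfg <- sim_config(n_rois = 60, n_modules = 4)
  for (seed in 1:20) {
    nt <- make_node_table(cfg, seed = seed)
    xyz <- as.matrix(nt[, c("x", "y", "z")])
    d <- as.matrix(dist(xyz))
    same <- outer(nt$module, nt$module, `==`)
    up <- upper.tri(d)
    expect_lt(mean(d[up & same]), mean(d[up & !same]))
  }
})

test_that("factor-model correlation matches its closed form and is PSD", {
  cfg0 <- sim_config(n_rois = 12, n_modules = 3, lambda_within = c(0, 0, 0),
                     lambda_global = c(0, 0, 0))
  expect_equal(condition_correlation(cfg0, 1), diag(12))

  cfg <- sim_config(n_rois = 12, n_modules = 3,
                    lambda_within = c(0.6, 0.6, 0.6),
                    lambda_global = c(0.2, 0.2, 0.2))
  r <- condition_correlation(cfg, 2)
  expect_equal(r[1, 2], 0.40, tolerance = 1e-12)  # same module: a^2 + b^2
  expect_equal(r[1, 12], 0.04, tolerance = 1e-12) # across modules: b^2
  expect_equal(diag(r), rep(1, 12))

  # default loadings: within and between coupling strictly increase with
  # level, and every target matrix is PSD
  dflt <- sim_config()
  within <- between <- numeric(3)
  for (l in 1:3) {
    r <- condition_correlation(dflt, l)
    within[l] <- r[1, 2]
    between[l] <- r[1, 160]
    expect_gte(min(eigen(r, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
  expect_true(all(diff(within) > 0))
  expect_true(all(diff(between) > 0))
})

test_that("loadings outside the admissible region are clipped with warning", {
  cfg <- sim_config(n_rois = 9, n_modules = 3,
                    lambda_within = c(0.9, 0.9, 0.9),
                    lambda_global = c(0.3, 0.3, 0.3))
  expect_warning(r <- condition_correlation(cfg, 1, jitter_within = 0.2),
                 "clipped")
  expect_lt(r[1, 2], 1)
})

test_that("simulated scans are deterministic and consistent with the target", {
  cfg <- sim_config(n_subjects = 2, n_rois = 12, n_modules = 3,
                    n_timepoints = 200)
  a <- simulate_scan(cfg, level = 2, seed = 99)
  b <- simulate_scan(cfg, level = 2, seed = 99)
  expect_identical(a$data, b$data)

  # large-T consistency: empirical correlation approaches the plant
  big <- sim_config(n_subjects = 1, n_rois = 12, n_modules = 3,
                    n_timepoints = 20000)
  sc <- simulate_scan(big, level = 3, seed = 7)
  target <- condition_correlation(big, 3)
  expect_lt(max(abs(cor(sc$data) - target)), 0.03)
})

test_that("phi = 0 gives white-noise columns", {
  cfg <- sim_config(n_subjects = 1, n_rois = 6, n_modules = 3,
                    n_timepoints = 2000, ar1_phi = 0)
  x <- simulate_scan(cfg, level = 1, seed = 3)$data
  rho1 <- vapply(seq_len(ncol(x)), function(j) {
    cor(x[-1, j], x[-nrow(x), j])
  }, numeric(1))
  expect_true(all(abs(rho1) < 3 / sqrt(nrow(x))))
})

test_that("cohorts have the full design, shared within-subject jitter, and are seed-reproducible", {
  cfg <- sim_config(n_subjects = 3, n_rois = 12, n_modules = 3,
                    n_timepoints = 60)
  co <- simulate_cohort(cfg, seed = 5)
  expect_length(co$scans, 9)
  expect_true(all(vapply(co$scans, function(s) {
    identical(dim(s$data), c(60L, 12L))
  }, logical(1))))
  # jitter constant across a subject's conditions: planted a must be
  # strictly increasing in level with equal increments across subjects
  tr <- co$truth
  for (s in unique(tr$subject)) {
    a_s <- tr$a[tr$subject == s][order(tr$level[tr$subject == s])]
    expect_true(all(diff(a_s) > 0))
    expect_equal(diff(a_s), c(0.10, 0.10), tolerance = 1e-10)
  }
  co2 <- simulate_cohort(cfg, seed = 5)
  expect_identical(co$scans, co2$scans)
  co3 <- simulate_cohort(cfg, seed = 6)
  expect_false(identical(co$scans[[1]]$data, co3$scans[[1]]$data))
  expect_identical(dim(co3$truth), dim(co$truth))
})

test_that("default cohort dimensions match the emulated study design", {
  cfg <- sim_config()
  expect_equal(cfg$n_subjects * length(cfg$condition_levels), 54)
  expect_equal(cfg$n_timepoints, 230)
  expect_equal(cfg$n_rois, 160)
})

test_that("cohorts round-trip through a directory", {
  cfg <- sim_config(n_subjects = 2, n_rois = 9, n_modules = 3,
                    n_timepoints = 40)
  co <- simulate_cohort(cfg, seed = 2)
  d <- withr::local_tempdir()
  write_cohort(co, d)
  nodes <- read_node_table(file.path(d, "nodes.tsv"))
  expect_equal(nodes$x, co$node_table$x, tolerance = 1e-12)
  sc <- read_series(file.path(d, "S02_VSW.tsv"), nodes, "S02", "VSW")
  expect_lt(max(abs(sc$data - co$scans[["S02_VSW"]]$data)), 1e-12)
})
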