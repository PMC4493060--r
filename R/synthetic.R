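# Synthetic cohort generator. A modular factor model stands in for the
# unavailable task-fMRI recordings: each ROI signal mixes a module factor,
# a global factor, and private noise, all AR(1) in time. Raising the
# factor loadings with condition level plants a graded increase in both
# within- and between-module coupling.

#' Simulation configuration
#'
#' Defaults emulate the study design this package targets: 18 subjects
#' scanned under three ordered conditions (rest, passive visual task,
#' visual decision task), 160 ROIs grouped into 6 functional modules, and
#' 230 retained volumes at a 2 s sampling interval.
#'
#' @param n_subjects number of subjects (default 18).
#' @param n_rois number of ROIs / network nodes (default 160).
#' @param n_timepoints retained volumes per scan (default 230).
#' @param n_modules number of ROI modules (default 6).
#' @param condition_levels ordered condition labels, lowest demand first.
#' @param lambda_within per-level loading of each ROI on its module factor.
#' @param lambda_global per-level loading on the shared global factor.
#' @param subject_sd SD of the per-subject additive jitter applied to both
#'   loadings; drawn once per subject and shared across that subject's
#'   conditions (within-subject design).
#' @param ar1_phi lag-1 autocorrelation of every latent factor and noise
#'   channel (default 0.3, an fMRI-like value).
#' @param module_center_spread_mm half-width of the cube module centres are
#'   placed in (default 60 mm).
#' @param module_sd_mm SD of ROI coordinates around their module centre
#'   (default 12 mm).
#' @param tr_seconds sampling interval (default 2 s).
#' @param rng_seed integer master seed of the generator.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 18, n_rois = 160, n_timepoints = 230,
                       n_modules = 6,
                       condition_levels = c("RS", "VSW", "VSD"),
                       lambda_within = c(0.45, 0.55, 0.65),
                       lambda_global = c(0.05, 0.15, 0.30),
                       subject_sd = 0.05, ar1_phi = 0.3,
                       module_center_spread_mm = 60, module_sd_mm = 12,
                       tr_seconds = 2, rng_seed = 0L) {
  cfg <- list(n_subjects = n_subjects, n_rois = n_rois,
              n_timepoints = n_timepoints, n_modules = n_modules,
              condition_levels = condition_levels,
              lambda_within = lambda_within, lambda_global = lambda_global,
              subject_sd = subject_sd, ar1_phi = ar1_phi,
              module_center_spread_mm = module_center_spread_mm,
              module_sd_mm = module_sd_mm, tr_seconds = tr_seconds,
              rng_seed = as.integer(rng_seed))
  L <- length(condition_levels)
  if (anyDuplicated(condition_levels)) {
    stop_netreconfig("condition levels must be distinct")
  }
  if (length(lambda_within) != L || length(lambda_global) != L) {
    stop_netreconfig("one loading per condition level is required")
  }
  if (any(lambda_within < 0 | lambda_within >= 1) ||
      any(lambda_global < 0 | lambda_global >= 1)) {
    stop_netreconfig("loadings must lie in [0, 1)")
  }
  if (any(lambda_within^2 + lambda_global^2 >= 1)) {
    stop_netreconfig("lambda_within^2 + lambda_global^2 must be < 1")
  }
  if (n_rois < n_modules) stop_netreconfig("need n_rois >= n_modules")
  if (!(abs(ar1_phi) < 1)) stop_netreconfig("ar1_phi must satisfy |phi| < 1")
  structure(cfg, class = "sim_config")
}

# Module sizes: floor(n/m) each, remainder spread over the first modules.
module_sizes <- function(n_rois, n_modules) {
  sizes <- rep(n_rois %/% n_modules, n_modules)
  r <- n_rois %% n_modules
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  sizes
}

#' Generate a synthetic node table
#'
#' Assigns ROIs to modules (sizes as equal as possible) and draws
#' coordinates around well-separated module centres, so that within-module
#' Euclidean distances are stochastically smaller than between-module
#' distances — mimicking the spatial clustering of a functional parcellation.
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed; defaults to the seed in `cfg`.
#' @return a validated node table.
#' @export
make_node_table <- function(cfg = sim_config(), seed = cfg$rng_seed) {
  with_seed(seed, {
    m <- cfg$n_modules
    spread <- cfg$module_center_spread_mm
    min_sep <- 2 * cfg$module_sd_mm
    centers <- NULL
    for (try in seq_len(10000L)) {
      cand <- matrix(stats::runif(3 * m, -spread, spread), nrow = m)
      if (m == 1 || min(stats::dist(cand)) >= min_sep) {
        centers <- cand
        break
      }
    }
    if (is.null(centers)) {
      stop_netreconfig("could not place ", m, " module centres with ",
                       "pairwise separation >= ", min_sep, " mm")
    }
    sizes <- module_sizes(cfg$n_rois, m)
    module <- rep(seq_len(m), times = sizes)
    coords <- centers[module, , drop = FALSE] +
      matrix(stats::rnorm(3 * cfg$n_rois, sd = cfg$module_sd_mm),
             ncol = 3)
    as_node_table(data.frame(
      roi_id = seq_len(cfg$n_rois) - 1L,
      label = sprintf("ROI_%03d", seq_len(cfg$n_rois)),
      x = coords[, 1], y = coords[, 2], z = coords[, 3],
      module = sprintf("M%d", module),
      stringsAsFactors = FALSE))
  })
}

# Clip jittered loadings into the admissible region; warn when clipping
# was actually needed.
clip_loadings <- function(a, b) {
  clipped <- FALSE
  if (a < 0 || a >= 1 || b < 0 || b >= 1 || a^2 + b^2 >= 1) clipped <- TRUE
  a <- min(max(a, 0), 0.995)
  b <- min(max(b, 0), 0.995)
  s <- a^2 + b^2
  if (s >= 1) {
    sc <- sqrt(0.99 / s)
    a <- a * sc
    b <- b * sc
  }
  if (clipped) warning("factor loadings clipped into the admissible region")
  c(a = a, b = b)
}

#' Target correlation implied by the factor model
#'
#' Each ROI signal is `x_i = a * g_m(i) + b * g + c * eps_i` with module
#' factor `g_m`, global factor `g`, private noise `eps_i`, and
#' `c = sqrt(1 - a^2 - b^2)`, all unit variance. The implied correlation is
#' `a^2 + b^2` within a module, `b^2` between modules, and 1 on the
#' diagonal — positive semi-definite by construction.
#'
#' @param cfg a [sim_config()].
#' @param level condition level index (1-based).
#' @param jitter_within,jitter_global per-subject additive offsets on the
#'   two loadings.
#' @return N x N target correlation matrix.
#' @export
condition_correlation <- function(cfg, level, jitter_within = 0,
                                  jitter_global = 0) {
  if (level < 1 || level > length(cfg$condition_levels)) {
    stop_netreconfig("invalid condition level index: ", level)
  }
  ab <- clip_loadings(cfg$lambda_within[level] + jitter_within,
                      cfg$lambda_global[level] + jitter_global)
  module <- rep(seq_len(cfg$n_modules),
                times = module_sizes(cfg$n_rois, cfg$n_modules))
  same <- outer(module, module, `==`)
  r <- matrix(ab["b"]^2, cfg$n_rois, cfg$n_rois)
  r[same] <- ab["a"]^2 + ab["b"]^2
  diag(r) <- 1
  unname(r)
}

# Stationary AR(1) path of length T with unit marginal variance.
ar1_path <- function(n, phi) {
  if (phi == 0) return(stats::rnorm(n))
  innov <- stats::rnorm(n - 1) * sqrt(1 - phi^2)
  as.numeric(stats::filter(c(stats::rnorm(1), innov), phi,
                           method = "recursive"))
}

#' Simulate one scan from the factor model
#'
#' Latent module factors, the global factor, and every private noise
#' channel follow a stationary AR(1) process; the mixed columns are then
#' standardised to mean 0, SD 1 (Pearson correlation is scale-free, so
#' standardisation loses nothing).
#'
#' @inheritParams condition_correlation
#' @param subject_id subject label carried into the scan.
#' @param seed RNG seed for this scan.
#' @return a [scan_series()] of dimension `n_timepoints` x `n_rois`.
#' @export
simulate_scan <- function(cfg, level, subject_id = "S01",
                          jitter_within = 0, jitter_global = 0,
                          seed = NULL) {
  ab <- suppressWarnings(
    clip_loadings(cfg$lambda_within[level] + jitter_within,
                  cfg$lambda_global[level] + jitter_global))
  a <- ab["a"]; b <- ab["b"]; cc <- sqrt(max(0, 1 - a^2 - b^2))
  tt <- cfg$n_timepoints
  n <- cfg$n_rois
  module <- rep(seq_len(cfg$n_modules),
                times = module_sizes(n, cfg$n_modules))
  with_seed(seed, {
    g_mod <- vapply(seq_len(cfg$n_modules),
                    function(i) ar1_path(tt, cfg$ar1_phi), numeric(tt))
    g_glob <- ar1_path(tt, cfg$ar1_phi)
    eps <- vapply(seq_len(n), function(i) ar1_path(tt, cfg$ar1_phi),
                  numeric(tt))
    x <- a * g_mod[, module, drop = FALSE] + b * g_glob + cc * eps
    x <- scale(x)
    attr(x, "scaled:center") <- NULL
    attr(x, "scaled:scale") <- NULL
    scan_series(x, subject_id = subject_id,
                condition = cfg$condition_levels[level],
                tr_seconds = cfg$tr_seconds)
  })
}

#' Simulate a full cohort
#'
#' Draws one loading jitter per subject (shared across that subject's
#' conditions, matching the within-subject design) and one scan per
#' subject x condition. The loading parameters actually used are recorded
#' in `truth`.
#'
#' @param cfg a [sim_config()].
#' @param seed master seed; defaults to `cfg$rng_seed`.
#' @return list of class `synthetic_cohort` with elements `node_table`,
#'   `scans` (list of [scan_series()], one per subject x condition), and
#'   `truth` (data.frame of per-scan loadings).
#' @export
simulate_cohort <- function(cfg = sim_config(), seed = cfg$rng_seed) {
  seeds <- derive_seeds(seed, c("nodes", "jitter", "scans"))
  nodes <- make_node_table(cfg, seed = seeds[["nodes"]])
  ns <- cfg$n_subjects
  nl <- length(cfg$condition_levels)
  jit <- with_seed(seeds[["jitter"]], {
    cbind(jw = stats::rnorm(ns, sd = cfg$subject_sd),
          jg = stats::rnorm(ns, sd = cfg$subject_sd))
  })
  scan_seeds <- with_seed(seeds[["scans"]],
                          sample.int(2147483646L, ns * nl))
  subjects <- sprintf("S%02d", seq_len(ns))
  scans <- vector("list", ns * nl)
  truth <- vector("list", ns * nl)
  k <- 0L
  for (s in seq_len(ns)) {
    for (l in seq_len(nl)) {
      k <- k + 1L
      scans[[k]] <- simulate_scan(cfg, level = l, subject_id = subjects[s],
                                  jitter_within = jit[s, "jw"],
                                  jitter_global = jit[s, "jg"],
                                  seed = scan_seeds[k])
      ab <- suppressWarnings(
        clip_loadings(cfg$lambda_within[l] + jit[s, "jw"],
                      cfg$lambda_global[l] + jit[s, "jg"]))
      truth[[k]] <- data.frame(subject = subjects[s],
                               condition = cfg$condition_levels[l],
                               level = l, a = ab[["a"]], b = ab[["b"]],
                               stringsAsFactors = FALSE)
    }
  }
  names(scans) <- vapply(scans, function(s) {
    paste(s$subject_id, s$condition, sep = "_")
  }, character(1))
  structure(list(node_table = nodes, scans = scans,
                 truth = do.call(rbind, truth), config = cfg),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to a directory
#'
#' Writes the node table TSV, one series TSV per scan, and a JSON file of
#' the planted loading parameters.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_node_table(cohort$node_table, file.path(dir, "nodes.tsv"))
  for (nm in names(cohort$scans)) {
    write_series(cohort$scans[[nm]], file.path(dir, paste0(nm, ".tsv")),
                 nodes = cohort$node_table)
  }
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       digits = NA, dataframe = "rows")
  invisible(dir)
}
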