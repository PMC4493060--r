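#' Study configuration
#'
#' Collects every analysis-side tuning parameter of the pipeline: the
#' familywise error level used for edge thresholding, the null-ensemble
#' settings behind the small-worldness index, the preprocessing truncation
#' counts, and the multiple-comparison levels of the group statistics.
#'
#' @param alpha_edge familywise error level for edgewise Bonferroni
#'   thresholding of the correlation matrix (default 0.05).
#' @param n_nulls number of degree-preserving rewired null networks per
#'   real network (default 100).
#' @param rewire_factor double-edge-swap attempts per edge when rewiring
#'   (default 10).
#' @param n_keep_timepoints volumes retained per scan after discarding the
#'   leading ones (default 230).
#' @param n_discard leading volumes dropped for scanner stabilisation
#'   (default 10).
#' @param fdr_q Benjamini-Hochberg level for the nodewise ANOVA (default 0.05).
#' @param posthoc_alpha significance level of post-hoc paired tests
#'   (default 0.05).
#' @param rng_seed integer master seed.
#' @param weighted_mode build weighted (|r|) instead of binary networks.
#' @param positive_only keep only positively correlated edges.
#' @param highpass_hz optional high-pass cutoff in Hz applied during
#'   preprocessing; `NULL` disables the filter stage.
#' @param n_restarts restarts of the modularity optimiser (default 100).
#'
#' @return a named list of class `study_config`.
#' @export
study_config <- function(alpha_edge = 0.05, n_nulls = 100, rewire_factor = 10,
                         n_keep_timepoints = 230, n_discard = 10,
                         fdr_q = 0.05, posthoc_alpha = 0.05,
                         rng_seed = 1L, weighted_mode = FALSE,
                         positive_only = FALSE, highpass_hz = NULL,
                         n_restarts = 100) {
  cfg <- list(alpha_edge = alpha_edge, n_nulls = n_nulls,
              rewire_factor = rewire_factor,
              n_keep_timepoints = n_keep_timepoints, n_discard = n_discard,
              fdr_q = fdr_q, posthoc_alpha = posthoc_alpha,
              rng_seed = as.integer(rng_seed),
              weighted_mode = isTRUE(weighted_mode),
              positive_only = isTRUE(positive_only),
              highpass_hz = highpass_hz,
              n_restarts = n_restarts)
  validate_study_config(cfg)
  structure(cfg, class = "study_config")
}

validate_study_config <- function(cfg) {
  if (!(cfg$alpha_edge > 0 && cfg$alpha_edge < 1)) {
    stop_netreconfig("alpha_edge must lie strictly between 0 and 1")
  }
  if (cfg$n_nulls < 1) stop_netreconfig("n_nulls must be >= 1")
  if (cfg$n_discard < 0) stop_netreconfig("n_discard must be >= 0")
  if (!(cfg$fdr_q > 0 && cfg$fdr_q < 1)) stop_netreconfig("fdr_q must lie in (0,1)")
  invisible(cfg)
}

#' Read or write a study configuration file
#'
#' The on-disk form is YAML or JSON (chosen by file extension) holding the
#' `study_config` fields, so that every run can log its fully resolved
#' configuration and seed.
#'
#' @param path file path ending in `.yaml`, `.yml`, or `.json`.
#' @return `read_study_config` returns a `study_config`.
#' @export
read_study_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop_netreconfig("unsupported config extension: ", ext)
  )
  do.call(study_config, raw[!vapply(raw, is.null, logical(1))])
}

#' @rdname read_study_config
#' @param cfg a `study_config`.
#' @export
write_study_config <- function(cfg, path) {
  ext <- tolower(tools::file_ext(path))
  x <- unclass(cfg)
  switch(ext,
    yaml = , yml = yaml::write_yaml(x, path),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                                null = "null"),
    stop_netreconfig("unsupported config extension: ", ext)
  )
  invisible(path)
}
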