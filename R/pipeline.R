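# End-to-end orchestration: simulate (or load) -> preprocess -> build
# networks -> metrics -> group statistics, all under one master seed.

# Canonical metric order of the study report.
STAT_METRICS <- c("Cp", "Lp", "Eloc", "Eglob", "sigma", "K", "Dp", "Q", "R")

#' Per-condition means and SDs of metric records
#'
#' @param records wide metric records (`subject`, `condition`, metrics...).
#' @param conditions condition order; defaults to order of appearance.
#' @param metrics metric columns to summarise.
#' @return data.frame: one row per metric with `mean_<cond>` and
#'   `sd_<cond>` columns.
#' @export
summarize_metrics <- function(records, conditions = NULL, metrics = NULL) {
  conditions <- conditions %||% unique(as.character(records$condition))
  metrics <- metrics %||% intersect(STAT_METRICS, names(records))
  if (!length(metrics)) {
    metrics <- setdiff(names(records), c("subject", "condition"))
  }
  out <- data.frame(metric = metrics, stringsAsFactors = FALSE)
  for (cond in conditions) {
    sel <- records$condition == cond
    out[[paste0("mean_", cond)]] <-
      vapply(metrics, function(mm) mean(records[[mm]][sel]), numeric(1))
    out[[paste0("sd_", cond)]] <-
      vapply(metrics, function(mm) stats::sd(records[[mm]][sel]), numeric(1))
  }
  out
}

# s x c matrix of one metric, subjects as rows, conditions ordered.
metric_table <- function(records, metric, conditions) {
  subjects <- unique(records$subject)
  m <- matrix(NA_real_, length(subjects), length(conditions),
              dimnames = list(subjects, conditions))
  for (r in seq_len(nrow(records))) {
    m[records$subject[r], as.character(records$condition[r])] <-
      records[[metric]][r]
  }
  m
}

#' Group statistics over metric records
#'
#' One repeated-measures ANOVA per metric plus Bonferroni-corrected
#' post-hoc paired t-tests over all condition pairs.
#'
#' @inheritParams summarize_metrics
#' @param posthoc_alpha significance level of the post-hoc tests.
#' @return list with `summary` (per-metric condition means/SDs plus F,
#'   df1, df2, p) and `posthoc` (per metric x pair rows).
#' @export
group_analysis <- function(records, conditions = NULL, metrics = NULL,
                           posthoc_alpha = 0.05) {
  conditions <- conditions %||% unique(as.character(records$condition))
  metrics <- metrics %||% intersect(STAT_METRICS, names(records))
  summary <- summarize_metrics(records, conditions, metrics)
  fits <- lapply(metrics, function(mm) {
    rm_anova(metric_table(records, mm, conditions))
  })
  summary$F <- vapply(fits, `[[`, numeric(1), "F")
  summary$df1 <- vapply(fits, `[[`, integer(1), "df1")
  summary$df2 <- vapply(fits, `[[`, integer(1), "df2")
  summary$p <- vapply(fits, `[[`, numeric(1), "p")
  posthoc <- do.call(rbind, lapply(seq_along(metrics), function(k) {
    ph <- posthoc_paired(metric_table(records, metrics[k], conditions))
    ph$metric <- metrics[k]
    ph$pair <- paste(conditions[ph$i], conditions[ph$j], sep = "-")
    ph$significant <- ph$p_adj < posthoc_alpha
    ph
  }))
  list(summary = summary, posthoc = posthoc)
}

#' Run the full study pipeline
#'
#' Simulates (or loads) a cohort, preprocesses every scan, builds the
#' subject x condition networks, computes the full metric suite including
#' small-worldness and robustness, and runs the group statistics at both
#' the global and the nodal level. Deterministic given `seed`.
#'
#' @param sim_cfg a [sim_config()] (ignored when `cohort` is supplied).
#' @param study_cfg a [study_config()].
#' @param seed master seed; defaults to `study_cfg$rng_seed`.
#' @param cohort optional pre-built cohort (as from [simulate_cohort()]);
#'   when supplied, the simulation stage is skipped.
#' @param out_dir optional directory for report files.
#' @return list of class `study_report`: `summary`, `posthoc`, `nodal`,
#'   `records`, `enod` (subjects x conditions x nodes array), and a
#'   `provenance` block (resolved configs, seed, package version).
#' @export
run_study <- function(sim_cfg = sim_config(), study_cfg = study_config(),
                      seed = study_cfg$rng_seed, cohort = NULL,
                      out_dir = NULL) {
  seeds <- derive_seeds(seed, c("simulate", "networks"))
  if (is.null(cohort)) {
    cohort <- simulate_cohort(sim_cfg, seed = seeds[["simulate"]])
  }
  conditions <- unique(vapply(cohort$scans, `[[`, character(1), "condition"))
  subjects <- unique(vapply(cohort$scans, `[[`, character(1), "subject_id"))
  nodes <- cohort$node_table
  n_scan <- length(cohort$scans)
  scan_seeds <- with_seed(seeds[["networks"]],
                          sample.int(2147483646L, n_scan))
  rec_rows <- vector("list", n_scan)
  enod <- array(NA_real_, c(length(subjects), length(conditions),
                            nrow(nodes)),
                dimnames = list(subjects, conditions, NULL))
  for (k in seq_len(n_scan)) {
    scan <- cohort$scans[[k]]
    res <- tryCatch({
      pre <- preprocess_scan(scan, detrend = TRUE,
                             highpass_hz = study_cfg$highpass_hz)
      corr <- pearson_matrix(pre)
      net <- if (study_cfg$weighted_mode) {
        weighted_network(corr, study_cfg$alpha_edge,
                         study_cfg$positive_only, nodes)
      } else {
        bonferroni_threshold(corr, study_cfg$alpha_edge,
                             study_cfg$positive_only, nodes)
      }
      network_metrics(net, nodes, n_nulls = study_cfg$n_nulls,
                      swaps_per_edge = study_cfg$rewire_factor,
                      n_restarts = study_cfg$n_restarts,
                      robustness = TRUE, seed = scan_seeds[k])
    }, error = function(e) {
      stop_netreconfig("scan ", scan$subject_id, "/", scan$condition, ": ",
                       conditionMessage(e))
    })
    rec_rows[[k]] <- data.frame(subject = scan$subject_id,
                                condition = scan$condition,
                                t(res$global), stringsAsFactors = FALSE)
    enod[scan$subject_id, scan$condition, ] <- res$Enod
  }
  records <- do.call(rbind, rec_rows)
  rownames(records) <- NULL
  ga <- group_analysis(records, conditions,
                       posthoc_alpha = study_cfg$posthoc_alpha)
  nodal <- nodal_group_analysis(enod, q = study_cfg$fdr_q,
                                posthoc_alpha = study_cfg$posthoc_alpha)
  report <- structure(list(
    summary = ga$summary, posthoc = ga$posthoc, nodal = nodal,
    records = records, enod = enod, conditions = conditions,
    provenance = list(study_config = unclass(study_cfg),
                      sim_config = if (is.null(cohort$config)) NULL else
                        unclass(cohort$config),
                      seed = seed,
                      package_version =
                        as.character(utils::packageVersion("netreconfig")),
                      r_version = paste(R.version$major, R.version$minor,
                                        sep = "."))),
    class = "study_report")
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

#' Write a study report to disk
#'
#' Long and summary metric TSVs, a nodal-results TSV, and one JSON file
#' mirroring the whole report.
#'
#' @param report a [run_study()] result.
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_study_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_report(report$records, report$summary, dir, prefix = "metrics")
  utils::write.table(report$nodal$anova, file.path(dir, "nodal_anova.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$posthoc, file.path(dir, "posthoc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(summary = report$summary,
                            posthoc = report$posthoc,
                            nodal_anova = report$nodal$anova,
                            provenance = report$provenance),
                       file.path(dir, "report.json"),
                       digits = NA, dataframe = "rows", auto_unbox = TRUE,
                       null = "null")
  invisible(dir)
}

# 36-slot outcome labels of a report: 9 ANOVA slots (sig/ns) followed by
# 27 post-hoc slots (up/down/ns). Post-hoc slots of a non-significant
# ANOVA, or with adjusted p >= alpha, are "ns".
report_labels <- function(report, alpha = 0.05) {
  metrics <- report$summary$metric
  lab <- character(0)
  for (mm in metrics) {
    lab <- c(lab, if (report$summary$p[report$summary$metric == mm] < alpha)
      "sig" else "ns")
  }
  for (mm in metrics) {
    anova_sig <- report$summary$p[report$summary$metric == mm] < alpha
    ph <- report$posthoc[report$posthoc$metric == mm, ]
    ph <- ph[order(ph$i, ph$j), ]
    lab <- c(lab, vapply(seq_len(nrow(ph)), function(r) {
      if (anova_sig && ph$significant[r]) ph$direction[r] else "ns"
    }, character(1)))
  }
  lab
}

#' Compare two study reports
#'
#' Builds the outcome-label vector of each report (one significance label
#' per metric's ANOVA plus one signed label per metric x condition pair)
#' and scores their agreement with [reproducibility_index()]. With the
#' canonical 9-metric set and 3 conditions this is the 36-comparison
#' scheme (9 ANOVA + 27 post-hoc slots).
#'
#' @param report_a,report_b [run_study()] results over the same metric set.
#' @param alpha significance level used for the labels.
#' @return list with `labels_a`, `labels_b`, `consistent` (logical), and
#'   `index` (percent agreement).
#' @export
compare_runs <- function(report_a, report_b, alpha = 0.05) {
  if (!identical(report_a$summary$metric, report_b$summary$metric)) {
    stop_netreconfig("reports have different metric sets")
  }
  la <- report_labels(report_a, alpha)
  lb <- report_labels(report_b, alpha)
  list(labels_a = la, labels_b = lb, consistent = la == lb,
       index = reproducibility_index(la, lb))
}
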