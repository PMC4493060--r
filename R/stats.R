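# Within-subject group inference: one-way repeated-measures ANOVA per
# metric, post-hoc paired t-tests with Bonferroni adjustment, nodewise
# ANOVA with Benjamini-Hochberg FDR, and the reproducibility index used
# to compare an analysis against a validation variant.

#' One-way repeated-measures ANOVA
#'
#' Partitions the total sum of squares of a complete subjects x conditions
#' table into subject, condition, and error components;
#' `F = (SS_cond / df1) / (SS_err / df2)` with `df1 = c - 1` and
#' `df2 = (c - 1)(s - 1)`. No sphericity correction is applied, so 18
#' subjects under 3 conditions give F(2, 34).
#'
#' @param values numeric s x c matrix, subjects as rows, conditions as
#'   columns; must be complete.
#' @return list of class `anova_result` with `F`, `df1`, `df2`, `p`.
#' @export
rm_anova <- function(values) {
  values <- as.matrix(values)
  s <- nrow(values)
  cc <- ncol(values)
  if (s < 2 || cc < 2) {
    stop_netreconfig("repeated-measures ANOVA needs >= 2 subjects and >= 2 ",
                     "conditions")
  }
  if (anyNA(values)) stop_netreconfig("incomplete subjects x conditions table")
  long <- data.frame(y = as.vector(values),
                     subject = factor(rep(seq_len(s), times = cc)),
                     condition = factor(rep(seq_len(cc), each = s)))
  fit <- stats::aov(y ~ condition + subject, data = long)
  # a numerically perfect fit is handled explicitly through the SS checks
  tab <- suppressWarnings(stats::anova(fit))
  f <- tab["condition", "F value"]
  p <- tab["condition", "Pr(>F)"]
  ss_cond <- tab["condition", "Sum Sq"]
  ss_err <- tab["Residuals", "Sum Sq"]
  ss_tol <- 1e-12 * max(sum(tab[, "Sum Sq"]), .Machine$double.eps)
  if (ss_cond <= ss_tol) {
    # no condition variance at all: the test statistic degenerates to 0
    f <- 0
    p <- 1
  } else if (ss_err <= ss_tol) {
    # perfectly consistent effect with no error variance
    f <- Inf
    p <- 0
  }
  structure(list(F = f, df1 = cc - 1L, df2 = (cc - 1L) * (s - 1L), p = p),
            class = "anova_result")
}

#' Post-hoc paired t-tests with Bonferroni adjustment
#'
#' One paired t-test per condition pair on the subject difference scores
#' (df = s - 1, two-tailed), Bonferroni-adjusted over the number of pairs
#' tested: `p_adj = min(1, m * p_raw)`.
#'
#' @param values numeric s x c matrix as in [rm_anova()].
#' @param pairs 2-column matrix of condition-column index pairs; defaults
#'   to all unordered pairs.
#' @return data.frame with one row per pair: `i`, `j`, `t`, `df`, `p_raw`,
#'   `p_adj`, and `direction` (`"up"` when condition j exceeds condition
#'   i on average, `"down"` otherwise, `"none"` for a zero mean difference).
#' @export
posthoc_paired <- function(values, pairs = NULL) {
  values <- as.matrix(values)
  s <- nrow(values)
  if (is.null(pairs)) {
    pairs <- t(utils::combn(ncol(values), 2))
  }
  m <- nrow(pairs)
  rows <- lapply(seq_len(m), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    d <- values[, j] - values[, i]
    tol <- 1e-12 * max(abs(d), 1)
    if (stats::sd(d) <= tol) {
      if (abs(mean(d)) <= tol) {
        tval <- 0; p <- 1
      } else {
        tval <- sign(mean(d)) * Inf; p <- 0
      }
    } else {
      tt <- stats::t.test(values[, j], values[, i], paired = TRUE)
      tval <- unname(tt$statistic); p <- tt$p.value
    }
    data.frame(i = i, j = j, t = tval, df = s - 1L, p_raw = p,
               p_adj = min(1, m * p),
               direction = if (mean(d) > 0) "up" else if (mean(d) < 0)
                 "down" else "none",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Benjamini-Hochberg step-up FDR
#'
#' Sorts the p-values ascending, finds the largest k with
#' `p_(k) <= k q / m`, and rejects every hypothesis with `p <= p_(k)`.
#'
#' @param pvalues vector of p-values in `[0, 1]`.
#' @param q target FDR level.
#' @return list with `reject` (logical mask in input order), `threshold`
#'   (the rejection cutoff `p_(k)`, 0 when nothing is rejected), and
#'   `p_adjusted`.
#' @export
fdr_bh <- function(pvalues, q = 0.05) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop_netreconfig("p-values must lie in [0, 1]")
  }
  adj <- stats::p.adjust(pvalues, method = "BH")
  reject <- adj <= q
  list(reject = reject,
       threshold = if (any(reject)) max(pvalues[reject]) else 0,
       p_adjusted = adj)
}

#' Nodewise group analysis of nodal efficiency
#'
#' Runs [rm_anova()] per node, corrects the N ANOVA p-values by
#' Benjamini-Hochberg FDR, and runs Bonferroni-corrected post-hoc paired
#' tests only within the FDR-surviving nodes.
#'
#' @param enod 3-d array subjects x conditions x nodes.
#' @param q FDR level across nodes.
#' @param posthoc_alpha significance level for the post-hoc tests.
#' @return list with `anova` (data.frame: node, F, df1, df2, p, p_fdr,
#'   significant) and `posthoc` (data.frame over surviving nodes and
#'   pairs, with signed direction).
#' @export
nodal_group_analysis <- function(enod, q = 0.05, posthoc_alpha = 0.05) {
  dims <- dim(enod)
  if (length(dims) != 3) {
    stop_netreconfig("enod must be a subjects x conditions x nodes array")
  }
  if (dims[2] < 2) stop_netreconfig("need at least 2 conditions")
  n_node <- dims[3]
  fits <- lapply(seq_len(n_node), function(v) rm_anova(enod[, , v]))
  pvec <- vapply(fits, `[[`, numeric(1), "p")
  fdr <- fdr_bh(pvec, q)
  anova_tbl <- data.frame(node = seq_len(n_node) - 1L,
                          F = vapply(fits, `[[`, numeric(1), "F"),
                          df1 = fits[[1]]$df1, df2 = fits[[1]]$df2,
                          p = pvec, p_fdr = fdr$p_adjusted,
                          significant = fdr$reject)
  surv <- which(fdr$reject)
  posthoc <- if (length(surv)) {
    do.call(rbind, lapply(surv, function(v) {
      ph <- posthoc_paired(enod[, , v])
      ph$node <- v - 1L
      ph$significant <- ph$p_adj < posthoc_alpha
      ph
    }))
  } else {
    data.frame(i = integer(), j = integer(), t = numeric(), df = integer(),
               p_raw = numeric(), p_adj = numeric(), direction = character(),
               node = integer(), significant = logical())
  }
  list(anova = anova_tbl, posthoc = posthoc)
}

#' Reproducibility index between two sets of outcome labels
#'
#' The fraction (as a percentage) of comparison slots whose labels agree
#' between a main analysis and a validation analysis. Labels encode
#' significance and, for post-hoc slots, direction (e.g. `"sig"`/`"ns"`,
#' `"up"`/`"down"`/`"ns"`); matching `"ns"` counts as consistent.
#'
#' @param main,validation character vectors of equal length.
#' @return the index in percent.
#' @export
reproducibility_index <- function(main, validation) {
  if (length(main) != length(validation)) {
    stop_netreconfig("label vectors differ in length: ", length(main),
                     " vs ", length(validation))
  }
  100 * mean(main == validation)
}
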