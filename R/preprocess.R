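# ROI-level temporal preprocessing. The fixed stage order is:
# discard/truncate -> linear detrend -> high-pass -> confound regression.
# All filtering is realised as least-squares projection, so each stage is
# idempotent and edge-effect free at short scan lengths.

series_data <- function(x) if (inherits(x, "scan_series")) x$data else as.matrix(x)

series_wrap <- function(x, template) {
  if (inherits(template, "scan_series")) {
    out <- template
    out$data <- x
    out
  } else x
}

# Residual of each column of `m` after projecting out the columns of `X`.
project_out <- function(m, X) {
  qr.resid(qr(X), m)
}

#' Discard leading volumes and truncate to a common length
#'
#' Scanner stabilisation volumes at the start of a scan are dropped and
#' the remainder truncated so that every condition contributes the same
#' number of time points to the correlation estimate.
#'
#' @param series a [scan_series()] or T x N matrix.
#' @param n_discard leading rows to drop.
#' @param n_keep rows to retain after the discard.
#' @return same type as `series`, with `n_keep` rows.
#' @export
discard_and_truncate <- function(series, n_discard = 10, n_keep = 230) {
  m <- series_data(series)
  if (nrow(m) < n_discard + n_keep) {
    stop_netreconfig("scan has ", nrow(m), " rows; need at least ",
                     n_discard + n_keep)
  }
  series_wrap(m[n_discard + seq_len(n_keep), , drop = FALSE], series)
}

#' Remove the per-column linear trend
#'
#' Subtracts the least-squares line over the time index from every
#' column; the result has zero mean and zero linear trend.
#'
#' @inheritParams discard_and_truncate
#' @return detrended series.
#' @export
linear_detrend <- function(series) {
  m <- series_data(series)
  if (nrow(m) < 3) stop_netreconfig("need at least 3 time points to detrend")
  X <- cbind(1, seq_len(nrow(m)))
  series_wrap(project_out(m, X), series)
}

# Discrete-cosine basis column k over T samples (SPM convention):
# f_k(t) = cos(pi * k * (2t + 1) / (2T)), t = 0..T-1, with frequency
# k / (2 * T * tr) Hz.
dct_basis <- function(n_time, k_max) {
  t_idx <- seq_len(n_time) - 1
  vapply(seq_len(k_max),
         function(k) cos(pi * k * (2 * t_idx + 1) / (2 * n_time)),
         numeric(n_time))
}

#' High-pass filter by discrete-cosine projection
#'
#' Projects each column onto the orthogonal complement of the constant
#' plus all discrete-cosine basis functions with frequency below
#' `cutoff_hz`, removing slow drifts without filter edge effects.
#'
#' @inheritParams discard_and_truncate
#' @param cutoff_hz cutoff frequency in Hz (must be below Nyquist).
#' @param tr_seconds sampling interval; taken from the scan when omitted.
#' @return filtered series.
#' @export
highpass_filter <- function(series, cutoff_hz = 0.01, tr_seconds = NULL) {
  m <- series_data(series)
  tr <- tr_seconds %||%
    (if (inherits(series, "scan_series")) series$tr_seconds else
       stop_netreconfig("tr_seconds required for matrix input"))
  nyquist <- 1 / (2 * tr)
  if (cutoff_hz >= nyquist) {
    stop_netreconfig("cutoff ", cutoff_hz, " Hz is not below the Nyquist ",
                     "frequency ", nyquist, " Hz")
  }
  n_time <- nrow(m)
  # basis column k has frequency k / (2 * n_time * tr)
  k_max <- floor(2 * n_time * tr * cutoff_hz - 1e-12)
  X <- cbind(1, if (k_max >= 1) dct_basis(n_time, k_max))
  series_wrap(project_out(m, X), series)
}

#' Regress nuisance covariates out of every ROI column
#'
#' Ordinary least squares against an intercept plus the confound columns;
#' the returned residuals are orthogonal to every confound.
#'
#' @inheritParams discard_and_truncate
#' @param confounds list with `data` (T x C matrix) and optional `names`,
#'   as returned by [read_confounds()].
#' @return residual series.
#' @export
regress_confounds <- function(series, confounds) {
  m <- series_data(series)
  C <- as.matrix(confounds$data)
  if (nrow(C) != nrow(m)) {
    stop_netreconfig("confound matrix has ", nrow(C), " rows but series has ",
                     nrow(m))
  }
  nms <- confounds$names %||% colnames(C) %||%
    paste0("confound_", seq_len(ncol(C)))
  X <- cbind(intercept = 1, C)
  colnames(X) <- c("intercept", nms)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop_netreconfig("confound design is rank deficient; collinear columns: ",
                     paste(bad, collapse = ", "))
  }
  series_wrap(qr.resid(qx, m), series)
}

#' Run the full preprocessing chain on one scan
#'
#' Fixed order: discard/truncate (when `n_keep` is given), linear detrend,
#' optional high-pass, optional confound regression. Stages not requested
#' are pass-through, so synthetic scans without confounds flow through
#' unchanged apart from detrending.
#'
#' @inheritParams discard_and_truncate
#' @param detrend apply [linear_detrend()].
#' @param highpass_hz cutoff for [highpass_filter()], or `NULL` to skip.
#' @param confounds confound matrix for [regress_confounds()], or `NULL`.
#' @param n_keep if non-`NULL`, apply [discard_and_truncate()] first.
#' @return preprocessed series.
#' @export
preprocess_scan <- function(series, n_discard = 0, n_keep = NULL,
                            detrend = TRUE, highpass_hz = NULL,
                            confounds = NULL) {
  out <- series
  if (!is.null(n_keep)) out <- discard_and_truncate(out, n_discard, n_keep)
  if (isTRUE(detrend)) out <- linear_detrend(out)
  if (!is.null(highpass_hz)) out <- highpass_filter(out, highpass_hz)
  if (!is.null(confounds)) out <- regress_confounds(out, confounds)
  out
}
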