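#' Extract fixed-window heartbeat templates
#'
#' Cuts one waveform per R peak whose full `[-pre, +post]` window lies inside
#' the record; the R sample sits at index `round(pre * fs) + 1`. The default
#' 0.2 s / 0.4 s window covers the P-QRS-T complex at normal heart rates.
#'
#' @param rec A (filtered) [signal_record()].
#' @param beats The [beat_series()] of that record.
#' @param pre,post Window extent in seconds before/after the R peak.
#' @return An object of class `template_set`: `templates` (matrix, one row
#'   per beat), `window`, `valid_mask`, `beat_index` (row indices into
#'   `beats$r_peaks`), `fs`, `subject_id`, `channel_role`.
#' @export
extract_templates <- function(rec, beats, pre = 0.2, post = 0.4) {
  if (!length(beats$r_peaks)) stop("beat series is empty")
  fs <- rec$fs
  npre <- round(pre * fs); npost <- round(post * fs)
  L <- npre + npost + 1L
  n <- length(rec$samples)
  ok <- which(beats$r_peaks - npre >= 1L & beats$r_peaks + npost <= n)
  tpl <- matrix(NA_real_, nrow = length(ok), ncol = L)
  for (k in seq_along(ok)) {
    i <- beats$r_peaks[ok[k]]
    tpl[k, ] <- rec$samples[(i - npre):(i + npost)]
  }
  if (!length(ok)) warning("no beat with a full window inside the record")
  structure(list(templates = tpl, window = c(pre = pre, post = post),
                 valid_mask = rep(TRUE, length(ok)), beat_index = ok,
                 fs = fs, subject_id = rec$subject_id,
                 channel_role = rec$channel_role),
            class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set> %s/%s: %d templates x %d samples (%d valid)\n",
              x$subject_id, x$channel_role, nrow(x$templates),
              ncol(x$templates), sum(x$valid_mask)))
  invisible(x)
}

#' Valid templates as a matrix
#' @param tset A `template_set`.
#' @return Matrix of the currently valid templates (one per row).
#' @export
valid_templates <- function(tset) tset$templates[tset$valid_mask, , drop = FALSE]

#' Reject outlier heartbeat waveforms by reference-cycle correlation
#'
#' Anchors validity on the clean reference channel: each experimental
#' template is correlated with the mean reference cycle over the beats the
#' two channels share; templates correlating below `min_corr` are marked
#' invalid. This removes noise-corrupted cycles so only valid experimental
#' waveforms remain.
#'
#' @param exp,ref `template_set`s extracted from the aligned experimental and
#'   reference channels of one session.
#' @param min_corr Minimum Pearson correlation with the mean reference cycle.
#' @return The experimental `template_set` with an updated `valid_mask`.
#' @export
reject_outliers <- function(exp, ref, min_corr = 0.8) {
  if (ncol(exp$templates) != ncol(ref$templates))
    stop("experimental and reference templates must share the window")
  common <- intersect(exp$beat_index, ref$beat_index)
  if (!length(common)) stop("no matched beat pairs between channels")
  mean_ref <- colMeans(ref$templates[ref$beat_index %in% common, , drop = FALSE])
  if (sd(mean_ref) == 0) stop("reference mean cycle is constant")
  ok <- vapply(seq_len(nrow(exp$templates)), function(k) {
    x <- exp$templates[k, ]
    if (sd(x) == 0) return(FALSE)
    cor(x, mean_ref) >= min_corr
  }, logical(1))
  exp$valid_mask <- exp$valid_mask & ok
  exp
}

#' Pearson correlation between two waveforms
#'
#' @param a,b Equal-length numeric vectors (length >= 3, non-constant).
#' @return Correlation in \[-1, 1\]; `NA` with a warning for constant input.
#' @export
pcc <- function(a, b) {
  if (length(a) != length(b)) stop("waveforms must have equal length")
  if (length(a) < 3) stop("waveforms must have length >= 3")
  if (sd(a) == 0 || sd(b) == 0) {
    warning("constant waveform: correlation undefined")
    return(NA_real_)
  }
  cor(a, b)
}

#' Range-normalized root-mean-square error
#'
#' `100 * RMSE(ref, exp) / (max(ref) - min(ref))` — the error between two
#' waveforms as a percentage of the reference amplitude range.
#'
#' @param ref,exp Equal-length numeric vectors; `ref` must have nonzero range.
#' @return NRMSE in percent.
#' @export
nrmse <- function(ref, exp) {
  if (length(ref) != length(exp)) stop("waveforms must have equal length")
  rng <- max(ref) - min(ref)
  if (rng == 0) stop("reference waveform has zero range")
  100 * sqrt(mean((ref - exp)^2)) / rng
}

#' Cohort morphology summary
#'
#' Mean and sample standard deviation, over subjects, of the per-subject mean
#' Pearson correlation and NRMSE between matched experimental and reference
#' heartbeat waveforms.
#'
#' @param pcc_values Per-subject mean PCC values.
#' @param nrmse_values Optional per-subject mean NRMSE values (percent).
#' @return List with `pcc_mean`, `pcc_sd` and (when NRMSE supplied)
#'   `nrmse_mean`, `nrmse_sd`.
#' @export
morphology_report <- function(pcc_values, nrmse_values = NULL) {
  if (!length(pcc_values)) stop("at least one subject required")
  out <- list(pcc_mean = mean(pcc_values),
              pcc_sd = if (length(pcc_values) > 1) sd(pcc_values) else 0)
  if (!is.null(nrmse_values)) {
    out$nrmse_mean <- mean(nrmse_values)
    out$nrmse_sd <- if (length(nrmse_values) > 1) sd(nrmse_values) else 0
  }
  out
}
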