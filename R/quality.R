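#' Greedy one-to-one peak matching
#'
#' Matches experimental to reference peak times: all pairs closer than
#' `window` are considered in order of increasing time difference and accepted
#' greedily, each peak being used at most once.
#'
#' @param ref_times,exp_times Peak times in seconds.
#' @param window Maximum pairing distance in seconds.
#' @return Data frame with columns `ref` and `exp` (indices into the input
#'   vectors) and `dt` (exp minus ref time).
#' @export
match_peaks <- function(ref_times, exp_times, window = 0.15) {
  if (!length(ref_times) || !length(exp_times))
    return(data.frame(ref = integer(0), exp = integer(0), dt = numeric(0)))
  dt <- outer(ref_times, exp_times, function(r, e) e - r)
  cand <- which(abs(dt) <= window, arr.ind = TRUE)
  if (!nrow(cand))
    return(data.frame(ref = integer(0), exp = integer(0), dt = numeric(0)))
  ord <- order(abs(dt[cand]))
  cand <- cand[ord, , drop = FALSE]
  used_r <- logical(length(ref_times)); used_e <- logical(length(exp_times))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_r[i] && !used_e[j]) { used_r[i] <- TRUE; used_e[j] <- TRUE; keep[k] <- TRUE }
  }
  cand <- cand[keep, , drop = FALSE]
  ord2 <- order(cand[, 1])
  data.frame(ref = cand[ord2, 1], exp = cand[ord2, 2],
             dt = dt[cand[ord2, , drop = FALSE]])
}

#' Signal detection error
#'
#' Percentage of the session excluded as out-of-range or noise-corrupted:
#' `100 * (1 - (S - N) / S)`, i.e. `100 * N / S`, where `S` is the total
#' signal duration and `N` the excluded duration (both in seconds).
#'
#' @param total_s Total signal duration S in seconds (> 0).
#' @param excluded_s Excluded duration N in seconds, in \[0, S\].
#' @return SDE in percent.
#' @export
sde <- function(total_s, excluded_s) {
  if (total_s <= 0) stop("`total_s` must be > 0")
  if (excluded_s < 0 || excluded_s > total_s)
    stop("`excluded_s` must lie in [0, total_s]")
  (1 - (total_s - excluded_s) / total_s) * 100
}

#' Instantaneous heart-rate deviation between channels
#'
#' Matches experimental beats to reference beats within 150 ms, then
#' compares the instantaneous heart rate `60 / NN` over each pair of
#' *consecutive matched* reference beats against the rate over the
#' corresponding pair of experimental beats, and summarizes the absolute
#' differences. Heart rate is only computed where two or more consecutive
#' R peaks are available on both channels, so missed or spurious detections
#' never contribute an interval.
#'
#' @param ref,exp [beat_series()] objects from aligned sessions.
#' @param window Matching window in seconds.
#' @return List with `mean` and `sd` (BPM) and the per-beat vector `dev`;
#'   all empty/NA when either series has fewer than 2 peaks or nothing
#'   matches.
#' @export
hr_deviation <- function(ref, exp, window = 0.15) {
  if (length(ref$r_peaks) < 2L || length(exp$r_peaks) < 2L)
    return(list(mean = NA_real_, sd = NA_real_, dev = numeric(0)))
  rt <- peak_times(ref); et <- peak_times(exp)
  mm <- match_peaks(rt, et, window)
  if (nrow(mm) < 2L)
    return(list(mean = NA_real_, sd = NA_real_, dev = numeric(0)))
  k <- which(diff(mm$ref) == 1L)          # consecutive reference beats
  if (!length(k)) return(list(mean = NA_real_, sd = NA_real_, dev = numeric(0)))
  hr_ref <- 60 / (rt[mm$ref[k + 1L]] - rt[mm$ref[k]])
  hr_exp <- 60 / (et[mm$exp[k + 1L]] - et[mm$exp[k]])
  dev <- abs(hr_exp - hr_ref)
  list(mean = mean(dev), sd = if (length(dev) > 1) sd(dev) else 0, dev = dev)
}

#' QRS detection ratio
#'
#' Percentage of reference beats that have a matching experimental beat
#' within `window` seconds (greedy one-to-one nearest matching).
#'
#' @param ref,exp [beat_series()] objects from aligned sessions.
#' @param window Matching window in seconds (default 0.15 s).
#' @return Ratio in percent of the reference beat count.
#' @export
qrs_ratio <- function(ref, exp, window = 0.15) {
  if (!length(ref$r_peaks)) stop("reference beat series is empty")
  mm <- match_peaks(peak_times(ref), peak_times(exp), window)
  100 * nrow(mm) / length(ref$r_peaks)
}

#' Skin-to-electrode impedance from a voltage-divider measurement
#'
#' A known resistor R in series with the skin-electrode interface is driven
#' by an AC source; from the channel amplitudes VA (across the interface) and
#' VB (across R), the impedance magnitude is `Z = R * VA / VB`.
#'
#' @param R Series resistance in kilo-ohms (> 0).
#' @param VA,VB Measured amplitudes in volts (`VB > 0`).
#' @return Impedance magnitude in kilo-ohms.
#' @export
impedance <- function(R, VA, VB) {
  if (R <= 0) stop("`R` must be > 0")
  if (VB <= 0) stop("`VB` must be > 0")
  R * VA / VB
}

#' Per-session quality report
#'
#' Computes the per-session rhythm/quality row: QRS detection ratio,
#' mean/sd absolute heart-rate deviation, signal detection error, the
#' two-sided Welch t-test p-value between the two instantaneous heart-rate
#' samples, time to the first experimental beat (TB, relative to the first
#' reference beat) and total saturated time (TS).
#'
#' The excluded time N of the signal detection error is the union of
#' out-of-range runs and 2 s windows of the experimental channel containing
#' no detected beat (saturation and noise corruption are counted together).
#'
#' @param ref_beats,exp_beats [beat_series()] from the aligned session.
#' @param exp_raw The raw (unfiltered) experimental [signal_record()], used
#'   for out-of-range detection.
#' @param clip_level Recorder range is `[-clip_level, clip_level]`; defaults
#'   to the record's `meta$clip_level` or 1.
#' @param window Beat-matching window in seconds.
#' @return A list of class `quality_report` with fields `qrs_ratio_pct`,
#'   `hr_dev_mean`, `hr_dev_sd`, `sde_pct`, `p_value`, `tb`, `ts`.
#' @export
quality_report <- function(ref_beats, exp_beats, exp_raw,
                           clip_level = NULL, window = 0.15) {
  fs <- exp_raw$fs
  dur <- length(exp_raw$samples) / fs
  if (is.null(clip_level))
    clip_level <- if (!is.null(exp_raw$meta$clip_level)) exp_raw$meta$clip_level else 1

  oor <- detect_out_of_range(exp_raw, -clip_level, clip_level)
  ts <- sum(oor$duration)

  # excluded-time mask: out-of-range runs plus beat-free 2 s windows
  n <- length(exp_raw$samples)
  excl <- logical(n)
  for (k in seq_len(nrow(oor))) {
    i0 <- floor(oor$start[k] * fs) + 1L
    i1 <- min(n, i0 + round(oor$duration[k] * fs) - 1L)
    excl[i0:i1] <- TRUE
  }
  et <- peak_times(exp_beats)
  win <- 2
  for (w0 in seq(0, dur - win, by = win)) {
    if (!any(et >= w0 & et < w0 + win)) {
      i0 <- floor(w0 * fs) + 1L
      i1 <- min(n, floor((w0 + win) * fs))
      excl[i0:i1] <- TRUE
    }
  }
  sde_pct <- sde(dur, sum(excl) / fs)

  qrs <- if (length(ref_beats$r_peaks)) qrs_ratio(ref_beats, exp_beats, window) else NA_real_
  hrd <- hr_deviation(ref_beats, exp_beats, window)

  hr_r <- 60 / ref_beats$nn_intervals
  hr_e <- 60 / exp_beats$nn_intervals
  p_value <- if (length(hr_r) >= 2 && length(hr_e) >= 2 &&
                 (sd(hr_r) > 0 || sd(hr_e) > 0)) {
    stats::t.test(hr_e, hr_r)$p.value
  } else if (length(hr_r) >= 2 && length(hr_e) >= 2) {
    if (isTRUE(all.equal(mean(hr_r), mean(hr_e)))) 1 else 0
  } else NA_real_

  mm <- match_peaks(peak_times(ref_beats), et, window)
  tb <- if (nrow(mm) && length(ref_beats$r_peaks)) {
    max(0, et[mm$exp[1]] - peak_times(ref_beats)[1])
  } else NA_real_

  structure(list(qrs_ratio_pct = qrs, hr_dev_mean = hrd$mean,
                 hr_dev_sd = hrd$sd, sde_pct = sde_pct, p_value = p_value,
                 tb = tb, ts = ts),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf(
    "<quality_report> QRS %.1f%% | HR dev %.2f +/- %.2f BPM | SDE %.1f%% | p %.2f | TB %.1f s | TS %.1f s\n",
    x$qrs_ratio_pct, x$hr_dev_mean, x$hr_dev_sd, x$sde_pct, x$p_value, x$tb, x$ts))
  invisible(x)
}
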