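#' @keywords internal
#' Hamming windowed-sinc bandpass taps with an exact DC null.
bandpass_taps <- function(fs, order = 300, low = 3, high = 45) {
  b <- as.numeric(signal::fir1(order, c(low, high) / (fs / 2), type = "pass"))
  b - mean(b)
}

#' Linear-phase FIR bandpass filter
#'
#' Windowed-sinc (Hamming) FIR bandpass, default order 300 with a 3-45 Hz
#' passband — the standard front-end for QRS-oriented ECG analysis: it removes
#' baseline wander and powerline interference while preserving the QRS
#' complex. The taps are mean-subtracted after the window design, placing an
#' exact null at DC (an uncorrected windowed-sinc of this order leaks offset
#' at low sampling rates relative to the 3 Hz edge). The filter is
#' linear-phase, so the constant group delay of `order / 2` samples is
#' compensated by shifting the output; R-peak positions are preserved.
#'
#' @param rec A [signal_record()].
#' @param order Filter order (even; 300 taps + 1 coefficients).
#' @param low,high Passband edges in Hz.
#' @return A filtered [signal_record()] with the same metadata.
#' @export
bandpass_fir <- function(rec, order = 300, low = 3, high = 45) {
  fs <- rec$fs
  if (fs <= 2 * high)
    stop("`fs` must exceed twice the upper cutoff frequency")
  if (length(rec$samples) <= order)
    stop("record shorter than the filter order")
  b <- bandpass_taps(fs, order, low, high)
  half <- order / 2
  xpad <- c(rec$samples, numeric(half))
  y <- as.numeric(signal::filter(b, 1, xpad))
  rec$samples <- y[(half + 1):(half + length(rec$samples))]
  rec
}

#' Frequency response magnitude of the bandpass filter
#'
#' Magnitude of the designed FIR at given frequencies — useful to check
#' passband gain and stopband attenuation.
#'
#' @param freqs Frequencies in Hz.
#' @param fs Sampling rate in Hz.
#' @param order,low,high Filter design parameters as in [bandpass_fir()].
#' @return Numeric vector of |H(f)|.
#' @export
bandpass_response <- function(freqs, fs, order = 300, low = 3, high = 45) {
  b <- bandpass_taps(fs, order, low, high)
  k <- 0:order
  vapply(freqs, function(f) {
    Mod(sum(b * exp(-2i * pi * f / fs * k)))
  }, numeric(1))
}

#' Detect R peaks with the Hamilton algorithm
#'
#' Implements the classic Hamilton/open-source QRS detector stages on an
#' already bandpass-filtered record: differentiate, rectify, 80 ms
#' moving-window integration, adaptive signal/noise peak thresholds
#' (coefficient 0.3125 between the running noise and signal peak means),
#' a 200 ms refractory period, T-wave discrimination inside 360 ms (a peak
#' whose maximum slope is less than half that of the previous QRS is treated
#' as a T wave), and a search-back pass triggered when no QRS is found within
#' 1.66 times the running mean RR interval. Each detection is finally
#' localized at the maximum of the filtered signal within 25 ms of the
#' fiducial.
#'
#' @param rec A bandpass-filtered [signal_record()], at least 2 s long.
#' @return A [beat_series()]; empty when no QRS is found (e.g. a flat record).
#' @export
detect_r_peaks <- function(rec) {
  x <- rec$samples
  fs <- rec$fs
  if (length(x) < 2 * fs)
    stop("record must be at least 2 s long")

  # differentiate -> rectify -> 80 ms moving-window integrate
  d <- c(diff(x), 0)
  a <- abs(d)
  w <- max(1L, round(0.08 * fs))
  m <- as.numeric(stats::filter(a, rep(1 / w, w), sides = 1))
  m[is.na(m)] <- 0

  # candidate peaks of the integrated signal
  dm <- diff(m)
  cand <- which(dm[-length(dm)] > 0 & dm[-1] <= 0) + 1L
  if (!length(cand) || max(m) <= 0) return(beat_series(integer(0), fs))

  refr <- round(0.2 * fs)
  slope_win <- round(0.05 * fs)
  slope_at <- function(i) {
    lo <- max(1L, i - slope_win); hi <- min(length(a), i + slope_win)
    max(a[lo:hi])
  }

  # learning phase: initialize running peak means from the first 2 s
  init <- m[seq_len(min(length(m), 2L * round(fs)))]
  spk <- rep(max(init), 8)               # signal-peak buffer
  npk <- rep(mean(init), 8)              # noise-peak buffer
  th_coef <- 0.3125

  qrs <- integer(0)
  rr_buf <- numeric(0)
  skipped <- integer(0)                  # sub-threshold candidates since last QRS

  accept <- function(i) {
    spk <<- c(spk[-1], m[i])
    if (length(qrs)) {
      rr <- (i - qrs[length(qrs)]) / fs
      rr_buf <<- utils::tail(c(rr_buf, rr), 8)
    }
    qrs <<- c(qrs, i)
    skipped <<- integer(0)
  }

  for (i in cand) {
    last <- if (length(qrs)) qrs[length(qrs)] else -Inf
    if ((i - last) < refr) next
    thr <- mean(npk) + th_coef * (mean(spk) - mean(npk))
    is_qrs <- m[i] > thr
    if (is_qrs && is.finite(last) && (i - last) / fs < 0.36 &&
        slope_at(i) < 0.5 * slope_at(last)) {
      is_qrs <- FALSE                    # T wave
    }
    if (is_qrs) {
      accept(i)
    } else {
      npk <- c(npk[-1], m[i])
      skipped <- c(skipped, i)
      # search-back: expected beat missed?
      if (length(rr_buf) >= 2 && is.finite(last) &&
          (i - last) / fs > 1.66 * mean(rr_buf) && length(skipped)) {
        ok <- skipped[skipped - last >= refr & m[skipped] > 0.5 * thr]
        if (length(ok)) accept(ok[which.max(m[ok])])
      }
    }
  }
  if (!length(qrs)) return(beat_series(integer(0), fs))

  # localize each detection at the filtered-signal maximum near the fiducial;
  # the integrator lags the QRS by about half its window.
  loc_win <- round(0.025 * fs)
  lag <- round(w / 2)
  peaks <- vapply(qrs, function(i) {
    c0 <- max(1L, i - lag)
    lo <- max(1L, c0 - 3L * loc_win); hi <- min(length(x), c0 + 3L * loc_win)
    j <- lo + which.max(x[lo:hi]) - 1L
    lo2 <- max(1L, j - loc_win); hi2 <- min(length(x), j + loc_win)
    as.integer(lo2 + which.max(x[lo2:hi2]) - 1L)
  }, integer(1))
  peaks <- sort(unique(peaks))
  if (length(peaks) >= 2L) {
    keep <- c(TRUE, diff(peaks) >= refr)
    while (!all(keep)) {
      peaks <- peaks[keep]
      keep <- c(TRUE, diff(peaks) >= refr)
    }
  }
  beat_series(peaks, fs)
}

#' Detect out-of-range (saturated) runs
#'
#' Finds maximal runs where the signal sits at or beyond the recorder range
#' `[lo, hi]` for at least `min_run` seconds. These runs are the out-of-range
#' time that the signal-detection-error statistic counts as excluded signal.
#'
#' @param rec A [signal_record()].
#' @param lo,hi Range bounds (`lo < hi`); samples `<= lo` or `>= hi` count as
#'   out of range.
#' @param min_run Minimum run length in seconds to report (default 0.1 s, so
#'   isolated clipped samples are ignored).
#' @return Data frame with columns `start` and `duration` (seconds); zero rows
#'   when the signal stays strictly inside the range.
#' @export
detect_out_of_range <- function(rec, lo, hi, min_run = 0.1) {
  if (lo >= hi) stop("`lo` must be < `hi`")
  oor <- rec$samples <= lo | rec$samples >= hi
  r <- rle(oor)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run * rec$fs
  data.frame(start = (starts[keep] - 1L) / rec$fs,
             duration = r$lengths[keep] / rec$fs)
}

#' Estimate the clock offset between two devices from sync events
#'
#' The LED channel of one device and the LUX channel of the other see the
#' same physical flashes; the offset between the two clocks is the mean of
#' the paired event-time differences.
#'
#' @param led_events,lux_events Event times in seconds (equal lengths, paired
#'   in order).
#' @return Offset in seconds (add to LED times to obtain LUX times).
#' @export
align_sessions <- function(led_events, lux_events) {
  if (!length(led_events) || !length(lux_events))
    stop("both event lists must be non-empty")
  if (length(led_events) != length(lux_events))
    stop("event lists must have equal length (paired in order)")
  mean(lux_events - led_events)
}
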