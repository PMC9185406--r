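#' Construct a signal record
#'
#' A `signal_record` holds one uniformly sampled channel together with its
#' sampling rate and session metadata. It is the unit of exchange between the
#' generator, the preprocessing stage and the quality/morphology reports.
#'
#' @param samples Numeric vector of sample values (arbitrary units).
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_role One of `"REF"`, `"EXP"`, `"LED"`, `"LUX"`.
#' @param subject_id Subject identifier token.
#' @param t0 Session start time in seconds (default 0).
#' @param meta Optional named list of extra metadata (e.g. ground-truth R-peak
#'   indices under `r_peaks_true`).
#' @return An object of class `signal_record`.
#' @export
signal_record <- function(samples, fs, channel_role = c("REF", "EXP", "LED", "LUX"),
                          subject_id = "S?", t0 = 0, meta = list()) {
  channel_role <- match.arg(channel_role)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  if (length(samples) == 0L)
    stop("`samples` must be non-empty")
  structure(
    list(samples = as.numeric(samples), fs = fs, channel_role = channel_role,
         subject_id = subject_id, t0 = t0, meta = meta),
    class = "signal_record"
  )
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record> %s/%s: %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$channel_role, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

#' Construct a beat series
#'
#' Detected R-peak sample indices for one channel, plus the derived NN-interval
#' series (seconds between successive peaks). Peaks must be strictly increasing
#' and at least 0.2 s apart (physiological refractory period).
#'
#' @param r_peaks Integer vector of R-peak sample indices (1-based, ascending).
#' @param fs Sampling rate in Hz.
#' @return An object of class `beat_series` with fields `r_peaks`,
#'   `nn_intervals` (empty when fewer than 2 peaks) and `fs`.
#' @export
beat_series <- function(r_peaks, fs) {
  r_peaks <- as.integer(r_peaks)
  if (is.unsorted(r_peaks, strictly = TRUE))
    stop("`r_peaks` must be strictly increasing")
  if (length(r_peaks) >= 2L && any(diff(r_peaks) < 0.2 * fs))
    stop("consecutive R peaks closer than the 0.2 s refractory period")
  nn <- if (length(r_peaks) >= 2L) diff(r_peaks) / fs else numeric(0)
  structure(list(r_peaks = r_peaks, nn_intervals = nn, fs = fs),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d peaks @ %g Hz", length(x$r_peaks), x$fs))
  if (length(x$nn_intervals))
    cat(sprintf(", mean NN %.0f ms", 1000 * mean(x$nn_intervals)))
  cat("\n")
  invisible(x)
}

#' R-peak times in seconds
#' @param beats A `beat_series`.
#' @return Numeric vector of peak times (seconds from record start).
#' @export
peak_times <- function(beats) (beats$r_peaks - 1L) / beats$fs
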