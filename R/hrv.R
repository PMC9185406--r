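#' Heart-rate-variability summary of a beat series
#'
#' Time-domain and Poincaré HRV statistics of the NN-interval series, plus
#' the dominant frequency of the evenly resampled NN tachogram:
#' \itemize{
#'   \item `mean_nni` — mean NN interval (ms);
#'   \item `sdnn` — sample standard deviation of NN (ms);
#'   \item `rmssd` — root mean square of successive differences (ms);
#'   \item `sdsd` — sample standard deviation of successive differences (ms);
#'   \item `sd1` — Poincaré minor-axis spread, `sdsd / sqrt(2)` (ms);
#'   \item `nn20` — count of successive differences strictly above 20 ms;
#'   \item `peak_freq` — frequency (Hz) of the maximum of the Welch spectrum
#'     of the NN series resampled at 4 Hz (120 s Hann segments, 50 percent overlap).
#' }
#'
#' @param beats A [beat_series()] with at least 3 R peaks.
#' @return A list of class `hrv_summary`.
#' @export
hrv_summary <- function(beats) {
  if (length(beats$r_peaks) < 3L)
    stop("HRV summary needs at least 3 R peaks")
  nn <- beats$nn_intervals * 1000          # ms
  d <- diff(nn)
  sdsd <- if (length(d) > 1) sd(d) else 0
  peak_freq <- nn_peak_frequency(beats)
  structure(list(
    mean_nni = mean(nn),
    sdnn = sd(nn),
    rmssd = sqrt(mean(d^2)),
    sdsd = sdsd,
    sd1 = sdsd / sqrt(2),
    nn20 = sum(abs(d) > 20),
    peak_freq = peak_freq
  ), class = "hrv_summary")
}

#' @keywords internal
#' Dominant frequency of the NN tachogram: linear-interpolation resampling at
#' `fs_r` Hz, Welch averaging of Hann-windowed segments (default 120 s, 50%
#' overlap), peak of the averaged periodogram excluding DC.
nn_peak_frequency <- function(beats, fs_r = 4, seg_s = 120) {
  t_nn <- peak_times(beats)[-1]            # NN attached to closing beat
  nn <- beats$nn_intervals * 1000
  if (length(nn) < 3 || diff(range(t_nn)) <= 0) return(NA_real_)
  tt <- seq(min(t_nn), max(t_nn), by = 1 / fs_r)
  x <- approx(t_nn, nn, xout = tt)$y
  x <- x - mean(x)
  nseg <- min(length(x), round(seg_s * fs_r))
  if (nseg < 8) return(NA_real_)
  step <- max(1L, floor(nseg / 2))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(nseg) / (nseg + 1)))
  psd <- 0
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)] * win
    psd <- psd + Mod(fft(seg))^2
  }
  freqs <- (seq_len(nseg) - 1L) * fs_r / nseg
  half <- freqs > 0 & freqs <= fs_r / 2
  freqs[half][which.max(psd[half])]
}

#' Radar-style percentage deviation between HRV summaries
#'
#' Expresses each experimental HRV parameter as its percentage deviation from
#' the reference value, `100 * (exp - ref) / ref` — the normalization used to
#' draw the two channels on a common radar chart with the reference at 100%.
#'
#' @param ref,exp `hrv_summary` objects (or named lists/vectors with the same
#'   fields).
#' @return Named numeric vector of percentage deviations; `NA` (with a
#'   warning) for parameters whose reference value is 0.
#' @export
radar_percent <- function(ref, exp) {
  fields <- c("mean_nni", "sdnn", "rmssd", "sdsd", "sd1", "nn20", "peak_freq")
  fields <- fields[fields %in% names(ref) & fields %in% names(exp)]
  out <- vapply(fields, function(f) {
    r <- as.numeric(ref[[f]]); e <- as.numeric(exp[[f]])
    if (!is.finite(r) || r == 0) NA_real_ else 100 * (e - r) / r
  }, numeric(1))
  if (anyNA(out))
    warning("parameters with zero/non-finite reference flagged as NA: ",
            paste(names(out)[is.na(out)], collapse = ", "))
  out
}
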