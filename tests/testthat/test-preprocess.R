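test_that("bandpass filter rejects DC and matches its design response", {
  fs <- 1000
  # constant input maps to ~0 (zero-DC passband)
  const <- signal_record(rep(3, 5000), fs)
  y <- bandpass_fir(const)$samples
  expect_lt(max(abs(y[500:4500])), 1e-6 * 3)

  # measured sine gain vs the closed-form frequency response of the design
  gain_at <- function(f) {
    t <- seq(0, 5, by = 1 / fs)
    rec <- signal_record(sin(2 * pi * f * t), fs)
    out <- bandpass_fir(rec)$samples
    max(abs(out[1000:4000]))           # steady-state amplitude
  }
  h25 <- bandpass_response(25, fs)
  expect_lt(abs(gain_at(25) - h25) / h25, 0.05)
  expect_gt(h25, 0.95)                 # 25 Hz is mid-passband

  h05 <- bandpass_response(0.5, fs)
  expect_lt(h05, 10^(-20 / 20))        # >= 20 dB down at 0.5 Hz
  expect_lt(gain_at(0.5), 10^(-20 / 20))
})

test_that("filter delay compensation preserves peak positions", {
  s <- clean_session()
  filt <- bandpass_fir(s$ref)
  gt <- s$ref$meta$r_peaks_true
  # each true R peak should be a local max of the filtered signal within 5 ms
  shifts <- sapply(gt[2:20], function(i) {
    which.max(filt$samples[(i - 25):(i + 25)]) - 26
  })
  expect_lte(max(abs(shifts)), 5)
})

test_that("detector finds clean beats within 20 ms of ground truth", {
  s <- clean_session()
  beats <- detect_r_peaks(bandpass_fir(s$ref))
  gt <- s$ref$meta$r_peaks_true
  expect_equal(length(beats$r_peaks), length(gt), tolerance = 0.02)
  mm <- match_peaks((gt - 1) / 1000, peak_times(beats), window = 0.02)
  expect_equal(nrow(mm), length(gt))
})

test_that("detector returns an empty series on flat input and errors on short input", {
  flat <- signal_record(rep(0, 5000), 1000)
  expect_length(detect_r_peaks(flat)$r_peaks, 0)
  expect_error(detect_r_peaks(signal_record(rnorm(500), 1000)), "2 s")
})

test_that("detector agrees with a brute-force oracle on clean signals", {
  # oracle: every local maximum above half the global max, >= 200 ms apart
  s <- clean_session()
  filt <- bandpass_fir(s$ref)
  x <- filt$samples
  loc <- which(diff(sign(diff(x))) < 0) + 1L
  loc <- loc[x[loc] > 0.5 * max(x)]
  keep <- c()
  for (i in loc) if (!length(keep) || i - keep[length(keep)] >= 200)
    keep <- c(keep, i)
  det <- detect_r_peaks(filt)$r_peaks
  expect_equal(length(det), length(keep))
  expect_lte(max(abs(det - keep)), 2)
})

test_that("detector sensitivity and PPV reach 99% on clean sessions", {
  res <- sapply(1:3, function(sd) {
    prof <- make_population(3, seed = sd)[[sd]]
    s <- synth_session(prof, no_degradation(), duration = 120, fs = 500,
                       seed = sd + 10)
    beats <- detect_r_peaks(bandpass_fir(s$ref))
    gt <- (s$ref$meta$r_peaks_true - 1) / 500
    mm <- match_peaks(gt, peak_times(beats), window = 0.05)
    c(sens = nrow(mm) / length(gt), ppv = nrow(mm) / length(beats$r_peaks))
  })
  expect_true(all(res >= 0.99))
})

test_that("detected rhythm recovers the programmed heart rate", {
  prof <- subject_profile("S01", heart_rate_mean = 72, heart_rate_sd = 2)
  s <- synth_session(prof, no_degradation(), duration = 120, fs = 500, seed = 1)
  beats <- detect_r_peaks(bandpass_fir(s$ref))
  expect_equal(mean(beats$nn_intervals), 60 / 72, tolerance = 0.01)
})

test_that("out-of-range runs respect the minimum run length", {
  fs <- 100
  x <- rep(0, 1000)
  x[201:400] <- 1.5                       # one 2 s run beyond hi
  rec <- signal_record(x, fs)
  runs <- detect_out_of_range(rec, -1, 1, min_run = 0.1)
  expect_equal(nrow(runs), 1)
  expect_equal(runs$start, 2.0)
  expect_equal(runs$duration, 2.0)

  # strictly inside the range: nothing
  expect_equal(nrow(detect_out_of_range(signal_record(runif(500, -0.5, 0.5), fs),
                                        -1, 1)), 0)

  # two sub-threshold runs split by one in-range sample: neither reported
  y <- rep(0, 1000)
  y[101:108] <- 2; y[110:117] <- 2
  expect_equal(nrow(detect_out_of_range(signal_record(y, fs), -1, 1,
                                        min_run = 0.1)), 0)
  expect_error(detect_out_of_range(rec, 1, -1), "lo")
})

test_that("a synthesized clip episode is recovered at its programmed length", {
  prof <- make_population(2, seed = 2)[[1]]
  degr <- degradation_spec(saturation_episodes = list(c(100, 40)),
                           onset_delay = 0, burst_rate = 0)
  s <- synth_session(prof, degr, duration = 300, fs = 250, seed = 6)
  runs <- detect_out_of_range(s$exp, -1, 1)
  expect_equal(nrow(runs), 1)
  expect_equal(runs$duration, 40, tolerance = 0.1 / 40)
  expect_equal(runs$start, 100, tolerance = 0.1)
})

test_that("clock alignment averages paired event differences", {
  expect_equal(align_sessions(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(align_sessions(c(1, 2, 3), c(1, 2, 3) + 2.5), 2.5)
  expect_equal(align_sessions(c(10, 20, 30), c(12.4, 22.5, 32.6)), 2.5)
  expect_error(align_sessions(numeric(0), 1), "non-empty")
  expect_error(align_sessions(c(1, 2), 1), "equal length")
})
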