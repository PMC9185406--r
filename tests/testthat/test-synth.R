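test_that("populations are deterministic and subjects distinct", {
  expect_error(make_population(1, seed = 1), "at least|>= 2")

  p17 <- make_population(17, seed = 1)
  expect_length(p17, 17)

  a <- make_population(2, seed = 7)
  b <- make_population(2, seed = 7)
  expect_identical(a, b)

  # all pairwise default-rendered template correlations well below identity
  pop <- make_population(5, seed = 3)
  tpl <- lapply(pop, function(p) render_beat(p$morphology_params, fs = 500))
  cc <- combn(5, 2, function(ij) cor(tpl[[ij[1]]], tpl[[ij[2]]]))
  expect_length(cc, 10)
  expect_true(all(cc < 0.999))
})

test_that("profiles enforce physiological invariants", {
  expect_error(subject_profile("x", 30, 1), "40, 180")
  expect_error(subject_profile("x", 60, -1), ">= 0")
  # a morphology whose T wave beats the R wave is rejected
  m <- canonical <- seatecg:::canonical_morphology()
  m$amp[m$wave == "T"] <- 2
  expect_error(subject_profile("x", 60, 1, morphology_params = m),
               "global maximum")
  expect_s3_class(subject_profile("x", 60, 1, morphology_params = canonical),
                  "subject_profile")
})

test_that("zero degradation gives an exactly scaled experimental channel", {
  s <- clean_session()
  g <- 0.4 * (1 - 0.3 * 0)   # profile has sex_hair_factor 0
  expect_identical(s$exp$samples, g * s$ref$samples)
  expect_identical(s$ref$meta$r_peaks_true, s$exp$meta$r_peaks_true)
})

test_that("session length and beat count follow duration and heart rate", {
  prof <- subject_profile("S01", heart_rate_mean = 60, heart_rate_sd = 0)
  s <- synth_session(prof, no_degradation(), duration = 300, fs = 1000, seed = 2)
  expect_length(s$ref$samples, 300000)
  expect_length(s$exp$samples, 300000)
  # 60 BPM, sd 0: one beat per second minus the start/end margins
  expect_gte(length(s$ref$meta$r_peaks_true), 298)
  expect_lte(length(s$ref$meta$r_peaks_true), 301)
})

test_that("sessions are deterministic and reject invalid episodes", {
  prof <- make_population(2, seed = 1)[[1]]
  degr <- degradation_spec(saturation_episodes = list(c(10, 5)), onset_delay = 1)
  s1 <- synth_session(prof, degr, duration = 30, fs = 500, seed = 9)
  s2 <- synth_session(prof, degr, duration = 30, fs = 500, seed = 9)
  expect_identical(s1$exp$samples, s2$exp$samples)
  expect_error(
    synth_session(prof, degradation_spec(saturation_episodes = list(c(25, 10))),
                  duration = 30, fs = 500, seed = 1),
    "beyond the session")
  expect_error(synth_session(prof, no_degradation(), duration = 30, fs = 50),
               "fs")
})

test_that("sync events carry a recoverable constant offset", {
  ev0 <- synth_sync_events(300, 3, seed = 4, offset = 0)
  expect_identical(ev0$led, ev0$lux)

  ev <- synth_sync_events(300, 3, seed = 4, offset = 2.5)
  expect_equal(align_sessions(ev$led, ev$lux), 2.5)

  ev1 <- synth_sync_events(300, 1, seed = 8, offset = 2.5)
  expect_length(ev1$led, 1)
  expect_equal(align_sessions(ev1$led, ev1$lux), 2.5)

  expect_error(synth_sync_events(300, 0), ">= 1")
})

test_that("more noise never helps QRS detection on average", {
  accs <- sapply(c(0.02, 0.3), function(ns) {
    mean(sapply(1:20, function(sd) {
      prof <- subject_profile("S01", 70, 2)
      degr <- degradation_spec(noise_sd = ns, burst_rate = 0,
                               saturation_episodes = list(), onset_delay = 0)
      s <- synth_session(prof, degr, duration = 20, fs = 250, seed = sd)
      eb <- detect_r_peaks(bandpass_fir(s$exp))
      rt <- (s$ref$meta$r_peaks_true - 1) / 250
      nrow(match_peaks(rt, peak_times(eb), 0.05)) / length(rt)
    }))
  })
  expect_gte(accs[1], accs[2])
})

test_that("session round-trips through the delimited text format", {
  prof <- make_population(2, seed = 1)[[1]]
  s <- synth_session(prof,
                     degradation_spec(saturation_episodes = list(c(3, 2)),
                                      onset_delay = 0.5),
                     duration = 10, fs = 250, seed = 3)
  path <- tempfile(fileext = ".tsv")
  write_session(s, path)
  r <- read_session(path)
  expect_equal(r$ref$fs, 250)
  expect_equal(r$ref$subject_id, s$ref$subject_id)
  expect_identical(r$ref$meta$r_peaks_true, s$ref$meta$r_peaks_true)
  expect_equal(r$exp$samples, s$exp$samples, tolerance = 1e-6)
  unlink(path)
})
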