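# Shared fixtures, built lazily once per test run. All fixtures are
# generated in code from fixed seeds; nothing is read from disk except the
# cohort summary tables shipped under extdata.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# one clean (degradation-free) 60 s session at 1 kHz, subject with 60 BPM
clean_session <- function() fixture("clean_session", function() {
  prof <- subject_profile("S01", heart_rate_mean = 60, heart_rate_sd = 2)
  synth_session(prof, no_degradation(), duration = 60, fs = 1000, seed = 5)
})

# small default-degradation population with harvested templates (fs 500)
default_sets4 <- function() fixture("default_sets4", function() {
  pop <- make_population(4, seed = 42)
  harvest_templates(pop, degradation_spec(), duration = 300, fs = 500,
                    seed = 420)
})

cohort_similarity <- function() {
  read.csv(system.file("extdata", "cohort_waveform_similarity.csv",
                       package = "seatecg"))
}

cohort_radar <- function() {
  read.csv(system.file("extdata", "cohort_hrv_radar.csv", package = "seatecg"))
}

# beat series with prescribed NN intervals (seconds), first peak at sample 1
beats_from_nn <- function(nn_s, fs = 1000) {
  beat_series(cumsum(c(1, round(nn_s * fs))), fs)
}
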