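#' @keywords internal
#' Run code with a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Canonical beat morphology: each wave is a Gaussian bump
#   a * exp(-(t - mu)^2 / (2 sigma^2)),  t in seconds relative to the R peak.
canonical_morphology <- function() {
  data.frame(
    wave  = c("P", "Q", "R", "S", "T"),
    amp   = c(0.15, -0.10, 0.80, -0.18, 0.35),
    mu    = c(-0.20, -0.035, 0.00, 0.040, 0.28),
    sigma = c(0.025, 0.010, 0.012, 0.011, 0.055),
    stringsAsFactors = FALSE
  )
}

# Per-subject uniform jitter ranges around the canonical beat (multiplicative
# for amplitude/width, additive seconds for latency). The R wave keeps latency
# 0 and a tight amplitude range so it remains the unique global maximum.
morphology_jitter_ranges <- function() {
  list(
    amp_mult   = list(P = c(0.3, 1.7), Q = c(0.3, 1.7), R = c(0.8, 1.2),
                      S = c(0.3, 1.7), T = c(0.3, 1.7)),
    mu_shift   = list(P = c(-0.05, 0.05), Q = c(-0.012, 0.012), R = c(0, 0),
                      S = c(-0.012, 0.012), T = c(-0.06, 0.06)),
    sigma_mult = list(P = c(0.6, 1.6), Q = c(0.6, 1.5), R = c(0.7, 1.3),
                      S = c(0.6, 1.5), T = c(0.6, 1.6))
  )
}

#' Construct a subject profile
#'
#' Describes one synthetic subject: resting heart rate statistics, the P-QRS-T
#' morphology parameters of their heartbeat, and a `sex_hair_factor` in
#' \[0, 1\] summarizing how much androgenic body hair degrades the dry-electrode
#' thigh contact (0 = unimpeded contact).
#'
#' @param subject_id Identifier token.
#' @param heart_rate_mean Mean heart rate in BPM, in \[40, 180\].
#' @param heart_rate_sd Heart-rate standard deviation in BPM (>= 0).
#' @param morphology_params Data frame with columns `wave`, `amp`, `mu`,
#'   `sigma` (one row per P, Q, R, S, T Gaussian bump; `mu`, `sigma` in
#'   seconds relative to the R peak).
#' @param sex_hair_factor Scalar in \[0, 1\] controlling additional
#'   thigh-channel attenuation and noise.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, heart_rate_mean, heart_rate_sd,
                            morphology_params = canonical_morphology(),
                            sex_hair_factor = 0) {
  if (heart_rate_mean < 40 || heart_rate_mean > 180)
    stop("`heart_rate_mean` must lie in [40, 180] BPM")
  if (heart_rate_sd < 0) stop("`heart_rate_sd` must be >= 0")
  if (sex_hair_factor < 0 || sex_hair_factor > 1)
    stop("`sex_hair_factor` must lie in [0, 1]")
  m <- morphology_params
  stopifnot(all(c("wave", "amp", "mu", "sigma") %in% names(m)))
  tpl <- render_beat(m, fs = 500)
  tgrid <- seq(-0.3, 0.5, by = 1 / 500)
  if (sum(tpl == max(tpl)) != 1L || abs(tgrid[which.max(tpl)]) > 0.01)
    stop("morphology must have a unique global maximum at the R wave")
  structure(list(subject_id = subject_id, heart_rate_mean = heart_rate_mean,
                 heart_rate_sd = heart_rate_sd, morphology_params = m,
                 sex_hair_factor = sex_hair_factor),
            class = "subject_profile")
}

#' Render one noise-free heartbeat waveform
#'
#' Evaluates the sum-of-Gaussian-bumps beat model on a uniform grid.
#'
#' @param morphology_params Morphology data frame (see [subject_profile()]).
#' @param fs Sampling rate in Hz.
#' @param pre,post Window extent in seconds before/after the R peak.
#' @return Numeric vector of length `round((pre + post) * fs) + 1`.
#' @export
render_beat <- function(morphology_params, fs, pre = 0.3, post = 0.5) {
  t <- seq(-pre, post, by = 1 / fs)
  y <- numeric(length(t))
  for (i in seq_len(nrow(morphology_params))) {
    p <- morphology_params[i, ]
    y <- y + p$amp * exp(-(t - p$mu)^2 / (2 * p$sigma^2))
  }
  y
}

#' Generate a population of synthetic subjects
#'
#' Samples `n_subjects` distinct subject profiles: heart rate mean/sd from
#' uniform resting ranges, per-wave morphology jittered uniformly around the
#' canonical beat (ranges in `morphology_jitter_ranges()`), and a
#' `sex_hair_factor` drawn to emulate a mostly-female cohort in which a
#' minority of members have androgenic body hair.
#'
#' @param n_subjects Number of subjects, between 2 and 50 (identification
#'   needs at least two classes).
#' @param seed Integer seed; the population is deterministic given the seed.
#' @return List of [subject_profile()] objects.
#' @export
make_population <- function(n_subjects, seed) {
  if (n_subjects < 2) stop("`n_subjects` must be >= 2 (identification needs >= 2 classes)")
  if (n_subjects > 50) stop("`n_subjects` must be <= 50")
  with_seed(seed, {
    jr <- morphology_jitter_ranges()
    lapply(seq_len(n_subjects), function(i) {
      m <- canonical_morphology()
      for (w in m$wave) {
        k <- which(m$wave == w)
        m$amp[k]   <- m$amp[k]   * runif(1, jr$amp_mult[[w]][1],   jr$amp_mult[[w]][2])
        m$mu[k]    <- m$mu[k]    + runif(1, jr$mu_shift[[w]][1],   jr$mu_shift[[w]][2])
        m$sigma[k] <- m$sigma[k] * runif(1, jr$sigma_mult[[w]][1], jr$sigma_mult[[w]][2])
      }
      hairy <- runif(1) < 4 / 17   # minority with substantial body hair
      subject_profile(
        subject_id      = sprintf("S%02d", i),
        heart_rate_mean = runif(1, 55, 95),
        heart_rate_sd   = runif(1, 1, 5),
        morphology_params = m,
        sex_hair_factor = if (hairy) runif(1, 0.2, 0.6) else runif(1, 0, 0.15)
      )
    })
  })
}

#' Construct a degradation specification
#'
#' Describes how the experimental thigh channel differs from the clean chest
#' reference: amplitude attenuation, additive white noise, baseline wander,
#' powerline interference, saturated (railed) episodes, and a delayed onset
#' during which no usable signal is present. The recorder clips at
#' `+/- clip_level`.
#'
#' Defaults emulate a session on the instrumented seat: micro-volt-range thigh
#' amplitudes (strong attenuation), low stationary broadband noise, episodic
#' high-noise bursts from intermittent skin contact (the mechanism that
#' removes roughly a quarter of QRS complexes while leaving quiet-period
#' beats clean), slow wander from posture shifts, saturated contact-loss
#' episodes and a short settling delay before the first usable beat.
#'
#' @param attenuation_gain Thigh amplitude relative to chest (> 0, < 1 in
#'   practice).
#' @param noise_sd Stationary additive white-noise standard deviation
#'   (signal units).
#' @param burst_rate Expected noise bursts per minute (Poisson).
#' @param burst_duration Mean burst length in seconds (exponential, clamped
#'   to \[0.5, 4\] s).
#' @param burst_noise_sd Additional white-noise sd inside bursts.
#' @param morph_drift Fractional slow drift of the experimental-channel beat
#'   morphology across the session (skin-electrode interface settling);
#'   0 disables drift, 0.15 lets per-wave amplitudes/widths drift by up to
#'   15 percent between session start and end.
#' @param baseline_wander_amp,baseline_wander_freq Baseline wander amplitude
#'   (signal units) and frequency (Hz).
#' @param powerline_amp,powerline_freq Powerline interference amplitude and
#'   frequency (default 50 Hz mains).
#' @param saturation_episodes List of `c(start_s, duration_s)` pairs during
#'   which the channel rails at the clip level.
#' @param onset_delay Seconds before the first usable beat (channel railed).
#' @param clip_level Recorder range is `[-clip_level, clip_level]`.
#' @return An object of class `degradation_spec`.
#' @export
degradation_spec <- function(attenuation_gain = 0.4,
                             noise_sd = 0.03,
                             burst_rate = 6,
                             burst_duration = 1.5,
                             burst_noise_sd = 0.3,
                             morph_drift = 0.15,
                             baseline_wander_amp = 0.10,
                             baseline_wander_freq = 0.3,
                             powerline_amp = 0.02,
                             powerline_freq = 50,
                             saturation_episodes = list(c(60, 15), c(150, 25)),
                             onset_delay = 2,
                             clip_level = 1) {
  if (attenuation_gain <= 0) stop("`attenuation_gain` must be > 0")
  if (noise_sd < 0 || burst_rate < 0 || burst_duration < 0 ||
      burst_noise_sd < 0 || morph_drift < 0 || baseline_wander_amp < 0 ||
      powerline_amp < 0 || onset_delay < 0)
    stop("noise/burst/wander/powerline amplitudes and onset_delay must be >= 0")
  for (ep in saturation_episodes)
    if (length(ep) != 2L || ep[1] < 0 || ep[2] < 0)
      stop("each saturation episode must be c(start_s, duration_s) with both >= 0")
  structure(list(attenuation_gain = attenuation_gain, noise_sd = noise_sd,
                 burst_rate = burst_rate, burst_duration = burst_duration,
                 burst_noise_sd = burst_noise_sd, morph_drift = morph_drift,
                 baseline_wander_amp = baseline_wander_amp,
                 baseline_wander_freq = baseline_wander_freq,
                 powerline_amp = powerline_amp, powerline_freq = powerline_freq,
                 saturation_episodes = saturation_episodes,
                 onset_delay = onset_delay, clip_level = clip_level),
            class = "degradation_spec")
}

#' Degradation-free specification
#'
#' Convenience constructor: pure attenuation, no noise, wander, powerline,
#' saturation or onset delay, so the experimental channel is exactly
#' `attenuation_gain` times the reference.
#'
#' @param attenuation_gain Thigh amplitude relative to chest.
#' @return A `degradation_spec`.
#' @export
no_degradation <- function(attenuation_gain = 0.4) {
  degradation_spec(attenuation_gain = attenuation_gain, noise_sd = 0,
                   burst_rate = 0, burst_noise_sd = 0, morph_drift = 0,
                   baseline_wander_amp = 0, powerline_amp = 0,
                   saturation_episodes = list(), onset_delay = 0)
}

#' Synthesize one paired REF/EXP session
#'
#' Renders the subject's beat train at Gaussian-distributed RR intervals
#' (mean `60 / heart_rate_mean` s, sd propagated from `heart_rate_sd`, floored
#' at 0.3 s). The reference channel is the clean train; the experimental
#' channel is the attenuated train — its beat shape slowly morphing across
#' the session when `morph_drift > 0` — plus stationary noise, episodic
#' noise bursts, wander and powerline, railed at the clip level inside
#' saturation episodes and before `onset_delay`. Both channels share the
#' same underlying R-peak times, returned as ground truth in
#' `meta$r_peaks_true` of each record.
#'
#' The `sex_hair_factor` of the profile further attenuates the experimental
#' channel (factor `1 - 0.3 * f`) and inflates its noise (factor
#' `1 + 0.5 * f`).
#'
#' @param profile A [subject_profile()].
#' @param degr A [degradation_spec()].
#' @param duration Session length in seconds (> 0); default 300 s (5 min).
#' @param fs Sampling rate in Hz (>= 100); default 1000 Hz.
#' @param seed Integer seed.
#' @return List with elements `ref` and `exp`, both [signal_record()]s.
#' @export
synth_session <- function(profile, degr = degradation_spec(), duration = 300,
                          fs = 1000, seed = 1) {
  if (fs < 100) stop("`fs` must be >= 100 Hz")
  if (duration <= 0) stop("`duration` must be > 0")
  for (ep in degr$saturation_episodes)
    if (ep[1] + ep[2] > duration)
      stop("saturation episode extends beyond the session")
  with_seed(seed, {
    n <- round(duration * fs)
    rr_mean <- 60 / profile$heart_rate_mean
    # delta method: sd(RR) ~ 60 * sd(HR) / HR^2
    rr_sd <- 60 * profile$heart_rate_sd / profile$heart_rate_mean^2

    # beat times: first beat after ~0.5 s, then Gaussian RR floored at 0.3 s
    t_beats <- numeric(0)
    t <- 0.5
    while (t < duration - 0.5) {
      t_beats <- c(t_beats, t)
      t <- t + max(0.3, rnorm(1, rr_mean, rr_sd))
    }

    beat <- render_beat(profile$morphology_params, fs)
    # drifted end-of-session beat shape for the experimental channel
    beat_end <- if (degr$morph_drift > 0) {
      m2 <- profile$morphology_params
      nw <- nrow(m2)
      m2$amp <- m2$amp * (1 + degr$morph_drift * runif(nw, -1, 1))
      m2$sigma <- m2$sigma * (1 + degr$morph_drift * runif(nw, -1, 1))
      render_beat(m2, fs)
    } else beat
    pre_n <- round(0.3 * fs)
    ref <- numeric(n)
    expb <- numeric(n)                        # pre-degradation EXP beat train
    idx_true <- integer(length(t_beats))
    for (k in seq_along(t_beats)) {
      i0 <- as.integer(round(t_beats[k] * fs)) + 1L   # R-peak sample index
      idx_true[k] <- i0
      lo <- i0 - pre_n
      hi <- lo + length(beat) - 1L
      src <- seq_along(beat)
      if (lo < 1L) { src <- src[(2L - lo):length(src)]; lo <- 1L }
      if (hi > n)  { src <- src[seq_len(length(src) - (hi - n))]; hi <- n }
      ref[lo:hi] <- ref[lo:hi] + beat[src]
      if (degr$morph_drift > 0) {
        wk <- t_beats[k] / duration           # drift mixing weight
        expb[lo:hi] <- expb[lo:hi] + (1 - wk) * beat[src] + wk * beat_end[src]
      }
    }
    if (degr$morph_drift == 0) expb <- ref

    f <- profile$sex_hair_factor
    gain <- degr$attenuation_gain * (1 - 0.3 * f)
    noise_sd <- degr$noise_sd * (1 + 0.5 * f)
    tt <- (seq_len(n) - 1) / fs
    exp_sig <- gain * expb
    if (noise_sd > 0) exp_sig <- exp_sig + rnorm(n, 0, noise_sd)
    # episodic contact-noise bursts; body hair makes them more frequent
    burst_rate <- degr$burst_rate * (1 + f)
    if (burst_rate > 0 && degr$burst_noise_sd > 0) {
      n_bursts <- stats::rpois(1, burst_rate * duration / 60)
      if (n_bursts > 0) {
        b_start <- runif(n_bursts, 0, duration)
        b_len <- pmin(4, pmax(0.5, stats::rexp(n_bursts, 1 / degr$burst_duration)))
        bmask <- rep(FALSE, n)
        for (k in seq_len(n_bursts)) {
          i0 <- floor(b_start[k] * fs) + 1L
          i1 <- min(n, floor((b_start[k] + b_len[k]) * fs))
          bmask[i0:i1] <- TRUE
        }
        exp_sig[bmask] <- exp_sig[bmask] +
          rnorm(sum(bmask), 0, degr$burst_noise_sd * (1 + 0.5 * f))
      }
    }
    if (degr$baseline_wander_amp > 0)
      exp_sig <- exp_sig + degr$baseline_wander_amp *
        sin(2 * pi * degr$baseline_wander_freq * tt + runif(1, 0, 2 * pi))
    if (degr$powerline_amp > 0)
      exp_sig <- exp_sig + degr$powerline_amp *
        sin(2 * pi * degr$powerline_freq * tt)
    rail <- rep(FALSE, n)
    for (ep in degr$saturation_episodes) {
      i0 <- floor(ep[1] * fs) + 1L
      i1 <- min(n, floor((ep[1] + ep[2]) * fs))
      rail[i0:i1] <- TRUE
    }
    if (degr$onset_delay > 0)
      rail[seq_len(min(n, round(degr$onset_delay * fs)))] <- TRUE
    exp_sig[rail] <- 2 * degr$clip_level    # drive into the rail, then clip
    if (any(rail) || noise_sd > 0 || degr$burst_noise_sd > 0)
      exp_sig <- pmin(pmax(exp_sig, -degr$clip_level), degr$clip_level)

    meta <- list(r_peaks_true = idx_true, t_beats_true = t_beats,
                 clip_level = degr$clip_level)
    list(ref = signal_record(ref, fs, "REF", profile$subject_id, meta = meta),
         exp = signal_record(exp_sig, fs, "EXP", profile$subject_id, meta = meta))
  })
}

#' Synthesize optical synchronization events
#'
#' The acquisition setup flashes a LED on one device and records it with a
#' luminosity (LUX) sensor on the other, so the two independent clocks can be
#' aligned in post-processing. This generates matched LED/LUX event-time lists
#' separated by a constant offset (plus optional timing jitter).
#'
#' @param duration Session length in seconds.
#' @param n_events Number of events (>= 1).
#' @param seed Integer seed.
#' @param offset Constant LUX-minus-LED offset in seconds.
#' @param jitter_sd Per-event Gaussian timing jitter sd in seconds.
#' @return List with numeric vectors `led` and `lux` (seconds).
#' @export
synth_sync_events <- function(duration, n_events, seed = 1, offset = 0,
                              jitter_sd = 0) {
  if (n_events < 1) stop("`n_events` must be >= 1")
  with_seed(seed, {
    led <- sort(runif(n_events, 0.05 * duration, 0.95 * duration))
    lux <- led + offset + if (jitter_sd > 0) rnorm(n_events, 0, jitter_sd) else 0
    list(led = led, lux = lux)
  })
}
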