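#' Run the full quality pipeline on one paired session
#'
#' Convenience wrapper: bandpass-filter both channels, detect R peaks on
#' each, and assemble the [quality_report()]. Optionally adds the two HRV
#' summaries with their radar percentages, and the session's mean-waveform
#' morphology scores (PCC/NRMSE of the mean valid experimental cycle against
#' the mean reference cycle after outlier rejection).
#'
#' @param session List with `ref` and `exp` [signal_record()]s.
#' @param hrv,morphology Logical switches for the optional report sections.
#' @param min_corr Outlier-rejection threshold for the morphology section.
#' @return List with `quality` plus optional `hrv` (list `ref`, `exp`,
#'   `radar_pct`), `morphology` (list `pcc`, `nrmse`, `n_valid`,
#'   `n_templates`) and the intermediate `ref_beats`/`exp_beats`.
#' @export
session_report <- function(session, hrv = FALSE, morphology = FALSE,
                           min_corr = 0.8) {
  ref_f <- bandpass_fir(session$ref)
  exp_f <- bandpass_fir(session$exp)
  rb <- detect_r_peaks(ref_f)
  eb <- detect_r_peaks(exp_f)
  out <- list(quality = quality_report(rb, eb, session$exp),
              ref_beats = rb, exp_beats = eb)
  if (hrv && length(rb$r_peaks) >= 3 && length(eb$r_peaks) >= 3) {
    hr <- hrv_summary(rb); he <- hrv_summary(eb)
    out$hrv <- list(ref = hr, exp = he, radar_pct = radar_percent(hr, he))
  }
  if (morphology && length(rb$r_peaks) && length(eb$r_peaks)) {
    tr <- extract_templates(ref_f, rb)
    te <- extract_templates(exp_f, eb)
    # pair channels on matched beats so templates describe the same cycles
    mm <- match_peaks(peak_times(rb), peak_times(eb))
    keep_r <- tr$beat_index %in% mm$ref
    keep_e <- te$beat_index %in% mm$exp[match(tr$beat_index[keep_r], mm$ref)]
    tr$templates <- tr$templates[keep_r, , drop = FALSE]
    tr$beat_index <- tr$beat_index[keep_r]
    tr$valid_mask <- tr$valid_mask[keep_r]
    idx_e <- match(mm$exp[match(tr$beat_index, mm$ref)], te$beat_index)
    ok <- !is.na(idx_e)
    tr$templates <- tr$templates[ok, , drop = FALSE]
    tr$beat_index <- tr$beat_index[ok]
    tr$valid_mask <- tr$valid_mask[ok]
    te$templates <- te$templates[idx_e[ok], , drop = FALSE]
    te$valid_mask <- te$valid_mask[idx_e[ok]]
    te$beat_index <- tr$beat_index          # now row-aligned with tr
    if (nrow(te$templates)) {
      te <- reject_outliers(te, tr, min_corr = min_corr)
      mref <- colMeans(tr$templates)
      if (any(te$valid_mask)) {
        mexp <- colMeans(valid_templates(te))
        out$morphology <- list(pcc = pcc(mref, mexp),
                               nrmse = nrmse(mref, mexp),
                               n_valid = sum(te$valid_mask),
                               n_templates = nrow(te$templates))
      }
    }
  }
  out
}

#' Harvest identification templates for a population
#'
#' Runs the full enrolment pipeline for each subject: synthesize a paired
#' session, filter both channels, detect R peaks per channel, extract
#' templates, pair the channels beat-by-beat, reject outlier experimental
#' cycles against the mean reference cycle, and return the valid
#' experimental templates — the per-subject feature sets that feed
#' [evaluate_identification()].
#'
#' @param pop List of [subject_profile()]s (e.g. from [make_population()]).
#' @param degr A [degradation_spec()] applied to every session.
#' @param duration,fs Session length (s) and sampling rate (Hz).
#' @param seed Base seed; subject `i`'s session uses `seed + i`.
#' @param min_corr Outlier-rejection threshold.
#' @return Named list (by subject id) of valid-template matrices.
#' @export
harvest_templates <- function(pop, degr = degradation_spec(), duration = 300,
                              fs = 500, seed = 1, min_corr = 0.8) {
  sets <- list()
  for (i in seq_along(pop)) {
    s <- synth_session(pop[[i]], degr, duration, fs, seed = seed + i)
    rf <- bandpass_fir(s$ref); ef <- bandpass_fir(s$exp)
    rb <- detect_r_peaks(rf); eb <- detect_r_peaks(ef)
    tr <- extract_templates(rf, rb)
    te <- extract_templates(ef, eb)
    mm <- match_peaks(peak_times(rb), peak_times(eb))
    ir <- match(mm$ref, tr$beat_index); ie <- match(mm$exp, te$beat_index)
    ok <- !is.na(ir) & !is.na(ie)
    tr$templates <- tr$templates[ir[ok], , drop = FALSE]
    te$templates <- te$templates[ie[ok], , drop = FALSE]
    tr$beat_index <- te$beat_index <- seq_len(sum(ok))
    tr$valid_mask <- te$valid_mask <- rep(TRUE, sum(ok))
    if (sum(ok)) te <- reject_outliers(te, tr, min_corr = min_corr)
    sets[[pop[[i]]$subject_id]] <- valid_templates(te)
  }
  sets
}
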