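---
title: "Thigh-ECG quality assessment and biometric identification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thigh-ECG quality assessment and biometric identification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Dry electrodes embedded in everyday furniture — here, a toilet seat — can
record a single-lead ECG from the thighs without any body-worn device. Thigh
ECG differs sharply from a chest lead: amplitudes are in the microvolt range,
the skin–electrode contact is gel-free and intermittent, and androgenic body
hair degrades it further. Two questions follow. First, *is the signal good
enough?* — answered by comparing every session against a simultaneously
recorded chest-lead reference (rhythm agreement, HRV agreement, waveform
morphology). Second, *who is sitting on the seat?* — a household appliance
must match each recording to one of a small set of enrolled users, which this
package treats as 1:N identification from heartbeat templates.

`seatecg` implements the full analysis pipeline — filtering, R-peak
detection, quality statistics, HRV summaries, morphology scoring, and
four-classifier identification — together with a synthetic paired-session
generator, so every stage is testable end-to-end without access to any
recorded cohort.

# The synthetic-data generator

## Beat model

A heartbeat is a sum of five Gaussian bumps (P, Q, R, S, T),

$$ b(t) = \sum_{w \in \{P,Q,R,S,T\}} a_w \exp\!\left(-\frac{(t-\mu_w)^2}{2\sigma_w^2}\right), $$

with $t$ in seconds relative to the R peak. This is the standard simplified
synthetic-ECG construction (the dynamical-model literature uses the same
Gaussian parameterization on a limit cycle); it reproduces the features the
pipeline consumes — a dominant R wave, realistic P/T morphology, per-subject
shape variation — without electrophysiological volume-conductor modeling,
which is out of scope.

Subjects are sampled by jittering a canonical beat: per-wave amplitudes
multiplied by uniform factors (0.3–1.7 for P, Q, S, T; 0.8–1.2 for R),
latencies shifted uniformly (up to ±50–60 ms for P and T, ±12 ms for Q and
S), widths scaled by 0.6–1.6. The ranges were set so that pairwise
correlations between R-aligned subject templates fall in roughly 0.5–0.95,
the spread seen between real people's R-aligned heartbeats; a validity check
rejects any draw whose global maximum is not uniquely the R wave. Heart rate
is uniform on 55–95 BPM with a 1–5 BPM standard deviation, and a
`sex_hair_factor` emulates a mostly-female cohort in which a minority (~4 of
17) have substantial body hair.

## RR intervals

RR intervals are Gaussian with mean $60/\mathrm{HR}$ s and standard
deviation propagated by the delta method,
$\sigma_{RR} = 60\,\sigma_{HR}/\mathrm{HR}^2$, floored at 0.3 s. This gives
directly controllable HRV statistics: programming a 3 BPM heart-rate sd at
60 BPM yields a 50 ms SDNN, which the pipeline recovers to within 20%.

## Degradation model

The experimental (thigh) channel is the attenuated beat train plus several
degradation terms, each with a physical interpretation and a default chosen
once to match the quality statistics reported for real seat sessions
(QRS detection ratio roughly 65–85%, signal detection error ~14–15%, heart
rate deviation of order 1–3 BPM, tens of seconds of saturated time):

| parameter | default | meaning |
|---|---|---|
| `attenuation_gain` | 0.4 | thigh amplitude relative to chest |
| `noise_sd` | 0.03 | stationary broadband noise (signal units) |
| `burst_rate` | 6 / min | episodic contact-noise bursts (Poisson) |
| `burst_duration` | 1.5 s | mean burst length (exponential, clamped 0.5–4 s) |
| `burst_noise_sd` | 0.3 | extra noise inside bursts |
| `morph_drift` | 0.15 | slow beat-shape drift across the session |
| `baseline_wander_amp/freq` | 0.10 / 0.3 Hz | posture/respiration wander |
| `powerline_amp/freq` | 0.02 / 50 Hz | mains interference |
| `saturation_episodes` | 15 s + 25 s | railed contact-loss episodes |
| `onset_delay` | 2 s | settling time before the first usable beat |
| `clip_level` | ±1 | recorder range |

Two structural choices matter. Corruption is **episodic**, not stationary:
low continuous noise plus Poisson bursts of heavy noise. Stationary noise
strong enough to lose ~25% of QRS complexes would degrade *every* template
equally and make template classification collapse, whereas real seat
recordings lose beats in bursts (intermittent contact) while quiet-period
beats stay clean — which is exactly what lets outlier rejection recover a
clean template set. Second, the experimental channel's beat shape **drifts**
slowly across the session (`morph_drift` linearly cross-fades the beat
toward a mildly re-jittered shape), modeling the settling of the
skin–electrode interface; this is the mechanism that makes the static
train-early/test-late protocol measurably harder than random splitting,
as observed on real data. The `sex_hair_factor` scales attenuation by
$1-0.3f$, noise by $1+0.5f$ and burst rate by $1+f$.

`no_degradation()` zeroes every term, leaving the experimental channel an
exact scalar multiple of the reference — the fixture for all clean-pipeline
property tests.

What the generator does **not** emulate: pathology-specific waveforms
(arrhythmia, ectopy), respiratory sinus-arrhythmia structure beyond a white
RR spectrum, motion artifacts correlated with the beat, electrode-material
differences, and between-session template aging. Passing tests therefore
demonstrate that the pipeline's algorithms behave correctly under the
modeled signal structure, not that the classifiers would reach the same
accuracy on new real cohorts.

The device sampling rate is nowhere specified for either recorder;
`synth_session()` defaults to 1 kHz as a declared convention. Tests and the
acceptance script run at 500 Hz (and 250 Hz for small fixtures) to keep
suites fast; every stage takes `fs` explicitly, so the choice is a problem
size, not an algorithmic constant.

# Preprocessing

**Filtering.** An order-300 FIR bandpass (3–45 Hz, Hamming windowed-sinc) is
the front end, matching standard ECG-biometrics practice. Only order and
band are conventionally reported, so the design method is ours: windowed
sinc, with taps mean-subtracted afterwards to put an exact null at DC — at
a 1 kHz rate the 3 Hz edge of an order-300 design has a transition band of
about 11 Hz, and without the correction a constant offset leaks through at
~30% gain. Group delay (order/2 samples, linear phase) is compensated by
shifting, so peak positions are preserved; whether the original analyses
compensated delay before beat matching is unstated, and we compensate and
document. `bandpass_response()` exposes the closed-form magnitude response
so tests can compare measured sine gains against the design rather than
against the implementation under test.

**R-peak detection.** `detect_r_peaks()` implements the Hamilton detector:
differentiate, rectify, 80 ms moving-window integration, adaptive
signal/noise peak averages with threshold coefficient 0.3125, a 200 ms
refractory period, T-wave discrimination inside 360 ms (a candidate whose
maximum slope is below half that of the previous QRS is a T wave), and
search-back at 1.66 times the running mean RR. The constants come from the
open-source description of the algorithm; the final fiducial is refined to
the filtered-signal maximum within ±25 ms. On clean synthetic sessions the
detector is exact (sensitivity and precision 100%, 0 ms localization error
against generator ground truth) and coincides with a brute-force oracle
("every local maximum above half the global maximum, 200 ms apart").

**Out-of-range detection.** Maximal runs at or beyond the recorder range
lasting at least `min_run = 0.1` s; the floor avoids counting isolated
clipped samples as saturation.

**Alignment.** The two recorders are electrically decoupled and synchronized
optically (a LED on one device filmed by a luminosity sensor on the other);
`align_sessions()` estimates the clock offset as the mean of paired
event-time differences.

# Quality, HRV and morphology statistics

The per-session quality row contains the QRS detection ratio (experimental
beats matched one-to-one to reference beats within 150 ms, as a percentage
of reference beats), the mean/sd absolute instantaneous heart-rate deviation,
the signal detection error $\mathrm{SDE} = 100\,N/S$ (percentage of session
time excluded), a Welch two-sided t-test p-value between the two
instantaneous heart-rate samples, time to first experimental beat (TB) and
total saturated time (TS).

Three definitions were genuinely open and are fixed as follows:

* **Heart-rate deviation** uses only pairs of *consecutive matched* beats:
  the instantaneous rate over a reference interval is compared with the rate
  over the corresponding experimental interval. Spurious or missed
  detections therefore never contribute an interval — without this, a single
  false positive injects a wild `60/NN` value and the statistic explodes.
* **Excluded time** $N$ in the SDE is the union of out-of-range runs and 2 s
  windows containing no detected experimental beat; saturation and noise
  corruption are deliberately pooled, since the statistic's verbal
  definition conflates them.
* **TB** is the delay of the first matched experimental beat relative to the
  first reference beat, floored at zero, so a clean session scores TB = 0.

The t-test is the unequal-variance (Welch) form. HRV summaries are sample-sd
based throughout (n−1); NN20 counts successive differences strictly above
20 ms (the common convention; the threshold's openness is noted where the
statistic is defined); SD1 is $\mathrm{SDSD}/\sqrt{2}$, the Poincaré
minor-axis identity, asserted to 1e−9 in tests. The tachogram's peak
frequency comes from 4 Hz linear-interpolation resampling and Welch
averaging of 120 s Hann segments with 50% overlap — no spectral settings are
conventionally fixed for this statistic, so these are declared defaults.
`radar_percent()` expresses each experimental HRV parameter as
$100\,( \mathrm{exp}-\mathrm{ref})/\mathrm{ref}$, the normalization used to
plot both channels on one radar chart with the reference at 100%.

Morphology scoring extracts one fixed-window template per beat (0.2 s
before to 0.4 s after the R peak, covering P-QRS-T at normal rates — the
window is a convention of ours), pairs the channels beat-by-beat, rejects
experimental cycles whose correlation with the mean reference cycle falls
below `min_corr = 0.8` (the mechanism is standard; the threshold is ours),
and scores the mean valid experimental cycle against the mean reference
cycle with the Pearson correlation and the range-normalized RMSE
$100\cdot\mathrm{RMSE}/(\max-\min)$ — range normalization is consistent
with the percent-scale values (12–61) reported for this statistic in the
validation cohort.

# Identification

Per-subject valid experimental templates feed two protocols. **Random**:
seeded disjoint 2/3–1/3 train/test splits, fresh per repetition (the split
fraction is a declared default; only "random selection" is conventional).
**Static**: train on the first 30 templates, test on the last 30, 20 or 15,
so enrolment and probing are separated by a temporal gap; the split is
constant across repetitions. Each experiment is repeated (default 30 times)
and, for population sizes below the cohort, a fresh seeded subject subset is
drawn per repetition so metrics average over household composition.

All four classifiers consume the same representation — flattened templates,
standardized per feature with parameters fitted on the training set only —
so differences between them reflect the classifier, not the features. The
binary-weight CNN additionally quantizes each template to 8-bit unsigned
integers (per-template min–max to 0–255; a constant template maps to 128 by
convention) before standardization, mirroring its memory-footprint
motivation.

* **SVM**: linear-kernel one-against-all, C = 1; one binary machine per
  class fused by maximum decision value (the underlying binary fits are
  libsvm via `e1071`).
* **GaussianNB**: Gaussian naive Bayes (`e1071`), with per-class feature
  sds floored at 1e−3 so zero-variance features keep finite densities.
* **3-NN**: Euclidean 3-nearest-neighbours with majority vote; ties are
  broken by the single nearest neighbour's class. The in-package predictor
  exists because the reference implementation breaks ties at random, which
  would break bit-for-bit reproducibility; a test cross-checks it against
  `class::knn` on tie-free problems.
* **BCNN**: a binary-weight 1D convolutional network written in plain R:
  conv(16 filters, width 7, full precision) → ReLU → max-pool 2 →
  conv(32, width 5, binarized) → ReLU → max-pool 2 → dense(64, binarized) →
  ReLU → full-precision softmax head. Binarized layers use
  $\mathrm{sign}(W)$ scaled by the mean absolute latent weight per output
  unit, straight-through gradients masked to $|W|\le 1$, and latent weights
  clipped to $[-1,1]$; keeping the first and last layers full precision is
  standard binary-network practice. Training is minibatch Adam (learning
  rate 0.01, batch 32, 30 epochs) with a fixed per-repetition seed. No
  architecture is conventionally fixed for this classifier; this one is an
  interpretation, documented as such, and "binary" is read as
  binarized-weight (the efficiency reading), not two-class. Each repetition
  re-trains from a fresh seeded initialization, including under the static
  protocol where the split itself is constant.

Metrics are accuracy and macro-averaged recall and precision; a class never
predicted contributes zero precision. The sweep is ordered by classifier,
protocol and population size, and is bit-for-bit reproducible from its seed.

# Problem sizes and numerical choices

The test-suite and acceptance-script fixtures use 5-minute sessions at
500 Hz (250 Hz for the smallest fixtures), populations of 2–17 subjects,
5–30 repetitions depending on classifier cost, and capped per-subject
template counts (45) for the population-size sweep — sizes chosen so the
full pipeline demonstrates every claimed property while the suites stay
quick on one CPU. The population-size sweep fixes a degradation with raised
stationary noise (`noise_sd = 0.05`) so accuracy sits clearly below ceiling
and the monotone population-size effect dominates subset-composition
randomness. Degenerate inputs are handled explicitly: fewer than two beats
yields empty (not erroneous) rate statistics, constant waveforms make the
correlation undefined (flagged NA) and the range-normalized error an error,
and a template window extending past the record skips that beat.

# Known limitations

* Synthetic subjects are stationary within the modeled drift; there is no
  between-session or between-day variability, so static-protocol results
  bound the easy direction of template aging only.
* The Hamilton implementation is faithful to the published stage structure
  but single-pass; it does not re-segment with per-channel tuned thresholds.
* The Gaussian-bump beat model cannot represent pathological morphologies;
  identification results on synthetic populations quantify algorithmic
  correctness, not expected field accuracy.
* HDF5 session I/O is not provided; sessions serialize to delimited text.
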