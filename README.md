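# seatecg

Signal quality, heart-rate variability and biometric identification for
single-lead ECG recorded from dry electrodes embedded in furniture — the
"invisible ECG" setting in which a toilet seat records the electrocardiogram
at the thighs while a simultaneous chest-lead reference is available for
validation.

Thigh ECG is hard: amplitudes are in the microvolt range, the gel-free
skin–electrode contact is intermittent, and body hair degrades it further.
The package answers the two questions such a system raises:

* **Is the signal usable?** Per-session quality statistics against the
  reference channel — QRS detection ratio, instantaneous heart-rate
  deviation, signal detection error `SDE(%) = 100·N/S` (excluded time `N`
  over session time `S`), Welch t-test p-value, time-to-first-beat,
  saturated time — plus HRV summaries (mean NNI, SDNN, RMSSD, SDSD,
  SD1 = SDSD/√2, NN20, tachogram peak frequency) with radar-style
  percentage deviations, and heartbeat-morphology scores (Pearson
  correlation and range-normalized RMSE between matched mean waveforms
  after correlation-based outlier rejection).
* **Who is sitting on the seat?** 1:N identification from fixed-window
  heartbeat templates under random and temporal-gap ("static" 30/30, 30/20,
  30/15) train/test protocols, sweeping household sizes from 2 to 17
  subjects with four classifiers: linear one-against-all SVM, Gaussian
  naive Bayes, deterministic 3-NN, and a binary-weight 1D convolutional
  network (BCNN) trained on 8-bit-quantized standardized templates.

The preprocessing chain is the field's standard one: an order-300 FIR
bandpass (3–45 Hz, Hamming windowed-sinc, group delay compensated) followed
by Hamilton R-peak detection (80 ms integration window, adaptive
signal/noise thresholds, 200 ms refractory period, T-wave discrimination,
search-back at 1.66× the running mean RR).

Because no public recording of this setting exists, the package includes a
first-class synthetic generator: per-subject P-QRS-T morphology as a sum of
Gaussian bumps, Gaussian RR intervals, and a degradation model for the
thigh channel (attenuation, stationary noise, episodic contact-noise
bursts, baseline wander, powerline, saturation episodes, delayed onset,
slow beat-shape drift). Its defaults are calibrated to the quality
statistics reported for real seat sessions; the methods vignette
(`vignettes/thigh-ecg-biometrics.Rmd`) documents every parameter and what
the generator does and does not emulate.

## Worked example

```r
library(seatecg)

# a 3-person household, one paired 5-min session each
pop <- make_population(3, seed = 1)
s <- synth_session(pop[[1]], degradation_spec(), duration = 300, fs = 500, seed = 11)
rep <- session_report(s, morphology = TRUE)
print(rep$quality)
#> <quality_report> QRS 80.3% | HR dev 0.90 +/- 3.01 BPM | SDE 14.0% | p 0.00 | TB 1.5 s | TS 42.0 s
c(pcc = rep$morphology$pcc, nrmse = rep$morphology$nrmse, n_valid = rep$morphology$n_valid)
#>       pcc     nrmse   n_valid
#> 0.9975044 9.4701363 250.0000000

# enrol all three subjects and identify held-out heartbeats
sets <- harvest_templates(pop, degradation_spec(), duration = 300, fs = 500, seed = 100)
res <- evaluate_identification(sets, c("SVM", "GaussianNB", "KNN3"),
                               protocol_spec("random", n_repetitions = 5),
                               population_sizes = 3, seed = 7)
summarize_identification(res)[, c("classifier", "accuracy_mean", "accuracy_sd")]
#>   classifier accuracy_mean accuracy_sd
#> 1 GaussianNB      99.73913   0.2381402
#> 2       KNN3      99.65217   0.3637652
#> 3        SVM      99.82609   0.2381402
```

Reading the quality row: the thigh channel recovered 80% of the reference
QRS complexes; matched beats agree on heart rate to 0.9 BPM on average; 14%
of the session is excluded as saturated or beat-free (42 s of it railed at
the recorder limit); the first usable thigh beat came 1.5 s after the first
reference beat. The mean valid thigh waveform correlates at 0.998 with the
reference cycle, with an error under 10% of the reference range, from 250
valid templates. All three fast classifiers then identify held-out
heartbeats in the 3-person household with ~99.7% accuracy.

A thin CLI over the same functions lives at `inst/cli/seatecg.R`
(`simulate`, `qc`, `identify` subcommands).

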