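# radarvitals

Non-contact vital-sign monitoring turns a millimetre-wave FMCW radar into
a heart-rate and breathing-rate sensor: chest displacement modulates the
phase of the radar return inside one range bin, and sub-millimetre
heartbeat motion is readable as slow-time phase at 77 GHz
(1 mm ≈ 3.23 rad). `radarvitals` implements the full pipeline in R for
signal-processing researchers who want a tested, hardware-free reference:

* **Forward model** — chirp-level simulation of the IF signal
  `y(k,l) = √P_R · exp(j(2π f_b k T_f + 4πR(lT_s)/λ + 2π d_m sinΘ/λ))`
  over configurable chest-displacement scenarios (breathing, heartbeat,
  random body movement, orientation, noise).
* **Vitals DSP** — range FFT, range-bin selection, phase unwrapping,
  cascaded-biquad Butterworth band-passes (cardiac 0.8–2 Hz, breathing
  0.1–0.5 Hz), motion denoising by a 1 s windowed energy threshold
  (E_th = 0.04 rad²), adaptive peak rejection (mean ± 1 SD interval
  rule) and rate estimation.
* **QRS reconstruction** — each detected beat becomes a symmetric
  triangular pulse expanded as a truncated Fourier cosine series
  (a_n = AB(1 − cos 2πn/B)/n²π² for B ≥ 2), synthesized at 100,000
  samples per beat and resampled to 5 Hz; periodogram and SNR quantify
  the cleanup.
* **ECG toolkit** — adu→mV normalization, Butterworth artifact removal
  (30 Hz low-pass, 50 Hz band-stop, 0.8 Hz high-pass), adaptive R-peak
  detection, a synthetic P-QRS-T generator, and a minimal WFDB reader.
* **RR features + classifier** — mean RR, normalized max difference,
  RMSSD, coefficient of variation, normalized absolute deviation, plus
  age and gender, feeding an 8-16-1 sigmoid MLP trained by
  Levenberg–Marquardt with early stopping on a 70/15/15 split.
* **Agreement metrics** — mean/variance/SD, skewness, Tukey-fence
  outlier counts, MSE/RMSE/MAE/MedAE and R² for validating estimates
  against a reference device.

## Worked example

Simulate a subject at 0.5 m breathing at 18 breaths/min with a 72 BPM
heartbeat, run the radar chain, and reconstruct the heartbeat train:

```r
library(radarvitals)

sc <- displacement_scenario(heart_freq = 1.2, breathing_freq = 0.3)
r  <- run_vitals_demo(sc, seed = 42)
r$estimate
#> <vitals_estimate: HR 72.0 BPM (27 peaks), BR 18.0 BPM (6 peaks), ok>

rec <- synthesize_train(r$estimate$hr_peak_times, 25.6)
pg  <- periodogram(rec)
pg$peak_freq
#> [1] 1.210938
estimate_snr(rec, pg$peak_freq)
#> [1] 4.68
```

The estimate recovers both ground-truth rates; the 128-sample 5 Hz
reconstruction concentrates its power at the heartbeat fundamental
(1.21 Hz is the periodogram bin nearest 1.2 Hz) with a positive SNR,
where the raw noisy peak train is typically several dB below zero.

Train the arrhythmia screen on a 200-subject synthetic RR cohort:

```r
res <- run_arrhythmia_demo(n_subjects = 200, seed = 42)
c(res$train_accuracy, res$test_accuracy)
#> [1] 1 1
head(res$subject_table, 3)
#>   subject age gender     actual accuracy false_calls
#> 1       1  81   male     normal        1           0
#> 2       2  46 female     normal        1           0
#> 3       3  58 female arrhythmia        1           0
```

The synthetic classes are separable by construction (see the methods
vignette for what this does and does not demonstrate about clinical
data).

A command-line front end is installed with the package
(`exec/radarvitals`): subcommands `simulate`, `process`, `reconstruct`,
`features`, `train`, `evaluate`, `metrics`, `demo-vitals`,
`demo-arrhythmia`.

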