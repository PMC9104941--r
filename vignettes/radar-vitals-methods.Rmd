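---
title: "Methods: radar vital-sign extraction and arrhythmia screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radar vital-sign extraction and arrhythmia screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radarvitals)
```

## The measurement model

A 77 GHz FMCW radar transmits linear chirps (4 GHz sweep in 50 µs,
sampled at 2 Msps in fast time, 20 chirps/s in slow time). After I/Q
mixing, the intermediate-frequency sample of chirp $l$ at fast-time index
$k$ is

$$y(k, l) = \sqrt{P_R}\, e^{\,j\left(2\pi f_b k T_f \;+\;
  \frac{4\pi}{\lambda} R(l T_s) \;+\; \frac{2\pi d_m \sin\Theta}{\lambda}
  \right)},$$

with beat frequency $f_b = \frac{B}{T_C}\frac{2R_0}{c}$. Vital-sign
displacements (≤ 5 mm, < 2 Hz) are far below the range-bin extent
$c/2B = 3.75$ cm, so the target stays in one bin and its motion appears
purely as slow-time phase: a displacement $\Delta R$ advances the phase
by $4\pi\Delta R/\lambda$ — about 3.23 rad per millimetre at 77 GHz.
Residual phase noise is neglected at sub-1.5 m range (range correlation);
the simulator still exposes an optional phase random walk.

The chest model superposes a sinusoidal breathing displacement
(default 4 mm at 0.1–0.5 Hz), a pulse-like heartbeat displacement, and
optional random-body-movement (RBM) bursts with smooth Hann onsets.
An orientation gain in $(0, 1]$ emulates measuring from the side or back.

### The heartbeat pulse shape

The heartbeat displacement is a raised-cosine pulse train. Two
constraints pin down its defaults:

* **Energy budget.** The motion-denoising rule (below) discards 1 s
  windows of cardiac-band phase whose mean square exceeds
  $E_{th} = 0.04\ \mathrm{rad^2}$. Clean heartbeat phase must sit below
  that; with the default 0.15 mm amplitude the cardiac-band mean square
  is ≈ 0.01 rad².
* **Harmonic content.** A narrow pulse (duty ≲ 0.35) puts nearly as much
  energy into its 2nd harmonic as its fundamental. For heart rates below
  60 BPM both land inside the 0.8–2 Hz cardiac band, and after a causal
  band-pass (whose group delay differs across the band) they combine into
  two positive humps per beat — peak counting then reads double the true
  rate. The default duty cycle of 0.65 concentrates energy at the
  fundamental while keeping a pulse-like crest.

0.15 mm is within the range reported for precordial skin displacement;
both parameters are scenario knobs.

## The processing chain

Per observation (25.6 s, 512 chirps): range FFT per chirp → one-sided
range profile; target bin = largest time-averaged magnitude at or above
`min_bin` (default 1, excluding DC leakage; ties to the smaller bin);
four-quadrant phase extraction in $(-\pi, \pi]$; unwrapping so successive
differences stay within $(-\pi, \pi]$.

### Band-splitting filters

Each band is a Butterworth band-pass realized as serially cascaded
biquad sections: cardiac 0.8–2 Hz with **seven** sections, breathing
0.1–0.5 Hz with **three**. The asymmetry is forced by physics: breathing
phase is tens of radians (4 mm ≈ 13 rad) while heartbeat phase is tenths
of a radian. With only two cardiac sections, breathing leakage into the
0.8–2 Hz band exceeds $E_{th}$ for breathing rates near the band edge and
every window is discarded; seven sections push the leakage to ≈ 0.1% so
the heartbeat fundamental dominates. Three breathing sections are the
fewest that reach 20 dB attenuation one octave outside the band edges.

Filtering is causal by default (as in a live monitor), with two
provisions:

* the series mean is removed first (the unwrapped phase carries the large
  constant $4\pi R_0/\lambda$, which a band-pass would turn into a long
  step transient);
* the start of the series is odd-reflection padded by 20 s before
  filtering and the pad discarded, emulating a monitor that has been
  running before the observation window. Without this, the switch-on
  transient of these narrow-band cascades rings for most of a 25.6 s
  observation. A `zero_phase` flag enables forward–backward filtering for
  offline use.

### Motion denoising

The band-filtered series is tiled into non-overlapping 1 s windows;
window *energy* is the mean of squared values (rad²), making the
threshold independent of the sampling rate. Cardiac windows above
$E_{th} = 0.04$ rad² are masked from peak detection. The same rule with
the same constant cannot be applied to the breathing band: any real
breathing signal (4 mm → ≈ 83 rad² mean square) is orders of magnitude
above 0.04, so a literal application discards every breathing window.
The breathing band instead uses the phase-equivalent of the largest
chest displacement the measurement regime assumes (5 mm):
$(4\pi \cdot 0.005/\lambda)^2 \approx 260$ rad², masking only windows
whose excursion no breathing motion could produce. Very large body
movements do not necessarily produce very large phase — they alias
(> λ/4 per chirp interval) and decorrelate the bin — so energy masking is
a guard against moderate motion, not a catch-all.

### Peak detection and rate estimation

Candidate peaks are strict local maxima with positive amplitude inside
retained windows, refined to sub-sample positions by a parabola through
the maximum and its neighbours (without refinement, gap quantization on
the 0.05 s chirp grid biases the interval statistics). Inter-peak
distances are screened once: a peak whose preceding distance falls
outside mean ± 1 SD of all distances is rejected, the earlier peak kept;
when all distances are equal (SD = 0, tolerance 1 ns) nothing is
rejected. The rate is 60 over the mean *usable* interval — intervals
between consecutive accepted peaks that neither span a rejected peak nor
cross a masked window. Averaging raw differences of accepted times
instead would fold rejection-merged double gaps into the mean and bias
rates low. Estimated rates outside the band's physiological range
(48–120 BPM cardiac, 6–30 breaths/min) are flagged rather than reported
as vitals.

## QRS-like signal reconstruction

Each detected heartbeat is replaced by a symmetric triangular pulse
$f(t) = A(1 - B|t|/T)$ on $|t| \le T/B$, expanded in a truncated Fourier
cosine series (the pulse is even, so sine terms vanish). Direct
integration over one period with fundamental $2\pi/T$ gives

$$a_0 = \frac{A}{B}, \qquad
  a_n = \frac{AB}{n^2\pi^2}\left(1 - \cos\frac{2\pi n}{B}\right)
  \quad (B \ge 2),$$

and for $1 \le B < 2$ (pulse truncated at the period boundary)
$a_0 = A(1 - B/4)$, $a_n = \frac{AB}{n^2\pi^2}(1 - \cos n\pi)$. Closed
forms for this pulse circulating in the applied literature
($a_0 = AB(2-B)$, $a_n = \frac{2BA}{n^2\pi^2}(1 - \cos\frac{n\pi}{B})$)
do not agree with the integral they are presented as evaluating — at
$B = 2$ they give zero mean although the pulse has positive area. The
package's ground truth is numerical integration; the correct closed form
is the default and the literature form is retained behind
`convention = "printed"` for comparison.

The period $T$ of each pulse is its local RR interval (mean of the two
adjacent gaps for interior peaks), so the train follows beat-to-beat
timing without overshoots. Synthesis uses 100,000 samples per beat
(rate $10^5 n / 25.6$ Hz for $n$ beats), then resampling to 5 Hz.
Resampling is done in the Fourier domain — spectrum truncation below the
output Nyquist, inverse transform on the coarse grid — an ideal
anti-aliasing low-pass. A polyphase FIR decimator at a ratio of
≈ 22,656:1 would need a degenerate filter design, while the synthesis
length is exactly $10^5 n$ samples, which the FFT handles cheaply.
Defaults $B = 4$ and 32 harmonics: with $B = 8$ the pulse's 2nd harmonic
carries enough periodogram power that the PSD argmax lands on the 2nd
harmonic for beat intervals ≥ 1 s, contradicting the fundamental-dominant
spectrum the reconstruction exists to produce.

SNR is measured on the mean-removed one-sided periodogram as the mass
within ± 1 bin of the fundamental and its 2nd harmonic against all
remaining mass.

## ECG toolkit

Raw ADC samples normalize as $(\mathrm{adu} - \mathrm{baseline}) /
\mathrm{gain}$, covering the two common clinical digitizations
(128 Hz/gain 200/baseline 0 and 360 Hz/gain 200/baseline 1024). Artifact
removal is a Butterworth cascade, all 4th order: low-pass 30 Hz (muscle
tremor), band-stop 48–52 Hz (mains; skipped with a warning when the rate
cannot represent 50 Hz), high-pass 0.8 Hz (baseline wander). R peaks are
detected on squared-derivative energy with an 80 ms moving average and an
adaptive threshold at half the rolling 2 s maximum, a 0.2 s refractory
interval, and refinement to the local amplitude extremum — squaring makes
the detector polarity-robust. The synthetic ECG generator places
Gaussian bumps (P, Q, R, S, T) per beat, scaled to the local RR interval,
and stores the trace in raw adu so the normalizer is exercised on every
round trip. A minimal WFDB reader (formats 16 and 212) lets the same
pipeline run on clinical records where available; all tests run on
synthetic data.

## RR features and the classifier

Seven features per subject: mean RR; normalized max difference
$(\max - \min)/\mu$; RMSSD with the denominator $n - 2$ as printed in the
source formulation (where $n$ counts intervals; the count-of-differences
denominator is available via `rmssd_denominator = "n_diff"`, and with
exactly two intervals the default is reported `NA` rather than
fabricated); coefficient of variation with sample SD; normalized absolute
deviation; age; gender (male = 1). Features are min–max scaled to [0, 1]
with constants fit on the training split only.

The network is three sigmoid layers of 8, 16 and 1 units (225
parameters). The feature vector has 7 dimensions, so the "input layer" of
8 units is the first weight layer, not the feature count. Weights
initialize from Normal(0, 1/fan-in), biases at zero. Training minimizes
MSE by Levenberg–Marquardt: per epoch the damped normal equations
$(J^\top J + \mu I)\,\delta = -J^\top r$ give a candidate step, accepted
only if training MSE decreases (otherwise $\mu \times 10$ and retry; on
acceptance $\mu / 10$; $\mu_0 = 10^{-3}$; $\mu > 10^{10}$ aborts).
Early stopping keeps the best-validation parameters (ties keep the
earlier epoch). The data split is 70/15/15 by largest-remainder rounding
(33 examples → 23/5/5), stratified by label. The decision threshold
is 0.5.

## What the synthetic cohort does and does not show

Normal subjects draw RR intervals from a low-variance Gaussian process
(CoV 2–4.5%); arrhythmic subjects from a high-variance process
(CoV 16–28%) with ectopic-like premature beats and compensatory pauses
(×0.55 / ×1.6 at 12% incidence); ages 20–83, both genders. These classes
are linearly separable in the CoV/RMSSD features by construction, so the
classifier's near-perfect accuracy on this cohort demonstrates that the
training machinery works — not that the feature set separates real
arrhythmias, where rhythm classes overlap, recordings carry artifacts,
and prevalence is unbalanced. The same caveat applies to the radar
simulator: it contains no clutter, multipath, antenna pattern, or
multiple targets, so passing recovery tests bounds algorithmic error,
not field performance.

## Numerical choices and degenerate inputs

* Phase extraction maps $-1 + 0j$ to $+\pi$ (half-open branch).
* Bin-selection ties break toward the smaller bin; `which.max` semantics.
* Peak rejection with SD = 0 uses a tolerance band of width
  max(SD, 10⁻⁹ s), so perfectly regular trains lose nothing.
* Sample conventions: variance/SD use $n - 1$; skewness is the adjusted
  Fisher–Pearson coefficient (population moments, small-sample factor);
  Tukey fences use linear-interpolation quartiles. Zero-variance input
  reports skewness and $R^2$ as `NA`.
* $R^2$ follows the source's convention — residuals against the paired
  reference but total sum of squares around the *estimate* mean —
  with the textbook reference-mean convention behind an option.
* Problem sizes in the test suite (512-chirp observations, 20-seed noise
  sweeps, 200-subject cohorts, 10⁵–10⁶-point integration grids) were
  chosen so the full suite completes in a few minutes on one core while
  leaving each property's expected effect far above its tolerance.

## Known limitations

* Single target, single receive channel; the angle-of-arrival term is a
  constant phase offset, not a beamformer.
* Heart rates below 48 BPM alias against the cardiac band's lower edge
  and are flagged rather than estimated.
* The energy mask cannot detect motion large enough to alias the
  slow-time phase (> λ/4 per chirp interval ≈ 20 mm/s); such windows
  decorrelate instead and typically surface as out-of-band rates.
* The Levenberg–Marquardt implementation builds the full Jacobian per
  epoch — appropriate for hundreds of examples and 225 parameters, not
  for large networks.
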