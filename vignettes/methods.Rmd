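---
title: "Methods: heart-rate and respiratory variability features for one-hour-ahead VT prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heart-rate and respiratory variability features for one-hour-ahead VT prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vtpredict)
```

## The problem and the model

Ventricular tachycardia (VT) is a rapid ventricular rhythm that can degrade
into fibrillation and sudden cardiac death.  Coronary-care-unit monitors
continuously record a lead-II ECG and a respiration trace; the question this
package addresses is whether a 5-minute window of those two signals, taken
roughly one hour before a VT alarm, can be distinguished from a window taken
during a stable period.

The method is a classical feature-then-classifier pipeline:

1. **R-peak detection** on the ECG (band-pass 5--15 Hz, derivative, squaring,
   150 ms moving-window integration, adaptive signal/noise thresholds with
   search-back, 200 ms refractory period, apex refinement on the raw signal).
2. **Ectopic handling** on the RR series.  An interval is suspicious when it
   deviates more than 20% from the median of its five nearest accepted
   neighbours; beats bounding suspicious intervals are re-estimated under the
   integrated pulse frequency modulation (IPFM) model, in which the k-th beat
   satisfies `integral_0^{t_k} (1 + m(t)) dt = k * T`, so the cumulative beat
   index is a smooth monotone function of time and a displaced beat can be
   re-placed by monotone cubic interpolation of time against index through
   the clean beats.  Flagged beats at the series edges are dropped.
3. **HRV features** (11): mean NN, SDNN, RMSSD, pNN50 (strictly greater than
   50 ms) in the time domain; VLF (0--0.04 Hz), LF (0.04--0.15 Hz), HF
   (0.15--0.4 Hz) and LF/HF from a Welch periodogram (512-point periodic Hann
   segments, 50% overlap, window-power normalization) of the NN tachogram
   resampled at 7 Hz by cubic splines and detrended by a smoothness-priors
   high-pass (-3 dB near 0.035 Hz); Poincare SD1, SD2 and SD1/SD2.
4. **RRV features** (3): the respiration trace is band-passed to
   0.1--0.5 Hz (zero phase), positive peaks are detected with a prominence
   threshold of 0.2 interquartile ranges, and the breath-to-breath periods
   are summarized as RPdM (mean), RPdSD (sample SD) and
   RPdV = 100 RPdSD / RPdM.
5. **Classification** by a one-hidden-layer backpropagation perceptron with
   targets +1 (pre-VT) and -1 (control), trained until the MSE falls below
   1e-5 or an epoch cap; three models are trained on one shared stratified
   2/3 split: HRV-only (11 inputs, 5 hidden), RRV-only (3 inputs, 5 hidden)
   and combined (14 inputs, 13 hidden).
6. **Evaluation**: sensitivity, specificity, accuracy, PPV, NPV at the
   natural threshold 0, and the ROC curve with trapezoidal AUC (which equals
   the pairwise Mann--Whitney statistic exactly, ties counting one half).

## Units

All intervals are carried in **seconds** and band powers in s^2.  Published
tables in this area sometimes label the same quantities "ms"/"ms^2" while
printing second-scale values (an SDNN of 0.061 is physiologic only in
seconds); the package states its units explicitly and never rescales.

## Conventions and numerical choices

* **SD conventions.** SDNN, SD1 and the dispersion inside RMSSD use the
  population convention (divide by n), under which `sd1 = rmssd / sqrt(2)`
  and `sd1^2 + sd2^2 = 2 * sdnn^2` hold exactly and serve as machine-precision
  test oracles.  `sd2` is defined as `sqrt(max(0, 2 sdnn^2 - sd1^2))`; the
  clamp can only engage on degenerate few-beat series far outside the regime
  of a 5-minute window.  RPdSD uses the sample convention (n - 1) because a
  window holds only on the order of a hundred breaths.
* **Welch normalization.** The one-sided PSD integrates to the signal
  variance on long stationary signals; band powers are trapezoidal integrals
  over the grid points inside each band.  A single rectangular full-length
  segment reproduces the plain periodogram exactly, which is tested against
  a brute-force DFT.
* **Detrending.** The smoothness-priors trend (second-difference penalty,
  solved as a pentadiagonal system) acts as a high-pass with -3 dB near
  0.035 Hz, chosen just below the VLF/LF boundary.  VLF is computed after
  detrending, which attenuates part of that band; this mirrors the pipeline
  order stated for the original analysis and is accepted.
* **Filters.** Butterworth designs go through the analog prototype and
  bilinear transform; zero-phase filtering uses odd-reflection padding with
  steady-state initial conditions.  The respiration band-pass is realized as
  an order-4 high-pass plus order-4 low-pass cascade because a direct
  transfer-function band-pass of 0.1--0.5 Hz is numerically unstable at
  higher sampling rates.
* **Decision threshold.** A score of exactly 0 is assigned to control -- the
  conservative choice for an alarm's positive predictive value.
* **Training.** Hidden activations are tanh, the output is linear, inputs
  are z-scored by training-set statistics (feature scales span five orders
  of magnitude, so normalization is required for gradient descent to make
  progress).  Learning rate (default 0.01), optional classic momentum, the
  epoch cap (default 50000) and uniform initialization scaled by fan-in are
  this package's choices; the +-1 target coding and the 1e-5 MSE stopping
  rule are inherited from the method being reproduced.

## The synthetic-data generator

The clinical recordings behind the method are not public, so the package
ships a generator whose defaults emulate the published group statistics
(means and SDs of all 14 parameters for 52 pre-VT and 52 control windows;
see `group_stats()`).

* **RR series** come from the forward IPFM model: beats fire when the
  integral of `1 + m(t)` crosses multiples of the mean period.  `m(t)` is an
  LF tone at 0.095 Hz plus an HF tone at 0.275 Hz (mid-band, incommensurate)
  plus band-limited VLF drift (0.004--0.030 Hz).  Component amplitudes carry
  a `1/sinc(f T)` correction for the interval-averaging of the beat process
  so the realized SDNN lands on target.  The residual variance is placed in
  the VLF drift deliberately: the published VLF + LF + HF powers account for
  only about 60% of SDNN^2, and drift contributes to SDNN while staying out
  of the LF/HF analysis bands for any heart rate.
* **ECG** is a sum of stereotyped Gaussian P-QRS-T bumps (R amplitude 1 mV)
  with white noise (default 2% of the R amplitude, a clean monitor-quality
  trace); the R apex lands within half a sample of each beat time.  Default
  sampling rates are 250 Hz (ECG) and 62.5 Hz (respiration), typical
  patient-monitor values; the true monitor rates were never published.
* **Ectopics** (default 1/min) advance a sinus beat by 40% of the preceding
  RR interval and leave the next beat unchanged, producing the classic
  short-interval + compensatory-pause pair.  Beats whose shortened interval
  would be unrenderable (< 0.27 s) are not eligible.
* **Respiration** is a pulse train: each breath is a symmetric Hann
  inspiration bump centered on its breath boundary, with a shallow negative
  expiration lobe sized so every breath integrates to zero (no net area
  means the 0.1 Hz high-pass edge produces no undershoot ringing, which
  would otherwise create spurious peaks).  Periods are i.i.d. truncated
  normal on 1.6--10 s -- 1.6 s because the mandated 0.1--0.5 Hz analysis
  band merges peaks spaced more tightly -- with latent parameters
  moment-matched so the realized mean and SD equal the targets.  Overlapping
  filtered pulse tails drag each peak toward its wider neighbour by about
  0.063 times the period asymmetry (measured once from the band-pass forward
  model); the rendered boundaries are pre-compensated by that amount.
* **Cohorts** draw per-window parameters from the group statistics with
  mean-matched truncation, so cohort means stay on target despite physical
  bounds.  The respiration pair (RPdM, RPdV) must satisfy a joint
  feasibility constraint; its latent means are calibrated by a fixed-seed
  Monte Carlo so the accepted draws keep both group means.  RPdSD is derived
  as `rpdm * rpdv / 100`: the published RPdM/RPdSD/RPdV triple is jointly
  unsatisfiable under independent draws (the printed per-record RPdV is a
  mean of ratios), and drawing RPdV directly preserves the one strongly
  significant group difference.
* **Feature-level cohorts** (`gen_feature_cohort()`) skip the waveforms:
  the 11 non-ratio parameters are drawn independently from mean-matched
  truncated normals and the 3 ratio parameters are recomputed for internal
  consistency.  Because RPdV is then a derived ratio, its group direction
  follows RPdSD/RPdM rather than the published RPdV row -- acceptable for
  classifier fixtures, where discriminability rather than direction matters.

### What a green test does and does not establish

The generator matches marginal group statistics of the 14 parameters; it
does not model any physiological mechanism linking respiration to VT onset,
inter-parameter covariance (beyond the derived ratios), nonstationarity
within a window, artifact bursts, electrode noise, or morphology changes.
Green calibration tests establish that the extraction pipeline recovers what
the generator put in and that the published effect sizes are learnable by
the perceptron -- they do not re-establish the published clinical
performance (AUC 0.93 on real recordings), which would require the original
data.

## Reproducibility

Every stochastic step takes an explicit seed, and cohort generation derives
per-window child seeds from one master seed.  Seeding R's Mersenne-Twister
thousands of times and using the first draws of each stream produces
visibly correlated values across streams, which biased early cohort means by
several standard errors; `with_seed()` therefore discards the first 16
draws after each seeding.  Identical seed and configuration give
byte-identical feature tables, model files and reports.

## Known limitations

* Exact time-rescaling invariance of the respiration statistics cannot hold
  across k in {0.5, 2}: that range spans the entire fixed 0.1--0.5 Hz
  analysis band, and near the band edges the filter itself smooths
  breath-to-breath variability.  The package tests the invariance
  components that survive this physics (mean-period scaling; amplitude
  invariance in full).
* Breathing faster than ~0.55 Hz is censored by design of the published
  band-pass; the generator does not attempt to produce it.
* The R-peak detector assumes an upright R wave in lead II; inverted-QRS
  morphologies would require a polarity flip upstream.
* The hidden-size defaults (5/5/13) reproduce the published architecture;
  `select_hidden()` reproduces the implied selection procedure but on a
  validation split, since how "best performance" was judged originally is
  not stated.
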