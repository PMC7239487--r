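---
title: "Methods: free-living EE estimation for preschool children"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: free-living EE estimation for preschool children}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(playEE)
```

# The estimation problem

Free play in 3–5-year-olds is made of short, irregular bouts — energetic
play, walking, running, seated rest — whose energy cost must be recovered
from wearable accelerometry because indirect calorimetry is impractical
outside supervised sessions. The pipeline calibrates per-window predictors
of energy expenditure (EE, kcal·min⁻¹) on paired accelerometer/calorimeter
recordings and quantifies how well they generalize to unseen children.
The unit of analysis is the 10 s window: small enough to resolve bout
structure, large enough for stable spectral estimates at 100 Hz.

# The criterion (indirect calorimetry)

Breath-by-breath VO₂/VCO₂ are assigned to left-closed 10 s bins, averaged
per bin, and smoothed with a 60 s moving average before Weir conversion.
Unstated details fixed here (all configurable in `smooth_gas()`):

* **Alignment.** The 60 s average is *centred* by default (window of six
  bins, `[i-3, i+2]`), with shrinking windows at the series edges; a
  trailing variant is provided for sensitivity analyses. Centred smoothing
  keeps the criterion phase-aligned with the movement signal, which matters
  because windows are matched by start time.
* **Empty bins** are linearly interpolated from their neighbours before
  averaging; edge gaps carry the nearest value. At the respiratory rates of
  this age group (≳25 breaths/min) empty 10 s bins essentially never occur.
* **Weir form.** The abbreviated two-term equation
  EE = 3.941·VO₂ + 1.106·VCO₂ omits urinary nitrogen, the standard choice
  for portable calorimetry where urine collection is impossible.
* **Resting EE** comes from Schofield's weight-and-height equations for
  3–10-year-olds, since sex, height and mass are the demographics recorded.
  MET normalization divides the criterion by this prediction, making errors
  comparable across body sizes.

# The feature catalog

`extract_features()` computes 28 statistics per axis and per vector
magnitude plus 6 cross-signal quantities (118 total). The field's feature
lists name these statistics without operational definitions; the definitions
below are locked by brute-force oracle tests (tolerance 1e-9 relative on
hundreds of random windows):

* percentiles by linear interpolation (type 7); IQR = P75 − P25;
* skewness and kurtosis as standardized third/fourth central moments
  (population moments; kurtosis is the Pearson form, not excess);
* coefficient of variation = SD/|mean| × 100, sentinel 0 at zero mean;
* median/zero crossings count sign changes of the median-/mean-centred
  signal, with exact zeros carrying the previous sign (leading zeros adopt
  the first non-zero sign) — this makes the count independent of how ties
  are sampled;
* mean absolute deviation about the mean; power = mean squared sample;
  log energy = Σ log(s² + ε) with ε = 1e-10 guarding log 0;
* lag-1 autocorrelation as the Pearson correlation of the signal with its
  one-sample shift, sentinel 0 for constant windows (as for all
  correlation-type features, so degenerate windows never propagate NA into
  the models);
* activation features: the mean-removed signal is rectified and filtered
  with a zero-phase 4th-order Butterworth lowpass at 5 Hz
  (`signal::filtfilt`, so run boundaries are not phase-shifted); runs above
  0.01 g (configurable) yield active-sample count, run count, mean run
  duration and run-duration SD (0 with fewer than two runs);
* dominant frequency/magnitude: magnitude spectrum of the mean-removed
  window, rectangular taper, restricted to 0.25–5.0 Hz with inclusive
  endpoints; ties resolve toward the lower frequency. No taper is used
  because windows are short and the statistic is an argmax, not a density
  estimate;
* orientation: from the per-axis means, tilt = arccos(m_z/‖m‖),
  roll = atan2(m_y, m_z), pitch = atan2(−m_x, √(m_y² + m_z²)), degrees;
  zero-norm mean gives the 0 sentinel.

Windows are strictly non-overlapping and complete: a trailing partial
window is discarded, so n samples yield ⌊n/1000⌋ windows at 100 Hz.
Synchronization with the criterion is exact start-time matching by default
(tolerance 1e-6 s), with a nearest-within-tolerance mode for shifted grids.

# Feature selection

`mrmr_select()` is greedy forward mRMR for a continuous target: relevance
is the univariate regression F statistic (r²(n−2)/(1−r²)); the first pick
maximizes relevance; later picks maximize score = relevance × (1 − R²),
where R is the candidate's *largest* absolute Pearson correlation with the
already-selected set. This combination was a genuinely open design choice,
and two simpler variants were rejected on planted-recovery grounds:

* a relevance/redundancy *quotient* lets an exact duplicate of the top
  feature score F/1 = F, which outranks every noise feature;
* *mean* redundancy lets the duplicate escape the penalty as soon as
  unrelated features join the set (mean(1, 0.12) ≈ 0.56).

The adopted score is an approximate partial F: a candidate is credited only
for the variance share its most collinear selected partner does not already
carry, so a perfect copy scores exactly 0 at every step while independent
noise keeps a positive score. Ties break toward catalog order, selection is
deterministic, and the k = 10 set is a prefix of k = 15 and k = 20 by
construction. A mutual-information variant (equal-frequency discretization,
10 bins, classic MIQ quotient) is available via `relevance = "mi"`.
Selection runs on pooled training windows (one model per placement), and on
kcal·min⁻¹ rather than METs — MET scaling is a per-subject constant, so it
changes relevance only through between-subject weighting.

# Models and cross-validation

The three architectures use the published hyperparameters as fixed
defaults: RF with 500 trees and 3 features per split (`randomForest`);
ε-insensitive RBF SVM with cost 6.0, γ 0.1, ε 0.1 (`e1071`; ε and the
maximum of 500 ANN iterations are unstated upstream and documented here);
single-hidden-layer ANN with 11 neurons, weight decay 0.1 and a linear
output (`nnet`). SVM and ANN inputs are standardized with training-fold
mean/SD (reapplied at prediction); RF consumes raw features. A constant
training target is represented for the SVM by an explicit constant
predictor, which is the ε-SVR solution libsvm refuses to emit. Negative
EE predictions are clipped to 0 — EE is physically non-negative.

LOSO-CV holds out every child in turn; mRMR is re-run inside each training
fold by default (leakage-safe; a fixed-feature mode exists for fidelity
experiments in which selection is done once on all training data). The
free-living arm uses fold-nested mRMR at k; the retrained-laboratory arm
refits the laboratory architectures on the free-living windows with the
full catalog, since the original laboratory feature sets and weights are
not available. Hold-out evaluation refuses any subject overlap with
training by construction.

# The synthetic-data generator

The generator defines the study conditions under which all recovery claims
are tested. Per child: a randomized schedule whose expected per-session
bout totals match the observed free-play averages (energetic play 11.7,
walking 2.8, running 2.4, seated 4.3 min, rescaled to the 1200 s session —
the rescaling shrinks the seated expectation to ≈4.1 min); a per-second MET
trajectory that follows activity targets (seated 1.3, walking 3.7, running
6.0, energetic play 4.5 METs) through first-order on/off kinetics with
τ = 30 s; slot EE = Schofield REE × slot-mean MET × a lognormal factor with
σ = 0.10 (biological variability); breaths at a MET-dependent respiratory
rate whose VO₂ inverts the Weir equation at RER 0.85 with 3% lognormal
measurement noise; and accelerometer signals built from site-specific
gravity orientation plus a band-limited oscillation whose amplitude
(0.16 g/MET hip, 0.28 g/MET wrist) and dominant frequency
(0.6 + 0.33·MET Hz, inside the 0.25–5 Hz analysis band) grow with activity
intensity, plus 0.02 g white noise, clipped at ±8 g. Movement tracks the
activity target instantly while EE lags through the kinetics — mechanics
lead metabolism.

`truth_ee` is exact ground truth in the sense that the breath stream
encodes it before measurement noise; with all noise terms at zero, running
the calorimetry module on generated breaths recovers it within 2% in steady
state (asserted as a cross-module test). Anthropometrics are age/sex
normals with means rounded from growth references, as only the age/sex
distribution of the study sample is known.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: biomechanically realistic limb trajectories,
device-specific artefacts (the proprietary binary format, calibration
drift, face-mask leaks), posture transitions faster than the kinetics
model, or between-child differences in movement economy (the activity→EE
map is shared across children up to REE scaling and noise). Error
magnitudes on synthetic cohorts are consequently optimistic relative to
human data; structural claims (leakage-free CV, selection behaviour,
calibration of the statistical battery, monotone degradation with noise)
are the transferable results.

# Agreement statistics

Session-level agreement follows the convention of plotting percent error,
(observed − predicted)/observed × 100, against the observed session total:
mean bias and 95% limits of agreement (bias ± 1.96 SD) in percent and in
raw kcal; an OLS regression of percent error on observed kcal for
proportional bias; and regression-based 95% prediction limits
(fit ± 1.96 residual SD) at requested magnitudes — both constant LOA and
regression-based limits are emitted because either convention appears in
agreement plots. The model comparison is a classic unreplicated
within-subject ANOVA: subject is the blocking factor, the error term is the
model×subject interaction mean square, F on (m−1, (m−1)(n−1)) df without
sphericity correction, with Fisher LSD (unadjusted pairwise t on the pooled
error MS) afterwards. Exactly identical model columns are reported as
F = 0, p = 1 rather than a ratio of rounding residue.

# Problem sizes and numerical tolerances

The shipped tests use cohorts of 4–25 children and sessions of 60–1200 s,
chosen so the whole suite (including the parameter-recovery and
hold-out-consistency studies at the full 15 + 10-child, 20-minute design)
completes in well under half an hour on a single core. Feature values are
locked to brute-force oracles at 1e-9 relative tolerance; closed-form
calorimetry values at 1e-6; the RF parameter-recovery bound is 1.5× the
generator's slot-noise floor σ·mean(EE) (the criterion's 60 s smoothing
averages slot noise down, so observed RMSE typically sits *below* the
floor); RM-ANOVA type-I error is checked at 0.05 ± 0.02 over 1000 null
matrices and LOA coverage at 93–97% on 10⁴ simulated differences.

# Known limitations

* The activation-feature and crossing definitions are plausible
  reconstructions locked by oracles, not recoveries of the original
  studies' exact code.
* Lag/lead features from adjacent windows are deliberately excluded, so
  window predictions ignore temporal dependence beyond the 60 s criterion
  smoothing.
* The retrained-laboratory arm shares this package's feature catalog; it
  reproduces the published architectures, not the published feature sets.
* Bland–Altman inference treats subjects as independent; with 10 hold-out
  children the proportional-bias regression has wide uncertainty, which the
  reported slope SE makes explicit.
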