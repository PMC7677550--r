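---
title: "Methods: from exploratory locomotion to stress-evoked vagal withdrawal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from exploratory locomotion to stress-evoked vagal withdrawal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Cardiac vagal withdrawal under threat — falling heart rate variability (HRV)
with rising heart rate — is a physiological signature of stress
vulnerability. This package implements a pipeline that predicts an
integrated HRV index (iHRV), measured while a subject explores a dark,
threatening virtual maze, from high-dimensional locomotor behavior recorded
earlier in two benign scenarios: an empty virtual room (a human open-field
test) and an elevated alley that narrows from 3.5 m to 0.5 m (a human
elevated-maze analogue). The room is 3.50 m by 6.00 m; each scenario lasts
90 s.

Because no subject-level data are publicly deposited for this paradigm, the
package ships a synthetic-cohort generator as a first-class, tested module.
Every downstream stage — R-peak detection, RR cleaning, HRV summaries, iHRV
construction, behavioral featurization, feature selection, boosted-tree
modelling, SHAP attribution — is exercised against the generator's latent
ground truth.

## Cardiorespiratory processing

**Decimation.** `decimate_signal()` reproduces the classic FIR decimator
(30-tap Hamming windowed sinc at the new Nyquist, applied forward-backward
for zero phase, then downsampling): ECG 1000 to 500 Hz, respiration to
100 Hz.

**R peaks.** `detect_r_peaks()` is a Pan-Tompkins chain: 5-15 Hz band-pass,
five-point derivative, squaring, 150 ms moving integration, adaptive dual
thresholds with search-back and a 200 ms refractory period. Detections are
refined in two stages: to the QRS energy peak within ±75 ms, then to the
raw-ECG maximum within ±25 ms. FIR filtering is zero-phase with mirrored
edge padding, so no group-delay correction is needed.

**RR cleaning.** `clean_rr()` applies a single-pass 3-standard-deviation
filter using the raw series' own mean and SD (the moments are deliberately
not robust and not iterated — the rule is applied once, literally), then
linearly interpolates flagged intervals between their nearest unflagged
neighbors; flagged endpoints copy the nearest unflagged value. The manual
visual-inspection step of laboratory practice is replaced by this automated
rule only.

**HRV formulas.** RMSSD, SDNN (sample SD, n−1), the HRV triangular index
(interval count divided by the modal count of a histogram with 1/128 s =
7.8125 ms bins anchored at 0 ms), and HR defined as 60000 / mean NN — the
HR formula is a package decision since acquisition software defaults are
not documented; it keeps HR consistent with the same segment the HRV
metrics use.

**Respiration rate.** Band-pass FIR 0.17-0.73 Hz (24 s kernel, zero-phase,
odd-reflection padding so slow oscillations keep their edge amplitude),
then peak detection with three gates: prominence of at least one robust SD
(1.4826 × MAD) of the filtered series, separation ≥ 0.8 s, width ≥ 0.4 s at
half prominence. Rate = peak count / duration. Two reading choices deserve
note. First, the "peaks above one robust SD" rule is implemented as a
*prominence* gate (the `findpeaks` convention): a height gate cannot pass a
clean sinusoid, whose robust SD (≈1.05 × amplitude) exceeds its own peak
height. Second, out-of-band input must come back missing, and a relative threshold
alone cannot reject it: after the band-pass, an out-of-band oscillation
leaves only noise, whose own peaks clear any self-referential threshold.
Two guards close this: the filtered series must retain at least 5% of the
raw signal's variance (otherwise there is no in-band respiratory content),
and estimated rates outside the passband-implied 10.2-43.8 breaths/min are
returned as missing with a warning.

**Segments.** `segment_summary()` computes {HR, RMSSD, SDNN, HRVTi, RR} per
segment using only intervals whose onset lies inside the segment; a segment
with fewer than 3 usable intervals is missing-flagged. The default
segmentation is consecutive 30-s blocks (three per session); the pipeline
itself uses the whole 90 s.

## The iHRV index

`fit_ihrv()` z-scores the five columns and eigendecomposes their
correlation matrix (correlation-matrix PCA is required for comparability of
bpm, ms and breaths/min; it also makes scores invariant to rescaling any
raw column). Components are oriented so the three HRV loadings sum
positive. A candidate component must load at least +0.3 on each of RMSSD,
SDNN and HRVTi, at most −0.3 on HR, and at most 0.2 in magnitude on
respiration rate; among candidates the one with the largest explained
variance wins. The numeric bounds (0.3 / 0.2) are package
operationalizations of "loads on HRV and HR but not on respiration", and
both are arguments. The pipeline fits and scores the iHRV on the
dark-maze (scenario 3) whole-session summaries, since that scenario's vagal
withdrawal is the prediction target; this is configurable.

## Behavioral featurization

Trajectories are linearly resampled to a uniform rate; positions are
smoothed with a 0.5-s moving average before central-difference
differentiation (odd-reflection padding keeps constant-velocity edges
artifact-free). The catalogue (~66 features) covers three families:

- **position**: corner/wall distances, center-zone occupancy and the
  center/periphery time ratio (capped at duration/dt and flagged when the
  periphery is never visited), grid coverage, center-entry latency,
  kinematics (speed, RMS horizontal and vertical acceleration, path
  length), trajectory shape (focus = 1 − entropy of the 0.25 m occupancy
  grid over visited cells / log K; concentric = path-length fraction moving
  within 45° of the tangent around the room center), head scans (yaw
  excursion beyond ±30° from heading returning within 3 s, counted only
  while walking faster than 0.2 m/s), and the alley measures (per-patch
  dwell, threshold crossing times, time on the 1-m starting board, time on
  the narrowest 0.5-m ledge, maximal longitudinal distance, retreats).
  Never-reached crossing thresholds are right-censored at the session
  length rather than set missing, so exploration-limited subjects keep
  complete rows.
- **gait**: heel strikes detected as sustained (≥0.1 s) foot-speed drops
  below 0.15 m/s with foot height in its lowest quartile; strides from
  consecutive ipsilateral strikes give count, speed mean/SD/CV, length
  stats, duration, stance fraction, cadence.
- **burst**: runs of gait cycles with gaps < 1.5 s, and immobility
  (horizontal speed < 0.1 m/s sustained ≥ 2 s).

The original study catalogued 172 features whose exact formulas live in
unavailable supplementary tables; this catalogue is a documented,
extensible subset guaranteed to include the nine features that dominate the
published attribution ranking (corner distance, vertical alley
acceleration, center/periphery ratio, narrow-ledge time, focus, stride
speed variability, walking head scans, board time, longitudinal distance).

## Feature selection and modelling

The cascade order is fixed: zero-variance removal (variance ≤ 1e−12, so
float-noise columns also drop), a Spearman screen at |rho| ≥ 0.1 against
the iHRV scores (absolute value by design — a strong negative correlate
should survive; a signed variant is available), then per-family
(position / gait / burst) Gaussian Lasso with 10-fold cross-validation,
seeded folds, and the minimum-CV-error penalty (the 1-SE rule is the other
defensible choice; minimum-error was fixed here and recorded). The final
set is the union of the family selections. Selection runs on the
training stratum only: subjects with low (STAI-T < 35) or moderately high
(> 45) trait anxiety train the model; moderate subjects (including exact
boundary values, a package decision) form the test set.

The regressor is a squared-error gradient-boosted tree ensemble written in
compiled code in this package (no boosting library is assumed at run time),
with exact greedy splits, xgboost-style gain with L2 leaf penalty
lambda = 1, and the four canonical tuned hyperparameters: learning rate eta
(log-uniform 0.01-0.3), maximum depth (2-8), minimum child weight (1-10)
and boosting rounds (log-uniform 50-1000). The bounds bracket common
defaults; the study names the tuned parameters but not their ranges.
Tuning is a tree-structured Parzen estimator: seeded random start-up,
good/bad split at the 25% quantile of observed CV errors, independent
per-dimension Gaussian KDEs, candidates scored by the good/bad density
ratio. The objective is mean 10-fold CV squared error with a fold
assignment fixed once per tuning run.

Attribution uses the exact path-dependent tree-SHAP algorithm (also
compiled here). Additivity — base value plus per-row attribution sum equals
the prediction — is asserted in the tests to 1e−6, and the implementation
is checked against a brute-force Shapley enumeration over feature subsets
on small ensembles.

## The synthetic cohort: what it emulates and what it does not

A standard-normal latent vulnerability trait drives, deterministically and
monotonically: wall-hugging (thigmotaxis) bias and center avoidance upward,
locomotor speed variability downward, and — scaled by the `coupling` effect
size — scenario-3 mean NN, beat-to-beat SD and RSA amplitude downward
(vagal withdrawal). Baseline physiology varies between subjects (mean NN
900 ± 40 ms, NN SD 45 ± 6 ms, RSA 28 ± 4 ms, respiration 12-18
breaths/min), independent of the trait; trait anxiety is uniform on 20-60
and independent of vulnerability, mirroring the published null association
between questionnaire anxiety and iHRV. Trajectories are biased
random-waypoint walks with lognormal segment speeds and exponential pauses;
yaw adds scripted 40°/1-s scan pulses at a Poisson rate decreasing in
vulnerability; gait places alternating heel strikes every half stride
(0.7 m default) of walking distance; ECG is a Ricker-wavelet QRS train with
P/T waves, baseline wander and white noise at a stated SNR (15 dB cohort
default; detector acceptance is checked at 10 dB); respiration is a noisy
sinusoid.

What a green test establishes: that every stage recovers the generator's
ground truth under the stated noise, and that the full pipeline recovers a
latent behavior-physiology coupling at realistic cohort size (n = 140,
test-set Pearson r ≥ 0.5 against measured iHRV). What it does not: the
generator's linear trait maps, waypoint kinematics and stationary
physiology are idealizations — real ECG artifacts, non-stationary gait,
postural sway and questionnaire structure are out of its scope, so green
tests here do not certify performance on human recordings. With uniform
STAI-T, the 35/45 cutoffs put roughly three quarters of subjects in the
training stratum (about 105/35 at n = 140) rather than an even split; the
test stratum is still ample for the correlation checks.

## Numerical choices and degenerate inputs

- FIR kernels: band-pass 0.3 s at 5-15 Hz (ECG), 24 s at 0.17-0.73 Hz
  (respiration); both zero-phase. FFT convolution is padded to a power of
  two for speed.
- Flat ECG or no supra-threshold peaks: empty beat series with a warning,
  never an error. Fewer than 4 beats cannot be cleaned; fewer than 3
  intervals yield missing HRV summaries, flagged.
- The center/periphery ratio guard, right-censored crossing times, and the
  respiration rate band flag are all documented above; each has a test.
- Determinism: every stochastic function takes a seed; the pipeline derives
  per-stage seeds from the master seed via a fixed integer mix, so whole
  runs are bit-reproducible (asserted on the evaluation JSON).

## Known limitations

- The feature catalogue is a ~66-feature documented subset, not the full
  172; parity would require the original supplementary formulas.
- The TPE tuner treats dimensions independently (no multivariate KDE); for
  a four-dimensional space this is standard and cheap, but it cannot model
  parameter interactions.
- Pan-Tompkins is tuned for the synthetic morphology at 500 Hz; pathological
  rhythms (ectopy, atrial fibrillation) are not emulated or claimed.
- The boosted-tree engine implements exact greedy splits only — no
  histogram approximation, monotone constraints or sparsity handling — which
  is appropriate at cohort scale (hundreds of rows) but not for large data.
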