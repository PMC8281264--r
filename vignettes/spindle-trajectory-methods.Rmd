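---
title: "Methods: spindle detection, sigma power, and maturational trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spindle detection, sigma power, and maturational trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindletraj)
```

# Scope

spindletraj implements a complete analysis chain for developmental sleep-EEG
studies: automatic detection of N2 sleep spindles on central derivations
(C3/C4), absolute NREM sigma power from per-epoch spectral analysis, and the
statistics used to describe how these quantities mature across childhood and
adolescence — polynomial age trajectories with covariate adjustment,
standardized piece-wise slopes, covariate-adjusted group contrasts by sex and
pubertal (Tanner) stage, longitudinal percent-change models, and Lin's
concordance for agreement between channel-reference dialects. Because
population PSG recordings cannot be redistributed, the package ships a
synthetic polysomnography generator and a cohort simulator with known ground
truth; every estimator is validated by parameter recovery against those
generators.

# The spindle detector

Spindles are bursts of 10–16 Hz activity that stand out from the N2
background. The detector quantifies "standing out" with a sliding spectral
ratio:

1. The signal is band-limited to 0.3–30 Hz (zero-phase Butterworth, order 4
   per pass) so recordings from different acquisition systems are
   comparable.
2. A 1-s FFT window advances in 0.2-s steps (five window starts per second)
   through the scored record. **Power S** is the summed spectral power over
   10–16 Hz in each window (µV²; the per-window spectrum is calibrated so a
   unit-amplitude in-band sinusoid carries 0.5 µV²).
3. Each window is assigned to the 30-s epoch containing its start, and its
   **power S ratio** is power S divided by the 30th percentile of power S
   over that epoch's windows. The percentile reference adapts to each
   epoch's own background level, which makes the detector invariant to
   amplitude scaling of the whole signal (a property the test suite
   asserts).
4. A spindle candidate opens at the first window of a run of at least five
   consecutive windows with ratio > 3, and closes at the first later window
   where the ratio falls below 1.5 **or** power S falls below 20% of the
   running peak — as power decays, whichever of those two thresholds is the
   higher one is crossed first, so first-crossing implements the "whichever
   was higher" rule. If neither happens within 5 s of onset, the whole run
   is discarded; sustained elevation is not a spindle.
5. Candidates are deleted when they overlap a scored arousal (any overlap by
   default; full containment is configurable), when their mean power S ratio
   is below the corresponding alpha- or beta-band ratio (each band against
   its own 30th-percentile reference — this removes alpha intrusions and
   broadband artifacts that leak into the 10–16 Hz sum), or when their
   midpoint lies outside N2.

Each surviving event is characterized by its peak power S (maximum 1-s
window power within the event), its peak frequency (maximal spectral bin
over 10–16 Hz of the peak window, refined to 0.25-Hz resolution by 4×
zero-padding, since a 1-s window natively resolves only 1 Hz), and a fast
flag (peak frequency in 12–16 Hz, lower edge inclusive). Subject-level
metrics are density (events per minute of N2), mean peak frequency, mean
peak power, and fast-spindle percent, computed per channel and averaged
across the two central derivations.

## Detection-unit reading

The published description applies the FFT to "1-s epochs advancing every
0.2 s (five windows per second)" and requires the ratio criterion over
"five consecutive epochs". We read those 1-s sliding windows as the
detection units: five consecutive windows span 0.8 s of onsets plus the 1-s
window, so the shortest detectable event footprint is ~1.8 s of signal.
Window starts advance continuously across the record (150 starts per 30-s
epoch); a window may straddle an epoch boundary and belongs to the epoch
containing its start. An earlier realization that tiled windows strictly
inside each epoch (146 starts) broke the five-per-second bookkeeping and
made spindles at epoch boundaries undetectable.

## Analysis-window taper

The published algorithm does not name a taper for the 1-s FFT. The default
here is a Tukey window with 25% edge taper rather than a full Hann. The
reason is quantitative: real (and simulated) spindles run 0.5–2 s, and with
a full Hann taper a burst of ≤ 0.8 s contributes almost nothing to windows
in which it sits off-center, so it elevates only 3–4 consecutive windows and
can never satisfy the five-window rule regardless of its amplitude. With a
Tukey(0.25) taper the detector reaches event-level sensitivity ≈ 0.95 and
precision ≈ 1.0 at spindle amplitude 3× the background RMS, versus ≈ 0.90
sensitivity with Hann, while the flanking alpha/beta comparison bands —
which exist precisely to catch spectral leakage — continue to reject
out-of-band bursts (a pure 9-Hz burst is rejected via the alpha ratio in the
test suite). `detector_config(taper = "hann")` restores the fully tapered
variant. Bursts shorter than ~0.7 s remain undetectable in principle under
the five-consecutive-window rule; this is a property of the published
criterion, not of the realization.

Other conventions: candidate onsets are the first supra-threshold window
start and offsets the end of the terminating window; events re-triggering
within one window step of the terminating window are merged (measured
between window starts — measuring between tail-inclusive event intervals
over-merges and lets an alpha burst absorb an adjacent genuine spindle); the
ratio "within the presumptive spindle" for the alpha/beta rule is the mean
over the event's windows (`ratio_aggregate = "max"` is available); the
alpha and beta comparison bands default to the flanking, non-overlapping
intervals [7.5, 10) and (16, 25] Hz.

# Sigma power

Absolute NREM sigma power is computed independently of the detector, as a
surrogate with different failure modes:

- Band limit 0.3–30 Hz with an order-8 Butterworth characteristic, applied
  with zero phase.
- Per 30-s epoch, 22 Hann windows of 2.56 s at half overlap (1.28-s step) —
  exactly 22 such windows fit in 30 s — are FFT'd, calibrated, and averaged
  into one spectrum with 1/2.56 s = 0.390625 Hz bins.
- Sigma power is the sum over bins spanning 11.33–14.84 Hz, both edges
  inclusive. These printed limits are grid multiples of the bin width
  (bins 29 × 0.390625 = 11.328 and 38 × 0.390625 = 14.844 Hz), so band
  membership is resolved by snapping the edges to the nearest bin center;
  ten bins contribute.
- Epochs are rejected when their peak absolute amplitude exceeds 250 µV
  (configurable) or when they overlap an annotated artifact; the
  "adjustment for rejected epochs" is the mean of per-epoch sigma power over
  accepted N2 + N3 epochs only, which keeps the result an intensity (µV²)
  independent of record length. Channel values (C3, C4) are averaged.
- ECG-interference correction is exposed as a hook only; the default is a
  no-op, since no published procedure is available to reimplement.

A numerical note: an order-8 Butterworth band-pass with a 0.3-Hz edge at
100–200 Hz sampling is numerically singular in transfer-function (b/a) form
— forward–backward filtering diverges — so the band limit is realized as
zero-phase frequency-domain weighting by the exact analytic order-8
Butterworth magnitude on a reflection-padded signal. Pass-band (13 Hz:
gain 0.99999) and stop-band (50 Hz: gain 0.017) behavior match the analog
prototype; the test suite verifies power conservation of the whole chain
against time-domain variance within 5%.

The windows-per-epoch count, the 0.390625-Hz resolution identity, and the
0.5-µV² Parseval calibration for a unit sinusoid are asserted directly in
the acceptance tests.

# Trajectory statistics

Age trajectories are estimated on one row per subject with age truncated to
6–21 years. The model ladder fits cubic, quadratic, and linear age terms
top-down, always retaining lower-order terms, and keeps the highest-ordered
age term significant at p < 0.05 — mirroring common practice in
developmental spectral-EEG work. Covariates (sex, race/ethnicity, BMI, AHI,
psychiatric/learning disorder, PSG system as a nominal factor) enter
additively. Population mean curves with pointwise 95% CIs are obtained by
marginal standardization: each subject's covariates are kept, age is set to
the target value, and predictions are averaged; the CI uses the variance of
that averaged prediction. Extrema ages are the argmin/argmax of the fitted
age polynomial over [6, 21] (stationary points against endpoints, reported
to 0.1 year).

Two properties of this ladder are worth knowing. First, with noiseless
inputs the residual variance collapses and t statistics are numerical
noise; the implementation detects near-perfect fits and judges the top term
by whether it contributes to the fitted values at all. Second, because the
cubic term is tested at α = 0.05, a true quadratic is classified as cubic in
about 5% of replicates by type-I error alone — the attainable
degree-recovery rate is capped near 95% by the selection rule itself, and
simulation results should be read against that ceiling.

Standardized piece-wise slopes divide the outcome by its full-sample SD
(one SD for all segments, so slopes are comparable across segments) and fit
covariate-adjusted linear models within age segments 6–10, 11–14, 15–17,
and 18–21. Group contrasts (sex; Tanner 1–3 versus 4–5, with missing Tanner
excluded from Tanner contrasts only) are covariate-adjusted least-squares
means computed with emmeans using proportional weights, which reproduces
marginal standardization over the observed covariate distribution.
Longitudinal analyses model the percent change
$100\,(x_{fu} - x_{bl})/x_{bl}$ per follow-up age group (12–14, 15–17,
18–22), additionally adjusting for the baseline value and the length of
follow-up; rows with zero baseline are excluded with a warning, and percent
changes beyond 5 IQR from the median are flagged but excluded only on
request. No multiple-testing correction is applied by default.

Agreement between contralaterally and ipsilaterally referenced derivations
is summarized with Lin's concordance correlation coefficient
$\rho_c = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)$ (moment
variances), with a Fisher-z CI using Lin's asymptotic variance. $\rho_c$
never exceeds $|r|$ and equals it only when means and variances match; both
properties are asserted in the suite.

# The synthetic generators

**EEG.** The sleep-EEG generator composes, over a user-specified stage
sequence: a 1/f background (spectral shaping of white noise, exponent
exact on the PSD, default slope 1.5 and RMS 10 µV); spindle bursts as
sinusoids under a raised-cosine envelope (band power analytically known),
placed by a homogeneous Poisson process within N2 epochs with overlap
rejection — default 4/min of N2, 11–15 Hz, 0.5–2 s, 30 µV peak envelope
(3× the background RMS); alpha-range contaminant bursts (1/min of N2,
8–9.5 Hz); scored arousals (10/h, 3–10 s, mild 8–12 Hz activity); and
movement artifacts (15/h, 0.5–1.5 s, 500 µV), which at the default rate
leave roughly 85–90% of epochs accepted by the artifact criterion — the
range reported for careful automatic processing of pediatric PSG. A single
integer seed drives one RNG stream; identical seed and configuration give
bit-identical output. Ground truth (onset, offset, frequency, amplitude,
kind) is returned for every embedded event, and the suite verifies it is
recoverable from the clean burst component by direct envelope thresholding,
independent of the detector.

What the generator does **not** emulate: K-complexes, REM phasic activity,
EMG/respiratory channels, non-stationary background, realistic spindle
frequency-chirp, or physiologically calibrated Tanner timing. Detection
scores on synthetic data therefore bound algorithmic behavior (rule
correctness, threshold logic, leakage handling), not clinical performance
on real recordings.

**Cohort.** The cohort simulator draws ages uniformly (cross-sectional:
6–21; longitudinal: baseline 5–12 with follow-up intervals 6–13 years
clipped so follow-up lands in 12–22), assigns sex, race/ethnicity, BMI,
AHI, disorder flags, and PSG system codes, samples Tanner stages from a
cumulative-logistic model whose cutpoints sit 1.5 years later in males, and
generates outcomes as polynomial(age) + covariate effects + Gaussian noise,
with a shared subject-level intercept linking the two longitudinal waves.
Default trajectories emulate the qualitative developmental picture (density
and fast-percent inverted-U with vertices at 15.2 and 19 years; frequency
rising; spindle and sigma power falling), with residual SDs sized so the age
trajectory explains roughly half the outcome variance. The density
trajectory is kept well above zero across 5–22 years (≈2.6–4.5 spindles/min)
— both because pediatric N2 densities are of that order and because percent
change divides by the baseline value. Generating parameters are returned
alongside the table; OLS on a noiseless cohort recovers them to ≤ 1e-8
relative error in the suite.

# Problem sizes and numerical conventions

All time handling uses seconds from recording start, half-open intervals,
and 0-based 30-s epochs; an event ending exactly on an epoch boundary
belongs to the earlier epoch. Detection tests use 10–30-minute all-N2
records at 100 Hz; trajectory recovery uses 100 replicate cohorts of
n = 500; null calibration uses 500 replicates of n = 120 (Kolmogorov–
Smirnov uniformity at α = 0.01). EDF output quantizes to 16 bits over a
per-channel symmetric physical range, giving round-trip error below
`max(abs(x))/32767`. Epochs whose 30th-percentile reference power is zero
in any comparison band have undefined ratios; their windows are excluded
from the track (counted, not NaN-propagated). Subjects with zero N2
minutes, or zero accepted NREM epochs, yield flagged `NA` metrics rather
than silent zeros.

# Limitations

Slow- and fast-spindle-specific density, power, and peak frequency are out
of scope (the algorithm reports a single event population plus a fast
percent); topographic analysis beyond the central pair is not supported;
staging and arousal scoring are consumed as annotations, never computed;
and the longitudinal design with two waves is analyzed by percent-change
regression, not growth-curve modeling.
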