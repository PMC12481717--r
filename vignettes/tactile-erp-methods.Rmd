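---
title: "Methods: multi-level tactile ERP analysis, dynamic CV and reliability"
author: "tactileERP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-level tactile ERP analysis, dynamic CV and reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tactileERP)
```

# The experiment the package models

The package analyses EEG recorded while a child receives graded
electro-tactile stimulation at five intensity levels (L1–L5), each level
repeated many times in random order, with 1 s of stimulation followed by
0.5 s of rest (a 1.5 s stimulus-onset asynchrony). Continuous EEG is recorded
at 1000 Hz from a 32-channel 10/20 saline cap. Two cohorts are compared: an
ASD-like group and a typically-developing (TD-like) group, n = 36 each, aged
roughly 1–5 years.

Because no clinical recordings ship with the package, the first-class
`synthetic_cohort` generator produces labelled datasets with the statistical
structure the downstream analysis assumes. Everything downstream (filtering,
epoching, component quantification, statistics, CV, ICC, classification) is
agnostic about whether its input came from the generator or from real EDF
files read with `readEDF()`.

# The synthetic cohort generator

Each subject's recording is the sum of three parts.

**Evoked responses.** Five ERP components — P100, N140, P200, N200, P300 —
are modelled as one-cycle raised-cosine (Hanning) bumps. Component `c` has a
nominal peak latency (75, 125, 175, 275, 325 ms), a kernel width (100, 110,
130, 140, 160 ms), a base amplitude (8, 9, 14, 11, 10 µV), a polarity (+1 for
P-components, −1 for N-components), a non-decreasing multiplicative gain over
the five levels (0.6, 0.8, 1.0, 1.2, 1.4 by default — a stronger stimulus
evokes a larger response), and a Gaussian spatial topography centred on a
component-specific electrode. Per-trial latency jitter is Gaussian (SD 3–6 ms
by default; multiplied by the group `dispersionFactor`, default 1.5, in the
ASD-like group, making its responses temporally more dispersed).

The kernel widths and amplitudes deserve a note. The preprocessing band-pass
(0.01–12 Hz, applied forward–backward) attenuates the peak of any
band-limited bump; for widths near 100 ms the attenuation is roughly 10%.
Narrower kernels would make a planted group difference systematically
unrecoverable through the pipeline's own measurement rule, so the defaults
are chosen wide enough that the full measurement chain preserves about 90% of
an injected amplitude, and base amplitudes are large enough that the reduced
(ASD-like) response stays clearly away from zero, where a signed
peak-picking rule loses meaning.

**Group structure.** `groupEffectSpec()` plants additive changes to component
*magnitude* at specific (electrode, component) sites — by default −10 µV at
P200/FP2, N200/F3 and P300/C4, i.e. reduced responses in the ASD-like group
(for a negative component a reduced magnitude means a less negative signed
amplitude). A linear age effect (−0.29 µV/year on magnitude, centred at the
cohort mean age) applies to both groups, and each subject carries a Gaussian
amplitude shift (SD 1.75 µV) representing between-subject variability. That
SD was set from the analytic relation f = (Δ/2)/σ so that, at the reduced
simulation scale used in testing (20 trials per level), the realized group
effect size is Cohen's f ≈ 1.7 — the effect size the power analysis module
works with. Measured across seeds, realized f falls in 1.65–1.75.

**Background activity and artifacts.** Noise is a mixture of white and
1/f-shaped Gaussian noise (default 15 µV total SD, half of the variance in
the 1/f part, produced by an IIR spectral-shaping cascade), optionally
spatially correlated across electrodes through a montage-distance Gaussian
kernel. Stereotyped blinks — 400 ms frontal-weighted raised-cosine bumps,
250 µV at FP1/FP2, Poisson-arriving at 1/min — give the artifact-rejection
stage something realistic to catch. None of these values is reported by a
clinical source; they are chosen so that every preprocessing stage is
non-trivially exercised, which is what the generator is for. What passing
tests show is therefore that the *pipeline machinery* is correct and
calibrated, not that the generator reproduces clinical EEG: real
paediatric EEG has non-stationary artifacts, movement, electrode drift and
far richer spatial structure than a Gaussian topography.

Determinism: a cohort seed fans out to per-subject and per-stage seeds via a
string hash, so the same `cohortSpec()` always yields bit-identical data, and
subject `i` can be regenerated without building the rest of the cohort.

# Preprocessing

The canonical stage order is **filter → epoch → baseline → reject**:

1. **Band-pass** (`bandpassFilter()`): third-order Butterworth high-pass at
   0.01 Hz and low-pass at 12 Hz, each applied forward and backward so the
   net phase is zero and component latencies are not shifted. The filter is
   realized as a compiled direct-form-II-transposed cascade with two
   numerical safeguards that matter at a 0.01 Hz edge at 1000 Hz sampling:
   even-reflection padding (three time constants of the slowest section, so
   the pads carry no spurious DC plateaus) and steady-state initial
   conditions at the channel's mean level. The amplitude response is the
   squared Butterworth magnitude; at 50 Hz residual amplitude is below 0.1%,
   at 5 Hz above 99%.
2. **Bad channels** (`detectBadChannels()`): a channel's log total power over
   0.5–100 Hz is estimated from a Welch spectrum using the *median* across
   segments (so a channel is not condemned for carrying occasional blinks),
   and flagged when it deviates from the cross-channel median by more than
   3.5 robust z-units in either direction. Flagged channels are replaced by
   the inverse-distance-weighted mean of their 4 nearest good neighbours on
   the 2-D montage (`interpolateChannels()`).
3. **Epoching** (`epochRecording()`): one epoch per stimulus event on the
   half-open window [−500, 1000) ms, exactly 1500 samples at 1000 Hz.
4. **Baseline** (`baselineCorrect()`): subtract the per-trial, per-channel
   mean over the full pre-stimulus interval (−500..0 ms).
5. **Rejection** (`rejectArtifactTrials()`): a trial is marked rejected when
   its maximum cross-channel peak-to-peak amplitude exceeds 200 µV. The data
   are never modified — rejection only toggles the kept mask — so the
   operation is reversible and monotone in the threshold. This deterministic
   rule stands in for ICA-based artifact removal, which is out of scope.

A re-run of the pipeline on its own output changes extracted component
amplitudes by roughly 2–5% at the component's generating electrode: a second
pass of the squared-magnitude low-pass attenuates whatever energy a compact
kernel keeps near the 12 Hz edge. Exact idempotence is not achievable for
components this brief; the property suite asserts the 6% bound.

# ERP component quantification

For each subject and level, kept trials are averaged (`averageEvoked()`).
Component amplitudes follow a peak-centred windowed-mean rule
(`peakWindowAmplitude()`): within fixed search windows — P100 50–100 ms,
N140 100–150, P200 150–200, N200 250–300, P300 300–350; the 200–250 ms gap
is deliberately unassigned — the peak is the maximum for P-components and
the minimum for N-components (the standard ERP signing convention), and the
reported amplitude is the mean over the 20 ms window centred on that peak,
clipped at the search-window edge if the peak sits within 10 ms of a
boundary. A flat window takes the earliest extremum and flags a tie.
`buildComponentTable()` assembles the long-format table over the eight
analysis electrodes (FP1/2, F3/4, C3/4, P3/4 by default).

# Group statistics

`ancovaComponent()` fits, per (electrode, component),
`amplitude ~ group + level + group:level + age` with sum-to-zero contrasts
and Type III sums of squares, reporting F, degrees of freedom, p, the age
slope, and partial eta squared computed as SS_effect/(SS_effect+SS_error).
Level is treated as a fixed between-cell factor on the subject-level table
(one row per subject × level) rather than as a repeated-measures term; no
sphericity machinery is used. Age-adjusted marginal means come from emmeans,
and `lsdPosthoc()` performs Fisher's LSD — all pairwise t-tests on the pooled
error term with *no* multiplicity adjustment, which is the definition of LSD.

Topographic queries: `groupDifferenceTopomap()` maps the per-electrode group
difference of a component (ASD minus TD, averaged over chosen levels) with a
companion threshold query (`topoExceeding()`, default 10 µV);
`levelAnovaTopomap()` runs a per-electrode one-way ANOVA across the five
levels within one group and maps the p-values.

Power analytics (`powerOneway()`, `solveN()`) use the noncentral F
distribution with λ = f²·N for the fixed-effects one-way ANOVA; at k = 2 this
agrees with two-sample t-test power (d = 2f) to three decimals. The two
worked values the package reproduces analytically: f = 1.71, α = 0.05,
n = 36/group gives power > 0.99, and f = 0.82 with n = 9/group gives ≥ 80%
power. `fdrAdjust()` is Benjamini–Hochberg.

# The dynamic coefficient of variation

`slidingCV()` quantifies across-level response dispersion over time: at one
electrode, a 10 ms window slides in 1 ms steps over 0–400 ms post-stimulus
(391 positions); at each time point inside a window the CV = SD/|mean| of
the five per-level evoked amplitudes is computed (sample SD, n−1), and the
window's value is the mean over its time points. A pooled variant (all
5 × 10 values as one set) is available behind `pooled = TRUE`; the per-point
form is the default because it is what the quantity's worked value
(sd(1:5)/mean(1:5) ≈ 0.527 for constant level amplitudes 1–5 µV) implies,
and because a per-point reading matches the verbal definition of the
statistic. ERP means cross zero, so the denominator uses |mean| with an
ε-guard (0.1 µV): windows whose mean magnitude falls under ε are reported at
the SD/ε bound, flagged, and excluded from `totalCV()` by default.
`compareCVGroups()` tests per-subject total CV per electrode between groups —
Welch's t by default (the groups are independent); a rank-matched paired
variant (subjects ordered by age) is retained as an option — with BH-FDR
across electrodes.

# Reliability (ICC)

`iccAbsoluteAgreement()` implements the single-measure, absolute-agreement,
two-way random-effects intraclass correlation ICC(2,1): with MSR, MSC and MSE
the between-subject, between-condition and residual mean squares of an
n × k measurement matrix,

$$\mathrm{ICC} = \frac{MSR - MSE}{MSR + (k-1)MSE + \frac{k}{n}(MSC - MSE)}.$$

For ERP features the k conditions are the five stimulus levels; for CV
features they are the analysis electrodes (`featureReliabilityReport()`).
Bands follow the four-level convention (<0.5 poor, 0.5–0.75 moderate,
0.75–0.9 good, ≥0.9 excellent, closed on the left); the cut-points are
configurable. Confidence intervals for ICC are not computed.

# Classification

`buildFeatures()` assembles subject-level matrices from named specifiers —
`"F8:P300:L2"` (a component amplitude) or `"CV:FP2"` (total CV over a span,
200–400 ms in the classification analysis). `evaluateClassifier()` runs
stratified k-fold cross-validation (default 10 folds; every fold's class
counts deviate from balance by at most one subject): per fold, features are
z-scored with training-fold statistics only, then an RBF-kernel SVM (C = 1,
γ = 1/(p·var)), LDA, or a three-layer neural network (one hidden layer of 16
logistic units, weight decay 0.01) is fitted and applied to the held-out
fold. Accuracy, sensitivity and specificity (ASD positive) recompute exactly
from the pooled confusion matrix; AUC comes from the pooled continuous
scores (SVM decision values, LDA posterior, network output probability) —
pooled across folds rather than averaged per fold. `featureSetSweep()` grids
feature sets × classifiers and sorts by accuracy, making feature selection
explicit rather than implicit.

# Numerical choices and degenerate inputs

* Filter: even-reflection padding, steady-state (step-response) initial
  state, compiled double-precision cascade; pad length three time constants
  of the high-pass, capped by the signal length.
* Peak ties: earliest extremum, flagged.
* CV: ε = 0.1 µV denominator guard; flagged windows excluded from totals
  (unless everything is flagged, in which case the total falls back to all
  windows rather than being undefined).
* ICC: zero total variance is an error (undefined ICC), as are matrices with
  missing cells or fewer than 2 rows/columns.
* Rejection thresholds that remove more than half the trials warn but do not
  stop the pipeline; a level with zero kept trials stops with the level
  named.
* Constant features are tolerated in classification (their in-fold SD guard
  maps them to zeros); constant age drops the ANCOVA covariate with a
  warning.

# Problem sizes used by the test and acceptance runs

Simulation-heavy checks run at reduced, stated scales chosen to keep the
whole suite fast while preserving the statistical content: planted-effect
recovery uses n = 36 per group at 20 trials per level on the three planted
electrodes (25 seeded cohorts in the test suite, 30 in the acceptance
script; with detection power ≈ 1, requiring ≥ 24/25 detections is the
binomial equivalent of a ≥ 99% detection-rate bound); null calibration of the
per-electrode level ANOVA uses 100 seeded single-group cohorts of 6 subjects
at 10 trials per level on four electrodes; the full 36 × 80-trial design is
exercised where it is cheap (event bookkeeping, power analytics).

# Known limitations

* The generator's Gaussian topographies and stationary noise are simplistic;
  parameter-recovery results quantify pipeline calibration, not clinical
  effect sizes.
* The 12 Hz low-pass attenuates compact component peaks by ~10%; recovered
  group deltas are accordingly ~0.9 of the planted values. This is a
  property of the prescribed filter, not of the estimator.
* Level is analysed as a between-cell factor; repeated-measures
  (within-subject) correlation is not modelled, so level-effect F statistics
  on data with strong subject effects are conservative.
* ICC confidence intervals, ICA artifact removal, re-referencing and
  time-frequency analyses are out of scope.
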