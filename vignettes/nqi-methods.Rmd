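---
title: "The nQi typing biomarker: model, synthetic validation design, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The nQi typing biomarker: model, synthetic validation design, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nqikit)
```

## The problem and the signal

Early Parkinson's disease (PD) impairs fine motor control before clinical
scales flag it. The hold time (HT) of a keystroke — release minus press —
is a millisecond-scale readout of a finger's press–release cycle, captured
passively during a person's ordinary computer use with no content logging
(only press/release timestamps and a LEFT/RIGHT/SPECIAL category are
stored; SPECIAL keys such as SHIFT involve nonstandard digit kinematics and
are dropped from the HT signal). In early PD the HT distribution is not so
much shifted as *destabilized*: its dispersion grows and prolonged holds
become more frequent. The nQi (neuroQWERTY index) converts that
variance-level structure into a single subject score.

The scientific question this package's pipeline addresses is a transport
question: does a score trained on controlled in-clinic typing generalize to
uncontrolled, sparse at-home typing? The validation layer is built around
that comparison.

## Pipeline model

For a subject's HT series in one setting:

* **Windows.** Non-overlapping 90-s bins on a fixed grid anchored at the
  subject's first keystroke, half-open `[t0 + 90k, t0 + 90(k+1))`. A fixed
  grid (rather than per-burst re-anchoring) makes segmentation
  deterministic and independent of how bursts are ordered; multi-hour
  at-home gaps simply yield empty bins. Windows with fewer than 30
  keystrokes are invalid and discarded; 10 valid windows (15 min of active
  typing, since each window is 1.5 min) is the subject eligibility
  threshold. Note the identity `active_minutes = 1.5 × valid_windows` is
  the same arithmetic the eligibility rule relies on.
* **Features.** Each valid window becomes a 7-vector. The exact reduction
  is pluggable through a named registry (`register_feature_set()`); the
  shipped default `nqi7_default` is variance-centric: mean, sample SD,
  coefficient of variation, IQR (type-7 quantiles), mean absolute lag-1
  successive difference, fraction of holds above twice the window median,
  and the SD after discarding holds above `outlier_cap_s` (default 0.5 s —
  holds that long are almost surely pauses, not press–release cycles).
  The lag-1 component is deliberately the only order-sensitive feature;
  components 1, 2, 4, 5, 7 scale linearly with the HT unit while 3 and 6
  are scale-free (the scale equivariance of component 7 holds as long as
  rescaling does not move values across the fixed cap).
* **Ensemble scoring.** `n_members` (default 50) linear ε-SVRs
  (ε = 0.1, C = 1), each trained on the pooled windows of a subject-level
  bootstrap resample of the training cohort — resampling whole subjects,
  not windows, respects the within-subject correlation of windows. The
  regression target is the subject's 0/1 group label; an alternative
  `updrs_normalized` target (UPDRS-III / 108) is available, in which case
  ε should be reduced to sit well below the target's spread. Features are
  z-scored with full-training-set statistics; constant components map to 0.
  A window's score is the **median** member response; a subject's nQi is
  the **mean** of window scores. The median-then-mean structure makes the
  window score robust to outlier members and the subject score an
  efficient aggregate over many windows.
* **Cutoffs.** Classification thresholds are chosen per setting by the
  closest-to-(0,1) criterion over all score midpoints (±∞ included); ties
  break toward the smaller threshold, i.e. toward sensitivity.

## Validation statistics

`roc_auc()` uses the rank identity (equal to pair counting with half
credit for ties), so AUC = U/(n₊·n₋) holds exactly against
`mann_whitney_u()`. `bootstrap_roc()` resamples subjects with replacement
(default 1000 draws; single-class resamples are redrawn and counted) and
reports the *mean* of the bootstrap AUC distribution as the headline AUC
with the empirical 5th–95th percentiles as CI; the full-sample AUC is kept
alongside since both conventions are common. `delong_paired()` implements
the placement-value (structural component) construction for two correlated
ROC curves measured on the same subjects; its variance needs at least two
subjects per class, below which a degenerate p = 1 is returned with a
warning. `bland_altman()` reports d ± 1.96·SDd with a closed-interval
within-LoA fraction. The Mann-Whitney wrapper delegates to
`stats::wilcox.test`, exact for min(n, m) ≤ 8 without ties, otherwise the
tie-corrected continuity-corrected normal approximation. Correlation is
Pearson by default (with a Spearman switch) and is always paired with an
ordinary least-squares line of best fit. No multiple-testing correction is
applied; p-values are reported raw.

## What the synthetic generator emulates

The generator exists so that every stage, including the cross-setting
validation, is exercised end to end without patient data. Its defaults
describe the study conditions the pipeline targets:

* **Cohorts.** Training 18 PD / 13 control (clinic only), evaluation
  25 PD / 27 control, disjoint by construction.
* **Hold times.** Log-normal body (median ≈ 95 ms, log-scale SD 0.28 for
  controls) plus a Bernoulli exponential-tail excess (weight 0.03, mean
  120 ms) for prolonged holds. The PD effect multiplies the log-scale SD
  by 1.25 and the tail weight by 1.6, leaving the location untouched: the
  group signal lives in the variance structure, which is what the feature
  set is built to see. Between-subject heterogeneity is log-normal
  (CV 0.20 on location/dispersion/speed; log-SD 0.5 on the tail weight,
  which is far more idiosyncratic). These effect sizes were fixed once so
  that the subject-level separability sits in the high-0.7s-to-0.9 AUC
  band — a realistic early-PD regime — rather than at a trivially
  separable extreme.
* **Clinic session.** 900 s of quasi-continuous typing: gamma inter-press
  intervals (mean 0.28 s, shape 2) with a 5% admixture of longer thinking
  pauses (mean 3 s), ~5% SPECIAL keys. This yields ≈ 10 valid windows per
  session.
* **Home activity.** 7 days; each day is skipped with probability 0.05,
  otherwise its typing volume is the subject's latent daily rate (across
  subjects: log-normal moment-matched to mean 24.07, SD 15.13 min/day)
  times a gamma day-to-day multiplier (shape 4). Volume is split into
  log-normal bursts (mean 150 s) placed with exponential gaps inside a
  16-hour waking span. Because the study regime measures typing volume as
  *valid-window active time* (valid windows × 1.5 min), burst time is
  scaled by a fixed calibration constant (0.79) that compensates
  window-edge effects; a design-time Monte-Carlo of 400 subjects put the
  resulting population mean at 114 valid windows (SD 75) and 24.5 min/day,
  matching the intended 112/71/24.1 regime.
* **Seeding.** One master seed fans out hierarchically
  (cohort → subject → session; and pipeline → stage), so cohorts, models
  and reports are byte-reproducible at every granularity.

**What it does not emulate.** Each subject's clinic and home sessions share
one latent profile with no setting-specific shift, so cross-setting
correlations of nQi and raw metrics come out near 1 and percentage
agreement near 95% — cleaner than any real transport setting, where task
context, keyboards and medication state add setting-specific variance.
Linguistic content, keyboard geometry, diurnal medication cycles, and
learning effects are absent. Passing the synthetic validation therefore
demonstrates that the pipeline's machinery is correct and leak-free, not
that the clinical effect sizes are reproduced; the clinical headline
numbers live on an unreleased cohort and are intentionally never asserted.

## Numerical choices and degenerate inputs

* Timestamps are epoch-relative seconds throughout; milliseconds appear
  only in formatted text. Even-length medians are the mean of the two
  central order statistics. Flight-time pairs spanning gaps > 5 s are
  dropped so session boundaries never enter the FT distribution.
* Rows with release < press are rejected (clock faults), not clamped.
* Windows with < 2 keystrokes cannot be featurized (degenerate-window
  error); all-constant training features abort training, while individual
  constant components are flagged and zeroed.
* All-identical scores make the cutoff degenerate; it is flagged and the
  (0,1)-distance tie rule applies.
* Model and report JSON use 17 significant digits so doubles round-trip
  bit-exactly; determinism tests compare artifacts byte for byte.
* The negative control (`pipeline_config(null_effects = TRUE)`) re-runs
  the full pipeline with the group multipliers at 1. A single 52-subject
  null cohort has an AUC sampling SD near 0.08, so leakage checks average
  the point AUC over several independent null cohorts rather than trusting
  one draw.

## Problem sizes used in the shipped checks

The test suite runs the full-size replica (18/13 training, 25/27
evaluation, 7 home days, 50 members, 1000 bootstrap draws) once, plus three
null replicas and a collection of small-cohort runs; generator regime
checks use 150 simulated subjects. These sizes keep the whole suite and the
reproduction script comfortably within a desktop-minutes budget while
leaving the Monte-Carlo bands (±40 windows; ±3 min/day on the mean of 150)
statistically meaningful.

## Known limitations

The exact 7 features of the original clinical algorithm are not public;
the registry decouples the shipped default from the rest of the pipeline
precisely because that definition may be refined. The ensemble's size,
resampling scheme and regression target are likewise package choices
(50 members, subject-level bootstrap, 0/1 label) made for reproducibility
and robustness rather than fidelity to an undisclosed original. UPDRS-III
enters only as metadata and an optional regression target; no claim about
severity tracking is made or tested.
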