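---
title: "Passive severity estimation: models, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Passive severity estimation: models, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moodsense)
```

This vignette is the package's account of its own methods: what is being
modelled, which knobs matter, what the synthetic cohort does and does not
emulate, and where the genuinely open design choices were resolved.

## The estimation problem

A participant with major depressive disorder wears a biosensor on each
wrist and carries a study phone for about nine weeks, with clinician
HDRS-17 assessments at screening, a baseline visit one week later, and
four biweekly follow-ups. The target of estimation is the *residualized*
score of each post-screening visit,

$$r_{iv} = \mathrm{HDRS}_{iv} - \mathrm{HDRS}_{i,\mathrm{screen}},$$

which removes the heterogeneous baseline presentation and makes the
regression a within-person change problem. Features come from the same
midnight-to-midnight day as the assessment (sleep from the trailing 48
hours), aggregated over four 6-hour clock windows, the 8 a.m.–6 p.m.
waking window and the full day. Windows are clock-time windows, resolved
with a fixed per-participant timezone offset stored in the cohort
manifest; the raw streams themselves are kept in UTC epoch seconds, and
every uniform channel reconstructs its timestamps exactly as
`start + i/rate`, so there is no cumulative drift.

## Feature families and their parameters

**Motionless masking.** EDA features are computed only where the wrist is
still, because motion artifacts mimic skin-conductance responses. The mask
scores 1-second epochs by the SD of the acceleration magnitude; epochs
below `sd_threshold_g` (default 0.02 g) merge into intervals, and
intervals shorter than `min_still_s` (30 s) are dropped. A single mask
from the left-wrist accelerometer is applied to both EDA channels — the
wrists move together at the timescale that matters here, and one mask
keeps left/right features comparable.

**Skin-conductance responses.** The detector low-pass filters at 1 Hz
(first-order Butterworth, run forward and backward over a reflect-padded
signal so filter edge transients cannot fabricate events at recording
boundaries) and then reads trough-to-peak upswings off maximal rising
runs, merging runs separated by a single-sample ripple. Events must have
amplitude ≥ `amp_threshold_uS` (0.05 µS) and rise time ≤ `max_rise_s`
(4 s). These thresholds are implementation defaults in the range standard
for wrist EDA; raising the amplitude threshold can only remove events
(a tested monotonicity). Bilateral asymmetry features are *signed*
right-minus-left differences and are exactly antisymmetric under wrist
swap. Normalized EDA features are per-participant z-scores over the
participant's whole study period, appended with a `_znorm` suffix.

**Heart-rate variability.** Inter-beat intervals are cleaned to
normal-to-normal intervals by a physiological range gate (0.3–2.0 s) and a
20% successive-change rule relative to the previously retained beat; the
retained fraction is reported as coverage. SDNN uses the sample (n−1)
denominator; RMSSD is the root mean square of successive differences —
both fixed in the documentation so the test oracles are unambiguous.
Frequency-domain powers integrate a Lomb–Scargle periodogram over
LF = [0.04, 0.15) Hz and HF = [0.15, 0.40) Hz. The periodogram is
computed directly on the unevenly sampled beats rather than on an
interpolated series, because interpolation biases spectra on gappy
optical data; no installed package provides it, so the classical
tau-offset form is implemented here and validated on constructed
sinusoidal modulations. Windows longer than 15 minutes are summarized as
the mean band power over up to six evenly spaced 5-minute sub-segments —
the standard short-term HRV epoch — which also keeps day-long windows
cheap.

**Sleep.** An actigraphy rule over the 48 h before the visit-day
midnight: per-minute activity counts, smoothed with a centred weighted
window, scored asleep below 0.02 g; the longest low-activity block
overlapping the 9 p.m.–11 a.m. night window is the sleep period. Minutes
with no accelerometer coverage (the daily charging gap) may *bridge* a
block but can never start or end one, so a 2-hour 3 a.m. gap does not cut
an 8-hour night in two. Below 50% coverage of the horizon the features
are missing with a recorded reason — missing data are never silently
zero anywhere in the pipeline.

**Mobility.** Location is downsampled to a 5-minute grid (last fix per
slot); interior gaps up to 6 h are linearly interpolated and flagged.
"Extrapolation" of location gaps could also have meant forward-fill; the
interpolation choice is deliberate and the observed/imputed flag is kept
so both can be compared. Home is the densest ~100 m cell of 00:00–06:00
fixes; time at home counts *observed* slots within 200 m (imputed slots
count toward coordinate statistics but not toward time at home, to avoid
imputation-induced home inflation). A slot is moving if it is displaced
more than 100 m from the previous adjacent slot; transition time is the
moving-slot count × 300 s; distances are haversine with R = 6371 km. The
"weighted stationary SD" is defined here as the dwell-time-weighted SD
over stationary bouts (each bout weighted by its duration), a
documented package choice.

## The model

Missing cells are imputed with training-column medians, recomputed inside
every cross-validation fold — the no-leakage property is tested by
perturbing held-out rows and asserting the fitted artifacts are
unchanged. The reducer is a linear variance-maximizing projection to 15
components concatenated with an RBF kernel projection to 10 components
(25 transformed features; the 15/10 split is configurable and capped by
the sample size). The kernel bandwidth is the inverse median squared
pairwise distance over a deterministic row subsample, so refits are
bit-reproducible. The regressor is the arithmetic mean of gradient-boosted
trees (learning rate 0.1; depth and rounds chosen by cross-validated MAE
over a small grid) and a 500-tree random forest. Folds are grouped by
participant under the user-split scenario (no participant straddles a
fold boundary) and ungrouped under time-split, matching what each
scenario claims to generalize over.

## Evaluation protocol

The user-split scenario holds out `ceiling(0.2 n)` participants, repeated
5 times (the repeat count is a package default; dispersion across repeats
gives the reported SDs). The time-split scenario trains on screening plus
the first three follow-ups of every participant and tests on the last two
visits. Metrics are computed on the residualized scale by default — with
the absolute reconstruction `clip(r̂ + screening, 0, 52)` available —
as MAE, RMSE (MAE ≤ RMSE is asserted on every report), Pearson r with a
Fisher-z 95% CI, and normalized MAE = 100·MAE/52. Baselines: training
median applied to all test rows; each participant's screening score
(residual prediction identically zero, hence an undefined correlation on
the residual scale); and the per-participant v2–v4 median, which is
definable only under time-split and reported as unavailable otherwise.
Model comparison is a one-way ANOVA over per-repeat MAE; with three
models and five repeats its degrees of freedom are (2, 12).

## All-relevant feature selection

The selector follows the Boruta scheme: each iteration appends shuffled
shadow copies of the active columns, fits a random forest, and scores a
hit for features whose importance exceeds the maximum shadow importance;
accumulated hits face two-sided binomial tests (p = 0.5) with Bonferroni
correction, confirming clear winners and removing clear losers, with
survivors left tentative (no rough-fix pass). Three calibration choices
in this implementation matter and were fixed after a simulation study on
planted-signal and pure-noise designs:

* **Scaled permutation importance** is the default measure rather than
  impurity. Impurity importance is positive for every column and, at the
  sample sizes typical here (a few hundred visit rows), lets a noise
  column that is correlated with the target by chance win its shadow
  duels almost deterministically.
* **Row subsampling (85% without replacement) per iteration.** On a fixed
  sample, duel outcomes are nearly deterministic, so the binomial model
  overstates evidence; resampling makes chance in-sample correlations
  vary across iterations while genuine signal persists. Subsampling is
  *without* replacement because duplicated rows leak through the
  forest's out-of-bag machinery.
* **A shadow pool of at least 10 columns**, so the max-shadow reference
  never collapses late in a run (a lone surviving feature against one
  shadow would win half its duels by symmetry and drift to confirmation).
  The Bonferroni correction runs across all attributes, not only the
  currently undecided ones.

At this operating point, 25 pure-noise features at n = 200 yield zero
confirmations in 19 of 20 seeds, and five planted linear effects with
joint R² ≈ 0.5 at n = 300 are all confirmed with at most one false
confirmation in 9 of 10 seeds; both checks are in the test suite at
reduced seed counts, deterministic given their seeds. Selection runs on
the raw feature matrix (not the 25 transformed features), since the
transformed components are not interpretable.

## The synthetic cohort: what it emulates, and what it does not

Latent severity is a per-participant linear improvement trend plus
stationary AR(1) day-to-day fluctuation — the simplest process with a
tunable within-person SD and trend. Defaults: screening level
N(16, 4²) clipped to plausible range, mean total decline 20% of the
screening level (between-participant SD 30% of that), AR(1) with
autocorrelation 0.8 and stationary SD 2.8, and integer-rounded rater
noise with SD 1.5 on visit scores (the clinician scale is integer-valued
with imperfect inter-rater reliability). These were calibrated so that
simulated cohorts reproduce two study-level conditions: a mean
within-participant visit-score SD near 3.7 (band 2.7–4.7 in the tests)
and a mean relative decline from the baseline visit to the last near 15%
(band 5–25%). The decline parameter is set above the 15% target because
the ratio estimator (decline divided by the noisy baseline score) is
biased downward by endpoint noise; 20% latent decline yields ≈ 13%
measured decline.

Severity couples to four channels through signed effect sizes (per HDRS
point of deviation from the screening-day severity): +12 min/day screen
time, −0.15 daily excursions, +0.4 SCRs/hour, −1.2 ms RMSSD at the
default multipliers. The *sign* of the phone-engagement coupling is
exposed as a parameter rather than hard-coded, because the direction
reported in the field's literature is ambiguous; the default (more screen
time when more severe) is one reading of it. Day-level noise SDs (25 min,
0.4 excursions, 1.5 SCR/h, 4 ms) are set so that single-day features are
noisy but a 5-visit, 30-participant cohort carries a clearly recoverable
signal — that is the regime the recovery tests certify.

Two tiers of generation exist by design. `generate_cohort()` synthesizes
raw streams — tonic-plus-phasic EDA on both wrists with a configurable
asymmetry, white-noise IBI whose jitter SD is RMSSD/√2, gravity-plus-burst
acceleration with a planted 23:30–07:30 sleep block, paired screen
events, calls/SMS/apps, and home-anchored GPS excursions — writing the
same dialects the readers parse, so a simulated cohort round-trips the
entire raw pipeline. Full device rates (EDA 4 Hz, ACC 32 Hz) over 63 days
and 31 participants are hundreds of billions of samples, so raw-tier
tests run on small cohorts (2–3 participants, a few days, reduced rates),
which is where the oracle chain — planted SCR lists, sleep blocks,
scripted trips, known RMSSD — is verified. `simulate_visit_features()` is
the second tier: it draws the same trajectories and couplings but emits
visit-level feature rows directly, which is what model-, evaluation- and
selection-level studies (20 cohorts × 30 participants) run on. What the
generator does *not* emulate: physiologically realistic EDA/ECG waveform
morphology, weather (injectable as an external table if desired),
circadian structure in phone use beyond a waking window, or correlated
multi-channel artifacts. Passing recovery tests therefore certify the
pipeline's correctness on data whose generating process is known — not
clinical performance on real patients.

## Degenerate inputs and numerical conventions

Empty channels produce empty interval sets and missing features, not
errors; a visit day with no data at all keeps its row, fully missing.
Constant NN series have SDNN = RMSSD = 0 but near-zero spectral power;
fewer than two beats is missing. Zero-variance estimate vectors make the
correlation missing with a reason rather than NaN-propagating. All
randomness flows from one integer seed through a deterministic
polynomial hash into per-stage, per-participant, per-day substreams, so
any stage can be regenerated in isolation; every fitted object is
bit-reproducible given its seed. Problem sizes in the shipped tests —
raw cohorts of 2 participants × 4 days at reduced rates, pipeline
recovery over 10 + 10 cohorts of 30 participants, selection over 10
seeds — were chosen as the smallest sizes at which the tested properties
are stable across reruns.

## Known limitations

The screening-visit residualization is the only personalization; there is
no online adaptation. The 877-feature inventory of the emulated study is
not reproduced column-for-column (its exact list, including weather, was
never published); the manifest is generated programmatically and the
modality partition, not the total, is the tested invariant. Timezone
handling assumes one fixed offset per participant. The time-split
scenario yields a single deterministic split, so its dispersion comes
from fold-level variation only. Boruta decisions, though final once made,
remain stochastic near the significance boundary: a weak feature can end
tentative in one seed and confirmed in another — the tests therefore
assert seed-fixed behaviour and distributional properties, not a unique
selection.
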