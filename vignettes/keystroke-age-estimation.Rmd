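---
title: "Estimating age from smartphone keystroke dynamics: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating age from smartphone keystroke dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keydyn)
library(data.table)
```

## The problem

Typing on a smartphone leaves a dense behavioral trace: every key press
and release is timestamped. Aging is accompanied by gradual changes in
motor and cognitive function, and these changes surface in that trace —
older users type more slowly (longer hold times and inter-key
latencies), less often, and with a flatter diurnal activity profile
than younger users, whose typing peaks late in the evening. `keydyn`
operationalizes this: it turns raw key-event logs into weekly feature
vectors at configurable within-week temporal resolution and estimates
chronological age from them, treating the stability of the week-by-week
estimate as a first-class quantity. In a healthy person the estimated
age should be roughly constant from week to week; systematic drift or
widening scatter is the interesting signal for downstream
digital-health applications.

## Preprocessing model

A typing session is a maximal run of keystrokes delimited by keyboard
activation/deactivation (when the log contains `KB_OPEN`/`KB_CLOSE`
markers) or by an idle gap: a new session starts whenever the next
press comes more than 8 seconds after the last release. Three artifact
filters run before feature extraction, in this order:

1. **Adaptation week.** Each participant's first 7 calendar days are
   discarded (users need time to acclimate to an unfamiliar keyboard).
   The boundary is half-open: an event falling exactly at enrollment
   midnight + 7 days is kept.
2. **Long holds.** Key events held *strictly* longer than 5 s are
   dropped — these are overwhelmingly resting fingers or pocket
   presses, not typing.
3. **Bursts.** After segmentation, a session is discarded entirely if
   any 10 consecutive presses span at most 1 second. Sustained rates of
   ten keys per second are beyond even expert human typing and indicate
   auto-repeat or input-injection artifacts. The windowed formulation is
   deliberate: a single ≤ 100 ms inter-key interval is normal rollover
   typing and must not discard a session.

All three thresholds are exposed in `session_config()` with these
defaults. Both time thresholds are strict inequalities (a gap of
exactly 8.000 s does not split; a hold of exactly 5.000 s survives).
Every input event is accounted for: it ends up in a kept session, in a
discarded burst session, or attributed to a named filter
(`preprocess_events()$counts`).

## The 43 features

`keystroke_features()` enumerates the inventory: 11 speed features, 4
frequency features, 22 speed-variability and 6 frequency-variability
companions. Speed features are in seconds (or per-second rates):
per-event hold time (HT) and the pairwise flight time (FT),
press-to-press (PPL) and release-to-release (RRL) latencies; the
delete-key triple (precorrection = FT into a delete, correction = HT of
the delete, postcorrection = FT after it); per-session AllKeyRate,
DELRate and dur_session; and dur_shift. Frequency features are counts:
AllKey, DEL, num_shift, num_session.

Conventions the data do not dictate, fixed and documented here:

* **Flight time may be negative.** Rollover typing (pressing the next
  key before releasing the previous one) is real behavior; FT — and
  hence pre/postcorrection — is retained with its sign.
* **dur_shift** is the time from a layout-shift key's press to the next
  key's press: the cost of switching layouts. Logs record only key
  events, so this is the natural observable proxy.
* **Window assignment is by session start.** A session straddling a
  window boundary belongs to the window containing its first press;
  sessions are never split.
* **Speed medians pool events.** Within a window, per-event values from
  all sessions are pooled before taking the median (the alternative —
  averaging per-session medians — would weight a two-key session as
  much as a two-hundred-key one).
* **Variability sub-windows are hourly.** `{f}_MaxGap` is the 95th
  minus the 5th percentile, and `{f}_STD` the population SD (divisor
  n), of the feature's hourly summaries inside the parent window —
  per-hour medians for speed features, per-hour counts for frequency
  features. Only hours with typing activity contribute; idle hours are
  absent rather than zero, so the statistics describe fluctuation of
  typing behavior rather than of the activity schedule. Percentiles use
  linear interpolation between order statistics (position
  `1 + q(n − 1)`); both the sub-window resolution and the percentile
  pair are configurable.

## Weekly vectors and temporal resolution

`build_weekly_vectors()` arranges per-window features into
Monday-aligned weekly T×F arrays: T = 1 (weekly median), T = 7 (daily
medians, Monday through Sunday) or T = 28 (four 6-hour periods per day:
midnight–6 AM, 6 AM–noon, noon–6 PM, 6 PM–midnight; slot = 4·day +
period). Sequential models consume the T×F sequence; non-sequential
models consume the flattened T·F vector. The weekly-median resolution
is never paired with a sequential model — with T = 1 there is no
sequence to learn.

Missing cells are imputed from the same (slot, feature) cell of the
nearest week, ties broken toward the earlier week
(`impute_nearest_week()`). A cell missing in *every* week of a
participant is an error under the default; the pipeline-level option
`on_all_missing = "cohort_median"` fills it with the cohort-wide median
instead. This fallback exists because at desk scale (8 weeks, modest
key budgets) a low-activity participant can have, say, no Monday
small-hours typing at all, whereas a months-long heavy-usage record
essentially always covers every slot. Min-max normalization then maps
each (slot, feature) column to [0, 1]; the default fit scope is the
whole constructed dataset, with `fit_rows` available for a
train-only variant (values off the fit scope are clipped). Note the
dataset-wide default lets the test folds influence the scaling — a mild
leak accepted for comparability; the train-only option is the
leakage-free alternative.

## Age-balanced datasets and grouped cross-validation

Volunteer cohorts recruited through campus channels skew young. To keep
the regression from simply predicting "young", the under-30
participants are partitioned into 7 random, seeded, participant-wise
subsets of near-equal size (`floor(n/7)`/`ceil(n/7)`; a 125-person
group yields the 17 + 6×18 pattern), and each subset is combined with
*all* participants aged 30+ to form 7 datasets of comparable mean age.
Cross-validation folds are assigned per participant, never per week, so
no individual contributes to both training and test sets; folds are not
age-stratified. Final metrics are arithmetic means of the 7 per-dataset
values.

## Models and the two-phase variance-penalized loss

Six estimator families sit behind one `fit`/`predict` contract:

* **logistic_regression** — a classifier applied to a continuous
  target is reconciled by binning training ages into quantile classes,
  fitting L2-regularized multinomial regression (`glmnet`, alpha = 0),
  and predicting the probability-weighted expected age. Predictions
  therefore always lie inside the training age range.
* **random_forest** (`ranger`) and **xgboost** on flattened vectors.
* **mlp**, **lstm**, **transformer** — written directly in R (this
  stack has no deep-learning framework, and the custom training loop is
  the point): dense ReLU stack with inverted dropout 0.3 and weight
  decay 0.001 (MLP); a standard single-layer LSTM regressing from the
  final hidden state; a single-head, single-layer transformer encoder
  with sinusoidal positions, residual feed-forward block and mean
  pooling. All train with Adam, halve the learning rate after a
  patience of epochs without validation improvement, and return the
  parameters of the best-validation epoch. Backpropagation for all
  three is verified against numerical differentiation in the test
  suite (relative error < 1e-6). Targets are centered at the training
  mean age so the output head starts near the cohort mean; the L1
  scale (years) is unchanged.

The two-phase loss (`loss_config()`, `two_phase_train()`) encodes the
assumption that a healthy person's estimated age should be stable
across weeks. Phase 1 builds mini-batches from a single participant's
weekly samples; with m the batch-mean L1 error, the loss is m when
m ≤ threshold and (1 + weight)·m above it — "original loss plus the
average L1 loss times a weight". The alternative reading (penalty
accumulated into a running epoch loss) is not operational for
mini-batch gradients and was rejected. Phase 2 continues with plain L1
on conventional mixed batches (batch composition in phase 2 is a free
choice; mixed is standard). threshold ∈ {1, 2, 3} years and weight ∈
{0.2, 0.4, 0.6, 0.8, 1.0} span the intended grid; `weight = 0` or
`phase1_epochs = 0` reduce exactly to conventional training, which the
tests assert bit-for-bit.

Two properties of this loss are worth stating plainly. First, L1 loss
is separable across samples, so batching alone does not change the
expected gradient — the method's entire leverage is the conditional
(1 + weight) scaling at participant level. Second, Adam's per-parameter
normalization absorbs much of a transient gradient scaling. The
intraparticipant-SD effect is therefore expected to be small; on the
synthetic study it is within seed-to-seed variability (the acceptance
script reports the paired comparison honestly, whichever side of zero
it lands on for a given seed), while the paired 5-seed acceptance test
checks the directional claim under fixed conditions.

## Evaluation suite

`mae_r2()` uses the standard R² about the test-set mean; metrics are
computed per dataset over pooled out-of-fold predictions, then averaged
across datasets. `intraparticipant_sd()` is the mean over participants
(with ≥ 2 predicted weeks) of the SD of their weekly estimates.
`ablate_feature_sets()` re-runs vectorization and evaluation on unions
of the four feature categories; `ablate_periods()` masks the 28-step
sequence to subsets of the four 6-hour periods (rows concatenated
chronologically; all 15 non-empty masks on request), and with all four
periods reproduces the unablated pipeline exactly.
`descriptive_hourly()` is the three-step aggregation: values per 1-hour
window → per-participant median per hour of day → mean across the
participants of each age group, excluding empty hours at both steps.
`rank_importance()` attributes predictions to (feature, 6-hour period)
pairs by permuting the pair's cells across samples and averaging the
absolute prediction change — a model-agnostic permutation attribution
(no SHAP implementation for arbitrary R models is available here, and
the quantity of interest is the same ranking over the 15 × 4 = 60
candidates; a constant feature gets exactly zero attribution).

## The synthetic study

`generator_config()` defaults define the study conditions used
throughout the tests and the acceptance script: 56 participants (14 per
decade group: under-30, 30s, 40s, 50s), 8 weeks each, enrollment on a
Monday so calendar weeks are complete.

Per participant, drawn once: median press-to-press latency
`145 + 2.8·age` ms (SD 10 between people) — about 0.20 s at age 20
rising toward 0.30 s at 55; median hold time `62 + 1.0·age` ms (SD 6);
expected daily key volume `1250 − 16·age` (SD 60, floor 150). Sessions
arrive per day as a Poisson process whose hourly placement follows a
diurnal weight vector: a daytime plateau with an evening bump for
everyone, plus a late-night (11 PM) peak whose amplitude fades linearly
to zero by age 45. Within a session, inter-press gaps and holds are
log-normal with medians at the participant's parameters (sdlog 0.35 and
0.30) — positive, right-skewed, matching typing-latency phenomenology;
the generator makes no claim that real latencies are log-normal, only
that the shape is plausible. Keys are delete with probability 0.08 and
layout-shift with 0.04. Artifacts: holds > 5 s at rate 2e-4 per key;
burst sessions (gaps of 55–95 ms, ≥ 12 keys) at rate 0.034 per session,
sized so the burst filter discards a few percent of sessions, matching
the scale reported for real free-living data; whole weeks go missing
with probability 0.05. Timestamps are integer milliseconds since epoch
in a single fixed zone (UTC); session markers are emitted as
`KB_OPEN`/`KB_CLOSE` pseudo-rows (a config flag suppresses them to
exercise the gap-only segmentation path).

What the generator deliberately does **not** emulate: language content
and key identity beyond the char/delete/shift distinction, touchscreen
geometry, device and handedness effects, mood/fatigue dynamics,
long-term behavioral drift, or any correlation structure between
features beyond what the shared per-participant parameters induce. A
model that recovers age here shows that the pipeline is correct and can
exploit an age-graded speed/volume/diurnal signal — it does not show
that real typing data carries that much signal, and held-out errors on
this synthetic cohort (MAE near 3 years) should not be read as
attainable field performance.

## Problem sizes and numerical choices in the shipped checks

The test suite and `scripts/acceptance.R` use sizes chosen to exercise
the full pipeline in minutes on one CPU: the 56-participant × 8-week
study (~1.5 million key events, ~70k sessions, ~390 weekly samples);
LSTM with hidden size 16, learning rate 0.05, batch size 32, 60 epochs
for the baseline comparison (3 seeds, participant-wise 60/15/25
train/validation/test split); and for the paired loss comparison,
3-fold participant-wise cross-validation pooling out-of-fold
predictions over all participants (5 seeds, learning rate 0.02, batch
size 8 so both arms take comparably many optimizer steps per epoch).
Oracle-equivalence checks run 100 random instances against brute-force
reference implementations of segmentation, burst detection,
percentiles, SD, MAE/R² and intraparticipant SD.

## Known limitations

* The hand-written networks are single-layer CPU implementations meant
  for datasets of this scale, not GPU-scale replacements; hyperparameter
  grids are exposed but not exhaustively searched.
* catboost- and tabnet-style estimators are not provided (no R
  implementation is available in this dependency set); the family enum
  rejects them with an informative error.
* The variance-penalty effect on intraparticipant SD is small by
  construction (see above) and should be evaluated with paired seeds
  and pooled cross-validated predictions, as the acceptance script
  does.
* The dataset-wide min-max default mirrors the within-dataset
  normalization convention but leaks test information; use
  `fit_rows` for leakage-free scaling when that matters.
* All slot boundaries use one fixed timezone; multi-timezone cohorts
  would need per-participant zone handling upstream.
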