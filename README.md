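# keydyn — smartphone keystroke dynamics for age estimation

`keydyn` is an R package for turning raw smartphone key-event logs —
one row per keystroke with press timestamp, release timestamp and key
type — into week-level behavioral feature vectors, and for estimating a
person's chronological age from them. It is aimed at digital-biomarker
and passive-sensing researchers who want a reproducible, end-to-end
pipeline: typing behavior slows and becomes less frequent with age, and
the strength of that signal (and its diurnal structure) is what the
package quantifies.

Because real keystroke logs of this kind are privacy-restricted, the
package ships a seeded synthetic log generator that emulates the key
structural properties of free-living typing data — age-graded speed and
volume, diurnal session rhythm with a late-evening peak for younger
users, delete/layout-shift keys, artifact bursts and missing weeks — so
that every stage is testable and every number below can be reproduced
from scratch.

## Pipeline

1. **Sessionization** (`parse_log()`, `preprocess_events()`): discard
   each participant's first (adaptation) week; drop key events held
   longer than 5 s; split events into typing sessions at keyboard
   open/close markers or whenever the next press comes more than 8 s
   after the last release; discard burst sessions containing ≥ 10
   consecutive keystrokes within 1 s.
2. **Feature extraction** (`extract_features()`): 43 features per
   (participant, time window) — 11 speed (hold time HT, flight time FT,
   press-to-press latency PPL, release-to-release latency RRL,
   pre/correction/postcorrection around the delete key, AllKeyRate,
   DELRate, dur_shift, dur_session), 4 frequency counts (AllKey, DEL,
   num_shift, num_session), and their temporal-variability companions:
   `{f}_MaxGap` = 95th − 5th percentile of hourly sub-window summaries,
   and `{f}_STD` = their population SD (22 speed-variability + 6
   frequency-variability).
3. **Weekly vectors** (`build_weekly_vectors()`): Monday-aligned T×F
   arrays at three temporal resolutions — weekly median (T = 1), daily
   median (T = 7), 6-hour median (T = 28; midnight–6 AM, 6 AM–noon,
   noon–6 PM, 6 PM–midnight per day) — with nearest-week imputation and
   min-max normalization.
4. **Age-balanced cohorts** (`build_cv_design()`): the under-30 group is
   partitioned into 7 participant-wise subsets (17 + 6×18 for n = 125),
   each combined with all older participants; participant-wise 10-fold
   cross-validation so no person contributes to both training and test.
5. **Models** (`model_spec()`, `fit_age_model()`): logistic regression
   (expected age over binned-age class probabilities), random forest,
   XGBoost, and hand-written gradient models — MLP, LSTM and a
   single-head transformer encoder — trained with Adam, plateau
   learning-rate decay and best-validation checkpointing.
6. **Variance-penalized two-phase loss** (`loss_config()`,
   `two_phase_train()`): phase 1 uses participant-grouped mini-batches;
   with batch-mean L1 error m, the loss is m + w·m whenever m exceeds a
   threshold (grid: threshold ∈ {1,2,3} years, w ∈ {0.2,…,1.0}); phase 2
   continues with plain L1 on mixed batches. The target metric is the
   intraparticipant SD of predicted ages across weeks
   (`intraparticipant_sd()`).
7. **Evaluation** (`mae_r2()`, `ablate_feature_sets()`,
   `ablate_periods()`, `descriptive_hourly()`, `rank_importance()`):
   MAE/R² averaged over the 7 balanced datasets, feature-set and
   6-hour-period ablations, three-step hourly age-group curves, and
   permutation attribution over the 60 (feature × period) candidates.

## Worked example

```r
library(keydyn)

cfg <- generator_config(seed = 42)        # 56 participants, 8 weeks
st  <- simulate_study(cfg)                # generate + preprocess logs
vec <- prepare_vectors(st, "six_hour_median")
d   <- assemble_dataset(vec, st$cohort)   # n x 28 x 15 arrays + ages

res <- holdout_eval(d,
  model_spec("lstm", list(hidden = 16L, lr = 0.05, epochs = 60L),
             "sequence", seed = 1),
  seed = 1)
```

Output from this exact run:

```
sessions kept: 70489 | discarded: 2515 (3.4%)
samples x timesteps x features: 381 x 28 x 15
test MAE 3.16 years | baseline 11.01 | R2 0.89 | intra-participant SD 1.53
```

3.4% of sessions are burst artifacts removed by the preprocessing
filter. The LSTM on 6-hour-median vectors estimates the age of held-out
participants to within 3.2 years on average, versus 11.0 years for
predicting the constant mean training age, and its week-to-week
predictions for the same person vary by about 1.5 years (SD). Ranking
the 60 (feature, period) attribution pairs for this model puts
`AllKeyRate`, `PPL` and `HT` on top — typing rate and latency carry the
age signal:

```r
head(rank_importance(res$model, d$x, d$features, seed = 1), 3)
#>       feature period attribution  rank
#> 1: AllKeyRate      3   0.8293706     1
#> 2:        PPL      3   0.7711694     2
#> 3:         HT      3   0.7560343     3
```

## Scope notes

The synthetic generator reproduces structural properties, not any real
cohort; see the methods vignette (`vignettes/keystroke-age-estimation.Rmd`)
for the generative model, parameter choices, design decisions and
limitations.
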