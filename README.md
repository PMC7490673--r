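# sensewarn

Reconstruction-based anomaly detection for early-warning signs of
psychotic relapse from smartphone passive sensing.

## The problem

People with schizophrenia spectrum disorders (SSDs) often show gradual
behavioral changes — disturbed sleep, altered sociability, changed
mobility — in the weeks before a clinical relapse. A smartphone carried
through daily life passively records proxies for these behaviors:
accelerometer traces, call and text logs, detected conversations, GPS
fixes, screen use, and inferred sleep. `sensewarn` implements a full
pipeline that turns such raw event streams into hourly behavioral
features and asks, day by day, *does today look unlike this person's
days of relative health?*

The clinical framing labels each study day either **NR30** (within the
30 days strictly before a recorded relapse) or **DRH** (days of relative
health, everything else). The pipeline's goal is anomaly flags that are
rare overall but enriched inside NR30 — a TPR/FPR ratio above 1.

## The method

1. **Features** (`extract_hourly_features`): one vector per
   participant-hour — mean acceleration norm, unique apps, call/text
   counts and durations by subtype, conversation count/duration, dwell
   time in DBSCAN-derived *primary*/*secondary*/*other* places
   (haversine metric, eps = 1 km, min 10 fixes), distance travelled,
   screen use, daily sleep onset/wake/duration replicated hourly, day of
   week, hour of day.
2. **Two-type imputation** (`impute_features`): hours where some
   channels reported get zeros for the silent channels (type 1); hours
   with no readings at all get the participant's hour-of-day means, with
   location carried forward from the last recorded place (type 2). The
   per-hour *fill fraction* (imputed/imputable features, = 1 exactly on
   type-2 hours) is itself a model feature.
3. **Splits** (`make_blocks`, `assign_splits`, `monte_carlo_partition`):
   days are cut into non-overlapping blocks; DRH-only data form a
   healthy train/validation pair H_R/H_CV (80/20), the rest pools into
   mixed sets that 100 stratified Monte Carlo iterations partition into
   a tuning set N_CV and a held-out test set N_T with equal NR30 days
   per participant.
4. **Reconstruction models** (`train_fnn_ad`, `train_gru_seq2seq`,
   `fit_lof`): a fully connected autoencoder over single hourly vectors
   (l = 1), a bidirectional-GRU encoder / GRU decoder that reconstructs
   24-hour windows in reverse order (l = 24, dropout and recurrent
   dropout 0.2), and a per-participant local-outlier-factor baseline
   whose neighbor count grows from 10 until validation score moments
   converge. Both networks are trained with hand-written
   backpropagation (verified against finite differences) and early
   stopping on H_CV.
5. **Scoring** (`mahalanobis_score`, `learn_threshold`): reconstruction
   errors e = |x − x'| on H_CV fit a Gaussian N(μ, Σ); each retained
   hour (predicted all l times) gets the Mahalanobis score
   s = ((e−μ)ᵀΣ⁻¹(e−μ))^{1/2}; a day's score s^d is the mean of its
   hourly scores; a per-participant threshold τ ∈ [0, 20] maximizing
   TPR/FPR on N_CV flags days with s^d > τ on N_T.
6. **Evaluation and post hoc** (`confusion_metrics`,
   `aggregate_monte_carlo`, `rank_models`, `feature_effect_ranking`,
   `missingness_odds_ratio`, `mannwhitney_type2`,
   `data_quality_regression`, `anomaly_rate_timeline`).

Because the original clinical dataset is private, the package ships a
first-class **synthetic cohort simulator** (`cohort_config`,
`generate_cohort`): seeded multi-month raw event streams with circadian
structure, log-normal participant heterogeneity, two-anchor mobility,
configurable near-relapse behavioral signatures with a gradual ramp-in,
and both missingness types. Every stage is testable without any
download.

## Worked example

```r
library(sensewarn)

sig <- list(
  sleep_duration  = list(kind = "additive", value = 1.5, unit = "sd",
                         ramp_days = 7),
  n_conversations = list(kind = "multiplicative", value = 3, ramp_days = 7))
cfg <- cohort_config(n_participants = 6, relapse_fraction = 2/6,
                     days_per_participant = 90, relapse_events_prob = 1,
                     signature = sig, type2_missing_rate = 0.25, seed = 1)
res <- run_experiment(cfg, archs = "fnn_ad", hidden_grid = 20,
                      pct_grid = 80, mc_iterations = 5, base_seed = 1)
res$summary
```

Printed on this machine:

```
           config sens_median   sens_q1   sens_q3 spec_median spec_q1 spec_q3 n_participants
1: fnn_ad_h20_p80   0.7196078 0.7127451 0.7264706           1       1       1              2
```

Reading: across the Monte Carlo test sets, the median relapse
participant had ~72% of their near-relapse days flagged while every
healthy test day stayed quiet (specificity 1 at this small scale) —
anomalies are rare but strongly enriched before the (simulated)
relapse, which is exactly the property the detection system is designed
for. With `signature = list()` the same numbers collapse toward chance.

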