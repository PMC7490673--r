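---
title: "Detecting behavioral anomalies before psychotic relapse: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting behavioral anomalies before psychotic relapse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sensewarn)
```

## The model in one paragraph

Each participant contributes a multivariate hourly time series
$X = \{x^{(1)}, \dots, x^{(L)}\}$, $x^{(i)} \in \mathbb{R}^m$, of
behavioral features derived from smartphone passive sensing. A
reconstruction model is trained only on days of relative health (DRH)
to reproduce its input; on the healthy validation set the element-wise
absolute errors $e = |x - x'|$ are modeled as
$e \sim \mathcal{N}(\mu, \Sigma)$. New hours are scored by the
Mahalanobis distance
$s = \big((e-\mu)^\top \Sigma^{-1} (e-\mu)\big)^{1/2}$, days by the
mean of their hourly scores $s^d$, and a per-participant threshold
$\tau \in [0, 20]$ — chosen on a mixed tuning set to maximize TPR/FPR,
where a true positive is an anomaly inside the 30-day near-relapse
window (NR30) — flags test days with $s^d > \tau$. The working
hypothesis is not that every near-relapse day is anomalous, but that
anomalies, while rare, are *enriched* before relapse (TPR/FPR > 1).

## Architectures

**FNN autoencoder (l = 1).** One fully connected encoder layer
compresses a standardized hourly vector to `hidden_units` dimensions
(activation configurable: `relu` default, `linear`, `tanh`), one
decoder layer reconstructs it. In the linear configuration the optimum
coincides with the top-k PCA subspace, which the tests exploit as an
oracle.

**GRU seq2seq (l = 24).** A bidirectional GRU encoder reads a 24-hour
window; the concatenated final states emit a next-step prediction
$x'^{(l+1)}$ and (through a learned projection) the decoder's initial
state $h^{(l+1)}$. A unidirectional GRU decoder receives the next-step
prediction as its first input — and subsequently its own outputs,
autoregressively — and reconstructs the window in reverse order
$\{x'^{(l)}, \dots, x'^{(1)}\}$. The description of how the encoder's
outputs reach the decoder is genuinely ambiguous in the source design;
we pass *both* (prediction as first token, state through the
projection), which subsumes either reading. Input dropout (fresh mask
per timestep) and recurrent dropout (one mask per sequence, applied to
the state as the gates see it) are both 0.2 during training only. Batch
normalization is deliberately omitted — the original work tried and
abandoned it.

Both networks are trained with Adam on mean squared error over
z-scored features and hand-written backpropagation (full BPTT for the
GRU), because no deep-learning runtime exists in the supported R
stack. Gradient correctness is asserted against central finite
differences in the test suite. Early stopping watches the healthy
validation loss with patience 5 and restores the best epoch's
parameters.

**LOF baseline.** A per-participant k-nearest-neighbor local outlier
factor fitted on that participant's healthy training hours, with the
neighbor count grown from 10 by 1 until the mean and SD of the
validation scores change by less than 1e-3 (relative), capped at 100.
LOF scores are one-dimensional, so the same Gaussian-scoring route
degenerates gracefully to $|s - \mu|/\sigma$.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `nr30_len` | 30 | days | the clinical near-relapse window |
| DBSCAN `eps_km`, `min_samples` | 1, 10 | km, fixes | significant-place definition |
| `block_len_days` | 5 | days | split granularity: long enough to limit temporal leakage, short enough to stratify 30 NR30 days into balanced halves (the source design never states it; exposed as config) |
| `pct_drh_in_train` | sweep {0,20,40,60,80} | % | how much relapse-participant DRH the healthy sets see |
| `hidden_units` | 10–50 | – | model capacity sweep |
| τ range | [0, 20] | score | threshold search range |
| early-stopping patience | 5 | epochs | criterion stated, patience chosen |
| covariance shrinkage | `1e-6·tr(Σ)/m`, ×10 until cond < 1e10 | – | guarantees invertibility |
| FPR floor in τ search | 1/(#DRH+1) | – | lets perfect separation win while keeping ratios finite |

Ties in the τ argmax break toward the **largest** τ (fewest alarms),
matching the clinical preference for rare alerts. The τ candidate grid
is every observed daily score clipped to [0, 20] plus midpoints, which
realizes every achievable confusion table; the unstated score scale
behind the "0 to 20" range is thereby sidestepped.

## The synthetic cohort: what it emulates, what it does not

The generator's stated world mirrors the source study's scales: ~30%
of participants relapse (1–3 events, weighted 78/5/17%), around 300
days of data each (acceptance runs scale down to 120), 30-day
near-relapse windows, and ~26% of hours lost to whole-hour (type-2)
missingness plus 5% channel-hour (type-1) dropout. Behavior is built
from per-participant log-normal random effects (sdlog 0.3) on Poisson
event rates, log-normal durations, a two-anchor home/secondary mobility
process with hour-dependent transition probabilities plus transient
"other" places, Gaussian daily sleep (onset ≈ 23:30 ± 0.75 h, duration
≈ 8 ± 0.75 h), and a fixed circadian activity multiplier. Relapse
signatures shift named features on NR30 days only, ramping in linearly
over 7 days (a gradual prodrome; the anomaly rate should rise before
the window, as the source's timeline figure shows). Counts shift by
thinning/duplication, durations multiplicatively, sleep additively
(optionally in SD units against the generator's own ground truth).

Deliberate simplifications: hours are conditionally independent given
the circadian curve (no within-day autocorrelation beyond it — the
source data's autocorrelation is uncharacterized); within-hour mobility
is anchored, so `distance_travelled` is jitter-scale and carries little
signal here; app identities are Zipf-weighted tokens. A green
end-to-end test therefore establishes that the pipeline detects a
planted, ramped, multi-feature behavioral shift under realistic
missingness and heterogeneity — not that it would achieve any
particular sensitivity on real clinical data.

Sleep observedness is a convention worth stating: daily sleep estimates
replicate across the day's 24 hours but count as *observed* only in
hours with raw device activity, because sleep is inferred from the same
sensors that go silent; otherwise type-2 hours could not exist on days
with a sleep record. Type-2 filling consequently uses hour-of-day means
for sleep features as for any other non-location feature.

## Numerical and degenerate-input choices

- Standardization statistics come from H_R only and are reused
  unchanged everywhere; features with zero variance get sd 1.
- Earth radius fixed at 6371.0088 km (IUGG mean).
- Dwell attribution: the interval between consecutive GPS fixes goes to
  the earlier fix's place; leading/trailing partial intervals extend to
  the hour boundaries; no interpolation across hours (convention
  documented and tested; the source is silent).
- DBSCAN is exact up to 3000 fixes; above that, points snap to
  eps/4 grid cells and weighted cells are clustered exactly — identical
  results for anchored mobility, asserted in the tests.
- Type-2 hours following no GPS fix at all fall back to the primary
  place (logged); distance on type-2 hours is 0, consistent with
  "remained at the last recorded location".
- Imputation means can be restricted to DRH days (the pipeline does
  this) so near-relapse behavior cannot leak into the imputed baseline.
- A threshold search where no τ attains TPR/FPR > 1 (e.g. all scores
  identical) is flagged `degenerate` rather than silently returned.
- Mann–Whitney U uses exact enumeration when both groups have ≤ 8
  values, otherwise midranks with tie-corrected variance and continuity
  correction; the two one-sided statistics are asserted to sum to
  $n_A n_B$ on every call.
- Effect sizes feed on hourly (not daily-aggregated) values, matching
  the source's per-hour effect figures; pooled-SD Cohen's d with the
  conventional classes (large > 0.8, medium 0.5–0.8).

## Open design points resolved here

- **Block length and the N_CV/N_T DRH ratio** are unstated in the
  source; defaults 5 days and 50/50, both configurable.
- **Hour-of-day–conditional imputation means** are computed per
  participant (not pooled), preserving behavioral identity; the source
  does not say which it used.
- **Window-prediction consolidation** averages the l predictions of an
  hour (variance-minimizing symmetric choice); only hours predicted
  exactly l times are scored.
- **Remainder blocks** (final short block) inherit the assignment of
  the participant's last full block, so no temporal fragment is
  orphaned or leaks.

## Known limitations

Training is pure R; it is comfortable at the tested scales (tens of
thousands of hours, hidden ≤ 50) but not at GPU scale. The GRU route
scores only hours with full l-coverage, so the first and last l−1 hours
of every contiguous block are unscored by design. The simulator's
missingness is unconditionally random, whereas real type-2 missingness
is behavior-correlated (the source's own post hoc analyses probe
exactly this); the missingness odds-ratio and Mann–Whitney machinery is
implemented and tested, but on synthetic data its null is true by
construction.
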