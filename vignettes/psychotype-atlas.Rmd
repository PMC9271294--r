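---
title: "Methods: the self-organizing psychotype atlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the self-organizing psychotype atlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the design
choices behind them.  It states no empirical result beyond what the test
suite and `scripts/acceptance.R` compute.

## The problem

Longitudinal midlife surveys measure dozens of psychological attitudes,
six-dimensional Ryff well-being at two waves roughly a decade apart, and a
baseline depression diagnosis.  The package turns such data into three
instruments: a 2-D *psychotype atlas* with depression and well-being
overlays; a *recommendation engine* that reads paths across the atlas as
sequences of small attitude changes; and *predictors* of psychological age
and future well-being whose outputs feed a relative-importance test of the
hedonic-treadmill hypothesis (does future well-being track a personal
baseline, or the present psychological profile?).

## The self-organizing map

A Kohonen map stores one codebook vector per cell of a `width` × `height`
rectangular lattice.  Training is sequential (online): samples are drawn
with replacement in a seeded order, the best-matching unit (BMU) of each
sample is located by Euclidean distance, and every cell moves toward the
sample with a Gaussian grid-distance weight.  Both the neighborhood radius
and the learning rate decay as `value0 / (1 + t/(T/2))` over the planned
total number of presentations `T` — the asymptotic schedule used by common
online-SOM implementations, so a map trained here is comparable to one
trained with those libraries at matched parameters.

Tunable parameters (see `som_config()`):

* `width`, `height` (cells; default 25 × 25, i.e. 625 psychotype cells);
* `sigma0` (grid units; default 1.8) — initial neighborhood radius;
* `learning_rate0` (dimensionless in (0, 1]; default 0.4);
* `convergence_tol` (default 1e-4, on z-scored features) and `patience`
  (default 5 epochs);
* `max_epochs` (default 50), one epoch being `n` presentations.

Numerical choices:

* **Feature scaling.** Distances are scale-sensitive, so features are
  z-scored on the training data and the scaler is stored in the model;
  every user-facing function takes raw item units.
* **Initialization.** The codebook starts uniform within the per-feature
  data ranges under the config seed — reproducible and data-scaled.
* **Convergence.** The per-epoch quantization error (mean BMU distance) of
  an online SOM fluctuates at the scale of the late learning rate, so the
  stopping rule tracks the *running best* error: training stops once the
  best has not improved by more than `convergence_tol` for `patience`
  consecutive epochs, and the returned codebook is the best epoch's state.
  The training log records the raw per-epoch values.
* **Tie-breaks.** BMU ties go to the lowest cell index; cells are numbered
  1-based row-major (serialized path coordinates also carry the 0-based
  equivalents).
* **Degenerate inputs.** Non-finite samples, empty matrices and feature
  mismatches are rejected with named errors; a 1 × 1 map is permitted and
  collapses onto its data.

## Overlays, clusters and paths

Mapping a test cohort assigns each subject to its BMU.  Per-cell metadata
are raw aggregates: depression odds are the count ratio
`n_depressed / n_nondepressed` (0 when no depressed subject maps there,
`Inf` and flagged `capped` when no non-depressed subject does, undefined on
unoccupied cells, which stay flagged as such).  No smoothing is applied, so
printed contingency tables pass through `cluster_stats()` unchanged.

Psychotype clusters come from complete-linkage hierarchical clustering of
the codebook with Euclidean distance (`stats::hclust`), cut to `n_clusters`
(default 3).  Cluster statistics re-index the labels by descending
depression odds so that "cluster 1" is always the depression-prone
psychotype; odds per cluster are computed from summed counts (not averaged
per cell), which is the convention that makes the totals row reproduce the
whole-cohort ratio exactly.  Odds–well-being association across occupied
cells uses Spearman rank correlation — odds are a heavy-tailed count ratio —
with two-sided p-values and no multiplicity adjustment across the six
dimensions; constant inputs are reported as degenerate rather than an error.

The atlas doubles as a weighted graph: nodes are cells, edges join
8-neighbors (sides and diagonals, so paths may move diagonally, as a drawn
route on the map does), and weights are codebook distances.  Shortest paths
use Bellman–Ford (the edge weights are non-negative, so Dijkstra is an
independent oracle in the tests); among equal-length paths the
lexicographically smallest cell sequence is returned, reconstructed by
walking from the source and taking the smallest-index neighbor that remains
on a shortest path, with a grid-distance progress rule that keeps the walk
finite across zero-weight plateaus (e.g. a constant codebook).
Recommendations rank features by the signed endpoint difference of their
codebook trajectories in original item units; ranking by the max–min range
along the path is available behind `method = "range"`.  Endpoints default to
the extreme-odds cells (ties: larger count of the relevant label, then
lowest index).

## Predictors

Both predictors are feed-forward MAE-loss regressors on the 32 items:
leaky-ReLU activations (slope 0.01), dropout 0.25 after each hidden layer,
L2 weight decay (1e-6 for age, 1e-7 for well-being), an Adam-style
optimizer (batch 32, step 1e-3), and 5-fold cross-validation in which the
held-out fold doubles as the early-stopping validation set (patience 10);
the final model refits on all training rows with a seeded 10% internal
validation split.  The well-being model emits all six dimensions
simultaneously (multilabel); the age model emits one output.  The default
architecture is deliberately desk-scale — 2 hidden layers of 64 units — with
the full-scale 4 × 256 / 4 × 400 variants available through
`predictor_config()`; the grid search that originally selected those
architectures is not re-run.  A constant target short-circuits to the
constant predictor, which is MAE-optimal.

Psychological age can be *corrected for chronological age*: a linear fit of
predicted on chronological age over the training split is subtracted, so
the corrected value is the chronological age plus the subject's deviation
from the typical prediction of their age peers.  A regression fit was chosen
over binned means because it is smooth, uses no binning parameter, and has
the required residualization property (corrected deltas uncorrelated with
age); same-age orderings are preserved by construction.

Because well-being scores pile up near the scale maximum, age trends are
summarized as the fraction of subjects at or above 90% of the maximum in
5-year age bins (`wellbeing_trend()`); empty bins are dropped with a
warning and bins with zero actual fraction are excluded from the curve
MAPE.  A known limitation: MAE-trained predictions shrink toward the
conditional center, so the predicted near-ceiling fraction underestimates
the actual one and the trend MAPE between predicted and actual curves is
large on the synthetic cohort even when per-subject errors are small.

## Feature selection and relative importance

`shadow_select()` implements all-relevant (Boruta-style) screening: each
round permutes a shadow copy of every feature, fits a random-forest
impurity importance (`ranger`, single-threaded and seeded for
reproducibility), and counts a hit when a real feature beats the round's
best shadow.  Decisions come from one-sided binomial tests of the hit count
against chance (p = 0.5): confirmation is tested at `alpha / n_features`
(Bonferroni) because a fixed sample contains chance correlations that can
repeatedly beat the shadow maximum, and false confirmations pollute the
downstream feature set; rejection — which merely prunes — is tested at the
nominal `alpha` (default 0.01 over 50 rounds).  With a multi-column target
the union over targets is returned, so a feature relevant to any well-being
dimension survives, and duplicated informative features are both kept
(relevance, not minimal-set, semantics).

`vif_filter()` computes `VIF = 1/(1 − R²)` from regressing each feature on
the others and removes the worst offender (ties: lowest column index) until
all VIFs are at or below 10; exact collinearity yields an infinite VIF and
immediate removal.  The study's manual screen of non-modifiable features is
human judgment and is represented only as a user-supplied exclusion of
columns before the call.

`en_importance()` regresses one follow-up well-being dimension on sex, age,
the model-predicted future value of that dimension, and all six baseline
scores.  Hyperparameters are chosen by 5-fold cross-validated MAE over
exactly the printed grid — L1 ratio 0 to 1 in steps of 0.01 and penalty
weights {1e-5, 1e-4, 1e-3, 1e-2, 1e-1, 0.0, 1.0, 10, 100}, the 0.0 entry
read literally as the unpenalized OLS limit.  Predictors are standardized
before fitting (the importance comparison needs a common scale; the
restricted grid {l1 = 0, penalty = 0} reproduces a closed-form OLS solve,
which the tests assert).  The winner is the largest absolute coefficient;
under the hedonic-treadmill hypothesis a baseline score would win, and the
planted cohort is constructed so that the model-derived prediction should.

## The synthetic cohort

`cohort_spec()` defaults encode the study geometry: 2718 training subjects
(all non-depressed) and a 1173-subject test partition with 394 depressed
and 779 non-depressed, 32 items on a 1–7 scale, ages uniform on 25–74, sex
Bernoulli(0.40 male).  The planted structure, chosen once:

* **Latent trait with a vulnerable mode.** Items would otherwise be
  independent noise, and a mean-shifted depressed blob is then nearly
  orthogonal to the 2-D plane the map learns, so depressed subjects would
  spread uniformly across it.  Instead the non-depressed population varies
  along a mood/adaptivity axis (the unit direction of `depression_shift`,
  scaled by `trait_sd` = 1.5 item units): a standard-normal main mode plus
  a depression-prone minority mode (12% of subjects, mean 2.8, sd 0.5 on
  the trait scale).  This is the generator's counterpart of the empirical
  observation that a map trained only on non-depressed people still
  contains a small depression-prone region.
* **Depression shift.** Depressed subjects are additionally mean-shifted by
  −0.8 on the twelve adaptive items and +0.8 on the maladaptive last
  quarter, placing them in the far tail of the same trait axis.
* **Well-being link.** Follow-up well-being is a fixed logistic squash of a
  linear item combination (positive loadings on staggered adaptive items,
  negative on the maladaptive block) plus Gaussian noise (`noise_sd` = 0.5
  scale points, clipped to the scale); with `noise_sd = 0` it is an exact
  function of the items, the limit in which the predictors must approach
  zero error.  Baseline well-being mixes 55% of the same signal with 45% of
  an independent reflected-Beta(5, 1.5) component mapped to the scale —
  right-skewed in the questionnaire sense (mass near the maximum) and a
  noisy proxy of the item signal, which is what gives the elastic-net
  comparison its intended structure.
* **Age signal.** Standardized age loads 0.8 on items 13–20, a block
  disjoint from the depression-shifted items, so age and depression signals
  are separable; without it psychological age would be unlearnable from the
  items and the age predictor untestable.
* **Seeding.** One global seed feeds deterministic per-subsystem streams
  (demographics, items, baseline well-being, follow-up noise), so
  regeneration is bit-identical and each stage can be varied independently.

What the generator does **not** emulate: real item wording or marginals,
item-level measurement models, missing data, attrition between waves,
cohort effects, or any dependence structure beyond the single trait axis.
Passing tests therefore demonstrate that the algorithms recover structure
they are designed to recover — not that the substantive findings hold in
real survey data, whose effect sizes (e.g. the published real-data
prediction errors) are explicitly out of scope here.

## Problem sizes

The test suite exercises the map at 1 × 1 to 12 × 12 with cohorts of a few
hundred to ~1800 subjects, and the full-geometry checks (25 × 25, 3891
subjects, both predictors, six elastic-net fits) run in the acceptance
script and the end-to-end test; selection benchmarks use 1000 × 25 designs
with 50 shadow rounds.  These sizes were chosen so the whole suite runs
comfortably on a single CPU while still covering the flagship
configuration.

## Known limitations

* Depression odds are raw ratios; cells with tiny counts have noisy odds,
  and endpoint selection inherits that noise.  The unsmoothed ratio was
  kept deliberately so printed contingency tables pass through unchanged.
* The hierarchical cut at k = 3 is a global choice; on some seeds the
  extreme corner of the map forms a tiny outlier cluster and the
  depression-prone region is then best seen at k = 4.
* The elastic-net grid treats penalty 0.0 literally; with 9 predictors and
  ~1000 rows the unpenalized fit is well-posed, but near-collinear designs
  would make that grid point fragile.
* Bellman–Ford is O(cells × edges) per endpoint pair; fine at 625 cells,
  not intended for much larger lattices.
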