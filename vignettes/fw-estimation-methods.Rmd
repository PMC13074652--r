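---
title: "Methods: fresh-weight estimation for greenhouse sweet pepper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fresh-weight estimation for greenhouse sweet pepper}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The estimation problem

Fresh weight (FW) of greenhouse fruit vegetables is the quantity growers and
yield models care about, but measuring it destructively removes the plant.
`pepperfw` estimates two FW targets of sweet pepper from non-destructive
morphological measurements:

* **shoot FW** (g) — vegetative tissue mass, excluding harvested fruit;
* **fruit FW** (g) — the *cumulative* mass of ripe fruit harvested up to the
  sampling date.

The measured predictors are plant height, four stem diameters (basal plus
one per stem segment, mm), three stem-segment lengths (main/left/right, cm,
matching the two-stem training system with a shared main axis), days after
transplanting (DAT), the interlighting treatment (CT = none, RB = red–blue,
FR = red–blue + far-red) and a pruning flag. What makes the problem hard is
dynamic biomass partitioning: as fruit set and repeated harvests progress,
the mapping from structure to FW changes with developmental stage, so a
single static scaling law fits shoot FW far better than fruit FW.

## The synthetic study dataset

The measurement campaign underlying the design (five growing seasons, three
cultivars, three lighting treatments, 36 design cells, 303 destructively
sampled plants) is not deposited anywhere, so the package ships a
first-class generator (`sim_config()`, `generate_dataset()`) that emulates
the *design and the statistical relationships the analysis assumes*, not any
particular plant:

* **Trait growth** is logistic in DAT per trait,
  $x(t) = A / (1 + e^{-r(t - m)})$, with defaults ($r = 0.03$/day, $m = 75$
  days) chosen so traits reach about 90% of their asymptote by DAT 150 —
  the saturating growth that motivates a sigmoid allometry. Asymptotes are
  realistic for a two-stem crop (lateral segments 120 cm, diameters
  14–22 mm).
* **Plant height** is derived: main segment + the taller lateral + a 15 cm
  canopy offset, with its own noise. Height is therefore an informative but
  imperfect proxy of total stem length, which is what gives the structural
  feature group its headroom over the basic group.
* **Shoot FW** is a logistic sigmoid of the realized *stick volume* (summed
  segment lengths): $FW = L/(1 + e^{-k(V - V_0)})$ with $L = 2000$ g,
  $k = 0.02$/cm, $V_0 = 150$ cm. With noise switched off this link is exact,
  which the allometric recovery tests exploit.
* **Fruit FW** is a DAT-dominated cumulative logistic ($L = 3000$ g,
  $k = 0.06$/day, midpoint 120 days), zero before a fruiting onset of DAT 45,
  shifted so it is continuous at onset and non-decreasing in DAT. A small
  structural modulation (weight 0.3 on the plant's relative stick-volume
  deviation) and treatment multipliers keep structure and management
  informative but secondary — mirroring the finding that time dominates
  fruit FW while structure dominates shoot FW.
* **Management effects** are multiplicative and small by design: treatment
  multipliers within ±5% (CT 1.00, RB/FR slightly above) and a pruning
  effect of 0.97 on shoot FW with pruning probability 0.3. This encodes the
  assumption, not a biological claim, that management contributes least.
* **Noise** is multiplicative lognormal with mean one (traits CV 8%, targets
  CV 12%), because all quantities are positive; CV 0 reproduces the exact
  deterministic links.
* **Units**: cm for lengths/height, mm for diameters, g for FW. The source
  measurements' units are not printed anywhere, so these were fixed once as
  the field-typical choices and documented here.

What the generator does *not* emulate: trait–trait residual correlation
beyond the shared growth curve, per-fruit harvest events, weather and
climate covariates, or between-greenhouse variation. Tests passing on this
data show the pipeline's logic and guarantees; they do not certify accuracy
on real crops.

## Allometric baselines

Three geometric stem-volume proxies (`plant_volume()`):

* **stick** — summed segment lengths (cm); a height-only variant is exposed
  via `stick_mode = "height"`;
* **cylinder** — $\sum_s \pi r_s^2 L_s$ (cm³), one radius per segment from
  that segment's diameter;
* **truncated cone** — $\sum_s (\pi L_s / 3)(r_1^2 + r_1 r_2 + r_2^2)$ with
  proximal-to-distal taper: the main segment from basal to main diameter,
  each lateral from the main diameter to its own. The field protocol
  (diameters at upper, middle and lower stem positions) under-determines the
  mapping of measured diameters onto cone radii; this is one consistent
  reading, fixed and documented.

Each proxy feeds two scaling laws (`fit_allometric()`): linear
$FW = \alpha V + \beta$ by OLS, and the logistic sigmoid
$FW = L/(1 + e^{-k(V - V_0)})$ by bounded Levenberg–Marquardt least squares.
Numerical choices for the sigmoid: start at $L_0 = 1.1\max FW$,
$V_0 = \mathrm{median}(V)$, $k_0 = 4/\mathrm{range}(V)$; bounds
$L \in (0, 10 \max FW]$, $k > 0$, $V_0 \in [\min V, \max V]$; at most 10 000
function evaluations; convergence at relative SSE change $10^{-10}$. If the
optimizer fails, or converges to a non-finite or non-positive $L$, the fit
falls back to the linear law per fit (per fold and target) and flags
`fallback_used` — silent fallback is deliberately impossible below four
points, where the call errors instead. Baselines are evaluated under the
same fold plan as the ML models (`evaluate_allometric()`), since a shared
cross-validation scheme is the only fair comparison.

## Group-wise augmentation and its quality control

With only 303 destructive samples spread over 36 (season, treatment, DAT)
groups, flexible models overfit. `augment_dataset()` expands training data
group-wise, never globally:

* groups with $n \le$ `n_thr` (default 10): resample rows and add Gaussian
  noise at $0.05\,\sigma_f$ per feature, with $\sigma_f$ the *within-group*
  sd — the within-group scope honours the goal of preserving local
  statistics (the whole-dataset alternative would inflate small groups);
* larger groups: a variational autoencoder per group (latent dim 8, hidden
  layers 64/32, batch norm + leaky ReLU + dropout 0.1, 500 epochs, batch 32,
  Adam at $10^{-3}$, KL weight $\lambda = 0.1$), trained on within-group
  z-scored features; samples are decoded standard-normal latent draws,
  de-standardized and clipped at zero below.

The ten continuous columns (eight traits + both FW targets) are generated;
year/cultivar ride along as metadata and the categorical/discrete fields
(season, treatment, DAT, pruning) are reassigned from the source group, never
generated. Generation is capped at 10× the group size under every
configuration. A single master seed fans out to per-group seeds through a
polynomial hash of the group key (`group_seed()`), so results do not depend
on group processing order. The dropout rate (0.1) and the VAE's training
internals beyond the hyperparameter table above are the package's own
documented defaults.

Quality is diagnosed by a marginal histogram KL divergence
(`kl_divergence_marginal()`): 20 equal-width bins over the pooled min–max
range, additive smoothing $10^{-8}$, direction KL(original ‖ augmented),
natural log — choices a KL diagnostic needs but that no convention pins
down, so they are fixed here once. The sweep `select_threshold()` re-runs the full
augmentation at candidate thresholds $n \in \{3, 5, 7, 10\}$ and picks the
feature-averaged KL argmin, ties toward the larger threshold (more VAE
groups shrink to Gaussian, so larger thresholds are the conservative side).
The package compares original records against the *synthetic rows only*
(not originals + synthetic), which is the stricter reading of
original-vs-augmented similarity. Average-KL values quoted for real
greenhouse data depend on the histogram scheme, so no numeric parity is
attempted — the working quality bound is KL ≤ 1.

## Learners and the stacked weighted ensemble

Four base learners (`train_base()`) mirror the four-learner ensemble
roster this pipeline is built around, without an AutoML framework: two gradient-boosted tree variants
with different leaf-growth policies (depthwise `max_depth = 5`, and
leaf-wise `max_leaves = 31`, both 150 rounds at learning rate 0.08 via
xgboost), a 200-tree random forest (ranger), and a feed-forward network
with hidden layers 32/8, batch norm + ReLU + dropout 0.2, Adam, MSE loss,
at most 500 epochs with early stopping at patience 80 on validation loss.
Hyperparameters the protocol leaves open (tree depth/rounds, FFNN learning
rate $10^{-3}$, batch 256, dropout) are fixed documented defaults sized for a few thousand
training rows; there is deliberately no tuning loop. Tree models take raw
features; the FFNN z-scores features and target on training statistics; the
treatment factor is one-hot encoded and pruning is 0/1.

Ensemble weights (`fit_ensemble_weights()`) come from greedy selection with
replacement over 100 rounds on out-of-fold (OOF) predictions: each round
adds the base model minimizing the running-average RMSE; weights are the
selection frequencies at the best-scoring round. That construction
guarantees $w_i \ge 0$, $\sum w_i = 1$, and ensemble OOF RMSE no worse than
the best single base (round one *is* the best single base). Weights are
fitted per target rather than shared across targets — the safer reading
when nothing forces one weight vector to serve both. Tests cross-check the
greedy optimum against an exhaustive simplex grid.

## Leakage-safe repeated cross-validation

`make_fold_plan()` builds a 5-fold × 3-repeat plan over *original* records
only, near-stratified by (season, treatment): records are ordered by stratum
(shuffled within, random cyclic offset) and dealt cyclically, so fold sizes
differ by at most one. Synthetic rows are rejected outright. `run_cv()`
regenerates augmentation *per training fold from that fold's originals
only* — the stricter resolution of "excluded if corresponding to test-fold
groups", satisfying it by construction — and asserts on every fold that (a)
test folds contain no synthetic rows and (b) every synthetic row's source
records lie in the fold's training originals. The FFNN's early-stopping
split is drawn from original training rows only. Metrics (R², RMSE) are
computed per repeat from OOF vectors (one prediction per original record per
repeat) and summarized as mean ± sd over repeats, matching the
per-repeat-error-bar convention. `make_aug_cache()` precomputes the per-fold
augmentation so both targets and all ablation variants share it.

## Interpretation

**Ablation** (`ablation_table()`): retrain the ensemble without one feature
group (basic / structural / temporal / management) under the identical fold
plan and report $\Delta R^2$ versus the full model, per target; negative
deltas are reported as-is. Ablation contrasts *feature sets*, and
augmentation shifts full and reduced models alike, so the default analysis
ablates on the original data; re-augmented ablation is available by passing
the augmentation config, at roughly ten times the cost.

**Shapley attribution** (`shapley_attribution()`): a permutation-sampling,
interventional estimator — the value of a feature subset is the mean
prediction over a seeded background sample with those features set to the
explained observation's values. It is model-agnostic because the explained
model is a heterogeneous weighted ensemble. Defaults: 100-row background,
200 permutations per observation. The telescoping permutation form is
exactly efficient (baseline + attributions = prediction) for any number of
sampled orderings; an exhaustive subset-enumeration oracle (feasible to ~12
features) backs the estimator in tests. One-hot treatment attributions are
summed back into a single factor for reporting.

## Problem sizes used by the tests

The test suite runs the full 303-record design for the generator,
augmentation-quality, allometry and leakage checks (5×3 plan). The
qualitative pattern checks (augmented ≥ original fruit-FW R²; largest
ablation ΔR² = structural for shoot, temporal for fruit) use three replicate
seeds, each with a 5-fold single-repeat plan — three independent replicates
distribute the repeats across the majority vote at a third of the cost of
three full 5×3 runs. Unit tests for the VAE and CV internals use reduced
designs (4-group, 42-record tables) and shorter VAE schedules where the
property under test does not depend on the full schedule; everything
quality-bound-related keeps the full 500-epoch schedule.

## Known limitations

* Marginal KL is the only augmentation diagnostic; joint (multivariate)
  structure of synthetic rows is not validated, so augmented data may
  contain trait combinations no real plant would show.
* The generator's independence assumptions (noise independent across traits
  given DAT) make the synthetic problem easier than real data; absolute R²
  values on synthetic data say nothing about real-crop accuracy.
* The VAE underestimates within-group variance at these group sizes (12–36
  rows), a known small-sample VAE behaviour; the KL diagnostic catches
  gross failures but not variance shrinkage per se.
* On the synthetic study the augmentation gain at the *ensemble* level is
  small and can sit within the repeat-to-repeat spread — the generator's
  clean group structure gives flexible models little overfitting to repair;
  the benefit is clearest for the FFNN. Large augmentation gains on real
  data are a property of harder, noisier measurements, which the tests here
  cannot certify.
* Single-greenhouse, two-stem architecture assumptions are baked into the
  feature set; transfer to other training systems is untested.
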