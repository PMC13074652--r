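# pepperfw

Fresh-weight (FW) estimation for greenhouse sweet pepper from
non-destructive morphological measurements: allometric baselines,
group-wise data augmentation with Kullback–Leibler quality control, a
stacked weighted ensemble of machine-learning regressors under
leakage-safe repeated cross-validation, and feature-attribution analysis.

## The problem

Sweet pepper grown in greenhouses continuously redistributes biomass
between vegetative tissue and developing fruit, so the mapping from what a
grower can measure without destroying a plant — height, stem diameters,
stem-segment lengths, days after transplanting (DAT), lighting treatment,
pruning — to shoot FW and cumulative harvested fruit FW (both in g) shifts
with developmental stage. The package compares three modeling strategies
for this problem:

1. **Allometric baselines.** A geometric stem-volume proxy
   V (stick = summed segment lengths; cylinder = Σ πr²L; truncated cone =
   Σ (πL/3)(r₁² + r₁r₂ + r₂²)) feeds either a linear scaling law
   FW = αV + β or a logistic sigmoid FW = L / (1 + e^{−k(V − V₀)}), fitted
   by least squares with an automatic linear fallback when the sigmoid
   optimizer does not converge.
2. **Machine-learning models.** Two gradient-boosted tree variants, a
   random forest and a feed-forward network (32/8 hidden units, batch
   normalization, dropout, Adam, early stopping at patience 80), combined
   by a **stacked weighted ensemble**: simplex-constrained weights fitted
   by greedy selection on out-of-fold predictions, guaranteeing the
   ensemble never trails its best base learner.
3. **Group-wise augmentation.** Within each (season, treatment, DAT)
   group: resampling plus Gaussian noise at 0.05 × the feature-wise sd for
   groups of n ≤ 10, a per-group variational autoencoder (latent dim 8,
   hidden 64/32, 500 epochs, KL weight λ = 0.1) for larger groups, capped
   at 10× the group size. Quality is tracked by a 20-bin marginal
   histogram KL divergence with the acceptability bound KL ≤ 1, and the
   Gaussian/VAE routing threshold is chosen by a KL sweep over
   n ∈ {3, 5, 7, 10}.

Evaluation is repeated 5-fold × 3-repeat cross-validation in which test
folds contain only original records and augmentation is regenerated per
training fold from that fold's originals — asserted, not assumed, on every
run. Interpretation combines feature-group ablation (ΔR² of the retrained
ensemble) and permutation-sampling Shapley attribution with an exhaustive
oracle for small feature counts.

Because the underlying greenhouse table is not publicly deposited, the
package ships a first-class synthetic generator that reproduces the
five-season experimental design (36 design cells, 303 plants) with
logistic trait growth, a sigmoid stick-volume→shoot-FW link and a
DAT-dominated cumulative fruit-FW link. All tests and results run on that
synthetic study; see `vignettes/fw-estimation-methods.Rmd` for what that
does and does not demonstrate.

## Worked example

The numbered scripts under `analysis/` run the whole study; each writes
its tables under `results/`. A condensed session:

```r
library(pepperfw)

records <- generate_dataset(sim_config(seed = 42))   # 303 plants, 36 groups
plan    <- make_fold_plan(records, k = 5, repeats = 3, seed = 2024)

# allometric baselines, out-of-fold
summarize_metrics(evaluate_allometric(records, plan))

# augmentation + quality control
sweep <- select_threshold(records, c(3, 5, 7, 10), augmentation_config(seed = 7))
aug   <- augment_dataset(records, augmentation_config(n_thr = sweep$n_thr, seed = 7))
augmentation_report(aug)$kl_mean

# ensemble under leakage-safe CV, with and without augmentation
cv <- run_cv(records, "fruit_fw", plan, augment = augmentation_config(seed = 7))
summarize_metrics(cv$metrics)
```

Running `Rscript analysis/01_simulate.R` through `05_interpret.R` prints,
on this machine:

```
Generated 303 records over 36 design rows (36 groups by season/treatment/DAT).
Correlation check: shoot FW vs stick volume r = 0.909 (vs DAT 0.887);
fruit FW vs DAT r = 0.946.
```

— the generator's two design targets: shoot FW tracks structure more
closely than time, fruit FW tracks time more closely than any trait.

```
Best shoot-FW baseline: stick + sigmoid (R2 0.861, RMSE 197.0 g).
```

— among the six allometric baselines the stick (length-only) proxy with
the sigmoid law wins for shoot FW. (On this synthetic study the stick
sigmoid *is* essentially the generating law for shoot FW, so it is a
strong baseline; the ML models' advantage shows on fruit FW, where no
static volume law fits.)

```
Threshold sweep (feature-averaged KL, nats):
 candidate    mean_kl
         3 0.21708151
         5 0.20931770
         7 0.20360344
        10 0.09421178
Chosen routing threshold: n_thr = 10
Feature-averaged marginal KL: 0.094 nats (quality bound: <= 1).
```

— augmented data stays distributionally close to the originals
(KL well under the ≤ 1 acceptability bound), and the sweep selects the
largest threshold, i.e. the VAE is reserved for groups with more than ten
plants.

```
Ensemble out-of-fold performance:
    model   target   variant   r2_mean        r2_sd rmse_mean   rmse_sd
 ensemble fruit_fw augmented 0.9471083 0.0017676420  252.2132 4.2075424
 ensemble fruit_fw  original 0.9474283 0.0002945387  251.4717 0.7049306
 ensemble shoot_fw augmented 0.8562070 0.0047470319  200.1698 3.3021286
 ensemble shoot_fw  original 0.8552477 0.0027204177  200.8487 1.8858736
```

— the ensemble never trails its best base learner (a guarantee of the
greedy weight construction). On this synthetic study the augmentation
benefit concentrates in the FFNN (fruit-FW R² 0.922 → 0.936); ensemble
and tree-model differences sit within the repeat-to-repeat spread,
because the generator's clean group structure leaves the flexible models
little room to overfit in the first place.

```
      group   target   r2_full r2_reduced      delta_r2
 structural shoot_fw 0.8549132  0.8450990  0.0098142081
   temporal fruit_fw 0.9480132  0.9319166  0.0160966211
Largest delta-R2 group: structural for shoot FW, temporal for fruit FW.
```

— ablation recovers the organ-specific pattern the generator encodes:
structure drives shoot FW, developmental time drives fruit FW. The
Shapley rankings agree: for fruit FW, DAT has mean |attribution| 413 g,
more than three times the next feature, while for shoot FW the stem
lengths lead.

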