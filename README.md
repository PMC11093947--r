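# penumbraDTI

Contrast-free estimation of the ischemic penumbra from diffusion tensor
MRI in a rodent stroke model, evaluated against the standard
perfusion–diffusion mismatch (PDM).

## The problem

After middle-cerebral-artery occlusion, the *penumbra* — hypoperfused but
still salvageable tissue — is clinically delineated as the mismatch
between a perfusion deficit (relative cerebral blood flow below 54% of the
contralateral hemisphere) and the ischemic core (mean diffusivity below
70% of contralateral). Measuring perfusion requires a gadolinium bolus,
which is contraindicated for many patients. This package implements a
voxel-wise machine-learning alternative that needs only the diffusion
acquisition:

1. **Phantom cohort** (`phantom_spec()`, `simulate_rat()`,
   `simulate_cohort()`): seeded synthetic rat brains — DWI
   (30 directions, b = 1,200 s/mm², 5 b = 0), a DSC bolus series
   (TR 0.6 s, TE 20 ms, 200 repetitions), Rician noise, per-animal
   variability, a core that grows between 0.5 h and 1.5 h, and recorded
   ground-truth labels.
2. **DTI metrics** (`fit_tensor()`, `compute_metrics()`,
   `exclude_csf()`): log-linear tensor fit and the 11 scalar maps
   FA, RA, p, q, MD, RD, AD, L, Cl, Cp, Cs, with CSF removed at
   MD > 800×10⁻⁶ mm²/s. The decomposition satisfies p = √3·MD and
   L² = p² + q² identically.
3. **Perfusion** (`signal_to_concentration()`, `fit_gamma_variate()`,
   `compute_perfusion_maps()`): gamma-variate bolus fit
   C(t) = K(t−t₀)^α e^{−(t−t₀)/β}; rCBV = K β^{α+1} Γ(α+1),
   rMTT = β(α+1), rCBF = rCBV/rMTT (central volume principle).
4. **PDM labeling** (`split_hemispheres()`, `delineate()`,
   `contiguity_correct()`, `compute_pv()`): the 30%/46% reduction rules
   against contralateral hemisphere means, small-component removal, and
   penumbral volume in mm³.
5. **Features** (`build_ic_reference()`, `extract_features()`,
   `select_features()`): 25 features per voxel — 11 metrics, Mahalanobis,
   mean cosine and correlation distances to the core, and 11 per-metric
   standardized Euclidean distances — plus neighborhood component
   analysis feature selection with the 2%-of-maximum-weight rule and a
   bypass when selection does not generalise better.
6. **Stacked ensemble** (`make_folds()`, `tune_and_fit_base()`,
   `fit_stacking()`, `train_cohort()`): MLP, GAM, decision tree, random
   forest and boosting, tuned by sequential model-based optimisation on a
   70/30 inner split, 1:1 class balancing per rat, leave-one-rat-out outer
   folds, and a ridge-logistic meta-learner over the five base
   probabilities.
7. **Evaluation** (`classification_metrics()`, `mcnemar_compare()`,
   `segmentation_agreement()`, `pv_agreement()`,
   `permutation_importance()`, `feature_contrast()`): median (IQR)
   classification metrics, McNemar comparisons, Dice and volume
   similarity, Pearson + Bland–Altman agreement of penumbral volumes, and
   random-forest permutation importance.

`run_cohort()` chains everything under one master seed with stage caching
and a JSON report; `vignettes/penumbra-estimation.Rmd` documents the
models, parameters and design choices.

## Worked example

```r
library(penumbraDTI)

spec <- phantom_spec(grid_shape = c(32L, 32L, 8L), n_rats = 1L, seed = 42L)
rat  <- simulate_rat(spec, 1)

tf  <- fit_tensor(rat$data$t0.5$dwi, rat$scheme,
                  mask = brain_mask_from_b0(rat$data$t0.5$dwi, rat$scheme),
                  voxel_size = rat$voxel_size)
mm  <- exclude_csf(compute_metrics(tf))

cc  <- signal_to_concentration(dsc_series(rat$dsc, rat$dsc_meta$TR,
                                          rat$dsc_meta$TE))
pm  <- compute_perfusion_maps(
  fit_gamma_variate(cc$conc, cc$t, baseline_sd = cc$baseline_sd,
                    mask = mm$brain_mask & cc$valid))

lv  <- delineate(mm, pm$rcbf, split_hemispheres(mm$brain_mask, rat$midline))
table(pdm = lv$labels, truth = rat$data$t0.5$truth$labels)
compute_pv(lv)
```

On this seed the mismatch labeling recovers the simulated lesion almost
voxel-for-voxel:

```
     truth
pdm      0    1    2    3    4
    0 6280    2   22    9    0
    1    0   50    0    0    0
    2    0    1  425    0    0
    3    0    0    6  441    0
    4    0    0    0    0  956
[1] 17.04
```

i.e. 425 of 453 true penumbral voxels labeled penumbra (code 2), a PDM
penumbral volume of 17.04 mm³ against a simulated truth of 18.12 mm³.
Codes: 0 excluded, 1 core, 2 penumbra, 3 normal tissue, 4 contralateral.

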