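# roiprog

ROI-based deep learning for a continuous brain-MRI progression index.

## What this package is for

Predicting which cognitively normal (NC) or subjective-cognitive-decline
(SCD) individuals will convert to mild cognitive impairment (MCI) years
later, from a single baseline T1-weighted MRI. Training data in such
longitudinal studies carry only binary outcomes (progressed vs stable), but
the clinically useful quantity is a *continuous* score that reflects where a
brain sits along the degeneration path. `roiprog` implements a two-step
convolutional framework for exactly this:

1. **Single-ROI screening (SRNet).** For each region of a label atlas (the
   116-region AAL nomenclature ships with the package), a small 3D CNN is
   trained on the 32³ patch at the ROI centroid and its held-out AUC for
   progressive-vs-stable classification is recorded. Regions are ranked by
   AUC and the top K (default 10) are kept.
2. **Multi-ROI network (MRNet) and the Progressive Index.** K backbone
   branches *sharing one parameter set* process the K selected ROI patches;
   their concatenated features (K × 64) feed one fully-connected softmax
   layer. Both networks minimize the cross-entropy

   L = −[ y·log F(M) + (1 − y)·log(1 − F(M)) ],

   and for a new scan M̂ the positive-class output ŷ = F(M̂) is the
   **Progressive Index (PI)** — a score in [0, 1] interpreted as the
   propensity to progress.

Each backbone is five 3×3×3 same-padded convolutions (ReLU; channels
16, 32, 64, 64, 64), max-pooling stride 2 after layers 1–4 and a global
average pool after layer 5, so a 32³ patch yields a 64-vector
(32 → 16 → 8 → 4 → 2 → GAP). The 3D conv engine is implemented in C++ with
deterministic hand-rolled kernels, so every training run is bit-reproducible
under a fixed seed regardless of BLAS backend or thread count.

Around the core model the package provides: NIfTI volume/atlas handling with
centroid patch extraction, a phantom-cohort simulator with planted
atrophy-like signal (so the pipeline is fully testable without
controlled-access imaging data), mean-threshold sensitivity/specificity,
ROC/AUC with bootstrap CIs, covariate-adjusted logistic models with odds
ratios, age-adjusted partial correlation, and a seeded end-to-end pipeline
driver with a command-line front end (`inst/cli/roiprog.R`).

## Worked example

A desk-scale phantom study: 6 spherical ROIs in 32³ volumes; progressive
subjects have ROI 1 darkened by 0.6 under voxel noise 0.2.

```r
library(roiprog)

study <- simulate_cohort(
  file.path(tempdir(), "demo"),
  shape = c(32, 32, 32), n_rois = 6, roi_radius = 3,
  effect = effect_spec(informative_labels = 1, intensity_shift = 0.6,
                       erosion_fraction = 0, noise_sd = 0.2),
  n_per_group = c(pMCI = 24, sMCI = 24), seed = 7)
atlas <- array(as.integer(round(load_nifti_volume(study$atlas_path))), c(32, 32, 32))

spec <- backbone_spec(channels = c(2, 4, 4, 4, 4))   # reduced for 16^3 patches
tab <- screen_rois(study$manifest, atlas, spec = spec,
                   cfg = train_config(epochs = 4, batch_size = 4, seed = 55,
                                      validation_fraction = 0.25),
                   patch_size = 16, n_splits = 3)
ranking <- rank_rois(tab, k = 3)
print(ranking)
#> ROI ranking: 6 screened, top 3 selected
#>   label_id  name       auc n_train n_val       seed
#> 1        1 roi_1 0.8425926      36    12 1589389281
#> 2        3 roi_3 0.6574074      36    12 1589389283
#> 3        2 roi_2 0.6111111      36    12 1589389282

fit <- train_mrnet(study$manifest, atlas, ranking, spec = spec,
                   cfg = train_config(epochs = 14, batch_size = 4, seed = 21,
                                      validation_fraction = 0.25),
                   patch_size = 16)
pi_tab <- score_cohort(fit, study$manifest, atlas)
print(threshold_metrics(pi_tab))
#> PI threshold 0.4972: SEN 1.0000, SPE 1.0000, AUC 1.0000 (48 labeled / 48 scored)

covs <- read.csv(study$covariates_path)
comb <- combined_model_eval(pi_tab, covs,
                            formula_terms = c("age", "gender", "education"),
                            n_boot = 500, seed = 9)
print(comb$roc)
#> AUC = 1.0000 (95% CI 1.0000-1.0000, 500 bootstrap resamples)
```

Reading the output: the screen ranks the planted region (ROI 1, mean
held-out AUC 0.84 over 3 repeated splits) first; the remaining AUCs hover
near chance. The MRNet trained on the top-3 patches separates the cohort
perfectly at the overall-mean PI threshold (0.497): sensitivity and
specificity 1.0 on the 48 labeled subjects, and the PI-plus-demographics
logistic model has apparent AUC 1.0. A phantom with a 3-SD planted effect is
an easy problem — the point of the example is the mechanics, not the
difficulty.

The same study can be driven end to end from a YAML config:

```sh
Rscript inst/cli/roiprog.R all --config study.yaml
```

with stages `simulate | screen | train | score | metrics | stats` writing
restartable artifacts (manifest, AUC table, ranking, model checkpoint, PI
table, metrics and model summaries) under the configured output directory.

## Vignette

`vignettes/progressive-index.Rmd` documents the model and its assumptions,
the coordinate/patch conventions, the training defaults and seed discipline,
what the phantom generator does and does not emulate, and the package's
design decisions (threshold rule, PI scaling in logistic models, null-
calibration protocol, dose-response study design).
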