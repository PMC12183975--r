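---
title: "An ROI-based deep-learning Progressive Index for pre-MCI conversion prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An ROI-based deep-learning Progressive Index for pre-MCI conversion prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Older adults who are still cognitively normal (NC), or report only subjective
cognitive decline (SCD), may already carry structural brain changes that
anticipate conversion to mild cognitive impairment (MCI) years later. A
clinically useful predictor should (a) localize where in the brain the signal
lives, and (b) output a *continuous* risk score rather than a hard binary
call, because at any point along a slow degeneration the truth is a fuzzy
state between "stable" and "progressive", even though the training data only
carry binary outcome labels.

`roiprog` implements a two-step convolutional framework for this task:

1. **SRNet screening.** For every region of interest (ROI) of an atlas
   parcellation (e.g. the 116-region AAL nomenclature shipped with the
   package), a small 3D CNN — one *backbone* plus a softmax head — is trained
   on the cubic patch centered at that ROI's centroid, and its held-out AUC
   for separating progressive from stable subjects is recorded. Ranking the
   ROIs by AUC and keeping the top K (default 10) yields the discriminative
   regions.
2. **MRNet and the Progressive Index.** A multi-ROI network stacks K
   backbone branches — *all sharing one parameter set* — over the K selected
   ROI patches, concatenates their K×64 features into a single
   fully-connected layer with two logits and softmax output. Both networks
   are trained with the cross-entropy loss
   `L = -[y log F(M) + (1 - y) log(1 - F(M))]`; at inference the positive
   class probability `F(M)` of a new scan is the **Progressive Index (PI)**,
   a score in [0, 1] read as the propensity to progress.

## The backbone, exactly

Each backbone is five 3×3×3 convolutions with ReLU activations and channels
16, 32, 64, 64, 64; a stride-2 max-pool follows each of the first four
layers and a global average pool follows the fifth, so a 32³ patch traverses
the spatial chain 32 → 16 → 8 → 4 → 2 and emits a 64-vector. Convolutions
use *same* padding: it is the only convention under which this chain closes
without cropping, and the package asserts the chain explicitly
(`backbone_dims_chain()`). The MRNet FC layer therefore consumes K × 64
inputs (640 for K = 10) — K times the SRNet's.

The engine behind these layers (`src/cnn.cpp`) uses hand-rolled matrix
kernels rather than BLAS. This costs some speed but buys bit-for-bit
reproducibility: results cannot drift with the BLAS backend, its thread
count, or its CPU-dispatched kernels, so a fixed seed pins every training
run exactly.

## Patch and coordinate conventions

* Voxel coordinates are **0-based** throughout the public API, matching the
  NIfTI voxel-index convention.
* An ROI centroid is the per-axis arithmetic mean of its voxel indices,
  rounded half-to-even (so the two-voxel ROI {0, 1} centers on 0).
* `extract_patch()` returns the half-open window
  `[c - size/2, c + size/2)`, giving an even-sized patch (32 is the default)
  a well-defined center voxel; voxels outside the volume are zero-filled, so
  ROIs near the border remain usable.
* Every patch is standardized (mean 0, SD 1; constant patches map to zeros)
  just before entering a network. This is on by default and configurable;
  it removes per-scan intensity offsets that a scanner, not biology, would
  otherwise contribute.
* Images are assumed skull-stripped and spatially normalized to the atlas
  space upstream; the package deliberately contains no registration code.

## Training and its seeds

Optimization settings are engineering choices (the reference description of
the architecture leaves them open): mini-batch Adam, learning rate 1e-3,
batch size 8, probability clipping at 1e-7 inside the loss, and a stratified
per-class validation split (default 20%) on which the per-epoch loss and the
screening AUC are recorded. Every stochastic ingredient — initialization
(He-normal weights), the split, the per-epoch shuffles, bootstrap resampling,
phantom generation — draws a named sub-seed via `derive_seed(master, tag)`,
so any stage can be reproduced in isolation and the per-ROI screening
results are independent of execution order.

Screening records the AUC on the held-out split, not on training data (a
network can overfit patch noise, so training AUC would be inflated). With
small cohorts a single split estimates that AUC with substantial variance —
a 20/20 split has a null standard deviation of ~0.09 — so `screen_rois()`
accepts `n_splits`: the recorded AUC is then the mean over that many
repeated stratified hold-outs, which we use (6 repeats) wherever the
calibration of null ROIs around AUC 0.5 matters.

Two screening contrasts are provided because cohort vocabularies offer two
natural choices: `"composite"` (default) pools all labeled rows — AD and
progressive subjects positive, stable subjects negative — while
`"ad_vs_nc"` restricts to rows tagged `AD` versus `NC`/`sNC`. Ranking ties
break by ascending label id.

## The phantom cohort generator

Real cohorts of this kind (ADNI, memory-clinic panels) are controlled
access, so the package ships a generator that emulates the *statistical
structure* the classifier assumes, not MRI appearance:

* a phantom atlas of non-overlapping spheres (`make_phantom_atlas()`),
  labeled 1..n;
* subject volumes with background 0.2 and ROI tissue 1.0;
* for progressive subjects, a chosen set of informative ROIs is darkened by
  `intensity_shift` and its outermost `erosion_fraction` of voxels (by
  distance from the centroid) is reset to background — an atrophy proxy
  combining intensity loss with boundary shrinkage — then Gaussian voxel
  noise is added;
* group tags reuse the longitudinal-study vocabulary (`sNC`, `pNC`, `rNC`,
  `sSCD`, `pSCD`, `AD`, `sMCI`, `pMCI`): `p*`/`AD` map to label 1, `s*` to
  label 0, and `r*` (unknown outcome at follow-up) to `NA`. Unknown-outcome
  subjects are drawn from the stable model but their label is withheld, so
  the scoring path for unlabeled subjects is exercised end to end.
* a synthetic covariate table (age, gender, education, brain size, an
  associative-memory score depressed in progressive subjects) accompanies
  each cohort so the covariate-adjusted models have realistic inputs.

What the generator does **not** emulate: MRI texture and partial-volume
effects, bias fields, registration error, deformation-based atrophy, or
longitudinal trajectories. Passing tests on phantoms therefore demonstrate
that the machinery — patch extraction, screening, ranking, shared-backbone
training, scoring, statistics — behaves correctly and reproducibly on data
with planted, known structure; they do not certify predictive performance
on real MRI.

## Study conditions used by the tests and the acceptance script

The synthetic study is fixed at: 48³ volumes, 30 spherical ROIs of radius 4,
informative labels 1–3, intensity shift 0.5, erosion 0.1, noise SD 0.2, and
100 subjects per class. At this volume scale the networks use 16³ patches
with a reduced backbone (channels 4/8/8/8/8) — the same five-layer,
four-pool architecture, sized to the phantom rather than to a full-brain
scan. Screening trains each SRNet for 3 epochs; the MRNet trains for 6
epochs with batch size 4. These sizes are the package's choices for a
desk-scale study; all of them are configurable.

Two design points deserve a note:

* **Null calibration.** The zero-effect check uses 40 subjects/class with a
  50% validation split and 6 repeated splits per ROI. From the null AUC
  standard deviation (~0.09 for one 20/20 split, ~0.04 after averaging 6
  repeats) the observed per-ROI AUCs should stay within 0.5 ± 0.15 with
  large margin; a single split would not support that band across 30 ROIs.
* **Dose response.** To verify that PI separation grows with effect size,
  cohorts at intensity shift 0, 0.25 and 0.5 are generated with erosion 0
  (so the dose is the shift alone) and each trained model is evaluated on
  an *independent* cohort simulated on the same atlas — out-of-sample gaps,
  unlike in-sample ones, cannot be inflated by overfitting the noise at
  shift 0.

## The evaluation layer

* `threshold_metrics()` classifies `PI >= threshold` as positive (ties
  positive), with the default threshold the *overall mean* PI across all
  scored subjects — including unknown-label ones, as an "overall average
  score" over a full validation cohort would be; sensitivity, specificity
  and AUC then use known labels only.
* `compute_auc()` is the rank-sum (Wilcoxon) AUC with ties credited 0.5;
  `roc_with_ci()` adds the ROC staircase and a stratified percentile
  bootstrap CI (default 2000 resamples, seeded).
* `group_pi_summary()` compares progressive vs stable PI with a linear
  model; unadjusted it reproduces the classical pooled-variance t-test
  exactly, and a zero-residual fit (all PI equal) is reported as statistic
  0, p 1.
* `fit_logistic()` wraps a maximum-likelihood logistic fit with Wald CIs
  and odds ratios, complete-case handling with dropped-row counts, and a
  separation flag (non-convergence or numerically saturated probabilities).
  PI enters models scaled to 0–100 (`pi_scale`), so its odds ratio refers
  to one PI percentage point — per-unit ORs on a [0, 1] score would be
  astronomically scaled and unreadable.
* `combined_model_eval()` fits `outcome ~ PI + clinical terms` and reports
  the ROC of the in-sample fitted probabilities (apparent performance, the
  usual convention for such combined models); a cross-validated variant is
  out of scope.
* `partial_pearson()` correlates residuals after regressing both variables
  on a covariate (typically age), with the t transform on n − 3 degrees of
  freedom.

## Numerical choices and degenerate inputs

* Probability clipping at 1e-7 before logs; softmax computed with the
  max-subtraction trick.
* Max-pool ties keep the first (lowest-index) voxel; erosion ordering
  breaks distance ties by voxel index; ranking ties break by ascending
  label id — all choices are deterministic so fixed seeds pin results.
* Constant patches standardize to zeros; a validation split that would
  empty a class is rejected with an error; single-class training data,
  absent atlas labels, and missing covariate columns raise named errors.
* Scoring a cohort never dies on one bad file: the subject's row is marked
  failed with the error message and the run continues.

## Limitations

* The phantom generator's realism limits are listed above; in particular,
  effect sizes are on the phantom intensity scale (background 0.2, tissue
  1.0) and do not translate directly into real atrophy rates.
* The two-logit softmax head is mathematically equivalent to the scalar
  sigmoid formulation of the loss; the PI is the positive-class output.
* Training is plain mini-batch Adam for a fixed epoch count — no
  augmentation, scheduling, or early stopping — because the framework's
  claims are about the ROI screening/PI construction, not about squeezing
  maximal accuracy from the optimizer.
* The CLI and pipeline driver run one study on one machine; distributed
  execution and workflow engines are out of scope.
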