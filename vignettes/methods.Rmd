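---
title: "Image-derived endophenotypes for genetic association: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-derived endophenotypes for genetic association: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis in one paragraph

Atlas-based summaries of structural brain MRI (FreeSurfer volumes,
voxel-based morphometry) can discard disease-relevant information that
does not respect atlas boundaries. The alternative implemented here
learns imaging features directly from the data: a 3D convolutional
neural network is trained to classify diagnostic status (cognitively
normal, mild cognitive impairment, Alzheimer's disease) from T1-weighted
volumes, the activations of its 100-unit penultimate dense layer are
taken as automatically extracted imaging features, those features are
reduced to their top 10 principal components, and each PC score is used
as a quantitative *endophenotype* in a genome-wide association scan —
one ordinary-least-squares regression per SNP per PC, adjusting for age,
sex, education and handedness. A multi-branch variant divides the brain
into a 3 x 3 x 3 grid of overlapping patches, trains one CNN per patch,
keeps the five patches with the best validation accuracy, and fuses them
into a single feature extractor, which both localizes the informative
anatomy and concentrates model capacity there.

Because the clinical cohort that motivates this design is access
restricted, the package ships a synthetic-cohort generator with planted
ground truth, and every stage of the pipeline is exercised and verified
against it.

## The synthetic cohort generator

`simulate_cohort()` produces aligned labels, covariates, genotypes, and
volumes:

* **Genotypes.** Each SNP draws a minor-allele frequency uniformly from
  `[maf_low, maf_high]` (default 0.05–0.5) and dosages are
  Binomial(2, MAF) per subject — Hardy–Weinberg proportions, no linkage
  disequilibrium. Marginal per-SNP regression does not require LD to be
  exercised, and independent SNPs make the null distribution of the scan
  exactly known; LD is listed as a limitation below.
* **Latent atrophy score.** Subject *i* carries
  \(a_i = \sum_k \beta_k \tilde g_{ik} + \mathrm{shift}(\mathrm{label}_i)
  + \gamma^\top c_i + \varepsilon_i\), with standardized causal dosages
  \(\tilde g\), a per-class shift (default 0 / 1 / 2 for CN / MCI / AD,
  in units of the residual SD \(\sigma = 1\)), small covariate effects
  (age +0.02 per year, sex +0.1; education and handedness 0 by default),
  and Gaussian noise.
* **Volumes.** A fixed analytic phantom — concentric ellipsoids with
  three intensity tiers (0.30 / 0.65 / 1.00) emulating CSF, gray and
  white matter on an exactly-zero background — minus a Gaussian
  attenuation blob whose amplitude is `atrophy_gain * a_i` (monotone in
  the atrophy score), plus voxel noise of SD 0.04 inside the brain mask.
  An analytic phantom rather than an atlas template keeps the generator
  dependency-free and is sufficient to exercise masking, segmentation,
  patch logic and feature learning. Tissue SNR (~16–25) is in the range
  of typical T1 acquisitions; `atrophy_gain = 0.08` makes a
  3-SD-separated cohort strongly but not trivially classifiable.
* **Blob placement.** The blob is centered *inside* the signal cell of
  the overlapping 3 x 3 x 3 patch grid, with SD = window/8 and offset
  toward the side of the cell least shared with neighboring windows
  (index 0 → start + w/4, 1 → center, 2 → start + 3w/4; default cell
  (1,1,0)). With 50%-overlapping windows no in-brain voxel belongs to
  only one patch, so a cell-center blob would be equally visible to
  several branches; the compact, offset placement is what makes
  "which patch carries the signal" a meaningful question. This is a
  geometric design decision made when the generator was written, not a
  calibration against any test outcome.
* **Class priors** default to 229 : 400 : 188 (CN : MCI : AD), the
  composition of the public Alzheimer's cohort this emulates; the
  default volume grid is 48³ (paper-scale volumes are 155 x 155 x 95),
  configurable, and most shipped analyses run at 32³ so the whole
  pipeline fits a single CPU.

What the generator does **not** emulate: scanner bias fields,
registration error, LD, population stratification, missing-at-random
genotyping patterns beyond simple missingness, or anatomy. Passing tests
therefore demonstrate that the *pipeline* is correct and calibrated —
not that the CNN architecture would achieve any particular accuracy on
real MRI.

## Preprocessing surrogates

Real pipelines use dedicated tools for skull stripping and tissue
segmentation. The package provides documented surrogates with the same
contracts, and accepts externally produced masks/segmentations wherever
a surrogate would run:

* `compute_brain_mask()` thresholds (Otsu or fixed) and keeps the
  largest 6-connected component.
* `crop_to_bbox()` removes the uninformative border (margin
  configurable, outside-mask voxels zeroed).
* `segment_tissues()` fits a 3-component univariate Gaussian mixture by
  EM to in-mask intensities with deterministic quantile initialization,
  orders components by mean (CSF < GM < WM), and hard-assigns voxels.
  Non-convergence raises an error carrying the log-likelihood trace. The
  EM is written in the package so the trace and initialization are fully
  specified; tests cross-check its estimates against an independent
  mixture implementation.
* `augment_rotations()` produces the six-angle rotation augmentation
  (−20°, −10°, −5°, 5°, 10°, 20°) with trilinear interpolation and zero
  fill. The rotation plane is not dictated by the source description;
  in-plane rotation about the z axis is the default (the common choice
  for axial acquisitions) and the axis is an argument. Augmentation is
  applied to training images only.

## The CNN and its training

There is no deep-learning framework in the package's dependency set;
the network is implemented directly (R orchestration, C++ kernels for
3D convolution and max-pooling) with exact backpropagation — verified
against central-difference gradients in the test suite at tolerance
1e-5.

The architecture is configuration, not code: repeated
`[3D conv (valid, stride 1) → ReLU → 2³ max-pool → batch norm]` blocks,
flatten, an optional hidden dense stack, dropout, a 100-unit dense
feature layer with ReLU, dropout, and a softmax head. The default
configuration uses four convolution blocks (channels 8–64, kernel 3),
which gives the canonical 14-layer accounting (4 conv + 4 pool + 4 batch
norm + feature dense + classifier); smaller inputs automatically get as
many blocks as their shape supports. Exactly two dropout layers (30%)
flank the feature layer. Training minimizes cross-entropy plus an L2
weight penalty with Adam (default learning rate 1e-3 — the de-facto
standard, configurable), retains the checkpoint with the best validation
AUC (ties resolved toward the later epoch, so short plateaued runs keep
their most-trained weights), and reports a per-epoch history. A
non-finite loss aborts with a training error naming the epoch: the
cross-entropy deliberately takes `log()` without an epsilon so a
collapsed softmax is detected rather than silently clipped.

Numerical notes: batch-norm running statistics are warm-started from the
first batch and then updated with momentum 0.9 — with the short
trainings used on CPU, the textbook zeros/ones initialization leaves
inference-mode activations miscalibrated for many epochs. Features are
extracted in inference mode (dropout off, running statistics), so
`extract_features()` is a pure function of the trained model.

Evaluation follows the repeated-split protocol: stratified 80/10/10
train/validation/test partitions, 10 repeats by default
(`split_plan()`, `split_dataset()`), test AUC averaged over repeats.
For three classes the AUC definition is not standard; macro-averaged
one-vs-rest AUC is used and stated wherever it is reported. "Training
AUC" in reports means best-epoch validation AUC. Ridge logistic
regression and a linear SVM on extracted features are included as
baseline comparators only.

## Multi-branch model

`make_patch_grid()` builds 27 overlapping patches: per axis, windows of
length `round(0.5 * L)` starting at 0, `floor((L−w)/2)`, and `L−w`
(generalized to evenly spaced starts for other `parts`). The 50% window
fraction makes adjacent windows overlap by half a window and the union
cover the axis; the fraction is an argument, so other overlap readings
are one flag away. Each patch trains its own scaled CNN on identical
splits; branches are ranked by validation accuracy (ties: higher
validation AUC, then lower lexicographic patch index — a deterministic
total order), and the top five are fused: per-branch dense features are
concatenated into a joint 100-unit dense layer and a softmax head, so
the fused feature contract is identical to the whole-brain path. The
trunks can be frozen or fine-tuned during fusion training
(`fine_tune`, default on — whether the original procedure retrained
branch trunks is not stated, so both modes exist).

## Endophenotypes and association

`fit_pca()` mean-centers the feature matrix (no variance scaling by
default — the PCA convention; scaling is a flag), takes the top 10
covariance eigenvectors, and fixes signs so each loading column's
largest-magnitude entry is positive. PCA is fit on all subjects'
features: the endophenotypes feed an association analysis, not a
prediction claim, so train/test leakage is not at issue (and this is
flagged here precisely because it would be if the features were reused
for accuracy claims).

`run_gwas()` regresses one PC on `[intercept, dosage, covariates]` per
SNP, with the Wald t-test on the dosage coefficient. The implementation
residualizes the phenotype and all dosages on the covariate design once
(Frisch–Waugh–Lovell) — algebraically identical to the per-SNP full
regression, and verified against `lm()` at 1e-10 in the tests. Missing
dosages are mean-imputed per SNP by default (keeps n constant;
per-SNP complete-case is a flag); SNPs below 1% observed MAF are
excluded and recorded (no QC is inherited from anywhere, so a minimal
filter prevents degenerate regressions; set 0 to disable). P-values are
bounded below at the smallest positive double so downstream logs and
inflation statistics stay finite. Scans are reported per PC with **no
cross-PC multiple-testing correction**, mirroring the per-endophenotype
reporting convention of the source analysis; treat cross-PC minima
accordingly. The genomic inflation factor is the median implied 1-df
chi-square over 0.4549364. Conventional 5e-8 / 5e-6 thresholds are
attached to results and Manhattan tables. Summary statistics are written
in the PLINK `.assoc.linear` dialect.

`roi_associations()` regresses each PC on each ROI volume (simple
regression; for the slope test the direction is immaterial, which is why
the choice is cosmetic and merely documented). Covariate adjustment is
optional and off by default. In synthetic mode, `synthetic_roi_table()`
supplies patch-cell mean intensities as ROI analogues.

## Orchestration

`run_all()` executes simulate → train (whole-brain or multi-branch) →
feature extraction → PCA → per-PC GWAS → ROI regressions, writing every
stage's artifacts plus a manifest with the seed and a configuration
hash; stages resume from existing artifacts under the same hash and
refuse artifacts from a different configuration. The package's interface
is R functions plus `scripts/acceptance.R`; no shell subcommand wrapper
is provided because the intended users drive the analysis from R.

## Problem sizes used in shipped checks

The shipped tests and the acceptance script run, by design, at: 24³
volumes for unit tests; 32³ volumes for pipeline-level checks; null
calibration with n = 400 subjects x 2,000 SNPs x 10 PCs; patch
localization with n = 120 binary cohorts (3-SD class separation) over
repeated seeds; and causal-SNP recovery (standardized effect 0.4,
n = 400, 2,000 SNPs) through the full multi-branch pipeline. Branch
pre-training in the recovery analysis uses compact per-patch networks
(two blocks, 4 and 8 channels) trained for 8 epochs on a 180-subject
training subsample, with the unused training subjects added to the
branch-ranking validation pool (they are unseen by every branch, and a
larger pool sharpens the accuracy ranking whose per-subject noise is
otherwise comparable to the between-patch contrast); fusion then
fine-tunes on the full training set. These sizes are the package's
chosen desk-scale study conditions. Small branch networks trained
longer rank blob-bearing patches far more reliably than larger networks
trained briefly at the same cost; when selection misses every
blob-bearing patch, the downstream association power collapses, so
branch-ranking fidelity is the binding constraint of the whole
analysis.

## Known limitations

* No LD, stratification, or kinship: the association model is marginal
  OLS, as in the analysis it implements; mixed models are out of scope.
* The phantom is not anatomy; accuracy numbers on synthetic cohorts do
  not transfer to real MRI.
* The CNN engine is single-threaded and CPU-oriented; it is faithful,
  not fast, and large-volume training is outside its design envelope.
* 3-class AUC is macro one-vs-rest by choice; other definitions exist.
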