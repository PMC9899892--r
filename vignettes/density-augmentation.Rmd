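---
title: "Density-stratified synthetic augmentation: models, phantoms and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-stratified synthetic augmentation: models, phantoms and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(densaug)
library(dplyr)
```

`densaug` packages a complete study design for one question: does adding
*synthetic* high-density mammograms to detector training mitigate the
density-driven performance gap in breast mass detection? This vignette is
the package's own account of the models it implements, the choices that
were genuinely open, and what its desk-scale results do and do not show.

## The phantom generator

Clinical mammography datasets are access-restricted, so the pipeline's unit
of data is a procedurally generated phantom that emulates their statistical
structure rather than their radiographic physics. A phantom is a
height × width matrix in [0, 1]:

* **Anatomy.** A half-elliptical breast is anchored on the chest wall (left
  edge), with mild seeded jitter of its semi-axes. The MLO view adds a
  bright pectoral wedge descending from the top-left corner; the wedge is
  excluded from the breast mask used for density accounting, as clinical
  density software excludes the pectoral muscle.
* **Density control.** Fibroglandular texture is band-pass filtered seeded
  noise (difference of Gaussian smoothings at scales 1.2 and 4 px) plus a
  linear bias toward the chest wall, where dense tissue concentrates. The
  binary dense set is the top-k order statistic of that field inside the
  breast mask, with k chosen to cover exactly the requested area fraction.
  This makes density control monotone and exactly invertible: the measured
  density (fraction of mask pixels above the fixed threshold
  `dense_threshold()` = 0.55) tracks the target to within a few points, with
  residual error coming only from the style transform and mass insertion.
  Fat renders near 0.40 and dense tissue near 0.74, so the 0.55 threshold
  separates them under every built-in style.
* **Truth scale.** The phantom's truth density is an area fraction, so it
  lives on the LIBRA-style percent-density scale and its BI-RADS category
  is assigned with the LIBRA cut points (2.8 / 25 / 75). The Volpara VBD
  cut points (3.5 / 7.5 / 15.5) are implemented for mapping external
  volumetric percentages, not for phantom truth.
* **Masses.** Bright Gaussian-profile ellipses (amplitude 0.32, radii
  roughly 3–5% of image height) placed rejection-wise inside the mask
  without box overlap, each contributing a ground-truth box. Masses are
  deliberately in the same intensity range as dense tissue — the masking
  phenomenon the study targets.
* **Domain styles.** `"hologic-like"` (sharp: no blur, gamma 1.0, noise
  0.010) and `"siemens-like"` (softer: blur 0.9 px, gamma 1.12, noise
  0.020) emulate the observation that vendor appearance differences
  dominate dataset identity.
* **Scale.** The default 256 × 160 keeps the clinical 1332:800 aspect ratio
  at 1/5.2 scale; every size-dependent default scales accordingly, and
  `c(1332, 800)` is available by configuration.

What the phantoms do *not* model: X-ray physics (no ray tracing or
scatter), microcalcifications, lymph nodes, skin lines, biopsy markers, or
realistic parenchymal patterns. Consequently, passing tests demonstrate
that the *pipeline machinery* behaves correctly and that translation can
learn a density-increasing mapping on images with this covariance
structure — they say nothing about perceptual realism on clinical data.

Cohort composition uses largest-remainder apportionment so category counts
are exact and deterministic; per-record densities are uniform inside the
category's interval, with the D interval capped at 95% to avoid degenerate
fully-dense images.

```{r phantom}
rec <- generate_phantom("MLO", 80, "hologic-like", n_masses = 1,
                        size = c(128, 80), seed = 1)
measure_density(rec$image[[1]], rec$mask[[1]])
plot_phantom(rec)
```

## Density mappings and splits

The three published mapping columns (Volpara VBD, LIBRA %, ACR 1–4) print
open intervals for categories B and C, leaving the interior boundaries
formally unassigned; `densaug` assigns each interior boundary to the lower
category, keeping the printed closed outer bounds (so 3.5 → A and
15.5 → D for Volpara; 2.8 → A and 75 → D for LIBRA). This is the only
deterministic total mapping consistent with the printed anchors.

`split_cohort()` reserves a fixed seeded test quota per category, then
either excludes real BI-RADS D records from training entirely or moves a
*ceiling* fraction of the remaining D records into training — ceiling
because 25% of 161 available D records must give 41, matching the reference
experiment's arithmetic. D records left over after train/test allocation
become the validation set (their size was never specified; making
validation the D remainder keeps the partition exhaustive and disjoint by
construction).

## The translator

The translator is a cycle-consistent adversarial pair: G maps low-density
images to high-density, F the reverse, with patch discriminators D_Y and
D_X. The objective is the printed three-term form with λ = 10 weighting an
L1 cycle-consistency term against two binary cross-entropy adversarial
terms. Points that were genuinely open, and how they were decided:

* **Adversarial form.** The text specifies binary cross entropy while the
  framework it cites defaults to least-squares. Both are implemented
  (`adv_mode = "bce"` / `"lsgan"`); BCE is the default because it is the
  printed equation. The generator side uses the standard non-saturating
  variant of the BCE gradient.
* **Architecture.** The reference defers to framework recommendations.
  Here: a residual generator `y = x + 0.5·tanh(conv stack)` (3 × 3 convs,
  8 channels, near-identity at initialisation, bounded residual) and a
  three-layer strided patch discriminator ending in per-patch sigmoids.
  Sizes are deliberately small so a full training run is a CPU desk job;
  widths and depth are config-exposed.
* **No identity-mapping loss** — the objective never mentions one.
* **Numerical safety.** The adversarial logs are clamped one-sidedly at
  1e-7, so a perfect discriminator evaluates to exactly 0 while degenerate
  outputs stay finite.
* **Optimisation.** Adam (β₁ = 0.5, β₂ = 0.999), batch size 1, learning
  rate decaying linearly to zero over the second half of training. The
  full-scale default is 2e-4 over up to 200 epochs; the desk preset
  (`desk_translator_config()`) uses 400 iterations at 64 × 64 with learning
  rate 1e-3, because a 3-conv residual net trained for a few hundred
  iterations needs the larger step to leave its identity-like
  initialisation. Both are configuration, not hidden constants.
* **Healthy-only rule.** `train_translator()` errors on any record with
  lesions: a translator fit on images containing masses could learn to
  insert or delete them, which would poison detection labels.

Training records the printed loss decomposition per iteration, and
`l_total = l_gan_xy + l_gan_yx + λ·l_cyc` holds to numerical precision in
every row. Inference (`translate()`) is deterministic, clips to [0, 1],
carries lesion boxes unchanged, and marks outputs `provenance =
"synthetic"` with a `parent_id`.

At desk scale a trained translator reliably raises the measured density of
held-out fatty phantoms (the acceptance suite demonstrates a one-sided sign
test at p < 0.05 on 20 held-out images and ≥ 90% lesion contrast-sign
preservation). Desk translation saturates density more aggressively than a
full-scale model would — with 8-channel generators the path of least
resistance is brightening most of the breast — which is acceptable for the
pipeline's purposes but is one more reason not to read perceptual claims
into phantom results.

`build_model_registry()` encodes the view policy: datasets with at least
`split_threshold` (default 100) images per view get separate CC and MLO
models; smaller ones get one combined-view model. One small plus two large
datasets therefore yields the familiar five-model registry.

## Augmentation strategies

`build_augmented_manifest()` appends, for every real training record, one
synthetic copy from a view-matched model (`single`, 1:1) or one per model
family (`combined`, 1:3 with three families), copying lesion boxes and
rewriting the synthetic record's BI-RADS label to D — the copies exist to
rebalance category D. The count law |augmented| = (1 + synthetic_per_real) ×
|real| holds exactly for every strategy. Synthetic copies are fixed once
per run rather than regenerated per epoch (regeneration frequency was
unspecified; fixed-once is reproducible and cheaper). The only geometric
training augmentation is seeded random horizontal flipping with consistent
box mirroring (`x → width − x − w`).

## Detection evaluation

* **Matching.** A detection is a true positive iff its IoU with an
  unclaimed ground-truth box *strictly exceeds* 0.10 ("greater than 10%"
  is implemented strictly as printed). Matching is greedy in descending
  score order, one-to-one, with lexicographic tie-breaks so input order
  never matters. Boxes are half-open pixel rectangles, so touching boxes
  have IoU 0.
* **FROC.** The score threshold sweeps the distinct score set; sensitivity
  is lesions hit / total lesions and FPPI is false positives / images. The
  partial AUC integrates sensitivity over FPPI clipped to [0, 1] by
  trapezoid, interpolating linearly at FPPI = 1 and holding the last
  sensitivity flat if the sweep ends below 1 FPPI; it is reported as a
  percent of the unit box. Because greedy matching of higher-scored
  detections never depends on lower-scored ones, matching once and
  thresholding is equivalent to re-matching at every threshold — the test
  suite verifies this against an independent enumeration oracle at 1e-9 on
  over a hundred random instances.
* **DeLong on free-response output.** DeLong's test needs a case-level ROC,
  but FROC output is per-detection. The package's concrete construction
  (`build_case_scores()`): one positive score per ground-truth lesion (its
  matched detection's score, 0 if missed) and one negative score per
  retained false positive, keeping the top 10 per image — the 10-FPPI cap.
  This is a documented interpretive choice, not a claim about how any
  particular prior analysis formed its pairs. The variance and covariance
  come from midrank structural components, verified against a naive O(n²)
  implementation at 1e-12.
* **Built-in detector.** A difference-of-Gaussians blob detector (scales
  2.5 / 8 px at desk size) with area and border filters, scored by mean
  band-pass response × √area — masses are broad coherent bumps while
  fibroglandular islands of similar peak contrast are small. It is
  deterministic and has no trainable parameters: in `run_experiment()` the
  augmentation arms therefore exercise the full data pathway (splits,
  translation, manifest counts, provenance, evaluation) rather than
  producing genuine detection gains. It is a pluggable stand-in: any
  function image → detections can replace it. Usefully, its stratified
  sensitivity declines monotonically from BI-RADS A to D on phantom
  cohorts, reproducing the fairness gap the study design measures.
* **Five-seed convention.** Repeated runs are summarised as mean ± 1.96·sd/√n
  across repetition seeds (normal-theory 95% CI); the CI convention for the
  original five-seed experiments was unstated, so the package states its
  own.

## Fréchet-distance bounds

Image sets are embedded by a fixed-seed random convolutional projection
(16 zero-mean 5 × 5 kernels, ReLU, 2 × 2 average pooling grid → d = 64)
after resizing to 64 × 40. This extractor needs no pretrained weights and
is bit-reproducible; its absolute distances are extractor-specific, so
published Inception-feature values are intentionally *not* comparable —
only the bounding protocol's logic transfers. The Fréchet distance uses
sample means and covariances with the matrix square root taken through
symmetric eigendecompositions; covariances get an 1e-6 ridge only when
near-singular (so well-conditioned closed-form cases are exact) and
negative eigenvalue tails are clipped at zero. The protocol: lower bound =
distance between two seeded halves of the real high-density set; upper
bound = distance between real low- and high-density sets; a synthetic set
passes if its distance to the real high-density set lies between the two.

## Reader study

Responses use a 6-point confidence scale mapped to the equally spaced
synthetic-probabilities (0.95, 0.77, 0.59, 0.41, 0.23, 0.05). The scale's
printed orientation is ambiguous; the package adopts choice 1 = most
confident synthetic, and notes that flipping the orientation mirrors every
AUC about 0.5 without affecting the summary machinery. Reader AUCs are
midrank Mann–Whitney statistics; across-reader cells are summarised with
the arithmetic mean and the *population* (divide-by-n) standard deviation —
the convention verified to reproduce the published ± values from their
printed per-reader AUCs (0.615 ± 0.052 and 0.954 ± 0.007). Simulated
readers (`simulate_reader()`) provide calibration: non-informative readers
average AUC 0.5, fully informed ones approach 1.

## Problem sizes and determinism

The package's own test and demonstration sizes are: 64 × 64 translator
training with 12 + 12 images and 400 iterations; 100–200 phantom cohorts at
128 × 80 or 256 × 160; two-seed experiment repeats; 100-instance oracle
sweeps. These are the sizes at which the full pipeline is routinely
re-verified end to end on one CPU. Every stochastic step takes an explicit
seed, child seeds are derived from labelled streams so stages are
decoupled, and identical configurations reproduce results bit-for-bit;
caller RNG state is always restored.

## Known limitations

* Phantoms share none of the fine structure that makes clinical
  translation hard; FID values and reader-study simulations on phantoms do
  not transfer to clinical images.
* The built-in detector is training-free, so augmentation cannot improve
  it; experiment arms quantify pipeline behaviour, not detection gains.
* Desk-scale translators saturate density rather than adding realistic
  parenchymal texture.
* The DeLong case-score construction for free-response output is one
  defensible reading among several; it is isolated in
  `build_case_scores()` so alternatives can be swapped in.
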