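---
title: "Detecting memorized replicas in synthetic neuroimaging data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting memorized replicas in synthetic neuroimaging data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replicheck)
```

## The detection model

A generative model trained on 3D brain volumes can memorize training
samples and emit near-copies of them. `replicheck` screens a synthetic
dataset for such replicas by comparing every synthetic volume x̂ against
the full training set and asking whether x̂ is *abnormally close* to any
single training volume.

Closeness is measured at three levels, because replication can be visible
in raw intensities, in abstract image content, or only in the anatomy of a
segmented structure:

| level | measures | input |
|---|---|---|
| image | MAE, RMSE, 3D SSIM | co-registered scalar volumes |
| feature | RMSE, cosine similarity | fixed-length embeddings |
| segmentation | Dice, average surface distance (mm) | integer label masks |

All measures are mapped onto a common distance footing before decisions
are made. Similarities are min-max scaled from their *theoretical* range to
[0, 1] and subtracted from 1 (Dice `v -> 1 - v`; SSIM and cosine
`v -> 1 - (v + 1)/2`); genuine distances (MAE, RMSE, feature RMSE, ASD)
pass through unchanged. Using the theoretical rather than the empirical
batch range is deliberate: batch-dependent normalization would make a
calibrated threshold meaningless on the next batch, which is exactly the
automation use case.

For the image and feature levels the decision variable is the **distance
ratio**: the distance to the closest training image divided by the mean
distance to the `n = 50` closest (the closest included). Including the
rank-1 image in the neighbourhood is a design choice the literature leaves
ambiguous; we include it because it bounds the ratio by 1, which gives the
threshold sweep a natural [0, 1] domain and makes thresholds comparable
across measures. The inclusion is confined to one function
(`distance_ratio()`), so the alternative convention is a one-line change
for users who want it. When the training set is smaller than `n`, `n` is
capped with a warning so small pilot studies still run.

Segmentation-level decisions use the *absolute* converted distance of the
closest pair instead of the ratio: the segmentation step has already
discarded background, so the raw closeness of the structures of interest
is the meaningful quantity and dividing by a neighbourhood mean would only
add noise from unrelated anatomies.

The decision rule is strict: replica iff `value < T`. Boundary values are
non-replicas. This matters for the degenerate-but-common case of exact
copies: they sit at value 0 and are flagged by any positive threshold,
while `T = 0` flags nothing.

## Threshold calibration

With ground-truth labels (from expert visual scoring of the RMSE-closest
pair per synthetic image, scores 3–4 on the 4-point scale meaning replica),
two calibrations are computed:

* **Sweep** (`sweep_thresholds()`): balanced accuracy — the mean of
  sensitivity and specificity with replica as the positive class — over a
  regular grid. For ratio-type variables the grid is [0, 1] in 0.01 steps;
  for absolute segmentation distances, whose scale depends on the measure,
  the grid is [0, max observed] in steps of 0.01 × max, i.e. always 101
  points relative to the value scale. Ties at the optimum resolve to the
  smallest threshold: deterministic, and conservative in the sense of
  flagging fewer images at equal accuracy.
* **Margin threshold** (`margin_threshold()`): the mean of the highest
  replica value and the lowest non-replica value. This is the automation
  threshold, placed mid-margin; a `separable` flag records whether the
  margin is actually positive. When classes overlap the threshold is still
  defined but flagged non-separable.

The ground-truth reader accepts either final labels or two raters' scores.
When raters disagree, it *refuses* to apply a silent majority rule and
demands an explicit `adjudicated` column — disagreement resolution is a
judgment call that should be visible in the data, not a hidden default.

## Feature extraction

The feature level is extractor-agnostic: the pipeline only ever sees a
numeric vector per volume. Pretrained 3D medical embeddings ship as large
binary weights, so the package instead (a) accepts precomputed embeddings
from CSV (`attach_features()`), and (b) provides a deterministic built-in,
`pooled_descriptor()`: the volume is min-max scaled to [0, 1], partitioned
per pyramid level `l` into `2^l` blocks per axis (boundary blocks absorb
remainders), and each block contributes its mean and population standard
deviation. Two levels on a 32×32×16 grid give a 144-element vector. The
descriptor is crude compared to a foundation-model embedding, but it is
deterministic, weight-free, monotone in perturbation magnitude, and — like
any registered extractor — exercises the identical retrieval code path.

## Numerical choices

* **3D SSIM** uses a uniform (boxcar) window of side 7 voxels, constants
  `k1 = 0.01`, `k2 = 0.03`, data range = joint max − min of the pair, all
  overridable via `measure_spec()`. Local statistics use population
  (divide-by-N) normalization, local SSIM is evaluated only where the
  window fits entirely, and the map is averaged. These are the most common
  published conventions, made explicit because SSIM values are only
  comparable under identical conventions. Implementation is separable
  cumulative-sum box filtering; the test suite checks it against a direct
  per-window reference to 1e-9.
* **ASD** is the symmetric mean of the two directed mean surface
  distances. Surface voxels are foreground voxels with a 6-connected
  background neighbour, the volume boundary counting as background.
  Distances are Euclidean in millimetres, honouring anisotropic spacing,
  computed with a separable lower-envelope Euclidean distance transform;
  the tests check it against an all-pairs brute-force oracle.
* **Degenerate masks** are flagged, never silently numeric: a label empty
  in both masks gives Dice 1 / ASD 0 ("agreement on absence") with a flag;
  empty in exactly one mask gives Dice 0 / ASD = the image's physical
  diagonal as an explicit penalty with a flag. The multiclass aggregate is
  the macro-average over labels present in at least one mask (absent-from-
  both labels are skipped), with per-label values attached so users can
  re-aggregate; how multiclass segmentations should be pooled is genuinely
  open, and macro-averaging penalizes anatomical mismatch without letting
  one label dominate.
* **Conversion guard**: `to_distance()` clamps values within 1e-9 of the
  theoretical range (floating-point slop) and errors beyond that.
* **Determinism**: every ranking breaks distance ties lexicographically by
  id; indices sort ids in the C locale; identical inputs produce
  byte-identical output tables.

## What the phantom simulator emulates — and what it does not

`generate_phantom()` builds a smooth Gaussian-random-field background
(boxcar-smoothed, radius 2, two passes) scaled to [0, 0.5], plus 1–3
additive ellipsoidal lesions of semi-axes 2–4 voxels and intensity
0.3–0.6, each labelled in a paired mask — a caricature of a lesion-bearing
CT or an angiography volume: smooth anatomy, compact bright foreground,
co-registered grid. The default grid is 32×32×16 at 1 mm isotropic: the
pipeline is shape-agnostic, and this size keeps a full study comfortably
inside a test run. `generate_study()` plants a configurable fraction of
synthetic entries as copies of training entries — exact, or perturbed by
Gaussian noise, intensity shift, or integer-voxel translation (masks move
with their volumes; translation crops rather than wraps, mimicking
registration jitter) — and records truth and provenance. A single study
seed drives a hierarchical derivation (study → subject → perturbation), so
each subject is reproducible independently of the others.

What passing tests on phantoms *show*: the measures, ranking, ratio,
calibration and reporting machinery are correct, deterministic, and behave
monotonically under graded corruption. What they *do not* show: performance
on real scanner data, where inter-subject variation is anatomical rather
than random-field, intensity distributions are modality-specific, and
near-replicas arise from model memorization rather than parametric
perturbation. In particular the phantoms' novel images are far from the
training set, so perfect separation on planted studies is expected by
construction and says nothing about the harder regimes (e.g. vessel-anatomy
similarity) where image-level measures are known to underperform
segmentation-level ones.

## Problem sizes and study conditions

The reference study shape used in the acceptance checks mirrors a
50-image audit with 90% replicas: 40 training phantoms, 50 synthetic, 45
planted exact copies. The graded-difficulty suite uses noise magnitudes
σ ∈ {0, 0.05, 0.1, 0.2} (on an intensity scale of ~[0, 1.1]) with 10
study seeds per level on 16×16×8 grids with 12 training / 10 synthetic
volumes each — small enough to rerun routinely, large enough that mean
ratios and balanced accuracies are stable in rank.

## Known limitations

* Inputs must be pre-registered to one grid; the package verifies shape
  and spacing and refuses mismatches rather than resampling. Registration,
  skull-stripping and intensity normalization are preprocessing, out of
  scope; volumes are assumed comparably scaled.
* Image-level all-pairs comparison scales as (synthetic × training); the
  CSV distance cache (`pairwise_distances(cache = ...)`) makes reruns
  incremental, but very large audits should prefer feature-level cosine.
* Augmentation-invariant retrieval is not attempted: if the generative
  model was trained with heavy augmentation, a replica may evade
  image-level measures. The extractor interface is the intended escape
  hatch.
* The built-in descriptor is not a learned embedding; for real audits,
  attach embeddings from an established 3D medical model via CSV.
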