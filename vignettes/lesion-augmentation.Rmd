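---
title: "Reshaping long-tailed detection data: methods and design notes"
author: "lesionAug"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reshaping long-tailed detection data: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of what it computes, which
knobs matter, and where the design was genuinely open.

## The procedure

`lesionAug` treats data augmentation as distribution reconstruction. Given
a YOLO-layout detection dataset with per-class instance counts
$N = (N_1, \dots, N_k)$, the pipeline:

1. **Diagnoses** the distribution: imbalance ratio
   $IR = \max N_i / \min N_i$, log-scale dispersion (population standard
   deviation of $\log N_i$), effective-category coverage and
   effective-sample proportion at a threshold $N_0$, and center/scale
   histograms of the boxes.
2. **Harvests donors**: every annotated box is cropped, with a small
   context pad, into a class-indexed bank.
3. **Plans pastes** by the deficit-to-target rule
   $\mathrm{pastes}_i = \max(0, T_i - N_i)$, classes processed in
   descending deficit.
4. **Synthesizes images**: a background is drawn uniformly from the whole
   dataset, donors are composited at uniformly sampled positions with
   jittered scale, then the environment stage degrades visibility
   (luminance, weather, occlusion).
5. **Screens** each candidate with a teacher detector in an accept–reject
   step; only samples whose every pasted box is confidently and
   consistently re-detected (and sufficiently visible) are kept.
6. **Writes** originals plus kept samples as a new YOLO dataset and
   recomputes all diagnostics from the files on disk.

Assumptions worth stating: instances, not images, are the unit of the
count vector (a per-category "sample" is a bounding box); pasting a donor
onto any background is pathologically admissible *a priori*, with
implausible composites removed a posteriori by the teacher screen rather
than by paste-time host-compatibility rules; and the teacher is treated as
a fixed, stateless predictor during a screening run.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `targetCount` ($T$) | user-set | instances/class | the post-augmentation floor; scalar or per-class. No single scalar can reproduce both an observed floor and an observed head-class ceiling, so per-class targets are plain configuration. |
| `scaleJitter` | (0.5, 2) | × native $\sqrt{wh}$ | widens scale coverage about the donor's native size; clipped so the scaled box stays inside the unit frame. |
| `maxOverlapIoU` | 0.1 | IoU | keeps pasted boxes from colliding with existing objects; also the cap used inside the synthetic generator so teacher matching stays unambiguous. |
| `maxPastePerImage` | 3 | boxes | bounds clutter per synthesized frame. |
| luminance gain | (0.4, 1.6) | × | "severe but recoverable" exposure range; gain 1 is bit-exact identity. |
| weather intensity | per effect, in [0, 1] | – | 0 is a bit-exact no-op by contract; blur maps intensity to $\sigma = 3 \cdot$ intensity px so repeated blurs compose in quadrature. |
| `maxBoxOcclusion` | 0.5 | fraction | occluder sets that would hide more of any pasted box are redrawn; visibility is computed on the pixel raster. |
| `confMin` ($\tau$) | 0.25 | confidence | screening thresholds are deliberate configuration: no published values exist for them, so they are mandatory fields with documented defaults. |
| `iouMin` ($\theta$) | 0.5 | IoU | the conventional localization-agreement threshold in detection. |
| `n0` | 200 | instances | the effectiveness threshold used in the coverage diagnostics. |

## What the synthetic generator emulates — and what it does not

`fixtureSpec()` defaults encode the study conditions the package is
exercised under: 30 classes with instance counts decaying geometrically
from 755 down to 2 (pre-augmentation $IR = 377.5$), 256 px frames, a
center-bias mixture law $(1-b)\,\mathrm{Uniform} + b\,\mathcal N(0.5,
0.12^2)$ truncated to the feasible band with $b = 0.6$, and normalized
$\sqrt{wh}$ scales uniform on (0.06, 0.22) — a long tail, central bias,
and narrow scale coverage, the three pathologies of field-photographed
data. Lesions are parameterized ellipse blobs (per-class color,
eccentricity, speckle) on vein-textured leaf ellipses over soil noise;
classes are visually separable but not photorealistic.

Passing tests on these fixtures therefore demonstrate the *mechanics*:
exact count realization, placement and scale laws, mask/box consistency,
determinism, and the distributional guarantees of the planner and screen.
They do not demonstrate that augmented PlantDoc images look plausible to a
trained detector, nor any mAP improvement — those require real images and
GPU training, which are outside this package's scope.

Where no reference value dictated a generator setting (center-bias weight,
scale band, lesion styles, objects per frame), it was fixed once at a
value typical of field datasets and is not tuned thereafter.

## Numerical choices

- **Logarithm base** for the dispersion statistic: natural log, population
  (not sample) standard deviation. Published before/after values near
  1.20/1.19 cannot discriminate the base without the full count vector, so
  the base is an explicit argument; changing it only rescales the value.
- **Zero-count classes** are excluded (with a message) from $IR$ and the
  log statistics instead of generating infinities.
- **Histogram binning**: half-open $[l, u)$ bins with the last bin closed;
  a value exactly on an interior edge belongs to the upper bin.
- **Pixel convention**: normalized center format, origin top-left, boxes
  half-open in continuous pixel coordinates; the covered pixel extent is
  `floor(x0)+1 .. ceiling(x1)`. Label numbers are printed with 6 decimals,
  making write/read round trips deterministic to $10^{-6}$.
- **Feathered alpha**: cosine ramp over 8% of the shorter crop side (≥ 1
  px); hard overlap is known to introduce boundary artifacts, and the soft
  border suppresses them. In feathered mode the recorded box is the extent
  of $\alpha > 0.5$; in hard mode pixels outside the pasted rectangle are
  bit-identical to the background.
- **Placement** is rejection sampling, uniform over centers keeping the
  whole box in frame, with a 50-attempt budget; exhaustion is a signal
  (the paste is skipped and retried on a new background), never a crash.
- **Seeding**: a single global seed is hashed with each stage's name into
  an independent 32-bit stream, so reordering stages cannot silently
  reshuffle another stage's randomness.

## Open design points, resolved

- **Stratification of multi-object images** (the 8:1:1 split): stratum =
  majority class of the image's boxes, ties to the lowest class id;
  label-free images form a background stratum. Largest-remainder
  apportionment keeps every stratum within one image of its exact share.
- **Teacher matching**: one-to-one greedy by descending IoU between pasted
  boxes and detections. Matching is independent of the thresholds, which
  makes the kept set provably monotone (non-increasing) in both $\tau$ and
  $\theta$.
- **Rejection granularity**: the whole sample is rejected if any pasted
  box fails (the conservative reading); `onReject = "resample"` re-draws a
  rejected sample afresh up to a small budget, `"drop"` (default) simply
  discards it. With a drop policy and an imperfect teacher the realized
  floor can fall short of $T$; resample mode restores it when the teacher
  accepts replacements.
- **Crop shape**: donors are box-shaped crops with a feathered border by
  default; ground-truth soft masks are used when the dataset carries them
  (the synthetic generator always does). Mask-shaped pasting of real data
  would require segmentation, which is out of scope.
- **Weather set**: fog, rain and blur — chosen as the three cheap,
  parameterizable visibility degradations; the profile is a list and
  extensible.
- **Screening scope**: only pasted boxes are screened; pre-existing
  annotations are trusted as ground truth.

## Problem sizes

The test suite exercises the full study conditions (30 classes, 755…2,
floor 54) at 128 px frames — about 1 800 generated images and 640 pastes,
run twice to verify determinism — and smaller 5-class fixtures (counts
20…2, 64 px) for the per-module tests; the whole suite runs in under two
minutes on one CPU. `scripts/acceptance.R` runs the same study conditions
at the generator's native 256 px. These sizes are the package's chosen
trade-off between statistical resolution and a test suite that stays
pleasant to run.

## Known limitations

- Backgrounds of augmented images re-contribute their original boxes to
  the written dataset, so head-class counts grow slightly beyond their
  input values; the floor guarantee refers to pasted instances plus
  originals and is unaffected.
- The oracle teacher validates the screening *mechanism*; it cannot stand
  in for a trained detector's judgment of visual plausibility.
- Occlusion accounting is raster-based and therefore quantized to pixels;
  tests allow the corresponding one-pixel tolerances.
- No mosaic/mixup, whole-image geometric augmentation, GAN synthesis, or
  COCO/VOC label dialects — deliberately outside the mechanism implemented
  here.
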