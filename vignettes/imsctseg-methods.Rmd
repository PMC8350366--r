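---
title: "Cascaded multiclass segmentation of intramedullary spinal cord tumors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cascaded multiclass segmentation of intramedullary spinal cord tumors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Intramedullary spinal cord tumors (IMSCT) — predominantly astrocytomas,
ependymomas and hemangioblastomas — appear on MRI together with two
companion structures that matter clinically: peritumoral edema and
liquid-filled cavities (syringes). Delineating all three, plus their
union (the whole lesion), supports monitoring, surgical planning and the
distinction between infiltration and edema. The imaging signature is
heterogeneous: on T2w all tumor types are iso- to hyperintense; on
gadolinium-enhanced T1w, hemangioblastomas enhance strongly, ependymomas
moderately, and astrocytomas partially, moderately or not at all.
Cavities are strongly T2w-hyperintense and never enhance; edema is
moderately T2w-hyperintense. Scans vary widely in native resolution
(sagittal in-plane 0.34–1.33 mm, slice thickness 1.5–5.2 mm) and field
of view, and the cord occupies a tiny fraction of the volume — severe
class imbalance for a voxel classifier.

`imsctseg` implements a fully automatic two-stage cascade for this task:

1. **Localization.** A 3D U-Net segments the spinal cord region on the
   T2w scan (one full-volume patch). The predicted mask is binarized at
   0.5 and converted to a 3D bounding box with a small margin.
2. **Segmentation.** Both contrasts are cropped to the box, concatenated
   as two channels, and a second 3D U-Net predicts four sigmoid channels
   — tumor core, cavity, edema, and whole lesion — on a patch grid whose
   overlapping predictions are stitched by voxel-wise averaging.

Cropping first mitigates class imbalance and makes the pipeline robust
to arbitrary fields of view; running the segmenter without step 1 is
supported (`use_cascade = FALSE`) as a comparison arm.

## Spatial standardization

All processing happens in a standard space of (1, 1, 2) mm voxels
(superior–inferior, anterior–posterior, right–left), obtained by
resampling (linear for images, nearest for masks) and a fixed centre
crop-or-pad — 512 × 256 × 32 voxels for clinical fields of view, i.e. a
51.2 × 25.6 × 6.4 cm box consistent with adult spinal cord anatomy;
smaller axes are zero-padded instead of cropped. Intensities are
z-score normalized (population standard deviation; constant images are
rejected rather than silently emitting NaN). Every step is recorded in
a `spatial_record`, so predictions are mapped back onto the native grid
exactly (nearest interpolation for labels).

Numerical conventions, fixed once and used everywhere:

* Voxel indices are 0-based in all geometric arithmetic; boxes are
  half-open `[lo, hi)`.
* Odd crop/pad differences put the extra voxel on the high-index side.
* The resampled grid size is `round(extent / target_spacing)` with
  round-half-to-even; the centre of the first voxel is the common
  physical anchor (the ITK convention), so integer spacing ratios
  round-trip exactly under nearest interpolation.
* Binarization thresholds are inclusive (ties go to foreground).

## The network

Both stages use the same modified 3D U-Net family: an encoder–decoder
with two (3×3×3 convolution → instance normalization → leaky ReLU)
blocks per level, 2×2×2 max pooling, filter counts doubling per level,
trilinear upsampling followed by a 1×1×1 channel-projection convolution
in the decoder (the spatial mixing is done by the block's own 3×3×3
convolutions after the skip concatenation),
dropout after each encoder block, and deep supervision: 1×1×1
segmentation heads at the two coarsest decoder levels whose logits are
upsampled and summed into the final logits before the sigmoid. The
final activation is a sigmoid even for the multiclass model — channels
are *not* mutually exclusive, which is what permits a whole-lesion
channel alongside the structure channels.

Reference configurations: localizer — 1 input channel (T2w), 1 output,
depth 4, 8 base filters; segmenter — 2 input channels (Gd-T1w + T2w),
4 outputs, depth 4, 16 base filters. Dropout defaults to 0.3 and the
leaky slope to 0.01 (both exposed; neither is prescribed by the
reference design). Instance normalization is computed per channel per
sample, which keeps the batch-size-1 localizer well defined.

The engine is implemented in this package (R orchestration over C++
kernels for convolution, pooling, upsampling and fused
normalization+activation) with hand-derived backpropagation; a
finite-difference gradient test pins its correctness to ~1e-7 relative
error. Deep supervision is realized as summed upsampled logits rather
than auxiliary loss terms, following the BraTS-2017 lineage of the
architecture.

## Training

* **Loss.** Soft Dice loss `1 − (2Σpg + s)/(Σp + Σg + s)` per channel;
  the multiclass loss is the unweighted mean over all four channels
  (whole lesion included). The smoothing term defaults to `s = 1`
  (unspecified upstream; exposed as `loss_smooth`). On binarized
  predictions and `s → 0` the loss is exactly `1 −` Dice score, which
  the test suite asserts as a cross-module identity.
* **Optimizer.** Adam (default moments), initial learning rate 0.001,
  one cosine annealing cycle spanning `max_epochs` (no warm restarts).
* **Early stopping.** Patience 50 epochs with epsilon 0.001: only a
  validation-loss improvement strictly greater than 0.001 resets the
  counter. Validation loss is the multiclass Dice loss on validation
  volumes assembled by full stitched inference — the same quantity the
  deployed model produces, hence the right thing for early stopping to
  protect.
* **Patching.** The localizer trains on one 512 × 256 × 32 patch at
  batch size 1; the segmenter on 128 × 128 × 32 patches with stride
  64 × 64 × 32 at batch size 8 (gradients averaged across the batch).
  Training uses the same deterministic stride grid as inference, with
  the final origin per axis clamped to the volume border so no voxel is
  missed; uniform random patch offsets are available behind
  `random_offset`.
* **Augmentation.** One random affine per sample: rotation ±5° about
  one randomly chosen axis (composed in physical space, so anisotropic
  voxels rotate correctly), scaling ±10% and translation ±3% in the
  sagittal plane; images are linearly interpolated, labels nearest and
  re-binarized, with the identical transform applied to both contrasts
  and all channels.
* **Splits.** Subject-level 60/20/20 train/validation/test; fractions
  are floored and the remainder goes to training (so 10 subjects split
  6/2/2). Seeds 1..12 give the repeated random splittings used for
  mean ± sd aggregation. All randomness flows from one global seed
  split into named substreams (phantom, split, init, per-epoch), making
  cohorts, splits and epoch logs bit-reproducible.

## Postprocessing

Per channel, in this order: binarize at 0.5 (ties to foreground), fill
3D holes (background components, 6-connectivity, not reaching the
volume border), then delete connected components (26-connectivity)
whose physical volume is *strictly* below the threshold — 0.2 cm³ for
tumor and whole lesion, 0.5 cm³ for cavity and edema. The chain is
idempotent. The whole-lesion channel is cleaned independently and is
not reconciled with the union of the structure channels; the voxel
count on which the two disagree is attached to the result
(`whole_union_mismatch`) so the discrepancy is visible rather than
silently resolved.

## Evaluation

Per structure and subject: Dice score with the field's false-positive
convention (a non-empty prediction of an absent structure scores 0;
the empty–empty case is excluded from averaging, not counted as 0);
detection at an inclusive 6 mm³ physical overlap (for absent
structures, a false positive is a prediction of at least 6 mm³ — the
same threshold reused for symmetry); voxel precision and recall
(undefined entries excluded); relative volume difference
`(V_gt − V_pred)/V_gt`, negative meaning over-segmentation, and its
absolute value. The whole-lesion inclusion check verifies that every
ground-truth lesion voxel lies inside the half-open bounding box
recorded by step 1. Aggregation is cohort mean per split, then
mean ± population standard deviation across splits. Metrics are
computed in standard space, before inversion to native grids.

A structural consequence of the zero-on-false-positive convention,
asserted on phantoms as an inequality (not as clinical values): Dice
restricted to subjects that carry a structure is never below the cohort
Dice that includes false-positive zeros.

## The phantom cohort generator

No public IMSCT dataset exists, so the package ships a synthetic
cohort generator that emulates the study conditions and makes the whole
train → infer → postprocess → evaluate loop testable at desk scale:

* **Geometry.** A physical field of view (default 96 × 48 × 48 mm,
  desk scale) is rasterized on a per-subject native grid whose spacing
  is drawn uniformly from the sagittal in-plane range [0.34, 1.33] mm
  and slice-thickness range [1.5, 5.2] mm — the resampler is therefore
  genuinely exercised on heterogeneous native grids. A smooth
  sinusoidal centreline (amplitude 3 mm by default) carries a 13
  mm-diameter cord, a 3 mm CSF sheath, and the 30 mm-diameter
  localization tube used as the cord ground truth.
* **Pathology.** Components are ellipsoids deformed along the
  centreline and clipped to the cord (intramedullary by construction):
  an elongated tumor (log-normal volume, median 1.2 cm³ at phantom
  scale — the clinical size heterogeneity is reproduced in shape, not
  in absolute volume), an edema shell extending the tumor along the
  cord (always touching it), and a cavity displaced along the cord that
  may touch or be disjoint from the tumor; when a large lesion fills
  the cord, the cavity is carved out of it as a tumoral cyst. A subject
  has a cavity with probability 0.67 and edema with probability 0.51,
  matching the clinical cohort's class imbalance; tumor types are drawn
  101:122:120 (astrocytoma : ependymoma : hemangioblastoma).
* **Contrast.** Mean intensities per tissue follow the qualitative
  radiology: on T2w, cavity > edema > tumor ≥ cord > background (CSF
  bright, below cavity); on Gd-T1w the tumor enhancement is strong for
  hemangioblastoma, moderate for ependymoma, and Bernoulli(0.5)
  none-or-moderate for astrocytoma (reported proportions are not
  published); the cavity never enhances. Additive Gaussian noise
  (sd 2, i.e. 20% of the smallest inter-tissue gap) exercises
  normalization while keeping within-mask mean orderings intact.

What the phantoms deliberately do **not** model: vertebrae and bone,
cardiac/respiratory motion artifacts, bias fields, partial volume at
ill-defined infiltrative boundaries, multi-focal hemangioblastoma
chains (a multi-blob option exists but defaults to one tumor), and
registration error between contrasts (phantoms are generated
co-registered; registration of real data is out of scope). Passing
end-to-end tests on phantoms therefore demonstrates that the pipeline's
machinery — preprocessing, cascade, training dynamics, stitching,
postprocessing, metrics — is correct and recoverable, not that clinical
accuracy figures transfer.

## Desk-scale experiment

`desk_run_config()` scales the study design to a single CPU:
96 × 48 × 24 standard-space voxels, a depth-3 / 4-base-filter localizer
and depth-3 / 8-base-filter segmenter, 32 × 32 × 16 patches with
16 × 16 × 16 stride, and short cosine-annealed training (at most 30
epochs; patience 10). `run_phantom_experiment(n = 40)` generates the
cohort, trains both stages on the 60% train split, and evaluates the
full cascade on the held-out test subjects: whole-lesion and
per-structure Dice, restricted-cohort Dice, localization Dice against
the 30 mm tube, and the bounding-box inclusion rate. The problem sizes
were chosen so the complete experiment runs in roughly a quarter of an
hour on one core; `scripts/acceptance.R` re-runs it from scratch and
writes the resulting statistics as JSON.

## Known limitations

* The training engine is CPU-bound and double-precision; it is meant
  for desk-scale experiments and method development, not for training
  clinical-resolution models (the architecture and pipeline support
  clinical shapes; the wall-clock does not).
* The localizer mask is used as-is (binarize at 0.5, no component
  filtering) before the bounding box; `largest_component = TRUE` is
  available when stray detections are a concern.
* Phantom realism bounds what the end-to-end numbers mean (see above);
  clinical metric values from private cohorts are treated as monitored
  reference points, not as test targets.
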