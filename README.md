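# imsctseg

Fully automatic multiclass segmentation of **intramedullary spinal cord
tumors** (IMSCT) on co-registered gadolinium-enhanced T1-weighted and
T2-weighted MRI, in R.

Intramedullary tumors — astrocytomas, ependymomas, hemangioblastomas —
come with two companion structures that matter clinically: peritumoral
**edema** and liquid-filled **cavities** (syringes). `imsctseg` segments
all three plus their union (the *whole lesion*) with a two-stage
cascaded pipeline of 3D U-Nets:

1. **Localize** — a 3D U-Net finds the spinal cord on the T2w scan;
   the predicted mask becomes a 3D bounding box (with margin).
2. **Segment** — both contrasts are cropped to the box, concatenated as
   two channels, and a multiclass 3D U-Net predicts four independent
   sigmoid channels (tumor, cavity, edema, whole) on a patch grid;
   overlapping patch predictions are stitched by voxel-wise averaging.

Around the cascade the package provides the full loop:

* **NIfTI spatial preprocessing** — resampling to the standard
  1 × 1 × 2 mm grid, fixed centre crop-or-pad (512 × 256 × 32 voxels =
  51.2 × 25.6 × 6.4 cm), z-score normalization, and exact inversion of
  all of it so predictions overlay the native scans;
* **training** — soft Dice / multiclass Dice loss, Adam with cosine
  annealing (lr 0.001), early stopping (patience 50, epsilon 0.001),
  random affine augmentation (±5° rotation, ±10% sagittal scaling,
  ±3% sagittal translation), subject-level 60/20/20 splits;
* **postprocessing** — binarize at 0.5, fill 3D holes, remove
  components smaller than 0.2 cm³ (tumor, whole) / 0.5 cm³ (cavity,
  edema);
* **evaluation** — Dice with the zero-on-false-positive convention,
  detection at a 6 mm³ overlap, precision/recall, signed/absolute
  relative volume difference, bounding-box inclusion, and mean ± sd
  aggregation over repeated random splits;
* **a synthetic phantom cohort generator** — curved cord + CSF +
  tumor/edema/cavity phantoms with clinically faithful two-contrast
  intensity rules, heterogeneous native resolution (in-plane
  0.34–1.33 mm, slices 1.5–5.2 mm) and cohort class imbalance (67%
  cavity, 51% edema), so the entire pipeline trains and evaluates at
  desk scale without clinical data.

The 3D convolutional engine (forward/backward passes, instance
normalization, leaky ReLU, deep supervision, Adam) is implemented in
the package itself — R orchestration over C++ kernels — and its
gradients are pinned by a finite-difference test.

## The model in brief

Both stages share one architecture family: a 3D U-Net of depth $D$
(filters double per level, $f_\ell = f_0 2^\ell$) with two
(conv 3×3×3 → InstanceNorm → LeakyReLU) blocks per level, 2×2×2 max
pooling, trilinear upsampling + convolution in the decoder, dropout in
the encoder, and deep supervision: 1×1×1 heads at the two coarsest
decoder levels, upsampled and summed into the final logits before a
**sigmoid** (channels are not mutually exclusive — that is what allows
a whole-lesion channel). Training minimizes the multiclass Dice loss

$$\mathcal{L} = \frac{1}{C}\sum_{c=1}^{C}\left[1 -
\frac{2\sum_v p_{cv} g_{cv} + s}{\sum_v p_{cv} + \sum_v g_{cv} + s}\right],$$

the unweighted mean of the per-channel soft Dice losses (smooth term
$s = 1$ by default). Reference configurations: localizer depth 4 /
8 base filters on T2w; segmenter depth 4 / 16 base filters on
Gd-T1w + T2w, 128 × 128 × 32 patches, stride 64 × 64 × 32, batch 8.

## Worked example

Generate a small phantom cohort, train a reduced cascade, and segment a
held-out subject (desk-scale: ~15 min on one CPU for the full 40-subject
experiment; the snippet below is the compact version):

```r
library(imsctseg)

config <- desk_run_config(seed = 1)   # 96x48x24 standard space, depth-3 nets
res <- run_phantom_experiment(n = 40, config)

round(res$summary, 3)
#>             whole_dice             tumor_dice            cavity_dice 
#>                  0.738                  0.691                  0.832 
#>             edema_dice cavity_dice_restricted  edema_dice_restricted 
#>                  0.168                  0.832                  0.587 
#>      localization_dice    bbox_inclusion_rate        cavity_fraction 
#>                  0.956                  1.000                  0.725 
#>         edema_fraction 
#>                  0.350
```

Reading the numbers: the held-out **whole-lesion Dice** of 0.74 and
**localization Dice** of 0.96 (against the 30 mm cord tube) say the
cascade machinery recovers the phantoms' lesions, and every test
subject's ground-truth lesion fell inside the step-1 bounding box
(`bbox_inclusion_rate`). **Edema** is by far the hardest structure —
a thin, moderately contrasted shell in a minority of subjects — and
its cohort Dice of 0.17 is further depressed *by construction of the
metric*: a predicted structure in a subject that has none scores 0.
Restricting to subjects that actually carry the structure raises it to
0.59 (`edema_dice_restricted`), reproducing the false-positive pattern
expected under class imbalance.

Per-subject metrics are tibbles, summaries have `tidy()` methods, and
training curves and reports have `autoplot()`:

```r
tidy(res$report)                      # structure x metric, mean +/- sd
autoplot(res$fits$segmenter)          # loss curves
autoplot(res$report)                  # per-structure Dice
```

A thin command-line wrapper covers the same loop on disk
(`inst/cli/imsctseg`):

```sh
Rscript inst/cli/imsctseg generate --n 20 --outdir cohort --seed 7
Rscript inst/cli/imsctseg train    --stage localizer --cohort cohort --outdir run
Rscript inst/cli/imsctseg train    --stage segmenter --cohort cohort --outdir run
Rscript inst/cli/imsctseg segment  --cohort cohort --models run --outdir preds
Rscript inst/cli/imsctseg evaluate --cohort cohort --preds preds --outdir metrics
```

`segment` writes one native-space 4-channel NIfTI per subject plus QC
and bounding-box logs; `evaluate` writes per-subject CSV metrics and an
aggregated JSON summary. Training the segmenter with `--no-cascade`
reproduces the single-step comparison arm (no cord cropping).

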