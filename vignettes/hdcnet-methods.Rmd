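---
title: "Methods: hierarchical dilation networks for retinal vessel segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical dilation networks for retinal vessel segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdcnet)
```

## The problem and the model

Retinal vessel segmentation assigns every pixel of a color fundus photograph
to vessel (1) or background (0).  The clinically interesting vessels are often
the thinnest ones — one to three pixels wide at typical fundus resolutions —
and they are exactly what plain encoder–decoder networks tend to miss.

The model family in this package is a U-shaped fully convolutional network
with three additions aimed at thin, multi-scale, low-contrast structure:

* **Hierarchical dilation convolution (HDC) blocks.**  The feature map is
  split evenly along the channel axis; one half passes through a 3×3
  convolution with dilation 1, the other through a 3×3 convolution with
  dilation 2, so the two halves see receptive fields of different sizes with
  no extra parameters over a plain split convolution.  The halves are
  re-concatenated, refined by a spatial-attention map, and added back to the
  block input: `F + SAM(Y3) ⊙ Y3`.  Channel count and resolution never
  change, so the block drops into any position of the network.
* **Spatial attention (SAM).**  Channel-wise max and mean maps (2 channels)
  pass through a single 7×7 convolution and a sigmoid, giving a per-pixel
  weight in (0, 1).  Max pooling highlights salient structure; average
  pooling aggregates context.
* **Residual dual efficient channel attention (RDECA)** on every skip
  connection.  Global max-pool and average-pool channel descriptors are
  concatenated (2C), reduced to C by a 1×1 convolution with ReLU, mixed by a
  kernel-3 1-D convolution across neighbouring channels (no dimensionality
  reduction, in the efficient-channel-attention style), and squashed to
  channel weights `w` by a sigmoid.  The skip feature becomes `x + x ⊙ w`;
  the `*_no_rc` ablation variants drop the additive term and use `x ⊙ w`.
* **DropBlock** after every convolution of the double-conv units (except in
  the plain U-Net variant).  Contiguous `block_size × block_size` patches are
  zeroed during training with seed probability
  `γ = rate·H·W / (block_size²·(H−block_size+1)·(W−block_size+1))`,
  and survivors are rescaled by the kept fraction.  Dropping patches rather
  than pixels removes whole local features, which is what regularizes a
  convolutional map; the defaults are block size 7 and rate 0.15.

The decoder mirrors the encoder: kernel-3, stride-2 transposed convolutions
(each followed by batch normalization and ReLU) double the resolution, the
RDECA-weighted skip feature is concatenated, and a double-conv unit (plus an
HDC block in the HDC variants) follows.  A 1×1 convolution and sigmoid
produce the vessel probability map.  Training minimizes binary cross-entropy
with Adam (learning rate 0.008, batch size 2 in the reference protocol;
100/50/80 epochs for DRIVE/CHASE-DB1/STARE).

## Variants

`hdc_model()` builds seven variants mirroring the ablation lattice:
`unet` (double convs only, no DropBlock), `sd_unet` (adds DropBlock — the
backbone), `sd_unet_rdeca` and `sd_unet_rdeca_no_rc`, `sd_unet_hdc`,
`hdcnet`, and `hdcnet_no_rc`.  The `no_rc` flag removes the residual
connection of the channel-attention module only: that is the residual the
ablation experiments isolate.  The HDC block's own residual is always
present — it is what makes the block a safe drop-in (with all weights zero
the block is exactly the identity).

## Width, depth, and the parameter-count calibration

The reference description does not print the network depth or base width, so
we recovered them from the published parameter totals.  Enumerating depth,
base width, bias usage, batch-norm placement and up-sampling kernel, exactly
one configuration reproduces the published U-Net total of 2,143,905
trainable parameters: **depth 3, base 32 channels, biases on, batch
normalization after every convolution and after every transposed
convolution, and kernel-3 stride-2 transposed convolutions**.  That
up-sampling convention (rather than the kernel-2 choice of the original
U-Net) is the one used by the Keras lineage of structured-dropout vessel
networks, and it is the package default; `calibrate_config()` re-runs the
grid search.

The same enumeration shows that no configuration of the architecture as
described — for any depth, base width, bias/normalization choice, branch
arrangement or module placement we tried — reproduces the published totals
for the structured-dropout backbone (3,029,729) or the full network
(7,156,771).  The backbone differs from U-Net only by DropBlock, which has
no parameters, yet the two published totals differ by 885,824; those two
numbers therefore cannot come from a shared configuration of this family
and must reflect implementation details that were never printed.
`count_parameters()` consequently reports what the implemented architecture
actually contains (2,676,994 for the full network at the calibrated
default), and we document the discrepancy rather than distort the
architecture to chase unexplained totals.

## Data pipeline

Images are zero-padded symmetrically to the nearest size divisible by
`2^depth` (the standard targets are 592×592, 1008×1008 and 704×704 for the
three public datasets); odd remainders put the extra pixel bottom/right, and
the `(top, left)` offsets are stored so `restore_original()` crops
predictions back to native resolution exactly — evaluation always runs at
native size.  Large training images can be cut into four corner-anchored
crops (`corner_crops()`), whose union provably covers every pixel.
Training-time augmentation applies random-angle rotation (image bilinear,
mask nearest-neighbour), additive Gaussian noise (σ = 0.02, image only),
hue/contrast/brightness jitter (±0.05/±0.2/±0.2, image only), and
horizontal/vertical/diagonal flips.  The jitter and noise magnitudes are not
printed in the reference description; the defaults were chosen once so that
vessels stay visible, and all are configurable.  Masks remain strictly
binary through every operation.

## Metrics

`confusion_counts()` thresholds at 0.5 with ties assigned to background (a
deliberate, stated tie-break — it changes counts).  Scores follow the
standard definitions (SE, SP, ACC, precision, recall, F1); any 0/0 ratio is
returned as `NA` and flagged, never silently zero.  AUC is the rank-based
Mann–Whitney statistic with ties counted one half, identical to the
trapezoidal ROC area.  Test-set results pool confusion counts and pixels
globally before scoring (`pool_metrics()`): pooling is the only convention
under which a single AUC per dataset is well defined, and a per-image option
remains available through the lower-level functions.  Evaluation covers all
pixels of the restored image; an optional mask argument supports
field-of-view sensitivity analyses.

## The phantom generator

`generate_phantom()` grows vessel trees as seeded random branching walks:
heading evolves by Gaussian increments (SD = `tortuosity`), walkers branch
with probability 0.03 per step with width reduction, and width tapers from
the root (3 px by default) to the tips (1 px).  The mask is the exact
hard-stamped skeleton; the image draws the same vessels anti-aliased,
darker than a background with a radial illumination gradient (darkest in
the green channel, as in real fundus contrast), plus Gaussian noise that
never touches the mask.  The defaults (64×64, two trees, widths 1–3 px)
put the mean vessel-pixel fraction near 9% over seeds, matching the
vessel density of real fundus data, and keep the thin-vessel regime
(1–2 px) well represented.

Phantoms emulate geometry and contrast, not photometric realism: there is
no optic disc, fovea, lesion, JPEG texture, or inter-image color variation.
A network that learns phantoms has demonstrated that the architecture,
gradients and training loop work end to end — not that it segments real
retinas at published accuracy.

## Numerical choices

* Batch normalization uses ε = 1e-5 and momentum 0.1; evaluation mode uses
  running statistics, so eval-mode prediction is deterministic and
  checkpoints round-trip bit-for-bit.
* The binary cross-entropy clamps probabilities to `[1e-7, 1 − 1e-7]`; the
  analytic gradient is zero where the clamp is active (the loss is flat
  there), which makes the backward pass agree with finite differences
  everywhere.
* DropBlock masks are drawn per channel and per sample, only over centers
  whose block fits inside the map; survivors are rescaled by
  `total/kept` so the expected activation sum is preserved.
* Dilated 3×3 convolutions pad by their dilation, preserving spatial dims.
* Stride-2 transposed convolutions cover output pixels unevenly, so a
  constant input produces a period-2 pattern rather than a constant map;
  interior translation invariance holds modulo `2^depth`.
* Channel-max ties in SAM and global-max ties in RDECA route gradients to
  the first maximizing position.
* Weight initialization is He-normal; the optimizer is Adam with the
  conventional β = (0.9, 0.999), ε = 1e-8 and no schedule (none is printed
  in the reference protocol).

## Desk-scale demonstrations and problem sizes

The test suite and the acceptance script run entirely on phantoms at
64×64 with reduced widths, chosen as the smallest sizes at which every
mechanism (multi-scale dilation, attention, pooling depth) is exercised:
the learning demonstration trains an `hdcnet` with depth 2 and base 16 on
four phantoms for 30 epochs at batch size 1 and learning rate 0.008, and
must reach a training F1 of at least 0.95.  DropBlock is disabled for that
demonstration on purpose: it is a memorization-capacity check of the
optimizer and gradients, and DropBlock exists precisely to impede
memorization.  The chance-level check uses a model whose output head is
zeroed, so every pixel scores exactly 0.5 and the tie-handling of the
rank AUC places it at 0.5.

## Other design decisions

* Validation split: the reference protocol plots validation accuracy but
  prints no split; `hdc_fit(validation_fraction = 0.1)` holds out 10% of
  training images, seed-controlled and disableable (the desk-scale tests
  train on everything).
* The third public dataset has no canonical train/test split; the CLI and
  the dataset helpers default to first-half train / second-half test by
  filename with an explicit partition file that overrides it.
* The SAM equation as printed pools `Y1` and `Y2` separately, while the
  surrounding text describes a CBAM-style module; we pool the concatenated
  `Y3` channel-wise (the CBAM convention) and treat the literal reading as
  an un-printed wiring detail.
* Whether reported test metrics come from the final or best-validation
  checkpoint is not stated; both are kept in the fit object.
* Skip features are concatenated, not summed; no cropping is needed because
  padding-1 convolutions preserve dimensions.

## Known limitations

Training is single-threaded CPU R with hand-written backpropagation: it is
exact (gradient-checked to 1e-8) but not fast, and is intended for
desk-scale experiments, not full-resolution training runs on the public
datasets.  Reproducing published benchmark accuracy requires those datasets
and GPU-scale budgets, both outside this package's scope.  The phantom
generator's realism limits are described above.
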