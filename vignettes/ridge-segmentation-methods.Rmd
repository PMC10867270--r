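---
title: "Methods: farmland ridge segmentation with strip pooling and a dilated pyramid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: farmland ridge segmentation with strip pooling and a dilated pyramid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Farmland ridges — the narrow raised strips that separate crop plots — are
thin, elongated, and cover a small fraction of an aerial image. Standard
square-window pooling struggles with such structures: it either averages
the ridge away or fails to connect its distant parts. `ridgeseg` implements
a per-pixel two-class segmentation network for low-altitude RGB imagery
that addresses both failure modes with two architectural devices:

* **strip pooling** in every decoder stage, which aggregates context along
  entire rows and entire columns and uses it to gate the feature map, and
* an **atrous spatial pyramid pooling (ASPP)** bottleneck on the deepest
  encoder output, which aggregates multi-scale context through dilated
  convolutions without losing resolution.

## The network

The encoder is five convolutional blocks. Each block is two 3×3
convolutions, each followed by batch normalization and a ReLU; blocks are
separated by 2×2 max pooling, so block *i* operates at scale `1/2^(i-1)`.
The default channel schedule is 64, 128, 256, 512, 512 (`base_channels`
scales the whole schedule; the tests and the bundled experiments use 16).
The outputs of blocks 1–4 branch off as skip connections; the block-5
output feeds the pyramid.

The published description of this architecture fixes the block count, the
skip topology, and the placement of the two modules, but not the per-block
layer design. The double-convolution block used here is the standard
encoder-decoder choice; it is an explicit assumption of this
implementation, and `ModelConfig` keeps it adjustable in width.

**ASPP.** Four parallel branches over the deepest map: one 1×1 convolution
and three 3×3 convolutions with dilation rates 6, 12, 18 (the canonical
setting of the module this design originates from; configurable through
`aspp_rates`). All branches are zero-padded to preserve the spatial size —
a dilation that exceeds the padded extent simply samples zeros. The four
outputs are concatenated along channels and fused by a 1×1 projection.
Each branch and the projection carry batch normalization and a ReLU.

**Decoder.** Four stages. Each stage doubles the resolution (bilinear
interpolation by default; a learned 2×2 stride-2 transposed convolution as
an option), fuses the matching skip (channel concatenation followed by a
3×3 convolution; additive fusion as an option), and then applies strip
pooling. A final 1×1 convolution emits the two class logits at full input
resolution. Prediction is the per-pixel argmax with exact ties assigned to
the background class — a deliberate asymmetry: on a tie the model does not
hallucinate a ridge.

**Strip pooling.** For an H×W×C input: average each row to an H×1 profile
and each column to a 1×W profile; refine each profile with a length-3
one-dimensional convolution (zero-padded, channel-mixing); broadcast both
back to H×W and add them pixel-wise; apply a 1×1 convolution and a sigmoid
to obtain a gate in (0,1); multiply the gate element-wise with the input.
A pixel's gate therefore depends on its entire row and entire column,
which is exactly the long-range dependency a thin stripe needs.

## Training protocol

Plain SGD (no momentum, no weight decay, no schedule — the protocol states
none, and this implementation does not invent one; all three are exposed
in `train_config` for experimentation), learning rate 0.01, batch size 4,
cross-entropy loss

```
loss(x, class) = -x[class] + log(sum_j exp(x[j]))
```

averaged over all pixels of the batch and computed with the log-sum-exp
stabilization. The nominal protocol is 100 epochs on 512×512 tiles.
Validation accuracy and mIoU are computed after every epoch; the best
checkpoint is the one maximizing validation mIoU, which is the headline
metric of this task. Initialization is Kaiming-style, deterministic given
`model_config(seed=)`; shuffling is deterministic given
`train_config(seed=)`, so a run is exactly reproducible.

The whole network — forward and backward — is implemented in this package
(im2col+GEMM convolutions in C++, a small reverse-mode tape in R). Every
layer's gradient is tested against central finite differences, and the
full model is audited for dead branches (every parameter must receive a
nonzero gradient from a random batch).

## Metrics

Per-class confusion counts give accuracy, precision, recall, and IoU, each
reported as a percentage; mIoU averages IoU over the two classes
(background and ridge). Dataset-level scores average the per-image metrics
(pooled-pixel aggregation is available as an option). When a class is
absent from both prediction and truth in an image, its precision, recall,
and IoU are defined as 100% so that per-image averaging stays well-defined
on background-only tiles; a zero denominator with disagreement present
yields 0 rather than an error.

## The synthetic scene generator

The drone dataset behind this architecture is not public, so the package
ships a generator that emulates its statistical structure rather than its
radiometry: thin, roughly parallel yellow-brown stripes (the ridges,
label 1) over green crop texture (label 0), with per-row/column Gaussian
boundary jitter ("complex, irregular edges"), and small bright elliptical
"vacancies" inside the crop area — distractors that resemble ridge
fragments but are labeled background. Colors are fixed base RGB triples
with per-pixel Gaussian noise. Two presets fix the nuisance levels:
`easy` (straight edges, no vacancies, noise sd 8) and `hard` (jitter sd
2.5 px, vacancy density 2% of crop area, noise sd 14).

The nominal dataset protocol is 600 tiles of 512×512 split 5:1 into
training and validation (500/100). When the tile count is not divisible by
the ratio sum, remainder tiles go to the training split, so the validation
fraction is never inflated. Per-tile seeds are derived deterministically
from the master seed, making datasets reproducible tile-by-tile. Because
tiles are synthesized independently there is no cropping-overlap policy to
choose.

What passing tests on this generator do **not** show: robustness to real
radiometry (shadows, soil moisture, perspective, stitching artifacts),
to label noise, or to ridge geometries other than near-axis-aligned
stripes. The generator is a controlled stand-in, not a reproduction of
the original imagery.

## Scaled-down study conditions

The bundled experiments (test suite and `scripts/acceptance.R`) run a
reduced configuration chosen to keep a full training run in the order of
minutes on one CPU core: 64×64 tiles, two ridges of width 5–9 px in mixed
orientation, 24 tiles split 5:1, `base_channels = 16`. The protocol's
learning rate (0.01) and batch size (4) are kept. Two runs are performed:

* **Learning check** — 20 epochs on the easy preset; the reduced network
  reaches validation mIoU well above 90%, and tiled inference on a
  1024×1024 easy scene (16×16 grid of 64-px tiles) matches the ground
  truth at a similar mIoU.
* **Robustness check** — the full 100-epoch protocol on the hard preset,
  then an audit on ten held-out hard scenes of how many vacancy pixels the
  model labels ridge. The claim under test is about the *converged* model,
  so this run uses the protocol's full epoch count rather than the short
  learning-check budget: the misclassification rate falls steadily with
  training and only the converged model clears the 20% property bound.
  Color is the only cue separating a vacancy from a ridge at this scale —
  at 64 px the scaled vacancies are nearly as wide as the ridges — which
  makes this the hardest property in the suite and explains why it needs
  convergence.

## Tiled inference

Rasters larger than the input size are zero-padded right/bottom to the
next multiple of the tile size, split into a rows×cols grid of
non-overlapping blocks (row-major, 0-based), segmented block by block, and
spliced back, then cropped to the original extent. The published
demonstration raster of 10752×8704 yields a 17×21 grid (357 blocks of
512×512). No overlap or blending is applied between blocks — seams are
accepted as faithful behavior of the plain splicing scheme. The grid
convention here is rows×cols; split and stitch audit tile count, shape,
and order, so a permuted tile list is rejected rather than mis-assembled.

## Numerical choices and degenerate inputs

* All arithmetic is double precision; convolutions are exact GEMMs, so
  forward passes are bit-reproducible on a given BLAS.
* Batch-norm uses batch statistics during training (eps 1e-5, running-stat
  momentum 0.1) and running statistics at inference.
* Bilinear upsampling uses the half-pixel-center (align-corners-false)
  convention; its backward pass is the exact adjoint.
* Input sizes must be divisible by 16 (five scales); violations raise an
  error naming the rule rather than silently cropping.
* Max-pool ties take the first maximum in column-major order.
* The loss validates labels against {0, ..., K-1}; a non-finite training
  loss aborts with the epoch and batch index.

## Known limitations

Single CPU implementation — no GPU, no mixed precision, no data
augmentation; at the full 512-px, base-64 scale, training 100 epochs on
600 tiles is out of desk-scale reach (the architecture is validated at
reduced scale instead). The generator's colors are fixed rather than
learned from data. Checkpoints are R serialization files, not portable
across deep-learning frameworks.
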