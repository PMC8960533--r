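---
title: "Dense attention U-Net for aneurysm segmentation: model, design choices, and what the tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dense attention U-Net for aneurysm segmentation: model, design choices, and what the tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Intracranial aneurysms on TOF-MRA occupy a few hundred voxels in volumes
of tens of millions, and their diameters span an order of magnitude
(< 3 mm to > 7 mm). `daunet` implements a 3D U-Net variant built for this
regime: dense feature reuse in the encoder, channel-and-spatial attention
gating before every pooling step, and a multiscale fusion head that lets
coarse semantic maps and fine edge maps vote together at full resolution.

The pipeline is patch-based. Each case is z-score normalized over the
whole volume, a 64³ patch is cropped around the lesion (or around tiles,
at inference), labels are binarized (treated aneurysms, label 2, are
mapped to background for training), and random mirror flips (probability
0.5 per axis) plus a uniform intensity offset (±0.1 on the normalized
scale) augment each draw.

### Encoder

`Layerin1` is a conventional convolution block (two 3³ convolutions with
group normalization and RReLU), a dense block, and a transition layer.
`Layerin2`, `Layerin3` and `Bottom` are dense block → CBAM → transition.
A dense block is two iterations of BN → RReLU → 3³ conv whose `growth`
output channels are concatenated with the block input, so its first
channels are the input untouched — the identity path the tests assert. A
transition is BN → RReLU → 1³ conv → 2³ average pooling: it restores the
published channel plan (16/32/64/128) and halves the grid, 64³ → 4³ over
the four stages.

### Attention

The channel gate pools the map globally by average and by max, passes
both C-vectors through a shared two-layer perceptron (hidden width C/r,
ReLU between, no biases), sums, and applies a sigmoid. The spatial gate
stacks the channel-mean and channel-max maps ([average; max] order) and
reduces them with a single 7³ convolution (padding 3, no bias) before the
sigmoid. Both gates are strict sigmoid outputs, so attention can only
attenuate — `|F''| ≤ |F|` elementwise, a property the suite checks.

### Decoder and fusion head

Each decoder stage is a stride-2 transposed 3³ convolution, concatenation
with the same-resolution encoder map, and two conventional convolution
blocks that reduce the fused width (summation was rejected: the
architecture explicitly narrows after fusion). The decoder ends at 32³;
the fusion head performs the return to 64³: the three decoder maps
(64 ch @ 8³, 32 ch @ 16³, 16 ch @ 32³) are trilinearly upsampled to 64³
and projected by 1³ convolutions to 32, 16 and 16 channels respectively,
concatenated to the 64-channel fused map, gated by CBAM, and classified
by a 3³ convolution with dropout. A single common projection width
cannot produce 64 channels from three maps, so the deepest map gets the
half share — the nearest realization of a "project to a common width,
concatenate to 64" head. The published layer table is internally
inconsistent about the classifier's input (16 vs 64 channels at 64³); the
64-channel reading is the only one consistent with its own attention row,
and `describe_network()` reports it.

## Parameter calibration

The reference model reports 38.35 M trainable parameters, but its layer
table pins only the stage filter counts; the dense growth and attention
reduction are free. With growth equal to the nominal filter count the
whole model holds ~2 M parameters, so the published footprint cannot come
from those values: the capacity must live in a wider dense bottleneck.
`daunet` therefore keeps growth = filter count for Layerin1–3 and widens
only the Bottom growth, calibrated to 1096, which lands the default at
38,505,578 parameters (within 0.5% of 38.35 M). Concentrating width at
the coarsest resolution (8³) is also the cheapest placement
computationally and follows the usual practice of widening the deepest
stage. The attention reduction stays at the conventional r = 16. This is
a deliberate deviation from reading the growth column literally; the
exact widths behind the published count are unrecoverable, so the count
is treated as a calibration constraint, not a derivation.

## Numerical machinery and conventions

No deep-learning framework exists in a plain scientific R stack, so the
package authors its own: 3D convolutions run as chunked im2col + GEMM in
C++ (RcppArmadillo), transposed convolutions reuse the conv
backward-data kernel (kernel 3, stride 2, padding 1, output padding 1 —
exact doubling), and a small reverse-mode tape differentiates the whole
graph. Fixed conventions, chosen once and documented so oracle tests are
stable:

- Tensors are R arrays with dim (depth, height, width, channels, batch) —
  the column-major mirror of the usual B × C × D × H × W notation. NIfTI
  (i, j, k) axes map to (depth, height, width) in order, unpermuted.
- Crop windows are low-inclusive `[c − s/2, c + s/2)` (0-based; 1-based
  `[c − s/2, c + s/2 − 1]`), zero-filled outside the volume.
- z-scoring uses the population standard deviation (divide by n), so the
  normalized sample itself has unit SD exactly and the operation is
  idempotent.
- Trilinear upsampling uses half-voxel-centre source coordinates
  (align-corners false) clamped at the borders.
- RReLU slopes are U(1/8, 1/3) in training, the midpoint 11/48 at
  inference; BN uses ε = 1e-5, biased variance, running-stat momentum
  0.1 (training mode requires batch ≥ 2 — batch statistics cannot be
  estimated from one sample); GN uses 4 groups with ε inside the square
  root, and is batch-composition invariant.
- Max pools and the voxel argmax break ties toward the first index /
  background, deterministically.
- The cross-entropy term is the standard truth-weighted log-probability;
  the transposed orientation sometimes printed for compound losses is
  undefined for one-hot truth (log 0) and is treated as a typographical
  transposition.
- Degenerate metric denominators never raise: empty-vs-empty scores 1.0
  (flagged), empty-prediction-vs-nonempty-truth scores 0.0.
- Dice smoothing e = 1e-5; loss weights (1 − α, α) = (0.3, 0.7).

## Training recipe

Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8) at initial rate 0.001; the
reduce-on-plateau schedule multiplies the rate by 0.1 when the monitored
validation Dice fails to improve for 10 consecutive epochs ("reduced by
0.1" is read multiplicatively — the subtractive reading would go
negative). Validation Dice, not loss, is monitored, and the
best-validation parameter set is retained. Full-scale defaults are 300
epochs at batch 8 on 64³ patches; the test suite and the acceptance
script run a miniature profile — filters 4/8/16/32, 32³ or 16³ patches,
batch 2 — chosen so the whole suite runs in minutes on one CPU. In the
two-phantom overfit experiment the plateau schedule is effectively
disabled (patience 1000): with one optimization step per epoch a
patience of 10 would collapse the rate long before convergence, and the
experiment's purpose is a capacity/descent sanity check at a fixed rate.
The 70/20/23 split utility mirrors the reference cohort proportions.

## The phantom generator

`generate_phantom()` emulates exactly the features the pipeline needs:
a dark noisy background (intensity 0.1), bright tubes (0.8) drawn as
smooth reflected random walks dilated to radius 1.5–2.5 voxels, and one
brighter (0.9) near-spherical bulge attached tangent to a vessel wall,
with Gaussian noise (σ = 0.05) on top and 0.5 mm isotropic spacing.
Bulge diameters are drawn inside the requested clinical stratum (< 3,
3–7, > 7 mm); ellipsoidal distortion (±20% per axis) is renormalized to
preserve volume, so the realized equivalent-sphere diameter stays in
class. The mask covers the bulge only — vessels are background — giving
the aneurysm-only task with realistic class imbalance (foreground < 2%,
typically ~0.2%).

What the phantoms do *not* model: flow artifacts and intensity
inhomogeneity, vessel branching topology, skull/brain background
structure, anisotropic voxels, treated-aneurysm appearance. Passing the
synthetic learnability tests therefore shows that the architecture,
gradients and optimization recipe work — that the model can learn a
bright-bulge-vs-bright-tube discrimination from realistic imbalance — not
that clinical-grade Dice on hospital data is reproduced; that requires
the real cohorts and GPU-scale training, which are out of scope here.

## Known limitations

- CPU-bound: a full-width 64³ forward pass takes ~15 s on one core;
  full-scale training is possible in principle but not practical — the
  package's purpose is correctness, transparency and desk-scale
  experiments.
- Only the sequential channel-then-spatial attention order is
  implemented; parallel arrangements are not.
- The sliding-window stitcher overwrites overlapping voxels with the
  last window's labels rather than averaging logits.
- Checkpoints are RDS files, readable only from R.
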