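# daunet

A native-R implementation of a 3D **dense convolutional attention U-Net**
for voxelwise segmentation of intracranial aneurysms in time-of-flight
magnetic resonance angiography (TOF-MRA) volumes, together with the full
preprocessing, training, inference and evaluation pipeline and a synthetic
vascular-phantom generator that makes the whole loop runnable without any
clinical data.

Intracranial aneurysms are focal bulges of cerebral arteries; ruptures
cause subarachnoid haemorrhage, so early detection on screening TOF-MRA
matters clinically. Aneurysms occupy a tiny fraction of a head volume and
vary strongly in size (< 3 mm to > 7 mm), which makes voxel segmentation a
heavily class-imbalanced, multi-scale problem. The package is aimed at
methods researchers in medical image analysis who want a transparent,
fully testable reference implementation: every tensor operation (3D
convolution, transposed convolution, pooling, trilinear upsampling, batch
and group normalization) and its reverse-mode gradient is implemented in
the package itself (Rcpp/RcppArmadillo + a small autograd tape), so there
is no deep-learning framework dependency and every layer can be checked
against brute-force oracles.

## The model

The network is a U-Net with three additions:

- **Pre-activation dense blocks** in the encoder: two rounds of
  BN → RReLU → 3³ conv whose outputs are concatenated with their input
  (DenseNet-style feature reuse); a transition layer
  (BN → RReLU → 1³ conv → 2³ average pooling) restores the channel plan
  and halves the grid.
- **Convolutional block attention (CBAM)** before each pooling step: a
  channel gate `M_c = σ(MLP(AvgPool F) + MLP(MaxPool F))` with a shared
  two-layer perceptron (reduction ratio *r*), followed by a spatial gate
  `M_s = σ(f^{7×7×7}[AvgPool F; MaxPool F])`, both multiplicative.
- **A multiscale fusion head**: the three decoder maps (1/8, 1/4, 1/2
  resolution) are trilinearly upsampled to full resolution, projected by
  1³ convolutions, concatenated to a 64-channel fused map, gated by CBAM,
  and classified by a 3³ convolution (dropout in training).

The encoder filter plan is 16/32/64/128 (Layerin1–3, Bottom), the decoder
64/32/16 (Trans1–3, stride-2 transposed 3³ convolutions with skip
concatenation), input patches are 1 × 64³ and the output is 2 × 64³ class
logits. Training minimises the compound loss

```
L = 0.3 · L_dice + 0.7 · L_CE ,   L_dice = 1 − 2Σpq / (Σp + Σq + e)
```

with Adam (initial learning rate 0.001, batch 8, 300 epochs at full
scale) and a reduce-on-plateau schedule that multiplies the rate by 0.1
after 10 stagnant epochs of validation Dice. Evaluation reports Dice,
sensitivity, specificity and precision from voxel confusion counts, with
optional stratification by lesion size (< 3, 3–7, > 7 mm by
equivalent-sphere diameter) and optional exclusion of treated-aneurysm
voxels (label 2).

The shipped default configuration carries 38,505,578 trainable parameters
(38.51 M); `describe_network()` prints the per-stage table for direct
comparison with the reference layer plan.

## Worked example

Two synthetic phantoms (noisy dark background, bright vessel tubes, one
bright 3–7 mm aneurysm bulge each) are enough to watch the network learn.
A reduced-width model (filters 4/8/16/32) on 32³ patches overfits them in
a few dozen steps on one CPU:

```r
library(daunet)

cases <- lapply(1:2, function(i) {
  ph <- generate_phantom(phantom_spec(seed = i, size_class = "3-7mm"))
  list(volume = ph$volume, mask = ph$mask, center = ph$center)
})
sum(cases[[1]]$mask$data)          # 393 foreground voxels (~0.15% of 64^3)

cfg <- network_config(filters = c(4, 8, 16, 32), growth = c(4, 8, 16, 32),
                      cbam_reduction = 4, input_size = 32, dropout_rate = 0)
tc  <- train_config(epochs = 200, batch_size = 2, patch_size = 32,
                    lr_patience = 1000, augment = FALSE, max_steps = 200,
                    stop_train_dice = 0.85, dice_check_every = 5, seed = 11)
fit <- train_network(cases, config = cfg, train_cfg = tc)
fit
#> <daunet_fit> 25 epoch(s), 25 step(s)
#>   best monitored Dice 0.8572 at epoch 25

glance(evaluate_cases(fit$final_network, cases, patch_size = 32))
#> # A tibble: 2 × 6
#>   group     n  dice sensitivity specificity precision
#>   <chr> <int> <dbl>       <dbl>       <dbl>     <dbl>
#> 1 all       2 0.857       0.839       1.000     0.893
#> 2 3-7mm     2 0.857       0.839       1.000     0.893
```

Training Dice 0.857 after 25 optimization steps: the model has learned to
carve the bulge out of the vessel tree almost perfectly (specificity ≈ 1
because background dominates; sensitivity 0.84 means a few boundary
voxels of the bulge are still missed). `tidy(fit)` returns the per-epoch
log and `autoplot(fit)` plots loss and Dice trajectories.

A command-line front end with `synth | train | predict | evaluate |
describe` subcommands lives at `inst/cli/daunet.R` (after installation:
`system.file("cli", "daunet.R", package = "daunet")`).

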