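# ---------------------------------------------------------------------------
# Convolutional building blocks. The .fwd_* helpers are the single forward
# code path shared by the functional API below and by the assembled network:
# `p(name)` resolves a parameter (plain array, or autograd node during
# training) and `st(name)` resolves a batch-norm running-statistics
# environment.
# ---------------------------------------------------------------------------

.init_conv_w <- function(k, ci, co) {
  array(rnorm(k^3 * ci * co, 0, sqrt(2 / (k^3 * ci))), dim = c(k, k, k, ci, co))
}

# Transposed conv mapping ci -> co; stored conv-style for the adjoint
# convolution, dim (3,3,3,co,ci).
.init_convt_w <- function(ci, co) {
  array(rnorm(27 * ci * co, 0, sqrt(2 / (27 * ci))), dim = c(3, 3, 3, co, ci))
}

#' Create a fresh batch-normalization running-statistics store
#'
#' @param channels number of feature channels.
#' @return an environment with `running_mean` (zeros) and `running_var`
#'   (ones), updated in place by training-mode batch normalization.
#' @export
new_bn_state <- function(channels) {
  e <- new.env(parent = emptyenv())
  e$running_mean <- numeric(channels)
  e$running_var <- rep(1, channels)
  e
}

.default_cfg <- function(...) {
  modifyList(list(norm = "gn", activation = "rrelu", rrelu_lower = 1 / 8,
                  rrelu_upper = 1 / 3, bn_eps = 1e-5, bn_momentum = 0.1,
                  gn_eps = 1e-5, gn_groups = 4L, use_cam = TRUE,
                  use_sam = TRUE),
             list(...))
}

.fwd_act <- function(x, cfg, training) {
  if (cfg$activation == "relu") ag_relu(x)
  else ag_rrelu(x, cfg$rrelu_lower, cfg$rrelu_upper, training)
}

.fwd_norm <- function(x, p, st, name, type, cfg, training) {
  if (type == "bn")
    ag_bn(x, p(paste0(name, ".gamma")), p(paste0(name, ".beta")), st(name),
          training, cfg$bn_eps, cfg$bn_momentum)
  else
    ag_gn(x, p(paste0(name, ".gamma")), p(paste0(name, ".beta")),
          cfg$gn_groups, cfg$gn_eps)
}

# Conventional convolution block: two rounds of 3^3 conv (padding 1) ->
# normalization (GN by default, BN under the ablation switch) -> activation.
.fwd_conv_block <- function(x, p, st, prefix, cfg, training) {
  for (i in 1:2) {
    x <- ag_conv3(x, p(paste0(prefix, "conv", i, ".w")),
                  p(paste0(prefix, "conv", i, ".b")), k = 3L, pad = 1L)
    x <- .fwd_norm(x, p, st, paste0(prefix, "norm", i), cfg$norm, cfg, training)
    x <- .fwd_act(x, cfg, training)
  }
  x
}

# Pre-activation dense block: two iterations of BN -> activation -> 3^3
# conv producing `growth` channels, each fused with its input by channel
# concatenation, so the block's first in_channels output channels are the
# untouched input (feature reuse).
.fwd_dense <- function(x, p, st, prefix, cfg, training) {
  for (i in 1:2) {
    h <- .fwd_norm(x, p, st, paste0(prefix, "norm", i), "bn", cfg, training)
    h <- .fwd_act(h, cfg, training)
    h <- ag_conv3(h, p(paste0(prefix, "conv", i, ".w")),
                  p(paste0(prefix, "conv", i, ".b")), k = 3L, pad = 1L)
    x <- ag_concat(list(x, h))
  }
  x
}

# Transition layer: BN -> activation -> 1^3 conv (channel restore) -> 2^3
# average pooling, halving every spatial dimension.
.fwd_transition <- function(x, p, st, prefix, cfg, training) {
  dims <- dim(ag_value(x))
  if (any(dims[1:3] %% 2L != 0L))
    stop("transition layer requires even spatial dimensions, got ",
         paste(dims[1:3], collapse = " x "))
  x <- .fwd_norm(x, p, st, paste0(prefix, "norm"), "bn", cfg, training)
  x <- .fwd_act(x, cfg, training)
  x <- ag_conv3(x, p(paste0(prefix, "conv.w")), p(paste0(prefix, "conv.b")),
                k = 1L, pad = 0L)
  ag_avgpool2(x)
}

# --- functional (plain array) API ------------------------------------------

#' Randomized leaky rectifier
#'
#' Identity for non-negative inputs. Negative inputs are scaled by a slope
#' `a`: drawn per element from U(lower, upper) in training mode (using the
#' ambient RNG stream), or fixed at the midpoint `(lower + upper) / 2` in
#' inference mode, which makes inference deterministic.
#'
#' @param x numeric array.
#' @param lower,upper slope bounds, `0 <= lower < upper < 1`. Defaults 1/8
#'   and 1/3.
#' @param training draw random slopes (TRUE) or use the midpoint (FALSE).
#' @return array of the same shape.
#' @export
rrelu <- function(x, lower = 1 / 8, upper = 1 / 3, training = FALSE) {
  if (!(lower >= 0 && lower < upper && upper < 1))
    stop("slope bounds must satisfy 0 <= lower < upper < 1")
  ag_rrelu(x, lower, upper, training)
}

#' Batch normalization over batch and space, per channel
#'
#' Standardizes each channel over the (batch, depth, height, width) values
#' then applies the learnable affine `gamma * xhat + beta`. In training
#' mode the batch statistics are used and the running estimates in `state`
#' are updated (exponential rate `momentum`); in inference mode the running
#' estimates are used. A training batch of 1 is an error: batch statistics
#' cannot be estimated from a single sample.
#'
#' @param x rank-5 array, dim (D, H, W, C, B).
#' @param gamma,beta per-channel scale and shift (default 1 and 0).
#' @param state a [new_bn_state()] environment; created fresh when omitted.
#' @param training logical.
#' @param eps variance floor constant. @param momentum running-stat update rate.
#' @return normalized array of the same shape.
#' @export
batch_normalize <- function(x, gamma = NULL, beta = NULL, state = NULL,
                            training = TRUE, eps = 1e-5, momentum = 0.1) {
  C <- dim(x)[4]
  if (is.null(gamma)) gamma <- rep(1, C)
  if (is.null(beta)) beta <- numeric(C)
  if (is.null(state)) state <- new_bn_state(C)
  ag_bn(x, gamma, beta, state, training, eps, momentum)
}

#' Group normalization over channel groups, per sample
#'
#' Channels are split into `groups` contiguous groups; each (sample, group)
#' slab is standardized over its channels and all voxels, with `eps` added
#' inside the square root, then the per-channel affine is applied. The
#' result is independent of batch composition, which is what makes it
#' usable at the small batch sizes volumetric segmentation forces.
#'
#' @inheritParams batch_normalize
#' @param groups number of channel groups (default 4); the channel count
#'   must be divisible by it.
#' @return normalized array of the same shape.
#' @export
group_normalize <- function(x, gamma = NULL, beta = NULL, groups = 4L,
                            eps = 1e-5) {
  C <- dim(x)[4]
  if (is.null(gamma)) gamma <- rep(1, C)
  if (is.null(beta)) beta <- numeric(C)
  ag_gn(x, gamma, beta, groups, eps)
}

#' Parameters for a pre-activation dense block
#'
#' @param in_channels input channel count.
#' @param growth channels added by each of the two internal 3^3
#'   convolutions; the block outputs `in_channels + 2 * growth` channels.
#' @param seed optional RNG seed for the weight draw.
#' @return a named list of arrays plus batch-norm states, usable with
#'   [dense_block()].
#' @export
dense_block_params <- function(in_channels, growth, seed = NULL) {
  if (growth < 1) stop("growth must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  c1 <- in_channels
  c2 <- in_channels + growth
  list(`norm1.gamma` = rep(1, c1), `norm1.beta` = numeric(c1),
       `conv1.w` = .init_conv_w(3L, c1, growth), `conv1.b` = numeric(growth),
       `norm2.gamma` = rep(1, c2), `norm2.beta` = numeric(c2),
       `conv2.w` = .init_conv_w(3L, c2, growth), `conv2.b` = numeric(growth),
       states = list(norm1 = new_bn_state(c1), norm2 = new_bn_state(c2)),
       in_channels = in_channels, growth = growth)
}

.pget <- function(params) function(n) {
  v <- params[[n]]
  if (is.null(v)) stop("missing parameter: ", n)
  v
}
.stget <- function(params) function(n) params$states[[n]]

#' Apply a pre-activation dense block
#'
#' Two iterations of BN -> activation -> 3^3 convolution (padding 1,
#' `growth` output channels), each fused with its input by channel
#' concatenation. The first `in_channels` output channels are the input,
#' untouched.
#'
#' @param x rank-5 array (D, H, W, C, B).
#' @param params from [dense_block_params()].
#' @param training logical; training-mode BN and random rectifier slopes.
#' @param activation `"rrelu"` or `"relu"`.
#' @return array with `in_channels + 2 * growth` channels.
#' @export
dense_block <- function(x, params, training = FALSE, activation = "rrelu") {
  cfg <- .default_cfg(activation = activation)
  .fwd_dense(x, .pget(params), .stget(params), "", cfg, training)
}

#' Parameters for a transition layer
#'
#' @param in_channels,out_channels channel counts before/after the 1^3
#'   convolution (`out_channels` is the stage's nominal filter count).
#' @param seed optional RNG seed.
#' @export
transition_params <- function(in_channels, out_channels, seed = NULL) {
  if (out_channels < 1) stop("out_channels must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  list(`norm.gamma` = rep(1, in_channels), `norm.beta` = numeric(in_channels),
       `conv.w` = .init_conv_w(1L, in_channels, out_channels),
       `conv.b` = numeric(out_channels),
       states = list(norm = new_bn_state(in_channels)),
       in_channels = in_channels, out_channels = out_channels)
}

#' Apply a transition layer
#'
#' BN -> activation -> 1^3 convolution to `out_channels` -> 2^3 average
#' pooling with stride 2: restores the stage's channel plan and exactly
#' halves every spatial dimension (even spatial input required).
#'
#' @inheritParams dense_block
#' @param params from [transition_params()].
#' @export
transition <- function(x, params, training = FALSE, activation = "rrelu") {
  cfg <- .default_cfg(activation = activation)
  .fwd_transition(x, .pget(params), .stget(params), "", cfg, training)
}

#' Parameters for a conventional convolution block
#'
#' @param in_channels,out_channels channel counts.
#' @param norm `"gn"` (default) or `"bn"` for the ablation variant.
#' @param seed optional RNG seed.
#' @export
conv_block_params <- function(in_channels, out_channels, norm = "gn",
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- list(`conv1.w` = .init_conv_w(3L, in_channels, out_channels),
            `conv1.b` = numeric(out_channels),
            `norm1.gamma` = rep(1, out_channels),
            `norm1.beta` = numeric(out_channels),
            `conv2.w` = .init_conv_w(3L, out_channels, out_channels),
            `conv2.b` = numeric(out_channels),
            `norm2.gamma` = rep(1, out_channels),
            `norm2.beta` = numeric(out_channels),
            norm = norm, out_channels = out_channels)
  if (norm == "bn")
    p$states <- list(norm1 = new_bn_state(out_channels),
                     norm2 = new_bn_state(out_channels))
  p
}

#' Apply a conventional convolution block
#'
#' Two rounds of 3^3 convolution (padding 1, stride 1) -> group
#' normalization (4 groups; or BN under the ablation switch) -> activation.
#' Spatial dimensions are unchanged.
#'
#' @inheritParams dense_block
#' @param params from [conv_block_params()].
#' @export
conv_block_gn <- function(x, params, training = FALSE, activation = "rrelu") {
  cfg <- .default_cfg(activation = activation,
                      norm = if (is.null(params$norm)) "gn" else params$norm)
  .fwd_conv_block(x, .pget(params), .stget(params), "", cfg, training)
}
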