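# ---------------------------------------------------------------------------
# Convolutional block attention: a channel-attention gate followed by a
# spatial-attention gate, both multiplicative on the feature map.
# ---------------------------------------------------------------------------

# Channel attention: global average- and max-pooled descriptors (C x 1^3)
# pass through a shared two-layer perceptron (hidden width C / r, ReLU
# after the first layer, implemented as bias-free 1^3 convolutions); the
# two outputs are summed and squashed by a sigmoid into per-channel weights.
.fwd_cam <- function(x, p, prefix) {
  w0 <- p(paste0(prefix, "w0"))
  w1 <- p(paste0(prefix, "w1"))
  Cr <- dim(ag_value(w0))[5]
  mlp <- function(v) {
    h <- ag_conv3(v, w0, numeric(Cr), k = 1L, pad = 0L)
    h <- ag_relu(h)
    ag_conv3(h, w1, numeric(dim(ag_value(w1))[5]), k = 1L, pad = 0L)
  }
  gate <- ag_sigmoid(ag_add(mlp(ag_gap(x)), mlp(ag_gmp(x))))
  list(gate = gate, out = ag_mul_gate(x, gate))
}

# Spatial attention: channel-wise mean and max maps (1 x D x H x W each)
# are concatenated in [average; max] order and reduced to one channel by a
# 7^3 convolution (padding 3, no bias); a sigmoid gives the spatial gate.
.fwd_sam <- function(x, p, prefix) {
  s <- ag_concat(list(ag_cmean(x), ag_cmax(x)))
  s <- ag_conv3(s, p(paste0(prefix, "sam.w")), numeric(1L), k = 7L, pad = 3L)
  gate <- ag_sigmoid(s)
  list(gate = gate, out = ag_mul_gate(x, gate))
}

.fwd_cbam <- function(x, p, prefix, cfg) {
  if (cfg$use_cam) x <- .fwd_cam(x, p, prefix)$out
  if (cfg$use_sam) x <- .fwd_sam(x, p, prefix)$out
  x
}

.init_cbam <- function(channels, reduction) {
  if (channels %% reduction != 0L)
    stop("attention channel count (", channels,
         ") is not divisible by the reduction ratio (", reduction, ")")
  hidden <- channels %/% reduction
  list(w0 = array(rnorm(channels * hidden, 0, sqrt(2 / channels)),
                  dim = c(1, 1, 1, channels, hidden)),
       w1 = array(rnorm(hidden * channels, 0, sqrt(2 / hidden)),
                  dim = c(1, 1, 1, hidden, channels)),
       sam.w = .init_conv_w(7L, 2L, 1L))
}

#' Parameters for a convolutional block attention module
#'
#' The channel gate uses a shared two-layer perceptron with hidden width
#' `channels / reduction` (no biases); the spatial gate uses a single
#' 7^3 convolution over the stacked channel-mean and channel-max maps.
#'
#' @param channels feature channel count C; must be divisible by
#'   `reduction`.
#' @param reduction channel reduction ratio r (default 16).
#' @param seed optional RNG seed for the weight draws.
#' @return named list with `w0` (1,1,1,C,C/r), `w1` (1,1,1,C/r,C) and
#'   `sam.w` (7,7,7,2,1).
#' @export
cbam_params <- function(channels, reduction = 16L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  c(.init_cbam(channels, reduction),
    list(channels = channels, reduction = reduction))
}

#' Channel attention gate
#'
#' Global average pooling and global max pooling reduce the feature map
#' from C x D x H x W to two C x 1 x 1 x 1 descriptors; both pass through
#' the shared perceptron (`w0` then ReLU then `w1`), are summed, and a
#' sigmoid yields the per-channel weights `M_c` in (0, 1). The output is
#' `M_c` broadcast-multiplied over space.
#'
#' @param x rank-5 array (D, H, W, C, B).
#' @param params from [cbam_params()].
#' @return list with `weights` (dim 1,1,1,C,B) and `output` (same shape as
#'   `x`).
#' @export
channel_attention <- function(x, params) {
  r <- .fwd_cam(x, .pget(params), "")
  list(weights = r$gate, output = r$out)
}

#' Spatial attention gate
#'
#' Channel-wise mean and max collapse the map from C x D x H x W to two
#' 1 x D x H x W maps, concatenated [average; max] and reduced to one
#' channel by a 7^3 convolution (padding 3); a sigmoid yields the spatial
#' map `M_s` in (0, 1), broadcast-multiplied over channels.
#'
#' @inheritParams channel_attention
#' @return list with `map` (dim D,H,W,1,B) and `output`.
#' @export
spatial_attention <- function(x, params) {
  r <- .fwd_sam(x, .pget(params), "")
  list(map = r$gate, output = r$out)
}

#' Convolutional block attention (channel then spatial)
#'
#' Exactly [channel_attention()] followed by [spatial_attention()];
#' preserves the input shape. Because both gates are strict sigmoid
#' outputs, the module can only attenuate magnitudes.
#'
#' @inheritParams channel_attention
#' @return array of the same shape as `x`.
#' @export
cbam <- function(x, params) {
  spatial_attention(channel_attention(x, params)$output, params)$output
}
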