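# Independent loop-based oracles and small fixtures. Everything here is
# deliberately written as naive per-element arithmetic, sharing no code
# with the package's vectorized/compiled implementations.

# Direct triple-loop 3D convolution (zero padding, unit stride).
oracle_conv3 <- function(x, w, b = NULL, pad = (dim(w)[1] - 1) %/% 2) {
  k <- dim(w)[1]
  ci <- dim(w)[4]; co <- dim(w)[5]
  d <- dim(x)
  if (is.null(b)) b <- numeric(co)
  out <- array(0, dim = c(d[1:3], co, d[5]))
  for (bb in seq_len(d[5])) for (oc in seq_len(co))
    for (od in seq_len(d[1])) for (oh in seq_len(d[2])) for (ow in seq_len(d[3])) {
      s <- b[oc]
      for (ic in seq_len(ci)) for (kd in seq_len(k)) for (kh in seq_len(k))
        for (kw in seq_len(k)) {
          id <- od + kd - 1 - pad; ih <- oh + kh - 1 - pad; iw <- ow + kw - 1 - pad
          if (id >= 1 && id <= d[1] && ih >= 1 && ih <= d[2] &&
              iw >= 1 && iw <= d[3])
            s <- s + x[id, ih, iw, ic, bb] * w[kd, kh, kw, ic, oc]
        }
      out[od, oh, ow, oc, bb] <- s
    }
  out
}

# Per-element channel-attention evaluation: pooled descriptors through the
# shared perceptron, summed, sigmoid.
oracle_channel_attention <- function(x, w0, w1) {
  d <- dim(x)
  C <- d[4]; B <- d[5]
  hid <- dim(w0)[5]
  W0 <- matrix(w0, C, hid)  # (1,1,1,C,hid) flattened: input channel rows
  W1 <- matrix(w1, hid, C)
  gate <- array(0, dim = c(1, 1, 1, C, B))
  for (bb in seq_len(B)) {
    avg <- numeric(C); mx <- numeric(C)
    for (cc in seq_len(C)) {
      v <- x[, , , cc, bb]
      avg[cc] <- mean(v); mx[cc] <- max(v)
    }
    mlp <- function(v) {
      h <- pmax(as.vector(v %*% W0), 0)
      as.vector(h %*% W1)
    }
    gate[1, 1, 1, , bb] <- 1 / (1 + exp(-(mlp(avg) + mlp(mx))))
  }
  gate
}

# Per-element spatial-attention evaluation: [mean; max] channel maps, 7^3
# convolution (padding 3), sigmoid.
oracle_spatial_attention <- function(x, w_sam) {
  d <- dim(x)
  B <- d[5]
  s <- array(0, dim = c(d[1:3], 2L, B))
  for (bb in seq_len(B)) for (id in seq_len(d[1])) for (ih in seq_len(d[2]))
    for (iw in seq_len(d[3])) {
      v <- x[id, ih, iw, , bb]
      s[id, ih, iw, 1, bb] <- mean(v)
      s[id, ih, iw, 2, bb] <- max(v)
    }
  conv <- oracle_conv3(s, w_sam, pad = 3)
  1 / (1 + exp(-conv))
}

# Loop-based batch normalization (training mode, biased variance).
oracle_batchnorm <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  out <- array(0, dim = d)
  for (cc in seq_len(d[4])) {
    v <- x[, , , cc, , drop = FALSE]
    mu <- mean(v)
    va <- mean((v - mu)^2)
    out[, , , cc, ] <- gamma[cc] * (x[, , , cc, ] - mu) / sqrt(va + eps) +
      beta[cc]
  }
  out
}

# Loop-based group normalization (eps inside the square root).
oracle_groupnorm <- function(x, gamma, beta, groups = 4L, eps = 1e-5) {
  d <- dim(x)
  cg <- d[4] %/% groups
  out <- array(0, dim = d)
  for (bb in seq_len(d[5])) for (g in seq_len(groups)) {
    ch <- ((g - 1) * cg + 1):(g * cg)
    v <- x[, , , ch, bb, drop = FALSE]
    mu <- mean(v)
    sig <- sqrt(mean((v - mu)^2) + eps)
    for (cc in ch)
      out[, , , cc, bb] <- gamma[cc] * (x[, , , cc, bb] - mu) / sig + beta[cc]
  }
  out
}

# Trilinear interpolation at half-voxel-centre coordinates, per element.
oracle_upsample <- function(x, out_sp) {
  d <- dim(x)
  out <- array(0, dim = c(out_sp, d[4], d[5]))
  axis <- function(i, n_in, n_out) {
    src <- (i - 0.5) * n_in / n_out - 0.5   # 0-based source coordinate
    src <- min(max(src, 0), n_in - 1)
    lo <- floor(src)
    list(lo = lo + 1, hi = min(lo + 1, n_in - 1) + 1, t = src - lo)
  }
  for (bb in seq_len(d[5])) for (cc in seq_len(d[4]))
    for (od in seq_len(out_sp[1])) for (oh in seq_len(out_sp[2]))
      for (ow in seq_len(out_sp[3])) {
        ad <- axis(od, d[1], out_sp[1])
        ah <- axis(oh, d[2], out_sp[2])
        aw <- axis(ow, d[3], out_sp[3])
        acc <- 0
        for (sd_ in 0:1) for (sh_ in 0:1) for (sw_ in 0:1) {
          wd <- if (sd_ == 0) 1 - ad$t else ad$t
          wh <- if (sh_ == 0) 1 - ah$t else ah$t
          ww <- if (sw_ == 0) 1 - aw$t else aw$t
          id <- if (sd_ == 0) ad$lo else ad$hi
          ih <- if (sh_ == 0) ah$lo else ah$hi
          iw <- if (sw_ == 0) aw$lo else aw$hi
          acc <- acc + wd * wh * ww * x[id, ih, iw, cc, bb]
        }
        out[od, oh, ow, cc, bb] <- acc
      }
  out
}

# Reduced-width configurations used throughout the suite.
mini_config <- function(input_size = 16L, ...) {
  network_config(filters = c(4L, 8L, 16L, 32L), growth = c(4L, 8L, 16L, 32L),
                 cbam_reduction = 4L, input_size = input_size, ...)
}

rand5 <- function(dims, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(rnorm(prod(dims)), dim = dims)
}
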