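#' @useDynLib daunet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif
#' @importFrom utils modifyList
NULL

# ---------------------------------------------------------------------------
# Reverse-mode automatic differentiation over rank-5 arrays.
#
# Tensors are plain R arrays with dim c(D, H, W, C, B): spatial axes first
# (depth, height, width), then channels, then batch. This is the column-major
# mirror of the usual B x C x D x H x W tensor notation.
#
# Every operator below is dual-mode: called on plain arrays it computes
# eagerly and returns an array; called with at least one `ag_node` input it
# returns a node recording the local backward closure, so that
# `ag_backward()` can accumulate gradients through the whole graph.
# ---------------------------------------------------------------------------

.ag_env <- new.env(parent = emptyenv())
.ag_env$counter <- 0L

ag_leaf <- function(value, name = NULL) {
  e <- new.env(parent = emptyenv())
  .ag_env$counter <- .ag_env$counter + 1L
  e$id <- .ag_env$counter
  e$value <- value
  e$grad <- NULL
  e$parents <- list()
  e$bfun <- NULL
  e$name <- name
  class(e) <- "ag_node"
  e
}

is_node <- function(x) inherits(x, "ag_node")

ag_value <- function(x) if (is_node(x)) x$value else x

# Build a node (or fall through to the eager value when no input tracks
# gradients). `inputs` and `gradfns` are parallel lists; only gradfns of
# node inputs are ever invoked.
ag_make <- function(value, inputs, gradfns) {
  idx <- which(vapply(inputs, is_node, logical(1)))
  if (length(idx) == 0L) return(value)
  e <- ag_leaf(value)
  e$parents <- inputs[idx]
  fns <- gradfns[idx]
  e$bfun <- function(dy) lapply(fns, function(f) f(dy))
  e
}

# Accumulate gradients of `root` (a scalar-valued node) into every node of
# its graph. Reverse topological order via iterative depth-first search.
ag_backward <- function(root, seed_grad = 1) {
  order <- vector("list", 64L)
  n_ord <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nd <- top$node
    key <- as.character(nd$id)
    if (top$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = nd, stage = 2L)
      for (p in nd$parents)
        if (is.null(seen[[as.character(p$id)]]))
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
    } else {
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_ord]] <- nd
    }
  }
  root$grad <- seed_grad
  for (i in seq(n_ord, 1L)) {
    nd <- order[[i]]
    if (is.null(nd$bfun) || is.null(nd$grad)) next
    gs <- nd$bfun(nd$grad)
    for (j in seq_along(nd$parents)) {
      p <- nd$parents[[j]]
      g <- gs[[j]]
      if (is.null(g)) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    nd$bfun <- NULL # release closures (and the activations they capture)
  }
  invisible(root)
}

# --- shape helpers ---------------------------------------------------------

# Reduce an array laid out (nv, C, B) by summation over spatial voxels,
# giving a C x B matrix.
.sum_spatial_cb <- function(a, nv, C, B) {
  matrix(.colSums(a, nv, C * B), C, B)
}

# Sum a full tensor over channels, giving dim (D,H,W,1,B).
.sum_channels <- function(a, dims) {
  nv <- prod(dims[1:3]); C <- dims[4]; B <- dims[5]
  m <- matrix(a, nv, C * B)
  out <- matrix(0, nv, B)
  for (b in seq_len(B))
    out[, b] <- .rowSums(m[, ((b - 1L) * C + 1L):(b * C), drop = FALSE], nv, C)
  array(out, dim = c(dims[1:3], 1L, B))
}

# Expand a channel gate (1,1,1,C,B) or spatial gate (D,H,W,1,B) to `dims`.
.expand_gate <- function(g, dims) {
  gd <- dim(g)
  nv <- prod(dims[1:3]); C <- dims[4]; B <- dims[5]
  if (all(gd[1:3] == 1L)) {
    array(rep(as.vector(g), each = nv), dim = dims)
  } else {
    m <- matrix(g, nv, B)
    array(m[, rep(seq_len(B), each = C)], dim = dims)
  }
}

# --- convolution -----------------------------------------------------------

# 3D convolution, kernel k x k x k, zero padding `pad`, unit stride.
# w has dim c(k,k,k,Cin,Cout); b is a length-Cout vector (pass a plain zero
# vector for bias-free layers).
ag_conv3 <- function(x, w, b, k, pad = (k - 1L) %/% 2L, stride = 1L) {
  xv <- ag_value(x); wv <- ag_value(w); bv <- ag_value(b)
  dims <- dim(xv)
  Co <- dim(wv)[5]
  ds <- (dims[1:3] + 2L * pad - k) %/% stride + 1L
  yv <- cpp_conv3_fwd(xv, as.integer(dims), wv, bv, Co, k, pad, stride)
  dim(yv) <- c(ds, Co, dims[5])
  fb <- NULL
  get_fb <- function(dy) {
    if (is.null(fb))
      fb <<- cpp_conv3_bwd_filter(xv, dy, as.integer(dims), Co, k, pad, stride)
    fb
  }
  ag_make(yv, list(x, w, b), list(
    function(dy) {
      dx <- cpp_conv3_bwd_data(dy, as.integer(dims), wv, Co, k, pad, stride)
      dim(dx) <- dims
      dx
    },
    function(dy) { dw <- get_fb(dy)$dw; dim(dw) <- dim(wv); dw },
    function(dy) get_fb(dy)$db))
}

# Transposed 3D convolution, kernel 3, stride 2, padding 1, output padding 1:
# doubles every spatial dimension. The weight is stored conv-style for the
# adjoint convolution: dim c(3,3,3,Cout,Cin).
ag_convt3 <- function(x, w, b) {
  xv <- ag_value(x); wv <- ag_value(w); bv <- ag_value(b)
  dims <- dim(xv)
  Ci <- dims[4]; B <- dims[5]
  Co <- dim(wv)[4]
  if (dim(wv)[5] != Ci)
    stop("transposed-conv weight maps ", dim(wv)[5], " input channels but ",
         "the input has ", Ci)
  out_dims <- c(2L * dims[1:3], Co, B)
  yv <- cpp_conv3_bwd_data(xv, as.integer(out_dims), wv, Ci, 3L, 1L, 2L)
  nv <- prod(out_dims[1:3])
  yv <- yv + rep(rep(bv, each = nv), times = B)
  dim(yv) <- out_dims
  fb <- NULL
  get_fb <- function(dy) {
    if (is.null(fb))
      fb <<- cpp_conv3_bwd_filter(dy, xv, as.integer(out_dims), Ci, 3L, 1L, 2L)
    fb
  }
  ag_make(yv, list(x, w, b), list(
    function(dy) {
      dx <- cpp_conv3_fwd(dy, as.integer(out_dims), wv, numeric(Ci), Ci,
                          3L, 1L, 2L)
      dim(dx) <- dims
      dx
    },
    function(dy) { dw <- get_fb(dy)$dw; dim(dw) <- dim(wv); dw },
    function(dy) {
      m <- matrix(dy, nv, Co * B)
      .rowSums(matrix(.colSums(m, nv, Co * B), Co, B), Co, B)
    }))
}

# --- pooling and resampling ------------------------------------------------

ag_avgpool2 <- function(x) {
  xv <- ag_value(x)
  dims <- dim(xv)
  stopifnot(all(dims[1:3] %% 2L == 0L))
  yv <- cpp_avgpool2_fwd(xv, as.integer(dims))
  dim(yv) <- c(dims[1:3] %/% 2L, dims[4:5])
  ag_make(yv, list(x), list(function(dy) {
    dx <- cpp_avgpool2_bwd(dy, as.integer(dims))
    dim(dx) <- dims
    dx
  }))
}

# Trilinear upsampling to spatial size `out_sp` (length-3 integer), using
# half-voxel-centre (align_corners = FALSE) source coordinates.
ag_upsample <- function(x, out_sp) {
  xv <- ag_value(x)
  dims <- dim(xv)
  out_sp <- as.integer(out_sp)
  yv <- cpp_upsample3_fwd(xv, as.integer(dims), out_sp[1], out_sp[2], out_sp[3])
  dim(yv) <- c(out_sp, dims[4:5])
  ag_make(yv, list(x), list(function(dy) {
    dx <- cpp_upsample3_bwd(dy, as.integer(dims),
                            out_sp[1], out_sp[2], out_sp[3])
    dim(dx) <- dims
    dx
  }))
}

# Global average / max pooling over the spatial axes: (D,H,W,C,B)->(1,1,1,C,B).
ag_gap <- function(x) {
  xv <- ag_value(x)
  dims <- dim(xv)
  nv <- prod(dims[1:3]); C <- dims[4]; B <- dims[5]
  yv <- array(.colMeans(xv, nv, C * B), dim = c(1L, 1L, 1L, C, B))
  ag_make(yv, list(x), list(function(dy) {
    .expand_gate(dy, dims) / nv
  }))
}

ag_gmp <- function(x) {
  xv <- ag_value(x)
  dims <- dim(xv)
  nv <- prod(dims[1:3]); C <- dims[4]; B <- dims[5]
  m <- matrix(xv, nv, C * B)
  idx <- integer(C * B)
  val <- numeric(C * B)
  for (j in seq_len(C * B)) {
    idx[j] <- which.max(m[, j]) # first-maximum tie break
    val[j] <- m[idx[j], j]
  }
  yv <- array(val, dim = c(1L, 1L, 1L, C, B))
  ag_make(yv, list(x), list(function(dy) {
    dm <- matrix(0, nv, C * B)
    dm[cbind(idx, seq_len(C * B))] <- as.vector(dy)
    array(dm, dim = dims)
  }))
}

# Channel-wise mean / max: (D,H,W,C,B) -> (D,H,W,1,B).
ag_cmean <- function(x) {
  xv <- ag_value(x)
  dims <- dim(xv)
  yv <- .sum_channels(xv, dims) / dims[4]
  ag_make(yv, list(x), list(function(dy) {
    .expand_gate(dy, dims) / dims[4]
  }))
}

ag_cmax <- function(x) {
  xv <- ag_value(x)
  dims <- dim(xv)
  nv <- prod(dims[1:3]); C <- dims[4]; B <- dims[5]
  val <- matrix(0, nv, B)
  idx <- matrix(0L, nv, B)
  m <- matrix(xv, nv, C * B)
  for (b in seq_len(B)) {
    slab <- m[, ((b - 1L) * C + 1L):(b * C), drop = FALSE]
    ic <- max.col(slab, ties.method = "first")
    idx[, b] <- ic
    val[, b] <- slab[cbind(seq_len(nv), ic)]
  }
  yv <- array(val, dim = c(dims[1:3], 1L, B))
  ag_make(yv, list(x), list(function(dy) {
    dyv <- matrix(dy, nv, B)
    dm <- matrix(0, nv, C * B)
    for (b in seq_len(B))
      dm[cbind(seq_len(nv), (b - 1L) * C + idx[, b])] <- dyv[, b]
    array(dm, dim = dims)
  }))
}

# --- elementwise -----------------------------------------------------------

ag_add <- function(x, y) {
  xv <- ag_value(x); yv <- ag_value(y)
  ag_make(xv + yv, list(x, y), list(function(dy) dy, function(dy) dy))
}

# Multiply a tensor by a gate broadcast over space (channel gate, dim
# (1,1,1,C,B)) or over channels (spatial gate, dim (D,H,W,1,B)).
ag_mul_gate <- function(x, g) {
  xv <- ag_value(x); gv <- ag_value(g)
  dims <- dim(xv)
  G <- .expand_gate(gv, dims)
  ag_make(xv * G, list(x, g), list(
    function(dy) dy * G,
    function(dy) {
      a <- dy * xv
      if (all(dim(gv)[1:3] == 1L)) {
        nv <- prod(dims[1:3])
        array(.colSums(matrix(a, nv, dims[4] * dims[5]), nv,
                       dims[4] * dims[5]),
              dim = dim(gv))
      } else {
        .sum_channels(a, dims)
      }
    }))
}

ag_sigmoid <- function(x) {
  xv <- ag_value(x)
  s <- 1 / (1 + exp(-xv))
  ag_make(s, list(x), list(function(dy) dy * s * (1 - s)))
}

ag_relu <- function(x) {
  xv <- ag_value(x)
  pos <- xv > 0
  ag_make(xv * pos, list(x), list(function(dy) dy * pos))
}

# Randomised leaky rectifier. In training mode the negative-side slope is
# drawn per element from U(lower, upper) using the ambient RNG stream; in
# inference mode the deterministic midpoint slope (lower+upper)/2 is used.
ag_rrelu <- function(x, lower = 1 / 8, upper = 1 / 3, training = FALSE) {
  xv <- ag_value(x)
  slope <- rep(1, length(xv))
  neg <- which(xv < 0)
  slope[neg] <- if (training) runif(length(neg), lower, upper)
  else (lower + upper) / 2
  yv <- xv * slope
  attributes(yv) <- attributes(xv)
  ag_make(yv, list(x), list(function(dy) dy * slope))
}

ag_dropout <- function(x, rate, training = FALSE) {
  if (!training || rate <= 0) return(x)
  xv <- ag_value(x)
  keep <- (runif(length(xv)) >= rate) / (1 - rate)
  yv <- xv * keep
  attributes(yv) <- attributes(xv)
  ag_make(yv, list(x), list(function(dy) dy * keep))
}

# --- normalization ---------------------------------------------------------

# Batch normalization over (batch, spatial) per channel. `state` is an
# environment holding running_mean / running_var, updated in training mode
# with exponential rate `momentum` and used verbatim in inference mode.
ag_bn <- function(x, gamma, beta, state, training = FALSE,
                  eps = 1e-5, momentum = 0.1) {
  xv <- ag_value(x); gv <- ag_value(gamma); bv <- ag_value(beta)
  dims <- dim(xv)
  nv <- prod(dims[1:3]); C <- dims[4]; B <- dims[5]
  m <- nv * B
  if (training && B < 2L)
    stop("batch normalization in training mode requires a batch of at least 2 ",
         "(batch statistics cannot be estimated from a single sample)")
  if (training) {
    cs <- .sum_spatial_cb(xv, nv, C, B)
    mu <- .rowSums(cs, C, B) / m
    cs2 <- .sum_spatial_cb(xv * xv, nv, C, B)
    var_ <- .rowSums(cs2, C, B) / m - mu^2
    var_ <- pmax(var_, 0)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var + momentum * var_
  } else {
    mu <- state$running_mean
    var_ <- state$running_var
  }
  invstd <- 1 / sqrt(var_ + eps)
  mu_f <- rep(rep(mu, each = nv), times = B)
  is_f <- rep(rep(invstd, each = nv), times = B)
  xhat <- (as.vector(xv) - mu_f) * is_f
  g_f <- rep(rep(gv, each = nv), times = B)
  b_f <- rep(rep(bv, each = nv), times = B)
  yv <- array(g_f * xhat + b_f, dim = dims)
  ag_make(yv, list(x, gamma, beta), list(
    function(dy) {
      dyv <- as.vector(dy)
      if (!training) return(array(dyv * g_f * is_f, dim = dims))
      s1 <- .rowSums(.sum_spatial_cb(dyv, nv, C, B), C, B) / m
      s2 <- .rowSums(.sum_spatial_cb(dyv * xhat, nv, C, B), C, B) / m
      s1f <- rep(rep(s1, each = nv), times = B)
      s2f <- rep(rep(s2, each = nv), times = B)
      array(g_f * is_f * (dyv - s1f - xhat * s2f), dim = dims)
    },
    function(dy) .rowSums(.sum_spatial_cb(as.vector(dy) * xhat, nv, C, B), C, B),
    function(dy) .rowSums(.sum_spatial_cb(as.vector(dy), nv, C, B), C, B)))
}

# Group normalization: per sample, channels are split into `groups`
# contiguous groups and standardized over (group channels, D, H, W), with
# eps added inside the square root; batch-size independent.
ag_gn <- function(x, gamma, beta, groups = 4L, eps = 1e-5) {
  xv <- ag_value(x); gv <- ag_value(gamma); bv <- ag_value(beta)
  dims <- dim(xv)
  nv <- prod(dims[1:3]); C <- dims[4]; B <- dims[5]
  if (C %% groups != 0L)
    stop("channel count (", C, ") is not divisible by the number of groups (",
         groups, ")")
  Cg <- C %/% groups
  m <- nv * Cg
  gm <- matrix(xv, m, groups * B)
  mu <- .colMeans(gm, m, groups * B)
  var_ <- .colMeans(gm * gm, m, groups * B) - mu^2
  invstd <- 1 / sqrt(pmax(var_, 0) + eps)
  mu_f <- rep(mu, each = m)
  is_f <- rep(invstd, each = m)
  xhat <- (as.vector(xv) - mu_f) * is_f
  g_f <- rep(rep(gv, each = nv), times = B)
  b_f <- rep(rep(bv, each = nv), times = B)
  yv <- array(g_f * xhat + b_f, dim = dims)
  ag_make(yv, list(x, gamma, beta), list(
    function(dy) {
      g <- as.vector(dy) * g_f
      s1 <- rep(.colMeans(matrix(g, m, groups * B), m, groups * B), each = m)
      s2 <- rep(.colMeans(matrix(g * xhat, m, groups * B), m, groups * B),
                each = m)
      array(is_f * (g - s1 - xhat * s2), dim = dims)
    },
    function(dy) .rowSums(.sum_spatial_cb(as.vector(dy) * xhat, nv, C, B), C, B),
    function(dy) .rowSums(.sum_spatial_cb(as.vector(dy), nv, C, B), C, B)))
}

# --- concatenation ---------------------------------------------------------

# Concatenate along the channel axis.
ag_concat <- function(xs) {
  vals <- lapply(xs, ag_value)
  dims <- dim(vals[[1]])
  Cs <- vapply(vals, function(v) dim(v)[4], integer(1))
  nv <- prod(dims[1:3]); B <- dims[5]
  Ct <- sum(Cs)
  out <- array(0, dim = c(dims[1:3], Ct, B))
  off <- 0L
  for (i in seq_along(vals)) {
    out[, , , (off + 1L):(off + Cs[i]), ] <- vals[[i]]
    off <- off + Cs[i]
  }
  offs <- c(0L, cumsum(Cs))
  ag_make(out, xs, lapply(seq_along(xs), function(i) {
    force(i)
    function(dy) dy[, , , (offs[i] + 1L):(offs[i + 1L]), , drop = FALSE]
  }))
}

# --- fused segmentation loss ----------------------------------------------

# Softmax over channels followed by the weighted Dice + cross-entropy
# compound loss: L = (1-alpha) * L_dice(foreground) + alpha * L_CE, with
# L_dice = 1 - 2*sum(p*q) / (sum(p) + sum(q) + smooth) on the foreground
# class and L_CE the mean voxelwise cross-entropy. Gradient with respect to
# the logits is analytic.
ag_segmentation_loss <- function(logits, onehot, alpha = 0.7, smooth = 1e-5) {
  zv <- ag_value(logits)
  q <- ag_value(onehot)
  dims <- dim(zv)
  nv <- prod(dims[1:3]); C <- dims[4]; B <- dims[5]
  nvox <- nv * B
  zm <- matrix(aperm(zv, c(1, 2, 3, 5, 4)), nvox, C) # voxel rows, class cols
  qm <- matrix(aperm(q, c(1, 2, 3, 5, 4)), nvox, C)
  zmax <- zm[, 1]
  for (cc in seq_len(C)[-1]) zmax <- pmax(zmax, zm[, cc])
  zm <- zm - zmax
  ez <- exp(zm)
  pm <- ez / .rowSums(ez, nvox, C)
  ce <- -sum(qm * log(pmax(pm, 1e-300))) / nvox
  fg <- C # foreground = last class (label 1)
  p1 <- pm[, fg]; q1 <- qm[, fg]
  S <- sum(p1) + sum(q1) + smooth
  I <- sum(p1 * q1)
  dice_l <- 1 - 2 * I / S
  loss <- (1 - alpha) * dice_l + alpha * ce
  ag_make(loss, list(logits), list(function(dy) {
    dce <- (pm - qm) / nvox
    u1 <- (2 * I - 2 * q1 * S) / S^2 # dL_dice / dp_fg
    dd <- pm * (-u1 * p1)            # softmax jacobian, common term
    dd[, fg] <- dd[, fg] + p1 * u1
    dz <- (1 - alpha) * dd + alpha * dce
    dz <- array(dz, dim = c(dims[1:3], B, C))
    aperm(dz, c(1, 2, 3, 5, 4)) * dy
  }))
}
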