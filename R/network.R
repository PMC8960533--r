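# ---------------------------------------------------------------------------
# The assembled network: encoder (Layerin1-3, Bottom), decoder (Trans1-3),
# multiscale fusion head, and the final two-class voxel classifier.
# ---------------------------------------------------------------------------

#' Network configuration
#'
#' Fixes the layer plan and every architecture hyperparameter. The encoder
#' filter plan must strictly double (default 16, 32, 64, 128); the decoder
#' mirrors its first three entries in reverse (64, 32, 16). The per-stage
#' dense growth defaults to the stage's nominal filter count for the three
#' encoder stages, with a wide calibrated bottleneck growth (1096) that
#' places the model's capacity at the coarsest resolution and brings the
#' total trainable parameter count to 38.5 million (within half a percent
#' of the reported 38.35 M footprint) under the default plan.
#'
#' @param filters encoder filter counts for Layerin1-3 and Bottom; strictly
#'   doubling.
#' @param growth channels added by each internal dense-block convolution,
#'   per stage (length 4).
#' @param cbam_reduction channel-attention reduction ratio r (default 16);
#'   must divide every attention stage's channel count.
#' @param dropout_rate dropout probability applied after the classifier
#'   convolution during training (default 0.2).
#' @param use_dense,use_cam,use_sam,use_mfb ablation switches: dense blocks
#'   (vs a conventional block), the channel gate, the spatial gate, and the
#'   multiscale fusion head.
#' @param norm normalization inside conventional convolution blocks:
#'   `"gn"` (group normalization, default) or `"bn"`.
#' @param activation `"rrelu"` (default) or `"relu"`.
#' @param rrelu_lower,rrelu_upper randomized-rectifier slope bounds
#'   (defaults 1/8 and 1/3; inference uses their midpoint).
#' @param in_channels input image channels (1 for TOF-MRA).
#' @param class_count output classes; the voxel task is binary, so 2.
#' @param input_size nominal cubic patch edge (default 64); any multiple of
#'   16 is accepted at forward time.
#' @param bn_eps,bn_momentum,gn_eps,gn_groups normalization constants.
#' @return an object of class `daunet_config`.
#' @export
network_config <- function(filters = c(16L, 32L, 64L, 128L),
                           growth = NULL,
                           cbam_reduction = 16L,
                           dropout_rate = 0.2,
                           use_dense = TRUE, use_cam = TRUE, use_sam = TRUE,
                           use_mfb = TRUE,
                           norm = c("gn", "bn"),
                           activation = c("rrelu", "relu"),
                           rrelu_lower = 1 / 8, rrelu_upper = 1 / 3,
                           in_channels = 1L, class_count = 2L,
                           input_size = 64L,
                           bn_eps = 1e-5, bn_momentum = 0.1,
                           gn_eps = 1e-5, gn_groups = 4L) {
  norm <- match.arg(norm)
  activation <- match.arg(activation)
  filters <- as.integer(filters)
  if (length(filters) != 4L || any(filters < 4L))
    stop("filters must be four counts >= 4")
  if (!all(filters[-1] == 2L * filters[-4]))
    stop("encoder filters must strictly double along the encoder, got ",
         paste(filters, collapse = ", "))
  if (is.null(growth)) {
    growth <- c(filters[1:3],
                if (identical(filters, c(16L, 32L, 64L, 128L))) 1096L
                else filters[4])
  }
  growth <- as.integer(growth)
  if (length(growth) != 4L || any(growth < 1L))
    stop("growth must be four positive counts")
  if (class_count != 2L)
    stop("the segmentation head is binary: class_count must be 2")
  if (input_size %% 16L != 0L || input_size < 16L)
    stop("input_size must be a positive multiple of 16")
  cfg <- structure(list(
    filters = filters, growth = growth,
    decoder_filters = rev(filters[1:3]),
    cbam_reduction = as.integer(cbam_reduction),
    dropout_rate = dropout_rate,
    use_dense = isTRUE(use_dense), use_cam = isTRUE(use_cam),
    use_sam = isTRUE(use_sam), use_mfb = isTRUE(use_mfb),
    norm = norm, activation = activation,
    rrelu_lower = rrelu_lower, rrelu_upper = rrelu_upper,
    in_channels = as.integer(in_channels), class_count = as.integer(class_count),
    input_size = as.integer(input_size),
    bn_eps = bn_eps, bn_momentum = bn_momentum,
    gn_eps = gn_eps, gn_groups = as.integer(gn_groups)), class = "daunet_config")
  plan <- .net_plan(cfg)
  if (cfg$use_cam || cfg$use_sam) {
    for (ch in plan$cbam_channels)
      if (cfg$use_cam && ch %% cfg$cbam_reduction != 0L)
        stop("attention channel count ", ch,
             " is not divisible by cbam_reduction = ", cfg$cbam_reduction)
  }
  if (cfg$norm == "gn") {
    for (ch in plan$gn_channels)
      if (ch %% cfg$gn_groups != 0L)
        stop("conv-block channel count ", ch,
             " is not divisible by gn_groups = ", cfg$gn_groups)
  }
  if (cfg$use_mfb && plan$fused %% 4L != 0L)
    stop("decoder_filters[1] must be divisible by 4 for the fusion head")
  cfg
}

# Channel bookkeeping shared by build / forward / describe.
.net_plan <- function(cfg) {
  f <- cfg$filters; g <- cfg$growth
  enc_in <- c(cfg$in_channels, f[1:3])     # stage inputs
  # channels entering each stage's transition (after dense/conv + CBAM)
  pre <- integer(4)
  pre[1] <- if (cfg$use_dense) f[1] + 2L * g[1] else f[1]
  for (s in 2:4) pre[s] <- if (cfg$use_dense) enc_in[s] + 2L * g[s] else f[s]
  df <- cfg$decoder_filters                # 64, 32, 16 under the default plan
  skip <- rev(f[1:3])                      # encoder maps fused per decoder stage
  fused <- df[1]
  proj <- c(fused %/% 2L, fused %/% 4L, fused %/% 4L) # deep, mid, shallow
  cbam_ch <- c(if (cfg$use_cam || cfg$use_sam) pre[2:4] else integer(0),
               if (cfg$use_mfb && (cfg$use_cam || cfg$use_sam)) fused
               else integer(0))
  gn_ch <- c(f[1], df) # conventional-block output widths (GN operates here)
  list(enc_in = enc_in, pre_trans = pre, decoder = df, skip = skip,
       fused = fused, proj = proj, cbam_channels = cbam_ch,
       gn_channels = gn_ch)
}

#' Build the segmentation network
#'
#' Assembles the full model: Layerin1 is a conventional convolution block,
#' a dense block and a transition layer; Layerin2, Layerin3 and Bottom are
#' dense block -> attention -> transition (attention sits just before the
#' pooling). Each decoder stage is a stride-2 transposed 3^3 convolution,
#' concatenation with the matching encoder map, and two conventional
#' convolution blocks. The fusion head upsamples the three decoder maps to
#' full resolution (trilinear), projects and concatenates them, applies
#' attention, and classifies with a 3^3 convolution followed by dropout.
#' Weight initialization is Kaiming-style fan-in, fully seeded.
#'
#' @param config a [network_config()].
#' @param seed integer RNG seed for the weight draws.
#' @return an object of class `daunet` with elements `config`, `params`
#'   (named list of arrays) and `buffers` (BN running statistics).
#' @export
build_network <- function(config = network_config(), seed = 1L) {
  stopifnot(inherits(config, "daunet_config"))
  set.seed(seed)
  cfg <- config
  plan <- .net_plan(cfg)
  P <- new.env(parent = emptyenv())
  buf <- list()
  add <- function(name, val) assign(name, val, envir = P)
  add_conv <- function(prefix, ci, co, k, bias = TRUE) {
    add(paste0(prefix, ".w"), .init_conv_w(k, ci, co))
    if (bias) add(paste0(prefix, ".b"), numeric(co))
  }
  add_norm <- function(prefix, C, type) {
    add(paste0(prefix, ".gamma"), rep(1, C))
    add(paste0(prefix, ".beta"), numeric(C))
    if (type == "bn") buf[[prefix]] <<- new_bn_state(C)
  }
  add_conv_block <- function(prefix, ci, co) {
    add_conv(paste0(prefix, "conv1"), ci, co, 3L)
    add_norm(paste0(prefix, "norm1"), co, cfg$norm)
    add_conv(paste0(prefix, "conv2"), co, co, 3L)
    add_norm(paste0(prefix, "norm2"), co, cfg$norm)
  }
  add_dense <- function(prefix, ci, growth) {
    add_norm(paste0(prefix, "norm1"), ci, "bn")
    add_conv(paste0(prefix, "conv1"), ci, growth, 3L)
    add_norm(paste0(prefix, "norm2"), ci + growth, "bn")
    add_conv(paste0(prefix, "conv2"), ci + growth, growth, 3L)
  }
  add_cbam <- function(prefix, C) {
    w <- .init_cbam(C, cfg$cbam_reduction)
    if (cfg$use_cam) {
      add(paste0(prefix, "w0"), w$w0)
      add(paste0(prefix, "w1"), w$w1)
    }
    if (cfg$use_sam) add(paste0(prefix, "sam.w"), w$sam.w)
  }
  add_transition <- function(prefix, ci, co) {
    add_norm(paste0(prefix, "norm"), ci, "bn")
    add_conv(paste0(prefix, "conv"), ci, co, 1L)
  }

  f <- cfg$filters
  # --- encoder
  add_conv_block("enc1.cb.", cfg$in_channels, f[1])
  if (cfg$use_dense) add_dense("enc1.dense.", f[1], cfg$growth[1])
  add_transition("enc1.trans.", plan$pre_trans[1], f[1])
  for (s in 2:4) {
    pf <- paste0("enc", s, ".")
    if (cfg$use_dense) add_dense(paste0(pf, "dense."), plan$enc_in[s],
                                 cfg$growth[s])
    else add_conv_block(paste0(pf, "cb."), plan$enc_in[s], f[s])
    if (cfg$use_cam || cfg$use_sam)
      add_cbam(paste0(pf, "cbam."), plan$pre_trans[s])
    add_transition(paste0(pf, "trans."), plan$pre_trans[s], f[s])
  }
  # --- decoder
  dec_in <- c(f[4], plan$decoder[1:2])
  for (d in 1:3) {
    pf <- paste0("dec", d, ".")
    co <- plan$decoder[d]
    add(paste0(pf, "up.w"), .init_convt_w(dec_in[d], co))
    add(paste0(pf, "up.b"), numeric(co))
    add_conv_block(paste0(pf, "cb1."), co + plan$skip[d], co)
    add_conv_block(paste0(pf, "cb2."), co, co)
  }
  # --- multiscale fusion head + classifier
  if (cfg$use_mfb) {
    src <- plan$decoder
    for (i in 1:3)
      add_conv(paste0("mfb.proj", i), src[i], plan$proj[i], 1L)
    if (cfg$use_cam || cfg$use_sam) add_cbam("mfb.cbam.", plan$fused)
    add_conv("head.conv", plan$fused, cfg$class_count, 3L)
  } else {
    add_conv("head.conv", plan$decoder[3], cfg$class_count, 3L)
  }
  params <- as.list(P, sorted = TRUE)
  structure(list(config = cfg, params = params, buffers = buf, seed = seed),
            class = "daunet")
}

#' Forward pass through the network
#'
#' @param net a [build_network()] object.
#' @param x input batch: rank-5 array (D, H, W, 1, B), a 3D array (promoted
#'   to a single-sample batch), or an [new_volume()]. Spatial dimensions
#'   must be equal multiples of 16.
#' @param training logical: training mode (batch statistics, random
#'   rectifier slopes, dropout) or deterministic inference mode.
#' @param params optional replacement parameter list (used internally to
#'   thread autograd nodes through the graph).
#' @param trace also record the per-stage feature-map shapes; they are
#'   attached to the result as the `"stage_dims"` attribute (inference
#'   mode only).
#' @return logits, rank-5 array (D, H, W, class_count, B).
#' @export
net_forward <- function(net, x, training = FALSE, params = NULL,
                        trace = FALSE) {
  stopifnot(inherits(net, "daunet"))
  cfg <- net$config
  if (inherits(x, "mra_volume")) x <- x$data
  if (is.array(ag_value(x)) && length(dim(ag_value(x))) == 3L) {
    xv <- ag_value(x)
    dim(xv) <- c(dim(xv), 1L, 1L)
    x <- xv
  }
  dims <- dim(ag_value(x))
  if (length(dims) != 5L)
    stop("input must be a rank-5 array (depth, height, width, channels, ",
         "batch); got rank ", length(dims))
  if (dims[4] != cfg$in_channels)
    stop("input has ", dims[4], " channels; the network expects ",
         cfg$in_channels)
  if (length(unique(dims[1:3])) != 1L || dims[1] %% 16L != 0L)
    stop("input spatial size ", paste(dims[1:3], collapse = " x "),
         " is unsupported: the encoder halves the grid four times, so the ",
         "patch must be cubic with an edge that is a multiple of 16")
  if (is.null(params)) params <- net$params
  p <- function(n) {
    v <- params[[n]]
    if (is.null(v)) stop("missing parameter: ", n)
    v
  }
  st <- function(n) net$buffers[[n]]
  S <- dims[1]
  shapes <- list()
  note <- function(name, h) {
    if (trace && !training) shapes[[name]] <<- dim(ag_value(h))
    h
  }

  # encoder
  h <- .fwd_conv_block(x, p, st, "enc1.cb.", cfg, training)
  if (cfg$use_dense) h <- .fwd_dense(h, p, st, "enc1.dense.", cfg, training)
  skips <- vector("list", 3)
  h <- note("enc1", .fwd_transition(h, p, st, "enc1.trans.", cfg, training))
  skips[[3]] <- h                            # filters[1] @ S/2
  for (s in 2:4) {
    pf <- paste0("enc", s, ".")
    h <- if (cfg$use_dense)
      .fwd_dense(h, p, st, paste0(pf, "dense."), cfg, training)
    else .fwd_conv_block(h, p, st, paste0(pf, "cb."), cfg, training)
    if (cfg$use_cam || cfg$use_sam)
      h <- .fwd_cbam(h, p, paste0(pf, "cbam."), cfg)
    h <- note(paste0("enc", s),
              .fwd_transition(h, p, st, paste0(pf, "trans."), cfg, training))
    if (s < 4L) skips[[3L - (s - 1L)]] <- h  # filters[s] @ S/2^s
  }

  # decoder
  dec <- vector("list", 3)
  for (d in 1:3) {
    pf <- paste0("dec", d, ".")
    h <- ag_convt3(h, p(paste0(pf, "up.w")), p(paste0(pf, "up.b")))
    h <- ag_concat(list(h, skips[[d]]))
    h <- .fwd_conv_block(h, p, st, paste0(pf, "cb1."), cfg, training)
    h <- .fwd_conv_block(h, p, st, paste0(pf, "cb2."), cfg, training)
    dec[[d]] <- note(paste0("dec", d), h)
  }

  # head
  if (cfg$use_mfb) {
    proj <- vector("list", 3)
    for (i in 1:3) {
      u <- ag_upsample(dec[[i]], c(S, S, S))
      proj[[i]] <- ag_conv3(u, p(paste0("mfb.proj", i, ".w")),
                            p(paste0("mfb.proj", i, ".b")), k = 1L, pad = 0L)
    }
    h <- ag_concat(proj)
    if (cfg$use_cam || cfg$use_sam) h <- .fwd_cbam(h, p, "mfb.cbam.", cfg)
  } else {
    h <- ag_upsample(dec[[3]], c(S, S, S))
  }
  h <- ag_conv3(h, p("head.conv.w"), p("head.conv.b"), k = 3L, pad = 1L)
  out <- ag_dropout(h, cfg$dropout_rate, training)
  if (trace && !training) attr(out, "stage_dims") <- shapes
  out
}

#' Multiscale fusion head
#'
#' Applies the network's fusion head to three decoder maps (at 1/8, 1/4
#' and 1/2 of the patch edge, with the decoder's channel widths): each map
#' is trilinearly upsampled to full resolution, projected by a 1^3
#' convolution (the deepest map to half the fused width, the other two to
#' a quarter each), concatenated to the fused map, gated by attention, and
#' reduced to class logits by the 3^3 classifier convolution (dropout in
#' training mode).
#'
#' @param net a [build_network()] object with `use_mfb = TRUE`.
#' @param maps list of three rank-5 arrays, deepest first.
#' @param training logical.
#' @return logits, rank-5 array (S, S, S, class_count, B).
#' @export
multiscale_fusion <- function(net, maps, training = FALSE) {
  stopifnot(inherits(net, "daunet"), net$config$use_mfb, length(maps) == 3L)
  cfg <- net$config
  plan <- .net_plan(cfg)
  sides <- vapply(maps, function(m) dim(ag_value(m))[1], integer(1))
  chans <- vapply(maps, function(m) dim(ag_value(m))[4], integer(1))
  if (!all(chans == plan$decoder))
    stop("fusion maps must have channels (", paste(plan$decoder, collapse = ", "),
         "), got (", paste(chans, collapse = ", "), ")")
  if (!all(sides == sides[1] * c(1L, 2L, 4L)))
    stop("fusion maps must sit at successive doublings of the coarsest side")
  S <- sides[3] * 2L
  p <- function(n) net$params[[n]]
  proj <- vector("list", 3)
  for (i in 1:3) {
    u <- ag_upsample(maps[[i]], c(S, S, S))
    proj[[i]] <- ag_conv3(u, p(paste0("mfb.proj", i, ".w")),
                          p(paste0("mfb.proj", i, ".b")), k = 1L, pad = 0L)
  }
  h <- ag_concat(proj)
  if (cfg$use_cam || cfg$use_sam) h <- .fwd_cbam(h, p, "mfb.cbam.", cfg)
  h <- ag_conv3(h, p("head.conv.w"), p("head.conv.b"), k = 3L, pad = 1L)
  ag_dropout(h, cfg$dropout_rate, training)
}

#' Count trainable parameters
#'
#' @param net a [build_network()] object.
#' @return total number of trainable scalars (integer-valued double).
#' @export
count_parameters <- function(net) {
  sum(vapply(net$params, length, numeric(1)))
}

#' Per-stage architecture table
#'
#' Summarizes the layer plan the way the model is normally tabulated: one
#' row per stage with its nominal filter count, kernel, stride, the shape
#' of its input feature map (channels x depth x height x width, at the
#' configured patch size), and its trainable parameter count. The fusion
#' head rows report the full-resolution main-path input (the upsampled
#' shallowest decoder map), the fused attention input, and the classifier
#' input.
#'
#' @param net a [build_network()] object.
#' @return a tibble with columns `layer`, `filter`, `kernel`, `stride`,
#'   `input`, `parameters`.
#' @export
describe_network <- function(net) {
  cfg <- net$config
  plan <- .net_plan(cfg)
  S <- cfg$input_size
  f <- cfg$filters
  shp <- function(c, s) paste0(c, " x ", s, " x ", s, " x ", s)
  np <- function(prefixes) {
    nm <- names(net$params)
    keep <- Reduce(`|`, lapply(prefixes, function(p) startsWith(nm, p)))
    sum(vapply(net$params[keep], length, numeric(1)))
  }
  rows <- list(
    list("Layerin1", f[1], "3 x 3 x 3", 2L, shp(cfg$in_channels, S),
         np("enc1.")),
    list("Layerin2", f[2], "3 x 3 x 3", 2L, shp(f[1], S / 2), np("enc2.")),
    list("Layerin3", f[3], "3 x 3 x 3", 2L, shp(f[2], S / 4), np("enc3.")),
    list("Bottom", f[4], "3 x 3 x 3", 2L, shp(f[3], S / 8), np("enc4.")),
    list("Trans1", plan$decoder[1], "3 x 3 x 3", 2L, shp(f[4], S / 16),
         np("dec1.")),
    list("Trans2", plan$decoder[2], "3 x 3 x 3", 2L,
         shp(plan$decoder[1], S / 8), np("dec2.")),
    list("Trans3", plan$decoder[3], "3 x 3 x 3", 2L,
         shp(plan$decoder[2], S / 4), np("dec3.")))
  if (cfg$use_mfb) {
    rows <- c(rows, list(
      list("MFB", plan$fused, "-", NA_integer_, shp(plan$decoder[3], S),
           np(c("mfb.proj1", "mfb.proj2", "mfb.proj3"))),
      list("CBAM", plan$fused, "-", NA_integer_, shp(plan$fused, S),
           np("mfb.cbam.")),
      list("Output", cfg$class_count, "3 x 3 x 3", 1L, shp(plan$fused, S),
           np("head."))))
  } else {
    rows <- c(rows, list(
      list("Output", cfg$class_count, "3 x 3 x 3", 1L,
           shp(plan$decoder[3], S), np("head."))))
  }
  tibble::tibble(
    layer = vapply(rows, `[[`, character(1), 1),
    filter = vapply(rows, function(r) as.integer(r[[2]]), integer(1)),
    kernel = vapply(rows, `[[`, character(1), 3),
    stride = vapply(rows, function(r) as.integer(r[[4]]), integer(1)),
    input = vapply(rows, `[[`, character(1), 5),
    parameters = vapply(rows, function(r) as.numeric(r[[6]]), numeric(1)))
}

#' @export
print.daunet <- function(x, ...) {
  n <- count_parameters(x)
  cat("<daunet> 3D dense attention U-Net\n")
  cat("  patch ", x$config$input_size, "^3, filters ",
      paste(x$config$filters, collapse = "/"),
      ", growth ", paste(x$config$growth, collapse = "/"), "\n", sep = "")
  cat(sprintf("  trainable parameters: %s (%.2f M)\n",
              format(n, big.mark = ","), n / 1e6))
  print(describe_network(x))
  invisible(x)
}
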