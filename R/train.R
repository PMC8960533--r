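# ---------------------------------------------------------------------------
# Training loop, inference, case evaluation, and dataset splitting.
# ---------------------------------------------------------------------------

#' Training settings
#'
#' Defaults reproduce the reference optimization recipe: Adam, initial
#' learning rate 0.001, 300 epochs at batch size 8, with the learning rate
#' multiplied by 0.1 whenever the validation Dice stagnates for 10
#' consecutive epochs. Tests and examples run a miniature profile (few
#' epochs, small batch, reduced patch) — scale, not mechanics, differs.
#'
#' @param epochs training epochs (default 300).
#' @param batch_size cases per optimization step (default 8; must be >= 2
#'   whenever the model contains batch-normalized dense blocks).
#' @param lr initial learning rate (default 0.001).
#' @param lr_factor,lr_patience plateau decay: multiply by `lr_factor`
#'   (default 0.1) after `lr_patience` (default 10) stagnant epochs of the
#'   monitored validation Dice.
#' @param alpha cross-entropy weight of the compound loss (default 0.7).
#' @param dice_smooth Dice smoothing constant (default 1e-5).
#' @param patch_size cubic crop edge fed to the network (default 64).
#' @param augment apply random flips and intensity offsets to training
#'   patches (default TRUE).
#' @param augment_spec_args list of overrides for [augment_spec()].
#' @param max_steps optional cap on total optimization steps.
#' @param stop_train_dice optional early-stop threshold on training-set
#'   Dice, checked every `dice_check_every` steps.
#' @param dice_check_every steps between training-Dice checks (default 10).
#' @param seed master seed: network initialization, shuffling, augmentation
#'   and rectifier noise all derive from it.
#' @param verbose print one line per epoch.
#' @return a list of class `train_config`.
#' @export
train_config <- function(epochs = 300L, batch_size = 8L, lr = 1e-3,
                         lr_factor = 0.1, lr_patience = 10L,
                         alpha = 0.7, dice_smooth = 1e-5,
                         patch_size = 64L, augment = TRUE,
                         augment_spec_args = list(),
                         max_steps = Inf, stop_train_dice = NULL,
                         dice_check_every = 10L,
                         seed = 1L, verbose = FALSE) {
  if (epochs < 1 || batch_size < 1) stop("epochs and batch_size must be >= 1")
  if (lr <= 0) stop("lr must be > 0")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, lr_factor = lr_factor,
                 lr_patience = as.integer(lr_patience),
                 alpha = alpha, dice_smooth = dice_smooth,
                 patch_size = as.integer(patch_size), augment = augment,
                 augment_spec_args = augment_spec_args,
                 max_steps = max_steps, stop_train_dice = stop_train_dice,
                 dice_check_every = as.integer(dice_check_every),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

.case_center <- function(case) {
  if (!is.null(case$center)) return(as.integer(round(case$center)))
  m <- .vol_data(case$mask)
  idx <- which(m == 1, arr.ind = TRUE)
  if (nrow(idx) == 0) return(as.integer(dim(m) %/% 2L))
  as.integer(round(colMeans(idx)))
}

# z-score, centre-crop, binarize: one case -> list(x = patch array,
# y = binary label patch).
.prepare_case <- function(case, patch_size) {
  z <- zscore_normalize(case$volume)$volume
  cr <- crop_centered(z, case$mask, center = .case_center(case),
                      size = patch_size)
  list(x = .vol_data(cr$volume),
       y = .vol_data(binarize_labels(cr$mask)))
}

.onehot <- function(y_list) {
  d <- dim(y_list[[1]])
  B <- length(y_list)
  q <- array(0, dim = c(d, 2L, B))
  for (b in seq_len(B)) {
    q[, , , 1L, b] <- 1 - y_list[[b]]
    q[, , , 2L, b] <- y_list[[b]]
  }
  q
}

.stack_x <- function(x_list) {
  d <- dim(x_list[[1]])
  B <- length(x_list)
  x <- array(0, dim = c(d, 1L, B))
  for (b in seq_len(B)) x[, , , 1L, b] <- x_list[[b]]
  x
}

.argmax_mask <- function(logits, b = 1L) {
  (logits[, , , 2L, b] > logits[, , , 1L, b]) * 1L
}

# Mean Dice of the network over prepared patches (inference mode).
.patch_dice <- function(net, prepared, params = NULL) {
  if (is.null(params)) params <- net$params
  mean(vapply(prepared, function(pc) {
    logits <- net_forward(net, array(pc$x, dim = c(dim(pc$x), 1L, 1L)),
                          training = FALSE, params = params)
    dice_score(confusion_counts(.argmax_mask(logits), pc$y))
  }, numeric(1)))
}

#' Train the segmentation network
#'
#' Optimizes the compound Dice + cross-entropy loss with Adam over
#' aneurysm-centred, z-scored, optionally augmented patches. The learning
#' rate follows the reduce-on-plateau schedule monitored on validation
#' Dice (training Dice when no validation set is given); the
#' best-validation parameter set is retained alongside the final one.
#'
#' @param train_cases list of cases; each case is a list with `volume`
#'   ([new_volume()]), `mask` ([new_label_mask()]) and optionally `center`
#'   (1-based crop centre; defaults to the mask centroid).
#' @param val_cases optional validation cases in the same format.
#' @param config a [network_config()].
#' @param train_cfg a [train_config()].
#' @return object of class `daunet_fit`: `network` (best-validation
#'   parameters), `final_network`, `log` (per-epoch tibble with loss,
#'   validation Dice and learning rate), `steps`, and the configs.
#' @export
train_network <- function(train_cases, val_cases = NULL,
                          config = network_config(),
                          train_cfg = train_config()) {
  if (length(train_cases) == 0) stop("empty training set")
  tc <- train_cfg
  set.seed(tc$seed)
  net <- build_network(config, seed = tc$seed)
  if (config$use_dense && tc$batch_size < 2L)
    stop("batch_size must be >= 2: dense blocks use batch normalization")
  prep_tr <- lapply(train_cases, .prepare_case, patch_size = tc$patch_size)
  prep_va <- if (!is.null(val_cases))
    lapply(val_cases, .prepare_case, patch_size = tc$patch_size)
  aug <- do.call(augment_spec, tc$augment_spec_args)
  opt <- adam_init(net$params)
  sched <- lr_schedule(tc$lr, tc$lr_factor, tc$lr_patience)
  n <- length(prep_tr)
  steps <- 0L
  stop_now <- FALSE
  log_rows <- list()
  best <- list(dice = -Inf, params = NULL, epoch = NA_integer_)
  for (epoch in seq_len(tc$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / tc$batch_size))
    epoch_losses <- numeric(0)
    for (batch in batches) {
      if (steps >= tc$max_steps) { stop_now <- TRUE; break }
      xs <- vector("list", length(batch))
      ys <- vector("list", length(batch))
      for (j in seq_along(batch)) {
        pc <- prep_tr[[batch[j]]]
        if (tc$augment) {
          a <- augment_case(pc$x, pc$y, aug)
          xs[[j]] <- a$volume; ys[[j]] <- a$mask
        } else {
          xs[[j]] <- pc$x; ys[[j]] <- pc$y
        }
      }
      xb <- .stack_x(xs)
      qb <- .onehot(ys)
      pnodes <- lapply(net$params, ag_leaf)
      logits <- net_forward(net, xb, training = TRUE, params = pnodes)
      loss <- ag_segmentation_loss(logits, qb, tc$alpha, tc$dice_smooth)
      ag_backward(loss)
      grads <- lapply(pnodes, function(nd) nd$grad)
      res <- adam_step(opt, net$params, grads, sched$lr)
      opt <- res$state
      net$params <- res$params
      steps <- steps + 1L
      epoch_losses <- c(epoch_losses, ag_value(loss))
      if (!is.null(tc$stop_train_dice) &&
          steps %% tc$dice_check_every == 0L) {
        td <- .patch_dice(net, prep_tr)
        if (td >= tc$stop_train_dice) { stop_now <- TRUE; break }
      }
    }
    if (length(epoch_losses) == 0L) break
    val_dice <- if (!is.null(prep_va)) .patch_dice(net, prep_va)
    else .patch_dice(net, prep_tr)
    sched <- lr_schedule_step(sched, val_dice)
    if (val_dice > best$dice)
      best <- list(dice = val_dice, params = net$params, epoch = epoch)
    log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
      epoch = epoch, loss = mean(epoch_losses), val_dice = val_dice,
      lr = sched$lr, steps = steps)
    if (tc$verbose)
      message(sprintf("epoch %3d  loss %.4f  val dice %.4f  lr %g",
                      epoch, mean(epoch_losses), val_dice, sched$lr))
    if (stop_now) break
  }
  best_net <- net
  if (!is.null(best$params)) best_net$params <- best$params
  structure(list(network = best_net, final_network = net,
                 log = do.call(rbind, log_rows), steps = steps,
                 best_epoch = best$epoch, best_dice = best$dice,
                 config = config, train_config = tc),
            class = "daunet_fit")
}

#' @export
print.daunet_fit <- function(x, ...) {
  cat("<daunet_fit> ", nrow(x$log), " epoch(s), ", x$steps, " step(s)\n",
      sep = "")
  cat(sprintf("  best monitored Dice %.4f at epoch %s\n", x$best_dice,
              x$best_epoch))
  invisible(x)
}

#' Segment a volume with a trained network
#'
#' The volume is z-score normalized, cropped (around `center`) or tiled
#' (sliding window), passed through the network in inference mode, argmaxed
#' per voxel, and the predicted patch labels are re-embedded at their
#' source coordinates; voxels never covered by a window are background.
#'
#' @param net a trained [build_network()] object (or a `daunet_fit`, whose
#'   best network is used).
#' @param vol an [new_volume()].
#' @param center 1-based crop centre (e.g. from a detection step or a
#'   manifest); required unless `sliding_window = TRUE`.
#' @param sliding_window tile the whole volume with windows of the patch
#'   size instead of a single centred crop.
#' @param patch_size window edge (default: the network's configured input
#'   size).
#' @param stride window stride for the sliding mode (default: the window
#'   size, i.e. non-overlapping tiles; overlapping voxels take the last
#'   window's label).
#' @return a [new_label_mask()] of the same shape as `vol`.
#' @export
predict_volume <- function(net, vol, center = NULL, sliding_window = FALSE,
                           patch_size = NULL, stride = NULL) {
  if (inherits(net, "daunet_fit")) net <- net$network
  stopifnot(inherits(net, "daunet"))
  ps <- as.integer(patch_size %||% net$config$input_size)
  z <- zscore_normalize(vol)$volume
  d <- dim(z$data)
  out <- array(0L, dim = d)
  run_window <- function(lo) {
    # window [lo, lo + ps - 1] per axis, zero-padded outside the volume
    centre <- lo + ps %/% 2L
    patch <- .pad_crop(z$data, centre, ps)
    logits <- net_forward(net, array(patch, dim = c(dim(patch), 1L, 1L)),
                          training = FALSE)
    pm <- .argmax_mask(logits)
    src_lo <- pmax(lo, 1L); src_hi <- pmin(lo + ps - 1L, d)
    dst_lo <- src_lo - lo + 1L; dst_hi <- src_hi - lo + 1L
    out[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]] <<-
      pm[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]]
    invisible(NULL)
  }
  if (sliding_window) {
    sv <- as.integer(stride %||% ps)
    starts <- lapply(d, function(dd) {
      s <- seq(1L, max(dd - ps + 1L, 1L), by = sv)
      if (s[length(s)] + ps - 1L < dd) s <- c(s, dd - ps + 1L)
      s
    })
    for (sx in starts[[1]]) for (sy in starts[[2]]) for (sz in starts[[3]])
      run_window(c(sx, sy, sz))
  } else {
    if (is.null(center))
      stop("a crop center is required unless sliding_window = TRUE")
    center <- as.integer(round(center))
    if (any(center < 1L) || any(center > d))
      stop("center lies outside the volume")
    run_window(center - ps %/% 2L)
  }
  new_label_mask(out, vol$spacing)
}

#' Evaluate a trained network over cases
#'
#' Predicts each case (around its crop centre) and scores the prediction
#' against the reference mask with [evaluate_masks()].
#'
#' @param net trained network or fit.
#' @param cases list of cases (`volume`, `mask`, optional `center`,
#'   optional `case_id`).
#' @param ignore_label optional truth label excluded from the confusion
#'   counts (e.g. 2).
#' @param patch_size optional override of the window edge.
#' @return a `daunet_metrics` report.
#' @export
evaluate_cases <- function(net, cases, ignore_label = NULL,
                           patch_size = NULL) {
  preds <- lapply(cases, function(cs)
    predict_volume(net, cs$volume, center = .case_center(cs),
                   patch_size = patch_size))
  truths <- lapply(cases, `[[`, "mask")
  ids <- vapply(seq_along(cases), function(i)
    cases[[i]]$case_id %||% sprintf("case_%03d", i), character(1))
  evaluate_masks(preds, truths, ignore_label = ignore_label, case_ids = ids)
}

#' Random train/validation/test split
#'
#' Splits case indices with the 70/20/23 proportions of a 113-case cohort
#' by default.
#'
#' @param n number of cases.
#' @param fractions length-3 positive weights for train/val/test.
#' @param seed RNG seed.
#' @return list with integer index vectors `train`, `val`, `test`.
#' @export
split_cases <- function(n, fractions = c(70, 20, 23), seed = 1L) {
  stopifnot(length(fractions) == 3L, all(fractions >= 0))
  set.seed(seed)
  fractions <- fractions / sum(fractions)
  ord <- sample.int(n)
  n_tr <- round(n * fractions[1])
  n_va <- round(n * fractions[2])
  n_tr <- min(n_tr, n)
  n_va <- min(n_va, n - n_tr)
  list(train = sort(ord[seq_len(n_tr)]),
       val = sort(ord[n_tr + seq_len(n_va)]),
       test = sort(ord[setdiff(seq_len(n), seq_len(n_tr + n_va))]))
}

#' Save / load a network checkpoint
#'
#' The checkpoint bundles the configuration, all parameters, the
#' batch-norm running statistics and the RNG state, so that
#' save -> load -> predict is bit-identical to predicting before saving.
#'
#' @param net a `daunet` network or `daunet_fit` (best network saved).
#' @param path checkpoint file path (`.rds`).
#' @return `save_checkpoint()` the path invisibly; `load_checkpoint()` the
#'   restored `daunet` network.
#' @export
save_checkpoint <- function(net, path) {
  if (inherits(net, "daunet_fit")) net <- net$network
  stopifnot(inherits(net, "daunet"))
  buffers <- lapply(net$buffers, function(e)
    list(running_mean = e$running_mean, running_var = e$running_var))
  rng <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  saveRDS(list(config = net$config, params = net$params, buffers = buffers,
               seed = net$seed, rng_state = rng,
               package_version = as.character(utils::packageVersion("daunet"))),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  buf <- lapply(ck$buffers, function(b) {
    e <- new.env(parent = emptyenv())
    e$running_mean <- b$running_mean
    e$running_var <- b$running_var
    e
  })
  structure(list(config = ck$config, params = ck$params, buffers = buf,
                 seed = ck$seed), class = "daunet")
}
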