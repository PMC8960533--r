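# Optimization recipe: plateau schedule, miniature training runs,
# prediction, checkpointing, case evaluation, splitting.

test_that("a frozen metric decays the learning rate after exactly the patience", {
  s <- lr_schedule(1e-3, factor = 0.1, patience = 10L)
  s <- lr_schedule_step(s, 0.5)   # first value establishes the best
  lrs <- numeric(0)
  for (i in 1:10) {
    s <- lr_schedule_step(s, 0.5) # stagnant
    lrs <- c(lrs, s$lr)
  }
  expect_true(all(lrs[1:9] == 1e-3)) # unchanged through 9 stagnant epochs
  expect_equal(lrs[10], 1e-4)        # decay lands on the 10th
  # improvement resets the stagnation counter
  s2 <- lr_schedule(1e-3)
  s2 <- lr_schedule_step(s2, 0.1)
  for (i in 1:9) s2 <- lr_schedule_step(s2, 0.1)
  s2 <- lr_schedule_step(s2, 0.2)
  expect_equal(s2$lr, 1e-3)
  expect_equal(s2$bad, 0L)
})

test_that("the learning-rate trace is a non-increasing step function with x0.1 steps", {
  set.seed(701)
  s <- lr_schedule(1e-3)
  trace <- numeric(0)
  for (i in 1:40) {
    s <- lr_schedule_step(s, runif(1, 0, 0.2 * (i < 5))) # improves then freezes
    trace <- c(trace, s$lr)
  }
  expect_true(all(diff(trace) <= 0))
  ratios <- unique(round(trace[-1] / trace[-length(trace)], 10))
  expect_true(all(ratios %in% c(1, 0.1)))
})

# two tiny phantom cases shared across the training tests
tiny_cases <- local({
  lapply(1:2, function(i) {
    ph <- generate_phantom(phantom_spec(shape = c(24L, 24L, 24L),
                                        vessel_count = 2L,
                                        size_class = "<3mm", seed = 20 + i))
    list(volume = ph$volume, mask = ph$mask, center = ph$center)
  })
})

tiny_tc <- function(epochs = 2L, ...) {
  train_config(epochs = epochs, batch_size = 2L, patch_size = 16L,
               augment = FALSE, seed = 3L, ...)
}

test_that("miniature training runs log epochs and are seed-deterministic", {
  cfg <- mini_config()
  f1 <- train_network(tiny_cases, config = cfg, train_cfg = tiny_tc())
  f2 <- train_network(tiny_cases, config = cfg, train_cfg = tiny_tc())
  expect_equal(nrow(f1$log), 2L)
  expect_identical(f1$log$loss[1], f2$log$loss[1]) # same seed, same first loss
  expect_true(all(is.finite(f1$log$loss)))
  g <- glance(f1)
  expect_identical(g$epochs, 2L)
  expect_s3_class(tidy(f1), "tbl_df")
  expect_error(train_network(list(), config = cfg), "empty")
})

test_that("training descends for a sweep of ablation configurations", {
  flag_sets <- list(
    list(),                                     # full model
    list(use_dense = FALSE),
    list(use_cam = FALSE),
    list(use_sam = FALSE),
    list(use_mfb = FALSE),
    list(use_dense = FALSE, use_cam = FALSE, use_sam = FALSE,
         use_mfb = FALSE),                      # plain U-Net backbone
    list(norm = "bn"),
    list(activation = "relu"))
  for (fl in flag_sets) {
    cfg <- do.call(mini_config, fl)
    fit <- train_network(tiny_cases, config = cfg,
                         train_cfg = tiny_tc(epochs = 4L))
    expect_lt(fit$log$loss[nrow(fit$log)], fit$log$loss[1])
  }
})

test_that("prediction re-embeds the patch at source coordinates", {
  cfg <- mini_config()
  fit <- train_network(tiny_cases, config = cfg, train_cfg = tiny_tc())
  pred <- predict_volume(fit, tiny_cases[[1]]$volume,
                         center = tiny_cases[[1]]$center, patch_size = 16L)
  expect_identical(dim(pred$data), dim(tiny_cases[[1]]$volume$data))
  expect_true(all(pred$data %in% c(0L, 1L)))
  # voxels outside the window stay background
  win_lo <- tiny_cases[[1]]$center - 8L
  outside <- pred$data
  sel <- pmax(win_lo, 1L)
  outside[sel[1]:min(win_lo[1] + 15L, 24L),
          sel[2]:min(win_lo[2] + 15L, 24L),
          sel[3]:min(win_lo[3] + 15L, 24L)] <- 0L
  expect_true(all(outside == 0L))
  expect_error(predict_volume(fit, tiny_cases[[1]]$volume), "center")
})

test_that("argmax uses the strict channel comparison", {
  logits <- array(0, dim = c(2, 2, 2, 2, 1))
  logits[, , , 2, ] <- 1
  expect_true(all(daunet:::.argmax_mask(logits) == 1L))
  logits[, , , 2, ] <- 0 # tie -> background
  expect_true(all(daunet:::.argmax_mask(logits) == 0L))
})

test_that("non-overlapping sliding windows equal stitched per-tile prediction", {
  cfg <- mini_config()
  fit <- train_network(tiny_cases, config = cfg, train_cfg = tiny_tc())
  vol <- new_volume(array(rnorm(32^3, 0.2, 0.1), dim = c(32, 32, 32)),
                    spacing = rep(0.5, 3))
  sw <- predict_volume(fit, vol, sliding_window = TRUE, patch_size = 16L)
  manual <- array(0L, dim = c(32, 32, 32))
  for (sx in c(1L, 17L)) for (sy in c(1L, 17L)) for (sz in c(1L, 17L)) {
    ctr <- c(sx, sy, sz) + 8L
    tile <- predict_volume(fit, vol, center = ctr, patch_size = 16L)
    manual[sx:(sx + 15), sy:(sy + 15), sz:(sz + 15)] <-
      tile$data[sx:(sx + 15), sy:(sy + 15), sz:(sz + 15)]
  }
  expect_identical(sw$data, manual)
})

test_that("checkpoint save/load/predict is bit-identical", {
  cfg <- mini_config()
  fit <- train_network(tiny_cases, config = cfg, train_cfg = tiny_tc())
  before <- predict_volume(fit, tiny_cases[[2]]$volume,
                           center = tiny_cases[[2]]$center, patch_size = 16L)
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(fit, ck)
  restored <- load_checkpoint(ck)
  after <- predict_volume(restored, tiny_cases[[2]]$volume,
                          center = tiny_cases[[2]]$center, patch_size = 16L)
  expect_identical(before$data, after$data)
  # logits themselves are bit-identical, not just the argmax
  z <- zscore_normalize(tiny_cases[[2]]$volume)$volume
  patch <- crop_centered(z, center = tiny_cases[[2]]$center, size = 16L)$volume
  l1 <- net_forward(fit$network, patch)
  l2 <- net_forward(restored, patch)
  expect_identical(l1, l2)
})

test_that("case evaluation scores perfect self-prediction at Dice 1", {
  masks <- lapply(tiny_cases, `[[`, "mask")
  rep_ <- evaluate_masks(masks, masks)
  expect_equal(rep_$summary$dice[rep_$summary$group == "all"], 1)
  # evaluate_cases agrees with per-case confusion arithmetic
  cfg <- mini_config()
  fit <- train_network(tiny_cases, config = cfg, train_cfg = tiny_tc())
  rep2 <- evaluate_cases(fit, tiny_cases, patch_size = 16L)
  for (i in seq_along(tiny_cases)) {
    pred <- predict_volume(fit, tiny_cases[[i]]$volume,
                           center = tiny_cases[[i]]$center, patch_size = 16L)
    cc <- confusion_counts(pred, tiny_cases[[i]]$mask)
    expect_equal(rep2$cases$dice[i], dice_score(cc))
  }
})

test_that("the random split respects the 70/20/23 proportions", {
  sp <- split_cases(113, seed = 4)
  expect_equal(length(sp$train), 70)
  expect_equal(length(sp$val), 20)
  expect_equal(length(sp$test), 23)
  expect_identical(sort(c(sp$train, sp$val, sp$test)), 1:113)
})
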