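# Network assembly: configuration validation, shape contracts, parameter
# accounting, determinism, the fusion head, and gradient flow.

test_that("configuration validation catches inconsistent plans", {
  expect_error(network_config(filters = c(16L, 32L, 64L, 100L)), "double")
  expect_error(network_config(class_count = 3L), "binary")
  expect_error(network_config(input_size = 40L), "multiple of 16")
  expect_error(network_config(filters = c(4L, 8L, 16L, 32L),
                              growth = c(4L, 8L, 16L, 32L),
                              cbam_reduction = 7L), "divisible")
})

test_that("the end-to-end shape contract holds for every ablation configuration", {
  x <- rand5(c(16, 16, 16, 1, 1), seed = 501)
  for (flags in expand.grid(dense = c(TRUE, FALSE), cam = c(TRUE, FALSE),
                            sam = c(TRUE, FALSE), mfb = c(TRUE, FALSE)) |>
         asplit(1)) {
    cfg <- mini_config(use_dense = flags[["dense"]], use_cam = flags[["cam"]],
                       use_sam = flags[["sam"]], use_mfb = flags[["mfb"]])
    net <- build_network(cfg, seed = 1)
    y <- net_forward(net, x)
    expect_identical(dim(y), c(16L, 16L, 16L, 2L, 1L))
    expect_true(all(is.finite(y)))
  }
})

test_that("norm and activation ablation variants also keep the shape contract", {
  x <- rand5(c(16, 16, 16, 1, 2), seed = 502)
  for (cfg in list(mini_config(norm = "bn"), mini_config(activation = "relu"))) {
    y <- net_forward(build_network(cfg, seed = 1), x)
    expect_identical(dim(y), c(16L, 16L, 16L, 2L, 2L))
  }
})

test_that("a batch of 8 passes through the network", {
  x <- rand5(c(16, 16, 16, 1, 8), seed = 503)
  y <- net_forward(build_network(mini_config(), seed = 1), x)
  expect_identical(dim(y), c(16L, 16L, 16L, 2L, 8L))
})

test_that("wrong input shapes raise descriptive errors", {
  net <- build_network(mini_config(), seed = 1)
  expect_error(net_forward(net, rand5(c(15, 15, 15, 1, 1))), "multiple of 16")
  expect_error(net_forward(net, rand5(c(16, 16, 16, 2, 1))), "channels")
})

test_that("the architecture table reports the doubling/halving layer plan", {
  net <- build_network(mini_config(input_size = 32L), seed = 1)
  tab <- describe_network(net)
  expect_identical(tab$layer,
                   c("Layerin1", "Layerin2", "Layerin3", "Bottom",
                     "Trans1", "Trans2", "Trans3", "MFB", "CBAM", "Output"))
  expect_identical(tab$input[1:7],
                   c("1 x 32 x 32 x 32", "4 x 16 x 16 x 16", "8 x 8 x 8 x 8",
                     "16 x 4 x 4 x 4", "32 x 2 x 2 x 2", "16 x 4 x 4 x 4",
                     "8 x 8 x 8 x 8"))
  expect_identical(sum(tab$parameters), count_parameters(net))
})

test_that("parameter counting is structural", {
  # a single bias-free 1-in/1-out 3^3 convolution holds 27 scalars
  expect_identical(length(daunet:::.init_conv_w(3L, 1L, 1L)), 27L)
  n1 <- count_parameters(build_network(mini_config(), seed = 1))
  n2 <- count_parameters(build_network(mini_config(), seed = 99))
  expect_identical(n1, n2) # invariant to weight values
})

test_that("each ablation switch strictly reduces the parameter count", {
  full <- count_parameters(build_network(mini_config(), seed = 1))
  for (drop in c("use_dense", "use_cam", "use_sam", "use_mfb")) {
    args <- list(); args[[drop]] <- FALSE
    n <- count_parameters(build_network(do.call(mini_config, args), seed = 1))
    expect_lt(n, full)
  }
})

test_that("building and inference are deterministic", {
  n1 <- build_network(mini_config(), seed = 5)
  n2 <- build_network(mini_config(), seed = 5)
  expect_identical(n1$params, n2$params)
  x <- rand5(c(16, 16, 16, 1, 1), seed = 504)
  y1 <- net_forward(n1, x)
  y2 <- net_forward(n1, x)
  expect_identical(y1, y2) # bit-exact inference determinism
})

test_that("the fusion head accepts the three decoder maps and fuses to logits", {
  cfg <- mini_config(input_size = 32L)
  net <- build_network(cfg, seed = 6)
  maps <- list(rand5(c(4, 4, 4, 16, 1), seed = 61),
               rand5(c(8, 8, 8, 8, 1)),
               rand5(c(16, 16, 16, 4, 1)))
  out <- multiscale_fusion(net, maps)
  expect_identical(dim(out), c(32L, 32L, 32L, 2L, 1L))
  expect_error(multiscale_fusion(net, rev(maps)), "channels")
  # constant maps stay constant through the trilinear resampling step
  k <- array(2, dim = c(4, 4, 4, 16, 1))
  up <- daunet:::ag_upsample(k, c(32L, 32L, 32L))
  expect_true(all(abs(up - 2) < 1e-12))
})

test_that("one optimization step touches every trainable tensor", {
  cfg <- mini_config()
  net <- build_network(cfg, seed = 7)
  set.seed(505)
  x <- rand5(c(16, 16, 16, 1, 2))
  fg <- array(runif(16^3 * 2) < 0.05, dim = c(16, 16, 16, 2))
  q <- array(0, dim = c(16, 16, 16, 2, 2))
  q[, , , 2, ] <- fg * 1; q[, , , 1, ] <- 1 - fg
  pn <- lapply(net$params, daunet:::ag_leaf)
  loss <- daunet:::ag_segmentation_loss(
    net_forward(net, x, training = TRUE, params = pn), q)
  daunet:::ag_backward(loss)
  gmax <- vapply(pn, function(nd)
    if (is.null(nd$grad)) 0 else max(abs(nd$grad)), numeric(1))
  expect_true(all(gmax > 0)) # no dead branch
})
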