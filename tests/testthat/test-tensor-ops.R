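# The compiled tensor kernels against naive loop oracles, and the
# reverse-mode gradients against central finite differences.

test_that("3D convolution matches the loop oracle for several kernel sizes", {
  set.seed(101)
  cases <- list(
    list(d = c(4L, 4L, 4L, 2L, 2L), ci = 2L, co = 3L, k = 3L),
    list(d = c(5L, 3L, 4L, 3L, 1L), ci = 3L, co = 2L, k = 3L),
    list(d = c(3L, 3L, 3L, 2L, 2L), ci = 2L, co = 4L, k = 1L),
    list(d = c(4L, 4L, 4L, 2L, 1L), ci = 2L, co = 1L, k = 7L))
  for (cs in cases) {
    x <- rand5(cs$d)
    w <- array(rnorm(cs$k^3 * cs$ci * cs$co),
               dim = c(cs$k, cs$k, cs$k, cs$ci, cs$co))
    b <- rnorm(cs$co)
    got <- daunet:::ag_conv3(x, w, b, k = cs$k)
    want <- oracle_conv3(x, w, b)
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("transposed convolution doubles spatial dims and is the conv adjoint", {
  set.seed(102)
  x <- rand5(c(3, 3, 3, 2, 2))
  w <- array(rnorm(27 * 3 * 2), dim = c(3, 3, 3, 3, 2))
  b <- rnorm(3)
  y <- daunet:::ag_convt3(x, w, b)
  expect_identical(dim(y), c(6L, 6L, 6L, 3L, 2L))
  # adjoint identity: <convT(x), dy> - <b, colsum(dy)> == <x, conv_s2(dy)>
  dy <- rand5(dim(y))
  dx <- daunet:::cpp_conv3_fwd(dy, as.integer(dim(y)), w, numeric(2), 2L,
                               3L, 1L, 2L)
  lhs <- sum(y * dy) - sum(b * apply(dy, 4, sum))
  rhs <- sum(x * dx)
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-12)
})

test_that("2^3 average pooling halves dims and averages checkerboards to 0.5", {
  # alternating 0/1 along depth: every 2^3 cell holds four 0s and four 1s
  x <- array(rep(c(0, 1), 32), dim = c(4, 4, 4, 1, 1))
  y <- daunet:::ag_avgpool2(x)
  expect_identical(dim(y), c(2L, 2L, 2L, 1L, 1L))
  expect_true(all(y == 0.5))
  set.seed(103)
  x2 <- rand5(c(4, 6, 4, 3, 2))
  y2 <- daunet:::ag_avgpool2(x2)
  expect_equal(y2[1, 1, 1, 2, 2], mean(x2[1:2, 1:2, 1:2, 2, 2]))
  expect_equal(y2[2, 3, 1, 1, 1], mean(x2[3:4, 5:6, 1:2, 1, 1]))
})

test_that("trilinear upsampling matches the per-voxel weight oracle", {
  set.seed(104)
  # one hot voxel, 2^3 -> 4^3 (the worked example geometry)
  x <- array(0, dim = c(2, 2, 2, 1, 1))
  x[1, 1, 1, 1, 1] <- 1
  got <- daunet:::ag_upsample(x, c(4L, 4L, 4L))
  want <- oracle_upsample(x, c(4L, 4L, 4L))
  expect_lt(max(abs(got - want)), 1e-12)
  # non-integer scale and multi-channel
  x2 <- rand5(c(3, 2, 4, 2, 2))
  got2 <- daunet:::ag_upsample(x2, c(5L, 7L, 6L))
  want2 <- oracle_upsample(x2, c(5L, 7L, 6L))
  expect_lt(max(abs(got2 - want2)), 1e-12)
  # constants stay constant
  xc <- array(3.25, dim = c(2, 2, 2, 1, 1))
  expect_true(all(abs(daunet:::ag_upsample(xc, c(6L, 6L, 6L)) - 3.25) < 1e-12))
})

# Central finite differences for a scalar-valued function of one input.
numgrad <- function(f, x, idx, eps = 1e-6) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

test_that("autograd gradients match finite differences per operator", {
  set.seed(105)
  dims <- c(3, 3, 3, 4, 2)
  x0 <- rand5(dims)
  probe <- sample(length(x0), 5)
  run <- function(fwd) {
    leaf <- daunet:::ag_leaf(x0)
    out <- fwd(leaf)
    daunet:::ag_backward(out, seed_grad = 1)
    f <- function(xv) daunet:::ag_value(fwd(xv))
    expect_lt(max(abs(leaf$grad[probe] - numgrad(f, x0, probe))), 1e-5)
  }
  w <- array(rnorm(27 * 4 * 2), dim = c(3, 3, 3, 4, 2))
  b <- rnorm(2)
  wt <- array(rnorm(27 * 3 * 4), dim = c(3, 3, 3, 3, 4))
  gate_c <- array(runif(4 * 2), dim = c(1, 1, 1, 4, 2))
  gate_s <- array(runif(27 * 2), dim = c(3, 3, 3, 1, 2))
  gamma <- rnorm(4, 1, 0.1); beta <- rnorm(4, 0, 0.1)
  red <- function(y) {
    # fixed random projection to a scalar, so every element matters
    set.seed(9); pr <- rnorm(length(daunet:::ag_value(y)))
    daunet:::ag_make(sum(daunet:::ag_value(y) * pr), list(y),
                     list(function(dy) array(dy * pr,
                                             dim = dim(daunet:::ag_value(y)))))
  }
  run(function(z) red(daunet:::ag_conv3(z, w, b, k = 3L)))
  run(function(z) red(daunet:::ag_convt3(z, wt, numeric(3))))
  run(function(z) red(daunet:::ag_upsample(z, c(5L, 4L, 6L))))
  run(function(z) red(daunet:::ag_gap(z)))
  run(function(z) red(daunet:::ag_gmp(z)))
  run(function(z) red(daunet:::ag_cmean(z)))
  run(function(z) red(daunet:::ag_cmax(z)))
  run(function(z) red(daunet:::ag_sigmoid(z)))
  run(function(z) red(daunet:::ag_mul_gate(z, gate_c)))
  run(function(z) red(daunet:::ag_mul_gate(z, gate_s)))
  run(function(z) red(daunet:::ag_gn(z, gamma, beta, groups = 4L)))
  run(function(z) red(daunet:::ag_bn(z, gamma, beta, daunet::new_bn_state(4),
                                     training = TRUE)))
  run(function(z) red(daunet:::ag_concat(list(z, z))))
  # pooling needs even spatial dims
  x0 <- rand5(c(4, 4, 4, 2, 2))
  probe <- sample(length(x0), 5)
  run(function(z) red(daunet:::ag_avgpool2(z)))
})

test_that("weight and gate gradients also match finite differences", {
  set.seed(106)
  x <- rand5(c(3, 3, 3, 2, 2))
  w0 <- array(rnorm(27 * 2 * 3), dim = c(3, 3, 3, 2, 3))
  probe <- sample(length(w0), 4)
  leaf <- daunet:::ag_leaf(w0)
  out <- daunet:::ag_conv3(x, leaf, numeric(3), k = 3L)
  set.seed(9); pr <- rnorm(length(daunet:::ag_value(out)))
  s <- daunet:::ag_make(sum(daunet:::ag_value(out) * pr), list(out),
                        list(function(dy) array(dy * pr, dim = dim(daunet:::ag_value(out)))))
  daunet:::ag_backward(s)
  f <- function(wv) {
    y <- daunet:::ag_conv3(x, wv, numeric(3), k = 3L)
    sum(y * pr)
  }
  expect_lt(max(abs(leaf$grad[probe] - numgrad(f, w0, probe))), 1e-5)
})

test_that("the fused segmentation loss matches the composed plain losses and its gradient checks out", {
  set.seed(107)
  z <- rand5(c(3, 3, 3, 2, 2))
  fg <- array(runif(27 * 2) < 0.3, dim = c(3, 3, 3, 2))
  q <- array(0, dim = c(3, 3, 3, 2, 2))
  q[, , , 2, ] <- fg * 1
  q[, , , 1, ] <- 1 - fg
  leaf <- daunet:::ag_leaf(z)
  loss <- daunet:::ag_segmentation_loss(leaf, q, alpha = 0.7, smooth = 1e-5)
  # value: softmax(z) through the plain-array compound loss
  softmax5 <- function(z) {
    p <- z
    for (b in 1:2) for (i in 1:3) for (j in 1:3) for (k in 1:3) {
      e <- exp(z[i, j, k, , b] - max(z[i, j, k, , b]))
      p[i, j, k, , b] <- e / sum(e)
    }
    p
  }
  expect_equal(daunet:::ag_value(loss),
               combined_loss(softmax5(z), q, alpha = 0.7, smooth = 1e-5),
               tolerance = 1e-10)
  daunet:::ag_backward(loss)
  probe <- sample(length(z), 6)
  f <- function(zv) combined_loss(softmax5(zv), q, alpha = 0.7, smooth = 1e-5)
  expect_lt(max(abs(leaf$grad[probe] - numgrad(f, z, probe))), 1e-6)
})
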