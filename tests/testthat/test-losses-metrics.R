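# Dice / compound losses and the four evaluation metrics.

test_that("the Dice loss follows direct substitution into its formula", {
  q <- array(0, dim = c(4, 4, 4))
  q[1:2, 1, 1] <- 1; q[3:4, 2, 1] <- 1      # 4 foreground voxels
  # perfect one-hot prediction: L = 1 - 8 / (8 + e)
  expect_equal(dice_loss(q, q, smooth = 1e-5), 1 - 8 / (8 + 1e-5),
               tolerance = 1e-12)
  # disjoint prediction
  p <- array(0, dim = c(4, 4, 4)); p[1:4, 4, 4] <- 1
  expect_equal(dice_loss(p, q, smooth = 1e-5),
               1 - 0 / (4 + 4 + 1e-5), tolerance = 1e-12)
  # empty vs empty: the literal formula returns 1 - 0/e = 1
  z <- array(0, dim = c(4, 4, 4))
  expect_equal(dice_loss(z, z), 1)
  # soft probabilities against the formula
  set.seed(601)
  ps <- array(runif(64), dim = c(4, 4, 4))
  expect_equal(dice_loss(ps, q, smooth = 1e-5),
               1 - 2 * sum(ps * q) / (sum(ps) + sum(q) + 1e-5),
               tolerance = 1e-12)
  expect_error(dice_loss(ps, array(0, dim = c(3, 3, 3))), "differ")
})

test_that("the compound loss recombines its parts with weights 0.3 and 0.7", {
  set.seed(602)
  d <- c(3, 3, 3, 2, 2)
  raw <- array(runif(prod(d)) + 0.05, dim = d)
  p <- raw
  p[, , , 1, ] <- raw[, , , 1, ] / (raw[, , , 1, ] + raw[, , , 2, ])
  p[, , , 2, ] <- 1 - p[, , , 1, ]
  fg <- array(runif(27 * 2) < 0.3, dim = c(3, 3, 3, 2))
  q <- array(0, dim = d)
  q[, , , 2, ] <- fg * 1; q[, , , 1, ] <- 1 - fg
  ce <- -sum(q * log(p)) / (27 * 2)
  expect_equal(combined_loss(p, q, alpha = 0.7),
               0.3 * dice_loss(p, q) + 0.7 * ce, tolerance = 1e-12)
  # perfect one-hot prediction: both terms at their minimum
  expect_lt(combined_loss(q, q), 1e-6)
  # monotone in each component at fixed alpha
  worse <- p
  worse[, , , 2, ] <- p[, , , 2, ] * 0.5
  worse[, , , 1, ] <- 1 - worse[, , , 2, ]
  expect_gt(combined_loss(worse, q), combined_loss(p, q) - 1e-9)
  expect_error(combined_loss(p, q, alpha = 1.2), "alpha")
})

test_that("confusion counts follow set arithmetic and honour the ignore label", {
  z <- array(0L, dim = c(10, 10, 10))
  cc <- confusion_counts(z, z)
  expect_identical(c(cc$TP, cc$FP, cc$FN, cc$TN), c(0L, 0L, 0L, 1000L))
  pred <- z; truth <- z
  truth[1:10, 1, 1] <- 1L         # 10 true foreground
  pred[3:12] <- 1L                # 10 predicted, 8 overlapping
  cc2 <- confusion_counts(pred, truth)
  expect_identical(c(cc2$TP, cc2$FP, cc2$FN), c(8L, 2L, 2L))
  # truth label 2 is excluded from every count
  t3 <- truth; t3[5, 5, 5:9] <- 2L
  cc3 <- confusion_counts(pred, t3, ignore_label = 2)
  expect_identical(cc3$n, 1000L - 5L)
  expect_identical(cc3$TP, 8L)
  expect_error(confusion_counts(pred, t3), "not binary")
  p3 <- pred; p3[1] <- 3L
  expect_error(confusion_counts(p3, truth), "\\{3\\}")
})

test_that("the four scores match hand arithmetic and the degenerate policy", {
  cc <- structure(list(TP = 8, FP = 2, FN = 2, TN = 988, n = 1000),
                  class = "confusion_counts")
  expect_equal(dice_score(cc), 0.8)
  expect_equal(sensitivity(cc), 0.8)
  expect_equal(specificity(cc), 988 / 990)
  expect_equal(precision(cc), 0.8)
  perfect <- structure(list(TP = 50, FP = 0, FN = 0, TN = 950, n = 1000),
                       class = "confusion_counts")
  expect_true(all(c(dice_score(perfect), sensitivity(perfect),
                    specificity(perfect), precision(perfect)) == 1))
  empty <- structure(list(TP = 0, FP = 0, FN = 0, TN = 1000, n = 1000),
                     class = "confusion_counts")
  expect_equal(dice_score(empty), 1)
  expect_equal(sensitivity(empty), 1)
  expect_equal(precision(empty), 1)
  miss <- structure(list(TP = 0, FP = 0, FN = 10, TN = 990, n = 1000),
                    class = "confusion_counts")
  expect_equal(dice_score(miss), 0)
  expect_equal(precision(miss), 0) # empty prediction vs non-empty truth
})

test_that("self-comparison gives Dice 1 and hard-field losses agree with scores", {
  set.seed(603)
  for (i in 1:5) {
    m <- array(as.integer(runif(6^3) < 0.2), dim = c(6, 6, 6))
    if (sum(m) == 0) m[1] <- 1L
    expect_equal(dice_score(confusion_counts(m, m)), 1)
    p <- array(as.integer(runif(6^3) < 0.2), dim = c(6, 6, 6))
    expect_equal(1 - dice_loss(p * 1, m * 1, smooth = 1e-9),
                 dice_score(confusion_counts(p, m)), tolerance = 1e-6)
  }
})

test_that("metrics are invariant under a common spatial permutation", {
  set.seed(604)
  p <- array(as.integer(runif(5^3) < 0.3), dim = c(5, 5, 5))
  t <- array(as.integer(runif(5^3) < 0.3), dim = c(5, 5, 5))
  perm <- sample(5)
  cc1 <- confusion_counts(p, t)
  cc2 <- confusion_counts(p[perm, , ], t[perm, , ])
  expect_identical(unclass(cc1), unclass(cc2))
})

test_that("case evaluation averages without weighting and stratifies by size", {
  m1 <- new_label_mask(array(0L, dim = c(8, 8, 8)), spacing = c(0.5, 0.5, 0.5))
  m1$data[3:5, 3:5, 3:5] <- 1L   # 27 voxels -> d = 2*(3*27*0.125/(4pi))^(1/3)
  m2 <- new_label_mask(array(0L, dim = c(8, 8, 8)), spacing = c(0.5, 0.5, 0.5))
  m2$data[2:4, 2:4, 2:4] <- 1L
  empty <- new_label_mask(array(0L, dim = c(8, 8, 8)), spacing = rep(0.5, 3))
  rep_ <- evaluate_masks(list(m1, empty), list(m1, m2))
  expect_equal(rep_$cases$dice, c(1, 0))
  expect_equal(rep_$summary$dice[rep_$summary$group == "all"], 0.5)
  d_expect <- 2 * (3 * 27 * 0.125 / (4 * pi))^(1 / 3)
  expect_equal(rep_$cases$diameter_mm[1], d_expect, tolerance = 1e-12)
  expect_identical(rep_$cases$size_class[1], "<3mm")
  # degenerate empty-vs-empty case is flagged and scored 1
  rep2 <- evaluate_masks(list(empty), list(empty))
  expect_true(rep2$cases$degenerate[1])
  expect_equal(rep2$cases$dice[1], 1)
  expect_error(evaluate_masks(list(m1), list(m1, m2)), "unpaired")
})

test_that("size classes split at 3 and 7 mm", {
  expect_identical(as.character(lesion_size_class(c(1, 2.99, 3, 5, 7, 7.01, 12))),
                   c("<3mm", "<3mm", "3-7mm", "3-7mm", "3-7mm", ">7mm", ">7mm"))
})

test_that("metrics reports write to CSV and JSON", {
  m <- new_label_mask(array(c(0L, 1L), dim = c(2, 2, 2)))
  rep_ <- evaluate_masks(list(m), list(m))
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_metrics(rep_, csv_path = csv, json_path = js)
  expect_equal(nrow(readr::read_csv(csv, show_col_types = FALSE)), 1L)
  expect_equal(jsonlite::read_json(js)$summary[[1]]$dice, 1)
})
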