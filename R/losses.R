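# ---------------------------------------------------------------------------
# Dice loss, compound Dice + cross-entropy loss.
# ---------------------------------------------------------------------------

# Promote a foreground-probability 3D/4D field to a rank-5 two-class
# probability array (background = 1 - p in channel 1, foreground in
# channel 2).
.to_prob5 <- function(p) {
  d <- dim(p)
  if (is.null(d)) d <- length(p)
  if (length(d) == 5L) return(p)
  if (length(d) == 3L) {
    out <- array(0, dim = c(d, 2L, 1L))
    out[, , , 1L, 1L] <- 1 - p
    out[, , , 2L, 1L] <- p
    return(out)
  }
  stop("expected a 3D foreground field or a rank-5 class-probability array")
}

#' Soft Dice loss
#'
#' `L = 1 - 2 * sum(p * q) / (sum(p) + sum(q) + smooth)`, with the sums
#' taken over the foreground class's voxels. The smoothing constant keeps
#' the denominator (and the gradient) finite; note that for an empty
#' prediction against an empty truth the literal formula returns 1, a
#' degenerate case the evaluation metrics (not the loss) score as 1.0.
#'
#' @param p predicted probabilities: a rank-5 array (D, H, W, classes, B)
#'   whose last channel is the foreground, or a 3D foreground-probability
#'   field.
#' @param q ground truth in the same layout (one-hot over classes, or a 3D
#'   binary field).
#' @param smooth small positive smoothing constant (default 1e-5).
#' @param mode `"foreground"` (default; the binary task) or `"mean"`, the
#'   per-class average used for label-2-aware experiments.
#' @return scalar loss in \[0, 1\].
#' @export
dice_loss <- function(p, q, smooth = 1e-5, mode = c("foreground", "mean")) {
  mode <- match.arg(mode)
  if (smooth <= 0) stop("smooth must be > 0")
  p <- .to_prob5(p); q <- .to_prob5(q)
  if (!identical(dim(p), dim(q)))
    stop("prediction and truth shapes differ: ",
         paste(dim(p), collapse = "x"), " vs ", paste(dim(q), collapse = "x"))
  C <- dim(p)[4]
  one_class <- function(k) {
    pk <- p[, , , k, , drop = FALSE]
    qk <- q[, , , k, , drop = FALSE]
    1 - 2 * sum(pk * qk) / (sum(pk) + sum(qk) + smooth)
  }
  if (mode == "foreground") one_class(C) else mean(vapply(seq_len(C),
                                                          one_class, 0))
}

#' Compound Dice + cross-entropy loss
#'
#' `L = (1 - alpha) * L_dice + alpha * L_CE` with `alpha = 0.7` by default,
#' i.e. weights 0.3 and 0.7 on the Dice and cross-entropy terms. `L_CE` is
#' the voxel-averaged cross-entropy in the standard orientation — the
#' truth-weighted negative log of the predicted probability (the
#' transposed orientation is undefined for one-hot truth, where it takes
#' the log of exact zeros).
#'
#' @inheritParams dice_loss
#' @param alpha cross-entropy weight in \[0, 1\].
#' @return scalar loss.
#' @export
combined_loss <- function(p, q, alpha = 0.7, smooth = 1e-5) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  p5 <- .to_prob5(p); q5 <- .to_prob5(q)
  if (!identical(dim(p5), dim(q5)))
    stop("prediction and truth shapes differ: ",
         paste(dim(p5), collapse = "x"), " vs ",
         paste(dim(q5), collapse = "x"))
  nvox <- prod(dim(p5)[c(1:3, 5)])
  ce <- -sum(q5 * log(pmax(p5, 1e-300))) / nvox
  (1 - alpha) * dice_loss(p5, q5, smooth) + alpha * ce
}
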