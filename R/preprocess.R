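# ---------------------------------------------------------------------------
# Patch-based preprocessing: z-score normalization, aneurysm-centred
# cropping, flip/intensity augmentation, and label binarization.
# ---------------------------------------------------------------------------

#' Z-score normalize a volume
#'
#' Standardizes intensities to mean 0 and population standard deviation 1
#' (the divisor is n, not n-1, so the normalized sample itself has unit
#' standard deviation). The statistics are returned for inversion and
#' reporting.
#'
#' @param vol an [new_volume()] object or a plain numeric array.
#' @return list with `volume` (same type as the input) and `stats`, a list
#'   with `mu` and `sigma`.
#' @export
zscore_normalize <- function(vol) {
  x <- .vol_data(vol)
  if (length(x) < 2L) stop("z-score normalization needs at least 2 voxels")
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma == 0)
    stop("zero variance: constant volume cannot be z-score normalized")
  z <- (x - mu) / sigma
  out <- if (inherits(vol, "mra_volume")) new_volume(z, vol$spacing) else z
  list(volume = out, stats = list(mu = mu, sigma = sigma))
}

# Extract a cubic window of edge `size` centred at `center` (1-based voxel
# index), low-inclusive: axis i covers indices center[i]-size/2 ..
# center[i]+size/2-1. Voxels outside the source are filled with `fill`.
.pad_crop <- function(arr, center, size, fill = 0) {
  d <- dim(arr)
  lo <- center - size %/% 2L           # first index, 1-based
  out <- array(fill, dim = rep(size, 3L))
  src_lo <- pmax(lo, 1L)
  src_hi <- pmin(lo + size - 1L, d)
  if (any(src_lo > src_hi)) return(out)
  dst_lo <- src_lo - lo + 1L
  dst_hi <- src_hi - lo + 1L
  out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
    arr[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
  out
}

#' Crop an aneurysm-centred cubic patch
#'
#' Extracts a `size`^3 patch centred on `center` from a volume and (if
#' given) its mask. The window on each axis is the low-inclusive span
#' `[center - size/2, center + size/2 - 1]` in 1-based voxel indices;
#' voxels falling outside the source are zero-filled (intensity 0,
#' label 0). Spacing is preserved.
#'
#' @param vol an [new_volume()] object (or plain array).
#' @param mask optional matching [new_label_mask()] (or plain array).
#' @param center integer length-3, 1-based voxel index; must lie inside the
#'   volume.
#' @param size patch edge length in voxels; positive and even (default 64).
#' @return list with `volume` and (when a mask was supplied) `mask`.
#' @export
crop_centered <- function(vol, mask = NULL, center, size = 64L) {
  x <- .vol_data(vol)
  d <- dim(x)
  center <- as.integer(round(center))
  size <- as.integer(size)
  if (size <= 0L || size %% 2L != 0L)
    stop("crop size must be positive and even, got ", size)
  if (length(center) != 3L || any(center < 1L) || any(center > d))
    stop("crop center (", paste(center, collapse = ", "),
         ") lies outside the volume bounds (", paste(d, collapse = " x "), ")")
  vout <- .pad_crop(x, center, size, fill = 0)
  res <- list(volume = if (inherits(vol, "mra_volume"))
    new_volume(vout, vol$spacing) else vout)
  if (!is.null(mask)) {
    mdat <- .vol_data(mask)
    if (!identical(dim(mdat), d))
      stop("volume and mask shapes differ: ", paste(d, collapse = "x"),
           " vs ", paste(dim(mdat), collapse = "x"))
    mout <- .pad_crop(mdat, center, size, fill = 0L)
    res$mask <- if (inherits(mask, "label_mask"))
      new_label_mask(mout, mask$spacing) else mout
  }
  res
}

#' Augmentation settings
#'
#' @param intensity_offset half-width of the uniform intensity offset added
#'   to the (normalized) volume; the draw is uniform in
#'   `[-intensity_offset, +intensity_offset]` unless `fixed_offset = TRUE`,
#'   in which case the constant `+intensity_offset` is added. Default 0.1.
#' @param flip_probability probability of mirroring each spatial axis,
#'   independently. Default 0.5.
#' @param fixed_offset use the fixed (non-random) offset mode.
#' @param seed optional integer; when given, the draw sequence is seeded so
#'   the augmentation is reproducible.
#' @return a list of class `augment_spec`.
#' @export
augment_spec <- function(intensity_offset = 0.1, flip_probability = 0.5,
                         fixed_offset = FALSE, seed = NULL) {
  if (flip_probability < 0 || flip_probability > 1)
    stop("flip_probability must lie in [0, 1]")
  if (intensity_offset < 0) stop("intensity_offset must be >= 0")
  structure(list(intensity_offset = intensity_offset,
                 flip_probability = flip_probability,
                 fixed_offset = isTRUE(fixed_offset), seed = seed),
            class = "augment_spec")
}

.flip_axis <- function(a, axis) {
  idx <- rep(list(quote(expr = )), 3L)
  idx[[axis]] <- rev(seq_len(dim(a)[axis]))
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

#' Randomly flip and intensity-shift a volume/mask pair
#'
#' Each spatial axis is independently mirrored with probability
#' `flip_probability`; the mask is flipped identically. A single intensity
#' offset draw (uniform in the +/- `intensity_offset` band, or the fixed
#' constant) is added to the volume only — label values are never altered.
#' With a `seed` in the spec the output is fully reproducible. The RNG draw
#' order is fixed: three flip draws (depth, height, width), then the offset.
#'
#' @param vol volume (object or array), typically already z-score
#'   normalized.
#' @param mask matching label mask (object or array).
#' @param spec an [augment_spec()].
#' @return list with `volume`, `mask`, and `draws` (the realized flips and
#'   offset).
#' @export
augment_case <- function(vol, mask, spec = augment_spec()) {
  x <- .vol_data(vol)
  m <- .vol_data(mask)
  if (!identical(dim(x), dim(m)))
    stop("volume and mask shapes differ: ", paste(dim(x), collapse = "x"),
         " vs ", paste(dim(m), collapse = "x"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  flips <- runif(3) < spec$flip_probability
  offset <- if (spec$fixed_offset) spec$intensity_offset else
    runif(1, -spec$intensity_offset, spec$intensity_offset)
  for (ax in which(flips)) {
    x <- .flip_axis(x, ax)
    m <- .flip_axis(m, ax)
  }
  x <- x + offset
  list(volume = if (inherits(vol, "mra_volume")) new_volume(x, vol$spacing) else x,
       mask = if (inherits(mask, "label_mask")) new_label_mask(m, mask$spacing) else m,
       draws = list(flips = flips, offset = offset))
}

#' Collapse treated-aneurysm labels for binary training
#'
#' Maps label 2 (treated aneurysm) to 0 so training sees the binary task
#' background-vs-untreated-aneurysm; label 1 is preserved. Excluding
#' truth-2 voxels from evaluation instead is available through the
#' `ignore_label` argument of [confusion_counts()] / [evaluate_masks()].
#'
#' @param mask a [new_label_mask()] object or plain array.
#' @return same type as the input, with values in \{0, 1\}.
#' @export
binarize_labels <- function(mask) {
  m <- .vol_data(mask)
  m[m == 2L] <- 0L
  if (inherits(mask, "label_mask")) new_label_mask(m, mask$spacing) else m
}
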