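# ---------------------------------------------------------------------------
# Volume and label-mask containers + NIfTI input/output.
#
# Axis convention: the 3D array axes are used in the order (depth, height,
# width) throughout the package. NIfTI images are read with RNifti and their
# (i, j, k) array axes are taken as (depth, height, width) in that order —
# a pure naming convention, no permutation is applied, and the voxel spacing
# travels with the object.
# ---------------------------------------------------------------------------

#' Construct a 3D intensity volume
#'
#' A volume is the unit the whole pipeline moves: a 3D scalar intensity grid
#' (arbitrary MRA units) together with its per-axis voxel spacing in mm.
#'
#' @param data 3D numeric array of voxel intensities; must be finite.
#' @param spacing numeric length-3, voxel size in mm per axis (strictly
#'   positive).
#' @return An object of class `mra_volume` with elements `data` and
#'   `spacing`.
#' @export
new_volume <- function(data, spacing = c(1, 1, 1)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("a volume must be a 3D array, got ", length(dim(data)), " dimensions")
  if (any(dim(data) < 1L)) stop("all volume dimensions must be >= 1")
  if (!all(is.finite(data)))
    stop("volume contains non-finite values (NA/NaN/Inf)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values (mm)")
  structure(list(data = data, spacing = spacing), class = "mra_volume")
}

#' Construct a voxel label mask
#'
#' Ground-truth and predicted segmentations share one container: a 3D
#' integer grid over the label set \{0, 1, 2\} (0 background, 1 untreated
#' unruptured aneurysm, 2 treated aneurysm), aligned with its volume.
#'
#' @param data 3D array of integer labels in \{0, 1, 2\}.
#' @param spacing voxel size in mm per axis.
#' @return An object of class `label_mask`.
#' @export
new_label_mask <- function(data, spacing = c(1, 1, 1)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("a label mask must be a 3D array, got ", length(dim(data)),
         " dimensions")
  vals <- unique(as.vector(data))
  bad <- setdiff(vals, c(0, 1, 2))
  if (length(bad) > 0)
    stop("label mask contains values outside {0, 1, 2}: {",
         paste(sort(bad), collapse = ", "), "}")
  storage.mode(data) <- "integer"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three strictly positive values (mm)")
  structure(list(data = data, spacing = spacing), class = "label_mask")
}

#' @export
print.mra_volume <- function(x, ...) {
  cat("<mra_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  cat("  intensity range [", signif(min(x$data), 4), ", ",
      signif(max(x$data), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  tab <- table(x$data)
  cat("<label_mask> ", paste(dim(x$data), collapse = " x "),
      " voxels, labels: ",
      paste(names(tab), "=", as.integer(tab), collapse = ", "), "\n", sep = "")
  invisible(x)
}

.read_nifti_array <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img2 <- array(as.numeric(img), dim = d[1:3])
    sp <- RNifti::pixdim(img)[1:3]
    return(list(data = img2, spacing = sp))
  }
  if (length(d) != 3L)
    stop("expected a 3D NIfTI image, got ", length(d), " dimensions in ", path)
  list(data = array(as.numeric(img), dim = d), spacing = RNifti::pixdim(img))
}

#' Read a volume or label mask from NIfTI
#'
#' Reads a `.nii` / `.nii.gz` file. `read_volume()` errors on non-finite
#' voxels; `read_mask()` validates the label set against \{0, 1, 2\} and
#' names any offending values in its error message.
#'
#' @param path path to a NIfTI-1 file.
#' @return `read_volume()` an [new_volume()] object; `read_mask()` a
#'   [new_label_mask()] object.
#' @export
read_volume <- function(path) {
  r <- .read_nifti_array(path)
  new_volume(r$data, r$spacing)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  r <- .read_nifti_array(path)
  new_label_mask(round(r$data), r$spacing)
}

#' Write a volume or label mask to NIfTI
#'
#' @param x an `mra_volume` or `label_mask`.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return the path, invisibly.
#' @export
write_volume <- function(x, path) {
  dat <- x$data
  attr(dat, "pixdim") <- x$spacing
  RNifti::writeNifti(RNifti::asNifti(dat), path)
  invisible(path)
}

#' @rdname write_volume
#' @export
write_mask <- function(x, path) {
  dat <- x$data
  attr(dat, "pixdim") <- x$spacing
  RNifti::writeNifti(RNifti::asNifti(dat), path, datatype = "int16")
  invisible(path)
}

.vol_data <- function(x) if (inherits(x, c("mra_volume", "label_mask"))) x$data else x
.vol_spacing <- function(x, default = c(1, 1, 1)) {
  if (inherits(x, c("mra_volume", "label_mask"))) x$spacing else default
}
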