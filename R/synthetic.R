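# ---------------------------------------------------------------------------
# Synthetic TOF-MRA-like vascular phantoms: a dark noisy background, bright
# tubular vessels (smooth random-walk centrelines dilated to tubes), and a
# bright near-spherical aneurysm bulge attached tangent to a vessel. The
# ground-truth mask covers the bulge only, so the task the phantoms pose is
# aneurysm-only segmentation with realistic class imbalance.
# ---------------------------------------------------------------------------

#' Phantom generation settings
#'
#' Defaults emulate an aneurysm-centred TOF-MRA training patch: a 64^3 grid
#' at 0.5 mm isotropic spacing, flow-bright vessels (~intensity 0.8) and a
#' slightly brighter aneurysm bulge (~0.9) on a dark background (~0.1),
#' plus Gaussian noise. The bulge diameter is drawn inside the requested
#' clinical size class (< 3 mm, 3-7 mm, > 7 mm).
#'
#' @param shape volume dimensions in voxels (length 3, default 64^3).
#' @param spacing voxel size in mm (default 0.5 isotropic).
#' @param vessel_count number of vessels (default 3).
#' @param vessel_radius tube radius range in voxels (default 1.5-2.5).
#' @param aneurysm_count number of bulges (default 1).
#' @param size_class `"<3mm"`, `"3-7mm"` (default) or `">7mm"`: the target
#'   equivalent-sphere diameter stratum of the bulge.
#' @param intensity_background,intensity_vessel,intensity_aneurysm mean
#'   intensities before noise, on \[0, 1\] (the pipeline z-scores, so these
#'   are conventions, not physical units).
#' @param noise_sigma Gaussian noise standard deviation (default 0.05).
#' @param distortion relative axis-scaling half-range of the ellipsoidal
#'   bulge (default 0.2). Axis scalings are renormalized to preserve the
#'   bulge volume, so the size class is unaffected.
#' @param diameter_mm optional fixed bulge diameter in mm; when `NULL`
#'   (default) the diameter is drawn uniformly inside the size class.
#' @param seed integer RNG seed; the phantom is fully determined by the
#'   spec including this seed.
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 64L), spacing = c(0.5, 0.5, 0.5),
                         vessel_count = 3L, vessel_radius = c(1.5, 2.5),
                         aneurysm_count = 1L,
                         size_class = c("3-7mm", "<3mm", ">7mm"),
                         intensity_background = 0.1,
                         intensity_vessel = 0.8,
                         intensity_aneurysm = 0.9,
                         noise_sigma = 0.05,
                         distortion = 0.2,
                         diameter_mm = NULL,
                         seed = 1L) {
  size_class <- match.arg(size_class)
  ints <- c(intensity_background, intensity_vessel, intensity_aneurysm)
  if (any(ints < 0 | ints > 1))
    stop("intensity levels must lie in [0, 1] before noise")
  if (distortion < 0 || distortion >= 1)
    stop("distortion must lie in [0, 1)")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 vessel_count = as.integer(vessel_count),
                 vessel_radius = vessel_radius,
                 aneurysm_count = as.integer(aneurysm_count),
                 size_class = size_class,
                 intensity_background = intensity_background,
                 intensity_vessel = intensity_vessel,
                 intensity_aneurysm = intensity_aneurysm,
                 noise_sigma = noise_sigma, distortion = distortion,
                 diameter_mm = diameter_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Diameter (mm) draw for a size class; kept strictly inside the stratum so
# the voxelized equivalent diameter stays in class.
.draw_diameter <- function(size_class) {
  switch(size_class,
         "<3mm" = runif(1, 2.0, 2.8),
         "3-7mm" = runif(1, 3.4, 6.6),
         ">7mm" = runif(1, 7.4, 9.5))
}

# Stamp a ball of radius r (voxels) at centre p into logical array `mask`.
.stamp_ball <- function(mask, p, r) {
  d <- dim(mask)
  lo <- pmax(ceiling(p - r), 1)
  hi <- pmin(floor(p + r), d)
  if (any(lo > hi)) return(mask)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  dx2 <- (xs - p[1])^2
  dy2 <- (ys - p[2])^2
  dz2 <- (zs - p[3])^2
  sub <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r^2
  mask[xs, ys, zs] <- mask[xs, ys, zs] | sub
  mask
}

# Rasterize an axis-scaled ellipsoid; `radii` are per-axis semi-axes in
# voxels.
.stamp_ellipsoid <- function(mask, p, radii) {
  d <- dim(mask)
  lo <- pmax(ceiling(p - radii), 1)
  hi <- pmin(floor(p + radii), d)
  if (any(lo > hi)) return(mask)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  dx2 <- ((xs - p[1]) / radii[1])^2
  dy2 <- ((ys - p[2]) / radii[2])^2
  dz2 <- ((zs - p[3]) / radii[3])^2
  sub <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
  mask[xs, ys, zs] <- mask[xs, ys, zs] | sub
  mask
}

#' Generate one vascular phantom
#'
#' Vessels are drawn as smooth random-walk centrelines dilated to tubes of
#' the configured radius; each aneurysm is an ellipsoidal bulge (volume-
#' preserving random axis distortion) attached tangent to a vessel
#' centreline point, painted brighter than the vessel. Gaussian noise is
#' added everywhere. The label mask marks bulge voxels only (vessel voxels
#' are background), and the phantom is fully determined by the spec's
#' seed.
#'
#' @param spec a [phantom_spec()].
#' @return a list of class `phantom_case`: `volume` ([new_volume()]),
#'   `mask` ([new_label_mask()], values \{0, 1\}), `center` (bulge centroid,
#'   1-based voxel index), `size_class`, `diameter_mm` (equivalent-sphere
#'   diameter of the realized mask), and `seed`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- spec$shape
  vessel <- array(FALSE, dim = d)
  centreline <- list()
  for (v in seq_len(spec$vessel_count)) {
    r <- runif(1, spec$vessel_radius[1], spec$vessel_radius[2])
    pos <- runif(3, 0.2, 0.8) * d
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    n_steps <- round(1.5 * max(d))
    pts <- matrix(NA_real_, n_steps, 3)
    for (s in seq_len(n_steps)) {
      pts[s, ] <- pos
      vessel <- .stamp_ball(vessel, pos, r)
      dir <- dir + rnorm(3, 0, 0.12)
      dir <- dir / sqrt(sum(dir^2))
      nxt <- pos + dir
      # reflect at the walls so the tube stays inside the grid
      for (ax in 1:3) {
        if (nxt[ax] < 2 || nxt[ax] > d[ax] - 1) dir[ax] <- -dir[ax]
      }
      pos <- pos + dir
    }
    centreline[[v]] <- list(points = pts, radius = r)
  }
  aneurysm <- array(FALSE, dim = d)
  for (a in seq_len(spec$aneurysm_count)) {
    dia_mm <- spec$diameter_mm %||% .draw_diameter(spec$size_class)
    r_vox <- dia_mm / 2 / spec$spacing  # per-axis semi-axis in voxels
    s <- runif(3, 1 - spec$distortion, 1 + spec$distortion)
    s <- s / prod(s)^(1 / 3)            # volume-preserving distortion
    radii <- r_vox * s
    margin <- radii + 1.5
    cand <- do.call(rbind, lapply(centreline, function(cl) cl$points))
    cand_r <- unlist(lapply(centreline, function(cl)
      rep(cl$radius, nrow(cl$points))))
    ok <- vapply(seq_len(nrow(cand)), function(j) {
      p <- cand[j, ]
      all(p > margin + cand_r[j]) && all(p < d - margin - cand_r[j])
    }, logical(1))
    if (!any(ok))
      stop("bulge cannot fit inside the volume: diameter ", round(dia_mm, 2),
           " mm exceeds the interior margin at spacing ",
           paste(spec$spacing, collapse = "x"), " mm")
    pick <- which(ok)[sample.int(sum(ok), 1)]
    p0 <- cand[pick, ]
    off <- rnorm(3); off <- off / sqrt(sum(off^2))
    centre <- p0 + off * cand_r[pick]   # tangent attachment to the tube wall
    aneurysm <- .stamp_ellipsoid(aneurysm, centre, radii)
  }
  vol <- array(spec$intensity_background, dim = d)
  vol[vessel] <- spec$intensity_vessel
  vol[aneurysm] <- spec$intensity_aneurysm
  vol <- vol + rnorm(length(vol), 0, spec$noise_sigma)
  mask <- array(0L, dim = d)
  mask[aneurysm] <- 1L
  idx <- which(aneurysm, arr.ind = TRUE)
  centroid <- as.integer(round(colMeans(idx)))
  structure(list(volume = new_volume(vol, spec$spacing),
                 mask = new_label_mask(mask, spec$spacing),
                 center = centroid,
                 size_class = spec$size_class,
                 diameter_mm = .equiv_diameter(mask, spec$spacing),
                 seed = spec$seed, spec = spec),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat("<phantom_case> ", paste(dim(x$volume$data), collapse = " x "),
      " voxels, size class ", x$size_class,
      ", equivalent diameter ", round(x$diameter_mm, 2), " mm, ",
      sum(x$mask$data), " foreground voxels\n", sep = "")
  invisible(x)
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` phantom volume/mask NIfTI pairs plus a CSV manifest with one
#' row per case (`case_id`, file names, bulge centre, size class, seed).
#' Per-case seeds are derived deterministically from the master seed, so
#' regenerating with the same seed reproduces the dataset bit-exactly.
#'
#' @param n number of cases (>= 1).
#' @param dir output directory (created if missing).
#' @param spec base [phantom_spec()]; per-case seed and size class override
#'   it.
#' @param size_classes optional character vector recycled over cases
#'   (default: cycle through the three strata).
#' @param seed master seed.
#' @return the manifest as a tibble (also written to `manifest.csv`).
#' @export
generate_dataset <- function(n, dir, spec = phantom_spec(),
                             size_classes = c("<3mm", "3-7mm", ">7mm"),
                             seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  classes <- rep_len(size_classes, n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- spec
    sp$seed <- as.integer((seed * 10007L + i * 7919L) %% .Machine$integer.max)
    sp$size_class <- classes[i]
    case <- generate_phantom(sp)
    id <- sprintf("case_%03d", i)
    vfile <- file.path(dir, paste0(id, "_volume.nii.gz"))
    mfile <- file.path(dir, paste0(id, "_mask.nii.gz"))
    write_volume(case$volume, vfile)
    write_mask(case$mask, mfile)
    rows[[i]] <- tibble::tibble(
      case_id = id, volume = basename(vfile), mask = basename(mfile),
      cx = case$center[1], cy = case$center[2], cz = case$center[3],
      size_class = case$size_class,
      diameter_mm = case$diameter_mm, seed = sp$seed)
  }
  manifest <- do.call(rbind, rows)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  manifest
}

#' Load a phantom dataset from a manifest
#'
#' Reads the volume/mask pairs listed in a [generate_dataset()] manifest
#' back into memory as training cases.
#'
#' @param manifest_path path to `manifest.csv` (file paths are resolved
#'   relative to its directory).
#' @return list of cases, each with `volume`, `mask`, `center`, `case_id`.
#' @export
load_dataset <- function(manifest_path) {
  man <- readr::read_csv(manifest_path, show_col_types = FALSE)
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    list(volume = read_volume(file.path(base, man$volume[i])),
         mask = read_mask(file.path(base, man$mask[i])),
         center = c(man$cx[i], man$cy[i], man$cz[i]),
         case_id = man$case_id[i],
         size_class = man$size_class[i])
  })
}
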