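#' Neighborhood specification for the local binary pattern operator
#'
#' Fixes the 8-neighbor ring of the 3x3 window and the mapping from ring
#' position to bit position. The default enumerates the ring clockwise from
#' the top-left corner, with the first offset contributing bit 0. Any fixed
#' ordering preserves every property of the operator (invariance, code
#' range); it is pinned for bit-exact reproducibility.
#'
#' @param offsets 8x2 integer matrix of in-plane index offsets.
#' @param bit_order Integer permutation of 0..7 assigning a bit to each
#'   offset position.
#' @return A `neighborhood_spec`.
#' @export
neighborhood_spec <- function(offsets = rbind(
                                c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
                                c(1, 1), c(1, 0), c(1, -1), c(0, -1)),
                              bit_order = 0:7) {
  offsets <- matrix(as.integer(offsets), ncol = 2)
  if (nrow(offsets) != 8L || anyDuplicated(split(offsets, row(offsets))) ||
      !all(offsets %in% -1:1) || any(offsets[, 1] == 0 & offsets[, 2] == 0)) {
    stop("offsets must be the 8 distinct cells of the 3x3 ring", call. = FALSE)
  }
  if (!setequal(bit_order, 0:7)) {
    stop("bit_order must be a permutation of 0..7", call. = FALSE)
  }
  structure(list(P = 8L, offsets = offsets, bit_order = as.integer(bit_order)),
            class = "neighborhood_spec")
}

# Vectorized LBP over every slice of `arr` along the plane spanned by
# `axes` (the third axis indexes slices). Threshold convention: a neighbor
# greater than or equal to the center sets its bit (s(0) = 1), so a constant
# image codes to 255 everywhere valid.
lbp_code_volume <- function(arr, axes, spec) {
  d <- dim(arr)
  a1 <- axes[1]; a2 <- axes[2]
  if (d[a1] < 3L || d[a2] < 3L) {
    stop("plane axes must span at least 3x3", call. = FALSE)
  }
  idx <- lapply(d, seq_len)
  idx[[a1]] <- 2:(d[a1] - 1L)
  idx[[a2]] <- 2:(d[a2] - 1L)
  center <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  code <- array(0, dim = dim(center))
  for (k in seq_len(8L)) {
    nb_idx <- idx
    nb_idx[[a1]] <- idx[[a1]] + spec$offsets[k, 1]
    nb_idx[[a2]] <- idx[[a2]] + spec$offsets[k, 2]
    nb <- do.call(`[`, c(list(arr), nb_idx, list(drop = FALSE)))
    code <- code + (nb >= center) * 2^spec$bit_order[k]
  }
  out <- array(0L, dim = d)
  valid <- array(FALSE, dim = d)
  out_idx <- c(list(out), idx)
  out <- do.call(`[<-`, c(list(out), idx, list(value = as.integer(code))))
  valid <- do.call(`[<-`, c(list(valid), idx, list(value = TRUE)))
  list(code = out, valid = valid)
}

#' 2D local binary pattern codes
#'
#' For each interior pixel, thresholds the 8 ring neighbors against the
#' center (neighbor >= center sets the bit) and packs the signs into a byte:
#' `code = sum_p s(I_p - I_c) 2^p`. Border pixels get code 0 and are marked
#' invalid. The code is invariant under any strictly increasing intensity
#' transform of a tie-free image.
#'
#' @param slice 2D numeric matrix, at least 3x3.
#' @param spec A [neighborhood_spec()].
#' @return List with `code` (integer matrix in \[0, 255\]) and `valid`
#'   (logical matrix, `FALSE` on the border).
#' @export
lbp2d <- function(slice, spec = neighborhood_spec()) {
  if (!is.matrix(slice)) slice <- as.matrix(slice)
  if (any(dim(slice) < 3L)) stop("slice must be at least 3x3", call. = FALSE)
  res <- lbp_code_volume(array(slice, dim = c(dim(slice), 1L)), c(1L, 2L), spec)
  list(code = array(res$code, dim = dim(slice)),
       valid = array(res$valid, dim = dim(slice)))
}

#' LBP on three orthogonal planes of a volume
#'
#' Applies the 2D operator slicewise along each of the three orthogonal
#' orientations: `map_yz` over sagittal y-z slices (varying x), `map_xz`
#' over coronal x-z slices (varying y), `map_xy` over axial x-y slices
#' (varying z). Every voxel thus carries a triple of plane codes. The
#' combined validity grid requires the full 3x3 neighborhood in all three
#' planes, i.e. it excludes the one-voxel border of every axis.
#'
#' @param vol A [volume()] or 3D array, at least 3x3x3.
#' @param spec A [neighborhood_spec()].
#' @return An `lbptop_maps` object: `map_yz`, `map_xz`, `map_xy` (integer
#'   code arrays), `valid`, `spacing`.
#' @export
lbp_top <- function(vol, spec = neighborhood_spec()) {
  spacing <- c(1, 1, 1)
  if (inherits(vol, "lbp_volume")) { spacing <- vol$spacing; vol <- vol$data }
  vol <- as.array(vol)
  if (length(dim(vol)) != 3L || any(dim(vol) < 3L)) {
    stop("volume must be at least 3x3x3", call. = FALSE)
  }
  yz <- lbp_code_volume(vol, c(2L, 3L), spec)
  xz <- lbp_code_volume(vol, c(1L, 3L), spec)
  xy <- lbp_code_volume(vol, c(1L, 2L), spec)
  structure(list(map_yz = yz$code, map_xz = xz$code, map_xy = xy$code,
                 valid = yz$valid & xz$valid & xy$valid, spacing = spacing),
            class = "lbptop_maps")
}

#' @export
print.lbptop_maps <- function(x, ...) {
  cat("<lbptop_maps> ", paste(dim(x$map_xy), collapse = " x "),
      " voxels, ", sum(x$valid), " valid\n", sep = "")
  invisible(x)
}

fwhm_to_sigma_vox <- function(fwhm_mm, spacing_mm) {
  fwhm_mm / (2 * sqrt(2 * log(2))) / spacing_mm
}

# Separable 1D Gaussian convolution along `axis` with symmetric (reflect)
# boundary, which preserves constants exactly. Kernel truncated at 4 sigma
# and renormalized to unit sum.
gauss_filter_axis <- function(arr, sigma_vox, axis) {
  if (sigma_vox <= 0) return(arr)
  r <- max(1L, ceiling(4 * sigma_vox))
  w <- stats::dnorm(-r:r, sd = sigma_vox)
  w <- w / sum(w)
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  a <- aperm(arr, perm)
  n <- d[axis]
  m <- matrix(a, nrow = n)
  pad_top <- m[pmin(r, n):1, , drop = FALSE]
  pad_bot <- m[n:max(1L, n - r + 1L), , drop = FALSE]
  if (r > n) { # degenerate tiny axis: extend reflection periodically
    while (nrow(pad_top) < r) pad_top <- rbind(m[n:1, , drop = FALSE], pad_top)
    while (nrow(pad_bot) < r) pad_bot <- rbind(pad_bot, m[n:1, , drop = FALSE])
    pad_top <- pad_top[(nrow(pad_top) - r + 1L):nrow(pad_top), , drop = FALSE]
    pad_bot <- pad_bot[1:r, , drop = FALSE]
  }
  p <- rbind(pad_top, m, pad_bot)
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (k in seq_along(w)) {
    out <- out + w[k] * p[(k):(k + n - 1L), , drop = FALSE]
  }
  aperm(array(out, dim = d[perm]), order(perm))
}

gauss_smooth <- function(arr, fwhm_mm, spacing_mm) {
  fwhm_mm <- rep_len(fwhm_mm, 3L)
  for (ax in 1:3) {
    arr <- gauss_filter_axis(arr, fwhm_to_sigma_vox(fwhm_mm[ax], spacing_mm[ax]), ax)
  }
  arr
}

#' Gaussian smoothing of LBP-TOP code maps
#'
#' Each code map is treated as an ordinary real scalar field and convolved
#' with a separable Gaussian whose per-axis sigma (in voxels) is
#' `fwhm / (2 sqrt(2 ln 2)) / spacing`. The default 4 mm FWHM suppresses the
#' noise sensitivity of the raw codes before voxelwise statistics. Reflect
#' boundary handling preserves constant maps exactly; the validity grid is
#' unchanged.
#'
#' @param maps An `lbptop_maps` object from [lbp_top()].
#' @param fwhm_mm Per-axis FWHM in mm (scalar recycled; default 4).
#' @param spacing_mm Voxel spacing override; defaults to the maps' spacing.
#' @return List of three real-valued arrays `map_yz`, `map_xz`, `map_xy`
#'   plus `valid` and `spacing`.
#' @export
smooth_codes <- function(maps, fwhm_mm = 4, spacing_mm = NULL) {
  stopifnot(inherits(maps, "lbptop_maps"))
  if (is.null(spacing_mm)) spacing_mm <- maps$spacing
  if (any(spacing_mm <= 0)) stop("spacing must be positive", call. = FALSE)
  if (any(fwhm_mm < 0)) stop("fwhm must be >= 0", call. = FALSE)
  structure(list(
    map_yz = gauss_smooth(maps$map_yz + 0, fwhm_mm, spacing_mm),
    map_xz = gauss_smooth(maps$map_xz + 0, fwhm_mm, spacing_mm),
    map_xy = gauss_smooth(maps$map_xy + 0, fwhm_mm, spacing_mm),
    valid = maps$valid, spacing = maps$spacing
  ), class = "lbptop_smoothed")
}

#' Histogram matching against a template
#'
#' Classic histogram equalization of the tonal distribution: within-mask
#' intensities of the input are mapped through the input's empirical CDF and
#' then the inverse of the template's CDF, using 256 bins spanning each
#' mask's own intensity range. The mapping is non-decreasing; voxels outside
#' the brain mask are set to 0. This is the conventional cross-scanner
#' intensity standardization the LBP features are an alternative to.
#'
#' @param vol Input [volume()]; must carry a brain mask.
#' @param template Template [volume()]; must carry a brain mask.
#' @param n_bins Number of histogram bins (default 256).
#' @return A [volume()] with matched intensities.
#' @export
histogram_equalize <- function(vol, template, n_bins = 256L) {
  stopifnot(inherits(vol, "lbp_volume"), inherits(template, "lbp_volume"))
  if (is.null(vol$brain_mask) || is.null(template$brain_mask)) {
    stop("histogram matching requires brain masks on input and template",
         call. = FALSE)
  }
  xi <- vol$data[vol$brain_mask]
  xt <- template$data[template$brain_mask]
  if (length(xi) == 0L || length(xt) == 0L) {
    stop("empty brain mask", call. = FALSE)
  }
  if (min(xi) == max(xi) || min(xt) == max(xt)) {
    stop("degenerate (constant) within-mask intensities", call. = FALSE)
  }
  breaks_i <- seq(min(xi), max(xi), length.out = n_bins + 1L)
  breaks_t <- seq(min(xt), max(xt), length.out = n_bins + 1L)
  centers_t <- (breaks_t[-1L] + breaks_t[-(n_bins + 1L)]) / 2
  bin_i <- findInterval(xi, breaks_i, all.inside = TRUE)
  bin_t <- findInterval(xt, breaks_t, all.inside = TRUE)
  cdf_i <- cumsum(tabulate(bin_i, n_bins)) / length(xi)
  cdf_t <- cumsum(tabulate(bin_t, n_bins)) / length(xt)
  # monotone lookup: earliest template bin whose CDF reaches the input CDF
  lut <- centers_t[pmin(n_bins, findInterval(cdf_i, cdf_t, left.open = TRUE) + 1L)]
  out <- array(0, dim = dim(vol$data))
  out[vol$brain_mask] <- lut[bin_i]
  volume(out, vol$spacing, brain_mask = vol$brain_mask)
}

#' Compute a feature image of a given type
#'
#' The three feature representations compared by the pipeline:
#' type 1 — the registered intensity volume as-is (no adjustment);
#' type 2 — histogram-matched intensities against a template;
#' type 3 — smoothed LBP-TOP code maps (gray-level invariant).
#' Types 1 and 2 yield a single plane; type 3 yields three.
#'
#' @param vol Input [volume()].
#' @param type Feature type, 1, 2 or 3.
#' @param template Template [volume()] (required for type 2).
#' @param fwhm_mm Smoothing FWHM in mm for type 3 (default 4).
#' @param spec [neighborhood_spec()] for type 3.
#' @return A `feature_image`: named list `planes` of real arrays, common
#'   `valid` grid, `spacing`, `type`.
#' @export
feature_image <- function(vol, type, template = NULL, fwhm_mm = 4,
                          spec = neighborhood_spec()) {
  stopifnot(inherits(vol, "lbp_volume"))
  type <- as.integer(type)
  if (type == 1L) {
    valid <- if (is.null(vol$brain_mask)) array(TRUE, dim(vol$data)) else vol$brain_mask
    planes <- list(intensity = vol$data)
  } else if (type == 2L) {
    if (is.null(template)) stop("type 2 requires a template volume", call. = FALSE)
    eq <- histogram_equalize(vol, template)
    valid <- vol$brain_mask
    planes <- list(intensity = eq$data)
  } else if (type == 3L) {
    sm <- smooth_codes(lbp_top(vol, spec), fwhm_mm = fwhm_mm)
    valid <- sm$valid
    if (!is.null(vol$brain_mask)) valid <- valid & vol$brain_mask
    planes <- list(yz = sm$map_yz, xz = sm$map_xz, xy = sm$map_xy)
  } else {
    stop("unknown feature type: ", type, " (must be 1, 2 or 3)", call. = FALSE)
  }
  structure(list(planes = planes, valid = valid, spacing = vol$spacing,
                 type = type),
            class = "feature_image")
}

#' Extract feature images for a whole cohort
#'
#' Reads every volume in the manifest, computes its feature image, and
#' stacks the result into per-plane matrices (voxels x subjects) ready for
#' voxelwise statistics. The shared validity grid is the conjunction of all
#' per-subject validity grids.
#'
#' @param manifest Manifest tibble (`subject_id`, `path`, `label`, `group`).
#' @param type Feature type 1, 2 or 3.
#' @param template Template [volume()] for type 2.
#' @param brain_mask Optional [binary_mask()] (or logical array) attached to
#'   every subject on read; required for type 2.
#' @param fwhm_mm Smoothing FWHM for type 3.
#' @param spec [neighborhood_spec()].
#' @return An `lbp_features` object: `planes` (named list of voxel x subject
#'   matrices), `dim`, `spacing`, `valid`, `subject_id`, `label`, `type`.
#' @export
collect_features <- function(manifest, type, template = NULL,
                             brain_mask = NULL, fwhm_mm = 4,
                             spec = neighborhood_spec()) {
  manifest <- validate_manifest(manifest)
  if (inherits(brain_mask, "lbp_mask")) brain_mask <- brain_mask$data
  n <- nrow(manifest)
  planes <- NULL; valid <- NULL; dm <- NULL; spacing <- NULL
  for (i in seq_len(n)) {
    v <- read_volume(manifest$path[i], brain_mask = brain_mask)
    fi <- feature_image(v, type, template = template, fwhm_mm = fwhm_mm,
                        spec = spec)
    if (is.null(planes)) {
      dm <- dim(fi$planes[[1]]); spacing <- fi$spacing
      planes <- lapply(fi$planes, function(p)
        matrix(NA_real_, nrow = prod(dm), ncol = n))
      valid <- fi$valid
    } else {
      if (!identical(dim(fi$planes[[1]]), dm)) {
        stop("subject ", manifest$subject_id[i], " is on a different grid",
             call. = FALSE)
      }
      valid <- valid & fi$valid
    }
    for (p in names(fi$planes)) planes[[p]][, i] <- as.vector(fi$planes[[p]])
  }
  structure(list(planes = planes, dim = dm, spacing = spacing, valid = valid,
                 subject_id = manifest$subject_id, label = manifest$label,
                 type = as.integer(type)),
            class = "lbp_features")
}

#' @export
print.lbp_features <- function(x, ...) {
  cat("<lbp_features> type ", x$type, ", ", length(x$subject_id),
      " subjects, ", length(x$planes), " plane(s) of ",
      paste(x$dim, collapse = " x "), " voxels (", sum(x$valid), " valid)\n",
      sep = "")
  invisible(x)
}
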