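#' Specify a synthetic phantom cohort
#'
#' The phantom emulates the statistical structure the classification method
#' assumes: nested tissue regions with T1-like contrast (CSF < GM < WM),
#' group-specific regional atrophy expressed as boundary shifts, per-subject
#' monotonic scanner-dependent intensity transforms (a gamma sweep standing
#' in for flip-angle variation), additive noise, and residual
#' linear-registration jitter as integer-voxel translations.
#'
#' Intensities are piecewise-constant per tissue plus a fixed low-amplitude
#' linear ramp added *before* the gamma transform, identical for every
#' subject. The ramp guarantees that no two in-plane neighbours tie, so
#' local-binary-pattern invariance under strictly increasing transforms
#' holds exactly rather than up to tie-breaking. Noise is added *after* the
#' gamma transform (it models the scanner, not the anatomy), so exact
#' invariance is only guaranteed at `noise_sigma = 0`.
#'
#' @param shape Grid dimensions (default 64^3).
#' @param spacing Voxel size in mm (default 2 mm isotropic).
#' @param n_per_group Subjects per class.
#' @param atrophy_fraction Linear shrink factor in (0, 1] applied to the two
#'   target blobs (hippocampus/amygdala stand-ins) in the patient group;
#'   0.85 means a 15 percent radius reduction.
#' @param ventricle_dilation Linear growth factor (>= 1) for the central
#'   ventricle blob in patients.
#' @param scanner_gammas Set of gamma exponents; each subject is assigned
#'   one at random, emulating scanner-dependent contrast.
#' @param noise_sigma Additive Gaussian noise standard deviation, expressed
#'   as a fraction of the subject's post-transform CSF-to-WM contrast (so
#'   signal-to-noise is comparable across simulated scanners).
#' @param jitter_mm Maximum per-axis rigid translation in mm; rounded down
#'   to whole voxels (sub-voxel resampling would break exact ground truth).
#' @param target_radius_frac Radius of each target blob as a fraction of the
#'   smallest grid axis.
#' @param seed Integer seed; identical spec + seed gives a bit-identical
#'   cohort.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(64, 64, 64),
                         spacing = c(2, 2, 2),
                         n_per_group = 20,
                         atrophy_fraction = 0.9,
                         ventricle_dilation = 1.1,
                         scanner_gammas = c(0.3, 1, 3),
                         noise_sigma = 0.1,
                         jitter_mm = 2,
                         target_radius_frac = 0.13,
                         seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 16),
            length(spacing) == 3L, all(spacing > 0),
            n_per_group >= 1)
  if (atrophy_fraction <= 0 || atrophy_fraction > 1) {
    stop("atrophy_fraction must be in (0, 1]", call. = FALSE)
  }
  if (ventricle_dilation < 1) stop("ventricle_dilation must be >= 1", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (jitter_mm < 0) stop("jitter_mm must be >= 0", call. = FALSE)
  if (length(scanner_gammas) < 1 || any(scanner_gammas <= 0)) {
    stop("scanner_gammas must be positive exponents", call. = FALSE)
  }
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 n_per_group = as.integer(n_per_group),
                 atrophy_fraction = atrophy_fraction,
                 ventricle_dilation = ventricle_dilation,
                 scanner_gammas = as.numeric(scanner_gammas),
                 noise_sigma = noise_sigma, jitter_mm = jitter_mm,
                 target_radius_frac = target_radius_frac,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Region label codes used in the ground-truth grid.
PHANTOM_LABELS <- c(background = 0L, csf = 1L, gm = 2L, wm = 3L,
                    target_left = 4L, target_right = 5L, ventricle = 6L)

# Base tissue intensities on [0, 1], T1-weighted ordering CSF < GM < WM.
# Target blobs are gray-matter structures; the ventricle is CSF-filled.
PHANTOM_INTENSITY <- c(background = 0, csf = 0.2, gm = 0.5, wm = 0.8,
                       target_left = 0.5, target_right = 0.5, ventricle = 0.2)

# Run `expr` under a temporary RNG state so package functions never disturb
# the caller's random stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

voxel_coords <- function(shape) {
  list(x = array(rep(seq_len(shape[1]), times = shape[2] * shape[3]), dim = shape),
       y = array(rep(rep(seq_len(shape[2]), each = shape[1]), times = shape[3]),
                 dim = shape),
       z = array(rep(seq_len(shape[3]), each = shape[1] * shape[2]), dim = shape))
}

ellipsoid_mask <- function(coords, center, radii) {
  ((coords$x - center[1]) / radii[1])^2 +
    ((coords$y - center[2]) / radii[2])^2 +
    ((coords$z - center[3]) / radii[3])^2 <= 1
}

# Geometry parameters, in voxel units relative to the grid.
phantom_geometry <- function(spec, patient = FALSE) {
  shape <- spec$shape
  center <- (shape + 1) / 2
  head_r <- 0.42 * shape
  target_r <- spec$target_radius_frac * min(shape)
  vent_r <- c(0.05, 0.10, 0.05) * min(shape)
  if (patient) {
    target_r <- target_r * spec$atrophy_fraction
    vent_r <- vent_r * spec$ventricle_dilation
  }
  offset <- c(0.17 * shape[1], -0.08 * shape[2], 0)
  geo <- list(
    center = center, head_r = head_r,
    gm_r = 0.90 * head_r, wm_r = 0.72 * head_r,
    target_r = target_r,
    target_left = center + c(-1, 1, 1) * offset,
    target_right = center + offset,
    vent_r = vent_r
  )
  margin <- 2 + floor(spec$jitter_mm / min(spec$spacing))
  if (any(center - head_r < margin) || any(center + head_r > shape - margin + 1)) {
    stop("phantom geometry exceeds the grid (head touches the border)",
         call. = FALSE)
  }
  if (any(abs(geo$target_right - center) + geo$target_r > geo$wm_r)) {
    stop("target blob geometry exceeds the white-matter core", call. = FALSE)
  }
  geo
}

phantom_labels <- function(spec, patient = FALSE) {
  geo <- phantom_geometry(spec, patient)
  co <- voxel_coords(spec$shape)
  lab <- array(PHANTOM_LABELS[["background"]], dim = spec$shape)
  lab[ellipsoid_mask(co, geo$center, geo$head_r)] <- PHANTOM_LABELS[["csf"]]
  lab[ellipsoid_mask(co, geo$center, geo$gm_r)] <- PHANTOM_LABELS[["gm"]]
  lab[ellipsoid_mask(co, geo$center, geo$wm_r)] <- PHANTOM_LABELS[["wm"]]
  lab[ellipsoid_mask(co, geo$target_left, rep(geo$target_r, 3))] <-
    PHANTOM_LABELS[["target_left"]]
  lab[ellipsoid_mask(co, geo$target_right, rep(geo$target_r, 3))] <-
    PHANTOM_LABELS[["target_right"]]
  lab[ellipsoid_mask(co, geo$center, geo$vent_r)] <- PHANTOM_LABELS[["ventricle"]]
  lab
}

# Deterministic tie-breaking ramp: amplitude `amp` over the grid diagonal,
# with incommensurate axis weights so no two in-plane neighbours share a
# value within one tissue. Added before the gamma transform.
phantom_ramp <- function(shape, amp = 0.02) {
  co <- voxel_coords(shape)
  r <- 0.37 * co$x + 0.59 * co$y + 0.83 * co$z
  amp * (r - min(r)) / (max(r) - min(r))
}

shift_array <- function(a, shift, fill = 0) {
  if (all(shift == 0L)) return(a)
  out <- array(fill, dim = dim(a))
  d <- dim(a)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    s <- shift[ax]
    if (abs(s) >= d[ax]) return(out)
    if (s >= 0) { src[[ax]] <- 1:(d[ax] - s); dst[[ax]] <- (1 + s):d[ax] }
    else { src[[ax]] <- (1 - s):d[ax]; dst[[ax]] <- 1:(d[ax] + s) }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Generate one phantom subject
#'
#' Builds the subject's tissue geometry (with atrophy/dilation applied for
#' patients), assigns base intensities plus the tie-breaking ramp, then
#' applies — in this order — rigid integer-voxel jitter, the subject's gamma
#' transform, and additive noise. The returned region-label grid is jittered
#' together with the image so ground truth stays voxel-aligned, but is
#' untouched by the intensity steps.
#'
#' @param spec A [phantom_spec()].
#' @param group +1 (patient) or -1 (control).
#' @param subject_seed Integer seed for this subject's jitter, gamma draw and
#'   noise.
#' @return A list with `volume` (an [volume()] whose brain mask is the
#'   jittered head envelope), `labels` (integer region grid; see
#'   `PHANTOM_LABELS`), `gamma` and `shift`.
#' @export
make_subject <- function(spec, group, subject_seed) {
  stopifnot(inherits(spec, "phantom_spec"), group %in% c(-1, 1))
  lab <- phantom_labels(spec, patient = group == 1)
  img <- array(PHANTOM_INTENSITY[lab + 1L], dim = spec$shape)
  ramp <- phantom_ramp(spec$shape)
  img[lab > 0L] <- img[lab > 0L] + ramp[lab > 0L]
  with_local_seed(subject_seed, {
    kmax <- as.integer(floor(spec$jitter_mm / spec$spacing))
    shift <- vapply(kmax, function(k)
      if (k >= 1L) sample.int(2L * k + 1L, 1L) - k - 1L else 0L, integer(1))
    gamma <- spec$scanner_gammas[sample.int(length(spec$scanner_gammas), 1L)]
    img <- shift_array(img, shift)
    lab <- shift_array(lab, shift, fill = PHANTOM_LABELS[["background"]])
    img <- img^gamma
    if (spec$noise_sigma > 0) {
      contrast <- PHANTOM_INTENSITY[["wm"]]^gamma - PHANTOM_INTENSITY[["csf"]]^gamma
      img <- img + stats::rnorm(length(img), sd = spec$noise_sigma * contrast)
    }
    list(volume = volume(img, spec$spacing, brain_mask = lab > 0L),
         labels = lab, gamma = gamma, shift = shift)
  })
}

# Analytic mask envelopes around the noiseless template geometry, padded so
# they cover both groups plus the worst-case jitter.
phantom_masks <- function(spec) {
  geo <- phantom_geometry(spec, patient = FALSE)
  co <- voxel_coords(spec$shape)
  pad <- 2 + floor(spec$jitter_mm / min(spec$spacing))
  ctr <- geo$center
  sector_shell <- function(lo, hi) {
    ellipsoid_mask(co, ctr, hi * geo$head_r) &
      !ellipsoid_mask(co, ctr, lo * geo$head_r)
  }
  masks <- list(
    AMG = ellipsoid_mask(co, geo$target_left, rep(geo$target_r + pad, 3)),
    HIP = ellipsoid_mask(co, geo$target_right, rep(geo$target_r + pad, 3)),
    ENT = sector_shell(0.68, 0.96) & co$y < ctr[2] - 0.18 * geo$head_r[2] &
      co$z < ctr[3],
    PHG = sector_shell(0.68, 0.96) & co$y > ctr[2] + 0.18 * geo$head_r[2] &
      co$z < ctr[3],
    TL = ellipsoid_mask(co, ctr, geo$head_r) & co$x < ctr[1] &
      co$z < ctr[3] - 0.15 * geo$head_r[3],
    LV = ellipsoid_mask(co, ctr, geo$vent_r * spec$ventricle_dilation + pad)
  )
  masks$OVALL <- Reduce(`|`, masks)
  purrr::imap(masks, ~ binary_mask(.x, name = .y, spacing = spec$spacing))
}

#' Generate a phantom cohort on disk
#'
#' Writes `n_per_group` patient (+1) and control (-1) subjects as NIfTI
#' volumes, the seven anatomical-knowledge masks (`AMG`, `HIP`, `ENT`,
#' `PHG`, `TL`, `LV` and their union `OVALL`), a noiseless unjittered
#' gamma=1 template volume, the template head mask, and the subject manifest
#' TSV. Per-subject seeds are drawn once from `spec$seed`, so the cohort is
#' reproducible bit-for-bit.
#'
#' @param spec A [phantom_spec()].
#' @param out_dir Output directory (created if needed).
#' @return A list with `manifest` (tibble), `masks` (named list of
#'   [binary_mask()]), `template` (a [volume()]), `labels` (named list of
#'   per-subject ground-truth grids) and `dir`.
#' @export
make_cohort <- function(spec, out_dir = tempfile("phantom_")) {
  stopifnot(inherits(spec, "phantom_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- spec$n_per_group
  subject_seeds <- with_local_seed(spec$seed,
                                   sample.int(.Machine$integer.max - 1L, 2L * n))
  groups <- rep(c(1L, -1L), each = n)
  ids <- sprintf("%s%02d", ifelse(groups == 1L, "pat", "ctl"),
                 c(seq_len(n), seq_len(n)))
  labels_list <- vector("list", 2L * n)
  paths <- character(2L * n)
  for (i in seq_len(2L * n)) {
    subj <- make_subject(spec, groups[i], subject_seeds[i])
    paths[i] <- file.path(out_dir, paste0(ids[i], ".nii.gz"))
    write_volume(subj$volume, paths[i])
    labels_list[[i]] <- subj$labels
  }
  names(labels_list) <- ids
  masks <- phantom_masks(spec)
  for (m in masks) {
    write_volume(m, file.path(out_dir, paste0("mask_", m$name, ".nii.gz")))
  }
  lab0 <- phantom_labels(spec, patient = FALSE)
  tmpl_img <- array(PHANTOM_INTENSITY[lab0 + 1L], dim = spec$shape)
  ramp <- phantom_ramp(spec$shape)
  tmpl_img[lab0 > 0L] <- tmpl_img[lab0 > 0L] + ramp[lab0 > 0L]
  template <- volume(tmpl_img, spec$spacing, brain_mask = lab0 > 0L)
  write_volume(template, file.path(out_dir, "template.nii.gz"))
  write_volume(binary_mask(lab0 > 0L, "brain", spec$spacing),
               file.path(out_dir, "brain_mask.nii.gz"))
  manifest <- tibble::tibble(subject_id = ids, path = paths,
                             label = groups,
                             group = ifelse(groups == 1L, "patient", "control"))
  write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
  list(manifest = manifest, masks = masks, template = template,
       labels = labels_list, dir = out_dir)
}
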