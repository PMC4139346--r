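#' Construct a volume object
#'
#' A `lbp_volume` wraps a 3D scalar array together with its voxel spacing in
#' millimetres and an optional brain (validity) mask on the same grid. All
#' pipeline functions assume volumes are already skull-stripped and linearly
#' co-registered to a common template grid; voxel correspondence is by index.
#'
#' @param data 3D numeric array.
#' @param spacing Numeric length-3, voxel size in mm per axis (strictly
#'   positive).
#' @param brain_mask Optional logical array of the same shape marking brain
#'   voxels.
#' @return An object of class `lbp_volume` with elements `data`, `spacing`
#'   and `brain_mask`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), brain_mask = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) {
    stop("volume data must be a 3D array, got ", length(dim(data)),
         " dimensions", call. = FALSE)
  }
  if (any(dim(data) <= 0L)) stop("all axes must have positive extent", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be three strictly positive voxel sizes in mm", call. = FALSE)
  }
  if (!is.null(brain_mask)) {
    brain_mask <- array(as.logical(brain_mask), dim = dim(brain_mask))
    if (!identical(dim(brain_mask), dim(data))) {
      stop("brain_mask shape ", paste(dim(brain_mask), collapse = "x"),
           " does not match data shape ", paste(dim(data), collapse = "x"),
           call. = FALSE)
    }
  }
  structure(list(data = data, spacing = spacing, brain_mask = brain_mask),
            class = "lbp_volume")
}

#' @export
print.lbp_volume <- function(x, ...) {
  cat("<lbp_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing, 4), collapse = " x "), " mm",
      if (!is.null(x$brain_mask))
        sprintf("  (brain mask: %d voxels)", sum(x$brain_mask)) else "",
      "\n", sep = "")
  invisible(x)
}

#' Construct a binary mask
#'
#' A named binary region-of-interest mask on the template grid, with values
#' strictly in \{0, 1\} (selected area = 1, background = 0). Conventional
#' names are the anatomical stand-ins `AMG`, `ENT`, `HIP`, `PHG`, `TL`, `LV`
#' and `OVALL` (the union of the six), but any identifier is accepted.
#'
#' @param data Logical or 0/1 3D array.
#' @param name Mask identifier.
#' @param spacing Voxel spacing in mm.
#' @return An object of class `lbp_mask`.
#' @export
binary_mask <- function(data, name = "mask", spacing = c(1, 1, 1)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("mask must be a 3D array", call. = FALSE)
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1, TRUE, FALSE))) {
    stop("mask values must be strictly 0/1", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("spacing must be three strictly positive voxel sizes in mm", call. = FALSE)
  }
  structure(list(data = array(as.logical(data), dim = dim(data)),
                 name = as.character(name), spacing = spacing),
            class = "lbp_mask")
}

#' @export
print.lbp_mask <- function(x, ...) {
  cat("<lbp_mask> '", x$name, "' ", paste(dim(x$data), collapse = " x "),
      " voxels, ", sum(x$data), " selected\n", sep = "")
  invisible(x)
}

#' Read a NIfTI-1 volume
#'
#' Reads a 3D NIfTI-1 image (`.nii` or `.nii.gz`); spacing is taken from the
#' header `pixdim`. A non-3D image is an error: the pipeline operates on
#' individual co-registered volumes, never on 4D stacks.
#'
#' @param path Path to a NIfTI-1 file.
#' @param brain_mask Optional logical array or `lbp_mask` to attach.
#' @return An [volume()] object.
#' @export
read_volume <- function(path, brain_mask = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    stop("expected a 3D image, got ", length(d), "D in ", path, call. = FALSE)
  }
  if (inherits(brain_mask, "lbp_mask")) brain_mask <- brain_mask$data
  volume(array(as.numeric(img), dim = d),
         spacing = as.numeric(RNifti::pixdim(img))[seq_len(3)],
         brain_mask = brain_mask)
}

#' Write a volume or mask to NIfTI-1
#'
#' @param x A [volume()], [binary_mask()] or 3D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param spacing Spacing override for plain arrays.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, spacing = NULL) {
  if (inherits(x, "lbp_volume")) {
    data <- x$data; sp <- x$spacing
  } else if (inherits(x, "lbp_mask")) {
    data <- array(as.numeric(x$data), dim = dim(x$data)); sp <- x$spacing
  } else {
    data <- as.array(x); sp <- if (is.null(spacing)) c(1, 1, 1) else spacing
  }
  if (!is.null(spacing)) sp <- spacing
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}

grid_of <- function(x) {
  if (inherits(x, "lbp_volume") || inherits(x, "lbp_mask")) {
    list(shape = dim(x$data), spacing = x$spacing)
  } else if (is.array(x) && length(dim(x)) == 3L) {
    list(shape = dim(x), spacing = c(NA_real_, NA_real_, NA_real_))
  } else {
    stop("not a volume, mask or 3D array", call. = FALSE)
  }
}

#' Check that volumes and masks share one grid
#'
#' Grid identity is shape plus spacing (within `tol` mm); full affine
#' orientation matching is deliberately not enforced, since inputs are
#' assumed pre-registered to a common template. Returns a per-input report
#' and, by default, raises an error naming the offending inputs when the
#' grids differ.
#'
#' @param volumes A list of [volume()] / [binary_mask()] objects (optionally
#'   named).
#' @param tol Spacing tolerance in mm.
#' @param error Raise an error on mismatch (default) instead of returning a
#'   failing report.
#' @return A tibble with one row per input (`name`, `shape`, `spacing`,
#'   `compatible`) and attribute `pass`.
#' @export
check_same_grid <- function(volumes, tol = 1e-6, error = TRUE) {
  if (length(volumes) == 0L) stop("empty input list", call. = FALSE)
  nms <- names(volumes)
  if (is.null(nms)) nms <- rep("", length(volumes))
  nms <- ifelse(nms == "", paste0("input", seq_along(volumes)), nms)
  grids <- lapply(volumes, grid_of)
  ref <- grids[[1L]]
  ok <- vapply(grids, function(g) {
    identical(as.integer(g$shape), as.integer(ref$shape)) &&
      (all(is.na(g$spacing)) || all(is.na(ref$spacing)) ||
         all(abs(g$spacing - ref$spacing) <= tol))
  }, logical(1))
  report <- tibble::tibble(
    name = nms,
    shape = vapply(grids, function(g) paste(g$shape, collapse = "x"), character(1)),
    spacing = vapply(grids, function(g)
      paste(signif(g$spacing, 8), collapse = "x"), character(1)),
    compatible = ok
  )
  attr(report, "pass") <- all(ok)
  if (error && !all(ok)) {
    stop("grid incompatibility: ", paste(nms[!ok], collapse = ", "),
         " differ from ", nms[1L], call. = FALSE)
  }
  report
}

#' Read a subject manifest
#'
#' Reads a tab-separated manifest with columns `subject_id`, `path`, `label`
#' and `group`. Labels are +1 (patient) / -1 (control); both classes must be
#' present and subject ids unique.
#'
#' @param path TSV file path.
#' @return A tibble with the four manifest columns.
#' @export
read_manifest <- function(path) {
  m <- readr::read_tsv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    path = readr::col_character(),
    label = readr::col_integer(),
    group = readr::col_character()
  ))
  validate_manifest(m)
}

#' Write a subject manifest
#'
#' @param manifest A manifest tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  readr::write_tsv(manifest, path)
  invisible(path)
}

validate_manifest <- function(m) {
  required <- c("subject_id", "path", "label", "group")
  missing <- setdiff(required, names(m))
  if (length(missing) > 0) {
    stop("manifest missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(m$subject_id)) stop("subject_ids must be unique", call. = FALSE)
  if (!all(m$label %in% c(-1L, 1L))) {
    stop("labels must be +1 (patient) or -1 (control)", call. = FALSE)
  }
  if (length(unique(m$label)) < 2L) {
    stop("manifest must contain both classes", call. = FALSE)
  }
  tibble::as_tibble(m)
}
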