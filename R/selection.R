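#' Selection criteria for the two-step feature selection
#'
#' Step one is data-driven: a voxelwise pooled-variance two-sample t-test
#' between the classes over the *training* subjects only, keeping voxels
#' with two-sided p below `alpha` (default 0.001, uncorrected — no
#' multiple-comparison correction is applied, by design). Step two is
#' knowledge-driven: the surviving voxels are intersected with a binary
#' anatomical mask; `mask = NULL` skips the second step.
#'
#' @param alpha Uncorrected p-value threshold in (0, 1); default 0.001.
#' @param mask A [binary_mask()], or `NULL` for first-step-only selection.
#' @return A `selection_criteria` object.
#' @export
selection_criteria <- function(alpha = 0.001, mask = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single value in (0, 1)", call. = FALSE)
  }
  if (!is.null(mask) && !inherits(mask, "lbp_mask")) {
    stop("mask must be a binary_mask or NULL", call. = FALSE)
  }
  structure(list(alpha = alpha, mask = mask), class = "selection_criteria")
}

# Vectorized pooled-variance two-sample t over the rows of X (voxels) given
# a logical split of the columns (subjects). Returns t, two-sided p and the
# pooled variance; zero pooled variance yields NA statistics.
row_pooled_t <- function(X, is_pos) {
  n1 <- sum(is_pos); n2 <- sum(!is_pos)
  X1 <- X[, is_pos, drop = FALSE]; X2 <- X[, !is_pos, drop = FALSE]
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  ss1 <- rowSums((X1 - m1)^2); ss2 <- rowSums((X2 - m2)^2)
  df <- n1 + n2 - 2L
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  t[sp2 <= 0] <- NA_real_
  p <- 2 * stats::pt(-abs(t), df = df)
  list(t = t, p = p, sp2 = sp2)
}

#' Fit the two-step feature selection on training subjects
#'
#' For every valid voxel of every plane, computes the pooled-variance
#' two-sample t statistic between classes over the supplied training
#' subjects (and only those — test subjects must never enter this fit), then
#' selects voxels with `p < alpha` that also fall inside the anatomical mask
#' when one is given. Voxels with zero pooled variance are never selected
#' (their p-value is undefined). The flat feature index is deterministic:
#' planes in their stored order, voxels in array linear order within each
#' plane.
#'
#' @param features An `lbp_features` object from [collect_features()].
#' @param criteria A [selection_criteria()].
#' @param subjects Subject ids (or logical/integer index) defining the
#'   training set; default all subjects.
#' @return A `selection_model`: per-plane `t`, `p` and `selected` arrays,
#'   the criteria, and `index` — a tibble (`plane`, `voxel`) of selected
#'   coordinates in flat order.
#' @export
fit_selection <- function(features, criteria = selection_criteria(),
                          subjects = NULL) {
  stopifnot(inherits(features, "lbp_features"),
            inherits(criteria, "selection_criteria"))
  idx <- subject_index(features, subjects)
  labels <- features$label[idx]
  if (sum(labels == 1L) < 2L || sum(labels == -1L) < 2L) {
    stop("need at least 2 training subjects per class", call. = FALSE)
  }
  keep <- as.vector(features$valid)
  if (!is.null(criteria$mask)) {
    if (!identical(dim(criteria$mask$data), features$dim)) {
      stop("mask grid ", paste(dim(criteria$mask$data), collapse = "x"),
           " does not match feature grid ",
           paste(features$dim, collapse = "x"), call. = FALSE)
    }
    keep <- keep & as.vector(criteria$mask$data)
  }
  planes <- vector("list", length(features$planes))
  names(planes) <- names(features$planes)
  for (p in names(features$planes)) {
    X <- features$planes[[p]][, idx, drop = FALSE]
    tt <- row_pooled_t(X, labels == 1L)
    sel <- keep & !is.na(tt$p) & tt$p < criteria$alpha
    planes[[p]] <- list(t = array(tt$t, dim = features$dim),
                        p = array(tt$p, dim = features$dim),
                        selected = array(sel, dim = features$dim))
  }
  index <- dplyr::bind_rows(lapply(names(planes), function(p)
    tibble::tibble(plane = p, voxel = which(as.vector(planes[[p]]$selected)))))
  structure(list(planes = planes, criteria = criteria, index = index,
                 dim = features$dim,
                 train_subjects = features$subject_id[idx]),
            class = "selection_model")
}

#' @export
print.selection_model <- function(x, ...) {
  cat("<selection_model> alpha ", x$criteria$alpha,
      if (!is.null(x$criteria$mask)) paste0(", mask '", x$criteria$mask$name, "'"),
      ": ", nrow(x$index), " voxels selected over ",
      length(x$planes), " plane(s)\n", sep = "")
  invisible(x)
}

subject_index <- function(features, subjects) {
  if (is.null(subjects)) return(seq_along(features$subject_id))
  if (is.logical(subjects)) return(which(subjects))
  if (is.character(subjects)) {
    idx <- match(subjects, features$subject_id)
    if (anyNA(idx)) {
      stop("unknown subjects: ",
           paste(subjects[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    return(idx)
  }
  as.integer(subjects)
}

#' Apply a fitted selection to subjects
#'
#' Reads each subject's feature values at the model's selected coordinates,
#' concatenating the planes into a single flat feature vector per subject
#' (types 1-2 have a single plane; the LBP-TOP type concatenates the three
#' plane parts).
#'
#' @param model A `selection_model` from [fit_selection()].
#' @param features An `lbp_features` on the same grid and plane set.
#' @param subjects Subjects to extract (default all).
#' @return Matrix of shape subjects x selected-features, with subject ids as
#'   row names. Zero selected voxels gives a 0-column matrix.
#' @export
apply_selection <- function(model, features, subjects = NULL) {
  stopifnot(inherits(model, "selection_model"),
            inherits(features, "lbp_features"))
  if (!identical(model$dim, features$dim)) {
    stop("feature grid does not match the selection model grid", call. = FALSE)
  }
  if (!identical(sort(names(model$planes)), sort(names(features$planes)))) {
    stop("feature planes do not match the selection model planes", call. = FALSE)
  }
  idx <- subject_index(features, subjects)
  parts <- lapply(names(model$planes), function(p) {
    vox <- model$index$voxel[model$index$plane == p]
    t(features$planes[[p]][vox, idx, drop = FALSE])
  })
  out <- do.call(cbind, parts)
  rownames(out) <- features$subject_id[idx]
  out
}
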