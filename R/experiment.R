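#' Compare the three feature types on one cohort
#'
#' Runs the full pipeline — feature extraction, two-step selection inside
#' the CV loop, linear SVM, repeated stratified CV — once per feature type
#' and collects the mean metrics into one comparison table. On a
#' multi-scanner cohort (per-subject gamma transforms) the expected ordering
#' is type 3 (LBP-TOP) > type 2 (histogram-matched) > type 1 (raw
#' intensities), the last near chance: unadjusted gray values from
#' different scanners are not comparable voxelwise.
#'
#' @param cohort A cohort list from [make_cohort()], or a manifest tibble
#'   (then `template` and `brain_mask` must be given for type 2).
#' @param types Feature types to compare (default 1:3).
#' @param criteria A [selection_criteria()].
#' @param cfg A [cv_config()].
#' @param template,brain_mask Overrides when `cohort` is a bare manifest.
#' @param fwhm_mm Smoothing FWHM for type 3.
#' @return A `lbp_type_comparison`: `table` tibble (one row per type with
#'   mean metrics) and `cv` / `metrics` lists keyed by type.
#' @export
compare_feature_types <- function(cohort, types = c(1L, 2L, 3L),
                                  criteria = selection_criteria(),
                                  cfg = cv_config(),
                                  template = NULL, brain_mask = NULL,
                                  fwhm_mm = 4) {
  if (is.data.frame(cohort)) {
    manifest <- cohort
  } else {
    manifest <- cohort$manifest
    if (is.null(template)) template <- cohort$template
    if (is.null(brain_mask) && !is.null(template$brain_mask)) {
      brain_mask <- template$brain_mask
    }
  }
  cvs <- list(); mets <- list()
  for (ty in types) {
    feats <- collect_features(manifest, ty, template = template,
                              brain_mask = brain_mask, fwhm_mm = fwhm_mm)
    cvs[[as.character(ty)]] <- run_cv(feats, criteria, cfg)
    mets[[as.character(ty)]] <- compute_metrics(cvs[[as.character(ty)]])
  }
  table <- dplyr::bind_rows(lapply(names(mets), function(ty)
    dplyr::mutate(mets[[ty]]$summary, type = as.integer(ty), .before = 1)))
  structure(list(table = table, cv = cvs, metrics = mets),
            class = "lbp_type_comparison")
}

#' @export
print.lbp_type_comparison <- function(x, ...) {
  cat("<lbp_type_comparison>\n")
  print(x$table)
  invisible(x)
}

#' Compare anatomical masks as second-step selectors
#'
#' Reruns the CV once per mask (plus optionally no mask, first-step
#' selection alone) on an already-extracted feature set, and tabulates the
#' mean metrics together with pairwise McNemar z-scores on a shared repeat.
#'
#' @param features An `lbp_features`.
#' @param masks Named list of [binary_mask()] objects (e.g. from
#'   [make_cohort()]).
#' @param alpha First-step p threshold.
#' @param cfg A [cv_config()].
#' @param include_no_mask Also run first-step-only selection (reported as
#'   `none`).
#' @param mcnemar_repeat Repeat used for the pairwise comparison.
#' @return A `lbp_mask_comparison`: `table` (per-mask mean metrics),
#'   `mcnemar` (pairwise z), `cv` list.
#' @export
compare_masks <- function(features, masks, alpha = 0.001, cfg = cv_config(),
                          include_no_mask = FALSE, mcnemar_repeat = 1L) {
  runs <- list()
  for (nm in names(masks)) {
    runs[[nm]] <- run_cv(features, selection_criteria(alpha, masks[[nm]]), cfg)
  }
  if (include_no_mask) {
    runs[["none"]] <- run_cv(features, selection_criteria(alpha, NULL), cfg)
  }
  table <- dplyr::bind_rows(lapply(names(runs), function(nm)
    dplyr::mutate(compute_metrics(runs[[nm]])$summary, mask = nm, .before = 1)))
  nms <- names(runs)
  pairs <- tidyr::expand_grid(mask_a = nms, mask_b = nms) |>
    dplyr::filter(.data$mask_a < .data$mask_b)
  mcn <- purrr::pmap_dfr(pairs, function(mask_a, mask_b) {
    dplyr::mutate(
      mcnemar_compare(cv_correct(runs[[mask_a]], mcnemar_repeat),
                      cv_correct(runs[[mask_b]], mcnemar_repeat)),
      mask_a = mask_a, mask_b = mask_b, .before = 1)
  })
  structure(list(table = table, mcnemar = mcn, cv = runs),
            class = "lbp_mask_comparison")
}

#' @export
print.lbp_mask_comparison <- function(x, ...) {
  cat("<lbp_mask_comparison>\n")
  print(x$table)
  invisible(x)
}

#' Run a full phantom experiment end to end
#'
#' Generates (or reuses) a phantom cohort, compares the three feature types
#' under the chosen mask, runs the McNemar comparison of the LBP-TOP
#' classifier against the histogram-matched baseline, builds the LBP-TOP
#' weight map, and — when `out_dir` is given — writes the metrics, ROC
#' points, predictions and comparison tables as TSV plus the weight maps as
#' NIfTI. One seed drives cohort generation and every CV.
#'
#' @param spec A [phantom_spec()] (its `seed` drives the cohort), or an
#'   existing cohort list from [make_cohort()].
#' @param mask_name Which cohort mask to use for the second selection step
#'   (default `"OVALL"`; `"none"` skips step two).
#' @param types Feature types to run.
#' @param alpha First-step p threshold.
#' @param cfg A [cv_config()].
#' @param out_dir Optional output directory for result files.
#' @return An `lbp_experiment`: the `comparison`, `mcnemar` (type 3 vs 2
#'   when both ran), `weight_map`, `cohort`, and `files` written.
#' @export
run_experiment <- function(spec, mask_name = "OVALL", types = c(1L, 2L, 3L),
                           alpha = 0.001, cfg = cv_config(),
                           out_dir = NULL) {
  cohort <- if (inherits(spec, "phantom_spec")) make_cohort(spec) else spec
  mask <- if (identical(mask_name, "none")) NULL else cohort$masks[[mask_name]]
  if (!identical(mask_name, "none") && is.null(mask)) {
    stop("unknown mask: ", mask_name, call. = FALSE)
  }
  comparison <- compare_feature_types(cohort, types = types,
                                      criteria = selection_criteria(alpha, mask),
                                      cfg = cfg)
  mcn <- NULL
  if (all(c("2", "3") %in% names(comparison$cv))) {
    mcn <- mcnemar_compare(cv_correct(comparison$cv[["3"]]),
                           cv_correct(comparison$cv[["2"]]))
  }
  wm <- if ("3" %in% names(comparison$cv)) weight_map(comparison$cv[["3"]]) else NULL
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    f_tab <- file.path(out_dir, "type_comparison.tsv")
    readr::write_tsv(comparison$table, f_tab)
    files <- f_tab
    for (ty in names(comparison$metrics)) {
      m <- comparison$metrics[[ty]]
      f1 <- file.path(out_dir, sprintf("metrics_type%s.tsv", ty))
      f2 <- file.path(out_dir, sprintf("roc_type%s.tsv", ty))
      f3 <- file.path(out_dir, sprintf("predictions_type%s.tsv", ty))
      readr::write_tsv(m$per_repeat, f1)
      readr::write_tsv(m$roc, f2)
      readr::write_tsv(comparison$cv[[ty]]$predictions, f3)
      files <- c(files, f1, f2, f3)
    }
    if (!is.null(mcn)) {
      f <- file.path(out_dir, "mcnemar_type3_vs_type2.tsv")
      readr::write_tsv(mcn, f); files <- c(files, f)
    }
    if (!is.null(wm)) files <- c(files, write_weight_map(wm, out_dir))
  }
  structure(list(comparison = comparison, mcnemar = mcn, weight_map = wm,
                 cohort = cohort, files = files),
            class = "lbp_experiment")
}

#' @export
print.lbp_experiment <- function(x, ...) {
  print(x$comparison)
  if (!is.null(x$mcnemar)) {
    cat("McNemar type 3 vs type 2:\n"); print(x$mcnemar)
  }
  invisible(x)
}
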