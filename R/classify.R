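#' Cross-validation configuration
#'
#' Stratified k-fold cross-validation repeated `n_repeats` times. Both the
#' first-step t-test selection and the per-feature standardization are refit
#' inside every training fold, so test subjects never leak into any fitted
#' component. A linear SVM is used throughout: its primal weights are what
#' the weight-map back-projection requires.
#'
#' @param n_folds Folds per repeat (default 10).
#' @param n_repeats Repeats of the whole CV (default 30).
#' @param seed Integer seed; every source of randomness in [run_cv()]
#'   derives from it.
#' @param svm_c SVM regularization constant C (default 1).
#' @param standardize Z-score features on the training fold (default TRUE).
#' @param stratified Keep class proportions across folds (default TRUE).
#' @return A `cv_config` object.
#' @export
cv_config <- function(n_folds = 10L, n_repeats = 30L, seed = 1L,
                      svm_c = 1, standardize = TRUE, stratified = TRUE) {
  stopifnot(n_folds >= 2L, n_repeats >= 1L, svm_c > 0)
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed),
                 svm_c = svm_c, standardize = isTRUE(standardize),
                 stratified = isTRUE(stratified)),
            class = "cv_config")
}

# Stratified fold assignment: shuffle within each class, deal round-robin.
assign_folds <- function(labels, n_folds, stratified) {
  fold <- integer(length(labels))
  if (stratified) {
    for (cl in unique(labels)) {
      i <- which(labels == cl)
      fold[sample(i)] <- rep_len(seq_len(n_folds), length(i))
    }
  } else {
    fold[sample(seq_along(labels))] <- rep_len(seq_len(n_folds), length(labels))
  }
  fold
}

# Train a linear SVM on a subjects x features matrix with labels in {-1,+1}.
# Decision scores are normalized so positive always favors class +1,
# regardless of e1071's internal label order.
fit_linear_svm <- function(X, y, cost) {
  fac <- factor(y, levels = c(-1, 1))
  m <- e1071::svm(x = X, y = fac, kernel = "linear", cost = cost,
                  scale = FALSE)
  w <- drop(t(m$coefs) %*% m$SV)
  b <- -m$rho
  # e1071 scores are positive for the first factor level seen in training
  if (as.character(m$levels[m$labels[1]]) == "-1") { w <- -w; b <- -b }
  list(weights = w, bias = b)
}

decision_scores <- function(svm_fit, X) {
  drop(X %*% svm_fit$weights) + svm_fit$bias
}

#' Repeated cross-validated SVM classification
#'
#' For each repeat, draws a seeded stratified fold split; for each fold,
#' fits the two-step selection on the training subjects only, standardizes
#' on the training fold, trains a linear SVM with labels +1/-1, and records
#' test predictions (sign of the decision score) and scores. All randomness
#' derives from `cfg$seed`, so identical inputs give identical results.
#'
#' A fold whose selection retains zero voxels (possible under null cohorts
#' at strict alpha) falls back to scoring every test subject 0 and
#' predicting the training majority class.
#'
#' @param features An `lbp_features` from [collect_features()].
#' @param criteria A [selection_criteria()].
#' @param cfg A [cv_config()].
#' @return An `lbp_cv` object: `predictions` tibble (`repeat_id`, `fold`,
#'   `subject_id`, `label`, `score`, `pred`), per-fold fitted components in
#'   `models`, plus config and grid metadata.
#' @export
run_cv <- function(features, criteria = selection_criteria(),
                   cfg = cv_config()) {
  stopifnot(inherits(features, "lbp_features"), inherits(cfg, "cv_config"))
  labels <- features$label
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == -1L)
  if (min(n_pos, n_neg) < cfg$n_folds && cfg$stratified) {
    stop("smallest class (", min(n_pos, n_neg),
         ") is too small for ", cfg$n_folds, "-fold stratification",
         call. = FALSE)
  }
  preds <- vector("list", cfg$n_repeats)
  models <- vector("list", cfg$n_repeats)
  with_local_seed(cfg$seed, {
    for (r in seq_len(cfg$n_repeats)) {
      fold <- assign_folds(labels, cfg$n_folds, cfg$stratified)
      fold_rows <- vector("list", cfg$n_folds)
      fold_models <- vector("list", cfg$n_folds)
      for (f in seq_len(cfg$n_folds)) {
        test_i <- which(fold == f)
        train_i <- which(fold != f)
        sel <- fit_selection(features, criteria, subjects = train_i)
        Xtr <- apply_selection(sel, features, subjects = train_i)
        Xte <- apply_selection(sel, features, subjects = test_i)
        ytr <- labels[train_i]
        if (ncol(Xtr) == 0L) {
          maj <- if (sum(ytr == 1L) >= sum(ytr == -1L)) 1L else -1L
          score <- rep(0, length(test_i))
          pred <- rep(maj, length(test_i))
          fold_models[[f]] <- list(index = sel$index, weights = numeric(0),
                                   bias = 0, center = numeric(0),
                                   scale = numeric(0),
                                   train_subjects = features$subject_id[train_i])
        } else {
          ctr <- rep(0, ncol(Xtr)); scl <- rep(1, ncol(Xtr))
          if (cfg$standardize) {
            ctr <- colMeans(Xtr)
            scl <- apply(Xtr, 2, stats::sd)
            scl[scl == 0] <- 1
          }
          Xtr <- sweep(sweep(Xtr, 2, ctr), 2, scl, "/")
          Xte <- sweep(sweep(Xte, 2, ctr), 2, scl, "/")
          svm_fit <- fit_linear_svm(Xtr, ytr, cfg$svm_c)
          score <- decision_scores(svm_fit, Xte)
          pred <- ifelse(score >= 0, 1L, -1L)
          fold_models[[f]] <- list(index = sel$index,
                                   weights = svm_fit$weights,
                                   bias = svm_fit$bias,
                                   center = ctr, scale = scl,
                                   train_subjects = features$subject_id[train_i])
        }
        fold_rows[[f]] <- tibble::tibble(
          repeat_id = r, fold = f,
          subject_id = features$subject_id[test_i],
          label = labels[test_i], score = score, pred = as.integer(pred))
      }
      preds[[r]] <- dplyr::bind_rows(fold_rows)
      models[[r]] <- fold_models
    }
  })
  structure(list(predictions = dplyr::bind_rows(preds), models = models,
                 config = cfg, criteria = criteria, dim = features$dim,
                 planes = names(features$planes), spacing = features$spacing,
                 subject_id = features$subject_id, label = features$label),
            class = "lbp_cv")
}

#' @export
print.lbp_cv <- function(x, ...) {
  cat("<lbp_cv> ", length(x$subject_id), " subjects, ",
      x$config$n_folds, "-fold x ", x$config$n_repeats, " repeats\n", sep = "")
  invisible(x)
}

#' Rank-based AUC (Mann-Whitney formulation)
#'
#' @param scores Numeric decision scores.
#' @param labels Class labels in \{-1, +1\}.
#' @return AUC in \[0, 1\]; ties contribute 1/2.
#' @export
auc_rank <- function(scores, labels) {
  pos <- labels == 1L
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("need both classes for AUC", call. = FALSE)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  tp <- cumsum(lab == 1L); fp <- cumsum(lab == -1L)
  # collapse tied scores to one operating point
  last_of_tie <- c(diff(scores[ord]) != 0, TRUE)
  tibble::tibble(
    threshold = c(Inf, scores[ord][last_of_tie]),
    tpr = c(0, tp[last_of_tie] / sum(labels == 1L)),
    fpr = c(0, fp[last_of_tie] / sum(labels == -1L))
  )
}

#' Classification performance metrics
#'
#' Per repeat: accuracy (fraction of correctly classified subjects),
#' sensitivity (true-positive rate on label +1), specificity (true-negative
#' rate on label -1), and AUC from the repeat's pooled decision scores via
#' the rank (Mann-Whitney) formulation. Means over repeats are reported
#' alongside, plus the AUC of all repeats' scores pooled together (the two
#' aggregations can differ; both are given).
#'
#' @param cv An `lbp_cv` from [run_cv()].
#' @return An `lbp_metrics`: `per_repeat` tibble, `summary` one-row tibble,
#'   `roc` tibble of per-repeat ROC points.
#' @export
compute_metrics <- function(cv) {
  stopifnot(inherits(cv, "lbp_cv"))
  pr <- cv$predictions
  if (nrow(pr) == 0L || anyNA(pr$score)) stop("missing decision scores", call. = FALSE)
  per_repeat <- pr |>
    dplyr::group_by(.data$repeat_id) |>
    dplyr::summarise(
      accuracy = mean(.data$pred == .data$label),
      sensitivity = mean(.data$pred[.data$label == 1L] == 1L),
      specificity = mean(.data$pred[.data$label == -1L] == -1L),
      auc = auc_rank(.data$score, .data$label),
      .groups = "drop")
  roc <- pr |>
    dplyr::group_by(.data$repeat_id) |>
    dplyr::reframe(roc_points(.data$score, .data$label))
  summary <- tibble::tibble(
    n_subjects = length(cv$subject_id),
    n_repeats = cv$config$n_repeats,
    accuracy = mean(per_repeat$accuracy),
    sensitivity = mean(per_repeat$sensitivity),
    specificity = mean(per_repeat$specificity),
    auc = mean(per_repeat$auc),
    auc_pooled = auc_rank(pr$score, pr$label))
  structure(list(per_repeat = per_repeat, summary = summary, roc = roc),
            class = "lbp_metrics")
}

#' @export
print.lbp_metrics <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<lbp_metrics> %d subjects, %d repeat(s)\n",
                     "  accuracy %.3f  sensitivity %.3f  specificity %.3f",
                     "  AUC %.3f\n"),
              s$n_subjects, s$n_repeats, s$accuracy, s$sensitivity,
              s$specificity, s$auc))
  invisible(x)
}

#' Per-subject correctness from one CV repeat
#'
#' @param cv An `lbp_cv`.
#' @param repeat_id Which repeat to read (default 1).
#' @return Tibble `subject_id`, `correct`, ordered by subject id.
#' @export
cv_correct <- function(cv, repeat_id = 1L) {
  stopifnot(inherits(cv, "lbp_cv"))
  cv$predictions |>
    dplyr::filter(.data$repeat_id == !!repeat_id) |>
    dplyr::transmute(.data$subject_id, correct = .data$pred == .data$label) |>
    dplyr::arrange(.data$subject_id)
}

#' McNemar comparison of two paired classifiers
#'
#' Compares per-subject correctness of two classifiers evaluated on the same
#' subjects: `b` counts subjects A got right and B wrong, `c` the converse;
#' `z = |b - c| / sqrt(b + c)` (no continuity correction by default), with a
#' two-sided normal p-value. `b = c = 0` is defined as z = 0. The two-sided
#' 95 percent significance threshold is z > 1.960.
#'
#' @param correct_a,correct_b Logical vectors (same subjects, same order) or
#'   tibbles from [cv_correct()] (joined on `subject_id`).
#' @param correction Apply the continuity correction `(|b-c|-1)` (clamped at
#'   0) instead of the plain statistic.
#' @return A one-row tibble: `b`, `c`, `z`, `p`, `significant`.
#' @export
mcnemar_compare <- function(correct_a, correct_b, correction = FALSE) {
  if (is.data.frame(correct_a) && is.data.frame(correct_b)) {
    j <- dplyr::inner_join(correct_a, correct_b, by = "subject_id",
                           suffix = c("_a", "_b"))
    if (nrow(j) != nrow(correct_a) || nrow(j) != nrow(correct_b)) {
      stop("classifiers were evaluated on different subjects", call. = FALSE)
    }
    correct_a <- j$correct_a; correct_b <- j$correct_b
  }
  if (length(correct_a) != length(correct_b)) {
    stop("correctness vectors differ in length", call. = FALSE)
  }
  b <- sum(correct_a & !correct_b)
  c <- sum(!correct_a & correct_b)
  if (b + c == 0L) {
    z <- 0
  } else {
    num <- abs(b - c) - if (correction) 1 else 0
    z <- max(0, num) / sqrt(b + c)
  }
  tibble::tibble(b = b, c = c, z = z, p = 2 * stats::pnorm(-z),
                 significant = z > stats::qnorm(0.975))
}

#' SVM weight maps back-projected to template space
#'
#' For one CV repeat, averages the absolute linear-SVM weight of each
#' (plane, voxel) over the repeat's folds, counting 0 whenever the voxel was
#' not selected in a fold, then min-max normalizes to \[0, 1\] over the
#' ever-selected voxels (a constant nonzero map normalizes to 1 everywhere
#' selected). Never-selected voxels are 0.
#'
#' @param cv An `lbp_cv` fitted with the linear kernel.
#' @param repeat_id Which repeat to aggregate (default 1).
#' @return An `lbp_weight_map`: named list `maps` of per-plane arrays in
#'   \[0, 1\], plus `spacing`.
#' @export
weight_map <- function(cv, repeat_id = 1L) {
  stopifnot(inherits(cv, "lbp_cv"))
  folds <- cv$models[[repeat_id]]
  acc <- lapply(cv$planes, function(p) numeric(prod(cv$dim)))
  names(acc) <- cv$planes
  ever <- lapply(acc, function(a) logical(length(a)))
  for (fm in folds) {
    if (length(fm$weights) == 0L) next
    offsets <- c(0L, cumsum(vapply(cv$planes, function(p)
      sum(fm$index$plane == p), integer(1))))
    for (pi in seq_along(cv$planes)) {
      p <- cv$planes[pi]
      vox <- fm$index$voxel[fm$index$plane == p]
      if (length(vox) == 0L) next
      w <- fm$weights[(offsets[pi] + 1L):offsets[pi + 1L]]
      acc[[p]][vox] <- acc[[p]][vox] + abs(w)
      ever[[p]][vox] <- TRUE
    }
  }
  n_folds <- length(folds)
  any_sel <- unlist(ever)
  vals <- unlist(acc) / n_folds
  sel_vals <- vals[any_sel]
  maps <- lapply(cv$planes, function(p) array(0, dim = cv$dim))
  names(maps) <- cv$planes
  if (any(any_sel)) {
    lo <- min(sel_vals); hi <- max(sel_vals)
    for (p in cv$planes) {
      v <- acc[[p]] / n_folds
      norm <- if (hi > lo) (v - lo) / (hi - lo) else rep(1, length(v))
      m <- numeric(length(v))
      m[ever[[p]]] <- norm[ever[[p]]]
      maps[[p]] <- array(m, dim = cv$dim)
    }
  }
  structure(list(maps = maps, spacing = cv$spacing), class = "lbp_weight_map")
}

#' Write weight maps as per-plane NIfTI files
#'
#' @param wm An `lbp_weight_map`.
#' @param dir Output directory.
#' @param prefix File name prefix.
#' @return Paths written, invisibly.
#' @export
write_weight_map <- function(wm, dir, prefix = "weights") {
  stopifnot(inherits(wm, "lbp_weight_map"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(wm$maps), function(p) {
    f <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, p))
    write_volume(wm$maps[[p]], f, spacing = wm$spacing)
    f
  }, character(1))
  invisible(paths)
}
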