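test_that("McNemar statistic follows z = |b - c| / sqrt(b + c)", {
  # symmetric discordance
  a <- c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE)
  b <- c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE)
  r <- mcnemar_compare(a, b)
  expect_equal(r$z, 0)
  expect_equal(r$p, 1)

  # b = 20, c = 5 -> z = 15 / 5 = 3.0 by hand
  ca <- c(rep(TRUE, 20), rep(FALSE, 5), rep(TRUE, 10))
  cb <- c(rep(FALSE, 20), rep(TRUE, 5), rep(TRUE, 10))
  r2 <- mcnemar_compare(ca, cb)
  expect_equal(r2$b, 20)
  expect_equal(r2$c, 5)
  expect_equal(r2$z, 3.0)
  expect_true(r2$significant)

  # no discordance at all is defined as z = 0
  r3 <- mcnemar_compare(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_equal(r3$z, 0)

  # continuity correction shrinks the statistic, clamped at zero
  r4 <- mcnemar_compare(ca, cb, correction = TRUE)
  expect_equal(r4$z, 14 / 5)
  r5 <- mcnemar_compare(c(TRUE, FALSE, TRUE), c(FALSE, TRUE, TRUE),
                        correction = TRUE)
  expect_equal(r5$z, 0)

  expect_error(mcnemar_compare(c(TRUE, TRUE), c(TRUE)), "length")
})

test_that("the two-sided 95% threshold used for significance is 1.960", {
  expect_equal(round(stats::qnorm(0.975), 3), 1.960)
  # a z just above/below the threshold flips significance
  ca <- c(rep(TRUE, 4), FALSE)
  cb <- c(rep(FALSE, 4), TRUE)  # b=4, c=1, z = 3/sqrt(5) = 1.342
  expect_false(mcnemar_compare(ca, cb)$significant)
})

test_that("rank AUC behaves as a proper concordance statistic", {
  set.seed(31)
  labels <- rep(c(1L, -1L), each = 500)
  # label-independent scores: AUC near 1/2
  expect_equal(auc_rank(rnorm(1000), labels), 0.5, tolerance = 0.06)
  # perfect ordering: AUC exactly 1; reversed: 0
  s <- c(runif(500) + 2, runif(500))
  expect_identical(auc_rank(s, labels), 1)
  expect_identical(auc_rank(-s, labels), 0)
  # invariant under strictly increasing transforms of the scores
  s2 <- rnorm(1000)
  expect_equal(auc_rank(exp(s2), labels), auc_rank(s2, labels))
  # all-tied scores give exactly 1/2
  expect_equal(auc_rank(rep(0, 1000), labels), 0.5)
  # agreement with an independent implementation
  skip_if_not_installed("pROC")
  expect_equal(auc_rank(s2, labels),
               as.numeric(pROC::auc(pROC::roc(labels, s2, quiet = TRUE,
                                              direction = "<"))))
})

test_that("linear SVM decision scores are oriented toward the +1 class", {
  set.seed(32)
  X <- rbind(matrix(rnorm(20 * 3, mean = 2), ncol = 3),
             matrix(rnorm(20 * 3, mean = -2), ncol = 3))
  y <- rep(c(1L, -1L), each = 20)
  for (perm in list(seq_len(40), sample(40))) {
    f <- lbptop:::fit_linear_svm(X[perm, ], y[perm], cost = 1)
    sc <- lbptop:::decision_scores(f, X[perm, ])
    expect_true(all(sc[y[perm] == 1L] > 0))
    expect_true(all(sc[y[perm] == -1L] < 0))
  }
})

test_that("repeated CV is deterministic and partitions subjects each repeat", {
  co <- cohort_effect()
  fe <- features_effect_t3()
  cfg <- cv_config(n_folds = 4, n_repeats = 2, seed = 99)
  cv1 <- cv_effect_t3()
  cv2 <- run_cv(fe, selection_criteria(0.001, co$masks$OVALL), cfg)
  expect_identical(cv1$predictions, cv2$predictions)

  for (r in 1:2) {
    pr <- dplyr::filter(cv1$predictions, repeat_id == r)
    expect_setequal(pr$subject_id, fe$subject_id)   # exhaustive
    expect_equal(nrow(pr), length(fe$subject_id))    # disjoint
    # stratification keeps classes spread over folds
    by_fold <- dplyr::count(pr, fold, label)
    expect_true(all(by_fold$n >= 1))
  }
})

test_that("no fold model ever saw its own test subjects", {
  cv <- cv_effect_t3()
  for (r in seq_along(cv$models)) {
    for (f in seq_along(cv$models[[r]])) {
      test_ids <- cv$predictions |>
        dplyr::filter(repeat_id == r, fold == f) |>
        dplyr::pull(subject_id)
      expect_length(intersect(test_ids, cv$models[[r]][[f]]$train_subjects), 0)
      expect_setequal(c(test_ids, cv$models[[r]][[f]]$train_subjects),
                      cv$subject_id)
    }
  }
})

test_that("fold selection models are reproducible from their training ids alone", {
  co <- cohort_effect()
  fe <- features_effect_t3()
  cv <- cv_effect_t3()
  fm <- cv$models[[1]][[2]]
  refit <- fit_selection(fe, selection_criteria(0.001, co$masks$OVALL),
                         subjects = fm$train_subjects)
  expect_identical(refit$index, fm$index)
})

test_that("metrics satisfy their defining identities", {
  cv <- cv_effect_t3()
  m <- compute_metrics(cv)
  n_pos <- sum(cv$label == 1L); n_neg <- sum(cv$label == -1L)
  for (r in seq_len(nrow(m$per_repeat))) {
    row <- m$per_repeat[r, ]
    expect_equal(row$accuracy,
                 (row$sensitivity * n_pos + row$specificity * n_neg) /
                   (n_pos + n_neg))
  }
  expect_true(all(m$per_repeat$auc >= 0 & m$per_repeat$auc <= 1))
  # ROC curves are monotone non-decreasing in both coordinates
  for (r in unique(m$roc$repeat_id)) {
    rr <- dplyr::filter(m$roc, repeat_id == r)
    expect_false(is.unsorted(rr$tpr))
    expect_false(is.unsorted(rr$fpr))
    expect_equal(max(rr$tpr), 1)
    expect_equal(max(rr$fpr), 1)
  }
  # all-correct predictions give unit rates
  cv_perfect <- cv
  cv_perfect$predictions$pred <- cv_perfect$predictions$label
  cv_perfect$predictions$score <- cv_perfect$predictions$label * 1.0
  mp <- compute_metrics(cv_perfect)
  expect_equal(mp$summary$accuracy, 1)
  expect_equal(mp$summary$sensitivity, 1)
  expect_equal(mp$summary$specificity, 1)
  expect_equal(mp$summary$auc, 1)
})

test_that("a strong-atrophy cohort is well classified with LBP-TOP + OVALL", {
  m <- compute_metrics(cv_effect_t3())
  expect_gte(m$summary$auc, 0.9)
})

test_that("weight maps are normalized over ever-selected voxels only", {
  cv <- cv_effect_t3()
  wm <- weight_map(cv, repeat_id = 1)
  all_vals <- unlist(wm$maps)
  expect_true(all(all_vals >= 0 & all_vals <= 1))
  expect_equal(max(all_vals), 1)
  # voxels never selected in any fold are exactly zero
  ever <- list()
  for (fm in cv$models[[1]]) {
    for (p in unique(fm$index$plane)) {
      ever[[p]] <- union(ever[[p]], fm$index$voxel[fm$index$plane == p])
    }
  }
  for (p in names(wm$maps)) {
    v <- as.vector(wm$maps[[p]])
    unsel <- setdiff(seq_along(v), ever[[p]])
    expect_true(all(v[unsel] == 0))
  }
  # degenerate constant-weight case maps to 1 by convention
  cv_one <- cv
  cv_one$models <- list(list(list(
    index = tibble::tibble(plane = "yz", voxel = c(3L, 5L)),
    weights = c(0.7, 0.7), bias = 0, center = c(0, 0), scale = c(1, 1),
    train_subjects = cv$subject_id)))
  wm1 <- weight_map(cv_one, 1)
  expect_equal(wm1$maps$yz[c(3, 5)], c(1, 1))
})

test_that("tidiers return tibbles and the glance row matches the metrics", {
  cv <- cv_effect_t3()
  expect_s3_class(tidy(cv), "tbl_df")
  g <- glance(cv)
  m <- compute_metrics(cv)
  expect_equal(g, m$summary)
  expect_equal(tidy(m), m$per_repeat)
  p <- ggplot2::autoplot(m)
  expect_s3_class(p, "ggplot")
})

test_that("a null cohort with noise classifies at chance level", {
  spec <- phantom_spec(shape = c(24, 24, 24), n_per_group = 10,
                       atrophy_fraction = 1, ventricle_dilation = 1,
                       scanner_gammas = 1, noise_sigma = 0.1, jitter_mm = 0,
                       seed = 505)
  co <- make_cohort(spec, withr::local_tempdir())
  fe <- collect_features(co$manifest, 1, brain_mask = co$template$brain_mask)
  cv <- run_cv(fe, selection_criteria(0.001), cv_config(n_folds = 5,
                                                        n_repeats = 3,
                                                        seed = 506))
  m <- compute_metrics(cv)
  # binomial SD at n=20 is 0.11 per repeat; allow 3 SDs around chance
  expect_lt(abs(m$summary$accuracy - 0.5), 0.34)
  expect_lt(abs(m$summary$auc - 0.5), 0.3)
})
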