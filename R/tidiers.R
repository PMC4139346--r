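#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy CV predictions
#'
#' @param x An `lbp_cv`.
#' @param ... Unused.
#' @return The predictions tibble (`repeat_id`, `fold`, `subject_id`,
#'   `label`, `score`, `pred`).
#' @method tidy lbp_cv
#' @export
tidy.lbp_cv <- function(x, ...) x$predictions

#' One-row CV summary
#'
#' @param x An `lbp_cv`.
#' @param ... Unused.
#' @method glance lbp_cv
#' @export
glance.lbp_cv <- function(x, ...) compute_metrics(x)$summary

#' Per-repeat metrics
#'
#' @param x An `lbp_metrics`.
#' @param ... Unused.
#' @method tidy lbp_metrics
#' @export
tidy.lbp_metrics <- function(x, ...) x$per_repeat

#' One-row metric means
#'
#' @param x An `lbp_metrics`.
#' @param ... Unused.
#' @method glance lbp_metrics
#' @export
glance.lbp_metrics <- function(x, ...) x$summary

#' ROC curves, one per CV repeat
#'
#' @param object An `lbp_metrics`.
#' @param ... Unused.
#' @return A ggplot of per-repeat ROC curves with the chance diagonal.
#' @method autoplot lbp_metrics
#' @export
autoplot.lbp_metrics <- function(object, ...) {
  ggplot2::ggplot(object$roc,
                  ggplot2::aes(.data$fpr, .data$tpr,
                               group = .data$repeat_id)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(alpha = 0.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC over %d repeat(s), mean AUC %.3f",
                                  object$summary$n_repeats,
                                  object$summary$auc)) +
    ggplot2::theme_minimal()
}

#' Feature-type comparison plot
#'
#' @param object An `lbp_type_comparison`.
#' @param ... Unused.
#' @return A ggplot of mean AUC per feature type.
#' @method autoplot lbp_type_comparison
#' @export
autoplot.lbp_type_comparison <- function(object, ...) {
  long <- object$table |>
    dplyr::select("type", "accuracy", "sensitivity", "specificity", "auc") |>
    tidyr::pivot_longer(-"type", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(factor(.data$type), .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "Feature type", y = NULL) +
    ggplot2::theme_minimal()
}

#' Mid-slice image of a weight map
#'
#' @param object An `lbp_weight_map`.
#' @param plane Which plane map to show (default first).
#' @param slice Axial slice index (default middle).
#' @param ... Unused.
#' @method autoplot lbp_weight_map
#' @export
autoplot.lbp_weight_map <- function(object, plane = names(object$maps)[1],
                                    slice = NULL, ...) {
  m <- object$maps[[plane]]
  if (is.null(slice)) slice <- ceiling(dim(m)[3] / 2)
  df <- tidyr::expand_grid(y = seq_len(dim(m)[2]), x = seq_len(dim(m)[1])) |>
    dplyr::mutate(w = as.vector(m[, , slice]))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$w)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "|w|") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Normalized SVM weights, plane %s, slice %d",
                                  plane, slice)) +
    ggplot2::theme_minimal()
}
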