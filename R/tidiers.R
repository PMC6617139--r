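#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an elimination trace
#'
#' One row per elimination step: the removed feature, its multivariate
#' p-value, and the refitted model's cross-validated accuracy.
#'
#' @param x An `elimination_trace` from [backward_eliminate()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.elimination_trace <- function(x, ...) {
  x$steps
}

#' Summarize an elimination trace
#'
#' @param x An `elimination_trace`.
#' @param ... Unused.
#' @return One-row tibble: task, candidate/retained counts, retained set,
#'   whether everything was eliminated.
#' @export
glance.elimination_trace <- function(x, ...) {
  tibble::tibble(
    task_id = x$task_id,
    n_candidates = length(x$screened_in),
    n_steps = nrow(x$steps),
    n_retained = length(x$retained),
    retained = paste(x$retained, collapse = "+"),
    all_eliminated = x$all_eliminated
  )
}

#' Tidy a classifier report
#'
#' The pooled out-of-fold predictions, one row per eye.
#'
#' @param x A `classifier_report` from [train_task()].
#' @param ... Unused.
#' @return A tibble: subject_id, truth, predicted.
#' @export
tidy.classifier_report <- function(x, ...) {
  x$predictions
}

#' Summarize a classifier report
#'
#' @param x A `classifier_report`.
#' @param ... Unused.
#' @return One-row tibble with task, features, folds, sensitivity,
#'   specificity, accuracy (%), and AUC.
#' @export
glance.classifier_report <- function(x, ...) {
  tibble::tibble(
    task_id = x$task_id,
    features = paste(x$feature_subset, collapse = "+"),
    folds = x$folds,
    sensitivity = x$sensitivity,
    specificity = x$specificity,
    accuracy = x$accuracy,
    auc = x$auc
  )
}

#' ROC curve plot for a classifier report
#'
#' @param object A `classifier_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.classifier_report <- function(object, ...) {
  pts <- object$roc_points
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("%s: AUC = %.3f", object$task_id, object$auc)) +
    ggplot2::theme_minimal()
  if ("class" %in% names(pts)) {
    p + ggplot2::geom_path(ggplot2::aes(colour = .data$class))
  } else {
    p + ggplot2::geom_path(colour = "steelblue")
  }
}

#' Elimination-path plot
#'
#' Cross-validated model accuracy after each removal step.
#'
#' @param object An `elimination_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.elimination_trace <- function(object, ...) {
  st <- object$steps
  if (!nrow(st)) {
    st <- tibble::tibble(step = 0, removed = "(none)", p_value = NA_real_,
                         accuracy_after = NA_real_)
  }
  ggplot2::ggplot(st, ggplot2::aes(x = .data$step, y = .data$accuracy_after)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$removed), vjust = -0.8,
                       size = 3) +
    ggplot2::labs(x = "Elimination step", y = "CV accuracy after removal (%)",
                  title = sprintf("Backward elimination: %s", object$task_id)) +
    ggplot2::theme_minimal()
}

#' Feature-map montage plot
#'
#' Raster plot of an angiogram with optional vessel-mask overlay, for quick
#' inspection of segmentations.
#'
#' @param img An [angiogram].
#' @param mask Optional logical overlay mask.
#' @return A ggplot.
#' @export
plot_angiogram <- function(img, mask = NULL) {
  stopifnot(inherits(img, "angiogram"))
  df <- tidyr::expand_grid(row = seq_len(img$height_px),
                           col = seq_len(img$width_px))
  df$intensity <- as.vector(t(img$pixels))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("%s (%.1f mm FOV)", img$layer, img$fov_mm))
  if (!is.null(mask)) {
    ov <- df[as.vector(t(mask)), , drop = FALSE]
    p <- p + ggplot2::geom_raster(data = ov, fill = "red", alpha = 0.4)
  }
  p
}
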