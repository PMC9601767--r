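#' Tidy a CAID evaluation
#'
#' Returns the evaluation's curve points: the precision-recall curve
#' (per-threshold precision, recall and F1) or the ROC curve.
#'
#' @param x A `caid_evaluation` from [caid_evaluate()].
#' @param curve `"pr"` (default) or `"roc"`.
#' @param ... Unused.
#' @return A tibble of curve points.
#' @method tidy caid_evaluation
#' @export
tidy.caid_evaluation <- function(x, curve = c("pr", "roc"), ...) {
  curve <- match.arg(curve)
  if (curve == "pr") {
    x$pr_curve[, c("threshold", "precision", "recall", "f1")]
  } else {
    x$roc_curve
  }
}

#' One-row summary of a CAID evaluation
#'
#' Headline metrics with the conventional reporting precision: Fmax and AUC
#' to 3 decimals, coverage to 2.
#'
#' @param x A `caid_evaluation`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance caid_evaluation
#' @export
glance.caid_evaluation <- function(x, ...) {
  tibble::tibble(
    variant = x$variant %||% NA_character_,
    fmax = round(x$fmax, 3),
    fmax_threshold = x$fmax_threshold,
    auc = round(x$auc, 3),
    coverage = round(x$coverage, 2),
    n_targets = x$n_targets,
    n_residues = x$n_residues
  )
}

#' @rdname tidy.caid_evaluation
#' @method tidy disorder_calibration
#' @export
tidy.disorder_calibration <- function(x, ...) {
  x$curve
}

#' One-row summary of a calibration
#'
#' @param x A `threshold_calibration` or `window_calibration`.
#' @param ... Unused.
#' @return A one-row tibble with the selected operating point.
#' @method glance disorder_calibration
#' @export
glance.disorder_calibration <- function(x, ...) {
  if (inherits(x, "window_calibration")) {
    tibble::tibble(best_window = x$best_window, fmax = x$best_metric)
  } else {
    tibble::tibble(best_threshold = x$best_threshold, f1 = x$best_metric)
  }
}

#' Plot a CAID evaluation curve
#'
#' @param object A `caid_evaluation`.
#' @param curve `"pr"` (precision-recall, default) or `"roc"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot caid_evaluation
#' @export
autoplot.caid_evaluation <- function(object, curve = c("pr", "roc"), ...) {
  curve <- match.arg(curve)
  if (curve == "pr") {
    dat <- tidy(object, "pr")
    ggplot2::ggplot(dat, ggplot2::aes(x = .data$recall, y = .data$precision)) +
      ggplot2::geom_path() +
      ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
      ggplot2::labs(
        x = "Recall", y = "Precision",
        title = sprintf("Precision-recall (Fmax = %.3f at %.3f)",
                        object$fmax, object$fmax_threshold),
        subtitle = object$variant
      ) +
      ggplot2::theme_minimal()
  } else {
    dat <- tidy(object, "roc")
    ggplot2::ggplot(dat, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_path() +
      ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
      ggplot2::labs(
        x = "False positive rate", y = "True positive rate",
        title = sprintf("ROC (AUC = %.3f)", object$auc),
        subtitle = object$variant
      ) +
      ggplot2::theme_minimal()
  }
}

#' Plot a calibration curve
#'
#' Metric-versus-threshold (or versus-window) curve with the selected
#' operating point marked.
#'
#' @param object A `threshold_calibration` or `window_calibration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot disorder_calibration
#' @export
autoplot.disorder_calibration <- function(object, ...) {
  if (inherits(object, "window_calibration")) {
    ggplot2::ggplot(object$curve,
                    ggplot2::aes(x = .data$window, y = .data$fmax)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::geom_vline(xintercept = object$best_window,
                          linetype = "dashed", colour = "firebrick") +
      ggplot2::labs(x = "Window (residues)", y = "Pooled Fmax",
                    title = sprintf("Window search: best = %d",
                                    object$best_window)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$curve,
                    ggplot2::aes(x = .data$threshold, y = .data$f1)) +
      ggplot2::geom_line() +
      ggplot2::geom_vline(xintercept = object$best_threshold,
                          linetype = "dashed", colour = "firebrick") +
      ggplot2::labs(x = "Threshold", y = "Pooled F1",
                    title = sprintf("Threshold search: best = %.3f",
                                    object$best_threshold)) +
      ggplot2::theme_minimal()
  }
}

#' Per-residue profile plot of the three scores
#'
#' Score traces along the sequence for one target, with the decision
#' thresholds as dashed lines.
#'
#' @param data Prediction tibble from [predict_disorder()].
#' @param config The [score_config()] whose thresholds to draw.
#' @return A ggplot object.
#' @export
plot_profile <- function(data, config = score_config()) {
  long <- prediction_tracks(data)
  thr <- tibble::tibble(
    variant = c("pLDDT", "RSA", "Bind"),
    threshold = c(config$thr_plddt, config$thr_rsa, config$thr_bind)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(data = thr,
                        ggplot2::aes(yintercept = .data$threshold),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::facet_wrap(ggplot2::vars(.data$variant), ncol = 1) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Residue position", y = "Score") +
    ggplot2::theme_minimal()
}
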