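#' Plot ROC / PR curves
#'
#' @param object A `dsb_eval`.
#' @param curve `"roc"` (default) or `"pr"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dsb_eval <- function(object, curve = c("roc", "pr"), ...) {
  curve <- match.arg(curve)
  if (curve == "roc") {
    ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
      ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
      ggplot2::geom_path() +
      ggplot2::labs(
        x = "False positive rate", y = "True positive rate",
        title = sprintf("ROC (AUROC = %.3f)", object$auroc)
      )
  } else {
    ggplot2::ggplot(object$pr, ggplot2::aes(.data$recall, .data$precision)) +
      ggplot2::geom_path() +
      ggplot2::ylim(0, 1) +
      ggplot2::labs(
        x = "Recall", y = "Precision",
        title = sprintf("Precision-recall (AUPR = %.3f)", object$aupr)
      )
  }
}

#' Plot an average signal profile
#'
#' @param object A `dsb_profile` from [average_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dsb_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$offset, .data$mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::labs(
      x = "Distance from site center (b)", y = "Mean coverage",
      title = sprintf("Average profile (%d sites)", attr(object, "n_sites"))
    )
}

#' Plot forest variable importance or logistic coefficients
#'
#' @param model A `dsb_model`.
#' @param top_n Show at most this many terms (default 20).
#' @return A ggplot.
#' @export
plot_importance <- function(model, top_n = 20L) {
  td <- tidy(model)
  value <- if (model$family == "forest") "importance" else "beta"
  td <- td[td$feature != "(Intercept)", , drop = FALSE]
  td <- head(td[order(-abs(td[[value]])), , drop = FALSE], top_n)
  td$feature <- factor(td$feature, levels = rev(td$feature))
  ggplot2::ggplot(td, ggplot2::aes(.data[[value]], .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = if (value == "importance") {
        "Variable importance (mean decrease in OOB accuracy)"
      } else {
        "Coefficient (log-odds)"
      },
      y = NULL
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
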