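#' Tidy and glance methods
#'
#' broom-style accessors: `tidy()` returns per-term information (variable
#' importance for the forest; coefficients, with odds ratios via
#' `exp(beta)`, for the logistic families) and `glance()` a one-row model
#' or evaluation summary.
#'
#' @param x A `dsb_model` or `dsb_eval`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.dsb_model <- function(x, ...) {
  if (x$family == "forest") {
    return(x$importance)
  }
  out <- x$coefficients
  out$odds_ratio <- beta_to_or(out$beta)
  out
}

#' @rdname tidy.dsb_model
#' @export
glance.dsb_model <- function(x, ...) {
  tibble(
    family = x$family,
    n_features = length(x$feature_names),
    oob_error = if (x$family == "forest") x$fit$oob_error else NA_real_,
    lambda = if (x$family == "lasso_logistic") {
      x$hyperparams$lambda_value
    } else {
      NA_real_
    }
  )
}

#' @rdname tidy.dsb_model
#' @param curve Which curve to return for an evaluation, `"roc"` or
#'   `"pr"`.
#' @export
tidy.dsb_eval <- function(x, curve = c("roc", "pr"), ...) {
  curve <- match.arg(curve)
  x[[curve]]
}

#' @rdname tidy.dsb_model
#' @export
glance.dsb_eval <- function(x, ...) {
  tibble(
    auroc = x$auroc, aupr = x$aupr,
    auroc_ci_lo = if (is.null(x$auroc_ci)) NA_real_ else x$auroc_ci[1],
    auroc_ci_hi = if (is.null(x$auroc_ci)) NA_real_ else x$auroc_ci[2],
    n_boot = x$n_boot, n_pos = x$n_pos, n_neg = x$n_neg
  )
}
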