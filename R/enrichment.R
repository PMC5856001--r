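#' Two-by-two colocalization statistics
#'
#' A feature-by-class contingency table counts positive sites with/without
#' a feature (`a`, `b`) and negative sites with/without it (`c`, `d`).
#' `colocalization()` returns the colocalization percentages per class,
#' `odds_ratio()` the association strength, and `enrichment_test()` a
#' two-sided Fisher exact p-value.
#'
#' @param a,b,c,d Non-negative integer cell counts: positives with /
#'   without the feature, negatives with / without it.
#' @return `colocalization()`: named numeric `(pct_pos, pct_neg)` in
#'   percent.
#' @examples
#' colocalization(91, 9, 11, 89)
#' odds_ratio(194, 806, 10, 990)
#' @export
colocalization <- function(a, b, c, d) {
  check_table(a, b, c, d)
  if (a + b == 0 || c + d == 0) abort("zero row total in contingency table")
  c(pct_pos = 100 * a / (a + b), pct_neg = 100 * c / (c + d))
}

check_table <- function(a, b, c, d) {
  v <- c(a, b, c, d)
  if (any(is.na(v)) || any(v < 0)) abort("cell counts must be non-negative")
  invisible(TRUE)
}

#' @rdname colocalization
#' @param haldane Add 0.5 to every cell before forming the ratio
#'   (stabilizes zero cells)? Default `FALSE`, in which case a zero `b` or
#'   `c` yields `Inf` and a zero `a` or `d` yields 0, never an exception.
#' @return `odds_ratio()`: a single number, possibly 0 or `Inf`.
#' @export
odds_ratio <- function(a, b, c, d, haldane = FALSE) {
  check_table(a, b, c, d)
  if (haldane) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  if (b * c == 0) {
    if (a * d == 0) return(NaN)
    return(Inf)
  }
  (a * d) / (b * c)
}

#' @rdname colocalization
#' @return `odds_ratio_pct()`: the odds ratio implied by two class
#'   percentages, `(p1/(100-p1)) / (p0/(100-p0))`.
#' @param pct_pos,pct_neg Colocalization percentages (0-100).
#' @export
odds_ratio_pct <- function(pct_pos, pct_neg) {
  (pct_pos / (100 - pct_pos)) / (pct_neg / (100 - pct_neg))
}

#' @rdname colocalization
#' @return `enrichment_test()`: two-sided Fisher exact p-value.
#' @export
enrichment_test <- function(a, b, c, d) {
  check_table(a, b, c, d)
  fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE))$p.value
}

#' Multiple-testing adjustment
#'
#' Bonferroni (`min(1, m p)`) or Benjamini-Hochberg step-up adjustment.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"bonferroni"` or `"BH"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "BH")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = method)
}

#' Logistic coefficient to odds ratio
#'
#' The multiplicative change in odds per unit of a predictor implied by a
#' logistic-regression coefficient: `exp(beta)`.
#'
#' @param beta Numeric vector of coefficients.
#' @return `exp(beta)`.
#' @examples
#' beta_to_or(c(0, 3.22))
#' @export
beta_to_or <- function(beta) {
  if (any(!is.finite(beta))) abort("`beta` must be finite")
  exp(beta)
}

#' Feature enrichment report
#'
#' Builds the per-feature colocalization report comparing positive and
#' negative sites: a site counts as feature-positive when its occupancy
#' fraction exceeds 0 (at least one overlapping base) or, for count
#' features, when the count is >= 1. Reports percentages, odds ratio,
#' Fisher p and the chosen multiple-testing adjustment, sorted by
#' decreasing odds ratio.
#'
#' @param pos_features,neg_features Feature tibbles (same columns) for the
#'   positive and negative sites, e.g. from [featurize_sites()].
#' @param correction `"bonferroni"` (default) or `"BH"`.
#' @param haldane Passed to [odds_ratio()].
#' @return Tibble with columns `feature`, `pct_pos`, `pct_neg`,
#'   `odds_ratio`, `p`, `p_adj`.
#' @export
enrichment_report <- function(pos_features, neg_features,
                              correction = c("bonferroni", "BH"),
                              haldane = FALSE) {
  correction <- match.arg(correction)
  feats <- intersect(names(pos_features), names(neg_features))
  feats <- feats[vapply(pos_features[feats], is.numeric, logical(1))]
  if (!length(feats)) abort("no shared numeric feature columns")
  rows <- purrr::map(feats, function(f) {
    a <- sum(pos_features[[f]] > 0)
    b <- sum(pos_features[[f]] <= 0)
    cc <- sum(neg_features[[f]] > 0)
    dd <- sum(neg_features[[f]] <= 0)
    pct <- colocalization(a, b, cc, dd)
    tibble(
      feature = f,
      pct_pos = pct[["pct_pos"]], pct_neg = pct[["pct_neg"]],
      odds_ratio = odds_ratio(a, b, cc, dd, haldane = haldane),
      p = enrichment_test(a, b, cc, dd)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- adjust_pvalues(out$p, method = correction)
  dplyr::arrange(out, dplyr::desc(.data$odds_ratio))
}
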