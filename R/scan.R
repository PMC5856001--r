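#' Score a genome in fixed-width bins
#'
#' Tiles the genome into bins (default 250 bases, the genome-wide
#' resolution of the method), featurizes every bin with the same encoders
#' used at training time, and scores them with a trained model. A feature
#' the model needs that cannot be computed from the supplied inputs is an
#' error, never a silent zero-fill.
#'
#' @param model A `dsb_model`.
#' @param genome A [genome()].
#' @param tracks Named list of peak-interval tibbles.
#' @param motifs,shape_table Optional motif / shape inputs (needed when
#'   the model was trained on those blocks).
#' @param width Bin width in bases (default 250).
#' @param min_rel_score Motif threshold used at training time.
#' @return A `dsb_score_track`: interval tibble of bins with a `score`
#'   column; attributes `model_family` and `width`.
#' @export
score_genome <- function(model, genome, tracks = NULL, motifs = NULL,
                         shape_table = NULL, width = 250L,
                         min_rel_score = 0.8) {
  stopifnot(inherits(model, "dsb_model"))
  bins <- bin_genome(genome, width = width)
  feats <- featurize_sites(bins,
    genome = genome, tracks = tracks,
    motifs = motifs, shape_table = shape_table,
    min_rel_score = min_rel_score
  )
  miss <- setdiff(model$feature_names, names(feats))
  if (length(miss)) {
    abort(paste0(
      "model feature(s) not computable from the supplied inputs: ",
      paste(miss, collapse = ", ")
    ))
  }
  bins$score <- predict(model, feats)
  attr(bins, "model_family") <- model$family
  attr(bins, "width") <- as.integer(width)
  class(bins) <- c("dsb_score_track", class(bins))
  bins
}

#' Call high- and low-score bins
#'
#' Splits a scored bin track into predicted DSBs (score >= `high`),
#' predicted controls (score <= `low`) and an unassigned middle band.
#'
#' @param track A `dsb_score_track` (or any interval tibble with `score`).
#' @param low,high Score thresholds, `0 <= low < high <= 1` (defaults
#'   0.25 / 0.75).
#' @return List with `predicted_dsb` and `predicted_control` interval
#'   tibbles.
#' @export
call_high_low <- function(track, low = 0.25, high = 0.75) {
  if (!"score" %in% names(track)) abort("`track` has no score column")
  if (!(low >= 0 && low < high && high <= 1)) {
    abort("need 0 <= low < high <= 1")
  }
  list(
    predicted_dsb = track[track$score >= high, , drop = FALSE],
    predicted_control = track[track$score <= low, , drop = FALSE]
  )
}

#' Independent signal stratified by prediction score
#'
#' Groups bins into score quantiles and reports the mean coverage of an
#' independent signal per group -- the validation view in which a genuine
#' break signal should increase with the predicted DSB score and a
#' spreading damage mark may decrease.
#'
#' @param track A `dsb_score_track`.
#' @param signal Interval tibble of the validation signal's peaks.
#' @param n_quantiles Number of score-quantile groups (>= 2, default 10).
#' @return Tibble with `quantile` (1 = lowest scores), `mean_score`,
#'   `mean_signal`, `n_bins`.
#' @export
signal_by_score <- function(track, signal, n_quantiles = 10L) {
  if (!"score" %in% names(track)) abort("`track` has no score column")
  if (n_quantiles < 2L) abort("`n_quantiles` must be >= 2")
  cover <- overlap_fraction(track, signal)
  q <- dplyr::ntile(track$score, n_quantiles)
  tibble(score = track$score, cover = cover, quantile = q) |>
    dplyr::group_by(.data$quantile) |>
    dplyr::summarise(
      mean_score = mean(.data$score),
      mean_signal = mean(.data$cover),
      n_bins = dplyr::n(),
      .groups = "drop"
    )
}

#' Transfer a trained model to another dataset or cell type
#'
#' Scores sites of a second dataset with a model trained elsewhere. Every
#' feature the model was trained on must be present in `features`
#' (computed from data available for the target cell type); missing
#' features are an error -- the feature intersection must be chosen
#' explicitly before training, never imputed here.
#'
#' @param model A `dsb_model`.
#' @param features Feature tibble for the target sites.
#' @return Numeric scores.
#' @export
transfer_predict <- function(model, features) {
  predict(model, features)
}
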