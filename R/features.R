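#' Featurize sites for DSB classification
#'
#' Builds the per-site predictor table used by every classifier in the
#' package, from any combination of three blocks:
#' * occupancy fractions in `[0, 1]` -- one column per epigenomic peak
#'   track, the fraction of the site covered by the track's peaks
#'   (a peak covering 60% of the site gives 0.6);
#' * motif counts -- one integer column per motif, the number of PWM hits
#'   at the relative-score threshold;
#' * DNA-shape summaries -- the 48 quantile/variance statistics.
#'
#' The same encoder is used at training time and by [score_genome()], so
#' genome-wide features are bit-for-bit identical to training features.
#'
#' @param sites Interval tibble.
#' @param genome A [genome()]; required for motif or shape features.
#' @param tracks Named list of interval tibbles (peak tracks).
#' @param motifs Named list of [motif()] objects, or `NULL`.
#' @param shape_table A `dsb_shape_table`, or `NULL`.
#' @param min_rel_score Motif relative-score threshold (default 0.8).
#' @return Feature tibble, rows aligned with `sites`.
#' @export
featurize_sites <- function(sites, genome = NULL, tracks = NULL,
                            motifs = NULL, shape_table = NULL,
                            min_rel_score = 0.8) {
  sites <- validate_intervals(sites)
  blocks <- list()
  if (!is.null(tracks)) {
    if (is.null(names(tracks)) || any(!nzchar(names(tracks)))) {
      abort("`tracks` must be a named list of interval tibbles")
    }
    blocks$occ <- as_tibble(purrr::map(tracks, ~ overlap_fraction(sites, .x)))
  }
  if (!is.null(motifs)) {
    if (is.null(genome)) abort("motif features need a genome with sequences")
    blocks$motif <- count_motif_occurrences(sites, genome, motifs,
      min_rel_score = min_rel_score
    )
  }
  if (!is.null(shape_table)) {
    if (is.null(genome)) abort("shape features need a genome with sequences")
    blocks$shape <- shape_features(sites, genome, shape_table)
  }
  if (!length(blocks)) abort("no feature blocks requested")
  out <- dplyr::bind_cols(blocks, .name_repair = "minimal")
  names(out) <- unlist(lapply(blocks, names), use.names = FALSE)
  if (anyDuplicated(names(out))) abort("duplicate feature names across blocks")
  out
}
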