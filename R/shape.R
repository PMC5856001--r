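#' Pentamer DNA-shape tables
#'
#' DNA shape is predicted from sequence by a sliding-pentamer lookup:
#' position `i` of a sequence takes the shape values tabulated for the
#' pentamer centered on it. Four features are carried: minor groove width
#' (MGW, Angstrom) and propeller twist (ProT, degrees) at base-pair
#' resolution, and roll (Roll) and helix twist (HelT, degrees) at
#' base-pair-step resolution, flattened to one value per pentamer center
#' (the mean of the two central steps).
#'
#' `read_shape_table()` loads a TSV (`pentamer`, `MGW`, `ProT`, `Roll`,
#' `HelT`). A table giving only one pentamer of each reverse-complement
#' pair is completed by the reverse-complement rule; a full table must
#' satisfy the structural symmetry `MGW(p) == MGW(revcomp(p))` (likewise
#' ProT) within `1e-6`.
#'
#' @param path Path to a shape-table TSV with a header.
#' @return A tibble of class `dsb_shape_table` with 1024 rows and an
#'   internal lookup attribute.
#' @export
read_shape_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  tab <- as_tibble(read.table(path, header = TRUE, sep = "\t",
    stringsAsFactors = FALSE
  ))
  need <- c("pentamer", "MGW", "ProT", "Roll", "HelT")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    abort(paste0("shape table missing column(s): ", paste(miss, collapse = ", ")))
  }
  shape_table(tab)
}

#' @rdname read_shape_table
#' @param tab Data frame with columns `pentamer`, `MGW`, `ProT`, `Roll`,
#'   `HelT`.
#' @export
shape_table <- function(tab) {
  tab <- as_tibble(tab)
  tab$pentamer <- toupper(tab$pentamer)
  if (any(nchar(tab$pentamer) != 5L) ||
    any(grepl("[^ACGT]", tab$pentamer))) {
    abort("pentamers must be 5-mers over ACGT")
  }
  if (anyDuplicated(tab$pentamer)) abort("duplicated pentamer rows")
  all_p <- all_pentamers()
  known <- setNames(rep(NA_integer_, 1024L), all_p)
  known[tab$pentamer] <- seq_len(nrow(tab))
  rc <- revcomp(all_p)
  # complete missing pentamers from their reverse complement
  src <- known
  need_fill <- is.na(known)
  src[need_fill] <- known[rc[need_fill]]
  gaps <- names(known)[is.na(src)]
  if (length(gaps)) {
    abort(paste0(
      "pentamer(s) missing even after reverse-complement completion: ",
      paste(head(gaps, 10), collapse = ", "),
      if (length(gaps) > 10) " ..."
    ))
  }
  full <- tibble(
    pentamer = all_p,
    MGW = tab$MGW[src], ProT = tab$ProT[src],
    Roll = tab$Roll[src], HelT = tab$HelT[src]
  )
  # structural symmetry of the base-pair features
  rc_idx <- match(rc, all_p)
  for (f in c("MGW", "ProT")) {
    dev <- max(abs(full[[f]] - full[[f]][rc_idx]))
    if (dev > 1e-6) {
      abort(paste0(
        f, " violates reverse-complement symmetry (max deviation ",
        format(dev), ")"
      ))
    }
  }
  lookup <- as.matrix(full[, c("MGW", "ProT", "Roll", "HelT")])
  rownames(lookup) <- full$pentamer
  attr(full, "lookup") <- lookup
  class(full) <- c("dsb_shape_table", class(full))
  full
}

all_pentamers <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(p5 = b, p4 = b, p3 = b, p2 = b, p1 = b,
    stringsAsFactors = FALSE
  )
  paste0(g$p1, g$p2, g$p3, g$p4, g$p5)
}

#' @rdname read_shape_table
#' @param x A `dsb_shape_table`.
#' @export
write_shape_table <- function(x, path) {
  stopifnot(inherits(x, "dsb_shape_table"))
  write.table(as.data.frame(x[, c("pentamer", "MGW", "ProT", "Roll", "HelT")]),
    path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Predict DNA shape along a sequence
#'
#' Slides a pentamer window over the sequence and looks each one up in the
#' shape table; position `i` (0-based, `2 <= i <= L - 3`) is described by
#' the pentamer `seq[i-2 .. i+2]`, so each feature vector has length
#' `L - 4`. Pentamers containing `N` yield `NA` at the affected positions.
#'
#' @param seq A DNA string of length >= 5.
#' @param table A `dsb_shape_table`.
#' @return Tibble with columns `pos` (0-based central position), `MGW`,
#'   `ProT`, `Roll`, `HelT`.
#' @export
predict_shape <- function(seq, table) {
  stopifnot(inherits(table, "dsb_shape_table"))
  L <- nchar(seq)
  if (L < 5L) abort("sequence must have length >= 5")
  codes <- seq_codes(seq) - 1L
  n <- L - 4L
  idx <- rep(0L, n)
  na <- logical(n)
  for (k in 0:4) {
    ck <- codes[(1L + k):(n + k)]
    na <- na | is.na(ck)
    ck[is.na(ck)] <- 0L
    idx <- idx * 4L + ck
  }
  idx <- idx + 1L
  lookup <- attr(table, "lookup")
  vals <- lookup[idx, , drop = FALSE]
  vals[na, ] <- NA_real_
  tibble(
    pos = 2:(L - 3L),
    MGW = unname(vals[, "MGW"]), ProT = unname(vals[, "ProT"]),
    Roll = unname(vals[, "Roll"]), HelT = unname(vals[, "HelT"])
  )
}

shape_feature_names <- function() {
  stats_nm <- c(paste0("q", seq(0, 100, 10)), "var")
  as.vector(t(outer(c("MGW", "ProT", "Roll", "HelT"), stats_nm, paste, sep = "_")))
}

#' Summarize a shape profile into 48 predictors
#'
#' For each of the four shape features, 12 statistics describe its
#' distribution across the site: the 11 quantiles at 0, 10, ..., 100%
#' (linear interpolation between order statistics, R type 7) plus the
#' population (divide-by-n) variance -- 48 predictors in total. Missing
#' positions (from `N` bases) are excluded.
#'
#' @param profile Tibble from [predict_shape()].
#' @return One-row tibble with 48 named columns
#'   (`MGW_q0 ... MGW_q100, MGW_var, ProT_q0, ...`).
#' @export
summarize_shape <- function(profile) {
  out <- purrr::map(c("MGW", "ProT", "Roll", "HelT"), function(f) {
    v <- profile[[f]]
    v <- v[!is.na(v)]
    if (!length(v)) abort(paste0("no non-missing ", f, " values to summarize"))
    q <- quantile(v, probs = seq(0, 1, 0.1), type = 7, names = FALSE)
    vals <- c(q, mean((v - mean(v))^2))
    setNames(vals, paste(f, c(paste0("q", seq(0, 100, 10)), "var"), sep = "_"))
  })
  as_tibble(as.list(unlist(out)))
}

#' Shape feature block for a set of sites
#'
#' @param sites Interval tibble.
#' @param genome A [genome()] with sequences.
#' @param table A `dsb_shape_table`.
#' @return Tibble with 48 columns, rows aligned with `sites`.
#' @export
shape_features <- function(sites, genome, table) {
  seqs <- site_sequences(sites, genome)
  dplyr::bind_rows(purrr::map(seqs, function(s) {
    summarize_shape(predict_shape(s, table))
  }))
}
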