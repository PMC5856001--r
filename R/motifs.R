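#' Motif models
#'
#' A `dsb_motif` holds a position frequency matrix (PFM: 4 x W counts over
#' A, C, G, T) together with the pseudocount and background used to derive
#' its log-odds position weight matrix (PWM). Scanning scores windows on
#' the min-max-normalized log-odds scale, so a "relative score" of 1 is the
#' consensus and 0 the anti-consensus; the classical "80% matching score"
#' threshold is `min_rel_score = 0.8` on this scale.
#'
#' @param counts 4 x W non-negative numeric matrix with rownames
#'   `A`, `C`, `G`, `T`.
#' @param motif_id,name Identifier and factor name.
#' @param pseudocount Total pseudocount added per column, distributed by
#'   the background (default 0.8).
#' @param background Base frequencies (A, C, G, T) summing to 1; default
#'   uniform.
#' @return A `dsb_motif` object.
#' @export
motif <- function(counts, motif_id = "motif", name = motif_id,
                  pseudocount = 0.8, background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) abort("PFM must have 4 rows (A, C, G, T)")
  if (ncol(counts) < 1L) abort("PFM must have at least one column")
  if (any(counts < 0)) abort("PFM counts must be non-negative")
  if (pseudocount <= 0) abort("`pseudocount` must be > 0")
  if (abs(sum(background) - 1) > 1e-6 || any(background <= 0)) {
    abort("`background` must be positive and sum to 1")
  }
  rownames(counts) <- c("A", "C", "G", "T")
  structure(
    list(
      motif_id = motif_id, name = name, counts = counts,
      pseudocount = pseudocount, background = background
    ),
    class = "dsb_motif"
  )
}

#' @exportS3Method base::print
print.dsb_motif <- function(x, ...) {
  cat("<dsb_motif> ", x$motif_id, " (", x$name, "), width ",
    ncol(x$counts), ", consensus ", motif_consensus(x), "\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname motif
#' @param x A `dsb_motif`.
#' @return `motif_pwm()`: the log2-odds weight matrix with attributes
#'   `min_score`/`max_score` (the attainable extremes used for relative
#'   scoring).
#' @export
motif_pwm <- function(x) {
  stopifnot(inherits(x, "dsb_motif"))
  probs <- sweep(
    x$counts + x$pseudocount * x$background, 2,
    colSums(x$counts) + x$pseudocount, "/"
  )
  pwm <- log2(probs / x$background)
  attr(pwm, "min_score") <- sum(apply(pwm, 2, min))
  attr(pwm, "max_score") <- sum(apply(pwm, 2, max))
  pwm
}

#' @rdname motif
#' @export
motif_consensus <- function(x) {
  pwm <- motif_pwm(x)
  paste0(c("A", "C", "G", "T")[apply(pwm, 2, which.max)], collapse = "")
}

#' Read JASPAR-format PFM files
#'
#' Parses the JASPAR text format: records of a `>ID NAME` header followed
#' by four rows `A [ n1 n2 ... ]` ... `T [ ... ]` (brackets optional).
#'
#' @param path Path to a JASPAR PFM file.
#' @inheritParams motif
#' @return Named list of [motif()] objects (names = motif ids), in file
#'   order.
#' @export
read_jaspar <- function(path, pseudocount = 0.8, background = rep(0.25, 4)) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) abort("not a JASPAR file (no '>' header)")
  rec <- split(lines, cumsum(hdr))
  out <- purrr::map(rec, function(r) {
    h <- strsplit(sub("^>\\s*", "", r[1]), "\\s+")[[1]]
    id <- h[1]
    nm <- if (length(h) > 1) paste(h[-1], collapse = " ") else h[1]
    body <- r[-1]
    rows <- lapply(c("A", "C", "G", "T"), function(b) {
      ln <- body[grepl(paste0("^", b, "\\b"), body)]
      if (length(ln) != 1L) {
        abort(paste0("motif ", id, ": missing or duplicated ", b, " row"))
      }
      s <- sub("^[ACGT]", "", ln)
      as.numeric(regmatches(s, gregexpr("[0-9.eE+-]+", s))[[1]])
    })
    w <- unique(lengths(rows))
    if (length(w) != 1L) {
      abort(paste0(
        "motif ", id, ": rows of unequal width (",
        paste(lengths(rows), collapse = ", "), ")"
      ))
    }
    motif(do.call(rbind, rows),
      motif_id = id, name = nm,
      pseudocount = pseudocount, background = background
    )
  })
  names(out) <- vapply(out, `[[`, character(1), "motif_id")
  out
}

# DNA string -> integer codes 1..4 (A,C,G,T), NA for N/other.
seq_codes <- function(seq) {
  code <- utf8ToInt(toupper(seq))
  out <- rep(NA_integer_, length(code))
  out[code == 65L] <- 1L
  out[code == 67L] <- 2L
  out[code == 71L] <- 3L
  out[code == 84L] <- 4L
  out
}

# Scores of every window of width W on one strand; NA where window has N.
pwm_window_scores <- function(codes, pwm) {
  w <- ncol(pwm)
  n <- length(codes) - w + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  na <- logical(n)
  for (j in seq_len(w)) {
    cj <- codes[j:(j + n - 1L)]
    na <- na | is.na(cj)
    v <- pwm[, j][cj]
    v[is.na(v)] <- 0
    sc <- sc + v
  }
  sc[na] <- NA_real_
  sc
}

#' Scan a sequence for motif hits
#'
#' Slides the motif's PWM over both strands and reports every window whose
#' min-max relative score reaches `min_rel_score`. Windows containing `N`
#' are skipped; hit coordinates are 0-based half-open on the forward
#' strand.
#'
#' @param seq A DNA string.
#' @param motif A [motif()].
#' @param min_rel_score Relative-score threshold in (0, 1]; default 0.8,
#'   the standard "80% matching score".
#' @return Tibble with columns `start`, `end`, `strand`, `score`
#'   (log2-odds), `rel_score`, sorted by `start`.
#' @export
scan_motif <- function(seq, motif, min_rel_score = 0.8) {
  stopifnot(inherits(motif, "dsb_motif"))
  if (min_rel_score <= 0 || min_rel_score > 1) {
    abort("`min_rel_score` must be in (0, 1]")
  }
  pwm <- motif_pwm(motif)
  lo <- attr(pwm, "min_score"); hi <- attr(pwm, "max_score")
  w <- ncol(pwm)
  L <- nchar(seq)
  empty <- tibble(
    start = integer(), end = integer(), strand = character(),
    score = numeric(), rel_score = numeric()
  )
  if (L < w) return(empty)
  one_strand <- function(codes, strand) {
    sc <- pwm_window_scores(codes, pwm)
    rel <- (sc - lo) / (hi - lo)
    hit <- which(!is.na(rel) & rel >= min_rel_score)
    if (!length(hit)) return(NULL)
    pos0 <- hit - 1L
    if (strand == "-") pos0 <- L - pos0 - w   # mirror to forward coords
    tibble(
      start = as.integer(pos0), end = as.integer(pos0 + w),
      strand = strand, score = sc[hit], rel_score = rel[hit]
    )
  }
  fwd <- seq_codes(seq)
  out <- dplyr::bind_rows(
    one_strand(fwd, "+"),
    one_strand(seq_codes(revcomp(seq)), "-")
  )
  if (!nrow(out)) return(empty)
  dplyr::arrange(out, .data$start, .data$strand)
}

#' Count motif occurrences per site
#'
#' Number of motif hits (both strands, overlapping hits all counted) fully
#' inside each site, for each motif -- the sequence feature block of the
#' DSB classifiers.
#'
#' @param sites Interval tibble.
#' @param genome A [genome()] with sequences.
#' @param motifs A [motif()] or named list of them (e.g. from
#'   [read_jaspar()]).
#' @param min_rel_score Relative-score threshold (default 0.8).
#' @return Tibble of integer counts, rows aligned with `sites`, one column
#'   per motif named `motif_<name>`.
#' @export
count_motif_occurrences <- function(sites, genome, motifs, min_rel_score = 0.8) {
  if (inherits(motifs, "dsb_motif")) motifs <- list(motifs)
  seqs <- site_sequences(sites, genome)
  cols <- purrr::map(motifs, function(m) {
    vapply(seqs, function(s) nrow(scan_motif(s, m, min_rel_score)),
      integer(1),
      USE.NAMES = FALSE
    )
  })
  names(cols) <- paste0(
    "motif_", vapply(motifs, function(m) m$name, character(1))
  )
  as_tibble(cols)
}
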