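#' Interval tibbles
#'
#' Genomic intervals are plain tibbles with columns `chrom` (character),
#' `start` and `end` (0-based half-open integers, `0 <= start < end`), and
#' optionally `name` and `score`. `as_intervals()` validates a data frame
#' and returns it in canonical form: sorted by (`chrom`, `start`, `end`)
#' with exact duplicate intervals collapsed (the documented
#' canonicalization; duplicates are permitted on input).
#'
#' @param x Data frame with at least `chrom`, `start`, `end`.
#' @param genome Optional [genome()]; when given, every `chrom` must be
#'   present in it and intervals must not extend past the chromosome end.
#' @return A canonical interval tibble.
#' @examples
#' as_intervals(data.frame(chrom = "chr1", start = 100, end = 600))
#' @export
as_intervals <- function(x, genome = NULL) {
  x <- validate_intervals(x)
  if (!is.null(genome)) check_chroms(x, genome)
  x <- dplyr::arrange(x, .data$chrom, .data$start, .data$end)
  dplyr::distinct(x, .data$chrom, .data$start, .data$end, .keep_all = TRUE)
}

validate_intervals <- function(x) {
  if (!is.data.frame(x)) abort("intervals must be a data frame")
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(paste0("missing interval column(s): ", paste(miss, collapse = ", ")))
  }
  x <- as_tibble(x)
  x$chrom <- as.character(x$chrom)
  x$start <- as.integer(round(x$start))
  x$end <- as.integer(round(x$end))
  bad <- which(is.na(x$start) | is.na(x$end) | x$start < 0L | x$start >= x$end)
  if (length(bad)) {
    abort(paste0(
      "invalid interval(s) (need 0 <= start < end) at row(s): ",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  x
}

check_chroms <- function(x, genome) {
  unknown <- setdiff(unique(x$chrom), names(genome$chrom_sizes))
  if (length(unknown)) {
    abort(paste0(
      "chromosome(s) absent from genome: ", paste(unknown, collapse = ", ")
    ))
  }
  invisible(x)
}

# IRanges view of one chromosome's intervals (1-based closed internally).
chrom_iranges <- function(x, chrom) {
  y <- x[x$chrom == chrom, , drop = FALSE]
  IRanges::IRanges(start = y$start + 1L, end = y$end)
}

#' Read BED-like interval files
#'
#' Reads BED3+ / narrowPeak files: whitespace-delimited, `track`, `browser`
#' and `#` lines skipped, columns beyond the third preserved as `name`
#' (column 4) and `score` (column 5) when parseable. Coordinates are kept
#' in the file's native 0-based half-open convention.
#'
#' @param path Path to a BED-like file.
#' @param genome Optional [genome()] used to check chromosome names.
#' @return Canonical interval tibble.
#' @export
read_bed <- function(path, genome = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) abort(paste0("no interval records in ", path))
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    abort(paste0(
      "line ", lineno[which(nf < 3L)[1]], ": fewer than 3 columns"
    ))
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0L | start >= end)
  if (length(bad)) {
    abort(paste0(
      "line ", lineno[bad[1]], ": malformed coordinates (",
      sub("\t", " ", lines[bad[1]]), ")"
    ))
  }
  out <- tibble(chrom = chrom, start = start, end = end)
  if (any(nf >= 4L)) {
    out$name <- vapply(fields, function(f) {
      if (length(f) >= 4L) f[[4L]] else NA_character_
    }, character(1))
  }
  if (any(nf >= 5L)) {
    out$score <- suppressWarnings(as.numeric(vapply(fields, function(f) {
      if (length(f) >= 5L) f[[5L]] else NA_character_
    }, character(1))))
  }
  as_intervals(out, genome = genome)
}

#' @rdname read_bed
#' @param x Interval tibble to write.
#' @export
write_bed <- function(x, path) {
  x <- validate_intervals(x)
  out <- data.frame(
    chrom = x$chrom, start = x$start, end = x$end,
    name = if ("name" %in% names(x)) x$name else ".",
    score = if ("score" %in% names(x)) x$score else 0,
    strand = "."
  )
  write.table(out, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Intersect replicate peak sets
#'
#' Keeps the intervals of `rep1` that overlap (by at least one base) some
#' interval of `rep2` -- the replicate-intersection step used to retain
#' reliable DSB peaks. By default the full `rep1` peak is kept; with
#' `clip = TRUE` each kept peak is clipped to the union of its overlap with
#' `rep2`.
#'
#' @param rep1,rep2 Interval tibbles.
#' @param clip Clip kept peaks to the overlapping region? Default `FALSE`.
#' @return Canonical interval tibble.
#' @export
intersect_replicates <- function(rep1, rep2, clip = FALSE) {
  rep1 <- as_intervals(rep1)
  rep2 <- as_intervals(rep2)
  out <- purrr::map(intersect(unique(rep1$chrom), unique(rep2$chrom)), function(ch) {
    ir1 <- chrom_iranges(rep1, ch)
    ir2 <- IRanges::reduce(chrom_iranges(rep2, ch))
    hit <- IRanges::overlapsAny(ir1, ir2)
    if (!any(hit)) return(NULL)
    keep <- rep1[rep1$chrom == ch, , drop = FALSE][hit, , drop = FALSE]
    if (clip) {
      ov <- IRanges::pintersect(
        IRanges::findOverlapPairs(ir1[hit], ir2)
      )
      # union of clipped pieces per source peak, re-expanded to rows
      src <- S4Vectors::queryHits(IRanges::findOverlaps(ir1[hit], ir2))
      pieces <- tibble(
        row = src,
        start = IRanges::start(ov) - 1L,
        end = IRanges::end(ov)
      )
      keep <- dplyr::bind_cols(
        keep[pieces$row, setdiff(names(keep), c("start", "end")), drop = FALSE],
        pieces[, c("start", "end")]
      )
      keep$chrom <- ch
    }
    keep
  })
  out <- dplyr::bind_rows(out)
  if (!nrow(out)) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  as_intervals(out)
}

#' Fraction of each site covered by a peak track
#'
#' For every site, the fraction of its bases covered by the union of the
#' track's intervals -- the standard occupancy encoding `x` (a peak
#' covering 60% of a site gives `x = 0.6`). Overlapping track peaks are
#' merged before counting, so the result is invariant to how covering
#' peaks are split.
#'
#' @param sites Interval tibble of sites.
#' @param track Interval tibble of peaks.
#' @return Numeric vector in `[0, 1]`, aligned with the rows of `sites`.
#' @export
overlap_fraction <- function(sites, track) {
  sites <- validate_intervals(sites)
  track <- validate_intervals(track)
  out <- numeric(nrow(sites))
  for (ch in unique(sites$chrom)) {
    i <- which(sites$chrom == ch)
    ir_s <- IRanges::IRanges(sites$start[i] + 1L, sites$end[i])
    ir_t <- IRanges::reduce(chrom_iranges(track, ch))
    if (length(ir_t)) {
      hits <- IRanges::findOverlaps(ir_s, ir_t)
      if (length(hits)) {
        inter <- IRanges::pintersect(
          ir_s[S4Vectors::queryHits(hits)], ir_t[S4Vectors::subjectHits(hits)]
        )
        cov <- tapply(IRanges::width(inter), S4Vectors::queryHits(hits), sum)
        out[i[as.integer(names(cov))]] <- as.numeric(cov)
      }
    }
  }
  out / (sites$end - sites$start)
}

#' Tile a genome into fixed-width bins
#'
#' Consecutive non-overlapping bins `[0,w), [w,2w), ...` per chromosome;
#' the trailing partial bin is emitted truncated so total bin length equals
#' genome length. Bins are labeled `chrom:start`.
#'
#' @param genome A [genome()].
#' @param width Bin width in bases (default 250, the genome-wide scanning
#'   resolution).
#' @return Canonical interval tibble with a `name` column.
#' @export
bin_genome <- function(genome, width = 250L) {
  stopifnot(inherits(genome, "dsb_genome"))
  width <- as.integer(width)
  if (is.na(width) || width < 1L) abort("`width` must be >= 1")
  if (!length(genome$chrom_sizes)) abort("empty genome")
  out <- purrr::map(names(genome$chrom_sizes), function(ch) {
    len <- genome$chrom_sizes[[ch]]
    starts <- seq(0L, len - 1L, by = width)
    tibble(
      chrom = ch, start = as.integer(starts),
      end = as.integer(pmin(starts + width, len)),
      name = paste0(ch, ":", starts)
    )
  })
  as_intervals(dplyr::bind_rows(out))
}

#' Label regions by DSB overlap
#'
#' Binary label per region: 1 iff the region overlaps at least one DSB
#' interval by at least one base.
#'
#' @param regions Interval tibble (e.g. genome bins).
#' @param dsb Interval tibble of DSB sites.
#' @return Integer vector of 0/1, aligned with `regions` rows.
#' @export
label_intervals <- function(regions, dsb) {
  regions <- validate_intervals(regions)
  dsb <- validate_intervals(dsb)
  out <- integer(nrow(regions))
  for (ch in unique(regions$chrom)) {
    i <- which(regions$chrom == ch)
    ir_r <- IRanges::IRanges(regions$start[i] + 1L, regions$end[i])
    ir_d <- chrom_iranges(dsb, ch)
    if (length(ir_d)) out[i] <- as.integer(IRanges::overlapsAny(ir_r, ir_d))
  }
  out
}

#' Average signal profile around site centers
#'
#' Aggregates per-base coverage of a signal track in fixed-width bins over
#' `[center - flank, center + flank)` across sites, the standard
#' metasite/average-profile view of a mark around DSBs. Sites whose window
#' would run past a chromosome end are dropped (and counted).
#'
#' @param signal Interval tibble of signal/peak intervals (coverage is the
#'   number of overlapping intervals per base).
#' @param sites Interval tibble of sites; profiles are anchored at each
#'   site's midpoint.
#' @param genome A [genome()] providing chromosome sizes.
#' @param flank Half-window in bases (> 0).
#' @param bin Bin width in bases (>= 1); `2 * flank` must be a multiple.
#' @return A tibble of class `dsb_profile` with columns `offset` (signed
#'   distance of the bin center from the site center) and `mean` (mean
#'   coverage); attributes `n_sites` and `n_dropped`.
#' @export
average_profile <- function(signal, sites, genome, flank = 2000L, bin = 50L) {
  signal <- validate_intervals(signal)
  sites <- validate_intervals(sites)
  stopifnot(inherits(genome, "dsb_genome"))
  flank <- as.integer(flank); bin <- as.integer(bin)
  if (flank <= 0L) abort("`flank` must be > 0")
  if (bin < 1L) abort("`bin` must be >= 1")
  if ((2L * flank) %% bin != 0L) abort("2*flank must be a multiple of `bin`")
  if (!nrow(sites)) abort("`sites` is empty")
  check_chroms(sites, genome)
  nb <- (2L * flank) %/% bin
  centers <- (sites$start + sites$end) %/% 2L
  win_start <- centers - flank
  win_end <- centers + flank
  ok <- win_start >= 0L & win_end <= genome$chrom_sizes[sites$chrom]
  n_drop <- sum(!ok)
  if (!any(ok)) abort("all sites dropped: windows exceed chromosome bounds")
  sites <- sites[ok, , drop = FALSE]
  win_start <- win_start[ok]
  acc <- matrix(0, nrow = sum(ok), ncol = nb)
  row0 <- 0L
  for (ch in unique(sites$chrom)) {
    i <- which(sites$chrom == ch)
    cov <- IRanges::coverage(
      chrom_iranges(signal, ch),
      width = genome$chrom_sizes[[ch]]
    )
    # one view per (site, bin)
    bs <- rep(win_start[i], each = nb) + rep(seq_len(nb) - 1L, length(i)) * bin
    v <- IRanges::Views(cov, start = bs + 1L, end = bs + bin)
    acc[i, ] <- matrix(IRanges::viewMeans(v), ncol = nb, byrow = TRUE)
    row0 <- row0 + length(i)
  }
  offsets <- as.integer(seq(-flank, flank - bin, by = bin) + bin %/% 2L)
  out <- tibble(offset = offsets, mean = colMeans(acc))
  attr(out, "n_sites") <- nrow(sites)
  attr(out, "n_dropped") <- n_drop
  class(out) <- c("dsb_profile", class(out))
  out
}
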