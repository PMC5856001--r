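#' Sequence composition
#'
#' GC fraction (case-insensitive, over non-N bases), soft-masked repeat
#' fraction (lowercase bases / length) and length of DNA sequences. When a
#' sequence is all N, its GC is undefined and returned as `NA` with
#' `gc_defined = FALSE`.
#'
#' @param seq Character vector of DNA sequences (`ACGTN`, either case).
#' @return Tibble with one row per sequence: `gc`, `repeat_frac`, `length`,
#'   `gc_defined`.
#' @examples
#' composition(c("ACGT", "acgtACGT", "NNNN"))
#' @export
composition <- function(seq) {
  if (!length(seq) || any(!nzchar(seq))) abort("sequences must be non-empty")
  res <- purrr::map(seq, function(s) {
    code <- utf8ToInt(s)
    is_lower <- code >= 97L
    up <- ifelse(is_lower, code - 32L, code)
    bad <- !(up %in% c(65L, 67L, 71L, 84L, 78L))
    if (any(bad)) {
      abort(paste0(
        "illegal character(s): ",
        paste(unique(intToUtf8(code[bad], multiple = TRUE)), collapse = " ")
      ))
    }
    n_n <- sum(up == 78L)
    denom <- length(up) - n_n
    tibble(
      gc = if (denom > 0) sum(up == 67L | up == 71L) / denom else NA_real_,
      repeat_frac = mean(is_lower),
      length = length(up),
      gc_defined = denom > 0
    )
  })
  dplyr::bind_rows(res)
}

# Composition of genomic windows via cached prefix sums; O(1) per window.
interval_composition <- function(intervals, genome) {
  intervals <- validate_intervals(intervals)
  gc <- lower <- nn <- numeric(nrow(intervals))
  for (ch in unique(intervals$chrom)) {
    i <- which(intervals$chrom == ch)
    pfx <- genome_prefix(genome, ch)
    s <- intervals$start[i]; e <- intervals$end[i]
    gc[i] <- pfx$gc[e + 1L] - pfx$gc[s + 1L]
    lower[i] <- pfx$lower[e + 1L] - pfx$lower[s + 1L]
    nn[i] <- pfx$n[e + 1L] - pfx$n[s + 1L]
  }
  len <- intervals$end - intervals$start
  denom <- len - nn
  tibble(
    gc = ifelse(denom > 0, gc / denom, NA_real_),
    repeat_frac = lower / len,
    length = len,
    n_frac = nn / len,
    gc_defined = denom > 0
  )
}

#' Sample matched non-DSB control sites
#'
#' Draws random genomic intervals matched *per site* to the positives:
#' each negative takes the exact length of its paired positive and must
#' match that positive's GC and repeat (soft-mask) fraction within absolute
#' tolerances. Candidates are placed uniformly on the genome and rejected
#' if they contain more than 10% N, violate a tolerance, or overlap the
#' exclusion set (the positives themselves plus `exclude`) or an already
#' accepted negative.
#'
#' @param positives Interval tibble of DSB sites.
#' @param genome A [genome()] with sequences.
#' @param ratio Negatives per positive (>= 1 gives `ceiling(ratio * n)`
#'   negatives, positives recycled). Default 1.
#' @param gc_tol Absolute GC tolerance (default 0.02).
#' @param repeat_tol Absolute repeat-fraction tolerance (default 0.05).
#' @param max_attempts Candidate draws per requested site before giving up
#'   (default 10000).
#' @param exclude Optional extra interval tibble to avoid (e.g. blacklist).
#' @param seed Integer seed; the draw is fully reproducible.
#' @return Canonical interval tibble of negatives with columns `name`
#'   (`neg_<k>`) and `matched_to` (row index of the paired positive).
#'   Errors if more than 5% of requested sites cannot be matched;
#'   unmatched sites below that are dropped with a warning and recorded in
#'   the `n_unmatched` attribute.
#' @export
sample_matched_negatives <- function(positives, genome, ratio = 1,
                                     gc_tol = 0.02, repeat_tol = 0.05,
                                     max_attempts = 10000L, exclude = NULL,
                                     seed = 1L) {
  positives <- as_intervals(positives, genome = genome)
  if (!nrow(positives)) abort("`positives` is empty")
  if (ratio <= 0) abort("`ratio` must be > 0")
  if (gc_tol <= 0 || gc_tol >= 1 || repeat_tol <= 0 || repeat_tol >= 1) {
    abort("tolerances must be in (0, 1)")
  }
  pos_comp <- interval_composition(positives, genome)
  n_target <- ceiling(ratio * nrow(positives))
  pair <- rep_len(seq_len(nrow(positives)), n_target)
  tgt_len <- pos_comp$length[pair]
  tgt_gc <- pos_comp$gc[pair]
  tgt_rep <- pos_comp$repeat_frac[pair]

  avoid <- positives[, c("chrom", "start", "end")]
  if (!is.null(exclude)) {
    avoid <- dplyr::bind_rows(avoid, validate_intervals(exclude)[, c("chrom", "start", "end")])
  }
  avoid_ir <- lapply(
    setNames(nm = names(genome$chrom_sizes)),
    function(ch) IRanges::reduce(chrom_iranges(avoid, ch))
  )

  chroms <- names(genome$chrom_sizes)
  sizes <- genome$chrom_sizes
  res_chrom <- character(n_target); res_start <- integer(n_target)
  done <- logical(n_target)
  attempts <- integer(n_target)

  batch <- 4L  # candidates proposed per unmatched target per round
  withr::with_seed(seed, {
    while (any(!done & attempts < max_attempts)) {
      todo <- rep(which(!done & attempts < max_attempts), each = batch)
      ch_i <- sample.int(length(chroms), length(todo),
        replace = TRUE, prob = sizes
      )
      room <- sizes[ch_i] - tgt_len[todo]
      valid <- room >= 0
      starts <- integer(length(todo))
      starts[valid] <- floor(runif(sum(valid)) * (room[valid] + 1))
      attempts[unique(todo)] <- attempts[unique(todo)] + batch
      cand <- tibble(
        chrom = chroms[ch_i], start = as.integer(starts),
        end = as.integer(starts + tgt_len[todo])
      )[valid, , drop = FALSE]
      tv <- todo[valid]
      if (!length(tv)) next
      comp <- interval_composition(cand, genome)
      ok <- comp$n_frac <= 0.10 & comp$gc_defined &
        abs(comp$gc - tgt_gc[tv]) <= gc_tol &
        abs(comp$repeat_frac - tgt_rep[tv]) <= repeat_tol
      ok[is.na(ok)] <- FALSE
      if (!any(ok)) next
      cand <- cand[ok, , drop = FALSE]; tv <- tv[ok]
      # resolve overlaps per chromosome: drop candidates hitting the
      # exclusion set or accepted negatives, then greedily de-overlap the
      # batch itself (first candidate per target wins)
      for (ch in unique(cand$chrom)) {
        j <- which(cand$chrom == ch)
        ir_c <- IRanges::IRanges(cand$start[j] + 1L, cand$end[j])
        acc <- which(done & res_chrom == ch)
        ir_a <- c(
          avoid_ir[[ch]],
          IRanges::IRanges(res_start[acc] + 1L, res_start[acc] + tgt_len[acc])
        )
        keep <- !IRanges::overlapsAny(ir_c, ir_a) & !duplicated(tv[j])
        keep[done[tv[j]]] <- FALSE
        if (!any(keep)) next
        # greedy pass over mutually overlapping batch candidates
        kj <- which(keep)
        hits <- IRanges::findOverlaps(ir_c[kj], ir_c[kj])
        q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
        pr <- which(q < s)
        drop <- logical(length(kj))
        for (h in pr[order(q[pr])]) {
          if (!drop[q[h]]) drop[s[h]] <- TRUE
        }
        sel <- j[kj[!drop]]
        t_i <- tv[sel]
        res_chrom[t_i] <- ch
        res_start[t_i] <- cand$start[sel]
        done[t_i] <- TRUE
      }
    }
  })

  n_unmatched <- sum(!done)
  if (n_unmatched / n_target > 0.05) {
    abort(paste0(
      n_unmatched, " of ", n_target, " control sites could not be matched ",
      "within max_attempts; consider loosening gc_tol/repeat_tol or using a ",
      "larger genome"
    ))
  }
  if (n_unmatched > 0) {
    warn(paste0(n_unmatched, " control site(s) unmatched and dropped"))
  }
  keep <- which(done)
  out <- tibble(
    chrom = res_chrom[keep],
    start = res_start[keep],
    end = res_start[keep] + tgt_len[keep],
    name = paste0("neg_", seq_along(keep)),
    matched_to = pair[keep]
  )
  out <- as_intervals(out)
  attr(out, "n_unmatched") <- n_unmatched
  out
}

#' QC report for matched controls
#'
#' Summarizes length, GC and repeat content of positive and negative sets
#' and, when the negatives carry a `matched_to` column, the maximum
#' per-pair deviation -- the quantitative check that the matching claim
#' holds.
#'
#' @param pos,neg Interval tibbles (negatives from
#'   [sample_matched_negatives()] ideally).
#' @param genome A [genome()] with sequences.
#' @return List with `summary` (per-set mean/quartiles of length, gc,
#'   repeat) and `max_pair_deviation` (tibble with `gc`, `repeat_frac`,
#'   `length`; `NA` when pairing is unknown).
#' @export
composition_report <- function(pos, neg, genome) {
  pos <- validate_intervals(pos)
  if (!is.data.frame(neg) || !nrow(neg)) abort("`neg` is empty")
  neg <- validate_intervals(neg)
  if (!nrow(pos)) abort("`pos` is empty")
  pc <- interval_composition(pos, genome)
  nc <- interval_composition(neg, genome)
  summarize_set <- function(comp, set) {
    tibble(
      set = set,
      n = nrow(comp),
      mean_length = mean(comp$length),
      median_length = stats::median(comp$length),
      mean_gc = mean(comp$gc, na.rm = TRUE),
      q25_gc = quantile(comp$gc, 0.25, na.rm = TRUE, names = FALSE),
      q75_gc = quantile(comp$gc, 0.75, na.rm = TRUE, names = FALSE),
      mean_repeat = mean(comp$repeat_frac)
    )
  }
  dev <- tibble(gc = NA_real_, repeat_frac = NA_real_, length = NA_real_)
  if ("matched_to" %in% names(neg)) {
    p <- pc[neg$matched_to, , drop = FALSE]
    dev <- tibble(
      gc = max(abs(nc$gc - p$gc)),
      repeat_frac = max(abs(nc$repeat_frac - p$repeat_frac)),
      length = max(abs(nc$length - p$length))
    )
  }
  list(
    summary = dplyr::bind_rows(
      summarize_set(pc, "positive"), summarize_set(nc, "negative")
    ),
    max_pair_deviation = dev
  )
}
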