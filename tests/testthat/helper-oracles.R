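# Independent brute-force oracles and tiny fixture builders used across the
# suite. These deliberately avoid the package's own code paths.

# per-base boolean coverage fraction of `site` by `track`
bf_overlap_fraction <- function(site_start, site_end, track) {
  bases <- site_start:(site_end - 1L)
  covered <- rep(FALSE, length(bases))
  for (i in seq_len(nrow(track))) {
    covered <- covered | (bases >= track$start[i] & bases < track$end[i])
  }
  mean(covered)
}

# exhaustive PWM window enumeration on both strands
bf_scan <- function(seq, m, min_rel) {
  pwm <- motif_pwm(m)
  w <- ncol(pwm)
  lo <- attr(pwm, "min_score")
  hi <- attr(pwm, "max_score")
  score_window <- function(s) {
    ch <- strsplit(s, "")[[1]]
    if (any(!ch %in% c("A", "C", "G", "T"))) return(NA_real_)
    sum(vapply(seq_len(w), function(j) {
      pwm[match(ch[j], c("A", "C", "G", "T")), j]
    }, numeric(1)))
  }
  hits <- list()
  L <- nchar(seq)
  if (L >= w) {
    for (p in 1:(L - w + 1)) {
      win <- toupper(substr(seq, p, p + w - 1))
      for (strand in c("+", "-")) {
        s <- if (strand == "+") win else {
          paste(rev(strsplit(chartr("ACGT", "TGCA", win), "")[[1]]), collapse = "")
        }
        sc <- score_window(s)
        if (!is.na(sc) && (sc - lo) / (hi - lo) >= min_rel) {
          hits[[length(hits) + 1]] <- data.frame(
            start = p - 1L, end = p - 1L + w, strand = strand
          )
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(), end = integer(), strand = character()))
  }
  out <- do.call(rbind, hits)
  out[order(out$start, out$strand), , drop = FALSE]
}

# pairwise concordance AUROC, ties counted 1/2
bf_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# two-sided Fisher p by exhaustive hypergeometric enumeration
bf_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- vapply(xs, function(x) {
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  }, numeric(1))
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# small deterministic genome with known sequence
toy_genome <- function(seq = NULL) {
  if (is.null(seq)) {
    seq <- paste(rep("ACGTTGCA", 125), collapse = "") # 1 kb, GC 0.5
  }
  genome(c(chr1 = seq))
}

# strongly informative 8-mer motif
toy_motif <- function() {
  counts <- matrix(1, nrow = 4, ncol = 8,
    dimnames = list(c("A", "C", "G", "T"), NULL)
  )
  # consensus GATTACCA
  cons <- c("G", "A", "T", "T", "A", "C", "C", "A")
  for (j in seq_along(cons)) counts[cons[j], j] <- 97
  motif(counts, motif_id = "TOY1", name = "TOY1")
}

tmp_file <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
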