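#' Simulate a soft-masked toy genome
#'
#' I.i.d. bases at a target GC content, with lowercase (soft-masked)
#' repeat blocks covering approximately the requested fraction. Defaults
#' reflect the human-genome-like regime the method runs on: GC 0.41,
#' ~30% repeat-masked sequence.
#'
#' @param n_chroms Number of chromosomes (default 1).
#' @param chrom_length Length of each chromosome in bases.
#' @param gc Target GC fraction (default 0.41).
#' @param repeat_fraction Target soft-masked fraction (default 0.3).
#' @param repeat_block Mean repeat block length in bases (default 500).
#' @param seed Integer seed; output is bitwise reproducible.
#' @return A [genome()] with sequences, chromosomes named `chr1..chrN`.
#' @export
simulate_genome <- function(n_chroms = 1L, chrom_length = 1e6, gc = 0.41,
                            repeat_fraction = 0.3, repeat_block = 500L,
                            seed = 1L) {
  if (gc <= 0 || gc >= 1) abort("`gc` must be in (0, 1)")
  if (repeat_fraction < 0 || repeat_fraction >= 1) {
    abort("`repeat_fraction` must be in [0, 1)")
  }
  chrom_length <- as.integer(chrom_length)
  base_codes <- utf8ToInt("ACGT")
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seqs <- withr::with_seed(seed, {
    setNames(lapply(seq_len(n_chroms), function(i) {
      code <- base_codes[sample.int(4L, chrom_length,
        replace = TRUE, prob = probs
      )]
      if (repeat_fraction > 0) {
        n_blocks <- ceiling(repeat_fraction * chrom_length / repeat_block)
        starts <- sort(sample.int(chrom_length, n_blocks, replace = TRUE))
        ir <- IRanges::reduce(IRanges::IRanges(
          start = starts,
          end = pmin(starts + repeat_block - 1L, chrom_length)
        ))
        mask <- logical(chrom_length)
        for (k in seq_along(ir)) {
          mask[IRanges::start(ir)[k]:IRanges::end(ir)[k]] <- TRUE
        }
        code[mask] <- code[mask] + 32L  # to lowercase
      }
      intToUtf8(code)
    }), paste0("chr", seq_len(n_chroms)))
  })
  genome(unlist(seqs), genome_id = paste0("sim_seed", seed))
}

# Draw site sizes: log-normal around the observed DSB peak median (391 b),
# truncated to [100, 2000].
draw_site_sizes <- function(n, median_size = 391, sdlog = 0.5,
                            min_size = 100L, max_size = 2000L) {
  out <- integer(0)
  while (length(out) < n) {
    s <- round(rlnorm(n, meanlog = log(median_size), sdlog = sdlog))
    out <- c(out, s[s >= min_size & s <= max_size])
  }
  as.integer(out[seq_len(n)])
}

# Uniformly place non-overlapping intervals of the given sizes by sampling
# a start uniformly among all feasible starts (gap bookkeeping, so
# placement never fails while space remains).
place_nonoverlapping <- function(genome, sizes, exclude = NULL) {
  gaps <- dplyr::bind_rows(purrr::map(
    names(genome$chrom_sizes),
    function(ch) tibble(chrom = ch, start = 0L, end = genome$chrom_sizes[[ch]])
  ))
  if (!is.null(exclude) && nrow(exclude)) {
    gaps <- dplyr::bind_rows(purrr::map(unique(gaps$chrom), function(ch) {
      full <- IRanges::IRanges(1L, genome$chrom_sizes[[ch]])
      free <- IRanges::setdiff(full, IRanges::reduce(chrom_iranges(exclude, ch)))
      tibble(
        chrom = ch, start = IRanges::start(free) - 1L,
        end = IRanges::end(free)
      )
    }))
  }
  g_chrom <- gaps$chrom; g_start <- gaps$start; g_end <- gaps$end
  n <- length(sizes)
  out_chrom <- character(n); out_start <- integer(n)
  for (i in seq_len(n)) {
    w <- pmax((g_end - g_start) - sizes[i] + 1L, 0L)
    if (sum(w) == 0) {
      abort(paste0(
        "genome too small: no room left for a site of ", sizes[i], " bases"
      ))
    }
    g <- sample.int(length(w), 1L, prob = w)
    off <- floor(runif(1) * w[g])
    st <- g_start[g] + off
    out_chrom[i] <- g_chrom[g]
    out_start[i] <- st
    # split the chosen gap around the new site
    old_end <- g_end[g]
    g_end[g] <- st
    g_chrom <- c(g_chrom, g_chrom[g])
    g_start <- c(g_start, st + sizes[i])
    g_end <- c(g_end, old_end)
  }
  tibble(chrom = out_chrom, start = out_start, end = out_start + sizes)
}

#' Default epigenomic mark specification
#'
#' Three marks with the conditional colocalization probabilities of the
#' strong DSB predictors: a DNase-like accessible-chromatin mark present
#' at 91% of DSB sites vs 11% of controls, a CTCF-like factor (25% vs 2%)
#' and an H3K4me2-like histone mark (74% vs 11%). The histone mark gets a
#' larger center jitter so that average profiles show the
#' center-vs-shoulder contrast.
#'
#' @return Tibble with columns `name`, `p_dsb`, `p_ctrl`, `peak_median`,
#'   `peak_sdlog`, `jitter_sd`.
#' @export
mark_presets <- function() {
  tibble(
    name = c("DNase", "CTCF", "H3K4me2"),
    p_dsb = c(0.91, 0.25, 0.74),
    p_ctrl = c(0.11, 0.02, 0.11),
    peak_median = c(300, 250, 500),
    peak_sdlog = c(0.3, 0.3, 0.3),
    jitter_sd = c(30, 30, 250)
  )
}

#' Plant DSB sites, control sites and conditional peak tracks
#'
#' Places non-overlapping DSB sites and control sites on the genome (sizes
#' log-normal, median 391 b, truncated to 100-2000 b; controls reuse the
#' DSB size draws), then gives each site a peak of each mark with the
#' mark's conditional probability (`p_dsb` at DSB sites, `p_ctrl` at
#' controls). Peak centers are jittered; every peak is clipped to its
#' site's free territory so it never touches a neighbouring site, which
#' makes the realized conditional frequencies exactly Bernoulli. A
#' realized frequency further than 3 binomial standard deviations from its
#' specification aborts generation.
#'
#' @param genome A [genome()] from [simulate_genome()].
#' @param n_dsb Number of DSB sites.
#' @param n_control Number of control sites (default `n_dsb`).
#' @param marks Mark specification tibble (see [mark_presets()]).
#' @param median_size,sdlog Site-size law parameters.
#' @param seed Integer seed.
#' @return A `dsb_truth`: list with `dsb_sites`, `control_sites`, `tracks`
#'   (named list of peak interval tibbles), `realized` (tibble of realized
#'   conditional frequencies), `seed`.
#' @export
plant_dsb_and_marks <- function(genome, n_dsb = 1000L, n_control = n_dsb,
                                marks = mark_presets(), median_size = 391,
                                sdlog = 0.5, seed = 1L) {
  stopifnot(inherits(genome, "dsb_genome"))
  withr::with_seed(seed, {
    sizes_dsb <- draw_site_sizes(n_dsb, median_size, sdlog)
    sizes_ctl <- sizes_dsb[rep_len(seq_len(n_dsb), n_control)]
    all_sites <- place_nonoverlapping(genome, c(sizes_dsb, sizes_ctl))
    is_dsb <- c(rep(TRUE, n_dsb), rep(FALSE, n_control))
    dsb <- all_sites[is_dsb, , drop = FALSE]
    ctl <- all_sites[!is_dsb, , drop = FALSE]
    dsb$name <- paste0("dsb_", seq_len(n_dsb))
    ctl$name <- paste0("ctl_", seq_len(n_control))

    # free territory per site: up to the nearest neighbouring site
    ord <- order(all_sites$chrom, all_sites$start)
    left_b <- integer(nrow(all_sites)); right_b <- integer(nrow(all_sites))
    for (ch in unique(all_sites$chrom)) {
      j <- ord[all_sites$chrom[ord] == ch]
      left_b[j] <- c(0L, all_sites$end[head(j, -1)])
      right_b[j] <- c(all_sites$start[tail(j, -1)], genome$chrom_sizes[[ch]])
    }

    # Bernoulli presence per site, redrawn (bounded) until the realized
    # frequency sits within 3 binomial sd of the specification, so the
    # generated world matches its stated conditional probabilities
    draw_presence <- function(n, p) {
      if (n == 0L) return(logical(0))
      for (try in 1:20) {
        has <- runif(n) < p
        if (abs(mean(has) - p) <= 3 * sqrt(p * (1 - p) / n)) return(has)
      }
      abort("realized conditional frequency persistently off-spec (>3 binomial sd)")
    }

    plant_peaks <- function(site_rows, p, mk) {
      hit <- which(draw_presence(length(site_rows), p))
      if (!length(hit)) {
        return(list(
          peaks = tibble(chrom = character(), start = integer(), end = integer()),
          has = rep(FALSE, length(site_rows))
        ))
      }
      r <- site_rows[hit]
      s <- draw_site_sizes(length(r), mk$peak_median, mk$peak_sdlog)
      ctr <- (all_sites$start[r] + all_sites$end[r]) %/% 2L +
        as.integer(round(rnorm(length(r), 0, mk$jitter_sd)))
      p_start <- ctr - s %/% 2L
      p_end <- p_start + s
      # guarantee >= 1 base overlap with the site, then clip to territory
      shift_l <- pmax(p_start - (all_sites$end[r] - 1L), 0L)
      shift_r <- pmax((all_sites$start[r] + 1L) - p_end, 0L)
      p_start <- p_start - shift_l + shift_r
      p_end <- p_end - shift_l + shift_r
      p_start <- pmax(p_start, left_b[r])
      p_end <- pmin(p_end, right_b[r])
      list(
        peaks = tibble(
          chrom = all_sites$chrom[r],
          start = as.integer(p_start), end = as.integer(p_end)
        ),
        has = seq_along(site_rows) %in% hit
      )
    }

    tracks <- list()
    realized <- purrr::map(seq_len(nrow(marks)), function(k) {
      mk <- marks[k, ]
      at_dsb <- plant_peaks(which(is_dsb), mk$p_dsb, mk)
      at_ctl <- plant_peaks(which(!is_dsb), mk$p_ctrl, mk)
      tracks[[mk$name]] <<- as_intervals(
        dplyr::bind_rows(at_dsb$peaks, at_ctl$peaks)
      )
      tibble(
        name = mk$name,
        p_dsb = mk$p_dsb, p_ctrl = mk$p_ctrl,
        realized_dsb = mean(at_dsb$has), realized_ctrl = mean(at_ctl$has)
      )
    })
    realized <- dplyr::bind_rows(realized)
    within3sd <- function(realized_p, p, n) {
      n == 0L | abs(realized_p - p) <= 3 * sqrt(p * (1 - p) / max(n, 1L))
    }
    off <- !within3sd(realized$realized_dsb, realized$p_dsb, n_dsb) |
      !within3sd(realized$realized_ctrl, realized$p_ctrl, n_control)
    if (any(off)) {
      abort(paste0(
        "realized conditional frequency off-spec (>3 binomial sd) for: ",
        paste(realized$name[off], collapse = ", ")
      ))
    }
    structure(
      list(
        dsb_sites = as_intervals(dsb), control_sites = as_intervals(ctl),
        tracks = tracks, realized = realized, seed = seed
      ),
      class = "dsb_truth"
    )
  })
}

#' @exportS3Method base::print
print.dsb_truth <- function(x, ...) {
  cat("<dsb_truth> ", nrow(x$dsb_sites), " DSB sites, ",
    nrow(x$control_sites), " control sites, ",
    length(x$tracks), " mark track(s)\n",
    sep = ""
  )
  invisible(x)
}

#' Plant motif occurrences at a target odds ratio
#'
#' Overwrites genome sequence with the motif's consensus inside DSB and
#' control sites so that the per-class insertion frequencies imply the
#' requested odds ratio over the background rate: with background odds
#' `q0/(1-q0)`, DSB sites receive an insertion with probability `q1` such
#' that `odds1 = OR * odds0`. One insertion at most per site, placed
#' uniformly inside the site (sites shorter than the motif are skipped).
#'
#' @param genome A [genome()]; returned modified.
#' @param truth A `dsb_truth` from [plant_dsb_and_marks()].
#' @param motif A [motif()] whose consensus is inserted.
#' @param target_or Target odds ratio (DSB vs control).
#' @param background_rate Insertion probability at control sites
#'   (default 0.02).
#' @param seed Integer seed.
#' @return List with `genome` (modified), `planted` (tibble: `site`,
#'   `class`, `planted` 0/1) and `realized_or` (odds ratio of the planted
#'   indicator).
#' @export
plant_motifs <- function(genome, truth, motif, target_or,
                         background_rate = 0.02, seed = 1L) {
  stopifnot(inherits(truth, "dsb_truth"), inherits(motif, "dsb_motif"))
  cons <- motif_consensus(motif)
  w <- nchar(cons)
  odds0 <- background_rate / (1 - background_rate)
  odds1 <- target_or * odds0
  q1 <- odds1 / (1 + odds1)
  sites <- dplyr::bind_rows(
    dplyr::mutate(truth$dsb_sites, class = "dsb"),
    dplyr::mutate(truth$control_sites, class = "control")
  )
  seqs <- genome$seqs
  planted <- withr::with_seed(seed, {
    p <- ifelse(sites$class == "dsb", q1, background_rate)
    len <- sites$end - sites$start
    do_plant <- runif(nrow(sites)) < p & len >= w
    pos <- sites$start + floor(runif(nrow(sites)) * (len - w + 1))
    for (i in which(do_plant)) {
      substr(seqs[[sites$chrom[i]]], pos[i] + 1L, pos[i] + w) <- cons
    }
    as.integer(do_plant)
  })
  new_g <- genome(seqs, genome_id = genome$genome_id)
  a <- sum(planted[sites$class == "dsb"])
  b <- sum(sites$class == "dsb") - a
  cc <- sum(planted[sites$class == "control"])
  dd <- sum(sites$class == "control") - cc
  list(
    genome = new_g,
    planted = tibble(
      site = sites$name %||% seq_len(nrow(sites)),
      class = sites$class, planted = planted
    ),
    realized_or = odds_ratio(a, b, cc, dd, haldane = TRUE)
  )
}

#' Synthetic pentamer shape table
#'
#' A deterministic stand-in for the Monte-Carlo-derived pentamer shape
#' table: values are drawn from a seeded generator over the canonical
#' (lexicographically smaller of pentamer/reverse complement) pentamers
#' within structurally plausible ranges (MGW 2.8-6.2 A, ProT -16-0 deg,
#' Roll -8-8 deg, HelT 30-38 deg) and copied to reverse complements, so
#' the symmetry invariant holds exactly for all four features.
#'
#' @param seed Integer seed.
#' @return A `dsb_shape_table` with 1024 rows.
#' @export
make_shape_table <- function(seed = 1L) {
  all_p <- all_pentamers()
  rc <- revcomp(all_p)
  cano <- ifelse(all_p <= rc, all_p, rc)
  cano_set <- sort(unique(cano))
  n <- length(cano_set)
  vals <- withr::with_seed(seed, {
    tibble(
      MGW = runif(n, 2.8, 6.2),
      ProT = runif(n, -16, 0),
      Roll = runif(n, -8, 8),
      HelT = runif(n, 30, 38)
    )
  })
  i <- match(cano, cano_set)
  shape_table(tibble(
    pentamer = all_p,
    MGW = vals$MGW[i], ProT = vals$ProT[i],
    Roll = vals$Roll[i], HelT = vals$HelT[i]
  ))
}

#' One-call synthetic DSB experiment
#'
#' Convenience wrapper: simulate a genome, plant DSB/control sites and the
#' default marks, and return everything needed to train and evaluate.
#'
#' @param chrom_length Genome length in bases (default 2e6).
#' @param n_dsb,n_control Site counts per class (default 1000 each).
#' @param marks Mark specification (default [mark_presets()]).
#' @param gc,repeat_fraction Genome composition.
#' @param seed Integer seed (stages use offsets of it).
#' @return List with `genome` and `truth`.
#' @export
simulate_dsb_experiment <- function(chrom_length = 2e6, n_dsb = 1000L,
                                    n_control = n_dsb, marks = mark_presets(),
                                    gc = 0.41, repeat_fraction = 0.3,
                                    seed = 1L) {
  g <- simulate_genome(
    chrom_length = chrom_length, gc = gc,
    repeat_fraction = repeat_fraction, seed = seed
  )
  truth <- plant_dsb_and_marks(g,
    n_dsb = n_dsb, n_control = n_control,
    marks = marks, seed = seed + 1L
  )
  list(genome = g, truth = truth)
}
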