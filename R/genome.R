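#' Genome objects
#'
#' A `dsb_genome` bundles chromosome sizes with (optionally) the chromosome
#' sequences themselves. Sequences are plain character strings in which
#' lowercase bases mark repeat-annotated (soft-masked) sequence, the
#' RepeatMasker convention; case is preserved throughout. All coordinates in
#' the package are 0-based half-open (BED convention).
#'
#' @param seqs Named character vector of chromosome sequences
#'   (`A/C/G/T/N`, either case), or `NULL` when only sizes are known.
#' @param chrom_sizes Named numeric vector of chromosome lengths in bases.
#'   Derived from `seqs` when omitted.
#' @param genome_id Optional tag carried along for provenance.
#'
#' @return An object of class `dsb_genome`: a list with elements
#'   `chrom_sizes`, `seqs` (possibly `NULL`), `genome_id`, and an internal
#'   cache environment used for per-chromosome prefix sums.
#' @examples
#' g <- genome(c(chr1 = "ACGTacgtNNAC"))
#' genome_size(g)
#' @export
genome <- function(seqs = NULL, chrom_sizes = NULL, genome_id = NULL) {
  if (is.null(seqs) && is.null(chrom_sizes)) {
    abort("supply `seqs` or `chrom_sizes`")
  }
  if (!is.null(seqs)) {
    if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")) {
      abort("`seqs` must be a named character vector of chromosome sequences")
    }
    sizes <- vapply(seqs, nchar, numeric(1))
    if (!is.null(chrom_sizes)) {
      if (!identical(sort(names(chrom_sizes)), sort(names(seqs)))) {
        abort("`chrom_sizes` names do not match `seqs` names")
      }
      if (any(chrom_sizes[names(sizes)] != sizes)) {
        abort("declared chromosome sizes disagree with sequence lengths")
      }
    }
    chrom_sizes <- sizes
  }
  if (any(chrom_sizes <= 0)) abort("all chromosome sizes must be > 0")
  structure(
    list(
      chrom_sizes = chrom_sizes,
      seqs = seqs,
      genome_id = genome_id,
      .cache = new.env(parent = emptyenv())
    ),
    class = "dsb_genome"
  )
}

#' @exportS3Method base::print
print.dsb_genome <- function(x, ...) {
  cat(
    "<dsb_genome> ", length(x$chrom_sizes), " chromosome(s), ",
    format(sum(x$chrom_sizes), big.mark = ","), " bases",
    if (is.null(x$seqs)) " (sizes only)" else "", "\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname genome
#' @param x A `dsb_genome`.
#' @export
genome_size <- function(x) {
  stopifnot(inherits(x, "dsb_genome"))
  sum(x$chrom_sizes)
}

#' Read and write genomes as FASTA
#'
#' `read_genome_fasta()` loads a (soft-masked) FASTA file into a
#' [genome()] object, preserving case. `write_genome_fasta()` writes one
#' back out.
#'
#' @param path Path to a FASTA file.
#' @param genome_id Optional tag stored on the object.
#' @return A `dsb_genome`.
#' @export
read_genome_fasta <- function(path, genome_id = NULL) {
  if (!file.exists(path)) abort(paste0("no such FASTA file: ", path))
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) abort("not a FASTA file (no '>' header)")
  idx <- cumsum(hdr)
  nm <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  body <- split(lines[!hdr], idx[!hdr])
  seqs <- vapply(body, paste0, character(1), collapse = "")
  names(seqs) <- nm[as.integer(names(body))]
  genome(seqs, genome_id = genome_id %||% basename(path))
}

#' @rdname read_genome_fasta
#' @param x A `dsb_genome` with sequences.
#' @param width Line width for wrapping sequence.
#' @export
write_genome_fasta <- function(x, path, width = 70L) {
  stopifnot(inherits(x, "dsb_genome"))
  if (is.null(x$seqs)) abort("genome has no sequences to write")
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(x$seqs)) {
    writeLines(paste0(">", nm), con)
    s <- x$seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Extract sequences for sites
#'
#' Retrieves the genomic sequence under each interval, case preserved.
#'
#' @param sites Interval tibble (`chrom`, `start`, `end`; 0-based half-open).
#' @param genome A [genome()] with sequences.
#' @return Character vector, one sequence per row of `sites`.
#' @export
site_sequences <- function(sites, genome) {
  sites <- validate_intervals(sites)
  stopifnot(inherits(genome, "dsb_genome"))
  if (is.null(genome$seqs)) abort("genome has no sequences")
  check_chroms(sites, genome)
  beyond <- sites$end > genome$chrom_sizes[sites$chrom]
  if (any(beyond)) {
    abort(paste0(
      "site(s) extend beyond chromosome end: row(s) ",
      paste(which(beyond), collapse = ", ")
    ))
  }
  substring(genome$seqs[sites$chrom], sites$start + 1L, sites$end)
}

#' Reverse complement
#'
#' Case-preserving reverse complement of DNA strings (`N` maps to `N`).
#'
#' @param seq Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  vapply(seq, function(s) {
    if (nchar(s) == 0L) return("")
    intToUtf8(rev(utf8ToInt(chartr("ACGTacgtNn", "TGCAtgcaNn", s))))
  }, character(1), USE.NAMES = FALSE)
}

# Per-chromosome prefix sums of GC / soft-masked / N indicators, cached on
# the genome so repeated composition queries are O(1).
genome_prefix <- function(genome, chrom) {
  key <- paste0("pfx_", chrom)
  cached <- genome$.cache[[key]]
  if (!is.null(cached)) return(cached)
  s <- genome$seqs[[chrom]]
  if (is.null(s)) abort(paste0("no sequence for chromosome ", chrom))
  code <- utf8ToInt(s)
  is_lower <- code >= 97L
  up <- ifelse(is_lower, code - 32L, code)
  is_gc <- up == 67L | up == 71L           # C, G
  is_n <- up == 78L                        # N
  bad <- !(up %in% c(65L, 67L, 71L, 84L, 78L))
  if (any(bad)) {
    abort(paste0(
      "illegal character(s) in sequence of ", chrom, ": ",
      paste(unique(intToUtf8(code[bad], multiple = TRUE)), collapse = " ")
    ))
  }
  pfx <- list(
    gc = cumsum(c(0, is_gc)),
    lower = cumsum(c(0, is_lower)),
    n = cumsum(c(0, is_n))
  )
  assign(key, pfx, envir = genome$.cache)
  pfx
}

`%||%` <- function(a, b) if (is.null(a)) b else a
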