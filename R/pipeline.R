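#' Run the three-step DSB prediction pipeline
#'
#' Wires the package into the full workflow: (1) read DSB peaks (and
#' intersect two replicates when both are given), (2) draw matched
#' non-DSB controls and featurize both sets from the supplied peak
#' tracks / motifs / shape table, (3) train a classifier and evaluate it
#' on the held-out split. All artifacts are written as plain text into
#' `out_dir` together with a JSON manifest capturing the configuration,
#' seeds and input checksums, sufficient to reproduce every number.
#'
#' @param config Named list (or path to a JSON file) with elements:
#'   `genome_fasta` (path), `dsb_bed` (path, or character vector of two
#'   replicate paths), `track_beds` (named character vector of paths,
#'   optional), `motif_file` (JASPAR path, optional), `shape_table`
#'   (TSV path, optional), `model` (`"forest"` or `"lasso"`, default
#'   forest), `ratio`, `gc_tol`, `repeat_tol`, `test_fraction`, `n_boot`,
#'   `seed`, `scan_width` (set to e.g. 250 to also score the genome).
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with `model`, `eval`, `dataset`, and paths of
#'   written artifacts.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(
    list(
      model = "forest", ratio = 1, gc_tol = 0.02, repeat_tol = 0.05,
      test_fraction = 0.3, n_boot = 2000L, seed = 1L, min_rel_score = 0.8,
      scan_width = NULL
    ),
    config
  )
  for (p in c(cfg$genome_fasta, cfg$dsb_bed, cfg$track_beds, cfg$motif_file,
              cfg$shape_table)) {
    if (!is.null(p) && !file.exists(p)) abort(paste0("missing input: ", p))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  genome <- stage("read-genome", read_genome_fasta(cfg$genome_fasta))
  dsb <- stage("read-dsb", {
    if (length(cfg$dsb_bed) == 2L) {
      intersect_replicates(
        read_bed(cfg$dsb_bed[1], genome), read_bed(cfg$dsb_bed[2], genome)
      )
    } else {
      read_bed(cfg$dsb_bed, genome)
    }
  })
  tracks <- NULL
  if (!is.null(cfg$track_beds)) {
    tracks <- stage(
      "read-tracks",
      purrr::map(as.list(cfg$track_beds), read_bed, genome = genome)
    )
  }
  motifs <- if (!is.null(cfg$motif_file)) {
    stage("read-motifs", read_jaspar(cfg$motif_file))
  }
  shp <- if (!is.null(cfg$shape_table)) {
    stage("read-shape", read_shape_table(cfg$shape_table))
  }

  neg <- stage("sample-null", sample_matched_negatives(
    dsb, genome,
    ratio = cfg$ratio, gc_tol = cfg$gc_tol,
    repeat_tol = cfg$repeat_tol, seed = cfg$seed + 1L
  ))
  featurize <- function(sites) {
    featurize_sites(sites,
      genome = genome, tracks = tracks, motifs = motifs,
      shape_table = shp, min_rel_score = cfg$min_rel_score
    )
  }
  pos_f <- stage("featurize", featurize(dsb))
  neg_f <- stage("featurize", featurize(neg))
  data <- stage("assemble", assemble_dataset(pos_f, neg_f,
    test_fraction = cfg$test_fraction, seed = cfg$seed + 2L
  ))
  model <- stage("train", switch(cfg$model,
    forest = train_forest(data, seed = cfg$seed + 3L),
    lasso = train_lasso(data, seed = cfg$seed + 3L),
    abort(paste0("unknown model: ", cfg$model))
  ))
  eval <- stage("evaluate", evaluate(model, data,
    n_boot = cfg$n_boot, seed = cfg$seed + 4L
  ))

  paths <- list(
    negatives = file.path(out_dir, "negatives.bed"),
    enrichment = file.path(out_dir, "enrichment.tsv"),
    eval = file.path(out_dir, "eval.tsv"),
    roc = file.path(out_dir, "roc.tsv"),
    pr = file.path(out_dir, "pr.tsv"),
    model = file.path(out_dir, "model.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_bed(neg, paths$negatives)
  write_tsv0 <- function(x, path) {
    write.table(as.data.frame(x), path,
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  write_tsv0(enrichment_report(pos_f, neg_f), paths$enrichment)
  write_tsv0(
    tibble(
      auroc = eval$auroc, aupr = eval$aupr,
      ci_lo = eval$auroc_ci[1] %||% NA_real_,
      ci_hi = eval$auroc_ci[2] %||% NA_real_,
      n_boot = eval$n_boot
    ),
    paths$eval
  )
  write_tsv0(eval$roc, paths$roc)
  write_tsv0(eval$pr, paths$pr)
  write_tsv0(tidy(model), paths$model)
  scan <- NULL
  if (!is.null(cfg$scan_width)) {
    scan <- stage("scan-genome", score_genome(model, genome,
      tracks = tracks, motifs = motifs, shape_table = shp,
      width = cfg$scan_width, min_rel_score = cfg$min_rel_score
    ))
    paths$scores <- file.path(out_dir, "bin_scores.tsv")
    write_tsv0(scan[, c("chrom", "start", "end", "score")], paths$scores)
  }
  manifest <- list(
    package = "dsbpredict",
    version = as.character(utils::packageVersion("dsbpredict")),
    config = cfg[setdiff(names(cfg), "track_beds")],
    track_beds = as.list(cfg$track_beds),
    input_md5 = as.list(tools::md5sum(unlist(
      c(cfg$genome_fasta, cfg$dsb_bed, cfg$track_beds, cfg$motif_file,
        cfg$shape_table)
    ))),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(
    model = model, eval = eval, dataset = data, scan = scan, paths = paths
  ))
}
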