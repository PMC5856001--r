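sim_small <- function(seed = 101) {
  sim <- simulate_dsb_experiment(chrom_length = 5e5, n_dsb = 300, seed = seed)
  tracks <- sim$truth$tracks
  pos <- featurize_sites(sim$truth$dsb_sites, tracks = tracks)
  neg <- featurize_sites(sim$truth$control_sites, tracks = tracks)
  d <- assemble_dataset(pos, neg, seed = seed + 1)
  m <- train_forest(d, num_trees = 200, seed = seed + 2)
  list(sim = sim, tracks = tracks, d = d, m = m)
}

test_that("score_genome featurizes bins with the training encoders", {
  s <- sim_small()
  track <- score_genome(s$m, s$sim$genome, tracks = s$tracks, width = 250)
  expect_equal(nrow(track), ceiling(5e5 / 250))
  expect_true(all(track$score >= 0 & track$score <= 1))
  # bins inside planted DSB sites outscore the rest
  lab <- label_intervals(track, s$sim$truth$dsb_sites)
  expect_gt(mean(track$score[lab == 1]), mean(track$score[lab == 0]) + 0.2)
  # featurizer round-trip: scoring the training sites reproduces the
  # training features (and therefore identical scores)
  pos_feats <- featurize_sites(s$sim$truth$dsb_sites, tracks = s$tracks)
  expect_identical(
    pos_feats,
    s$d$features[s$d$labels == 1, , drop = FALSE]
  )
  # missing track is an error, never zero-fill
  expect_error(
    score_genome(s$m, s$sim$genome, tracks = s$tracks[-1]),
    "DNase"
  )
  # toy-size check: 10 kb in 40 bins
  g10 <- genome(chrom_sizes = c(chr1 = 10000))
  expect_equal(nrow(bin_genome(g10, 250)), 40L)
})

test_that("call_high_low partitions bins by score thresholds", {
  track <- tibble::tibble(
    chrom = "chr1", start = seq(0, 750, 250), end = seq(250, 1000, 250),
    score = c(0.1, 0.5, 0.8, 1)
  )
  hl <- call_high_low(track, low = 0.25, high = 0.75)
  expect_equal(hl$predicted_dsb$start, c(500L, 750L))
  expect_equal(hl$predicted_control$start, 0L)
  n_mid <- nrow(track) - nrow(hl$predicted_dsb) - nrow(hl$predicted_control)
  expect_equal(n_mid, 1L)
  # all 0.5 with band (0.25, 0.75): both calls empty
  track$score <- 0.5
  hl2 <- call_high_low(track)
  expect_equal(nrow(hl2$predicted_dsb), 0L)
  expect_equal(nrow(hl2$predicted_control), 0L)
  track$score <- 1
  expect_equal(nrow(call_high_low(track)$predicted_dsb), nrow(track))
  expect_error(call_high_low(track, low = 0.8, high = 0.2), "low < high")
})

test_that("signal_by_score is monotone for planted and flat for uniform signal", {
  withr::with_seed(110, {
    track <- tibble::tibble(
      chrom = "chr1", start = seq(0, 249750, 250), end = seq(250, 250000, 250),
      score = runif(1000)
    )
  })
  # signal only in the top-scoring decile of bins
  top <- track[rank(track$score) > 900, ]
  tab <- signal_by_score(track, top[, c("chrom", "start", "end")], n_quantiles = 10)
  expect_equal(nrow(tab), 10L)
  expect_equal(tab$mean_signal[1:9], rep(0, 9))
  expect_gt(tab$mean_signal[10], 0.9)
  # uniform signal: flat
  unif <- tibble::tibble(chrom = "chr1", start = 0, end = 250000)
  tab2 <- signal_by_score(track, unif, n_quantiles = 5)
  expect_true(all(tab2$mean_signal == 1))
  # anti-correlated signal: decreasing
  bottom <- track[rank(track$score) <= 100, ]
  tab3 <- signal_by_score(track, bottom[, c("chrom", "start", "end")], n_quantiles = 10)
  expect_gt(tab3$mean_signal[1], tab3$mean_signal[10])
  # graded signal (coverage proportional to score rank) is monotone in rank
  # correlation across deciles
  rk <- rank(track$score)
  graded <- tibble::tibble(
    chrom = "chr1", start = track$start,
    end = track$start + pmax(1, round(250 * rk / 1000))
  )
  tab4 <- signal_by_score(track, graded, n_quantiles = 10)
  expect_gt(cor(tab4$quantile, tab4$mean_signal, method = "spearman"), 0.9)
})

test_that("transfer_predict requires the training features and ignores column order", {
  s <- sim_small(seed = 120)
  test_feats <- s$d$features[s$d$split == "test", , drop = FALSE]
  direct <- predict(s$m, s$d)
  expect_equal(transfer_predict(s$m, test_feats), direct)
  expect_equal(transfer_predict(s$m, rev(test_feats)), direct)
  expect_error(
    transfer_predict(s$m, test_feats[, -1, drop = FALSE]),
    "unavailable"
  )
  # a second cell type drawn from the same generative process transfers
  s2 <- sim_small(seed = 130)
  b_feats <- s2$d$features[s2$d$split == "test", ]
  b_labels <- s2$d$labels[s2$d$split == "test"]
  e_within <- evaluate(s2$m, s2$d, n_boot = 0)
  e_transfer <- evaluate_scores(
    transfer_predict(s$m, b_feats), b_labels, n_boot = 0
  )
  expect_lt(abs(e_transfer$auroc - e_within$auroc), 0.1)
})
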