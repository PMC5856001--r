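# feature tables drawn straight from the conditional-occupancy law, for
# model tests that do not need a genome
bernoulli_features <- function(n, p_by_mark) {
  tibble::as_tibble(lapply(p_by_mark, function(p) as.numeric(runif(n) < p)))
}

make_planted_dataset <- function(n_per_class = 2000, seed = 1,
                                 p_pos = list(DNase = 0.91),
                                 p_neg = list(DNase = 0.11)) {
  withr::with_seed(seed, {
    pos <- bernoulli_features(n_per_class, p_pos)
    neg <- bernoulli_features(n_per_class, p_neg)
  })
  assemble_dataset(pos, neg, seed = seed + 1)
}

test_that("assemble_dataset stratifies, reproduces, and checks columns", {
  pos <- tibble::tibble(a = runif(100), b = runif(100))
  neg <- tibble::tibble(a = runif(100), b = runif(100))
  d <- assemble_dataset(pos, neg, test_fraction = 0.3, seed = 5)
  expect_equal(sum(d$split == "train"), 140L)
  expect_equal(sum(d$split == "test"), 60L)
  tab <- table(d$labels[d$split == "test"])
  expect_lte(abs(tab[["0"]] - tab[["1"]]), 1L)
  d2 <- assemble_dataset(pos, neg, test_fraction = 0.3, seed = 5)
  expect_identical(d$split, d2$split)
  expect_error(
    assemble_dataset(pos[, "a", drop = FALSE], neg),
    "differ.*b"
  )
})

test_that("forest recovers a planted mark and ranks it first in importance", {
  d <- make_planted_dataset(
    n_per_class = 2000, seed = 10,
    p_pos = list(DNase = 0.91, CTCF = 0.25, H3K4me2 = 0.74),
    p_neg = list(DNase = 0.11, CTCF = 0.02, H3K4me2 = 0.11)
  )
  m <- train_forest(d, seed = 11)
  e <- evaluate(m, d, n_boot = 200, seed = 12)
  expect_gt(e$auroc, 0.85)
  expect_equal(m$importance$feature[1], "DNase")
  expect_true(all(m$importance$importance[1] > m$importance$importance[-1]))
  # bootstrap CI brackets the point estimate
  expect_lte(e$auroc_ci[1], e$auroc + 0.01)
  expect_gte(e$auroc_ci[2], e$auroc - 0.01)
  # same seed, same model
  m2 <- train_forest(d, seed = 11)
  expect_equal(m$importance, m2$importance)
  expect_equal(predict(m, d), predict(m2, d))
})

test_that("forest on label-shuffled data sits at chance", {
  d <- make_planted_dataset(n_per_class = 500, seed = 20)
  withr::with_seed(21, {
    d$labels <- sample(d$labels)
  })
  m <- train_forest(d, seed = 22)
  e <- evaluate(m, d, n_boot = 0)
  expect_gt(e$auroc, 0.4)
  expect_lt(e$auroc, 0.6)
})

test_that("forest errors on single-class or undersized training data", {
  d <- make_planted_dataset(n_per_class = 100, seed = 30)
  d_bad <- d
  d_bad$labels <- rep(1L, length(d$labels))
  expect_error(train_forest(d_bad), "single class")
  expect_error(train_forest(d, min_class_size = 1000), "training rows per class")
})

test_that("lasso keeps the informative feature and zeroes decoys", {
  withr::with_seed(40, {
    n <- 800
    pos <- tibble::tibble(
      signal = as.numeric(runif(n) < 0.85),
      noise1 = runif(n), noise2 = runif(n), noise3 = as.numeric(runif(n) < 0.5)
    )
    neg <- tibble::tibble(
      signal = as.numeric(runif(n) < 0.10),
      noise1 = runif(n), noise2 = runif(n), noise3 = as.numeric(runif(n) < 0.5)
    )
  })
  d <- assemble_dataset(pos, neg, seed = 41)
  m <- train_lasso(d, lambda = "lambda.1se", seed = 42)
  co <- tidy(m)
  expect_gt(co$beta[co$feature == "signal"], 0)
  expect_equal(co$beta[grepl("noise", co$feature)], rep(0, 3))
  # fully null features collapse to the intercept-only model
  withr::with_seed(43, {
    null_pos <- tibble::tibble(x1 = runif(300), x2 = runif(300))
    null_neg <- tibble::tibble(x1 = runif(300), x2 = runif(300))
  })
  d0 <- assemble_dataset(null_pos, null_neg, seed = 44)
  m0 <- train_lasso(d0, lambda = "lambda.1se", seed = 45)
  expect_equal(tidy(m0)$beta[-1], rep(0, 2))
  # constant features are dropped with a warning
  dc <- assemble_dataset(
    dplyr::mutate(pos, flat = 1), dplyr::mutate(neg, flat = 1),
    seed = 46
  )
  expect_warning(train_lasso(dc, seed = 47), "constant")
})

test_that("unpenalized logistic hits the closed-form log odds and flags separation", {
  # single binary feature with train table (30, 10, 10, 30): beta = ln(9)
  feats <- tibble::tibble(x = c(rep(1, 30), rep(0, 10), rep(1, 10), rep(0, 30)))
  d <- structure(
    list(
      features = feats,
      labels = c(rep(1L, 40), rep(0L, 40)),
      split = rep("train", 80), seed = 1L
    ),
    class = "dsb_dataset"
  )
  m <- train_logistic(d)
  expect_equal(
    m$coefficients$beta[m$coefficients$feature == "x"], log(9),
    tolerance = 1e-6
  )
  expect_true(all(c("std_error", "p_value") %in% names(m$coefficients)))
  # perfectly separable data must error, not return garbage
  d_sep <- structure(
    list(
      features = tibble::tibble(x = c(rep(1, 40), rep(0, 40))),
      labels = c(rep(1L, 40), rep(0L, 40)),
      split = rep("train", 80), seed = 1L
    ),
    class = "dsb_dataset"
  )
  expect_error(train_logistic(d_sep), "separation")
})

test_that("null-feature Wald p-values are roughly uniform", {
  hits <- withr::with_seed(60, {
    vapply(1:60, function(i) {
      feats <- tibble::tibble(x = runif(200))
      d <- structure(
        list(
          features = feats, labels = rep(c(1L, 0L), each = 100),
          split = rep("train", 200), seed = 1L
        ),
        class = "dsb_dataset"
      )
      train_logistic(d)$coefficients$p_value[2]
    }, numeric(1))
  })
  expect_gt(mean(hits), 0.35) # uniform mean is 0.5
  expect_lt(mean(hits < 0.05), 0.15) # nominal 5% level
})

test_that("AUROC equals concordance and is invariant to monotone transforms", {
  # worked example: three positives (0.9, 0.8, 0.2), one negative (0.4)
  e <- evaluate_scores(c(0.9, 0.8, 0.2, 0.4), c(1, 1, 1, 0), n_boot = 0)
  expect_equal(e$auroc, 2 / 3)
  # perfect separation
  e2 <- evaluate_scores(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0), n_boot = 0)
  expect_equal(e2$auroc, 1)
  expect_equal(e2$aupr, 1)
  expect_equal(e2$roc$fpr[1], 0)
  expect_equal(e2$roc$tpr[1], 0)
  expect_equal(tail(e2$roc$fpr, 1), 1)
  expect_equal(tail(e2$roc$tpr, 1), 1)
  # random scores with heavy ties: trapezoid AUROC == pairwise concordance
  withr::with_seed(70, {
    for (rep in 1:5) {
      n <- sample(50:500, 1)
      scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)
      labels <- rbinom(n, 1, 0.4)
      if (sum(labels) %in% c(0, n)) next
      got <- evaluate_scores(scores, labels, n_boot = 0)$auroc
      expect_equal(got, bf_auroc(scores, labels))
      # strictly monotone transform leaves AUROC unchanged
      got2 <- evaluate_scores(plogis(5 * scores - 1), labels, n_boot = 0)$auroc
      expect_equal(got2, got)
    }
  })
  expect_error(evaluate_scores(c(1, 2), c(1, 1), n_boot = 0), "both classes")
})

test_that("venn_summary percentages follow the half-up 2 d.p. rule", {
  expect_equal(percent_of(18084, 18510), 97.70)
  expect_equal(percent_of(605, 73363), 0.82)
  # three identical sets: nothing exclusive anywhere
  x <- data.frame(chrom = "chr1", start = c(0, 100), end = c(50, 150))
  v <- venn_summary(x, x, x)
  expect_equal(v$pct[v$quantity == "pred_in_neither"], 0)
  expect_equal(v$n[v$quantity == "refA_predicted"], 2)
  expect_equal(v$of[v$quantity == "refA_only_predicted"], 0)
  # predictions recovering one reference but not the other
  pred <- data.frame(chrom = "chr1", start = 0, end = 50)
  refb <- data.frame(chrom = "chr1", start = 100, end = 150)
  v2 <- venn_summary(pred, x, refb)
  expect_equal(v2$pct[v2$quantity == "refA_predicted"], 50)
  expect_equal(v2$pct[v2$quantity == "pred_in_neither"], 0)
})

test_that("tidy/glance expose importance, coefficients and eval summaries", {
  d <- make_planted_dataset(n_per_class = 200, seed = 80)
  m <- train_forest(d, num_trees = 100, seed = 81)
  expect_named(tidy(m), c("feature", "importance"))
  g <- glance(m)
  expect_equal(g$family, "forest")
  expect_gte(g$oob_error, 0)
  e <- evaluate(m, d, n_boot = 100, seed = 82)
  ge <- glance(e)
  expect_true(all(c("auroc", "aupr", "auroc_ci_lo", "n_boot") %in% names(ge)))
  expect_equal(nrow(tidy(e, "pr")), nrow(e$pr))
  ml <- train_lasso(d, seed = 83)
  expect_true("odds_ratio" %in% names(tidy(ml)))
})
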