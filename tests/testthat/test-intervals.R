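test_that("read_bed parses BED3+, skips headers, and rejects bad coordinates", {
  f <- tmp_file(c("chr1\t100\t600"))
  x <- read_bed(f)
  expect_equal(nrow(x), 1L)
  expect_equal(x$end - x$start, 500L)

  f2 <- tmp_file(c(
    "track name=x", "# comment",
    "chr1\t10\t20\tpeak1\t7", "chr2\t5\t8"
  ))
  x2 <- read_bed(f2)
  expect_equal(nrow(x2), 2L)
  expect_equal(x2$name[x2$chrom == "chr1"], "peak1")
  expect_equal(x2$score[x2$chrom == "chr1"], 7)

  f3 <- tmp_file(c("chr1\t600\t100"))
  expect_error(read_bed(f3), "line 1")
  f4 <- tmp_file(c("chr1\tabc\t100"))
  expect_error(read_bed(f4), "malformed")

  g <- toy_genome()
  f5 <- tmp_file(c("chrX\t1\t10"))
  expect_error(read_bed(f5, genome = g), "chrX")
})

test_that("as_intervals canonicalizes: sorted, duplicates collapsed", {
  x <- data.frame(
    chrom = c("chr2", "chr1", "chr1", "chr1"),
    start = c(5, 50, 10, 10),
    end = c(9, 60, 20, 20)
  )
  y <- as_intervals(x)
  expect_equal(nrow(y), 3L)
  expect_true(!is.unsorted(order(y$chrom, y$start)))
  expect_equal(y$start, c(10L, 50L, 5L))
})

test_that("intersect_replicates keeps rep1 peaks overlapping rep2", {
  a <- data.frame(chrom = "chr1", start = c(100, 1000), end = c(600, 1200))
  b <- data.frame(chrom = "chr1", start = 500, end = 800)
  # identical sets come back unchanged; disjoint sets are empty
  expect_equal(
    intersect_replicates(a, a)[, c("chrom", "start", "end")],
    as_intervals(a)[, c("chrom", "start", "end")]
  )
  disjoint <- data.frame(chrom = "chr1", start = 5000, end = 5100)
  expect_equal(nrow(intersect_replicates(a, disjoint)), 0L)
  # default keeps the whole rep1 peak; clip=TRUE clips to the overlap
  kept <- intersect_replicates(a, b)
  expect_equal(kept$start, 100L)
  expect_equal(kept$end, 600L)
  clipped <- intersect_replicates(a, b, clip = TRUE)
  expect_equal(clipped$start, 500L)
  expect_equal(clipped$end, 600L)
})

test_that("intersect_replicates result is never larger than rep1 (property)", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      a <- as_intervals(tibble::tibble(
        chrom = "chr1", start = s <- sample(0:5000, 30), end = s + sample(10:200, 30, TRUE)
      ))
      b <- as_intervals(tibble::tibble(
        chrom = "chr1", start = s2 <- sample(0:5000, 20), end = s2 + sample(10:200, 20, TRUE)
      ))
      expect_lte(nrow(intersect_replicates(a, b)), nrow(a))
    }
  })
})

test_that("overlap_fraction matches the occupancy encoding and a per-base oracle", {
  site <- data.frame(chrom = "chr1", start = 100, end = 600)
  expect_equal(overlap_fraction(site, data.frame(chrom = "chr1", start = 200, end = 500)), 0.6)
  expect_equal(overlap_fraction(site, data.frame(chrom = "chr1", start = 700, end = 900)), 0)
  expect_equal(overlap_fraction(site, data.frame(chrom = "chr1", start = 0, end = 1000)), 1)
  # split-invariance: abutting pieces cover the same fraction
  split_track <- data.frame(chrom = "chr1", start = c(200, 350), end = c(350, 500))
  expect_equal(overlap_fraction(site, split_track), 0.6)
  # randomized agreement with the per-base coverage oracle
  withr::with_seed(7, {
    for (rep in 1:10) {
      tr <- tibble::tibble(
        chrom = "chr1", start = s <- sample(0:900, 8), end = s + sample(5:150, 8, TRUE)
      )
      got <- overlap_fraction(site, tr)
      expect_equal(got, bf_overlap_fraction(100L, 600L, tr))
    }
  })
})

test_that("bin_genome tiles chromosomes, truncating the trailing bin", {
  g <- genome(chrom_sizes = c(chr1 = 1000))
  expect_equal(nrow(bin_genome(g, 250)), 4L)
  g2 <- genome(chrom_sizes = c(chr1 = 1001))
  b2 <- bin_genome(g2, 250)
  expect_equal(nrow(b2), 5L)
  expect_equal(b2$end[5] - b2$start[5], 1L)
  expect_error(bin_genome(g, 0), "width")
  # total bin length conserves genome length (multi-chromosome)
  g3 <- genome(chrom_sizes = c(chr1 = 997, chr2 = 1250, chr3 = 50))
  b3 <- bin_genome(g3, 250)
  expect_equal(sum(b3$end - b3$start), genome_size(g3))
})

test_that("label_intervals flags >=1-base overlap and matches brute force", {
  g <- genome(chrom_sizes = c(chr1 = 1000))
  bins <- bin_genome(g, 250)
  # a DSB spanning the bin-0/bin-1 boundary labels both
  lab <- label_intervals(bins, data.frame(chrom = "chr1", start = 240, end = 260))
  expect_equal(lab, c(1L, 1L, 0L, 0L))
  expect_equal(
    label_intervals(bins, data.frame(chrom = "chr1", start = 0, end = 1000)),
    rep(1L, 4)
  )
  expect_equal(
    label_intervals(bins, data.frame(chrom = "chr2", start = 0, end = 10)),
    rep(0L, 4)
  )
  withr::with_seed(11, {
    regions <- as_intervals(tibble::tibble(
      chrom = sample(c("chr1", "chr2"), 200, TRUE),
      start = s <- sample(0:5000, 200), end = s + sample(1:100, 200, TRUE)
    ))
    dsb <- as_intervals(tibble::tibble(
      chrom = sample(c("chr1", "chr2"), 50, TRUE),
      start = s2 <- sample(0:5000, 50), end = s2 + sample(1:100, 50, TRUE)
    ))
    brute <- vapply(seq_len(nrow(regions)), function(i) {
      as.integer(any(
        dsb$chrom == regions$chrom[i] &
          dsb$start < regions$end[i] & dsb$end > regions$start[i]
      ))
    }, integer(1))
    expect_equal(label_intervals(regions, dsb), brute)
  })
})

test_that("average_profile localizes shifted signal and flattens uniform signal", {
  g <- genome(chrom_sizes = c(chr1 = 100000))
  centers <- seq(10000, 90000, by = 2000)
  sites <- as_intervals(tibble::tibble(
    chrom = "chr1", start = centers - 200, end = centers + 200
  ))
  # signal shifted +100 b from every center
  sig <- tibble::tibble(chrom = "chr1", start = centers + 90, end = centers + 110)
  prof <- average_profile(sig, sites, g, flank = 500, bin = 20)
  expect_s3_class(prof, "dsb_profile")
  expect_true(prof$offset[which.max(prof$mean)] %in% c(90L, 110L))
  expect_true(all(diff(prof$offset) == 20L))
  # uniform signal -> flat profile
  unif <- tibble::tibble(chrom = "chr1", start = 0, end = 100000)
  prof2 <- average_profile(unif, sites, g, flank = 500, bin = 50)
  expect_true(all(prof2$mean == 1))
  # all sites dropped -> error
  edge <- data.frame(chrom = "chr1", start = 0, end = 10)
  expect_error(average_profile(sig, edge, g, flank = 500, bin = 50), "dropped")
})
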