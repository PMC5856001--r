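test_that("synthetic shape table is complete, symmetric and deterministic", {
  tab <- make_shape_table(seed = 9)
  expect_equal(nrow(tab), 1024L)
  expect_identical(tab, make_shape_table(seed = 9))
  expect_false(identical(tab$MGW, make_shape_table(seed = 10)$MGW))
  rc <- revcomp(tab$pentamer)
  i <- match(rc, tab$pentamer)
  for (f in c("MGW", "ProT", "Roll", "HelT")) {
    expect_equal(tab[[f]], tab[[f]][i])
  }
  expect_true(all(tab$MGW >= 2.8 & tab$MGW <= 6.2))
  expect_true(all(tab$HelT >= 30 & tab$HelT <= 38))
})

test_that("shape tables round-trip through TSV and complete from canonical halves", {
  tab <- make_shape_table(seed = 2)
  f <- tempfile(fileext = ".tsv")
  write_shape_table(tab, f)
  tab2 <- read_shape_table(f)
  expect_equal(as.data.frame(tab2), as.data.frame(tab))
  # a canonical-only half table completes to the full 1024
  rc <- revcomp(tab$pentamer)
  half <- as.data.frame(tab[tab$pentamer <= rc, ])
  expect_lt(nrow(half), 1024L)
  completed <- shape_table(half)
  expect_equal(as.data.frame(completed), as.data.frame(tab))
  # symmetry violations are rejected
  broken <- as.data.frame(tab)
  broken$MGW[broken$pentamer == "AAAAA"] <- broken$MGW[broken$pentamer == "AAAAA"] + 1
  expect_error(shape_table(broken), "symmetry")
  # true gaps are reported
  gap <- as.data.frame(tab)[-(1:3), ]
  gap <- gap[!gap$pentamer %in% revcomp(as.data.frame(tab)$pentamer[1:3]), ]
  expect_error(shape_table(gap), "missing")
})

test_that("predict_shape is a sliding pentamer lookup", {
  tab <- make_shape_table(seed = 3)
  s <- "ACGTACGTA"
  prof <- predict_shape(s, tab)
  expect_equal(nrow(prof), nchar(s) - 4L)
  expect_equal(prof$pos, 2:(nchar(s) - 3))
  for (k in seq_len(nrow(prof))) {
    pent <- substr(s, k, k + 4)
    expect_equal(prof$MGW[k], tab$MGW[tab$pentamer == pent])
    expect_equal(prof$HelT[k], tab$HelT[tab$pentamer == pent])
  }
  # minimal length gives a single position
  expect_equal(nrow(predict_shape("ACGTA", tab)), 1L)
  expect_error(predict_shape("ACGT", tab), ">= 5")
  # N contaminates the overlapping pentamers only
  p2 <- predict_shape("ACGTNACGTACGT", tab)
  expect_true(all(is.na(p2$MGW[p2$pos %in% 2:6])))
  expect_true(all(!is.na(p2$MGW[p2$pos > 6])))
  # reverse-complement mirror (table is symmetric in all four features)
  s3 <- "ACGGTTACCGGATA"
  a <- predict_shape(s3, tab)
  b <- predict_shape(revcomp(s3), tab)
  expect_equal(b$MGW, rev(a$MGW))
  expect_equal(b$ProT, rev(a$ProT))
})

test_that("summarize_shape emits the 48 quantile/variance predictors", {
  tab <- make_shape_table(seed = 4)
  prof <- predict_shape(strrep("ACGT", 50), tab)
  s <- summarize_shape(prof)
  expect_equal(ncol(s), 48L)
  expect_equal(
    names(s)[1:12],
    c(paste0("MGW_q", seq(0, 100, 10)), "MGW_var")
  )
  # constant vector: all quantiles equal the constant, variance 0
  const <- tibble::tibble(
    pos = 1:10, MGW = 5, ProT = -3, Roll = 1, HelT = 34
  )
  sc <- summarize_shape(const)
  expect_true(all(sc[paste0("MGW_q", seq(0, 100, 10))] == 5))
  expect_equal(sc$MGW_var, 0)
  # 1..11 hits the closed form under linear-interpolation quantiles
  lin <- tibble::tibble(
    pos = 1:11, MGW = 1:11, ProT = 1:11, Roll = 1:11, HelT = 1:11
  )
  sl <- summarize_shape(lin)
  expect_equal(unlist(sl[paste0("MGW_q", seq(0, 100, 10))], use.names = FALSE), as.numeric(1:11))
  # population variance, not sample variance
  expect_equal(sl$MGW_var, mean((1:11 - 6)^2))
  # quantile vectors are monotone and bracket min/max
  rnd <- predict_shape(strrep("AACGGT", 40), tab)
  sr <- summarize_shape(rnd)
  q <- unlist(sr[paste0("ProT_q", seq(0, 100, 10))], use.names = FALSE)
  expect_true(!is.unsorted(q))
  expect_equal(q[1], min(rnd$ProT))
  expect_equal(q[11], max(rnd$ProT))
  expect_error(summarize_shape(const[0, ]), "non-missing")
})

test_that("shape_features blocks are strand-invariant for symmetric tables", {
  tab <- make_shape_table(seed = 6)
  g <- toy_genome()
  sites <- data.frame(chrom = "chr1", start = c(0, 100), end = c(60, 220))
  sf <- shape_features(sites, g, tab)
  expect_equal(dim(sf), c(2L, 48L))
  g_rc <- genome(c(chr1 = revcomp(g$seqs[[1]])))
  L <- genome_size(g)
  sites_rc <- data.frame(
    chrom = "chr1", start = L - sites$end, end = L - sites$start
  )
  sf_rc <- shape_features(sites_rc, g_rc, tab)
  expect_equal(as.data.frame(sf_rc), as.data.frame(sf))
})
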