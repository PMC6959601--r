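make_cm <- function(counts, n_ind = NULL) {
  counts <- as.matrix(counts)
  if (is.null(n_ind)) n_ind <- ncol(counts) / 2
  count_matrix(counts,
               condition = rep(c("induced", "vehicle"),
                               c(n_ind, ncol(counts) - n_ind)))
}

test_that("size factors follow median-of-ratios and agree with DESeq2", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2)
  expect_equal(unname(size_factors(m)), c(1, 1))
  m2 <- cbind(c(10, 20, 30), c(20, 40, 60))
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  # permutation equivariance
  expect_equal(unname(size_factors(m2[, 2:1])),
               unname(size_factors(m2))[2:1])
  expect_error(size_factors(cbind(c(0, 5), c(3, 0))), "all-nonzero")

  set.seed(61)
  m3 <- matrix(rnbinom(600, mu = 50, size = 5), ncol = 6)
  skip_if_not_installed("DESeq2")
  expect_equal(unname(size_factors(m3)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m3)),
               tolerance = 1e-10)
})

test_that("identical counts give log2FC 0 and p near 1", {
  set.seed(62)
  base <- matrix(rnbinom(400, mu = 100, size = 10), ncol = 4)
  cm <- make_cm(cbind(base, base), n_ind = 4)
  res <- test_region_differential(cm)
  expect_equal(res$log2FC, rep(0, 100))
  expect_equal(res$p, rep(1, 100))
})

test_that("swapping condition labels negates log2FC and swaps gained/lost", {
  set.seed(63)
  cnt <- matrix(rnbinom(800, mu = 80, size = 8), ncol = 8)
  cnt[1:10, 1:4] <- cnt[1:10, 1:4] * 4
  cm1 <- count_matrix(cnt, condition = rep(c("induced", "vehicle"), each = 4),
                      regions = peak_set("chr1", seq(0, 990, 10)[1:100],
                                         seq(0, 990, 10)[1:100] + 5))
  cm2 <- cm1
  cm2$samples$condition <- rev(cm1$samples$condition)
  r1 <- test_region_differential(cm1)
  r2 <- test_region_differential(cm2)
  expect_equal(r1$log2FC, -r2$log2FC, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  c1 <- classify_sites(r1)
  c2 <- classify_sites(r2)
  expect_identical(c1$gained$name, c2$lost$name)
  expect_identical(c1$lost$name, c2$gained$name)
})

test_that("a strong planted effect is detected reliably (4-fold, 2v2)", {
  set.seed(64)
  # 500 independent single-region experiments; libraries equal by design
  hits <- replicate(500, {
    cnt <- matrix(c(rnbinom(2, mu = 800, size = 20),
                    rnbinom(2, mu = 200, size = 20)), 1)
    cm <- make_cm(cnt, n_ind = 2)
    res <- test_region_differential(cm, sf = rep(1, 4))
    q <- bh_adjust(res$p)
    q[1] < 0.05 && res$log2FC[1] > 0
  })
  expect_gte(mean(hits), 0.95)
})

test_that("type-I error of the moderated t does not exceed nominal", {
  set.seed(65)
  cnt <- matrix(rnbinom(5000 * 8, mu = 100, size = 10), 5000)
  res <- test_region_differential(make_cm(cnt, n_ind = 4))
  # the fixed-prior moderation is conservative by construction; it must
  # never be anti-conservative
  expect_lte(mean(res$p < 0.05), 0.05 + 2.576 * sqrt(0.05 * 0.95 / 5000))
})

test_that("BH adjustment matches the hand step-up and handles edge cases", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(66)
  for (i in 1:50) {
    p <- runif(sample(1:80, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-14)
  }
})

test_that("gained/lost classification applies the FDR and sign rule", {
  rec <- data.frame(region_id = c("r1", "r2", "r3"),
                    log2FC = c(1, 3, -2), p = c(0.001, 0.2, 0.0005),
                    q = c(0.04, 0.20, 0.01))
  cls <- classify_sites(rec, alpha = 0.05)
  expect_identical(cls$records$direction, c("gained", "unchanged", "lost"))
})

test_that("count matrices round-trip through their TSV layout", {
  set.seed(67)
  regions <- peak_set("chr1", c(0, 100, 250), c(50, 180, 420))
  cm <- count_matrix(matrix(rpois(12, 40), 3), regions = regions,
                     condition = c("induced", "induced", "vehicle", "vehicle"))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_count_matrix(cm, f1, f2)
  back <- read_count_matrix(f1, f2)
  expect_equal(unname(back$counts), unname(cm$counts))
  expect_identical(back$samples$condition, cm$samples$condition)
  expect_equal(back$regions$start, regions$start)
})
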