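# focus/background sets built so overlap counts hit an exact 2x2 table:
# peaks at x*1000 of width 100; annotation covers the first `k` of them
grid_peaks <- function(n, offset = 0) {
  peak_set("chr1", offset + (seq_len(n) - 1) * 1000,
           offset + (seq_len(n) - 1) * 1000 + 100)
}

test_that("odds ratio, Woolf SE and exact p match hand values", {
  focus <- grid_peaks(4)
  background <- grid_peaks(4, offset = 100000)
  annot <- annotation_track(
    peak_set("chr1", c(0, 1000, 2000, 100000), c(100, 1100, 2100, 100100)),
    "rep")
  r <- odds_ratio_overlap(focus, annot, background)  # table (3,1,1,3)
  expect_equal(c(r$a, r$b, r$c, r$d), c(3, 1, 1, 3))
  expect_equal(r$or, 9)
  expect_equal(r$p, 34 / 70, tolerance = 1e-12)
  expect_equal(r$log_or_se, sqrt(1 / 3 + 1 + 1 + 1 / 3), tolerance = 1e-12)
  expect_false(r$corrected)
  # focus = background -> OR exactly 1
  r1 <- odds_ratio_overlap(focus, annot, focus)
  expect_equal(r1$or, 1)
  # zero cell -> Haldane-Anscombe correction, finite OR, flagged
  annot0 <- annotation_track(peak_set("chr1", 100000, 100100), "rep")
  r0 <- odds_ratio_overlap(focus, annot0, background)
  expect_equal(r0$a, 0)
  expect_true(r0$corrected)
  expect_true(is.finite(r0$or) && r0$or > 0)
  expect_error(odds_ratio_overlap(focus[0, ], annot, background), "non-empty")
})

test_that("Fisher exact p equals exhaustive enumeration on small tables", {
  for (a in 0:6) for (b in 0:6) for (c_ in 0:6) for (d in 0:6) {
    if ((a + b) == 0 || (c_ + d) == 0) next
    p_pkg <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
    expect_equal(p_pkg, min(1, oracle_fisher_p(a, b, c_, d)),
                 tolerance = 1e-10)
  }
})

test_that("windowed profiles reduce to raw odds ratios at peak width", {
  set.seed(81)
  focus <- grid_peaks(30)
  background <- grid_peaks(40, offset = 200000)
  keep <- sample(c(TRUE, FALSE), 70, replace = TRUE)
  allp <- rbind(as.data.frame(focus), as.data.frame(background))[keep, ]
  annot <- annotation_track(peak_set(allp$chrom, allp$start, allp$end), "rep")
  wp <- windowed_profile(focus, annot, windows = 100, background = background)
  raw <- odds_ratio_overlap(focus, annot, background)
  expect_equal(wp$or, raw$or)
  expect_equal(wp$p, raw$p)
  expect_error(windowed_profile(focus, annot, windows = c(100, 10),
                                background = background), "ascending")
  expect_error(windowed_profile(focus, annot, windows = -5,
                                background = background), "> 0")
})

test_that("local planted annotation gives larger OR at small windows", {
  set.seed(82)
  n <- 300
  pos <- sort(sample.int(2.9e6, n)) + 2000
  focus <- peak_set("chr1", pos - 50, pos + 50)
  bgpos <- sort(sample.int(2.9e6, 1500)) + 2000
  background <- peak_set("chr1", bgpos - 50, bgpos + 50)
  # annotation planted within 400 bp of every focus summit
  annot <- annotation_track(
    peak_set("chr1", pos + sample(100:400, n, TRUE), pos + 600), "near")
  wp <- windowed_profile(focus, annot, windows = c(1000, 100000),
                         background = background)
  expect_gt(wp$or[1], wp$or[2])
})

test_that("overlap fractions report exact and round-half-up percentages", {
  # the worked example: 139 of 503 sites at open chromatin -> prints 28%
  n <- 503
  peaks <- grid_peaks(n)
  open <- annotation_track(ps_subset(grid_peaks(n), seq_len(139)), "DNase_open")
  fr <- fraction_overlapping(peaks, open)
  expect_equal(fr$numerator, 139)
  expect_equal(fr$percent, 100 * 139 / 503, tolerance = 1e-12)
  expect_equal(fr$percent_int, 28)
  # disjoint and covering annotations
  expect_equal(fraction_overlapping(peaks,
    annotation_track(peak_set("chr2", 0, 10), "x"))$percent_int, 0)
  expect_equal(fraction_overlapping(peaks,
    annotation_track(peak_set("chr1", 0, 1e6), "x"))$percent_int, 100)
  # round-half-up at exactly .5
  fr2 <- fraction_overlapping(grid_peaks(8), annotation_track(
    ps_subset(grid_peaks(8), 1:1), "x"))
  expect_equal(fr2$percent_int, 13)  # 12.5 -> 13
})

test_that("cistrome overlap chi-squared matches the closed form", {
  univ <- grid_peaks(1000)
  A <- ps_subset(univ, 1:100)
  # joint 10 = expectation under independence -> statistic 0
  B0 <- ps_subset(univ, c(1:10, 101:190))
  r0 <- cistrome_overlap_test(A, B0, univ)
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p, 1)
  # joint 50 -> Pearson statistic 197.53
  B1 <- ps_subset(univ, c(1:50, 101:150))
  r1 <- cistrome_overlap_test(A, B1, univ)
  expect_equal(r1$statistic, 1000 * (50 * 850 - 50 * 50)^2 /
                 (100 * 900 * 100 * 900), tolerance = 1e-12)
  expect_equal(round(r1$statistic, 2), 197.53)
  expect_lt(r1$p, 1e-15)
  # agreement with the standard Pearson test, no continuity correction
  tb <- r1$table
  expect_equal(r1$statistic,
               unname(stats::chisq.test(tb, correct = FALSE)$statistic),
               tolerance = 1e-10)
  # identical sets maximize the statistic for fixed margins
  rAA <- cistrome_overlap_test(A, A, univ)
  expect_gt(rAA$statistic, r1$statistic)
  expect_error(cistrome_overlap_test(A, grid_peaks(5, offset = 5e6), univ),
               "universe")
  expect_error(cistrome_overlap_test(univ, A, univ), "degenerate")
})
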