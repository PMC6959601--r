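test_that("narrowPeak parsing honours summit offsets, midpoints and errors", {
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t100\t200\tp1\t0\t.\t5\t4\t3\t25",
               "chr1\t300\t400\tp2\t0\t.\t5\t4\t3\t-1"), f)
  ps <- read_narrowpeak(f)
  expect_equal(ps$start, c(100, 300))
  expect_equal(ps$summit, c(25, 50))  # -1 -> midpoint
  expect_equal(ps$score, c(5, 5))     # signalValue column

  writeLines("chr1\t100\t200\tp1\t0\t.", f)
  expect_equal(read_narrowpeak(f)$summit, 50)  # 6 columns -> midpoint

  writeLines(c("chr1\t100\t200\tp1\t0\t.\t5\t4\t3\t25",
               "chr1\t200\t100\tp2\t0\t.\t5\t4\t3\t10"), f)
  expect_error(read_narrowpeak(f), "line 2")
  writeLines("chr1\t100", f)
  expect_error(read_narrowpeak(f), "line 1")
  writeLines("chr1\t100\t200\tp1\t0\t.\t5\t4\t3\t25", f)
  expect_error(read_narrowpeak(f, layout = genome_layout("chr1", 50)),
               "beyond chromosome")
})

test_that("BED round-trip preserves coordinates, order and names exactly", {
  set.seed(11)
  f <- withr::local_tempfile(fileext = ".bed")
  for (i in 1:25) {
    ps <- random_peakset(sample(0:40, 1))
    write_bed(ps, f)
    back <- read_bed(f)
    expect_identical(back$chrom, ps$chrom)
    expect_identical(back$start, ps$start)
    expect_identical(back$end, ps$end)
    expect_identical(back$name, ps$name)
  }
  # empty set -> empty file
  write_bed(peak_set(character(0), numeric(0), numeric(0)), f)
  expect_identical(readLines(f), character(0))
  # two chroms -> chrom-major order in the file
  ps <- peak_set(c("chr2", "chr1"), c(5, 50), c(15, 80))
  write_bed(ps, f)
  expect_identical(sub("\t.*", "", readLines(f)), c("chr1", "chr2"))
  # narrowPeak round-trip keeps summits
  ps <- peak_set("chr1", c(10, 100), c(90, 200), summit = c(3, 77))
  fn <- withr::local_tempfile(fileext = ".narrowPeak")
  write_narrowpeak(ps, fn)
  expect_identical(read_narrowpeak(fn)$summit, c(3, 77))
})

test_that("merge_intervals merges bookended intervals and is idempotent", {
  m <- merge_intervals(peak_set("chr1", c(100, 150), c(200, 250)), gap = 0)
  expect_equal(c(m$start, m$end), c(100, 250))
  m <- merge_intervals(peak_set("chr1", c(100, 200), c(200, 300)), gap = 0)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(100, 300))
  m <- merge_intervals(peak_set("chr1", c(100, 210), c(200, 300)), gap = 5)
  expect_equal(nrow(m), 2)
  m <- merge_intervals(peak_set("chr1", c(100, 204), c(200, 300)), gap = 5)
  expect_equal(nrow(m), 1)
  set.seed(21)
  for (i in 1:10) {
    ps <- random_peakset(30)
    g <- sample(0:20, 1)
    once <- merge_intervals(ps, g)
    expect_identical(merge_intervals(once, g), once)
  }
})

test_that("consensus matches the per-base support oracle and the 3-of-4 rule", {
  r1 <- peak_set("chr1", 100, 200)
  r2 <- peak_set("chr1", 150, 250)
  r3 <- peak_set("chr1", 180, 220)
  r4 <- peak_set(character(0), numeric(0), numeric(0))
  cs <- consensus_peaks(list(r1, r2, r3, r4), 3)
  expect_equal(c(cs$start, cs$end), c(180, 200))
  # identical peak in all four replicates survives unchanged
  same <- peak_set("chr1", 500, 700)
  cs <- consensus_peaks(list(same, same, same, same), 3)
  expect_equal(c(cs$start, cs$end), c(500, 700))
  # present in only 2 of 4 -> excluded under the 3-of-4 rule
  cs <- consensus_peaks(list(r1, r1, r4, r4), 3)
  expect_equal(nrow(cs), 0)
  expect_error(consensus_peaks(list(r1, r2), 3), "min_support")

  set.seed(31)
  for (i in 1:30) {
    reps <- lapply(seq_len(sample(2:6, 1)), function(j) random_peakset(sample(1:15, 1)))
    k <- sample(seq_along(reps), 1)
    got <- consensus_peaks(reps, k)
    want <- oracle_consensus(reps, k)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got[, c("chrom", "start", "end")],
                   want[, c("chrom", "start", "end")],
                   ignore_attr = TRUE)
    }
    # permutation invariance in replicate order
    got2 <- consensus_peaks(rev(reps), k)
    expect_identical(got[, 1:3], got2[, 1:3])
  }
})

test_that("overlap membership uses half-open >=1 bp overlap and matches all-pairs", {
  q <- peak_set("chr1", 100, 200)
  expect_true(overlap_membership(q, list(t = peak_set("chr1", 199, 300)))[1, 1])
  expect_false(overlap_membership(q, list(t = peak_set("chr1", 200, 300)))[1, 1])
  set.seed(41)
  for (i in 1:10) {
    q <- random_peakset(50)
    tracks <- lapply(1:3, function(j) random_peakset(sample(1:30, 1)))
    names(tracks) <- paste0("t", 1:3)
    expect_identical(unname(overlap_membership(q, tracks)),
                     oracle_membership(q, tracks))
  }
})

test_that("TSS distances are strand-aware, tie-broken and match brute force", {
  tss <- tss_table(c("gA", "gB"), c("chr1", "chr1"), c(1000, 5000), c("+", "-"))
  pk <- peak_set("chr1", 1400, 1600, summit = 100)  # summit 1500
  expect_equal(tss_distance(pk, tss)$distance, 500)
  tssm <- tss_table("gA", "chr1", 1000, "-")
  expect_equal(tss_distance(pk, tssm)$distance, -500)
  # equidistant TSS -> smallest gene_id
  tie <- tss_table(c("gZ", "gA"), c("chr1", "chr1"), c(1400, 1600), c("+", "+"))
  expect_equal(tss_distance(pk, tie)$gene_id, "gA")
  expect_error(tss_distance(pk, tie[0, ]), "empty")

  set.seed(51)
  tss <- tss_table(sprintf("g%02d", 1:20), sample(c("chr1", "chr2"), 20, TRUE),
                   sample.int(9000, 20), sample(c("+", "-"), 20, TRUE))
  pk <- random_peakset(100)
  got <- tss_distance(pk, tss)
  want <- oracle_nearest_tss(pk, tss)
  expect_equal(got$gene_id, want$gene_id)
  expect_equal(got$distance, want$distance)
})

test_that("TSS distance bins classify promoter proximity", {
  expect_equal(classify_region(800), "promoter_<=1kb")
  expect_equal(classify_region(-2500), "promoter_2-3kb")
  expect_equal(classify_region(50000), "distal")
  expect_equal(classify_region(c(-1000, 1001, 3000, 3001)),
               c("promoter_<=1kb", "promoter_1-2kb", "promoter_2-3kb", "distal"))
})
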