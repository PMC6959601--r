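toy_ranked <- function() ranked_list(c("g1", "g2", "g3", "g4"), c(2, 1, -1, -2))

test_that("enrichment score reproduces hand and oracle values", {
  rk <- toy_ranked()
  expect_equal(enrichment_score(rk, c("g1", "g2"))$es, 1.0)
  # bottom gene: misses -1/3 each, then hit +1; extreme is -1
  expect_equal(enrichment_score(rk, "g4")$es, oracle_es(rk, "g4"))
  expect_equal(enrichment_score(rk, "g4")$es, -1.0)
  # reversing a symmetric list negates the ES
  rev_rk <- ranked_list(c("g4", "g3", "g2", "g1"), c(2, 1, -1, -2))
  expect_equal(enrichment_score(rev_rk, c("g1", "g2"))$es,
               -enrichment_score(rk, c("g1", "g2"))$es)
  expect_error(enrichment_score(rk, "zz"), "intersect")
  expect_error(enrichment_score(rk, c("g1", "g2", "g3", "g4")), "entire")
  # curve is returned for plotting and ends at 0
  res <- enrichment_score(rk, c("g1", "g2"), return_curve = TRUE)
  expect_equal(res$curve[length(res$curve)], 0, tolerance = 1e-12)
})

test_that("fast and naive ES agree on random instances to 1e-12", {
  set.seed(111)
  for (i in 1:300) {
    N <- sample(10:80, 1)
    genes <- sprintf("g%03d", 1:N)
    rk <- ranked_list(genes, round(rnorm(N), 3))
    m <- sample(1:(N - 1), 1)
    members <- sample(genes, m)
    w <- sample(c(0, 1, 2), 1)
    expect_equal(enrichment_score(rk, members, weight = w)$es,
                 oracle_es(rk, members, weight = w), tolerance = 1e-12)
  }
})

test_that("ranked lists sort by descending score with gene-id tie-break", {
  rk <- ranked_list(c("b", "a", "c"), c(1, 1, 2))
  expect_identical(names(rk), c("c", "a", "b"))
  expect_error(ranked_list(c("a", "a"), c(1, 2)), "duplicate")
})

test_that("permutation p matches exhaustive enumeration for tiny lists", {
  # N=4, |S|=1: the four possible sets give |ES| values; exact p follows
  rk <- toy_ranked()
  for (g in c("g1", "g4")) {
    obs <- enrichment_score(rk, g)$es
    all_es <- vapply(names(rk), function(x) enrichment_score(rk, x)$es,
                     numeric(1))
    same <- sign(all_es) == sign(obs)
    # large-n_perm limit of the add-one estimator is the combinatorial p
    exact_p <- sum(same & abs(all_es) >= abs(obs) - 1e-12) / sum(same)
    suppressWarnings({
      r <- permutation_test(rk, g, n_perm = 4000, seed = 5)
    })
    expect_equal(r$p_perm, exact_p, tolerance = 0.05)
  }
  # same seed -> identical result, different seed -> same ES
  suppressWarnings({
    r1 <- permutation_test(rk, "g1", n_perm = 500, seed = 9)
    r2 <- permutation_test(rk, "g1", n_perm = 500, seed = 9)
  })
  expect_identical(r1, r2)
})

test_that("permutation results separate planted signal from noise", {
  set.seed(112)
  N <- 400
  genes <- sprintf("g%03d", 1:N)
  score <- rnorm(N)
  sig <- sample(genes, 30)
  score[genes %in% sig] <- score[genes %in% sig] + 2.5
  rk <- ranked_list(genes, score)
  r <- permutation_test(rk, sig, n_perm = 2000, seed = 3)
  expect_gt(r$nes, 1)
  expect_lt(r$p_perm, 0.01)
  expect_true(all(r$leading_edge %in% sig))
  # leading edge genes sit at the top of the list for a positive ES
  expect_true(all(match(r$leading_edge, names(rk)) <= which.max(
    enrichment_score(rk, sig, return_curve = TRUE)$curve)))
})

test_that("ES agrees with the independent fgsea implementation", {
  skip_if_not_installed("fgsea")
  set.seed(113)
  N <- 200
  genes <- sprintf("g%03d", 1:N)
  stats <- sort(rnorm(N), decreasing = TRUE)
  names(stats) <- genes
  rk <- ranked_list(genes, stats)
  for (i in 1:20) {
    members <- sample(genes, sample(5:40, 1))
    es_pkg <- enrichment_score(rk, members)$es
    es_f <- fgsea::calcGseaStat(stats, selectedStats = sort(match(members, genes)),
                                gseaParam = 1, scoreType = "std")
    expect_equal(es_pkg, es_f, tolerance = 1e-10)
  }
})

test_that("ChIP gene sets apply the 10 kb summit-to-TSS rule", {
  tss <- tss_table(c("gA", "gB"), c("chr1", "chr1"), c(5000, 40000), c("+", "-"))
  pk <- peak_set("chr1", 5300, 5700, summit = 200)  # summit 5500, 500 bp away
  gs <- chip_gene_set(pk, tss)
  expect_identical(gs$members, "gA")
  far <- peak_set("chr1", 19800, 20200, summit = 200)  # 20000: 14.5kb/20kb away
  expect_length(chip_gene_set(far, tss)$members, 0)
  expect_length(chip_gene_set(pk[0, ], tss)$members, 0)
  # boundary: exactly 10 kb is included
  edge <- peak_set("chr1", 14800, 15200, summit = 200)  # summit 15000
  expect_identical(chip_gene_set(edge, tss)$members, "gA")
})

test_that("DE ranking scores sign(log2FC) * -log10(p) with stable ties", {
  de <- data.frame(gene = c("g1", "g2", "g3"), log2FC = c(2, 1, -3),
                   p = c(0.01, 0.01, 1e-6))
  rk <- de_ranked_list(de)
  expect_identical(names(rk), c("g1", "g2", "g3"))
  expect_equal(unname(as.numeric(rk)), c(2, 2, -6))
  expect_error(de_ranked_list(data.frame(gene = c("a", "a"),
                                         log2FC = 1, p = 0.5)), "duplicate")
  expect_error(de_ranked_list(data.frame(gene = "a", log2FC = 1, p = 0)),
               "\\(0, 1\\]")
  set.seed(114)
  de <- data.frame(gene = sprintf("g%03d", 1:100), log2FC = rnorm(100),
                   p = runif(100))
  rk <- de_ranked_list(de)
  sc <- sign(de$log2FC) * (-log10(de$p))
  expect_identical(names(rk), de$gene[order(-sc, de$gene)])
})

test_that("paired rankings are zero for identical pairs and antisymmetric", {
  set.seed(115)
  ng <- 150
  prim <- matrix(rnbinom(ng * 4, mu = 200, size = 10), ng,
                 dimnames = list(sprintf("g%03d", 1:ng), NULL))
  pc_same <- paired_counts(cbind(prim, prim),
                           pair = rep(paste0("P", 1:4), 2),
                           tissue = rep(c("primary", "metastasis"), each = 4))
  rk <- paired_ranking(pc_same, mode = "replicates")
  expect_true(all(as.numeric(rk) == 0))
  # swapping the tissue labels negates every score
  met <- matrix(rnbinom(ng * 4, mu = 200, size = 10), ng)
  pc <- paired_counts(cbind(prim, met),
                      pair = rep(paste0("P", 1:4), 2),
                      tissue = rep(c("primary", "metastasis"), each = 4))
  pc_sw <- paired_counts(cbind(prim, met),
                         pair = rep(paste0("P", 1:4), 2),
                         tissue = rep(c("metastasis", "primary"), each = 4))
  r1 <- paired_ranking(pc, mode = "replicates")
  r2 <- paired_ranking(pc_sw, mode = "replicates")
  expect_equal(as.numeric(r1[sort(names(r1))]),
               -as.numeric(r2[sort(names(r2))]), tolerance = 1e-10)
  # single-pair mode needs a valid target
  expect_error(paired_ranking(pc, mode = "single_pair", target_pair = "nope"),
               "absent")
  rs <- paired_ranking(pc, mode = "single_pair", target_pair = "P2")
  expect_length(rs, ng)
})

test_that("both directions of the paired analysis detect strong coupling", {
  cfg <- sim_config(seed = 116,
                    chrom_lengths = c(chr1 = 300000, chr2 = 200000),
                    n_sites = 450, n_genes = 200,
                    n_base_peaks = c(ELF5 = 150, FOXA1 = 160, ER = 120))
  set.seed(116)
  genes <- sprintf("g%04d", 1:200)
  sig <- sample(genes, 35)
  pp <- simulate_patient_pairs(cfg, sig, genes)
  gs <- gene_set(sig, "signature")
  # forward: one responsive patient against the signature
  rk1 <- paired_ranking(pp$pc, mode = "single_pair",
                        target_pair = pp$responsive[1])
  r1 <- permutation_test(rk1, gs, n_perm = 1000, seed = 1)
  expect_gt(r1$nes, 0)
  expect_lt(r1$p_perm, 0.05)
  # reversed: all pairs as replicates against the same signature
  rk2 <- paired_ranking(pp$pc, mode = "replicates")
  r2 <- permutation_test(rk2, gs, n_perm = 1000, seed = 2)
  expect_gt(r2$nes, 0)
  expect_lt(r2$p_perm, 0.05)
})

test_that("GMT and RNK files round-trip", {
  sets <- list(gene_set(c("a", "b", "c"), "s1"), gene_set("d", "s2"))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  back <- read_gmt(f)
  expect_identical(back[[1]]$members, c("a", "b", "c"))
  expect_identical(back[[2]]$name, "s2")
  rk <- toy_ranked()
  fr <- withr::local_tempfile(fileext = ".rnk")
  write_rnk(rk, fr)
  tab <- read.table(fr, sep = "\t")
  expect_identical(tab[[1]], names(rk))
})
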