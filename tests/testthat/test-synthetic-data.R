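# a scaled-down configuration for fast structural checks
small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed,
             chrom_lengths = c(chr1 = 300000, chr2 = 200000),
             n_sites = 450, n_genes = 120,
             n_base_peaks = c(ELF5 = 150, FOXA1 = 160, ER = 120), ...)
}

test_that("the generator is fully deterministic under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_all(small_cfg(seed = 5), d1)
  s2 <- simulate_all(small_cfg(seed = 5), d2)
  f1 <- setdiff(list.files(d1), "manifest.json")
  expect_identical(f1, setdiff(list.files(d2), "manifest.json"))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  simulate_all(small_cfg(seed = 6), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "genome.fa"))),
                         unname(tools::md5sum(file.path(d3, "genome.fa")))))
})

test_that("perfect reproducibility makes consensus recover base peaks exactly", {
  cfg <- small_cfg(seed = 7, replicate_reproducibility = 1, peak_jitter_sd = 0)
  gen <- simulate_genome(cfg)
  pk <- simulate_peaks(cfg, gen)
  reps <- pk$peaks$ELF5$vehicle
  expect_identical(reps[[1]]$start, reps[[2]]$start)
  cons <- consensus_peaks(reps, 3)
  expect_equal(nrow(cons), sum(gen$sites$ELF5))
  expect_identical(cons$start, reps[[1]]$start)
  expect_identical(cons$end, reps[[1]]$end)
})

test_that("consensus recall under partial reproducibility follows the binomial tail", {
  # rho = 0.5, 4 replicates, 3-of-4 rule: a base is covered by >= 3
  # replicates with P(Bin(4, .5) >= 3) = 0.3125
  cfg <- small_cfg(seed = 8, replicate_reproducibility = 0.5,
                   peak_jitter_sd = 0)
  gen <- simulate_genome(cfg)
  recalls <- vapply(1:4, function(k) {
    cfg <- small_cfg(seed = 8 + k, replicate_reproducibility = 0.5,
                     peak_jitter_sd = 0)
    pk <- simulate_peaks(cfg, gen)
    cons <- consensus_peaks(pk$peaks$ELF5$vehicle, 3)
    nrow(cons) / sum(gen$sites$ELF5)
  }, numeric(1))
  expect_equal(mean(recalls), pbinom(2, 4, 0.5, lower.tail = FALSE),
               tolerance = 0.05)
})

test_that("zero repeat density with background rate zero yields no repeats", {
  cfg <- small_cfg(seed = 9, repeat_density = 0, repeat_prob_background = 1e-9)
  gen <- simulate_genome(cfg)
  expect_lte(nrow(gen$tracks$MIR), 2)
})

test_that("planted repeats carry a scannable embedded ETS motif", {
  cfg <- small_cfg(seed = 10)
  gen <- simulate_genome(cfg)
  mir <- gen$tracks$MIR
  # site-linked repeats were named first, before coordinate sorting
  linked <- ps_subset(mir, mir$name %in%
                        paste0("MIR_", seq_len(sum(gen$sites$repeat_flag))))
  rate <- motif_presence_rate(linked, gen$genome, gen$pwms$ETS)
  expect_gte(rate$rate, 0.95)
})

test_that("all emitted files re-parse through the package's own readers", {
  d <- withr::local_tempdir()
  simulate_all(small_cfg(seed = 11), d)
  layout <- read_chrom_sizes(file.path(d, "chrom_sizes.tsv"))
  expect_s3_class(layout, "GenomeLayout")
  expect_silent(read_tss(file.path(d, "tss.bed"), layout = layout))
  expect_silent(read_narrowpeak(file.path(d, "ELF5_induced_rep1.narrowPeak"),
                                layout = layout))
  for (f in list.files(d, pattern = "^track_.*bed$")) {
    expect_silent(read_bed(file.path(d, f), layout = layout))
  }
  expect_silent(read_meme(file.path(d, "motifs.meme")))
  cm <- read_count_matrix(file.path(d, "counts.tsv"), file.path(d, "samples.tsv"))
  expect_s3_class(cm, "CountMatrix")
  pc <- read_paired_counts(file.path(d, "paired_counts.tsv"),
                           file.path(d, "paired_samples.tsv"))
  expect_identical(sort(unique(pc$samples$tissue)),
                   c("metastasis", "primary"))
  expect_silent(read_gmt(file.path(d, "signature.gmt")))
  mf <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_true(all(vapply(mf$files, function(x)
    file.exists(file.path(d, x$path)), logical(1))))
})

test_that("count simulation matches its negative-binomial moments", {
  cfg <- small_cfg(seed = 12, gained_fraction = 0, lost_fraction = 0)
  regions <- peak_set("chr1", (0:4999) * 50, (0:4999) * 50 + 40)
  truth <- data.frame(chrom = character(0), pos = numeric(0),
                      status = character(0))
  # near-Poisson limit: variance/mean -> 1
  cfg_p <- small_cfg(seed = 12, nb_dispersion = 1e-4)
  scp <- simulate_counts(cfg_p, regions, truth)
  sf <- exp(colMeans(log(scp$cm$counts)))
  norm <- sweep(scp$cm$counts, 2, sf / mean(sf), "/")
  vm <- mean(apply(norm, 1, var) / rowMeans(norm))
  expect_equal(vm, 1, tolerance = 0.1)
  # shipped dispersion: variance/mean ~= 1 + dispersion * mean
  scd <- simulate_counts(small_cfg(seed = 13), regions, truth)
  normd <- sweep(scd$cm$counts, 2, exp(colMeans(log(scd$cm$counts + 0.5))), "/")
  vmd <- mean(apply(normd, 1, var) / rowMeans(normd))
  expect_equal(vmd, 1 + 0.1 * 100, tolerance = 0.2 * 11)
})

test_that("expression coupling raises log2FC only at gained-site genes", {
  cfg <- small_cfg(seed = 14, gained_fraction = 0.3)
  gen <- simulate_genome(cfg)
  pk <- simulate_peaks(cfg, gen)
  de <- simulate_de(cfg, pk$truth, gen$tss)
  expect_gt(length(de$coupled_genes), 3)
  cpl <- de$de$gene %in% de$coupled_genes
  expect_gt(mean(de$de$log2FC[cpl]), mean(de$de$log2FC[!cpl]) + 0.8)
  # null coupling: p-values uniform
  cfg0 <- small_cfg(seed = 15, de_coupling = 0)
  gen0 <- simulate_genome(cfg0)
  pk0 <- simulate_peaks(cfg0, gen0)
  de0 <- simulate_de(cfg0, pk0$truth, gen0$tss)
  expect_gt(stats::ks.test(de0$de$p, "punif")$p.value, 0.01)
})

test_that("patient pairs plant the signature only in responsive metastases", {
  cfg <- small_cfg(seed = 16)
  genes <- sprintf("g%04d", 1:200)
  sig <- sample(genes, 30)
  pp <- simulate_patient_pairs(cfg, sig, genes)
  expect_length(pp$responsive, cfg$n_responsive_pairs)
  y <- log2(pp$pc$counts + 0.5)
  d <- sapply(unique(pp$pc$samples$pair), function(pr) {
    mi <- pp$pc$samples$pair == pr & pp$pc$samples$tissue == "metastasis"
    pi <- pp$pc$samples$pair == pr & pp$pc$samples$tissue == "primary"
    mean(y[genes %in% sig, mi] - y[genes %in% sig, pi])
  })
  resp <- names(d) %in% pp$responsive
  expect_gt(min(d[resp]), max(d[!resp]))
  expect_equal(mean(d[resp]), cfg$signature_effect, tolerance = 0.35)
})
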