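#' Configuration for the synthetic-data generator
#'
#' Defaults define the study conditions the whole test battery runs under:
#' a 2 Mb two-chromosome genome carrying ~2000 candidate TF-binding sites
#' on a jittered grid, three factors (an inducible ETS factor plus FOXA1-
#' and ER-like cistromes sharing sites with it), four replicates per
#' condition at realistic ChIP reproducibility, negative-binomial region
#' counts with a planted 2-fold binding gain at 10% of contrast-factor
#' sites, MIR-like repeats planted at a target odds ratio of 2 around the
#' inducible factor's sites, expression changes coupled to planted gains
#' within 10 kb, and a 7-patient matched primary/metastasis design with 3
#' responsive pairs (4-fold signature induction).
#'
#' @param seed master seed; every artifact derives its own stream from it.
#' @param chrom_lengths named bp lengths.
#' @param n_sites candidate binding sites genome-wide (the TFBS universe).
#' @param n_genes genes/TSS placed uniformly.
#' @param factors factor names; the first is the induced factor.
#' @param contrast_factor factor whose binding is contrasted
#'   induced/vehicle.
#' @param n_base_peaks named per-factor base-peak counts.
#' @param n_replicates replicates per factor/condition.
#' @param replicate_reproducibility probability a replicate recovers a base
#'   peak.
#' @param peak_jitter_sd bp SD of replicate boundary jitter.
#' @param peak_width bp width of base peaks.
#' @param gained_fraction,lost_fraction fractions of contrast-factor sites
#'   planted as gained / lost.
#' @param gained_log2_effect planted log2 fold change of gained (and, with
#'   opposite sign, lost) regions.
#' @param nb_mean,nb_dispersion negative-binomial mean and dispersion
#'   (var = mu + dispersion * mu^2) of region counts.
#' @param repeat_prob_background probability a non-focus site carries a
#'   repeat.
#' @param repeat_enrichment_or target odds ratio of repeat overlap at the
#'   induced factor's sites vs the site universe.
#' @param repeat_density per-Mb rate of additional unlinked background
#'   repeats.
#' @param repeat_width bp width of planted repeats.
#' @param motif_prob_gained,motif_prob_lost,motif_prob_other probability of
#'   an ETS motif instance at gained / lost / other non-focus sites (focus
#'   sites always carry one).
#' @param de_coupling mean log2FC planted at genes with a gained site
#'   within 10 kb of the TSS; `de_sd` is the per-gene SD.
#' @param de_sd see above.
#' @param n_patient_pairs,n_responsive_pairs matched-pair design.
#' @param signature_effect log2 fold change of signature genes in
#'   responsive metastases.
#' @param patient_nb_dispersion NB dispersion of patient counts.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(seed = 1,
                       chrom_lengths = c(chr1 = 1200000, chr2 = 800000),
                       n_sites = 2000,
                       n_genes = 400,
                       factors = c("ELF5", "FOXA1", "ER"),
                       contrast_factor = "FOXA1",
                       n_base_peaks = c(ELF5 = 600, FOXA1 = 700, ER = 500),
                       n_replicates = 4,
                       replicate_reproducibility = 0.85,
                       peak_jitter_sd = 15,
                       peak_width = 240,
                       gained_fraction = 0.1,
                       lost_fraction = 0.05,
                       gained_log2_effect = 1,
                       nb_mean = 100,
                       nb_dispersion = 0.1,
                       repeat_prob_background = 0.25,
                       repeat_enrichment_or = 2,
                       repeat_density = 50,
                       repeat_width = 180,
                       motif_prob_gained = 0.95,
                       motif_prob_lost = 0.2,
                       motif_prob_other = 0.5,
                       de_coupling = 1.5,
                       de_sd = 0.5,
                       n_patient_pairs = 7,
                       n_responsive_pairs = 3,
                       signature_effect = 2,
                       patient_nb_dispersion = 0.1) {
  cfg <- as.list(environment())
  stopifnot(cfg$replicate_reproducibility > 0,
            cfg$replicate_reproducibility <= 1,
            cfg$gained_fraction >= 0, cfg$gained_fraction < 1,
            cfg$lost_fraction >= 0,
            cfg$nb_dispersion > 0, cfg$nb_mean > 0,
            cfg$contrast_factor %in% cfg$factors,
            all(cfg$factors %in% names(cfg$n_base_peaks)))
  class(cfg) <- "SimConfig"
  cfg
}

# hierarchical sub-seed: one independent stream per artifact, all derived
# from the master seed; adding an artifact never perturbs another's draws
sub_seed <- function(seed, k) {
  (((seed %% 65521) * 32749) + k * 4099 + 17) %% 2147483647
}

# plant a DNA word into a character vector of bases at 1-based position
plant_word <- function(bases, word, at) {
  w <- strsplit(word, "")[[1]]
  idx <- at + seq_along(w) - 1
  ok <- idx >= 1 & idx <= length(bases)
  bases[idx[ok]] <- w[ok]
  bases
}

#' Simulate the genome: sequence, layout, TSS, sites and annotation tracks
#'
#' Background sequence is i.i.d. uniform ACGT. Candidate binding sites sit
#' on a jittered grid (guaranteeing >= 600 bp separation so peaks never
#' collide). The induced factor occupies a subset of sites; the other
#' factors share sites with it (co-binding structure). Repeat intervals,
#' each carrying an embedded ETS motif instance, are planted at the induced
#' factor's sites at odds `repeat_enrichment_or` times background odds,
#' plus unlinked repeats at `repeat_density`/Mb. Enhancer, super-enhancer,
#' HOT and DNase-open annotations are placed disjointly over sites. ETS /
#' forkhead / ERE motif words are planted at the corresponding factor
#' sites; gained sites of the contrast factor are motif-rich and lost sites
#' motif-poor.
#'
#' @param config a [sim_config()].
#' @return List: `genome` (DNAStringSet), `layout`, `tss`, `sites`
#'   (site-level ground-truth data.frame), `tracks` (named list of
#'   annotation PeakSets), `pwms`.
#' @export
simulate_genome <- function(config) {
  cfg <- config
  set.seed(sub_seed(cfg$seed, 1))
  lens <- cfg$chrom_lengths
  if (any(lens < 50000)) stop("simulate_genome: chromosomes too short", call. = FALSE)
  pwms <- builtin_pwms()

  # jittered site grid proportional to chromosome length
  n_per <- round(cfg$n_sites * lens / sum(lens))
  n_per[length(n_per)] <- cfg$n_sites - sum(n_per[-length(n_per)])
  slot <- lens / n_per
  if (any(slot < 900)) stop("simulate_genome: too many sites for genome size", call. = FALSE)
  sites <- do.call(rbind, lapply(seq_along(lens), function(i) {
    k <- n_per[i]
    pos <- floor((seq_len(k) - 1) * slot[i] + slot[i] * 0.3 +
                   stats::runif(k) * slot[i] * 0.4)
    data.frame(chrom = names(lens)[i], pos = pos, stringsAsFactors = FALSE)
  }))
  ns <- nrow(sites)
  sites$site_id <- paste0("site_", seq_len(ns))

  # factor occupancy: induced factor first, others share its sites
  focus <- cfg$factors[1]
  occ <- matrix(FALSE, ns, length(cfg$factors),
                dimnames = list(NULL, cfg$factors))
  focus_idx <- sort(sample.int(ns, cfg$n_base_peaks[[focus]]))
  occ[focus_idx, focus] <- TRUE
  for (f in cfg$factors[-1]) {
    nf <- cfg$n_base_peaks[[f]]
    n_shared <- round(0.6 * nf)
    shared <- sample(focus_idx, min(n_shared, length(focus_idx)))
    own <- sample(setdiff(seq_len(ns), shared), nf - length(shared))
    occ[c(shared, own), f] <- TRUE
  }
  for (f in cfg$factors) sites[[f]] <- occ[, f]

  # gained/lost status of contrast-factor sites (binding change is planted
  # quantitatively, in the count model; presence/absence stays symmetric)
  cf_idx <- which(sites[[cfg$contrast_factor]])
  n_g <- round(cfg$gained_fraction * length(cf_idx))
  n_l <- round(cfg$lost_fraction * length(cf_idx))
  st <- sample(cf_idx)
  sites$status <- "regular"
  sites$status[st[seq_len(n_g)]] <- "gained"
  sites$status[st[n_g + seq_len(n_l)]] <- "lost"

  # repeats: focus sites carry them at a rate solved so that the odds ratio
  # of focus vs the full site universe (which contains the focus, as in an
  # all-TFBS background) equals `repeat_enrichment_or`
  p0 <- cfg$repeat_prob_background
  f_share <- sum(sites[[focus]]) / ns
  or_vs_universe <- function(p1) {
    pbg <- f_share * p1 + (1 - f_share) * p0
    (p1 / (1 - p1)) / (pbg / (1 - pbg))
  }
  p1 <- stats::uniroot(function(p1) or_vs_universe(p1) - cfg$repeat_enrichment_or,
                       lower = p0, upper = 0.999)$root
  sites$repeat_flag <- stats::runif(ns) < ifelse(sites[[focus]], p1, p0)

  # ETS motif presence per site
  pm <- ifelse(sites[[focus]], 1,
        ifelse(sites$status == "gained", cfg$motif_prob_gained,
        ifelse(sites$status == "lost", cfg$motif_prob_lost,
               cfg$motif_prob_other)))
  sites$has_ets <- stats::runif(ns) < pm

  # background sequence with planted words
  ets_word <- pwm_consensus(pwms$ETS)
  fkh_word <- pwm_consensus(pwms$FKH)
  ere_word <- pwm_consensus(pwms$ERE)
  seqs <- lapply(seq_along(lens), function(i) {
    ch <- names(lens)[i]
    bases <- sample(c("A", "C", "G", "T"), lens[i], replace = TRUE)
    si <- sites[sites$chrom == ch, ]
    p <- si$pos + 1  # 1-based plant anchor per site
    plant_at <- c(
      (p - floor(nchar(ets_word) / 2))[si$has_ets],
      (p + 30)[si$FOXA1],
      (p - 45)[si$ER],
      (p + 55)[si$repeat_flag])  # repeats carry an embedded ETS instance
    plant_w <- c(rep(ets_word, sum(si$has_ets)),
                 rep(fkh_word, sum(si$FOXA1)),
                 rep(ere_word, sum(si$ER)),
                 rep(ets_word, sum(si$repeat_flag)))
    if (length(plant_at)) {
      letters_ <- strsplit(plant_w, "")
      idx <- unlist(mapply(function(a, l) a + seq_along(l) - 1, plant_at,
                           letters_, SIMPLIFY = FALSE))
      val <- unlist(letters_)
      ok <- idx >= 1 & idx <= length(bases)
      bases[idx[ok]] <- val[ok]
    }
    paste(bases, collapse = "")
  })
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- names(lens)
  layout <- genome_layout(names(lens), as.numeric(lens))

  # repeat track: site-linked repeats plus unlinked background repeats
  rw <- cfg$repeat_width
  rep_site <- sites[sites$repeat_flag, ]
  rep_df <- data.frame(chrom = rep_site$chrom,
                       start = pmax(0, rep_site$pos - floor(rw / 4)))
  n_bg <- round(cfg$repeat_density * sum(lens) / 1e6)
  bg_chrom <- sample(names(lens), n_bg, replace = TRUE, prob = lens / sum(lens))
  bg_start <- floor(stats::runif(n_bg) * (lens[bg_chrom] - rw))
  rep_df <- rbind(rep_df, data.frame(chrom = bg_chrom, start = bg_start))
  repeats <- annotation_track(
    peak_set(rep_df$chrom, rep_df$start, rep_df$start + rw,
             name = paste0("MIR_", seq_len(nrow(rep_df)))), "MIR")

  # disjoint context annotations over sites (each site gets at most one)
  ctx <- sample(c("enhancer", "super_enhancer", "HOT", "DNase_open", "none"),
                ns, replace = TRUE, prob = c(0.20, 0.06, 0.10, 0.25, 0.39))
  sites$context <- ctx
  mk_ctx <- function(lab, width) {
    s <- sites[sites$context == lab, ]
    annotation_track(peak_set(s$chrom, pmax(0, s$pos - width / 2),
                              s$pos + width / 2,
                              name = paste0(lab, "_", seq_len(nrow(s)))), lab)
  }
  tracks <- list(MIR = repeats,
                 enhancer = mk_ctx("enhancer", 500),
                 super_enhancer = mk_ctx("super_enhancer", 500),
                 HOT = mk_ctx("HOT", 500),
                 DNase_open = mk_ctx("DNase_open", 400))

  # an "external experiment" gained list overlapping the planted gains
  g_idx <- which(sites$status == "gained")
  ext <- c(g_idx[stats::runif(length(g_idx)) < 0.6],
           sample(setdiff(seq_len(ns), g_idx), max(1, length(g_idx))))
  es <- sites[sort(ext), ]
  tracks$external_gained <- annotation_track(
    peak_set(es$chrom, pmax(0, es$pos - 120), es$pos + 120,
             name = paste0("ext_", seq_len(nrow(es)))), "external_gained")

  # site universe track (all candidate sites as +/-120 bp intervals)
  tracks$tfbs_universe <- annotation_track(
    peak_set(sites$chrom, pmax(0, sites$pos - 120), sites$pos + 120,
             name = sites$site_id), "tfbs_universe")

  # TSS placed uniformly
  g_chrom <- sample(names(lens), cfg$n_genes, replace = TRUE,
                    prob = lens / sum(lens))
  g_pos <- floor(stats::runif(cfg$n_genes) * (lens[g_chrom] - 1))
  tss <- tss_table(sprintf("g%04d", seq_len(cfg$n_genes)), g_chrom, g_pos,
                   sample(c("+", "-"), cfg$n_genes, replace = TRUE))

  list(genome = genome, layout = layout, tss = tss, sites = sites,
       tracks = tracks, pwms = pwms)
}

#' Simulate replicate peak calls per factor and condition
#'
#' Each replicate keeps a base peak with probability
#' `replicate_reproducibility` and jitters its boundaries by
#' `N(0, peak_jitter_sd)`; summits stay at the planted site position.
#' Binding gains/losses do not alter presence/absence (they live in the
#' count model), so both conditions share the same reproducibility process.
#'
#' @param config a [sim_config()].
#' @param gen output of [simulate_genome()].
#' @return List: `peaks` (nested list `[[factor]][[condition]][[replicate]]`
#'   of PeakSets), `truth` (site-level ground truth).
#' @export
simulate_peaks <- function(config, gen) {
  cfg <- config
  set.seed(sub_seed(cfg$seed, 2))
  sites <- gen$sites
  half <- floor(cfg$peak_width / 2)
  out <- list()
  for (f in cfg$factors) {
    si <- sites[sites[[f]], ]
    if (!nrow(si)) stop("simulate_peaks: factor ", f, " has no sites", call. = FALSE)
    out[[f]] <- list()
    for (cond in c("vehicle", "induced")) {
      reps <- list()
      for (r in seq_len(cfg$n_replicates)) {
        keep <- stats::runif(nrow(si)) < cfg$replicate_reproducibility
        sk <- si[keep, , drop = FALSE]
        jit <- function(n) round(stats::rnorm(n, 0, cfg$peak_jitter_sd))
        start <- pmax(0, sk$pos - half + jit(nrow(sk)))
        end <- pmax(start + 1, sk$pos + half + jit(nrow(sk)))
        # keep the summit inside the (jittered) interval
        summit <- pmin(pmax(sk$pos - start, 0), end - start - 1)
        reps[[r]] <- peak_set(sk$chrom, start, end, name = sk$site_id,
                              score = round(stats::runif(nrow(sk), 50, 500), 1),
                              summit = summit,
                              set_name = sprintf("%s_%s_rep%d", f, cond, r))
      }
      out[[f]][[cond]] <- reps
    }
  }
  list(peaks = out, truth = sites)
}

#' Simulate the region x sample count matrix with planted binding changes
#'
#' Counts are negative binomial, `var = mu + dispersion * mu^2`, around
#' `nb_mean` times a per-sample library factor. Regions overlapping a
#' planted gained site get mean `x 2^gained_log2_effect` in induced
#' samples; lost regions the reciprocal.
#'
#' @param config a [sim_config()].
#' @param consensus a [peak_set()] of regions to count over.
#' @param truth site-level truth from [simulate_peaks()].
#' @return List: `cm` (a [count_matrix()]), `region_truth` (data.frame
#'   region_id, status).
#' @export
simulate_counts <- function(config, consensus, truth) {
  cfg <- config
  set.seed(sub_seed(cfg$seed, 3))
  nreg <- nrow(consensus)
  status <- rep("regular", nreg)
  for (stt in c("gained", "lost")) {
    ts <- truth[truth$status == stt, ]
    if (nrow(ts)) {
      tgr <- GenomicRanges::GRanges(ts$chrom,
                                    IRanges::IRanges(ts$pos + 1, ts$pos + 1))
      hit <- GenomicRanges::countOverlaps(ps_granges(consensus), tgr) > 0
      status[hit] <- stt
    }
  }
  n <- cfg$n_replicates
  sfs <- exp(stats::rnorm(2 * n, 0, 0.1))
  cond <- rep(c("induced", "vehicle"), each = n)
  eff <- ifelse(status == "gained", cfg$gained_log2_effect,
                ifelse(status == "lost", -cfg$gained_log2_effect, 0))
  mu <- matrix(cfg$nb_mean, nreg, 2 * n)
  mu[, cond == "induced"] <- cfg$nb_mean * 2^eff
  mu <- sweep(mu, 2, sfs, "*")
  cnt <- matrix(stats::rnbinom(nreg * 2 * n, mu = mu, size = 1 / cfg$nb_dispersion),
                nreg, 2 * n)
  rownames(cnt) <- consensus$name
  colnames(cnt) <- paste0(cond, "_", rep(seq_len(n), 2))
  cm <- count_matrix(cnt, regions = consensus, condition = cond,
                     replicate = rep(seq_len(n), 2))
  list(cm = cm,
       region_truth = data.frame(region_id = consensus$name, status = status,
                                 stringsAsFactors = FALSE))
}

#' Simulate a differential-expression table coupled to planted gains
#'
#' Genes with a planted gained site within 10 kb of their TSS draw
#' `log2FC ~ N(de_coupling, de_sd^2)`, others `N(0, de_sd^2)`; the p-value
#' is the two-sided normal tail of `log2FC / de_sd`, so it is uniform for
#' null genes and consistent with the effect size for coupled ones.
#'
#' @param config a [sim_config()].
#' @param truth site-level truth.
#' @param tss the TSS table.
#' @return List: `de` (data.frame gene, log2FC, p, FDR), `coupled_genes`.
#' @export
simulate_de <- function(config, truth, tss) {
  cfg <- config
  set.seed(sub_seed(cfg$seed, 4))
  gsite <- truth[truth$status == "gained", ]
  coupled <- vapply(seq_len(nrow(tss)), function(i) {
    any(gsite$chrom == tss$chrom[i] & abs(gsite$pos - tss$position[i]) <= 10000)
  }, logical(1))
  mu <- ifelse(coupled, cfg$de_coupling, 0)
  lfc <- stats::rnorm(nrow(tss), mu, cfg$de_sd)
  p <- 2 * stats::pnorm(-abs(lfc) / cfg$de_sd)
  p <- pmax(p, 1e-300)
  de <- data.frame(gene = tss$gene_id, log2FC = lfc, p = p,
                   FDR = bh_adjust(p), stringsAsFactors = FALSE)
  list(de = de, coupled_genes = tss$gene_id[coupled])
}

#' Simulate matched primary/metastasis patient pairs
#'
#' Gene baseline means are gamma-distributed; counts are negative binomial
#' with per-sample library factors. In responsive pairs the signature genes
#' (the planted coupled genes) get mean `x 2^signature_effect` in the
#' metastasis sample only.
#'
#' @param config a [sim_config()].
#' @param signature_genes character vector of signature gene ids.
#' @param genes all gene ids.
#' @return List: `pc` (a [paired_counts()]), `responsive` (pair ids).
#' @export
simulate_patient_pairs <- function(config, signature_genes, genes) {
  cfg <- config
  if (cfg$n_patient_pairs < 2) stop("simulate_patient_pairs: need >= 2 pairs",
                                    call. = FALSE)
  set.seed(sub_seed(cfg$seed, 5))
  ng <- length(genes)
  base <- stats::rgamma(ng, shape = 2, scale = 100)
  pairs <- sprintf("P%d", seq_len(cfg$n_patient_pairs))
  responsive <- sample(pairs, cfg$n_responsive_pairs)
  sig <- genes %in% signature_genes
  cols <- list()
  meta <- list()
  for (pr in pairs) {
    for (tis in c("primary", "metastasis")) {
      sf <- exp(stats::rnorm(1, 0, 0.1))
      mu <- base * sf
      if (tis == "metastasis" && pr %in% responsive) {
        mu[sig] <- mu[sig] * 2^cfg$signature_effect
      }
      cols[[paste0(pr, "_", tis)]] <-
        stats::rnbinom(ng, mu = mu, size = 1 / cfg$patient_nb_dispersion)
      meta[[paste0(pr, "_", tis)]] <- c(pr, tis)
    }
  }
  cnt <- do.call(cbind, cols)
  rownames(cnt) <- genes
  md <- do.call(rbind, meta)
  pc <- paired_counts(cnt, pair = md[, 1], tissue = md[, 2])
  list(pc = pc, responsive = sort(responsive))
}

#' Generate and write every synthetic input, with ground-truth sidecars
#'
#' Runs [simulate_genome()], [simulate_peaks()], consensus over the
#' contrast factor, [simulate_counts()], [simulate_de()] and
#' [simulate_patient_pairs()], writes every artifact in its standard
#' on-disk format under `out_dir` (FASTA, chrom sizes, TSS BED, annotation
#' BEDs, narrowPeaks, count/DE/paired TSVs, signature GMT, ground-truth
#' TSVs) and a `manifest.json` listing all files with md5 checksums.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param min_support consensus support threshold (default 3, of the
#'   configured 4 replicates).
#' @return Invisibly, a list with all in-memory objects plus `manifest`.
#' @export
simulate_all <- function(config, out_dir, min_support = 3) {
  cfg <- config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)

  gen <- simulate_genome(cfg)
  Biostrings::writeXStringSet(gen$genome, p("genome.fa"))
  write_chrom_sizes(gen$layout, p("chrom_sizes.tsv"))
  write_tss(gen$tss, p("tss.bed"))
  write_meme(gen$pwms, p("motifs.meme"))
  for (nm in names(gen$tracks)) {
    write_bed(gen$tracks[[nm]], p(paste0("track_", nm, ".bed")))
  }

  pk <- simulate_peaks(cfg, gen)
  for (f in cfg$factors) {
    for (cond in names(pk$peaks[[f]])) {
      for (r in seq_along(pk$peaks[[f]][[cond]])) {
        write_narrowpeak(pk$peaks[[f]][[cond]][[r]],
                         p(sprintf("%s_%s_rep%d.narrowPeak", f, cond, r)))
      }
    }
  }
  utils::write.table(pk$truth, p("truth_sites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  cfp <- pk$peaks[[cfg$contrast_factor]]
  cons_veh <- consensus_peaks(cfp$vehicle, min_support)
  cons_ind <- consensus_peaks(cfp$induced, min_support)
  cons <- merge_intervals(peak_set(
    c(cons_veh$chrom, cons_ind$chrom),
    c(cons_veh$start, cons_ind$start),
    c(cons_veh$end, cons_ind$end),
    set_name = paste0(cfg$contrast_factor, "_consensus")))
  write_bed(cons, p("consensus_contrast.bed"))

  sc <- simulate_counts(cfg, cons, pk$truth)
  write_count_matrix(sc$cm, p("counts.tsv"), p("samples.tsv"))
  utils::write.table(sc$region_truth, p("truth_regions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  de <- simulate_de(cfg, pk$truth, gen$tss)
  utils::write.table(de$de, p("de_table.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(de$coupled_genes, p("truth_coupled_genes.txt"))
  write_gmt(gene_set(de$coupled_genes, name = "planted_signature"),
            p("signature.gmt"))

  pp <- simulate_patient_pairs(cfg, de$coupled_genes, gen$tss$gene_id)
  write_paired_counts(pp$pc, p("paired_counts.tsv"), p("paired_samples.tsv"))
  writeLines(pp$responsive, p("truth_responsive_pairs.txt"))

  files <- sort(list.files(out_dir, recursive = TRUE))
  files <- setdiff(files, "manifest.json")
  manifest <- list(seed = cfg$seed,
                   files = lapply(files, function(f) {
                     list(path = f,
                          md5 = unname(tools::md5sum(file.path(out_dir, f))))
                   }))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(config = cfg, gen = gen, peaks = pk, consensus = cons,
                 counts = sc, de = de, patients = pp, manifest = manifest))
}
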