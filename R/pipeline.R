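#' Pipeline configuration
#'
#' Paths to every input (in the layout written by [simulate_all()], or
#' assembled by hand) plus the analysis thresholds. Defaults mirror the
#' decision points of the underlying study design: consensus 3-of-4
#' replicates, FDR 0.05, |FC| 1.5 for differentially expressed genes, the
#' 10 kb peak-to-gene rule, and 1e5 permutations.
#'
#' @param input_dir directory holding the inputs.
#' @param factors factor names with replicate narrowPeak files present.
#' @param contrast_factor factor tested for differential binding.
#' @param n_replicates replicates per factor/condition.
#' @param min_support consensus support threshold.
#' @param alpha FDR threshold for gained/lost calls and DE genes.
#' @param fc fold-change threshold for DE gene selection.
#' @param tss_max_distance bp for ChIP-to-gene assignment.
#' @param n_perm permutations for rank enrichment.
#' @param seed seed for permutation streams.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(input_dir,
                            factors = c("ELF5", "FOXA1", "ER"),
                            contrast_factor = "FOXA1",
                            n_replicates = 4,
                            min_support = 3,
                            alpha = 0.05,
                            fc = 1.5,
                            tss_max_distance = 10000,
                            n_perm = 1e5,
                            seed = 1) {
  stopifnot(alpha > 0, alpha < 1)
  cfg <- as.list(environment())
  class(cfg) <- "PipelineConfig"
  cfg
}

pipeline_inputs <- function(cfg) {
  p <- function(...) file.path(cfg$input_dir, ...)
  peaks <- unlist(lapply(cfg$factors, function(f) {
    lapply(c("vehicle", "induced"), function(cond) {
      vapply(seq_len(cfg$n_replicates),
             function(r) p(sprintf("%s_%s_rep%d.narrowPeak", f, cond, r)), "")
    })
  }))
  c(peaks,
    p("chrom_sizes.tsv"), p("genome.fa"), p("tss.bed"), p("motifs.meme"),
    p("counts.tsv"), p("samples.tsv"), p("de_table.tsv"),
    p("paired_counts.tsv"), p("paired_samples.tsv"), p("signature.gmt"),
    p("track_MIR.bed"), p("track_DNase_open.bed"), p("track_enhancer.bed"),
    p("track_super_enhancer.bed"), p("track_HOT.bed"),
    p("track_external_gained.bed"), p("track_tfbs_universe.bed"))
}

#' Run the full cistrome-modulation pipeline
#'
#' Stage order: replicate consensus -> differential binding (gained/lost at
#' FDR `alpha`) -> motif centrality and presence -> genomic-context odds
#' ratios, open-chromatin fraction and external-cistrome chi-squared ->
#' co-binding combinations -> rank enrichment (binding-coupled expression
#' and patient pairs). All inputs are validated before any stage runs;
#' per-stage tables are written under `out_dir` along with a versioned
#' `summary.json` and a machine-parsable log (one event per line).
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory.
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(cfg, out_dir) {
  need <- pipeline_inputs(cfg)
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    stop("run_pipeline: missing input(s): ",
         paste(utils::head(missing, 4), collapse = ", "), call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "pipeline.log")
  log_event <- function(stage, msg) {
    cat(sprintf("%s\tINFO\t%s\t%s\n",
                format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage, msg),
        file = logfile, append = TRUE)
  }
  p_in <- function(...) file.path(cfg$input_dir, ...)
  p_out <- function(...) file.path(out_dir, ...)
  log_event("init", sprintf("seed=%d min_support=%d alpha=%g fc=%g tss=%d n_perm=%d",
                            cfg$seed, cfg$min_support, cfg$alpha, cfg$fc,
                            cfg$tss_max_distance, as.integer(cfg$n_perm)))
  layout <- read_chrom_sizes(p_in("chrom_sizes.tsv"))
  tss <- read_tss(p_in("tss.bed"), layout = layout)
  summary <- list(schema_version = "1.0",
                  parameters = list(min_support = cfg$min_support,
                                    n_replicates = cfg$n_replicates,
                                    fdr_alpha = cfg$alpha,
                                    fc_threshold = cfg$fc,
                                    tss_max_distance = cfg$tss_max_distance,
                                    n_perm = cfg$n_perm,
                                    seed = cfg$seed))

  # stage 1: replicate consensus per factor/condition
  consensus <- list()
  for (f in cfg$factors) {
    for (cond in c("vehicle", "induced")) {
      reps <- lapply(seq_len(cfg$n_replicates), function(r) {
        read_narrowpeak(p_in(sprintf("%s_%s_rep%d.narrowPeak", f, cond, r)),
                        layout = layout)
      })
      cs <- consensus_peaks(reps, cfg$min_support,
                            set_name = paste0(f, "_", cond))
      consensus[[paste0(f, "_", cond)]] <- cs
      write_bed(cs, p_out(sprintf("consensus_%s_%s.bed", f, cond)))
    }
  }
  summary$consensus <- lapply(consensus, nrow)
  log_event("consensus", paste(names(summary$consensus),
                               unlist(summary$consensus), collapse = " "))

  # stage 2: differential binding on the contrast factor's regions
  cm <- read_count_matrix(p_in("counts.tsv"), p_in("samples.tsv"))
  records <- test_region_differential(cm)
  cls <- classify_sites(records, alpha = cfg$alpha)
  utils::write.table(cls$records, p_out("diffbind_records.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_bed(cls$gained, p_out("gained.bed"))
  write_bed(cls$lost, p_out("lost.bed"))
  summary$differential <- list(n_regions = nrow(cls$records),
                               n_gained = nrow(cls$gained),
                               n_lost = nrow(cls$lost))
  log_event("diffbind", sprintf("regions=%d gained=%d lost=%d",
                                nrow(cls$records), nrow(cls$gained),
                                nrow(cls$lost)))

  # stage 3: motif centrality around the induced factor's summits, and
  # motif presence at gained vs lost sites
  genome <- load_genome(p_in("genome.fa"))
  pwms <- read_meme(p_in("motifs.meme"))
  focus <- consensus[[paste0(cfg$factors[1], "_induced")]]
  prof <- positional_distribution(focus, genome, pwms)
  utils::write.table(prof, p_out("motif_centrality.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pres <- list()
  for (set in c("gained", "lost")) {
    ps <- cls[[set]]
    pres[[set]] <- if (nrow(ps)) {
      motif_presence_rate(ps, genome, pwms[[1]])
    } else list(numerator = 0, denominator = 0, rate = NA_real_)
  }
  summary$motif <- list(centrality_mass = sum(prof$mass),
                        presence_gained = pres$gained$rate,
                        presence_lost = pres$lost$rate)
  log_event("motif", sprintf("mass=%.3f gained_rate=%s lost_rate=%s",
                             sum(prof$mass), format(pres$gained$rate),
                             format(pres$lost$rate)))

  # stage 4: genomic-context enrichment
  universe <- read_bed(p_in("track_tfbs_universe.bed"), layout = layout)
  mir <- annotation_track(read_bed(p_in("track_MIR.bed"), layout = layout), "MIR")
  open <- annotation_track(read_bed(p_in("track_DNase_open.bed"), layout = layout),
                           "DNase_open")
  ext <- read_bed(p_in("track_external_gained.bed"), layout = layout)
  or_mir <- odds_ratio_overlap(focus, mir, universe)
  write_odds_ratios(list(or_mir), p_out("context_or.tsv"))
  frac_open <- if (nrow(cls$gained)) {
    fraction_overlapping(cls$gained, open)
  } else list(numerator = 0, denominator = 0, percent = NA_real_,
              percent_int = NA_real_)
  chi <- tryCatch(cistrome_overlap_test(cls$gained, ext, universe),
                  error = function(e) list(statistic = NA_real_, p = NA_real_))
  summary$context <- list(mir_or = or_mir$or, mir_p = or_mir$p,
                          open_fraction_pct = frac_open$percent_int,
                          external_chisq = chi$statistic,
                          external_chisq_p = chi$p)
  log_event("context", sprintf("mir_or=%.3f open_pct=%s chisq=%s",
                               or_mir$or, format(frac_open$percent_int),
                               format(chi$statistic)))

  # stage 5: co-binding combinations over the site universe
  tracks <- lapply(cfg$factors, function(f) consensus[[paste0(f, "_induced")]])
  names(tracks) <- cfg$factors
  memb <- overlap_membership(universe, tracks)
  enh <- read_bed(p_in("track_enhancer.bed"), layout = layout)
  se <- read_bed(p_in("track_super_enhancer.bed"), layout = layout)
  de_tab <- utils::read.table(p_in("de_table.tsv"), sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  de_genes <- de_tab$gene[de_tab$FDR < cfg$alpha &
                            abs(de_tab$log2FC) > log2(cfg$fc)]
  de_tss <- tss[tss$gene_id %in% de_genes, , drop = FALSE]
  near_de <- if (nrow(de_tss)) {
    td <- tss_distance(universe, de_tss)
    !is.na(td$distance) & abs(td$distance) <= cfg$tss_max_distance
  } else rep(FALSE, nrow(universe))
  klass <- ifelse(near_de, "DE_promoter",
           ifelse(overlap_membership(universe, list(se = se))[, 1], "super_enhancer",
           ifelse(overlap_membership(universe, list(enh = enh))[, 1], "enhancer",
                  "other")))
  bm <- binding_matrix(memb, class = klass, loci = universe)
  write_binding_matrix(bm, p_out("binding_matrix.tsv"))
  combos <- lapply(unique(klass), function(k) {
    cbind(class = k, combination_counts_by_class(bm, k))
  })
  combos <- do.call(rbind, combos)
  utils::write.table(combos, p_out("cobinding_combinations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cof <- tryCatch(select_cofactors(bm, cfg$factors[1]),
                  error = function(e) numeric(0))
  summary$cobinding <- list(n_loci = nrow(universe),
                            cofactors = names(cof))
  log_event("cobind", sprintf("loci=%d cofactors=%s", nrow(universe),
                              paste(names(cof), collapse = "+")))

  # stage 6: rank enrichment (ChIP-coupled expression, patient pairs)
  ranked <- de_ranked_list(de_tab)
  gained_set <- chip_gene_set(cls$gained, tss,
                              max_distance = cfg$tss_max_distance,
                              name = "gained_chip")
  gsea <- if (length(gained_set$members) &&
              any(names(ranked) %in% gained_set$members)) {
    enrichment_batch(ranked, list(gained_set), n_perm = cfg$n_perm,
                     seed = cfg$seed)
  } else NULL
  if (!is.null(gsea)) {
    utils::write.table(gsea, p_out("gsea_results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  pc <- read_paired_counts(p_in("paired_counts.tsv"), p_in("paired_samples.tsv"))
  signature <- read_gmt(p_in("signature.gmt"))[[1]]
  pp <- patient_pair_enrichment(pc, signature, n_perm = cfg$n_perm,
                                seed = cfg$seed)
  utils::write.table(pp, p_out("patient_pair_enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summary$enrichment <- list(
    gained_set_size = length(gained_set$members),
    nes = if (!is.null(gsea)) gsea$nes[1] else NA_real_,
    padj = if (!is.null(gsea)) gsea$padj[1] else NA_real_,
    significant_pairs = pp$pair[pp$padj < cfg$alpha])
  log_event("gsea", sprintf("set=%d nes=%s pairs=%s",
                            length(gained_set$members),
                            format(summary$enrichment$nes),
                            paste(summary$enrichment$significant_pairs,
                                  collapse = ",")))

  jsonlite::write_json(summary, p_out("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  log_event("done", "ok")
  invisible(summary)
}
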