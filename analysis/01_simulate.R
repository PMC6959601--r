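#!/usr/bin/env Rscript
# Stage 1 - generate the synthetic study data.
#
# Builds the full input bundle under data_sim/: a 2 Mb genome whose candidate
# TF-binding sites carry planted ETS/forkhead/ERE motifs, MIR-like repeats at
# 2x odds around the induced factor's sites, disjoint enhancer / super
# enhancer / HOT / DNase annotations, four replicate narrowPeak calls per
# factor and condition at 85% reproducibility, region counts with a planted
# 2-fold binding gain at 10% of contrast-factor sites, a coupled DE table,
# and a 7-patient matched primary/metastasis design with 3 responsive pairs.
# Ground-truth sidecars (truth_*.tsv) make every later stage scorable.

suppressMessages(library(cistromeShift))

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1

out_dir <- "data_sim"
cfg <- sim_config(seed = seed)
sim <- simulate_all(cfg, out_dir)

cat(sprintf("simulated %d candidate sites on %d chromosomes (seed %d)\n",
            nrow(sim$gen$sites), length(cfg$chrom_lengths), seed))
cat(sprintf("planted: %d gained / %d lost %s sites; %d repeat-linked sites; %d coupled genes\n",
            sum(sim$peaks$truth$status == "gained"),
            sum(sim$peaks$truth$status == "lost"),
            cfg$contrast_factor,
            sum(sim$peaks$truth$repeat_flag),
            length(sim$de$coupled_genes)))
cat(sprintf("%d files written to %s (see manifest.json)\n",
            length(sim$manifest$files), out_dir))
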