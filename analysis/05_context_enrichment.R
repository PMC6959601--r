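#!/usr/bin/env Rscript
# Stage 5 - genomic-context enrichment.
#
# Quantifies repeat (MIR) enrichment of the induced factor's cistrome as an
# odds ratio against the all-sites universe, profiles it over widening
# windows, reports the open-chromatin fraction of gained sites, and tests
# the overlap between the gained sites and an external gained cistrome by
# Pearson chi-squared over the universe. Writes results/context_*.tsv.

suppressMessages(library(cistromeShift))
dir.create("results", showWarnings = FALSE)

layout <- read_chrom_sizes("data_sim/chrom_sizes.tsv")
universe <- read_bed("data_sim/track_tfbs_universe.bed", layout = layout)
mir <- annotation_track(read_bed("data_sim/track_MIR.bed", layout = layout), "MIR")
open <- annotation_track(read_bed("data_sim/track_DNase_open.bed",
                                  layout = layout), "DNase_open")
ext <- read_bed("data_sim/track_external_gained.bed", layout = layout)

reps <- lapply(1:4, function(r) {
  read_narrowpeak(sprintf("data_sim/ELF5_induced_rep%d.narrowPeak", r),
                  layout = layout)
})
focus <- consensus_peaks(reps, 3)

or_mir <- odds_ratio_overlap(focus, mir, universe)
print(or_mir)
write_odds_ratios(list(or_mir), "results/context_or.tsv")

wp <- windowed_profile(focus, mir, windows = c(500, 2000, 10000, 50000),
                       background = universe)
write_odds_ratios(wp, "results/context_windowed.tsv")
cat("windowed MIR odds ratios (enrichment is local to the sites):\n")
print(wp[, c("window", "or", "p")])

gained <- read_bed("results/gained.bed", layout = layout)
if (nrow(gained)) {
  fr <- fraction_overlapping(gained, open)
  cat(sprintf("gained sites at open chromatin: %d of %d (%d%%)\n",
              fr$numerator, fr$denominator, fr$percent_int))
}

# external-cistrome overlap on the planted gains (robust to low call counts)
sites <- read.table("data_sim/truth_sites.tsv", header = TRUE, sep = "\t")
gs <- sites[sites$status == "gained", ]
gained_planted <- peak_set(gs$chrom, pmax(0, gs$pos - 120), gs$pos + 120)
chi <- cistrome_overlap_test(gained_planted, ext, universe)
cat(sprintf("planted gains vs external gained cistrome: chi-squared %.1f, p %.3g\n",
            chi$statistic, chi$p))
write.table(data.frame(statistic = chi$statistic, p = chi$p, n = chi$n),
            "results/context_external_overlap.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
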