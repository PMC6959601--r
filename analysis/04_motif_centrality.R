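#!/usr/bin/env Rscript
# Stage 4 - motif positional centrality and presence at gained/lost sites.
#
# Scans the genome under the induced factor's consensus peaks for the
# ETS/forkhead/ERE models, builds the jointly-normalized positional
# centrality profile (total probability mass across all curves = 1), and
# compares ETS motif presence between gained and lost contrast-factor
# sites. Writes results/motif_centrality.tsv, results/motif_presence.tsv.

suppressMessages(library(cistromeShift))
dir.create("results", showWarnings = FALSE)

layout <- read_chrom_sizes("data_sim/chrom_sizes.tsv")
genome <- load_genome("data_sim/genome.fa")
pwms <- read_meme("data_sim/motifs.meme")

reps <- lapply(1:4, function(r) {
  read_narrowpeak(sprintf("data_sim/ELF5_induced_rep%d.narrowPeak", r),
                  layout = layout)
})
focus <- consensus_peaks(reps, 3)
prof <- positional_distribution(focus, genome, pwms, half_window = 250)
write.table(prof, "results/motif_centrality.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
mass_near0 <- sapply(split(prof, prof$motif), function(d)
  sum(d$mass[abs(d$offset_bin) <= 50]) / sum(d$mass))
cat("fraction of each curve's mass within +/-50 bp of the summit:\n")
print(round(mass_near0, 3))
cat(sprintf("grand total mass (jointly normalized): %.6f\n", sum(prof$mass)))

gained <- read_bed("results/gained.bed", layout = layout)
lost <- read_bed("results/lost.bed", layout = layout)
rows <- lapply(list(gained = gained, lost = lost), function(ps) {
  if (!nrow(ps)) return(data.frame(n = 0, with_motif = 0, rate = NA))
  r <- motif_presence_rate(ps, genome, pwms$ETS)
  data.frame(n = r$denominator, with_motif = r$numerator, rate = r$rate)
})
pres <- cbind(set = names(rows), do.call(rbind, rows))
write.table(pres, "results/motif_presence.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(pres)
cat("(an ETS motif is planted at almost all gained sites and few lost\n",
    "sites, so the gained-site rate should exceed the lost-site rate\n",
    "whenever both sets are non-empty)\n")
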