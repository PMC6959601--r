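#!/usr/bin/env Rscript
# Stage 3 - differential binding of the contrast factor (FOXA1).
#
# Runs the moderated-t on the region count matrix, classifies gained/lost
# sites at FDR < 0.05, and scores the calls against the planted truth.
# Writes results/diffbind_records.tsv, results/gained.bed, results/lost.bed
# and results/diffbind_recovery.tsv.

suppressMessages(library(cistromeShift))
dir.create("results", showWarnings = FALSE)

cm <- read_count_matrix("data_sim/counts.tsv", "data_sim/samples.tsv")
cat(sprintf("count matrix: %d regions x %d samples\n",
            nrow(cm$counts), ncol(cm$counts)))
cat("size factors:", round(size_factors(cm), 3), "\n")

cls <- classify_sites(test_region_differential(cm), alpha = 0.05)
write.table(cls$records, "results/diffbind_records.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_bed(cls$gained, "results/gained.bed")
write_bed(cls$lost, "results/lost.bed")

truth <- read.table("data_sim/truth_regions.tsv", header = TRUE, sep = "\t")
status <- truth$status[match(cls$records$region_id, truth$region_id)]
tab <- table(truth = status, called = cls$records$direction)
print(tab)

called <- cls$records$direction == "gained"
sens <- sum(called & status == "gained") / max(1, sum(status == "gained"))
fdr <- if (any(called)) sum(called & status != "gained") / sum(called) else 0
rec <- data.frame(n_regions = nrow(cls$records),
                  n_true_gained = sum(status == "gained"),
                  n_called_gained = sum(called),
                  sensitivity = sens, empirical_fdr = fdr)
write.table(rec, "results/diffbind_recovery.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("\ngained-site sensitivity %.3f, empirical FDR %.3f\n", sens, fdr))
cat("NOTE: at a 2-fold planted effect with NB dispersion 0.1 and 4v4\n",
    "replicates the per-region z-score is ~3, so low sensitivity at\n",
    "FDR < 0.05 is the expected operating point of this design;\n",
    "see the methods vignette for the power analysis.\n")
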