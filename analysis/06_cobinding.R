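#!/usr/bin/env Rscript
# Stage 6 - co-binding combinations by genomic class.
#
# Crosses the site universe with the three factors' consensus cistromes,
# classifies each site (DE-gene promoter / super enhancer / enhancer /
# other), selects the induced factor's cofactors by phi correlation, and
# tallies exact factor combinations per class (UpSet distinct mode).
# Writes results/cobinding_*.tsv.

suppressMessages(library(cistromeShift))
dir.create("results", showWarnings = FALSE)

layout <- read_chrom_sizes("data_sim/chrom_sizes.tsv")
universe <- read_bed("data_sim/track_tfbs_universe.bed", layout = layout)
tss <- read_tss("data_sim/tss.bed", layout = layout)

tracks <- lapply(c(ELF5 = "ELF5", FOXA1 = "FOXA1", ER = "ER"), function(f) {
  reps <- lapply(1:4, function(r) {
    read_narrowpeak(sprintf("data_sim/%s_induced_rep%d.narrowPeak", f, r),
                    layout = layout)
  })
  consensus_peaks(reps, 3)
})
memb <- overlap_membership(universe, tracks)

de <- read.table("data_sim/de_table.tsv", header = TRUE, sep = "\t")
de_genes <- de$gene[de$FDR < 0.05 & abs(de$log2FC) > log2(1.5)]
de_tss <- tss[tss$gene_id %in% de_genes, ]
td <- tss_distance(universe, de_tss)
near_de <- !is.na(td$distance) & abs(td$distance) <= 10000
se <- read_bed("data_sim/track_super_enhancer.bed", layout = layout)
enh <- read_bed("data_sim/track_enhancer.bed", layout = layout)
klass <- ifelse(near_de, "DE_promoter",
         ifelse(overlap_membership(universe, list(se))[, 1], "super_enhancer",
         ifelse(overlap_membership(universe, list(enh))[, 1], "enhancer",
                "other")))
bm <- binding_matrix(memb, class = klass, loci = universe)
write_binding_matrix(bm, "results/cobinding_matrix.tsv")

phi <- phi_correlation(bm)
cat("phi correlations between factor cistromes over the site universe:\n")
print(round(phi, 3))
cof <- select_cofactors(bm, "ELF5")
cat("cofactors of ELF5 (phi >= 0.2):", paste(names(cof), collapse = ", "), "\n")

combos <- do.call(rbind, lapply(unique(klass), function(k) {
  cbind(class = k, combination_counts_by_class(bm, k))
}))
write.table(combos, "results/cobinding_combinations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\ntop combinations at DE-gene promoters:\n")
print(head(combos[combos$class == "DE_promoter", ], 5))
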