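# cistromeShift

Toolkit for quantifying how induced binding of one transcription factor
redistributes the cistromes of others, and how those binding changes couple
to gene expression. The motivating setting is hormone-dependent breast
cancer, where induction of the ETS factor ELF5 recruits the pioneer factor
FOXA1 (and with it ER) to new genomic sites; the package implements the
statistical machinery such a study needs, end to end, and ships a
deterministic synthetic-data generator with planted ground truth so that
every stage is testable without any external download.

Intended users are computational biologists analysing multi-factor,
multi-condition ChIP-seq experiments together with matched expression data.

## What it computes

- **Consensus peaks.** Replicate peak calls (narrowPeak/BED) are reduced to
  the maximal runs of base pairs supported by ≥ k of n replicates (default
  3 of 4), via coverage arithmetic on `IRanges`.
- **Differential binding.** On a region × sample count matrix with
  median-of-ratios size factors `s_j`, the per-region statistic works on
  `y_ij = log2(c_ij / s_j + 0.5)`:

  `log2FC = mean(y_induced) − mean(y_vehicle)`,
  `s̃² = (d₀·s̄² + d·s²) / (d₀ + d)`,
  `t = log2FC / sqrt(s̃² (1/n₁ + 1/n₂))`, with `d = n₁+n₂−2`, prior weight
  `d₀ = 4`, and p from `t_{d+d₀}`. Sites are gained/lost when the BH
  q-value < α (default 0.05) with the matching sign.
- **Motif centrality.** Log2-odds PWM scanning (both strands, N scores as
  background), best-hit positional distributions around peak summits with
  all curves jointly normalized to total probability mass 1, and motif
  presence rates at gained vs lost sites.
- **Genomic-context enrichment.** Peak-level 2×2 tables against an explicit
  background universe: `OR = ad/bc` with Haldane–Anscombe correction on
  zero cells, Woolf SE `sqrt(1/a+1/b+1/c+1/d)`, Fisher's exact two-sided p;
  windowed OR profiles; overlap fractions with round-half-up percentages;
  Pearson χ² (df = 1, no continuity correction) for the overlap of two
  gained-site sets over a universe.
- **Co-binding.** φ correlations of binary binding vectors, cofactor
  selection, and exact combination counts per genomic class (UpSet
  "distinct" mode).
- **Rank enrichment.** Weighted Kolmogorov–Smirnov running-sum ES
  (hit step `|s_i|^w / Σ_S |s|^w`, miss step `−1/(N−|S|)`), gene-set
  permutation null with add-one p and `NES = ES / mean(|ES_null| same
  sign)`, ChIP-derived gene sets (summit within 10 kb of the TSS), and a
  bidirectional matched primary/metastasis patient design with per-patient
  dispersion borrowed from the remaining pairs.
- **Synthetic data.** `sim_config()` / `simulate_all()` generate genome,
  motifs, repeats, annotations, replicate peaks, counts, DE tables and
  patient pairs with ground-truth sidecars, byte-identical under a fixed
  seed.

## Worked example

The `analysis/` directory holds the numbered workflow
(`01_simulate.R` … `08_patient_pairs.R`); each script reads `data_sim/`,
writes tables under `results/`, and prints what it found. For instance,
after `Rscript analysis/01_simulate.R 1`:

```
simulated 2000 candidate sites on 2 chromosomes (seed 1)
planted: 70 gained / 35 lost FOXA1 sites; 629 repeat-linked sites; 209 coupled genes
```

`Rscript analysis/05_context_enrichment.R` then reports the repeat-context
enrichment of the induced factor's consensus cistrome against the
all-sites universe:

```
OR[MIR] = 2.209 (95% CI 1.818-2.684), p = 1.64e-15  [a=274 b=253 c=658 d=1342]
```

i.e. 274 of 527 consensus peaks overlap a MIR-like repeat versus 658 of
2000 universe sites — recovering the planted two-fold odds ratio. And
`Rscript analysis/08_patient_pairs.R 1` flags exactly the planted
responsive metastases:

```
significant pairs (padj < 0.05, NES > 0): P3, P4, P6
recovered 3 of 3 planted responsive pairs, 0 false positive(s)
reversed analysis (pairs as replicates): NES 5.68, p 2.22e-04
```

An in-memory equivalent for interactive use:

```r
library(cistromeShift)
cfg <- sim_config(seed = 1)
sim <- simulate_all(cfg, "data_sim")
run_pipeline(pipeline_config("data_sim", n_perm = 1e4), "results_pipeline")
```

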