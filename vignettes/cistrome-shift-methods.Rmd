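---
title: "Methods: quantifying induced cistrome redistribution"
author: "cistromeShift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying induced cistrome redistribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
models and their assumptions, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, the numerical
choices, and the known limitations. The biological setting throughout is an
inducible transcription factor (an ETS-family factor such as ELF5) whose
elevated binding redistributes the cistromes of a pioneer factor (FOXA1)
and of ER, with consequences for gene expression and endocrine resistance.

## Coordinates and interval algebra

All coordinates are 0-based half-open (`[start, end)`, the BED convention);
narrowPeak summits are offsets from `start`. Peaks are unstranded; only TSS
carry strand. Bookended intervals (`[a,b)`, `[b,c)`) merge at gap 0 —
worth stating because tools disagree here.

Consensus peaks implement the strictest reading of a "k of n replicates"
rule: the maximal runs of base pairs covered by at least `min_support`
(flattened) replicates, computed by coverage arithmetic. This differs from
the laxer alternative of returning whole peaks that overlap enough
replicates; the per-base reading is exactly checkable against a brute-force
support sweep, which the test suite does on random instances. Each
consensus interval's summit is reset to its midpoint, since replicate
summits have no canonical combination.

Nearest-TSS distances are signed by gene orientation (positive =
downstream) and tie-broken to the lexicographically smallest gene id, for
full determinism. Promoter bins default to ≤ 1 kb / 1–2 kb / 2–3 kb /
distal; the cut points are a convention, not an estimate, and are
configurable via `classify_region(breaks = )`.

## Differential binding

The test is a moderated t on log-transformed normalized counts,

$$y_{ij} = \log_2(c_{ij}/s_j + 1/2), \qquad
\tilde{s}^2_g = \frac{d_0 \bar{s}^2 + d\, s^2_g}{d_0 + d},$$

with median-of-ratios size factors $s_j$, pooled within-condition variance
$s^2_g$, residual df $d = n_1 + n_2 - 2$, and a fixed prior weight
$d_0 = 4$ pulling every region toward the across-region mean variance
$\bar{s}^2$; p-values come from $t_{d + d_0}$ and gained/lost calls apply
BH at $\alpha = 0.05$ with the sign of the fold change. The pseudo-count
1/2 bounds the transform at zero counts.

Two calibration facts, both established by simulation in the test suite
and worth knowing before trusting the output:

* **The test is conservative, not anti-conservative.** With a fixed prior
  weight and homogeneous true variances, the statistic is
  $Z/\sqrt{0.4 + 0.6\,\chi^2_6/6}$-distributed under the null for the 4v4
  design — lighter-tailed than the reference $t_{10}$ — so the observed
  type-I error at nominal 0.05 is ≈ 0.035–0.040. The suite asserts the
  defensible direction (never exceeding nominal). A data-estimated prior
  df in the style of hierarchical variance models would sharpen this; it
  is deliberately out of scope to keep the statistic small and exactly
  documentable.
* **Power at the shipped effect size is intrinsically low.** At a 2-fold
  planted change with NB dispersion 0.1 and mean 100,
  $\mathrm{var}(\log_2 c) \approx (1/\mu + \alpha)/\ln^2 2 \approx 0.23$,
  so the 4v4 log2FC of 1 carries a z-score of ≈ 2.95. Even an oracle
  z-test with known variance cannot exceed ≈ 0.45 sensitivity under BH at
  FDR 0.05 with 10% of regions affected (the BH threshold self-consistency
  collapses the fixed point further for the t). Detecting 2-fold binding
  shifts reliably needs either lower dispersion, more replicates, or a
  larger effect — a statement about the design, not the implementation.
  The 4-fold / dispersion 0.05 configuration, by contrast, is detected in
  > 95% of simulations.

## Motif scanning and centrality

Scores are $\log_2$ odds of the PWM against its background; cells below
$10^{-4}$ are floored (then columns renormalized) so sharp matrices never
yield $-\infty$. `N` contributes 0 (background). Both strands are scanned;
ties resolve to the leftmost offset, then the + strand. The default hit
threshold is 60% of the PWM's maximum achievable score — a PWM-portable
relative criterion; it is a config knob (`score_min`), as is the ±250 bp
centrality window.

Positional profiles bin best-hit centers by offset from the summit (10 bp
bins). The default normalization is *joint*: the total mass across all
curves in a profile set is 1, so curves are comparable in absolute terms;
per-curve normalization is available (`normalize = "per_motif"`). An empty
profile (nothing passes threshold) is returned with total mass 0 and a
warning rather than an error, since it is a legitimate scientific outcome.

## Context enrichment

Odds ratios count *peaks* (≥ 1 bp overlap), not base pairs, matching how
such overlaps are usually reported; the 2×2 table is
(focus∩annot, focus∖annot; background∩annot, background∖annot). The
background universe is always an explicit argument — an odds ratio without
a stated universe is meaningless — and the universe may contain the focus
(as when comparing one factor's sites against all TF-binding sites).
Haldane–Anscombe (+0.5 on all cells) applies only when a cell is zero and
is flagged in the result; the Woolf SE uses the corrected cells; the exact
p always uses the raw counts. The two-gained-set overlap test is Pearson's
χ² without continuity correction, appropriate for the large-count regime
it is used in; degenerate margins raise errors rather than returning 0/1.

Percentages from `fraction_overlapping()` round half up (27.63% → 28%),
since that is how such fractions are conventionally printed.

## Rank enrichment

The ES is the weighted KS running-sum statistic (weight exponent default
1; 0 gives the classic unweighted statistic). The null permutes *gene
sets* (random same-size draws from the ranked universe), matching the
model of the fast preranked-GSEA tools; phenotype permutation would need
sample-level data the interface does not require. The p-value uses the
add-one estimator restricted to same-sign null scores, and
`NES = ES / mean(|ES_null| same sign)`. Consequences: p is never 0 (floor
`1/(1+n_same)`), and with very one-sided nulls the same-sign count can be
small — below 10 the result carries an unstable-null warning. Exact ties
between the positive and negative running-sum extremes are resolved to the
positive side, with a 1e-12 tolerance because long-double accumulation can
split mathematically exact ties at the last bit.

ChIP-derived gene sets use the 10 kb summit-to-TSS rule. DE rankings score
genes by `sign(log2FC) * (-log10 p)` — monotone in both direction and
evidence; the ranking metric is a convention and other monotone choices
would reorder only within evidence levels.

The paired primary/metastasis design normalizes all samples jointly,
forms per-pair metastasis-minus-primary differences in log2, and scores
genes either across pairs (replicates mode: mean difference over a
moderated across-pair SE) or for a single pair with variance borrowed from
the *other* pairs — the design in which each patient is judged against the
spread of the rest. Per-patient significance is BH-adjusted across the
pair batch; "responsive" means padj < 0.05 with positive NES.

## The synthetic generator

`sim_config()` defaults define the study conditions everything is tested
under: a 2 Mb two-chromosome genome; 2000 candidate TF sites on a jittered
grid (≥ 600 bp apart, so peaks never collide and ground truth stays
unambiguous); three factors sharing sites (the induced factor first, 60%
of each other factor's sites shared with it); four replicates per
condition keeping each base peak with probability 0.85 and jittering
boundaries by N(0, 15 bp); NB counts with mean 100 and dispersion 0.1;
10% of contrast-factor sites gained at 2-fold (5% lost, reciprocal);
MIR-like repeats planted so the odds ratio of repeat overlap at the
induced factor's sites versus the full site universe is 2 (solved
numerically for the within-universe attenuation); expression log2FC of
N(1.5, 0.5²) at genes with a gained site within 10 kb (N(0, 0.5²)
otherwise, p-values consistent by construction, hence uniform under null);
and 7 patient pairs of which 3 are responsive with a 4-fold signature
induction. Binding changes are planted *quantitatively* (in counts) while
replicate variability is planted *in presence/absence* — separating the
two failure modes so consensus and differential testing are validated
independently.

Each artifact draws from its own stream seeded hierarchically from the
master seed, so adding an artifact never perturbs another's draws, and
every output is byte-identical under a fixed seed.

What the generator does **not** emulate: realistic sequence composition
(background is i.i.d. uniform), peak-width and signal heterogeneity,
per-region baseline count variation (means are flat at `nb_mean`),
GC/mappability artifacts, duplicate reads, and correlated replicate
failure. Passing tests therefore demonstrate correctness of the statistics
under their stated models, not robustness to the full messiness of real
ChIP-seq. One visible desk-scale artifact: with 200+ coupled genes on a
2 Mb genome, ±10 kb promoter windows tile much of the genome, so the
"DE-promoter" class in the co-binding stage is large relative to a real
genome.

## Problem sizes

The shipped configurations are chosen so the whole battery runs on one
CPU in minutes: 2 Mb genomes, ~2000 sites, 5000-region calibration
matrices, 500-draw uniformity checks at 2000 permutations, 10–20 seed
replications for planted-recovery properties, and 10⁴ permutations for
the end-to-end enrichment checks (the `permutation_test()` default of 10⁵
matches the scale used for published p-values; the analysis scripts pass
10⁴).

## Known limitations

* The moderated t's fixed $d_0$ makes it conservative (above); its
  sensitivity at 2-fold/dispersion-0.1/4v4 is bounded low by the design
  itself.
* Counting units are peaks; base-pair-level enrichment is not implemented.
* The Venn/UpSet counting unit is the query interval; counts will differ
  from summit- or merged-region-based counting when peaks are wide.
* PWM hits are thresholded, not E-value calibrated; no de-novo discovery.
* The patient analysis assumes one primary and one metastasis per pair and
  borrows dispersion across pairs; it does not model tumor purity or
  batch.
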