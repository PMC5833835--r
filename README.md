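# hicdynamics

Differential chromatin-interaction analysis for bridge-linker Hi-C.

When a cell changes state — for example a leukemia cell line induced to
differentiate — its large-scale genome architecture (A/B compartments, TAD
boundaries) tends to stay put, while contacts *inside* TADs, particularly
between gene promoters and distal enhancers, reorganize and track gene
expression. `hicdynamics` implements the computational pipeline for
detecting and quantifying those changes from two conditions with replicate
Hi-C libraries, histone-mark peak calls (a promoter mark such as H3K4me3
and a distal acetylation mark such as H3K27ac), and a differential
expression table. It is aimed at computational genomicists who want each
stage as a tested, composable R function rather than a monolithic script.

## What it does

* **Read pairs** — bridge-linker trimming (5′ fragment kept when the full
  linker `CGCGATATCTTATCTGACT` / `GTCAGATAAGATATCGCGT` splits a read),
  duplicate removal, data-driven span-threshold estimation from strand
  orientation, and classification into full segments, self-ligations,
  intra- and inter-chromosomal ligations.
* **Matrices** — binned contact matrices, ICE balancing, observed/expected
  transforms, replicate correlation at 1 Mb.
* **Compartments** — per-chromosome PC1 of the O/E correlation matrix,
  activity-oriented A/B labels, and replicate-consistent switch calls.
* **TAD dynamics** — internal/external interaction fold changes tested
  against an empirical null built from within-condition replicate ratios;
  σ-deviation categories; DEG distribution across categories; boundary
  stability.
* **Gene-regulatory interactions** — 40-kb bins annotated as gene regions
  (promoter-mark peak at an expressed TSS) or regulatory regions (distal
  acetylation peak); within-TAD bin pairs tested with the MA-plot binomial
  random-sampling statistic; Gain/Loss calls at BH-adjusted p < 0.001.
* **Enrichment statistics** — Fisher exact enrichment, Mann–Whitney
  comparisons, per-region signal fold changes, condition-specific peak
  enrichment in called regions, network hub degrees.
* **Synthetic data** — a generator with planted truth (distance-decaying
  Poisson contacts, TAD blocks, compartment checkerboard, planted
  interaction changes, coupled peaks and expression, linker-bearing reads)
  so the whole pipeline is testable offline.

The statistical core is the MARS test. For a candidate pair with pooled
counts C1, C2 and condition totals n1, n2, counts are modeled as
Ci ~ Binomial(ni, pi); with X = log2 C1, Y = log2 C2, M = Y − X and
A = (X + Y)/2, the null conditional law of M given A = a is approximately
normal with mean log2(n2/n1) and variance
4(1 − p̂) / ((n1 + n2) p̂ ln²2), where p̂ = 2ᵃ/√(n1 n2). The z score against
that law gives the two-sided p-value. See the methods vignette
(`vignettes/hicdynamics-methods.Rmd`) for derivations, design decisions and
known limitations.

## Worked example

Simulate the default two-condition study (2 × 20 Mb genome, 40-kb bins, two
replicates per condition, 60 planted interaction changes) and run the
differential pipeline:

```r
library(hicdynamics)

cfg   <- truth_config(seed = 1)
truth <- generate_truth(cfg)
maps  <- simulate_contact_maps(truth, cfg)
pe    <- simulate_peaks_expression(truth, cfg)

# replicate-intersected ("convincing") peaks, pooled over conditions
conv <- function(mark, cond)
  overlap_partition(pe$peaks[[mark]][[cond]]$rep1,
                    pe$peaks[[mark]][[cond]]$rep2)$common_a
promoter <- rbind(conv("promoter", "cond1"), conv("promoter", "cond2"))
distal   <- rbind(conv("distal",   "cond1"), conv("distal",   "cond2"))

genes <- classify_degs(pe$expression)      # |log2FC| > 0.9, padj < 0.01
table(genes$de_status)
#>     up   down stable
#>     30     33    337

ann   <- annotate_bins(truth$bins, promoter, distal, genes, truth$tads)
cand  <- extract_candidate_pairs(ann, maps$cond1, maps$cond2)
res   <- mars_test(cand$C1, cand$C2, attr(cand, "n1"), attr(cand, "n2"))
calls <- call_gain_loss(cbind(cand, res[, c("M", "A", "p1_hat", "p2_hat", "z", "p")]))
table(calls$call)
#> Gain Loss   NS
#>   30   24  441

head(calls[calls$call == "Gain", c("gene_bin", "reg_bin", "C1", "C2", "M", "z", "p_adj")], 3)
#>    gene_bin reg_bin  C1  C2        M         z        p_adj
#> 40      113     115 166 354 1.092566  8.346044 2.495770e-15
#> 63      152     153 250 547 1.129613 10.657796 7.937411e-24
#> 77      194     198 105 225 1.099536  6.687974 3.862375e-10
```

The 30 Gain and 24 Loss calls are planted pairs recovered at their ~2×
contact fold change (`M ≈ ±1`); with this seed recall is 0.90 at precision
1.00 against the 60 planted pairs. The same objects feed the TAD test
(`tad_foldchange_test`, here flagging 2 of 99 TADs that happen to contain
several planted pairs) and the compartment caller
(`ice_balance` → `pc1_track` → `orient_and_label` → `compartment_changes`).

The enrichment layer works on plain counts. A typical question at this layer: are
differentially expressed genes over-represented among the genes involved in
differential interactions? With 225 DEGs among 753 involved genes, against
1,649 among 12,266 genes overall:

```r
unlist(fisher_enrichment(225, 528, 1424, 10089, alternative = "greater"))
#>   odds_ratio      p_value
#> 3.019164e+00 2.556874e-34
```

i.e. a three-fold enrichment of DEGs among genes with differential
gene-regulatory interactions, far below the p < 1e-22 significance bar.

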