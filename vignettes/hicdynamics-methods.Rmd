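---
title: "Models and methods behind hicdynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hicdynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicdynamics)
```

# What the package computes

`hicdynamics` implements a pipeline for asking how chromatin conformation
changes relate to transcription between two cell states measured with a
bridge-linker Hi-C protocol, plus ChIP-seq peak calls and an expression
table. The stages are:

1. **Read-pair processing** — bridge-linker trimming, duplicate removal,
   strand-geometry classification of pairs into full segments,
   self-ligations, intra- and inter-chromosomal ligation products.
2. **Contact matrices** — binned symmetric count matrices, iterative
   correction (ICE), observed/expected (O/E) transforms, replicate
   reproducibility.
3. **A/B compartments** — first principal component of the per-chromosome
   O/E correlation matrix, activity-oriented sign, and a conservative
   both-replicates rule for compartment switches.
4. **TAD interaction dynamics** — per-TAD internal/external counts, an
   empirical fold-change null built from within-condition replicate ratios,
   and seven σ-deviation categories of internal fold change.
5. **Differential gene-regulatory interactions** — promoter-mark and distal
   acetylation peaks annotate 40-kb bins as gene regions and regulatory
   regions; within-TAD bin pairs are tested with an MA-plot binomial
   random-sampling statistic and called Gain/Loss at a
   Benjamini–Hochberg-adjusted p below 0.001.
6. **Downstream statistics** — Fisher enrichment of DEGs in Gain/Loss gene
   sets, Mann–Whitney signal comparisons, condition-specific peak enrichment
   in called regions, and hub degrees in a user-supplied regulatory network.

Everything is exercised end to end on a synthetic genome with planted
truth; no external data are required for any test.

# The MA-plot random-sampling (MARS) test

For one candidate bin pair, let $C_1$ and $C_2$ be the pooled contact counts
in the two conditions and $n_1$, $n_2$ the total intra-chromosomal Hi-C
counts per condition. The model is binomial sampling,
$C_i \sim \mathrm{Bin}(n_i, p_i)$, and the null hypothesis is
$H_0: p_1 = p_2$. With $X = \log_2 C_1$, $Y = \log_2 C_2$,

$$ M = Y - X, \qquad A = \tfrac{1}{2}(X + Y), $$

the conditional distribution of $M$ given $A = a$ is approximately normal
under $H_0$. The common sampling probability is estimated from the observed
$a$ as $\hat p = 2^a / \sqrt{n_1 n_2}$, and the delta method gives

$$ \operatorname{Var}(X) = \frac{1 - \hat p}{n_1 \hat p \ln^2 2}, \qquad
   \operatorname{Var}(Y) = \frac{1 - \hat p}{n_2 \hat p \ln^2 2}. $$

Because $(M, A)$ are treated as jointly normal with
$\operatorname{Cov}(M, A) = (\operatorname{Var}Y - \operatorname{Var}X)/2$
and $\operatorname{Var}(A) = (\operatorname{Var}X + \operatorname{Var}Y)/4$,
conditioning on $A = a$ (with $\hat p$ estimated from that same $a$) leaves

$$ E[M \mid a] = \log_2\frac{n_2}{n_1}, \qquad
   \operatorname{Var}(M \mid a)
   = \frac{4\operatorname{Var}X \operatorname{Var}Y}
          {\operatorname{Var}X + \operatorname{Var}Y}
   = \frac{4 (1 - \hat p)}{(n_1 + n_2)\, \hat p \ln^2 2}, $$

so $z = (m - \log_2(n_2/n_1)) / \sqrt{\operatorname{Var}(M \mid a)}$ and the
two-sided p-value comes from the standard normal.

Design notes:

* $M$ is oriented condition 2 minus condition 1 so that a **Gain**
  (strengthened in the treated state) has $M > 0$. Some write-ups halve $M$;
  the $z$ statistic is invariant to any consistent rescaling of $M$, so the
  standard definition is used.
* The statistic is a *first-order* delta approximation. Its conditional
  mean and variance agree with a $10^6$-draw binomial Monte-Carlo oracle to
  within Monte-Carlo resolution at expected counts of about 1000 and above;
  at counts of 20–500 the approximation carries a small deliberate bias
  (conditional variance underestimated by roughly 1% at count 100, more at
  count 20). What matters for inference at those counts is calibration, which
  is checked directly: on 50,000 simulated null pairs the type-I error at
  $\alpha = 10^{-3}$ lands inside $[5 \times 10^{-4}, 2 \times 10^{-3}]$, and
  a decile chi-square test does not reject uniformity of the p-values at the
  1% level. A Kolmogorov–Smirnov test is *not* appropriate for that check:
  the counts are discrete, p-values contain ties, and KS rejects on ties
  alone.
* Counts enter raw (pooled over replicates), not ICE-corrected: the binomial
  sampling model describes integer read sampling, which balancing weights
  would destroy. The minimum pooled count for a testable pair is
  $C_1 + C_2 \ge 10$ (configurable); below that the normal approximation is
  not trusted.
* The promoter window operationalizing "near a TSS" is ±2 kb, configurable;
  no standard value exists and results should be checked for sensitivity.

# The TAD empirical-null fold-change test

For each TAD, internal counts sum over distinct bin pairs inside the TAD and
external counts over intra-chromosomal pairs with exactly one bin inside.
The diagonal is excluded from internal sums: self-bin counts are dominated
by short-range religation artifacts rather than conformation. Counts are
depth-normalized by the total intra-chromosomal mass, put back on the mean
raw-total scale, and given a 0.5 pseudocount before logs.

The null distribution is *empirical*: within-condition replicate log2 ratios
(one per TAD per condition) are pooled across both conditions into a
background; the observed statistic for replicate pairing $k$ is the log2
fold change of condition-2 replicate $k$ over condition-1 replicate $k$, and
its two-sided p-value is its add-one-corrected rank in the background,

$$ p = \min\!\left(1,
   \frac{1 + 2\min(\#\{b \le o\}, \#\{b \ge o\})}{N + 1}\right). $$

A TAD is significant when **every** replicate pairing's internal p-value is
below $\alpha = 0.05$. External p-values are reported but do not gate
significance. Two properties of this design are worth knowing:

* Because the background pools TADs of different sizes, the test is exactly
  calibrated only when the replicate-noise scale is comparable across TADs;
  with no planted changes the pipeline flags 0% of TADs at the default
  conditions, comfortably below $\alpha$.
* Normalizing by total mass makes strong localized gains *redistribute*:
  when 10% of TADs double internally in condition 2, unchanged TADs shift
  slightly down and some of them cross the empirical threshold. The planted
  2× boosts themselves are recovered at 100%; interpretation of the flagged
  set should keep the compositional effect in mind (the same caveat applies
  to any total-count normalization).

σ-categories divide TADs by $(f - \bar f)/\sigma_f$ of the internal log2
fold change $f$ at edges $\pm 0.5$, $\pm 1$, $\pm 2$, giving seven classes
from strongest decrease (1) to strongest increase (7). The edges are
configuration, not doctrine.

# Compartment calling

Per chromosome the pipeline takes the ICE-balanced matrix, forms O/E ratios
(per-diagonal expectation over unmasked bins), computes the Pearson
correlation matrix of bin contact profiles, and extracts the first principal
component. The eigenvector sign is arbitrary, so each chromosome is oriented
against a marker of activity — TSS density per bin by default — making A the
active compartment by construction. Bins masked by balancing, or with zero
loading, are `undefined`.

Compartment switches require replicate agreement: a bin is `A_to_B` only if
*all* condition-1 replicates label it A and *all* condition-2 replicates
label it B. A switch seen by a single replicate is reported `unchanged`;
a bin undefined in any replicate is `undefined`. Fractions are reported over
all bins and sum to one.

Known limitation: ICE masks the lowest-coverage 2% of bins, and compartment
boundary bins are intrinsically lower-coverage (their short-range neighbours
lie partly in the other compartment). Since real switches happen at
boundaries, a switch can occasionally be lost to masking; at the default
conditions the planted 1% switch set is recovered within the stated ±0.3
percentage points, but on unlucky seeds individual boundary bins drop into
the mask.

# Read-pair classification

Pairs on different chromosomes are inter-chromosomal ligations. On the same
chromosome a span threshold separates religation artifacts from genuine
contacts: below it, inward pairs (upstream mate `+`, downstream `-`) are
unligated **full segments** and outward pairs are **self-ligations**;
same-strand short pairs require a ligation event and count as intra. The
threshold is estimated from the data as the left edge of the smallest
log-spaced span bin whose four strand-orientation fractions are all within
0.05 of 0.25 (artifacts have fixed geometry, so short bins are unbalanced);
with fewer than 1000 intra pairs, or no balanced bin, the estimator falls
back to 3 kb — the expected scale for a 4-cutter library — with a warning.

Linker trimming keeps the 5′ fragment when a full linker copy (either
orientation, exact match by default) splits the read into two non-empty
fragments; the leftmost copy wins, reads without a linker pass through
whole, and kept fragments shorter than 20 bp (a mappability floor) are
flagged discarded rather than dropped silently.

# The synthetic data generator

The generator defines the study conditions under which every claim above is
tested. Expected counts for bins $i < j$ on one chromosome are

$$ \lambda_{ij} \propto (d_{ij} + 1)^{-\alpha}
   \cdot T^{[\text{same TAD}]}
   \cdot \gamma^{[\text{same compartment}]}
   \cdot \beta^{[\text{both in a boosted TAD, cond 2}]}
   \cdot \delta^{\pm[\text{planted pair, cond 2}]}, $$

scaled so each condition's expected intra mass is `depth` × (1 −
`inter_frac`), with a flat inter-chromosomal floor carrying the rest; each
replicate draws its upper triangle independently from a Poisson law.
Replicate variability therefore enters only through resampling — the
simplest model under which the binomial sampling assumption of the MA test
approximately holds. Real Hi-C replicates are overdispersed; passing these
tests shows the machinery is correct under the stated model, not that real
libraries are this well behaved.

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| genome | 2 × 20 Mb, 40-kb bins | ≥ 40 TADs, seconds-scale tests |
| TAD size | 280–520 kb | ~400 kb average, the observed scale |
| depth | 10⁶ pairs/replicate | ~150 M genome-wide interactions scaled by 40 Mb / 3 Gb |
| α (decay) | 1.0 | canonical Hi-C distance decay |
| T (TAD block) | 2 | typical within-TAD enrichment |
| γ (compartment) | 2 | clear checkerboard at toy depth |
| δ (planted effect) | 2 | the fold change the recovery claims are about |
| planted pair separation | 1–4 bins (40–160 kb) | the distance scale of the promoter–enhancer loops the pipeline targets |
| planted pairs | 30 Gain + 30 Loss | enough for stable recall/precision at n = 60 |
| expression noise | sd 0.3, 2 replicates/condition | RNA-seq-like log2 noise |

Planted effects are separated into channels — gene-regulatory pair changes
(δ), condition-2 TAD boosts (β), and A→B compartment flips — and each study
scenario activates only the channel it measures. The default genome plants
only δ-pairs; the TAD scenarios plant only boosts (or nothing, for the null
calibration); the compartment scenario plants a 1% A→B switch as contiguous
boundary shifts of existing B blocks, which is both the biologically
sensible form of a switch and the form a coverage-masked pipeline can
recover. Mixing channels is possible (all are config fields) but then, for
example, a planted compartment flip is *real* differential contact signal
and will rightly surface in the TAD and pair tests.

Expression p-values come from a z-test with the generator's known noise
standard deviation, then BH adjustment, so DEG labels are re-derivable with
`classify_degs()` at the study thresholds (|log2 FC| > 0.9, adjusted
p < 0.01). Genes attached to planted Gain/Loss pairs receive ±2 mean log2
fold changes; genes in boosted TADs get a +1 shift, emulating the coupling
between rising internal interactions and upregulation.

# Numerical choices

* ICE: damped multiplicative updates (`b ← b / sqrt(s)`), convergence when
  the max relative row-sum deviation over unmasked bins falls below 1e-5,
  weights rescaled so corrected and raw total mass agree; lowest-coverage 2%
  of bins masked. Re-running on a corrected matrix changes weights by less
  than the tolerance (fixed point).
* O/E expectation per diagonal is the mean over unmasked bins of that
  chromosome; zero-expected diagonals are left undefined rather than
  imputed.
* Empirical TAD p-values use the add-one rank correction, so they live in
  $(0, 1]$ and a result more extreme than the whole background reports
  $1/(N+1)$, never 0.
* BH ties break by stable sort on input order; all internal coordinates are
  0-based half-open (BED native), converted only at the IRanges boundary.
* The Fisher odds ratio is reported as the sample ratio $ad/bc$ (with
  $\infty$ when $bc = 0$ and $ad > 0$), not the conditional MLE that
  `fisher.test` prints; p-values are the exact hypergeometric tails.
* Problem sizes in the shipped checks: 50,000 null pairs for calibration,
  $10^6$ Monte-Carlo draws per oracle grid point, and the default toy
  genome (1,000 bins, 4 contact maps) for the recovery runs — all chosen so
  the full suite completes in about a minute while keeping every claim
  statistically resolvable.

# What passing tests do and do not show

The synthetic system emulates distance decay, TAD blocks, compartment
checkerboards, replicate Poisson noise, condition-specific peaks, and
DE-coupled planted interactions. It does not emulate overdispersed
biological replicates, restriction-fragment geometry, mappability and GC
biases (ICE is exercised on synthetic coverage variation only), sequence
content beyond the linker, or the true density of peaks and genes per bin.
Recovery rates quoted anywhere in this package are statements about the
generator's conditions, at the stated depths and effect sizes — not about
any particular real library.
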