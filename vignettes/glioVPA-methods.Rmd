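---
title: "Methods: unreplicated differential expression, consensus filtering and integrative statistics in glioVPA"
author: "glioVPA authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unreplicated differential expression, consensus filtering and integrative statistics in glioVPA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glioVPA)
```

# The design this package models

A panel of glioma cell lines — classically seven established adherent
glioblastoma lines and seven stem-like lines — is profiled by RNA-Seq once
VPA-naive and once VPA-treated, with matched H3-acetylation ChIP-Seq. Each
line contributes exactly one treated/untreated library pair, so there is no
within-condition replication anywhere in the design. All inference in
glioVPA is built around that constraint:

* per-line differential calls use an exact test for a single pair of
  counts (Audic–Claverie);
* robustness comes from requiring calls in a majority of lines of *both*
  lineages, not from replicate variance;
* GSEA permutes gene sets, not phenotype labels, because there are no
  phenotype replicates to permute;
* the paired subtype comparison across lines uses an exact signed-rank
  test suited to n = 7 pairs.

# The Audic–Claverie test

Given `x` reads for a gene in a library of `N1` total mapped reads, the
count `y` in a second library of `N2` reads follows, under the null of
equal underlying expression,

$$p(y \mid x) \;=\; \left(\frac{N_2}{N_1}\right)^{y}
\frac{(x+y)!}{x!\,y!\,\left(1+\frac{N_2}{N_1}\right)^{x+y+1}}.$$

`acConditional()` evaluates this in log space via `lgamma` (factorials
overflow doubles beyond trivial counts); `acPValue()` accumulates the
`up` ($y' \ge y$) or `down` ($y' \le y$) tail with a streaming
log-sum-exp in compiled code, truncating the infinite upper tail when the
geometric remainder bound falls below $10^{-18}$ of the accumulated mass.
Two-sided p-values are twice the smaller tail, capped at 1. P-values far
below double underflow in any single term remain finite; results are
clamped into $(0, 1]$.

Two properties are worth knowing. First, the inclusive tails overlap in
the observed point mass, so `up + down = 1 + p(y|x)` exactly — the test
suite uses this as an internal invariant. Second, the two-sided p-value is
*not* symmetric under swapping $(x, N_1) \leftrightarrow (y, N_2)$, even
for equal library sizes: the swap exchanges a row tail for a column tail
through the same lattice point (at $N_1 = N_2$, $x=0, y=2$ gives $1/2$
versus $1/4$). Only the conditional point mass itself is symmetric at
equal library sizes.

The default alternative is `"up"`: up- and down-regulated gene lists are
reported separately in this field, and a one-sided test is the natural
unit for a directional consensus. The two-sided and down variants are
flags away.

## Multiple testing

Adjustment is Benjamini–Hochberg per cell line (`stats::p.adjust`),
recorded in output provenance. The commercial pipeline this analysis
pattern originates from does not document its adjustment; BH is the
field-standard choice for genome-wide screens and is stated explicitly
rather than guessed at in output.

## Fold changes

`foldChange()` works on counts-per-million with a pseudocount
(default 0.5 CPM): `fc = (cpm(y) + pseudo) / (cpm(x) + pseudo)`. The
pseudocount keeps ratios defined at zero counts and shrinks extreme
low-count ratios toward 1; increasing it moves every fold change
monotonically toward 1 (property-tested). Whether published fold changes
of this kind are computed on RPKM or normalized counts is generally
unstated; CPM with a declared pseudocount is the reproducible choice.

# Consensus filtering and fold-change tiers

A gene enters the consensus signature at tier `fc_cutoff` when it is
called up (q < 0.01, fold change at or above the cutoff) in at least
`min_support = 4` of the 7 adherent *and* at least 4 of the 7 stem lines.
Genes absent from one line's table simply count as non-supporting there.
Signatures are nested across tiers by construction
(`fc ≥ 5 ⊆ fc ≥ 4 ⊆ fc ≥ 3 ⊆ fc ≥ 2`), which the suite checks on random
panels. The same majority rule, applied to the promoter
euchromatinization call matrix, defines the epigenetically concordant
gene set; `fcTierTable()` reports both and their intersection per tier.

# Promoter windows and overlap calls

The promoter of a gene is the 1000 bp immediately upstream of its TSS,
ending at and excluding the TSS base: `[TSS-1000, TSS)` on the + strand,
`[TSS, TSS+1000)` on the −strand, clipped at the chromosome origin. No
base-level convention is universal here; the half-open reading is declared
once and used everywhere. Windows come from `GenomicRanges::promoters()`
and overlap calls from `findOverlaps()` with a configurable
`min_overlap_bp` (default 1 bp); the suite verifies the interval-tree path
against an all-pairs brute-force oracle on random instances. Differential
region calling itself (treated-vs-naive ChIP enrichment) is consumed as
BED input, not computed: it is upstream of this package's scope.

Coordinates live in `GRanges` (1-based closed) in memory, the Bioconductor
idiom; BED I/O converts at the boundary and round-trips bit-exactly, and
the half-open BED semantics are preserved in overlap behaviour (touching
regions do not overlap).

# Gene-family enrichment

`enrichmentTest()` defaults to Fisher's exact test on the table
`[[k, K], [n−k, N−K]]`: the `n`-gene candidate list (containing `k` family
members) is compared against the *whole genome* of `N` genes containing
`K` family members, with the genome column not reduced by the list. This
"list vs genome" convention is how such enrichments are typically quoted
in this literature (and is what reproduces published values of this form
exactly); the alternative "draw" convention — the list as a draw of `n`
from the universe, tail of Hypergeom(N, K, n) — is available via
`convention = "draw"` and differs modestly (the genome convention counts
the list in both margins). Sidedness defaults to the one-sided enrichment
tail; a point-probability two-sided variant is provided. The universe size
is user input: genome annotation universes are rarely distributed as id
lists.

# GSEA

`enrichmentScore()` implements the weighted Kolmogorov–Smirnov-like
running sum: walking the ranked list, hits add $|m_i|^p / N_R$ (with
$N_R = \sum_{hits} |m|^p$) and misses add $1/(N - N_h)$; the ES is the
deviation of largest magnitude. The default exponent is 1; 0 gives the
unweighted statistic. The ranking metric is the mean log2 fold change
across the per-line tables, sorted descending with lexicographic
tie-breaking, so rankings are deterministic.

The null is **gene-set permutation**: `n_perm` random same-size sets drawn
from the ranked universe. NES divides the ES by the mean magnitude of
same-sign null scores. The nominal p uses an add-one rule over the
magnitude of all null scores,
$p = (1 + \#\{|ES_{null}| \ge |ES|\}) / (n_{perm} + 1)$; this is never
zero, attains its floor $1/(n_{perm}+1)$ for a set stronger than every
permutation, and is calibrated — the suite verifies a rejection rate
within [0.03, 0.07] at $\alpha = 0.05$ over 500 random sets. (Counting
only same-sign permutations against an all-permutation denominator, a
formulation sometimes seen, roughly doubles the type-I error; glioVPA
deliberately avoids it.) FDR q follows the sign-matched pooled-null NES
recipe: the fraction of pooled null NES at least as extreme, divided by
the fraction of observed NES at least as extreme, capped at 1.

One practical note from the calibration experiments: gene sets scored
against a *shared* ranked metric have correlated enrichment scores, so
empirical rejection rates over many sets on one metric fluctuate more
than a binomial count would; the calibration experiment therefore pools
sets across several independent random metrics.

# Subtype scoring

The per-sample signature score is the mean over signature genes of the
per-gene z-scored $\log_2(\text{RPKM}+1)$ — the simplest monotone choice,
invariant to uniform affine rescaling of expression; genes with zero
cross-sample spread contribute 0. Published per-sample "enrichment" scores
of this kind are rarely defined precisely; the definition here is declared
rather than inferred. The subtype call is the argmax of the mesenchymal
and proneural scores ("indeterminate" on an exact tie). Treatment shifts
are tested per lineage with `wilcoxonSignedRankExact()` on the
(naive, vpa) score pairs across cell lines — per-sample scores across the
7 lines of a lineage, matching the granularity at which such p-values are
reported (n = 7 paired samples).

The signed-rank test drops zero differences, assigns mid-ranks to tied
magnitudes, and for up to 25 pairs computes the exact null distribution of
$W^+$ over all $2^n$ sign assignments by convolution (mid-ranks are
doubled to stay integral); beyond that a normal approximation with
continuity and tie correction takes over. The suite checks the exact path
against full enumeration for every n ≤ 12 and against
`wilcox.test(exact = TRUE)` on tie-free data.

# Dose–response pharmacology

`fit4PL()` fits the variable-slope model
$R(c) = b + (t - b) / (1 + 10^{(\log_{10}IC_{50} - \log_{10}c)\,h})$
by Levenberg–Marquardt least squares on all replicate points, after
normalizing fluorescence to the intra-plate no-drug control mean (=100%).
Initialisation is a deterministic multi-start grid (hill −0.5/−1/−2;
midpoint at the dose nearest the response midpoint and at the median log
dose) — no randomness. The fit is box-constrained to the geometry of a
decreasing viability curve: bottom at or above zero, both plateaus on the
correct side of the data midpoint, negative slope, midpoint within two
decades of the dose span. Without these constraints the lower plateau is
unidentified when the dose range barely reaches it, and IC50 estimates
under realistic noise become erratic; with them, noise-free curves are
recovered to numerical accuracy and the median IC50 error at 5% Gaussian
noise over 20 seeds is about 10%. Monotone-increasing responses are
flagged and reported non-converged, as are flat responses.

Both IC50 variants are reported: the curve midpoint (`ic50`, what
variable-slope fitting naturally yields) and the absolute concentration
giving 50% of control growth (`ic50_abs`, the common operational
definition), flagged when extrapolated beyond the fitted dose span. They
coincide only for a symmetric 0–100% curve. Sensitization is
`ic50Reduction() = 1 − IC50(VPA)/IC50(naive)`, positive when pretreatment
shifts the curve left.

`sirnaRescue()` computes, per siRNA, the VPA-induced temozolomide effect
as a ratio of ratios of mean proliferation readings and normalizes it to
the control siRNA (≡ 1); values above 1 indicate desensitization (the
presumed rescue). The statistic is scale-invariant per siRNA.
`ddctFold()` is the standard $2^{-\Delta\Delta C_T}$ with a reference
transcript and calibrator sample.

# Synthetic data: what it emulates and what it does not

The generators are pure functions of (parameters, seed), always produce
data that pass the package's own validation, and serialize a ground-truth
manifest next to every dataset.

* `simAnnotation()`: non-overlapping gene bodies with log-uniform lengths
  (500 bp–100 kb), random strands, exonic length a random fraction of the
  body.
* `simCounts()`: log-normal baseline abundances (median ~20 CPM,
  sdlog 1.5), library sizes uniform in 5–20 million reads, counts
  negative-binomial (dispersion 0.1) around abundance × depth. The NB
  default deliberately violates the Poisson sampling assumption of the
  Audic–Claverie test, stressing it the way biological data would; a
  Poisson mode exists for exact-calibration experiments (e.g. the
  majority-rule boundary test, where behaviour must be exact). A fraction
  of genes (default 5%) is planted as treatment-upregulated with log2
  effects drawn uniformly (default 1–3), each carried by a configurable
  number of lines per lineage — support is first-class so that the
  4-of-7 rule can be probed exactly at its boundary (4 vs 3 supporting
  lines). A designated family is preferentially planted. Optional subtype
  blocks add lineage-specific baselines and a cross-lineage treatment
  shift. For end-to-end recovery experiments the planted family effects
  are drawn at 4–8 fold (log2 2–3): genes planted at 2-fold cannot, by
  construction, robustly clear a 2-fold consensus cutoff in four of seven
  lines under NB noise, and the recovery experiments are meant to plant
  unambiguous signal.
* `simChipRegions()`: each concordant gene's promoter receives an
  overlapping region with a per-line concordance probability (default
  0.9), plus uniform background regions.
* `simDoseResponse()`: 4PL curves evaluated at eight doses spanning
  1–8000 µM in triplicate with Gaussian noise on the percent scale and
  control wells at 0 µM — the in-silico analogue of a 96-well resazurin
  plate.

What the generators do **not** emulate: GC/length biases and mappability,
gene–gene correlation, compositional effects of a few very highly
expressed genes, batch structure, ChIP signal strength (regions are
binary), or heteroscedastic plate effects. Passing tests on these data
demonstrate the statistical machinery recovers planted truth under the
stated noise model; they do not certify performance on any real dataset.

# Numerical choices and degenerate inputs

* AC tails: log-sum-exp accumulation; upper-tail truncation at a relative
  geometric remainder of 1e-18; p-values clamped to (0, 1].
* Zero-count fold changes are defined only with a positive pseudocount;
  `pseudo = 0` with `x = 0` is an error, not an Inf.
* PCA: variance ranking on `log2(RPKM+1)` by default (raw RPKM via flag);
  ties broken by gene id; per-component sign fixed so the
  largest-magnitude loading is positive; constant matrices are an error.
* Empty region sets yield all-FALSE call columns; a region chromosome
  absent from the annotation is a warning, not an error.
* Consensus with a lineage smaller than `min_support` is an error (the
  rule would be unsatisfiable).
* Wilcoxon: all-zero differences are a degenerate-input error; fewer than
  3 non-zero pairs is an error.
* GSEA: empty intersections and whole-universe sets are errors; `n_perm`
  below 100 is rejected.

# Problem sizes used by the test and acceptance suites

The suites run on simulated panels of 300–5000 genes and the full 14-line
design; the end-to-end recovery experiment uses five studies of 5000 genes
with a 30-member family (12 members planted) and 200 GSEA permutations per
set; the AC oracle grids cover all counts up to 200 at library ratios
0.5/1/2; overlap correctness uses 100 random instances of up to 1000×1000
intervals. These sizes were chosen to exercise every code path at
full-study shape while keeping a complete run in the minutes range on a
single CPU.

# Known limitations

* The Audic–Claverie test assumes Poisson sampling; on overdispersed data
  it is anti-conservative per line. The consensus rule absorbs much of
  this in practice, but per-line q-values on NB data should not be read as
  calibrated FDRs.
* Single TSS per gene: alternative promoters are not modelled.
* The fold-change definition (CPM + pseudocount) will differ slightly from
  pipelines that ratio RPKM or raw counts, most visibly at low counts.
* `fit4PL()` is purpose-built for decreasing viability curves; it refuses
  rather than fits increasing dose–response relationships.
* GSEA FDR q-values inherit the usual caveats of sign-matched pooled
  permutation nulls with few sets: with a handful of sets the observed-NES
  denominator is coarse.
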