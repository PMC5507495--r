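---
title: "Methods: from storage viability curves to a longevity module"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from storage viability curves to a longevity module}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedlong)
```

## The problem

Orthodox seeds acquire their storage life span (longevity) late in
maturation, after the end of seed filling. The phenotype is measured by
controlled deterioration: seed lots harvested at successive phenological
stages (7.1 through 9 in soybean, spanning roughly 57 to 77 days after
flowering) are stored at 35&deg;C and 75% relative humidity, and germination
is assayed over storage time on 4 replicates of 25 seeds. The longevity
statistic is **P50**, the storage time at which germination falls to half
its initial value. Over these stages P50 moves from essentially 0 days to
about 28 days at physiological maturity and about 48 days in the dry mature
seed.

`seedlong` links that trait to transcription: it normalizes an RNA-seq
count matrix over the same stages, builds a Pearson-correlation-thresholded
co-expression network over transcription factor (TF) genes, scores every
gene's **gene significance** (GS) — the absolute Pearson correlation
between its stage-mean expression profile and the P50 trajectory — and
extracts the module of TFs whose expression tracks the acquisition of
longevity. Around this core sit the supporting statistics such a study
needs: stage-wise differential expression, hypergeometric GO
over-representation, chi-square family enrichment, bin-wise Wilcoxon
enrichment with z-score conversion, Venn contrast algebra, sugar
(RFO/sucrose) ratios, and comparative 2^-ddCt qPCR quantification.

## The P50 estimator

Loss of viability during storage is sigmoid. We model pooled replicate
counts at storage time $t$ as Binomial with success probability

$$q(t) = \frac{1}{1 + e^{(t - m)/s}},$$

fitted by maximum likelihood (a binomial GLM of germination on time). P50
is the time at which the fitted curve crosses half the fitted *initial*
viability — the value at the earliest observed time, not an absolute 50
percentage points. With the logistic form this crossing has the closed form
$t = m + s \log(1 + 2e^{(t_0 - m)/s})$, which reduces to the midpoint $m$
whenever initial viability is near 100%. Anchoring at the earliest observed
time (rather than literal $t = 0$) makes the estimator exactly equivariant
to time shifts; the two definitions coincide on designs that include a
fresh control.

Choices worth knowing about:

* if the GLM does not converge (e.g. step-like curves), the estimate falls
  back to linear interpolation of the pooled observed proportions at half
  the initial proportion, taking the earliest crossing;
* if germination never falls below half its initial value within the
  observed window, the estimate is censored and reported as a lower bound
  at $\max(t)$;
* flat segments at exactly 50% resolve to the earliest crossing time.

On simulated 4 x 25-seed assays sampled weekly to 70 days, the estimator
recovers true P50 values of 28 and 48 days with a mean absolute error of
1-2% (the acceptance script recomputes this at run time).

## Normalization, filtering and differential expression

Size factors are median-of-ratios: the reference profile is the per-gene
geometric mean over samples (genes positive everywhere), each sample's
factor is its median count ratio to that reference, and factors are
rescaled to geometric mean 1. A consequence of that rescaling is that
multiplying one library by a constant changes the normalized matrix by a
single global factor while preserving all relative expression; tests assert
exactly this.

The expression layer used everywhere downstream is
$\log_2(\text{normalized} + 1)$; the pseudocount is configurable. Genes are
retained when their log2-scale variance across samples is strictly greater
than 1 — a threshold that is only meaningful on a log scale, which is why
the filter is defined there. Low-variance reference genes (the qPCR
normalizers) sit far below this cutoff by design.

Differential expression is a deliberate approximation of a DESeq2-style
analysis, simple enough for its operating characteristics to be verified by
simulation: a per-gene Wald test of the log ratio of normalized group
means, with variance from the negative binomial model
$\mathrm{Var}(K) = \mu + \alpha\mu^2$ and a *single pooled dispersion*
$\alpha$. When not supplied, $\alpha$ is estimated by method of moments
from the replicated groups as the ratio of summed excess variances to
summed squared means. We pool moments rather than averaging per-gene
estimates because with two replicates each per-gene estimate has roughly
one degree of freedom; the median of such estimates is severely biased low
and inflates the type-I error several-fold, while the pooled ratio is
nearly unbiased (type-I error about 0.055 at nominal 0.05 in the
calibration suite). There is no shrinkage and no per-gene dispersion trend;
significance requires both an adjusted p below alpha (BH) and a fold change
of at least the threshold, with the two-fold boundary *inclusive*. The
fold change is the plain ratio of group means (offset-stabilized only at
zero means) so that an exact two-fold ratio sits exactly on the threshold.

Sample-level diagnostics are the pairwise Pearson correlation matrix of the
log2 layer and a median-centered PCA (per-gene median subtracted, SVD). The
PCA sign convention — the largest-magnitude loading of each component is
positive — exists purely so coordinates are reproducible across runs.

## Network, gene significance, longevity module

Network edges connect TF genes whose log2 expression profiles across all
libraries have Pearson correlation of at least 0.97, positive correlations
only; the boundary is inclusive, since a published cutoff of "0.97" does
not specify strictness and inclusivity is the weaker reading. Nodes are
genes with at least one qualifying edge. No layout is computed — the graph
is exported (edge list, GraphML) for external viewers.

GS is computed on *fresh-stage means*: replicates are averaged per stage
first, so replicate imbalance cannot weight the correlation, and the
rapidly-dried 7.2 sample is excluded because it has no position on the
developmental P50 trajectory. At least 3 stages are required; with fewer,
a correlation against a trait vector is too unstable to be meaningful, and
the function refuses. The longevity module is the set of network nodes with
GS strictly above 0.9; family composition and induced edge density are
reported with it.

## Enrichment statistics

* **Chi-square family enrichment**: per TF family, a 2x2 Pearson chi-square
  (1 df, no Yates correction — matching common tool behaviour) of cohort
  membership against the TF background, plus the family's share of the
  cohort.
* **Hypergeometric GO tests**: upper tail $P(X \ge k)$ for
  over-representation, lower tail for under-representation; the reported
  direction is the side on which the observed count falls relative to its
  expectation. The genome size $N$ is the number of genes in the supplied
  annotation table. Annotations are consumed as already-propagated
  gene-to-term lists; no ontology graph traversal is attempted. Because the
  correction behind published "corrected P-values" of this kind is often
  unnamed, both BH and Bonferroni are available and the choice is explicit.
* **Bin-wise Wilcoxon**: each functional bin's per-gene statistic
  (stage-wise log2 expression change) is rank-sum tested against all other
  genes, two-sided. Bins smaller than 10 use exact enumeration of the
  permutation distribution of the rank sum (which handles ties correctly);
  larger bins use the normal approximation with tie correction. P-values
  are Bonferroni-corrected over bins and converted to signed z-scores,
  $z = \Phi^{-1}(1 - p/2)$ with the sign of the bin's median shift, so a
  corrected p of 0.05 maps to |z| = 1.96.

## The synthetic-data generator

The generator exists so that every stage of the pipeline can be tested
against known ground truth. Its defaults encode the study design it
emulates: 10 libraries (stages 7.1, 7.3, 8.1, 8.2 single; 7.2 and 9
duplicated; a duplicated rapidly-dried 7.2 sample), a P50 trajectory of
0/28/33/38/43/48 days over the six fresh stages (the 0, 28 and 48 endpoints
are the published trait values; intermediate stages are interpolated), 32
TF families, and 4 x 25-seed viability assays.

Latent log2 stage means contain four planted cohorts among 2000 genes:

* a **longevity module** (27 genes) whose log2 means are an affine function
  of the P50 trajectory (dynamic range 8 log2 units) plus stage-wise
  Gaussian noise (sd 0.25) — at these settings latent profiles correlate
  with P50 at about 0.99, so the module is recoverable but not trivially
  noise-free;
* a **transient tail** (80 genes) with Gaussian bumps (4.5-6.5 log2 units,
  width 3 days) centred between stages 7.2 and 7.3, family-sampled with
  AP2/EREBP and WRKY up-weighted (about 19% and 11% of the tail);
* a **chloroplast-like cohort** (111 genes) starting high and decaying
  monotonically after stage 7.1;
* **reference genes** (50) flat with log2 variance well under 0.1, plus
  random-walk filler genes of which roughly half pass the variance filter.

Counts are negative binomial with a single dispersion (default 0.05, a bulk
RNA-seq scale consistent with biological replicates that are 97-98%
similar) around library-size-scaled stage means; library sizes are
log-uniform on [0.5, 2]. The rapidly-dried 7.2 sample's latent means are a
60/40 mixture of the 7.3 and 8.1 stage means, emulating the observation
that premature drying fast-forwards the transcriptome to between those
stages; the weight is configurable.

Viability curves are logistic in time with the per-stage scale growing
proportionally with P50 (floored at 0.5 days), so a stage with P50 = 0
loses essentially all viability immediately — matching the phenotype of
seeds harvested before longevity is acquired. Replicate counts are
Binomial(25, q(t)).

Sugar tables follow the published chemistry qualitatively: glucose and
fructose decline to near zero, stachyose rises (plateauing in the axis,
declining late in cotyledons), sucrose declines in the axis, so the axis
RFO/Suc ratio is non-decreasing. Replicate noise is one multiplicative
factor per row applied to all sugars, which preserves the RFO/Suc ratio
exactly — a deliberate construction standing in for per-extraction
efficiency variation.

What the generator does **not** emulate: read-level artefacts (GC/length
bias, mapping ambiguity), per-gene dispersion trends, batch effects,
between-field biological variation (seeds in the emulated design are pooled
from up to 200 plants, and the replicate noise level is a free knob), or
real genome annotation. Gene ids follow a deliberately synthetic
`SYN.01G000001` pattern. Passing tests therefore demonstrate that the
statistics are implemented correctly and are well calibrated under the
stated generative model — not that the model captures every feature of real
seed RNA-seq data.

## Problem sizes and numerical conventions

The test and acceptance suites run at sizes chosen to exercise the
statistics at stable operating points while completing quickly: 2000-gene
matrices for recovery runs (20 seeds), 500-gene matrices for DE calibration
(200 replicates of 2-vs-2 contrasts), 200 replicates for P50 recovery.
Percentages are rounded half-up to match how published tables print them;
BH/Bonferroni go through `stats::p.adjust`; the hypergeometric tails through
`stats::phyper`; the chi-square through `stats::chisq.test`; components and
GraphML through `igraph`. Determinism is by explicit seeding: all
generators set the RNG from `config$seed` (offset per generator), so equal
seeds give bit-identical output.

## Known limitations

* The DE test's single pooled dispersion under-serves genes whose true
  dispersion departs strongly from the pool; with many replicates a
  per-gene or trended estimate would dominate. The design target here is
  the 1-2 replicate regime of the emulated study.
* The P50 logistic fit assumes monotone decay; dormancy-release patterns
  (transient rises in germination) would be fit poorly and fall back to
  interpolation.
* GS on six stage means is a correlation over six points: its sampling
  variability is substantial, which is exactly why the module criterion is
  evaluated as average precision/recall over seeded replicates rather than
  per-run.
* The network uses hard thresholding, not WGCNA-style soft thresholding or
  topological overlap; no claim of scale-freeness is computed.
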