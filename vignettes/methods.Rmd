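---
title: "Methods: differential histone-mark analysis and expression integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential histone-mark analysis and expression integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(markdiff)
```

## Scope and model

markdiff analyses a two-group (case/control) design with a broad
repressive histone mark measured by ChIP-seq and matched mRNA-seq on the
same subjects. Counts over genomic regions (consensus enrichment domains,
promoters, gene bodies) or genes are modeled as negative binomial,
`x_gk ~ NB(mean = s_k μ_g, dispersion φ)`, with a single common φ shared
across rows. This is the simplest model that accommodates the
biological overdispersion of replicated tissue samples; tagwise or
trended dispersion shrinkage is deliberately out of scope, as is any
GLM/covariate machinery (age, PMI and similar covariates cannot be
adjusted for here).

Both data layers run through one chain: TMM normalization → common
dispersion → conditional exact test → permutation fold-change cutoff →
call at `p < α` **and** `|log2FC| > cutoff`. Symmetry between the layers
is itself a design decision: the expression side mirrors the
histone-mark criteria exactly, and the criteria actually used are
recorded in each fit's `glance()` and in the workflow metadata.

## Coordinates and gene models

All interval arithmetic is 0-based half-open (BED convention); GTF input
is converted on read. Multiple transcripts collapse to the outermost
TSS/TES with the union of exons and CDS — the analysis is gene-level
throughout and a single TSS/TES per gene keeps promoter and body
definitions unambiguous. Promoters are the 3 kb strictly *upstream* of
the TSS (not a window around it); gene bodies run TSS to TES. Overlap
between a promoter and a neighbouring gene's body is resolved by the
fixed precedence CDS > UTR > intron > promoter > intergenic (the
ordering is configurable in `classify_positions()`); "UTR" operationally
means exonic non-coding sequence, so the three body categories always
partition the body. Both promoter and body regions are emitted for every
gene regardless of overlaps with other genes — no ambiguity filter is
applied.

Metagene coordinates span 5 kb upstream of the TSS to 5 kb downstream of
the TES in 100 bins; a width remainder of r bp widens the r most-5′ bins
by 1 bp so the bins tile the span exactly. Bin 1 is always the 5′-most
bin in transcription direction. Profiles default to raw mean counts per
bin; a per-bp normalization flag exists because bin widths differ across
genes.

## The statistical core

**TMM.** Implemented from the published definition (two-sided rank-based
trims of 30% on M and 5% on A, inverse delta-method precision weights,
factors centered to product one, reference = sample whose
75th-percentile count fraction is closest to the mean). M and A are
computed as differences/sums of `log2(x/N)` terms; the algebraically
equivalent single-log form differs in the last ulp and can flip a rank
at a trim boundary, so the formulation is fixed and the test suite holds
the implementation to an independently coded oracle at 1e-8.

**Dispersion.** Default is a trimmed (10% per side) mean over rows of
the within-group method-of-moments estimate
`max(0, (s² − x̄)/x̄²)` on counts scaled to a common effective library,
groups pooled by degrees of freedom. It is simple, fast and
oracle-testable; a profile-likelihood estimator (per-row group means
profiled out, φ optimized on [1e-6, 30]) is available via
`method = "profile"`. On an all-constant matrix both return 0 with a
warning.

**Exact test.** Counts are rescaled to the geometric-mean effective
library (`f_k N_k`) and rounded half-even (R's `round()`), so the group
sums live on one scale. Conditional on the row total, split
probabilities come from NB group-sum distributions
(`size = n_i/φ, mean = n_i μ̂`, with `μ̂ = S/(n_A+n_B)`); φ = 0 reduces to
the exact binomial split. The two-sided p-value sums the probabilities
of all splits no more likely than the observed one, with a 1e-8 relative
slack on the equality comparison to absorb floating-point ties between
symmetric splits. A row of all zeros gets p = 1. Fold-changes use
normalized group means augmented by a prior count of 0.5, preventing
infinite values at zero counts; |log2FC| (absolute scale) is what the
cutoff is applied to.

**Permutation cutoff.** Sample labels are reassigned into groups of the
original sizes; in a 6-vs-6 design only C(12,6) − 1 = 923 distinct
non-identity relabelings exist, so for the default 1000 rounds the
distinct splits are enumerated and sampled without replacement first,
then resampled; the count of distinct splits is recorded in the result.
Per-relabeling |log2FC| values for all rows are pooled, and the cutoff
is a quantile of that pool. Two modes exist because "10th percentile of
the fold-change distribution" is genuinely ambiguous: `literal` (the
default) takes the 10th percentile — an extremely permissive threshold,
typically near 0.03 on null-like data — while `upper_tail` takes the
90th percentile, the conventional null-tail reading. The mode used is
always recorded in output metadata.

A consequence worth stating plainly: with the literal cutoff the
fold-change filter is essentially vacuous and the procedure's false
discovery rate is governed by the raw `p < .05` rule alone, so the FDR
among calls depends strongly on how many rows truly change. The
package's recovery benchmark (tests and acceptance script) therefore
plants effects in 25% of rows at |log2FC| = 2 (mean count 100, φ = 0.1,
6 vs 6) and uses the upper-tail mode; under sparser alternatives (say
10% of rows) no pooled-quantile cutoff near the 90th percentile can hold
FDR under 15% at this α, and users who need strict error control should
use the `p_adjust = "BH"` flag instead of raw p-values.

## Peaks and consensus

The domain caller is intentionally minimal, matching the character of a
broad mark: fixed non-overlapping windows (default 1 kb), one
genome-wide Poisson background rate (total tags / windows), windows with
upper-tail probability below 1e-3 kept, significant windows within 1 kb
merged. There is no local background, fragment-shift model or
FDR-calibrated threshold; externally produced peak BED files can be
substituted anywhere a peak set is consumed. Consensus regions keep the
genome bases covered by peaks from ≥2 distinct samples (per-base
semantics, oracle-testable); because the external tooling this replaces
aligns whole peaks rather than bases, an alternative `union` mode keeps
every peak that overlaps peaks of enough other samples. Both are
documented rather than asserting which the original tooling used.

## Gene calls and integration

Method 1 maps passing consensus regions to genes by ≥1 bp gene-body
overlap ("including" is read literally; a flag extends the footprint to
promoters). Method 2 calls genes from promoter and body count matrices
directly. The union of the three sets is the differentially marked set;
per-gene direction comes from the most significant supporting call
(smallest p, ties by larger |log2FC|, then region id/method order), and
genes supported in conflicting directions carry an explicit flag. The
divergent sets are pure set operations on the call table — mRNA up with
mark down, and the mirror — and genes with concordant changes stay in
the common set but in neither divergent set. Direction attribution by
minimum p across regions is a package decision (the alternatives —
promoter-only or body-only attribution — are not obviously better and
are recoverable from the evidence table).

Expression strata rank genes by cross-sample mean normalized expression,
excluding genes shorter than 5 kb *before* taking the top/bottom sets
(the default 1000 per set shrinks with a warning when fewer genes
qualify); ties break by gene id so the sets are reproducible. Stratified
profiles pool tags across samples by default. The mark–expression
correlation is Spearman on per-gene mean normalized body (default)
counts versus expression. Clustering of divergent genes' (Δmark, ΔmRNA)
vectors uses Ward's linkage on Euclidean distances
(`hclust(method = "ward.D2")`), verified in tests against an independent
Lance–Williams recursion; dendrograms export as Newick. Cell-type
partitions intersect the common set with user-supplied marker lists —
marker derivation from single-cell data is input, not computation.

## The synthetic-data generator

The generator emulates the study conditions end to end: 6 + 6 samples;
200 genes (lengths log-uniform 2–50 kb, so genes on both sides of the
5 kb profile filter exist) on two 4 Mb chromosomes; NB counts with
φ = 0.1 and mean region count 100 (`library_size_mean = 100 ×
n_regions`), per-sample library factors lognormal with CV 0.2; planted
effects of |log2FC| = 2 split as ±Δ/2 between the groups so overall
abundance is preserved; 10% of genes carry a mark effect and 15% an
expression effect, with half of the smaller effect set inversely coupled
(opposite signs) — proportions that echo, at desk scale, the relative
sizes of the marked, expressed and common gene sets a study of this
design reports. A per-gene latent abundance shared between layers with
correlation −0.6 gives highly expressed genes systematically lower mark
levels, the repressive-mark signature that the stratified profiles and
the correlation analysis detect. Tags are single-base positions (read
midpoints) placed uniformly within their region, which makes
tag-counting round-trips exact and unambiguous; a uniform genome-wide
background rate is available (default 0).

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: mappability and GC bias, fragment-size
effects, copy-number variation, centromeric/repeat artifacts, batch
structure, cell-type composition differences between groups, and any
non-uniform within-region tag placement. Results on real libraries
depend on upstream alignment and filtering choices the package only
consumes.

## Numerical choices and problem sizes

Rounding of rescaled counts is half-even; quantiles are R type 7;
p-value equality uses 1e-8 relative slack; prior count 0.5; permutation
seeds are explicit arguments and the workflow derives per-stage seeds
deterministically from one integer. Degenerate inputs are defined:
empty tag sets give empty peak sets, all-constant matrices give φ = 0
with a warning, zero-total rows give p = 1 and are never called, fully
clipped promoters at chromosome edges become zero-width intervals that
count zero tags.

The test suite and acceptance script run at deliberately desk-scale
sizes chosen as the package's own benchmark conditions: 200-gene
workflows, 1000–2000-row matrices for calibration checks (type-I rate,
dispersion recovery), 5 replicate seeds for the recovery benchmark, 20
randomized instances for each exact set-logic and consensus oracle
comparison, and oracle enumeration of every exact-test instance with row
totals ≤ 200. These sizes give stable pass/fail behavior under fixed
seeds while keeping a full run in minutes.

## Known limitations

Raw `p < .05` without multiple-testing correction follows the procedure
this package operationalizes; BH adjustment is available but off by
default. The common-dispersion model understates per-row variance
heterogeneity. The domain caller's global background will over-call in
genomes with large-scale coverage trends. The headline gene counts of
any particular tissue study are functions of its library depth, genome
and annotation and are not reproducible from synthetic data; what the
package guarantees is the correctness of each operation against
independent oracles and the recovery of planted truth under its stated
simulation conditions.
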