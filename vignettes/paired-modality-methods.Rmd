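---
title: "Methods: paired comparison of single-cell and single-nucleus RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired comparison of single-cell and single-nucleus RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnpair)
```

# The problem

Profiling the same donors' pancreatic islets twice — fresh tissue as whole
cells (scRNA-seq) and frozen tissue as nuclei (snRNA-seq) — yields two
views of the same biology that disagree in systematic ways: nuclei carry
almost no mitochondrial or ribosomal transcripts, are enriched for
intronic (nascent) reads, and deplete the classic cytoplasmic marker
mRNAs (*INS*, *GCG*, *SST*, *PPY*, *PRSS1*, *KRT19*) that annotation
references were built on. `scnpair` implements the comparison framework
for such designs: a shared QC cascade, marker discovery with explicit
gates, UMI-threshold detection comparison, annotation-concordance metrics,
and donor-level paired statistics. Because real paired donor data of this
kind sit under restricted access, the package also owns a synthetic
generator that reproduces the design's qualitative structure with known
ground truth, so every stage is testable.

# Quality control

Per barcode we compute the feature count (genes with ≥ 1 UMI), total UMI
count, complexity `log10(features)/log10(counts)`, and mitochondrial /
ribosomal count fractions over *all* genes (including MALAT1, which is
only removed from the matrix after filtering — so the QC metrics match
what was measured pre-normalization). Complexity is undefined for
barcodes with fewer than 2 counts; such barcodes necessarily fail the
count threshold, so no separate rule is needed.

The cascade order is fixed: per-sample gene-prevalence filter (default ≥
10 barcodes per feature), initial ≥ 200-feature barcode filter, doublet
removal (doublet calls are *inputs* — from a doublet predictor on real
data, from ground truth on synthetic data), then the threshold block
(features ≥ 500, counts ≥ 500, complexity ≥ 0.80 — the rule is strictly
"below 0.80 fails", so a barcode at exactly 0.80 is retained —
mitochondrial fraction ≤ 5%, ribosomal ≤ 35%), then MALAT1 removal. The
gene-prevalence rule is a single pass and deliberately not re-applied
after barcode removal; a second application can therefore remove further
genes, which is why the idempotence property is checked on the cascade
proper. Removed barcodes record *every* failed criterion, not the first,
because per-criterion accounting across overlapping reasons is how such
tables are reported.

All quantile summaries (sample summary tables, score summaries) use the
type-7 linear-interpolation convention, R's default; at reported
precision the choice is immaterial, but it is pinned so oracles are
exact.

# Normalization and marker gates

Counts are log-normalized as `ln(1 + c / total · scale)` with scale
10,000. Marker discovery is group-vs-rest: genes are screened to those
detected (count ≥ 1) in at least `min_pct` of the group (0.25 in the
loose cluster pass, 0.50 in the strict cell-type pass) with
`|avg_log2FC| ≥ 1`, where

`avg_log2FC = log2(mean(expm1(x_group)) + 1) − log2(mean(expm1(x_rest)) + 1)`

— the Seurat-v4-style formula, documented here because the fold-change
definition materially affects which genes are tested. Survivors get a
two-sided Wilcoxon rank-sum test on the normalized values and BH
adjustment *within the tested family per group* (pre-filtering before
testing changes the BH family, so it must be pinned). The gated marker
output keeps `fdr < 0.05` and `avg_log2FC > 1`. `pct.2` defaults to the
detection fraction over the pooled complement; an unweighted per-type
mean is available as an option since both readings of "average across all
other cell types" are defensible. Note the deliberate coexistence of two
detection thresholds: `pct.1/pct.2` use UMI ≥ 1 (the marker-test
convention), while the "expressed" rule in the detection module uses
UMI ≥ 3.

For pooled sizes up to 50 the rank-sum p-value is exact: the permutation
distribution over subsets is built by dynamic programming on doubled
midranks, which reproduces full enumeration at polynomial cost and
respects ties; above 50 a normal approximation with midrank tie
correction and continuity correction is used. The two agree within 0.02
at small n (a tested property). Constant genes give p = 1. BH itself
delegates to `stats::p.adjust`; an independent sort-based step-up
implementation lives in the test suite as the oracle.

# Detection comparison

A gene is "expressed" in a scope if any barcode has ≥ 3 UMIs (variant: in
≥ 10% of barcodes). Detection operates on raw counts of the post-QC
matrix — an integer threshold must not see normalized values — and the
modality partition (both / cell-only / nucleus-only) is reported as
percentages of the union, rounded half-up to integers as in printed
summaries, while stored values keep full precision. Whether the gene
universe is pre- or post-QC filtering changes the denominators; this
implementation computes on the post-QC matrix and says so.

# Annotation concordance

Labels from different annotation methods are first harmonized
(ductal variants → ductal, gamma+epsilon → gamma, mast/macrophage →
immune, stellate/Schwann variants → mesenchymal; alpha and beta stay
distinct, alpha+beta is its own category). Unmapped labels are an error
listing the offenders rather than a silent pass-through, unless
explicitly whitelisted. Agreement is quantified three ways:

* directed overlap: `100 · |A∩B| / |A|` per type — asymmetric by
  construction, both directions share the intersection count;
* per-type Jaccard `|A∩B| / |A∪B|` and its unweighted mean over types
  with nonempty union (a size-weighted mean is optional);
* weighted Jaccard on composition vectors, `Σ min(pₖ,qₖ) / Σ max(pₖ,qₖ)`.
  The min/max (Ruzicka) form is the standard proportion-aware "weighted
  Jaccard"; it is symmetric, bounded by 1 with equality iff the
  compositions coincide, and is the definition used throughout —
  flagged here because the name alone does not pin a formula.

Barcodes unlabeled by one method are excluded pairwise-complete from that
pair's comparisons. Per-donor weighted-Jaccard blocks are emitted for
both groupings — modality-vs-modality within a method, and
method-vs-method within a modality — since either contrast can be the
question of interest. Prediction/mapping scores are consumed as input
columns in [0, 1]; no reference mapping is computed here.

# Paired donor-level statistics

Per-barcode metrics are first collapsed to one value per donor and
modality (mean by default, median optionally) to avoid pseudo-replication;
differences are always nucleus − cell, so negative shifts mean lower
values in nuclei. The location estimate is the Hodges–Lehmann shift. Two
estimators are provided because the two common definitions disagree at
n = 4: `walsh`, the classical HL estimator (median of all n(n+1)/2 Walsh
averages), and `plain_median` (median of the differences). For the
shipped donor summary metrics the intronic and mitochondrial shifts round
identically under both, while the features-per-barcode shift rounds to
2478 only under the Walsh estimator (plain median: 2454.5). `walsh` is
therefore the default and every result row names the estimator it used.

Significance uses the exact paired Wilcoxon signed-rank test: zeros
dropped, midranks on |d|, and for n ≤ 25 the full 2ⁿ sign-assignment null
computed by subset-sum dynamic programming (the test suite checks it
against literal enumeration and against `stats::wilcox.test` in the
tie-free case); larger n uses the tie-corrected normal approximation.
With four same-sign pairs the two-sided p is exactly 2/16 = 0.125 — the
floor of the design — which is why effect sizes and intervals, not
p-values, carry the conclusions at this scale.

Uncertainty comes from a percentile bootstrap: donors (difference values)
are resampled with replacement, the HL estimate recomputed per resample,
and the 2.5/97.5 empirical percentiles reported; 10,000 resamples by
default, fully determined by the seed. At n = 4 the resample space is
finite (4⁴ = 256 equally likely draws), and the tests verify the
percentile endpoints against that exhaustive enumeration. The percentile
interval may exclude the point estimate at tiny n; this is logged, not
"corrected". BH adjustment is applied within declared analysis families.

# The synthetic generator

Each singlet barcode draws a cell type from its donor's composition, a
log-normal library size, and Poisson counts with per-gene mean
`libsize · ((1−a)·profile(type) + a·soup) · bias`, where `a` is the
sample's ambient fraction and the soup is the composition-weighted
average of the sample's own type profiles — so the soup is INS-dominated
exactly when beta cells dominate, as in islets. Doublets are the
elementwise sum of two distinct singlet barcodes of the same sample, so
count conservation is testable from the emitted matrix and truth alone.
Poisson sampling (rather than negative binomial) is the simplest model
that exercises every downstream statistic; overdispersion would change
power but not the correctness properties the suite asserts.

The gene universe defaults to 2,000 genes: 10 types × 15 canonical
markers (the first four types are beta/alpha/delta/gamma with INS, GCG,
SST, PPY as their lead markers), 40 nuclear-enriched genes, 13 `MT-`
genes, 50 `RPL/RPS` genes, MALAT1, and background. Every type allocates
the same total mass per gene class, which makes expected mito/ribo
fractions exact by construction; each type's own markers are enriched
4-fold (log2 = 2) over the mean of the other types, and the lead marker
carries 85% of the type's marker budget so hormone genes dominate their
cell types and the soup. Modality effects resolve to a per-gene bias
vector: mito and ribo classes are pinned so the expected count fractions
hit their targets exactly (cells 3.4%/8.6%, nuclei 0.05%/0.2%), canonical
markers are depleted (×0.35) and nuclear-enriched genes elevated (×2.5)
in nuclei, and the remaining block is rescaled so expected library size
is preserved. Ambient fractions (1–7%), doublet rates (3–14%) and
intronic fractions (cells ~19%, nuclei ~54%; emitted as per-sample
metadata only, not modeled at read level) vary per donor within the
ranges the design targets.

What the generator does *not* emulate: read-level structure
(splicing/introns), batch or integration manifolds, realistic
transcriptome-wide rate calibration, negative-binomial overdispersion by
default, and the empirically low cross-modality marker overlap —
class-level biases shift marker *levels* between modalities but mostly
preserve rank order within a type, so synthetic marker lists agree across
modalities far more than real ones do. Passing tests therefore
demonstrate correctness of the statistical machinery under a known model,
not that real cells and nuclei behave like the model.

# Sizes, seeds and numerical choices

Test and example runs use scaled-down designs chosen to exercise every
code path at seconds-to-minutes scale: 2–4 donors, 60–2,000 barcodes per
sample, 60–2,000 genes. The marker-recovery check uses the full default
universe at ~200 barcodes per type; the modality-effect sign-recovery
check uses 100 seeded replicates of a 4-donor, 60-barcode, 300-gene
design with reduced library sizes (~500/220 counts per barcode) so that
feature counts do not saturate the small universe. All randomness flows
through one explicitly seeded generator; identical seeds give
byte-identical matrices and results. MTX files are 1-based on disk and
converted at the boundary; TSV output stores doubles at 17 significant
digits so read-back compares equal; gene symbols are matched
case-sensitively; mito/ribo gene sets are explicit lists, with `MT-` /
`RPL|RPS` prefix helpers provided.

# Known limitations

Ambient-RNA estimation, doublet prediction, clustering, integration and
reference label transfer are consumed as inputs, never computed.
The directed-overlap denominator for published "overlap %" summaries of
marker *lists* is ambiguous in the field; all three denominators
(Jaccard, |A|, |B|) are implemented and reports state which is used.
Inference at n = 4 donors is floor-limited (smallest exact two-sided
p = 0.125); the package reports effect sizes with bootstrap intervals for
exactly that reason, and the bootstrap itself is coarse at such n — its
endpoints are best read as attainable-range summaries.
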