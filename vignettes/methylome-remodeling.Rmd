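---
title: "Methods: integrative 5hmC/5mC remodeling analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative 5hmC/5mC remodeling analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and data model

`epiremodel` implements an integrative analysis of brain methylome
remodeling between a mock and a treated group, built around five data
carriers:

* `bin_counts` — integer read counts of an enrichment assay (5hmC pull-down,
  MeDIP) over a fixed-width binned genome, with per-sample group labels and
  library sizes;
* `cpg_site_table` — per-CpG (methylated, total) read counts per sample for
  base-resolution 5mC;
* expression tables — per-gene mean normalized counts, log2 fold change, p
  and FDR from a bulk differential-expression fit;
* a cells × genes count matrix with cluster and group labels for
  single-nucleus data;
* interval annotations (gene models with exons and immediate-early-gene
  flags, CpG islands, repeat elements with class labels, chromatin-state
  segments).

All coordinates are 0-based half-open internally, which is also the BED
convention, so interval files pass through the readers unchanged. Reads are
assigned to bins by their fragment midpoint so each read contributes to
exactly one bin and totals are conserved; terminal bins clipped below half
the bin width are flagged and excluded from differential testing to avoid
density inflation on short chromosome tails.

# Differential 5hmC calling

Counts in 500 bp bins (the default width; any width is supported) are
compared between groups with an exact negative-binomial test:

1. Library sizes are equalized by linearly scaling each sample's counts to
   the geometric-mean library size. This is a simplification of full
   quantile-adjusted conditional maximum likelihood (qCML): the NB-quantile
   mapping is replaced by linear scaling, which is accurate when library
   sizes are within a modest factor of one another, as replicate enrichment
   libraries normally are. The adjusted group sums are rounded for the
   conditional enumeration.
2. A single common dispersion is estimated by maximizing the conditional
   log-likelihood of the adjusted counts given per-group bin totals,
   optimized one-dimensionally on the shrunken scale
   $\delta = \phi/(1+\phi)$. Tagwise or trended dispersion is out of scope.
3. Each bin's adjusted group sums are tested conditionally on their total:
   the null distribution of the treated sum is the NB-convolution
   conditional law (a conditional binomial when $\phi = 0$), enumerated
   exactly over the support. Two-sided p values double the smaller tail
   (including the observed point) and are capped at 1 — the standard
   convention for conditional exact tests. The fold change is
   $\log_2\!\frac{\bar y_T + 0.5}{\bar y_M + 0.5}$; the 0.5 pseudo-count
   enters the fold change only, never the test.
4. Benjamini–Hochberg adjustment is applied over all tested bins;
   significant bins (FDR < 0.05) become directed region calls and adjacent
   significant bins of the same direction are merged (gap of zero bins;
   a flag reports unmerged bins instead, since either reading of
   "differential regions" is defensible).

Genome-wide context is summarized by an ordinary least-squares regression of
treated on mock group-mean CPM over all bins (a slope below 1 indicates
global loss) and by strand-aware, length-normalized meta-profiles over
region sets with an unpaired t test of per-region means.

# DMR calling

Per-CpG differential methylation uses a beta-binomial likelihood-ratio test.
The shared concentration $\theta$ is estimated **once per table** by pooling
the within-group residual variance of per-sample methylation proportions
across sites (method of moments, intra-class correlation clamped to
$[10^{-3}, 0.5]$) and is held fixed in both the common-mean and
group-specific-mean fits. Two numerical properties motivated this design
over a free per-site profile likelihood:

* at a site with perfectly separated groups the likelihood is flat in
  $\theta$, and a per-site profile can wander to tiny concentrations where
  the *null* model gains pathological likelihood (the test then reports
  p ≈ 0.004 for data as extreme as 0/30 vs 30/30 pooled, where the evidence
  is overwhelming);
* a six-observation dispersion estimate is so noisy that per-site power
  collapses even at a true shift of 0.3.

Residual moments are taken around each group's own mean, so a real group
shift cannot masquerade as overdispersion. With the concentration fixed,
each model only moves its mean(s) (1-D likelihood maximizations), the
models are nested, and the statistic is referred to $\chi^2_1$.

Site flagging mirrors the two-step convention of regression-based
methylation callers: each site's signed z score is combined with neighbors
within 100 bp by Stouffer's method (isolated sites are unchanged; the
radius is configurable and 0 disables the step), then BH adjustment across
all tested sites flags DM sites at adjusted p < 0.05. Without this step,
isolated site noise fragments true DMRs: a single missed interior CpG can
open a ≥ 100 bp gap and split a region below the site-count filter.

DMR construction then follows the merge-and-filter rule: consecutive DM
sites strictly less than 100 bp apart chain into candidates (non-DM sites
inside a span are recorded but do not break the chain; distance is
site-to-site); candidates are retained when they contain more than 5 DM
CpGs and the absolute mean methylation difference over DM sites exceeds
0.2. A sign-consistency guard (≥ 80% of DM sites sharing the majority
sign) is applied by default because the literal rule could admit
mixed-direction candidates; `sign_consistency = NULL` restores the strict
literal behavior. Sites with pooled per-group coverage below 10 are
skipped and reported.

# Annotation and enrichment

Regions are annotated at their midpoint with fixed precedence
promoter > 5′UTR > exon > 3′UTR > TTS > intron > intergenic, with the
promoter window TSS−2000..TSS+500 and the TTS window extending 1000 bp past
the transcription end, both strand-aware and configurable. UTR categories
are part of the vocabulary but are only populated when UTR intervals are
supplied; the bundled gene models carry exons only. CpG-island and repeat
overlap are orthogonal any-overlap flags, with the repeat class taken from
the longest-overlap element. Chromatin-state enrichment builds a 2×2 table
per state label (query vs background × overlaps vs not) and applies a
two-sided Fisher exact test with BH adjustment; odds ratios are the sample
cross-product ratio, so swapping query and background inverts them exactly.
Repeat elements overlapping differential 5hmC calls are labeled by the
direction with the larger total overlap (ties resolve toward gain) and
summarized as gain fractions per class; their expression response is
cross-tabulated as up / down / unchanged with the same 0.15 log2FC
threshold used for bulk genes, plus an unmeasured bucket.

# Concordance and gene-set overlap

Bulk DEGs require mean normalized counts strictly above 150 and
|log2FC| strictly above 0.15. Concordance classification follows the
region-based definition: a gain-activated gene has expression log2FC > 0
and at least one gain region at raw p < 0.05 in its gene body (txStart to
txEnd, no flanks); loss-repressed genes are the mirror. The raw-p default
follows the definition verbatim even though region *calling* uses FDR;
`use_adjusted = TRUE` switches to the stricter reading. Any expressed gene
qualifies — the definition states no significance filter on expression, so
none is imposed. For 5mC the sets intersect DEG status with DMR direction
(hyper ∩ down, hypo ∩ up). A gene with significant regions in both
directions is resolved by its most significant region and the conflict is
reported. Disease-list overlap uses a one-sided exact binomial tail with
hit probability |list| / |universe|; the universe defaults to all genes in
the expression table — the smallest defensible superset — and enrichment
(not depletion) is the alternative, since only excess overlap is claimed.

# IEG bin-matrix statistics

For each gene, the body window spans TSS−1000 to TES+1000 and the promoter
window TSS−3000 to TSS+1000 (strand-aware, clipped at chromosome bounds;
body length = gene + 2000, promoter length = 4000 before clipping). Windows
are tiled into 500 bp regions (terminal partials dropped by default — the
tiling is defined as continuous full regions — with a flag to keep them),
each split into ten 50 bp sub-bins. Reads are pooled across replicates
within each group — the statistic is defined on a 2 × 10 group-by-bin
matrix, not per sample — counted by midpoint and scaled to CPM of the
pooled group library. The per-tile statistic is the pooled-variance
Student's t on the two 10-vectors with 18 degrees of freedom ("Student's
t-test" is read as pooled-variance, with Welch available by flag); raw p
values are emitted alongside BH adjustment within each gene and context,
since multiplicity handling across a gene's tiles is not standardized.

Sorted-fraction levels combine linearly as
$\text{combined} = 0.28\,L_{\text{NeuN}^+} + 0.72\,L_{\text{NeuN}^-}$,
the assumed cortical composition; the neuronal fraction is a parameter of
`cell_type_weights()`, not an estimate. Compartment expression fold
changes average member clusters without weighting and use a 0.01
pseudo-count. The IEG summary correlates expression log2FC with gene-body
5hmC log2FC (expected positive) and promoter 5mC log2FC (expected
negative), reporting Pearson and Spearman for IEGs and for non-IEG control
genes separately.

# Single-nucleus DEG burden

For each cluster with at least 50 cells per group, both groups are
downsampled to 50 cells (per group, the balanced reading; a pooled draw is
not offered because unbalanced tests conflate burden with group size), a
per-gene DE test is run, and the DEG count recorded; this repeats 10 times
with derived child seeds, and cluster burdens are compared pairwise with
two-sided unpaired t tests on the 10-repetition vectors. The DE engine is a
two-sided Wilcoxon rank-sum on log1p of per-cell counts normalized to
10,000 (the common single-cell convention), vectorized with tie and
continuity corrections to match `wilcox.test(exact = FALSE)`; it stands in
for the hurdle-model fit used upstream, which is interchangeable behind
this interface, and is named in the result object. DEGs require FDR < 0.01
and |log2FC| ≥ 0.15 — inclusive here, following the "at least" wording,
in contrast to the strict bulk thresholds, which follow theirs.

# The synthetic study and its defaults

`simulate_truth()` plus the per-stage simulators generate a complete study
with planted ground truth; `simulate_fixture()` writes it as plain-text
files and `run_pipeline()` runs all seven stages on such a directory with a
JSON manifest. One master seed fans out deterministically to per-stage
child seeds, so any stage can be regenerated alone.

Defaults define the study conditions:

* genome 2 × 5 Mb, 500 bp bins; 300 genes with exons, 5% IEG-like;
* 5hmC: 3 + 3 replicates, ~1e6 reads per sample (±10% depth factors),
  gamma-distributed bin intensities, common NB dispersion 0.05, 50 gain +
  50 loss regions of 4 bins at 3-fold (effect sizes are not reported by
  the study, so recovery-feasible desk-scale values are fixed here);
  planted regions are bin-aligned so truth matching is exact, library
  sizes equal column sums so CPM sums to 1e6 per sample;
* 5mC: planted DMRs of 10 CpGs spaced 20–50 bp (CpG-island-shore-like
  density, coherent with the 100 bp merge rule), methylation shift ±0.3
  from baselines 0.3 (hyper) / 0.7 (hypo) so shifted levels stay inside
  (0,1); ~2000 background CpGs at baseline 0.7 (0.1 inside CpG islands);
  coverage Poisson with mean 30; beta-binomial concentration 100,
  i.e. ~1% intra-class correlation between biological replicates, a
  realistic figure for inbred-strain methylomes — concentrations implying
  several-percent ICC make the stated per-site conditions unrecoverable
  for any calibrated test, which contradicts the design being emulated;
  half the DMRs are anchored in gene bodies to give 5mC concordance
  substance;
* expression: log2FC = planted effect + N(0, 0.1); genes overlapping
  planted gain/loss regions are concordant (log2FC ±1) with probability
  0.8; IEG-like genes get graded effects (5hmC body log2FC uniform on
  [0.3, 1.5], promoter 5mC at −0.5× that, expression at 0.8× that);
  p values come from a one-sample z against the noise model — a labeled
  synthetic stand-in for an upstream DE fit, not a model of one;
* single-nucleus: three clusters (two neuronal, one not) of 150 cells per
  group over 800 genes (modeled genes padded with background transcriptome
  ids), background mean 1 count/cell, NB dispersion 0.3, planted burdens
  40/20/5 at log2FC 1 with DEG baselines near 3 counts/cell. Planted DEGs
  are kept a small fraction of the per-cell library because normalization
  couples genes: when planted DEGs dominate the library, per-cell scaling
  deflates every other gene and both power and specificity degrade — an
  artifact shared with real normalization pipelines that the generator
  deliberately keeps modest. High-burden clusters still show a few
  composition-driven down-calls, which is faithful to practice.

What the generator does *not* emulate: read-level data, sequence
composition, GC or mappability bias, input-control correction, spatially
correlated replicate effects, doublets or ambient RNA. Passing recovery
tests on this generator therefore demonstrates the correctness and
calibration of the statistics under their own assumptions, not robustness
to the full messiness of sequencing data.

Problem sizes used by the test suite (20,000 bins, ~2,400 CpGs, 900 cells,
10–20 simulation seeds per property) were chosen as comfortable desk-scale
settings where the Monte-Carlo noise of every asserted quantity is small
relative to its acceptance margin.

# Numerical choices and degenerate inputs

* Exact-test tails always include the observed point; zero-total bins
  report p = 1 and log fold change 0.
* The dispersion optimizer's lower boundary (δ ≤ 2e-6) is reported as
  exactly 0; an all-zero matrix warns and returns dispersion 0.
* Beta-binomial fits clamp means to [1e-6, 1−1e-6] on the logit scale and
  the concentration to e^[−7, 14]; sites with all-zero totals are skipped.
* Fisher odds ratios with empty cells report NA (no coverage) or Inf
  (empty margin) rather than a corrected estimate.
* `region_ttest` returns t = 0, p = 1 for identical constant rows and
  p = 0 with infinite t for different constant rows.
* Correlations on constant vectors warn and return NA.
* `meta_profile` on identical groups reports fold change 1 and p = 1
  without attempting a degenerate t test.
* The seed fan-out is `(master·10007 + stage·65537 + index·257) mod
  (2^31 − 19)`, keeping every derived seed a valid 32-bit integer.

# Known limitations

The simplified qCML ignores NB-quantile effects for strongly unequal
library sizes; the common dispersion is global, so bin-specific biological
variability is not modeled; the annotation precedence is an explicit
stand-in for an unspecified upstream convention and is config-exposed; the
DMR background for state enrichment must be supplied by the caller (the
pipeline uses all pre-filter merge candidates); and the burden stage's DE
engine is a rank-sum stand-in whose absolute DEG counts will differ from a
hurdle model even though the burden *contrast* between clusters — the
quantity of interest — is preserved.
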