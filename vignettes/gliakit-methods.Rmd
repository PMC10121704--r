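---
title: "gliakit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gliakit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gliakit packages the quantification machinery used in single-cell and
histological studies of cortical glia in the SOD1(G93A) mouse model of ALS:
droplet QC, Xist/Y sex inference, signature scoring, clustering and
differential expression, preranked gene-set enrichment, and four image
quantifications (Yen-thresholded integrated density, Sholl profiling,
brightest-substack volume fraction, nuclear co-localization counts). Every
stage can be validated against synthetic data with planted, recorded ground
truth; the generators are first-class, tested code, not throwaway fixtures.

## The synthetic count model

`simulate_counts()` draws UMI counts from a negative binomial with a shared
dispersion (default 0.1, i.e. size 10), the standard overdispersed model for
droplet UMI data. Each cell type carries its own expression-fraction profile:
a lognormal baseline (sdlog 1.5) perturbed per type by a factor of
2^N(0, 0.25), with marker genes elevated by their configured fold (default
8x) in their own type and suppressed 50-fold elsewhere, so that
expressing-fraction criteria discriminate between types. Library sizes are
lognormal (median 5000 UMIs, sdlog 0.3). The default design mirrors the
emulated study: 16 samples (2 conditions x 4 ages x 2 sexes), a 3.9% doublet
rate, and ambient contamination of 1.5% (the middle of the reported 1-2%
range). Per-sample cell counts default to 4000, within the study's
2,500-6,800 range; tests and examples scale `n_cells_per_sample` and
`n_genes` down, never the rates.

Sex structure: Xist is expressed only in female singlets (0.3% of the
transcriptome, high enough that essentially every female cell has at least
one Xist UMI) and four Y-linked genes (Ddx3y, Eif2s3y, Uty, Kdm5d) only in
male singlets at 0.04% each. Doublets sum two independently drawn singlet
profiles (the second parent has its own library size); ambient contamination
adds Poisson counts from the sample-mean profile at `ambient_fraction` of the
droplet's library size, after doublet formation. In a mixed-sex sample this
reproduces the two real failure modes of the sex classifier: male cells with
ambient Xist, and cross-sex doublets.

Planted condition effects multiply the chosen genes' expression fractions by
`2^log2fc` in SOD1 samples (optionally restricted to cell types and ages),
after fixing those genes' baseline at a moderate level (5e-4 of the
transcriptome, about 2-3 UMIs per cell). The fixing matters: a fold change
planted on a gene with near-zero expression is invisible to any fold-change
statistic computed with pseudocounts, so the generator plants effects where
the assay can in principle see them. Dispersion and per-type depth are free
parameters of the simulator, not calibrated to any deposited dataset.

What the generator does **not** emulate: batch effects beyond the
condition/age/sex design, gene-gene correlation beyond cell-type structure,
ambient profiles estimated per droplet, or UMI saturation. Tests passing on
this data show the pipeline's statistics and bookkeeping are correct, not
that any biological conclusion transfers to real tissue.

## QC, sex assignment and scoring

`filter_droplets()` keeps barcodes with >= 100 total UMIs (a barcode at
exactly 100 is kept). `assign_sex()` applies the rules verbatim on raw
counts: male iff Xist < 1 and nFeature_Y > 0; female iff Xist > 0,
nFeature_Y < 2 and nCount_Y < 2; everything else is "undefined" and marked
for exclusion. The two rules are mutually exclusive as printed, so their
order of evaluation does not matter. Counts are raw because the thresholds
(1 and 2) are count-scaled quantities.

The per-type QC gates use strict inequalities exactly as printed
(astrocytes nFeature > 1000, 2000 < nCount < 10000, mito% < 8; microglia
nFeature > 700, 1000 < nCount < 10000, mito% < 5; oligodendrocytes
nFeature > 1300, 2500 < nCount < 50000, mito% < 5): a cell sitting exactly
on a threshold is dropped. The gates are monotone — relaxing a threshold can
only keep more cells — and this is property-tested.

`module_score()` bins genes into 24 equal-frequency bins by mean expression
and samples 100 control genes (with replacement) per signature gene from the
matching bin; the score is mean signature expression minus mean pooled
control expression. The bin count and control count are the canonical
defaults of this scoring procedure; ties in mean expression break by gene
name so the score is invariant to gene order. Cell-cycle phase is the
positive argmax of the S and G2M scores, G1 otherwise, with exact ties going
to S (a declared rule; exact ties essentially never occur on real data).

The confounder genes (Sod1, Gm8566, Cmss1, Cdk8, Xist, Gm42418, Gm424181,
Malat1) plus mitochondrial, ribosomal and sex-linked genes are excluded
before clustering only — they stratify cells by state or sex rather than
type — and remain in the matrix for differential expression.

## Clustering and differential expression

`pca_embed()` selects 2000 highly variable genes (or all positive-variance
genes if fewer), centres and unit-scales each with values capped at 10, and
decomposes by SVD; 17 components for a full dataset and 16 for subtype
analyses are the defaults. `cluster_cells()` builds a 20-nearest-neighbour
graph in PC space, reweights edges by shared-neighbour Jaccard similarity
(pruning below 1/15), and runs Louvain modularity optimization at the given
resolution (0.5 full dataset, 0.2 subtypes). Acceptance is truth recovery
(adjusted Rand index against planted labels), not partition identity with
any particular implementation's output.

`differential_expression()` is a vectorized Welch t-test (Wilcoxon
selectable) on log-normalized values (`log1p` of counts per 10,000). The
fold change is `log2((mean(expm1 x_A)+1) / (mean(expm1 x_B)+1))` — the
back-transformed group means with a pseudocount of 1, matching the ecosystem
in which the |log2FC| > 1 threshold was calibrated. Genes detected in fewer
than 3 cells of the union are not tested; zero-variance genes report p = 1
with a flag rather than NaN. Multiple testing uses Bonferroni by default
(the emulated toolkit's default), Benjamini-Hochberg by flag; the
significance flag (p_adj < 0.05 and |log2FC| > 1) is stored, never used to
drop rows. Marker detection pre-filters to genes with >= 10% expressing
cells in the cluster and log2FC > 0.25 before testing, as the emulated
toolkit does.

`pseudobulk()` sums raw counts per (condition, age, sex) group;
`pseudobulk_pca()` normalizes columns to a common depth, applies `log1p`,
centres genes and returns both scores and loadings, so a sample displaced
along a component can be traced to the genes loading it (the package's tests
plant a stress-gene module in the 4-month SOD1 samples and recover exactly
those genes in the extreme loadings).

## Preranked GSEA

`enrichment_score()` implements the weighted Kolmogorov-Smirnov running sum:
hits increment by `|r|^p` normalized over the set's hits (p = 1 by default,
p = 0 selectable), misses decrement by `1/(N - N_hit)`; the enrichment score
is the maximum signed deviation, and the leading edge ("core enrichment") is
the hit genes at or before the positive extremum (at or after, for a
negative score). The implementation evaluates the running sum only at hits
and the points just before them, which provably contains both extrema; tests
compare it against a full brute-force running sum on every instance and
against an independent implementation.

`gsea_preranked()` uses a gene-label permutation null (the preranked-mode
null — stated explicitly because it differs from phenotype permutation):
`n_perm` draws of the same number of positions per set. NES divides the
observed score by the mean |null score| of matching sign; the p-value is
one-sided within the same-sign nulls with the +1 correction, so it is never
zero; sets with no same-sign nulls report the 1/(1+n_perm) bound with a
flag. Sets are filtered to 10-800 genes after intersection with the
universe; BH adjustment runs across retained sets; a result is "relevant"
only when p_adj < 0.05 **and** more than one gene is in the leading edge.
Ranking ties break by gene name, and a degenerate all-equal ranking is
flagged, because the score depends on order.

## Image quantification

All image operations work on `[y, x, z]` arrays with physical pixel sizes;
coordinates are micrometres with the origin at the image corner and y down.

**Thresholds.** `yen_threshold()` maximizes Yen's maximum-correlation
criterion over all 255 cut points of a 256-bin histogram and is tested
against an exhaustive naive evaluation; `otsu_threshold()` (between-class
variance) shares the histogram machinery. Pixels strictly above the level
are foreground.

**Integrated density.** "Integrated density limited to the threshold" is
read as the sum of suprathreshold voxel intensities (area times mean of
suprathreshold), computed per image with the Yen threshold and averaged per
animal; the threshold used is recorded in the output, and the alternative
reading (mean intensity) is deliberately not implemented to keep the output
unambiguous.

**Sholl.** Profiles start 5 um from the soma centre with 5 um steps on the
thresholded maximum projection. Each circle is sampled at arc steps of at
most half a pixel; an intersection is a maximal contiguous foreground run
along the circularly closed sample sequence. Two rasterization subtleties
are handled explicitly: a sample landing exactly on a pixel edge (to
sub-nanometre precision) reads foreground if either neighbouring pixel is
foreground (pixels as closed regions), and background gaps narrower than one
pixel of arc are closed before counting, because a raster cannot represent
an inter-process gap below the pixel size — such holes are staircase
aliasing, not separations. With these rules the measured profile equals the
analytic segment-circle crossing count exactly on noiseless rendered trees,
and remains exact at the simulator's default noise once sub-resolution
speckles (components under 9 px) are removed from the mask. Radii whose
circle leaves the image are reported missing, not zero. The soma centre is
supplied, or taken as the centroid of the largest foreground component.

**Volume fraction.** The 20 brightest frames (by mean intensity, ties to the
lower z index, original z order preserved) are thresholded per frame — Otsu
by default, because the external macro's per-frame method is not described
in the text, with Yen selectable and the method recorded — and the mean
covered fraction is the volume fraction. A frame with no dynamic range
counts as 0 (uniformly dark, flagged blank) or 1 (uniformly bright, flagged
saturated).

**Co-localization.** Nuclei are segmented from the max-projected DAPI
channel: Gaussian smoothing (sigma one tenth of the expected 10-um nucleus
diameter), Otsu threshold, connected components filtered to 0.25-4x the
nominal nucleus area. A nucleus is marker-positive when the mean marker
intensity inside its mask exceeds the marker's automatic threshold; a
constant (empty) marker channel yields zero positives. Outputs are the
percentage of marker-positive nuclei among DAPI+ and any requested
conditional ratios (CC3+ among APC+), with raw counts.

## Pipeline orchestration

`run_sc_pipeline()` chains the single-cell stages and records a manifest in
which every excluded cell is attributed to exactly one gate. One ordering
choice is deliberate: the per-type QC gates run *after* clustering and
annotation, because the gates are defined per cell type and a type label
must exist first — the same order the emulated workflow used. Cells in
clusters that match no marker set (or more than one) are excluded as
ambiguous rather than silently assigned. The "study mode" defaults —
100-UMI pre-filter, the printed QC gates, resolutions 0.5/0.2, 17/16 PCs,
10-800 set sizes, 5-um Sholl geometry, 20 brightest frames — ship in
`default_parameters()`, so a default run needs no arguments. The intended
command-line surface is fulfilled by these exported functions plus
`run_imaging_pipeline()`; an R analysis package of this kind is driven from
R scripts, and a shell wrapper would add a second interface to maintain
without adding capability.

## Problem sizes, tolerances and limitations

The test suite and the acceptance script run the generators at deliberately
modest sizes — hundreds of cells per sample, gene universes of 250-600,
image fields of 64-212 um — chosen so that each property is still sharply
testable: the planted effects are far from the decision thresholds (planted
log2FC of 2 against a threshold of 1), and exactness claims (Sholl, Yen,
co-localization) are made on noiseless renders where the analytic answer is
defined. QC-gate thresholds are rescaled in pipeline-level tests because a
few-hundred-gene toy universe cannot produce nFeature > 1000; the gate
logic itself is always tested at the printed values.

Known limitations: the clustering is exact-kNN (O(n^2) distances), fine for
tens of thousands of cells but not for millions; GSEA uses plain permutation
p-values (no adaptive refinement), so the smallest attainable p is
1/(1+n_perm); the Sholl implementation is 2-D, on projections, by design;
and nucleus segmentation assumes roughly disk-shaped, well-separated nuclei
— densely packed or lobed nuclei would need a watershed step that is out of
scope here.
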