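---
title: "Detecting tumor-immune hybrid cells and telling them from doublets"
author: "scHybrid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting tumor-immune hybrid cells and telling them from doublets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

A hybrid cell is a single neoplastic cell that co-expresses a tumor
lineage program and an immune (here macrophage/monocyte) program,
plausibly arising from tumor-immune cell fusion or cytoplasmic material
transfer. In droplet scRNA-seq the same dual-lineage signature is produced
by an artifact: a doublet, the library of two cells captured in one
droplet, which is approximately the element-wise **sum** of two singlet
libraries. The two differ in exactly one generative property — a hybrid
expresses both programs within **one** library at singlet depth, a doublet
is two libraries at roughly double depth. Everything in this package is
organized around making that distinction operational.

# The synthetic-data model

The paper-scale datasets this method targets are patient biopsies; the
package instead ships a generative emulator with known truth so the whole
pipeline is testable on a laptop.

**Counts.** Each gene receives a lognormal baseline weight (sdlog 1);
each lineage program (tumor, macrophage, T, stromal; 50 marker genes each,
the leading symbols being the canonical markers of those populations in
uveal melanoma) multiplies its markers by `marker_fold = 10` and
normalizes to a proportion vector. A cell draws a library size
`L ~ Lognormal(mean 2000, sdlog 0.35)` and gene counts
`NB(mu = L * p_g, dispersion 0.1)`. A hybrid draws
`lambda ~ U(0.3, 0.7)` and uses `lambda * tumor + (1 - lambda) *
macrophage` as its proportion vector — at a singlet library size. A
doublet is the exact sum of two distinct singlet columns. Defaults:
900/500/300/200 singlets per population, 5% hybrids, 10% doublets
(about 2,200 cells), 2,000 genes.

These defaults were fixed once, on two grounds: they are within the
realistic range for a desk-scale droplet sample (about 2,000 UMI per cell,
strong lineage markers at 10x enrichment, a T-cell group large enough to
survive the 20-cell filter of the interaction module), and they realize
the property the generator exists to encode — spiked doublets carry about
twice the singlet depth (the asymmetry the doublet scorers exploit), while
hybrids do not. The marker fold, depth distribution and dispersion were
not revisited afterwards; all downstream behavior was achieved by fixing
the analysis, not the data.

**What the generator does not emulate:** ambient RNA, batch effects, UMI
saturation, cell-cycle structure, per-gene trends in dispersion, and —
importantly — any hybrid-specific transcriptional novelty: synthetic
hybrids are exact program mixtures. Passing tests therefore demonstrate
that the pipeline separates mixtures-at-singlet-depth from
sums-at-double-depth under clean conditions; they do not show robustness
to ambient contamination or to hybrids whose expression is not a convex
combination of their parents.

**Intensities (cyCIF arm).** Per-cell mean fluorescent intensities are
lognormal per marker per population (sdlog 0.4; background meanlog
log(50), positive log(500)). Populations include the two confusers the
gating rules must reject (basophil-like CD45+/HTR2B+/CD203c+ and
Treg-like CD45+/HTR2B+/CD25+). In the peripheral-blood compartment the
hybrid population carries elevated TMSB10/GPX1 means relative to
circulating tumor cells; in tumor tissue the phenotype markers are matched
between hybrid and tumor cells.

# Preprocessing

Counts are filtered to genes detected in at least 3 cells, normalized as
`log1p(1e4 * count / cell_total)` (zeros map to zero; the sparsity
pattern is preserved), reduced to 2,000 highly variable genes by
dispersion of the normalized values, centered, unit-scaled, and embedded
with PCA. This log-CP10K route replaces a regularized negative-binomial
variance-stabilization on purpose: the hybrid decision depends on
*relative* lineage expression, not on the specific variance transform, and
the simpler transform is exactly reproducible.

**PC selection.** The retained components are the smallest prefix whose
cumulative variance ratio (over the computed components) exceeds 95%,
restricted to components with individual ratio >= 5%. The two thresholds
can conflict on real data; the resolution implemented is: cumulative
prefix first, then the individual filter, then a fallback — 10 components
(matching the doublet module's fixed `PCs = 1:10`) when nothing passes,
two when only one does. `selectPCs()` exposes the rule for direct testing.

**Graph and clustering.** The neighbor graph is a shared-nearest-neighbor
graph: cells are connected when either lists the other among its `k = 20`
nearest neighbors (Euclidean distance in PC space), weighted by the
Jaccard overlap of their neighbor sets and pruned below 1/15 — the
standard construction in this field's clustering workflows, and
deliberately chosen over a plain unweighted kNN union, which in our tests
fails to separate the rare hybrid group from adjacent heterotypic-doublet
cells. Partitioning is Leiden (modularity objective) at a given resolution
and seed.

`clusterCells()` defaults to resolution 1.0, the conventional general-
purpose setting. `runHybridPipeline()` defaults to resolution 3.0: a
hybrid population of a few percent of cells and the tumor+macrophage
doublets adjacent to it in expression space only separate into distinct
clusters under deliberate over-clustering, and the cluster-level doublet
consensus needs that separation. Over-clustering is harmless downstream —
the calling rule compares a candidate against every reference cluster, so
splitting a pure population into several subclusters does not change
calls.

# Dual module scores

Marker genes are the top 50 by differential expression between the
annotated tumor and macrophage cells (two-sided Wilcoxon rank-sum on the
normalized matrix; Bonferroni adjustment; log2 fold change in the
`log2(mean(expm1(x)) + 1)` convention; ranking by adjusted p, then
absolute fold change, then symbol for determinism).

The module score of a gene set cuts all genes into `nbin = 24` equal-size
bins by data-wide mean expression, draws 100 control genes (without
replacement, seeded) from the bin of each set gene, pools the controls as
a unique set, and reports per cell the mean expression over the set minus
the mean over the pooled controls. Pooling *unique* controls is the
convention under which the degenerate case "set = all genes, controls =
whole bins" scores exactly zero. Binned controls remove the
depth/abundance component, and the score is invariant to adding a
constant to the matrix. Very small samples can make 24 bins too fine; the
error message suggests lowering `nbin` (e.g. 12), which is how the
smallest sample of a cohort is handled in practice.

# Calling hybrid clusters

The manual step this package formalizes is reading per-cluster score
violin plots: a hybrid cluster is one whose tumor score is visibly higher
than every immune/stromal cluster *and* whose macrophage score is visibly
higher than every tumor cluster. The formalization:

* one-sided Mann-Whitney tests per comparison, BH-adjusted within each
  family, all adjusted p <= 0.05 (`alpha`);
* an effect-size floor per comparison: AUC (probability that a random
  candidate cell outscores a random reference cell) >= 0.75. Significance
  alone is not enough: with a hundred cells per cluster, the rank test
  detects technically real but practically negligible shifts — a
  low-depth pure-tumor subcluster, whose scores compress toward zero,
  can reach p ~ 1e-6 against other tumor clusters at AUC ~ 0.6, while
  genuine hybrid clusters sit near AUC 1. The floor is the "visible in
  the violin" criterion made explicit; 0.75 was chosen between those two
  regimes and then frozen;
* candidate-level control: each cluster's call is an intersection-union
  test (its p is the largest adjusted comparison p), BH-adjusted across
  all candidate clusters;
* reference hygiene: clusters flagged as doublet artifacts (below) and
  clusters that are Tukey outliers (median > Q3 + 1.5 IQR) on the
  opposite-lineage score are excluded from comparison families. The
  outlier exclusion lets two genuine hybrid clusters in one sample be
  called instead of blocking each other, and keeps unflagged artifact
  clusterettes out of the reference set. Zero, one, or several clusters
  may be called.

The decision uses only ranks, so it is invariant to monotone
transformations of the scores and to cluster relabeling.

# The doublet guard

Three scores, all built on the same primitive — simulate artificial
doublets as random pair-sums of observed libraries, embed them jointly
with the observed cells (log-CP10K, highly variable genes, 10 PCs), and
ask how artificial-like each observed cell's neighborhood is:

* **pANN**: fraction of artificial cells among the
  `K = round(pK * n_merged)` nearest neighbors, with `pN = 0.25` (so
  `n_art = pN/(1-pN) * n_obs`) and `pK = 0.09`;
* **kNN fraction**: artificial-neighbor fraction `f` over
  `k_sim ~ round(0.5 * sqrt(n))` neighbors, corrected for the simulation
  ratio `r = n_art/n_obs` as `(f/r) / (f/r + (1-f))`;
* **density ratio**: artificial density within the radius of the
  `k_sim`-th observed neighbor, normalized per simulated and per observed
  cell.

These are contract-level reimplementations of the published
simulation-based scorers, not line-for-line ports; the consensus behavior
is what matters downstream. The expected-doublet count (`nExp`) used by
hard classifiers is recorded in the configuration but unused — the
adjudication is rank-based: per method, each cluster's median score gets a
percentile rank among cluster medians (ties share the lower rank, so
identical clusters are never flagged); a cluster ranking above 0.8 in at
least 2 of 3 methods is flagged, and a hybrid call on a flagged cluster is
demoted with the reason recorded. "Elevated in a consensus of methods,
relative to the majority of clusters" is deliberately conservative: single
noisy scorers cannot demote a hybrid cluster.

The pipeline runs scoring and adjudication *before* calling, so artifact
clusters are excluded from calling references; calling first and
adjudicating afterwards demotes the same calls but compares candidates
against artifact clusters, which can block genuine ones.

# Differential expression, panels, enrichment

Hybrid-vs-tumor and hybrid-vs-macrophage DE reuse the Wilcoxon machinery,
with hybrid-cluster cells removed from the reference side. Panel selection
across samples applies, per sample: adjusted p <= 0.05 and |log2FC| >= 1;
then keeps genes passing in >= 2 samples; then narrows the two crowded
categories (top 10 up-vs-tumor by adjusted p; down-vs-mac only at
log2FC <= -2 in every passing sample). A configurable include-list holds
curated additions. The relaxed |log2FC| >= 0.58 list feeds enrichment.
Enrichment itself is a local hypergeometric upper-tail test against GMT
gene sets with BH adjustment — the same statistic family as web-based
over-representation services, with the pathway collection supplied as an
input file rather than an API. The universe defaults to the genes
surviving the QC filter in the sample under test.

# Ligand-receptor inference

For each ordered (sender, receiver) pair of cell types (>= 20 cells each)
and each ligand-receptor pair (expressed in >= 10% of sender and receiver
cells respectively), the statistic is the mean of ligand expression in
senders and receptor expression in receivers; the null shuffles cell-type
labels 1,000 times and `p = #(null >= observed) / 1000`, without
smoothing, significance at p <= 0.05. Multi-subunit receptor complexes
are out of scope — the bundled pair table expresses the signaling axes of
interest (GAS6-AXL, CXCL12-CXCR4, LGALS9-P4HB, IGF1-IGF1R, TYROBP-CD44,
APP-CD74, ANXA1-FPR1/3) as simple pairs, and those genes are planted in
the synthetic generator's programs so that recovery is testable. When
several samples are available the intended use is per-sample inference
with post-hoc intersection ("conserved in all samples"), matching the
per-patient analysis the interaction-count summaries describe. Note that
the p-values are Monte-Carlo estimates: they are reproducible for a fixed
seed and cell order, but reordering cells changes the permutation draws
within Monte-Carlo error.

# cyCIF quantification

Input starts at the per-cell mean-intensity table (registration and
segmentation are upstream, out of scope). A marker is positive at
intensity >= its minimum intensity value — thresholds are explicit
configuration, optionally derived from a negative-control table by
`thresholdFromControls()`, replacing per-sample manual histogram gating
with a reproducible rule. Classes: hybrid (CD45+ and >= 1 melanocyte
marker), tumor (>= 1 melanocyte marker; CD45, CD25, CD203c all negative),
excluded (CD45+ cells whose *only* melanocyte positivity is HTR2B and
which are CD25+ or CD203c+ — indistinguishable from basophils/Tregs), and
other. The strict reading — a second melanocyte marker rescues a
CD25+ cell — is the default; `strict_htr2b_exclusion = FALSE` gives the
broader exclusion. Percent positive is `100 * positive / total` within a
class (errors, rather than returning 0, when the class is empty), and
group comparisons use Welch's t-test with Welch-Satterthwaite degrees of
freedom. Significance is read at p <= 0.05 throughout (one methods
sentence in the source literature states the inequality the other way
round; that is treated as a typo, consistent with how its results are
reported).

# Numerical and testing choices

Exact statistics are delegated to R's standard machinery
(`wilcox.test` with exact small-sample p-values, `phyper`, `t.test`,
`p.adjust`) and validated in the test suite against independent
enumeration/closed-form oracles; the module score is validated against a
brute-force reimplementation to 1e-12. All stochastic stages (generator,
control-gene draws, artificial doublets, Leiden, permutations) take
explicit seeds and restore the caller's RNG state. Problem sizes in the
test suite — about 2,200 cells, 2,000 genes, ten end-to-end seeds, 1,000
label permutations over 1,000 evaluated pair-type combinations — were
chosen as the smallest sizes at which the cluster-level decisions are
stable; the null-calibration design uses distinct genes per
ligand-receptor pair because combinations sharing genes are strongly
correlated under the shared permutation set.

# Known limitations

* Synthetic hybrids are exact program mixtures; hybrid-specific novel
  expression is not modeled, so marker-recall results bound only the
  mixture case.
* The depth signal that separates doublets from hybrids enters the
  embedding through detection (zero-pattern) differences; protocols with
  saturating depth would weaken it, and the generator does not model
  saturation.
* Homotypic doublets (two cells of the same type) are largely invisible
  to all three scorers, here as for the published tools; the consensus
  rule only protects cluster-level conclusions.
* Cluster lineage annotation is majority vote over provided per-cell
  annotations; a mis-annotated source dataset propagates.
* The Mann-Whitney formalization of the violin-plot decision, the 0.75
  AUC floor, the 0.8 consensus rank threshold and the Tukey outlier
  exclusion are this package's design choices where the source procedure
  was manual; each is exposed as a parameter.
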