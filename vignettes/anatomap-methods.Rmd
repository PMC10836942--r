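---
title: "anatomap: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{anatomap: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anatomap)
```

# The spatial heatmap model

A spatial heatmap (SHM) colors anatomical *spatial features* — organs,
tissues, cells annotated in an SVG drawing — by quantitative assay values
through a numeric color key. `anatomap` treats the problem in three layers:

1. an **aSVG model** (`svg_doc`, `spatial_feature`): any drawable element or
   group carrying an `id` is a colorable feature; document order defines the
   layer stack (0 = bottom);
2. an **assay model** (`assay_table`, `sc_assay`): genes × samples (or
   cells) with per-sample metadata (feature label, condition, replicate)
   and an explicit `value_space` tag (`counts`, `normalized`, `log`,
   `lfc`), so every figure states what its numbers mean;
3. a **rendering layer** that joins the two through a
   `feature_sample_map` (exact, case-sensitive label matching, optionally
   routed through a user translation table) and a `color_key`.

## Coordinate and feature conventions

Geometry is kept in the SVG-native frame (user units, y increases
*downward*) and attributes are preserved verbatim, so writing a parsed
document reproduces the source; renderers flip the axis at draw time. A
group's id "covers" its id-less drawable descendants — they inherit the
group fill at render time — while id-bearing descendants become features of
their own. This matches how public anatomogram files are annotated, where
outline paths inside an organ group usually carry no ids themselves. How
nested conflicting ids should map to features is not standardized; this
group-covers-descendants rule is this package's choice.

When documents are combined (`combine_docs`), canvases tile with a gap of
2% of the larger canvas dimension (any fixed rule would do; this one keeps
adjacent anatomies visually separate at all sizes), and colliding ids are
suffixed `"__k"` with k the 2-based document position — deterministic and
reversible.

## The color key

`make_color_key(values, palette, k)` builds k bins over k + 1 equally
spaced breaks spanning the data range. Bin i covers `[b_i, b_{i+1})`; the
last bin is right-closed, a value exactly on an interior break falls in the
*higher* bin, and out-of-range values clamp to the end bins, making
`color_of` a total, monotone function. The degenerate all-equal case uses
breaks at value ± 1 so everything lands in the middle bin. Defaults: a
yellow–orange–red ramp for absolute abundances, and a blue–white–red ramp
centered at zero for log fold changes (`value_space == "lfc"`), the
standard convention for signed effects. Unmeasured features and orphan
cells are light grey (`#D3D3D3`), deliberately outside every palette.
Replicates are aggregated by the arithmetic mean for display (median
selectable); one key is shared across all panels by default (`per_gene`
available) so a color means the same number everywhere in a figure.

# Normalization

`normalize_assay` implements two canonical schemes:

* **median-of-ratios size factors**: per sample j,
  `s_j = median_g count_gj / geomean_g`, over genes with a positive
  geometric mean, rescaled so the factors have geometric mean 1 — the
  standard count normalization that is robust to a minority of
  differentially abundant genes;
* **CPM**: column scaling to one million.

Both optionally log2-transform with a pseudo-count (default 1). Relative
(treatment vs control) values are per-gene, per-feature differences of
replicate means in log space, i.e. log2 fold changes.

# Spatial enrichment

Given K query features, a gene is **enriched** in feature F when, in at
least `K - 1 - outliers` of its `K - 1` pairwise comparisons F vs G, the
BH-adjusted p-value is ≤ α and the log2 fold change is ≥ `lfc_min`
(depleted: ≤ `-lfc_min`). K counts the query feature itself; `outliers`
(0 ≤ outliers ≤ K − 2) relaxes the one-vs-rest stringency so genes shared
by a few features are still discoverable. Two direct consequences are
useful as sanity checks and are enforced by the test suite: at
`outliers = 0` enrichment sets of different features are disjoint, and the
called set can only grow as `outliers` increases.

## The test statistic

Counts are log-normalized internally (CPM, log2, pseudo-count 1) and genes
with zero variance across the compared replicates — plus, for counts input,
genes below CPM 1 in fewer than the smallest group size of samples — are
dropped up front.

Two engines are provided:

* `engine = "welch"`: per-gene, per-pair Welch two-sample t-tests
  (Welch–Satterthwaite df), BH across genes within each comparison. This is
  the plain closed-form test; `pairwise_de()` exposes it directly and the
  suite pins it to the textbook formula at 1e-12.
* `engine = "moderated"` (default): the same mean contrasts, but the
  per-gene variance is the one-way within-group residual variance across
  the K features, squeezed toward an empirical-Bayes prior before testing.
  The prior (s₀², d₀) is fitted by moment matching on log s²: with
  e_g = log s_g² − ψ(d/2) + log(d/2), the excess spread of e over the
  theoretical χ² log-variance identifies d₀ through the trigamma function
  (inverted by Newton iteration), and its mean identifies s₀². Each
  variance becomes (d₀ s₀² + d s_g²)/(d₀ + d) with d + d₀ degrees of
  freedom.

The moderated engine is the default because with typical spatial designs —
a handful of replicates per tissue — per-gene variance estimates at ~6 df
make the all-pairwise-comparisons rule extremely conservative: a gene must
clear the BH threshold in *every* comparison, so per-comparison power
enters multiplicatively. Sharing variance information across genes is the
standard remedy in expression analysis and restores sensitivity without
touching the decision rule, the thresholds, or type-I control (the null
false-call rate stays below α; the suite checks this on a 2,000-gene null
simulation). Per gene and feature the result tables report the *minimum*
|lfc| and *maximum* adjusted p over the supporting comparisons — the
conservative summary — plus the support count.

Dispersion-modeling negative-binomial tests and covariate adjustment are
out of scope; for designs with batch structure an external DE framework
should be used upstream and its log-fold-changes plotted directly.

# Mining

* `similarity_search`: Pearson/Spearman correlation (Spearman = rank
  transform with average ranks, then Pearson) or Euclidean distance to a
  query gene; selectors are a fixed count, a percentage
  (`ceil(p/100 × n)`, counting the query; default 15%), or a similarity
  threshold. Ties break lexicographically by gene id so results are
  reproducible.
* `hcluster` / `cut_tree`: agglomerative clustering (correlation or
  Euclidean distance; average/complete/single linkage) with height- or
  count-based tree cutting. Cluster labels are numbered by first leaf
  appearance.
* `adjacency`: unsigned soft-threshold network a_ij = |cor_ij|^β, default
  β = 6, the common unsigned-network default. The topological-overlap
  transform is deliberately omitted: edges in the exported graphs *are*
  adjacencies, and connectivity is the sum of a gene's adjacencies within
  its module.
* `detect_modules`: average-linkage clustering of 1 − a cut at a fixed
  height (default 0.6), clusters below `min_size` unassigned (label 0).
  A fixed-height cut is a documented simplification of adaptive tree-cut
  methods: it is fully deterministic and sufficient for well-separated
  co-abundance blocks; finely nested modules on large real networks may
  require external tooling.
* `hypergeom_enrich`: upper-tail hypergeometric test of a cluster against
  user-supplied gene sets (GMT), BH across sets. Annotation retrieval is
  the user's responsibility.

GraphML export prunes edges below adjacency 0.1 — a display default that
keeps module graphs legible; the cutoff only affects export, never the
module computation.

# Co-visualization

Cell groups link to anatomical features through a `tissue_cell_map`
(group → svg id, with an orphan set). Five mapping routes: existing
annotations, marker genes, manual pairs, clustering plus a user table, and
co-clustering. Marker mapping scores each group by the mean log expression
of each feature's enriched markers and assigns the argmax feature only
when it beats the runner-up by a margin δ (default 0.5 log2 units) —
groups without a clear winner stay orphans, and orphans are *always*
rendered grey, in every coloring scheme.

Coloring schemes: `fixed_by_group` (categorical tissue colors),
`cell_by_group` (per-group summary of a gene's single-cell expression,
applied to cells and matched features), `feature_by_group` (bulk value per
feature, applied to the feature and its cells), and `cell_by_value` (every
cell its own value, features by bulk, one shared key). When every cell in
a group carries the same value the three numeric schemes agree — a useful
internal consistency property that the tests exercise.

**Co-clustering** is a deliberately simple, fully specified procedure:
intersect genes (≥ 50 required), log-normalize both sides, average cells
into per-cluster pseudo-profiles (existing group labels when present,
otherwise kmeans on the top principal components with k = number of bulk
features and a fixed seed), correlate pseudo-profiles with bulk feature
means, and assign each cluster to its best-correlated feature when that
correlation is at least 0.3, else orphan. The 0.3 floor and the marker
margin δ = 0.5 are package defaults, configurable and documented here;
both err toward orphaning rather than mis-assignment.

**PCA** is computed natively (centering + SVD) with each component's sign
fixed so its largest-magnitude loading is positive — fully deterministic.
UMAP and tSNE are optional plug-ins that honor the seed when their
packages are installed; nothing in the package requires them.

**scSHM registration**: spatially resolved cells are mapped onto a target
feature by translation plus one uniform scale that aligns bounding-box
centers and preserves aspect, so relative pairwise distances are preserved
up to one global factor. True image registration is not attempted; the
overlay is a faithful *shape-preserving* placement, not an anatomical
deformation.

**Deconvolution views** display a user-supplied cell-type expression
matrix and proportion vector (must sum to 1 ± 1e-6) next to the bulk SHM;
estimating proportions is the deconvolution method's job, not this
package's.

# The synthetic-data generator

`simulate_bulk` draws negative-binomial counts with variance μ + φμ²
(φ = 0.1 for bulk, 0.3 for cells — typical tissue-level and single-cell
overdispersion), gene base means log-normal(log 50, 1), per-sample
library-size multipliers log-normal(0, 0.15), and plants multiplicative
2^lfc effects (default lfc = 3, 5% of genes) in assigned features,
recording the truth. `simulate_cells` draws per-feature cell groups around
the feature's true mean profile at single-cell depth (20% of bulk) and,
optionally, disjoint rectangular spatial regions per group.
`make_toy_asvg` lays out jittered polygons on a grid with an optional
semi-transparent overlay layer. All generators are pure functions of their
seed.

What the generator emulates: library-size variation, count
overdispersion, feature-specific effects, group-structured cells with a
bulk-consistent signal, simple spatial segregation. What it does not:
doublets, ambient RNA, dropout beyond NB sampling, batch effects,
continuous spatial gradients, irregular anatomical shapes. Passing tests
therefore demonstrate algorithmic correctness under a clean generative
model, not robustness to every artifact of real assays.

# Numerical choices and problem sizes

* Variance floor 1e-8 when a replicate group is exactly constant, so test
  statistics stay defined; genes with equal means get p = 1 outright.
* Degenerate color keys (all values equal) center on the value with unit
  half-width.
* SVG output uses fixed 4-decimal float formatting, making rendering pure:
  identical inputs give byte-identical files. The end-to-end pipeline
  (simulate → enrich → shm → covis) is byte-deterministic given a seed.
* Dendrogram ties resolve by the clustering backend's input-order rule;
  all test oracles use generic (tie-free) random data.
* The test suite and the acceptance script run the enrichment recovery at
  2,000 genes × 5 features × 4 replicates, co-clustering at 4 features ×
  100 cells, and oracle checks at 10,000 random key lookups and 100 random
  hypergeometric instances — sizes chosen so every property is exercised
  at full strength while the whole suite stays fast on one CPU.

# Known limitations

* CSS stylesheet cascades, SVG 2 features, animation and fonts are out of
  scope; presentation attributes and inline `style` cover annotated
  anatomies in practice.
* Elliptical arc path segments are linearized for bounding boxes and
  rasterization (exact for output SVG, approximate for PNG rendering).
* Grayscale conversion of embedded rasters supports PNG input; JPEG
  rasters embed at full color.
* The enrichment engine assumes approximately normal log-scale values
  within groups; strongly zero-inflated data should be filtered or
  modeled upstream.
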