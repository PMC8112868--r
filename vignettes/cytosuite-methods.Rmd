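---
title: "cytosuite: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cytosuite: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`cytosuite` is a scriptable three-stage framework for single-cell
marker-expression cytometry: liquid mass cytometry (CyTOF, ~40 metal-tagged
markers per cell), imaging mass cytometry (IMC, per-cell mean intensities
from segmented tissue images) and fluorescence flow cytometry. Stage 1
imports pre-gated per-sample FCS files or IMC cell tables into a single
layered container, transforms and quality-controls them; stage 2 computes
2-D embeddings and unsupervised clusterings; stage 3 turns clusters into
annotated cell populations and tests their abundance and marker expression
between two groups of samples. Everything upstream of the per-sample event
matrix — segmentation, bead normalization, debarcoding, compensation,
manual pre-gating, batch *correction* — is deliberately out of scope; the
MDS diagnostics only help *detect* batch structure.

# Data model

The container is an S4 `Experiment`: a raw and a transformed cells ×
channels matrix (always the same shape; transforms never overwrite raw), a
per-cell sample map, a panel table with per-channel use-flags
(`use_clustering`, `use_reduction`), sample metadata, and named layers of
reductions (cells × 2), clusterings and free-text cell labels. Cells are
rows; columnar per-marker access dominates the downstream statistics.
Cluster labels are 1-based integers per K; annotation layers are separate
text vectors, so table-driven merging never destroys the integer labels it
came from.

On disk the container is one HDF5 file (`/assays/{raw,transformed}`,
`/cell_meta`, `/sample_meta`, `/panel`, `/reductions/<name>`,
`/clusterings/<name>/...` including per-K consensus matrices, and a JSON
provenance log). HDF5 object headers are not byte-stable across writes, so
the reproducibility contract is defined on content: `experiment_checksum()`
is an md5 over the canonically serialized container content with
provenance timestamps stripped. Two runs of the same seeded command chain
yield identical checksums.

# Transforms and downsampling

Marker intensities are variance-stabilized entrywise with
$y = \operatorname{asinh}(x/c)$. Default cofactors by modality: $c = 5$
(mass cytometry), $c = 150$ (fluorescence), $c = 0.8$ (IMC). Only the IMC
value is part of the IMC recovery protocol — mean per-cell intensities
normalized to $[0,1]$ are first multiplied by $65{,}535$ to restore the
instrument's 16-bit dynamic range, then transformed with $c = 0.8$; the
other two cofactors are field convention and overridable.

"Adaptive" downsampling is implemented as two modes, both stated
interpretations because the term has no precise published definition:
`equal_per_sample` draws `min(target, n_s)` cells per sample without
replacement (rectifying unequal cell recovery, which otherwise biases
clustering toward large samples), and `total_cap` splits a total budget
into per-sample quotas, remainder to the largest samples in decreasing
size order. Per-sample draws are seeded by (global seed, sample index), so
adding a sample never perturbs another sample's draw.

# Stage-1 QC

Per-sample median marker profiles feed (a) classical multidimensional
scaling — double-centering $B = -\tfrac12 J D^2 J$, eigen-decomposition,
coordinates scaled by $\sqrt{\lambda}$ — and (b) an annotated heatmap with
average-linkage hierarchical ordering. Classical (metric) MDS was chosen
over stress-optimizing SMACOF because no stress optimization is reported
for this workflow and classical MDS is exact for Euclidean input, which
makes it testable to 1e-8. Numerical conventions: axes ordered by
decreasing eigenvalue; each axis sign-fixed so its largest-magnitude
coordinate is positive; negative eigenvalues (non-Euclidean input)
truncated to zero with a warning, as in common PCoA practice. Whether QC
should use all markers or lineage-only is not prescribed; the default is
all panel markers, selectable by flag.

# Embeddings

UMAP (via `uwot`, defaults `n_neighbors = 15`, `min_dist = 0.1`) and tSNE
(via `Rtsne`, default `perplexity = 30`, enforced
$\mathrm{perplexity} < (n-1)/3$) run on the reduction-flagged markers,
single-threaded with exact nearest neighbours so a fixed seed reproduces
coordinates exactly. Marker columns are put into a canonical order
internally, which makes coordinates exactly invariant to panel column
permutations (floating-point summation order would otherwise leak through
the optimizer). Embedding-stage downsampling leaves non-embedded cells
with `NA` coordinates while clustering still uses all cells; the two are
computed independently. `embedding_density()` is a Gaussian product-kernel
KDE evaluated at each cell with per-axis Scott bandwidths
$h_j = \hat\sigma_j n^{-1/6}$; identical points on an axis are a
degenerate input and raise an error suggesting jitter.

# Clustering

**SOM + consensus ensemble.** An online SOM (default 10 × 10 grid, 100
nodes — large enough to support over-clustering up to K = 56, the scale
used for a whole-immune panel) is trained for `rlen = 10` shuffled passes,
learning rate linearly 0.05 → 0.01, Gaussian neighborhood radius linearly
from $\lceil \tfrac23 \sqrt{x^2 + y^2} \rceil$ to 0; codes are initialized
from a seeded sample of cells. Nodes are then consensus-metaclustered: for
each of `reps = 100` repetitions, 90% of nodes (`p_item = 0.9`) are
subsampled, hierarchically clustered (Euclidean, average linkage) and cut
at every K in `2..maxK`; consensus(i, j) is the co-clustering count over
the co-sampling count (never-co-sampled pairs are reported as 0 and
flagged). The final node partition at each K is average-linkage clustering
of `1 − consensus`. Cells inherit their node's metacluster, so labels for
*every* K are stored and can be revisited without re-running. A batch SOM
mode exists; with a zero neighborhood its update is exactly Lloyd's
k-means step, which is used as an equivalence oracle in the tests.

**Elbow statistic.** $A(K)$ is the area under the empirical CDF of the
off-diagonal consensus values and $\Delta(K) = (A(K) - A(K-1))/A(K-1)$
(with $\Delta(2) = A(2)$). One property worth knowing when reading the
elbow plot: for perfectly separable data the consensus matrix is exactly
binary, so $A(K) = 1 - \sum_c \binom{n_c}{2}/\binom{n}{2}$ is purely
combinatorial and $\Delta(K)$ past the true K settles near 0.08 for
three equal groups rather than exactly 0 — the elbow is the *drop*
(here ~0.5 → ~0.08), not a literal zero. The acceptance tests assert the
combinatorial value itself plus the contrast
$\Delta(K_{true}) > 4\max_{K>K_{true}}\Delta(K)$.

**kNN-graph communities.** Exact k-nearest neighbours (Euclidean,
`k = 30` default) define a union graph whose edges are weighted by the
Jaccard overlap of the two endpoints' *self-inclusive* neighbour sets
$\tilde N(i) = N(i) \cup \{i\}$ (so mutual neighbours sharing all other
neighbours weigh exactly 1), followed by seeded Louvain modularity
maximization; communities are relabeled 1..K by decreasing size. Louvain
rather than Leiden matches the classic construction this mirrors. A
caveat discovered during testing and worth stating: on *low-dimensional*
geometric blobs the within-blob kNN graph has cheap balanced cuts, and
partitions that split a 50-cell blob can strictly exceed the modularity of
the true 2-block partition (measured Q = 0.509 vs 0.4996 in 40
dimensions) — any faithful modularity maximizer must then return more
communities than blobs. In high-dimensional marker space the union-kNN
graph of a compact population is expander-like and does not split; the
recovery tests therefore use 100-dimensional blobs, verified stable across
30 independent draws. On real low-dimensional embeddings, expect Louvain
to over-partition compact islands.

**k-means.** Lloyd iterations from k-means++ seeding, best of
`n_starts = 10` restarts by total within-cluster sum of squares; empty
clusters are repaired by stealing the point farthest from its centroid.
On tiny instances the result is checked against the exhaustive-partition
optimum.

All recovery checks use the adjusted Rand index, since integer labels are
arbitrary up to permutation.

# Annotation

`cluster_medians()` (median transformed expression per cluster × marker)
backs the identification heatmaps. `imc_rank()` ranks clusters *within
each marker* ascending (1 = lowest), mid-rank on ties; ranking across
clusters per marker (not across markers per cluster) follows how ranked
heatmaps are read, and the mid-rank tie policy keeps ranks invariant under
any strictly monotone per-marker transform — the property that makes ranks
more trustworthy than raw medians for lower-resolution IMC data. The
maximum rank equals the number of clusters displayed. Merging clusters
into named cell types is strictly table-driven: the merge table must cover
every cluster at the chosen K exactly once, is stored in provenance, and
`unmerge_clusters()` recovers the original integer labels exactly;
applying a second table on top gives higher-level annotations.

# Differential testing

Abundance testing operates on per-sample cluster *proportions* (rows sum
to 1), not counts — count-based GLMs are left to external differential
discovery tools via the CSV export. Two-group tests: Wilcoxon rank-sum
(default; exact distribution when $n_x + n_y \le 20$ and tie-free, normal
approximation with tie and continuity corrections otherwise) or Welch's
unequal-variance t. Fold changes are $\log_2(\bar p_A/\bar p_B)$ with the
first contrast level positive; a half-minimum pseudo-count keeps the
volcano finite when a group mean is zero (flagged in the output).
Benjamini–Hochberg step-up FDR is applied across populations for abundance
tests, and jointly across all (population, marker) pairs for expression
tests — the family is not prescribed anywhere authoritative, and the joint
correction is the conservative choice. Expression tests summarize each
(population, marker) as the per-sample median of transformed expression
within the population; samples lacking the population are omitted for that
population, and pairs left with fewer than 2 samples in either group
return NA with a note rather than a fabricated p-value. Significance
flags use strict `fdr < threshold`.

# The synthetic-data generator

`simulate_experiment()` is the fixture engine for every stage and a
first-class, tested module. Populations are Gaussian in *transformed*
(asinh) space — clusters are approximately Gaussian there, and the inverse
transform keeps raw intensities in range — and the raw assay is
back-computed as $c \sinh(y)$ so the FCS import path is exercised end to
end. Per-sample abundances are Dirichlet around group-adjusted base
abundances; realized counts are multinomial.

The default stated world: 8 populations over 10 markers (8 one-hot
lineage archetypes, mean 3 on the defining marker and 0.5 elsewhere, 2
functional markers at 1; within-population SD 0.35), base abundances
(0.24, 0.20, 0.15, 0.12, 0.10, 0.10, 0.08, 0.01) including one rare 1%
population emulating a regulatory-T-cell-sized subset, 2 groups × 8
samples, 5,000 cells per sample, Dirichlet concentration 100 (≈30%
between-sample CV for a 10% population — a realistic biological spread),
and one effect: a 2× abundance multiplier on the 10% population P5 in
group A. Because abundances are compositional, a 2× spike renormalizes to
a ≈1.82× realized ratio and slightly depresses the other populations;
the tests account for both. What the generator does *not* emulate:
spillover, batch effects, acquisition drift, doublets, or spatial
structure for IMC — a green recovery test establishes algorithmic
correctness on well-specified mixtures, not robustness to instrument
artifacts.

# Reproducibility and the CLI

Every stochastic operation takes a seed; modules derive child seeds from
the global seed by stage name (`derive_seed()`), so inserting a pipeline
stage does not reshuffle the draws of the others. The CLI
(`cli_main()`, subcommands `simulate`, `import`, `qc`, `reduce`,
`cluster`, `elbow`, `annotate`, `rank`, `abundance`, `difftest`,
`volcano`, `export-fcs`) reads/writes the HDF5 container, appends a
provenance record per run, mirrors every flag in an optional YAML config
(explicit flags win), and exits 0/1/2 for success/domain error/usage
error. Every figure-producing path returns or writes the underlying
table.

# FCS support

The bespoke reader covers FCS 3.0/3.1, list mode, single dataset,
`$DATATYPE` F/D and integer data with uniform `$PnB` of 16 or 32 (promoted
to double), both byte orders. Multi-dataset files, non-list modes and
non-uniform integer widths are rejected with the offending keyword named.
`$PnE` log-amplification keywords are *ignored* — inputs are expected to
be pre-scaled cytometer exports — and this is the loudest documented
deviation from a full-standard parser. The writer emits FCS 3.1,
little-endian float32, `$PnS` defaulting to `$PnN`, and refuses non-finite
values; write → read round-trips are exact in shape and float32-accurate
in value.

# Known limitations

- Two-group designs only; no paired or mixed-effects models (export the
  abundance table for those).
- Exact kNN only: the graph clustering targets ≤10^5–10^6 cells, consistent
  with running the SOM ensemble (which scales much better) on larger data.
- No spillover compensation, no batch correction, no debarcoding.
- IMC is supported at the cell-table level; images and segmentation stay
  upstream.
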