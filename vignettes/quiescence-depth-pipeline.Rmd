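---
title: "Consensus clustering and quiescence-depth pseudo-ordering: methods and design"
author: "quiestree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus clustering and quiescence-depth pseudo-ordering: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quiestree)
```

# Scope

`quiestree` re-implements, as a tested and reusable pipeline, the
computational cascade used to reconstruct the heterogeneity of adult neural
stem cells (radial glia, RG) from single-cell RNA-seq counts: quality
filtering, ensemble consensus clustering, marker gating and validation,
background-matched population scoring, a bootstrapped-MST principal-graph
pseudo-ordering of quiescence depth, cross-species cluster homology over
ortholog groups, and clonal lineage-tracing statistics. Every stage can be
exercised on synthetic data with planted ground truth, so the whole cascade
is testable offline.

This vignette explains the models and the design decisions, states the
defaults with their rationale, and is explicit about what the synthetic
benchmarks do and do not show about real data.

# The synthetic-data generator

The generator is first-class code, not a fixture: it defines the study
conditions under which the pipeline is validated.

**Count model.** Counts are negative binomial with mean
$\mu_{gc} = \ell_c \, p_{g(c)}$ and variance $\mu + \mu^2/\theta$. Per-cell
library sizes $\ell_c$ are log-normal; per-gene relative abundances are
log-normal (sdlog 1.2), a standard heavy-tailed stand-in for a real
transcriptome. The dispersion default is $\theta = 10$: UMI-collapsed
counts are close to Poisson, with moderate biological overdispersion on
top. Cluster structure is planted by multiplying each cluster's disjoint
marker block by $e^{\mathrm{logfc}}$ in member cells (default natural-log
fold change 2). The first $\lceil 0.02\,G \rceil$ genes are named with an
`mt-` prefix and carry a configurable share of each cell's counts, so the
mitochondrial percentage can be computed by name convention exactly as on
real data.

**Low-quality mode.** A configurable fraction of cells has libraries scaled
to 10% and a mitochondrial share inflated sixfold (default 3% becomes
18%). This emulates lysed or dying cells, which in real droplet data show
both a narrow low peak in the detected-genes histogram and a high
mitochondrial tail; dying cells commonly reach 20% mitochondrial content
and beyond. With the default library size (2,500) and 2,000 genes, the
good-cell mode of the detected-genes histogram sits near 900, and the
low-quality mode falls at a few hundred — a clearly bimodal histogram, which
is the shape the QC stage is designed around.

**Quiescence-depth axis.** In trajectory mode each cell receives a latent
depth $d \sim U(0,1)$. A "deep" module's means scale by
$1 + (F - 1)\,d$ and a "shallow" module's by $1 + (F - 1)(1 - d)$ with
$F = e^{\mathrm{depth\_logfc}}$ (default $F = 2$), acting multiplicatively
on NB means so counts stay integer-valued and overdispersed. An optional
Y-branch adds two branch-specific modules beyond a branch point. The
standard trajectory benchmark uses 800 cells, 40+40 module genes, $F = 2$,
and deep, tight libraries (mean 8,000, sdlog 0.15): the source libraries
for this kind of experiment are sequenced to saturation, and a benchmark
with saturated detection ensures the dominant embedding axis is the planted
biology rather than detection depth. On shallow data a detected-genes axis
competes with the biological one — a genuine property of count data that
users should expect on lightly sequenced samples.

**Doublets, clones, orthologs.** Injected doublets are exact gene-wise sums
of two random singlet columns (column totals conserved exactly — a test
invariant). Clone tables draw a Bernoulli composition per clone with a
per-timepoint probability of being RG-only, organized into hemispheres with
4–11 clones each, matching the scale of real clonal chase experiments.
Ortholog tables contain two species with a configurable fraction of
one-to-many groups (two zebrafish paralogs for one mouse gene, the
teleost-duplication pattern) and of groups missing from one species.

**What the generator does not emulate:** ambient RNA, UMI collisions,
batch effects between replicates, cell-cycle structure, or realistic gene–
gene correlation beyond the planted modules. Passing the planted benchmarks
therefore demonstrates algorithmic correctness under the stated statistical
structure, not performance on any particular real dataset.

# Quality control

Cells are filtered in a fixed order, then genes:

1. **Complexity filter.** A loess curve (span 0.5, degree 2, gaussian
   family) of detected genes on total molecules; cells whose residual
   exceeds 3 standard deviations of the residuals on either side are
   flagged. Cells below the trend have degraded libraries; cells above it
   are doublet suspects. The cut is two-sided by default with a
   `two_sided = FALSE` switch exposed, since the wording of the underlying
   rule ("beyond three standard deviations") does not fix sidedness.
   The residual SD is the plain standard deviation, not a robust MAD.
2. **Thresholds.** Remove cells with fewer than 200 detected genes
   (strict `<`) or more than 10% mitochondrial counts (strict `>`), then
   drop genes expressed in fewer than 10 surviving cells. The boundary
   conventions (keep-at-threshold) follow common practice; the thresholds
   themselves are the conventional defaults for this tissue and chemistry.
3. **Normalization.** Counts-per-10k followed by `log1p` everywhere
   downstream.

Variable genes are selected by a variance-stabilizing procedure: a loess
fit of log10 variance on log10 mean predicts each gene's expected standard
deviation, counts are standardized against it with clipping at $\sqrt{n}$,
and genes are ranked by the variance of the clipped standardized counts.

Principal components are retained when they both explain over 1% of the
variance among the leading components and pass a JackStraw-style
permutation test: in each of 100 replicates, 1% of genes are permuted
across cells and the PCA is recomputed with them included; the permuted
genes' loadings form the null. Each real gene gets an empirical tail
p-value per component, and the component's p-value is a binomial test of
how many genes beat the nominal level. Re-projecting permuted genes onto
fixed components is not a valid null (the observed genes built those
components, so everything looks significant); recomputing the PCA is what
makes the test calibrated, and the permuted fraction is kept small so the
structure being tested is intact.

# Ensemble consensus clustering

The shared-nearest-neighbor graph uses exact Euclidean kNN on the PC
scores, with edge weights either as the Jaccard overlap of the two kNN
sets or from the rank of the closest shared neighbor (1 − mean rank of the
closest shared neighbor / k, zero when none is shared), symmetrized by
maximum.

The base ensemble spans the algorithm families used in this literature:
modularity partitioning of the SLM family (Leiden with modularity
objective), multilevel Louvain, walktrap, optionally spinglass (slow, off
by default), plus two embedding-based methods — density peaks and a
Gaussian mixture with BIC-selected component count. The embedding-based
methods see only the leading 8 embedding columns by default: kernel
density estimates and covariance models degrade quickly with dimension
while the leading components carry the cluster structure. Density peaks'
manual decision graph is automated by the $\gamma = \rho\,\delta$ outlier
rule, choosing the center count at the largest relative gap in the sorted
$\gamma$ sequence. A failing base method is recorded and skipped, never
fatal.

The ensemble is combined by cluster-based similarity partitioning:
$M_{ij}$ is the fraction of runs placing cells $i,j$ together. Robust
clusters come from average-linkage hierarchical clustering on $1 - M$ cut
at height 0.2 — a conservative cut requiring at least 80% co-clustering
within cluster cores. The quantification of "conservative" as 0.2 is a
design choice exposed in the configuration; no canonical number exists.

**Merging.** Cluster pairs that are dendrogram siblings (the most similar
pairs by mean co-clustering, tested in ascending merge height) are merged
when fewer than 10 genes pass the pipeline's single DE criterion —
Wilcoxon rank-sum, BH-FDR 0.05, |log2FC| ≥ 0.25 — iterated to a fixed
point. The same DE criterion is used everywhere a DE test is needed
(merging, doublet-cluster detection, marker calls), stated once and reused,
as a deterministic nonparametric replacement for a hurdle-model test.
Sibling one-vs-one testing (rather than one-vs-rest) is the design choice;
merging is a contraction, so the cluster count never increases and the
loop terminates in at most $K - 1$ merges.

**Gates and validation.** Each final cluster gets a greedy boolean marker
gate: terms (gene, direction, threshold) are added while the F1 against
the rest improves by at least 0.01, thresholds searched over expression
deciles, at most 4 terms. The threshold search is restricted to the 100
genes with the largest absolute signed AUROC for the cluster — a
pre-filter that keeps the decile search tractable without changing which
markers can win. Clusters are then validated by a ridge-regularized linear
score on the gate genes only, 5-fold cross-validated; a cluster passes
when its held-out AUROC exceeds 0.7, i.e. it can be re-identified from a
handful of genes. A linear classifier keeps the validation deterministic.

# Doublet detection

Two cluster-level strategies and one cell-level strategy:

- **Mock doublets.** Artificial doublets are built as sums of random cell
  pairs, rescaled to the mean parental depth by binomial thinning — each
  count is thinned with the scale as success probability. Thinning is the
  statistically correct downsampling: a hard rounding of scaled counts
  erases summed 1-counts and displaces the mocks along the detection axis,
  which destroys the detector. Real and mock cells are co-embedded
  (variable genes, PCs explaining over 1% variance), and each real cell is
  scored by the fraction of its 30 nearest neighbors that are mocks. The
  default flag threshold is the overall mock fraction — the score a cell
  in a purely doublet-dense neighborhood would center on.
- **Doublet clusters.** A cluster C is a candidate doublet cluster when,
  for some pair (A, B), almost no genes are DE between C and A∪B beyond
  those DE between A and B in the same direction, and C's centroid
  projects inside the A–B segment (projection parameter in [0, 1]).

The per-cell score of the mock-doublet detector stands in for both
cell-level scoring strategies described for this pipeline; the
scoring-by-simulation description is the one given in enough algorithmic
detail to re-implement.

# Population scoring and gating

Gene-set scores are background-matched: genes are binned into 25
equal-occupancy bins by mean expression; each set gene draws 100 control
genes from its own bin (a bin smaller than the draw is used in full); the
score is the mean set expression minus the mean of the per-gene control
averages. Averaging controls within each gene's pool first makes the score
of the all-genes set exactly zero and keeps the score a strictly relative
quantity: uniformly high expression does not score.

Built-in sets: glial (GFAP, GLUL, GJA1, FABP7), neuroblast (NEUROD1/2/4/6,
STMN1, DPYSL3, GAP43, BHLHE22, TUBB5), and ribosomal-protein genes by name
pattern (`^rp[sl]`, configurable per species convention). Ribosomal
content rises as stem cells approach activation, which is why it separates
pre-activated RG from deeply quiescent RG.

Gating is quantile-based: quiescent RG have glial score above the 0.7
quantile with ribosomal and neuroblast scores below the 0.3 quantile;
pre-activated RG additionally have high ribosomal score; neuroblasts have
low glial and high ribosomal and neuroblast scores; everything else —
including an optional excluded list of proliferating cells supplied via a
cell-cycle set — is "other". The 0.7/0.3 quantiles are explicit stand-ins
for a selection originally made by eye on score scatter plots; they are
configurable and documented as such.

# Signed AUROC ranking and preranked GSEA

Each gene is used as a one-dimensional classifier for a target cell set;
the signed statistic is $2\,\mathrm{AUC} - 1 \in [-1, 1]$, computed from
mid-tie ranks, so the sign says whether the gene's expression favors the
target or its complement. The raw AUC is exposed as an attribute.

Preranked GSEA uses the weighted Kolmogorov–Smirnov running sum with
weight |statistic|, a gene-label permutation null (the set is reassigned
to random ranking positions), NES = ES divided by the mean |null ES| of
the same sign, same-signed tail p-values with the +1 convention, and BH
correction across sets. The running-sum extremes occur only at hit
boundaries, which allows an $O(m \log m)$ evaluation per set and makes the
200-draw null-calibration check cheap. The enrichment scores agree with an
independent implementation (`fgsea`) to 1e-6 in the test suite, while the
permutation machinery remains this package's own.

# Pseudo-ordering of quiescence depth

The stage mirrors the custom trajectory reconstruction it re-implements:

1. **Diffusion map** on variable genes: Gaussian kernel with local
   bandwidth (distance to the 10th neighbor), row-normalized transition
   matrix, eigendecomposition through the symmetric conjugate, components
   2..(k+1) scaled by eigenvalues. A disconnected kernel graph is
   reconnected through the symmetric kNN union with a warning.
2. **Bootstrapped MST distances**: 1,000 minimum spanning trees, each on a
   two-thirds subsample without replacement; the distance between two
   cells is their mean along-tree path length over the trees containing
   both. Path length is the summed Euclidean edge length (the alternative —
   edge count — is noted but not used; Euclidean lengths preserve scale
   information for the MDS step). Pairs never co-sampled (possible at
   small tree counts) are imputed by shortest paths through the
   observed-distance graph, which converges to a no-op as the tree count
   grows. The inner loop (Prim's algorithm plus per-root path
   accumulation) is compiled code; 1,000 trees over 800 cells take a few
   seconds.
3. **Classical MDS** to 3 dimensions (double-centered, top eigenvectors),
   with Kruskal stress reported and zero-padding if the distance rank is
   deficient.
4. **Elastic principal tree** with at most 100 nodes, minimizing mean
   squared point-to-node distance plus $\lambda$ times summed squared edge
   lengths (stretching, default 0.01) and $\mu$ times squared deviation of
   each non-leaf node from its neighbors' mean (bending/branching
   stiffness, default 0.1). All energy terms are quadratic in length, so
   the parameters are scale-free. Growth is by topological grafting: at
   each step the best of bisecting a high-error edge or grafting a leaf at
   a high-error node is applied, chosen among the 5 highest-error
   candidates of each kind after local re-optimization. Five candidates
   rather than fewer is load-bearing: with too few candidates the greedy
   growth can commit to a branch that breaks the backbone of a noisy
   filament.
5. **Pruning**: maximal paths between topological nodes whose two
   endpoint neighborhoods are dominated by the same cluster are removed,
   shortest spurs first, only when the graph stays connected and every
   dominant cluster stays represented; with a single cluster this
   degenerates to keeping at most one path, which is the guard against
   infinite pruning and also the behavior wanted on a planted linear
   trajectory. In a tree only spur paths can be removed without
   disconnection.
6. **Projection and ordering**: orthogonal projection onto the nearest
   edge (parameter clamped to the segment), pseudo-order = along-graph
   distance from the root scaled to [0, 1], branch = maximal-path id of
   the projected edge. The root is chosen as the tip whose projected cells
   have the highest glial-minus-ribosomal score — the deep-quiescence end —
   and is overridable; the original analysis oriented the axis by biology,
   not algorithmically.
7. **Depth-associated genes**: per-gene Spearman correlation with the
   pseudo-order, t-approximation p-values, BH-FDR; the signed correlations
   feed directly into the preranked GSEA.

On the standard trajectory benchmark the full stack recovers the planted
depth with |Spearman| ≥ 0.9 across seeds, and doubling the tree count
changes the ordering by less than 1% rank correlation.

# Cross-species homology

Counts are collapsed onto ortholog groups by summation over paralogs —
summation, not mean or max, preserves the count nature of the data for
downstream normalization, and keeps the teleost one-to-many duplicates
instead of discarding them. Every collapse is recorded in an audit table;
total counts are conserved up to exactly the genes without a group.

Cluster homology is scored by a re-implementation of the neighbor-voting
procedure: a cell–cell Spearman correlation network over shared variable
groups (selected by the same variance-stabilizing ranking on the combined
matrix), row-normalized into voting weights; each training cluster's
labels vote across the network, and the AUROC of the received votes for
each test cluster is recorded; the two directions are averaged. A test
side with a single cluster is trivially recovered and reported as 1 by
contract.

Per-cluster gene-set co-expression is classified three ways, formalizing a
call originally applied qualitatively: "co-expressed" when some cluster's
mean module score exceeds the 0.99 quantile of random-set nulls and a
strict majority of the set's genes are individually enriched in that same
cluster (one-sided rank test at the gene's best cluster, Bonferroni over
the cluster choice, then BH across the set's genes — without the
Bonferroni step the best-of-K selection inflates gene-level calls);
"spread" when genes are individually enriched across two or more clusters
with no single qualifying cluster; "absent" otherwise; "not evaluable"
below 3 covered groups.

# Clonal statistics

The proportion of RG-only clones (clones containing only radial glia,
whether one or many cells) is reported with a hierarchical percentile
bootstrap: hemispheres are resampled first, then clones within each
resampled hemisphere, respecting the clustering of clones within animals.
The comparison against the deep-quiescent cluster's population share uses
an exact two-sided binomial test by minimum-likelihood summation (all
outcomes at most as likely as the observed one, with the same relative
tolerance factor as the standard implementation — the test suite checks
agreement with `binom.test` to 1e-12 across a parameter grid).

Expression-in-clones comparisons use the Mann–Whitney U test (exact null
when tie-free and small, tie-corrected normal approximation with
continuity correction otherwise) together with Cliff's delta
$(\#\{x>y\} - \#\{x<y\})/(nm)$ and a 10,000-replicate percentile bootstrap
CI. Ties count half in U, so $\delta = 2U/(nm) - 1$ holds exactly — an
identity asserted in the tests. The percentile bootstrap for the delta CI
is a design choice; the original report does not state its CI method.

# Orchestration and determinism

`pipeline_config()` holds every stage parameter in one flat, serializable
list, with the stage defaults above. `run_pipeline()` executes the enabled
stages in order, writes artifacts when an output directory is given, and
returns a manifest recording the per-stage seeds. One global seed fans out
to per-stage seeds through a fixed affine map, so toggling one stage never
perturbs another stage's random stream; identical config and seed give
identical outputs. The exported functions and `run_pipeline()` are the
package's interface; there is no shell entry point, as the natural unit of
use is an R session or script.

# Problem sizes used in validation

The test suite and the acceptance script use: 1,500 cells / 6 clusters /
30 markers at log fold change 2 for clustering; 1,000 cells with 10%
low-quality for QC; 1,000 cells with 5% injected doublets and one mock per
cell for doublet detection; 800 cells / 1,000 trees / 100 nodes for the
pseudo-ordering; 300 cells / 4 clusters for homology; 300 clones over 30
hemispheres for the clonal contrast; 200 random draws at 500 permutations
for the GSEA null calibration. These sizes were chosen so each planted
effect is comfortably identifiable while a complete validation run stays
in the minutes range on one CPU.

# Known limitations

- Density estimation (density peaks) and mixture fitting degrade above ~8
  embedding dimensions; both are therefore restricted to the leading
  components, and density peaks' automated center rule can be unstable on
  data without clear peaks.
- The elastic tree growth is greedy; pathological embeddings can still
  produce spurious branches, which is what the cluster-based pruning is
  for. Cycles are out of scope — topologies are trees only.
- Quantile-based gating assumes the population prevalences are roughly
  compatible with the chosen quantiles; strongly unbalanced datasets need
  adjusted quantiles.
- The mock-doublet detector needs cluster structure: within one
  homogeneous population, doublets are not geometrically distinguishable.
- Cross-species calls depend on the quality of the supplied ortholog
  table; the package harmonizes and audits, it does not infer orthology.
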