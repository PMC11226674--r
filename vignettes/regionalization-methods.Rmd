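---
title: "Methods: turnover-based regionalization and map comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: turnover-based regionalization and map comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical machinery in `betaregion`: the
turnover model and its assumptions, the regionalization procedure, the
V-measure comparison with its null models, the synthetic data generator the
package validates itself on, and the numerical choices made where a
published description leaves the details open.

## Turnover

Dissimilarity between two cell assemblages X and Y is the turnover
component of beta diversity, Simpson's index

$$\beta_{sim} = 1 - \frac{a}{\min(b, c) + a},$$

where in taxonomic mode $a = |X \cap Y|$, $b = |X \setminus Y|$,
$c = |Y \setminus X|$, and in phylogenetic mode $a$, $b$, $c$ are summed
branch lengths of the tree edges incident to both cells, only X, or only Y.
An edge is incident to a cell when at least one of its descendant tips
occurs there, so a cell's edge set is automatically closed under the
ancestor relation. Taking the min of the unique fractions makes the index
insensitive to richness difference: a strict subset scores 0 (pure
nestedness is not turnover) and branch- or taxon-disjoint assemblages score
1. Note that taxon-disjoint assemblages are *not* generally branch-disjoint
— deep edges whose descendants span both assemblages contribute to $a$ —
so phylogenetic turnover between taxonomically disjoint cells can be well
below 1; it equals taxonomic turnover exactly on a star phylogeny with unit
branch lengths, which the tests assert.

Choices worth stating:

* **Root edge.** A stem edge below the root (if the Newick has one) is
  excluded: it is shared by every non-empty assemblage and carries no
  turnover information. Edges in the topology proper are all used.
* **Taxa missing from the tree** are dropped with a warning and a count
  (`n_dropped_taxa`), mirroring the incomplete phylogenetic coverage of
  real compilations. A cell left with no tree-matched taxon is an error,
  not a silent zero.
* **Zero-length branches** are kept; they contribute 0 to every component
  either way.
* **Posterior uncertainty.** Pβsim is computed per tree and summarized by
  the elementwise median; an even tree count uses the midpoint of the two
  central order statistics, with no interpolation scheme beyond that.
* **Performance contract.** The cell × edge incidence matrix is built once
  per tree and all pairs are computed by one matrix product, never by a
  per-pair tree traversal. A 400-cell, 96-tip matrix takes well under a
  second; the tests verify elementwise equality (1e-12) with a naive
  per-pair enumeration.

Per-cell *distinctiveness* is the mean of a cell's dissimilarities to all
other cells — a map of biotic uniqueness.

## Regionalization

Seven agglomerative linkages are candidates: UPGMA, WPGMA, WARD, CL, SL,
UPGMC, WPGMC (that order is the package's a-priori preference; see below).
Each dendrogram is scored against the input dissimilarities by the Pearson
correlation of cophenetic versus input distances and by the Gower
distortion (sum of squared deviations). The selected linkage maximizes the
correlation, breaking ties by minimal distortion and then by the preference
order; scores equal to within 1e-12 are treated as exact ties so
floating-point noise cannot overturn the preference. On ultrametric input
several linkages reproduce the input perfectly, and the tie rule then
yields UPGMA — the standard choice in this literature, and the method the
selection procedure is expected to confirm on well-structured data. Ward's
method is `ward.D2` (squared-dissimilarity Ward on the raw input), the
textbook form.

**Cluster count.** For each k up to 30 the dendrogram is cut and the
variance explained is computed as

$$VE(k) = 1 - \frac{\sum_{\text{within-cluster pairs}} d^2}
                  {\sum_{\text{all pairs}} d^2},$$

the complement of the within/total squared-dissimilarity ratio. No
published formula exists for this curve in the regionalization literature;
this definition is standard, costs one pass over the matrix, and is
provably nondecreasing for nested cuts, with VE(1) = 0 and VE(n) = 1. The
region count is the elbow: the interior k maximizing perpendicular distance
to the chord joining the curve's endpoints after min–max normalization of
both axes (ties to the smallest k). "Maximum curvature" admits several
operationalizations; the normalized chord rule is scale-free and
deterministic. A perfectly linear curve has no elbow and returns the
smallest interior k with a warning; an all-zero dissimilarity matrix yields
a degenerate curve of ones, also with a warning.

**Validity rules.** A cluster is a valid region only if (i) it has strictly
more than `min_cells = 10` cells — the strict reading, so an 11-cell
cluster is the smallest valid region — and (ii) it is spatially aggregated.
Aggregation is operationalized as: the largest connected component of the
cluster on the grid adjacency graph contains at least
`aggregation_threshold = 0.5` of its cells (a cluster split 6/6 between two
distant patches sits exactly at the boundary and passes at 0.5, fails at
0.6). The threshold is configurable because "clearly aggregated in space"
has no canonical number. Cells of invalid clusters are labelled
`"unassigned"` and excluded from downstream comparisons.

**Realms.** The realm tier re-cuts the *same* dendrogram at the elbow
recomputed over k strictly below 15. Because cuts of one dendrogram nest,
every region falls wholly inside one realm; the majority rule in
`assign_realms()` is therefore unanimous and exists only as a guard for
dendrograms supplied from elsewhere.

## Ordination

NMDS minimizes Kruskal stress-1 with monotone regression of configuration
distances on dissimilarity ranks. The isotonic engine is `vegan::monoMDS`;
`nmds()` runs it from `n_starts` random uniform initial configurations
(default 200 in the analysis scripts — enough to make the best-of-starts
stress reproducible across seeds in practice) and keeps the lowest-stress
solution. Convergence uses a stress-gradient tolerance of 1e-7 and a
minimum-stress cutoff of 1e-6 within at most 300 iterations per start. Ties
among equal dissimilarities get Kruskal's primary treatment by default
(`weakties = TRUE`, vegan's default); strict secondary ties can be
requested through `...` — the difference matters only for degenerate
inputs such as all-equal dissimilarity matrices, which flatten to zero
stress under primary ties but not under strict ones.

The configuration is then superimposed on the cell centroids by orthogonal
Procrustes (translation, rotation, reflection, uniform scaling — reflection
and scaling included because only the similarity class of the configuration
is identified by NMDS). Stress is untouched by a similarity transform, and
the tests assert it.

## Map comparison

Two regionalizations are reduced to an area cross-tabulation over the cells
valid in both (unassigned cells are outside every region and drop out).
With joint area fractions $p_{ij}$ and natural-log Shannon entropies,
homogeneity $h = 1 - H(B|A)/H(B)$, completeness $c = 1 - H(A|B)/H(A)$, and
the V-measure $V_\beta = 2hc/(h+c)$ — the area-weighted harmonic mean. The
log base cancels in $h$ and $c$; it matters only for the per-region
homogeneity map, $1 - H(B \mid A{=}i)/\log n_B$, which is normalized by the
compared scheme's region count ($1$ when $n_B = 1$). Degenerate margins are
defined by continuity: $h = 1$ when $H(B) = 0$, $c = 1$ when $H(A) = 0$,
$V_\beta = 0$ when $h + c = 0$.

**Null models.** Each direction of a comparison gets its own null: scheme A
is compared against `n_null = 999` random Voronoi regionalizations built
with B's observed region count (seed cells sampled uniformly without
replacement, each cell assigned to the nearest seed centroid, distance ties
to the lowest seed index), and vice versa. Only the region *count* of the
randomized scheme is preserved, not its region areas — the Voronoi
construction decides the rest. p-values use the add-one estimator
$(\#\{V_{null} \ge V_{obs}\} + 1)/(n_{null} + 1)$: ties count against
significance and p = 0 is impossible, which is mildly conservative
relative to reporting raw proportions. SES is
$(V_{obs} - \bar V_{null})/\mathrm{sd}(V_{null})$, reported per direction
and never pooled; it is `NA` when the null distribution has zero spread.
Under independent Voronoi pairs the discrete null distribution of p is
uniform on $\{1/(n+1), \dots, 1\}$, so the exact rejection probability at
$\alpha = 0.05$ with 199 nulls is $9/200 = 0.045$; the calibration test
checks the observed rate against that value, and that the SES mean sits
within $\pm 0.3$ of zero.

The Mantel test between two dissimilarity matrices is the Pearson
correlation of upper-triangle vectors with a two-sided permutation p-value
(simultaneous row/column permutation of the second matrix, add-one
estimator).

## Synthetic data: what it emulates, and what it does not

The generator stands in for a continental-scale study system: an equal-area
hexagon lattice plays the role of a Behrmann-projected hexagon grid (cell
area defaults to 5 × 10⁴ km²); a Yule tree (birth rate 1 — the rate only
scales branch lengths, which βsim normalizes away) plays the reconstructed
phylogeny; a jittered posterior multiplies each branch by independent
lognormal(0, `sd_log = 0.1`) noise with fixed topology, since the
dissimilarity consumes branch lengths and topology noise is a separate
question; planted Voronoi regions give ground truth; and assemblages are
clade-structured — tips are partitioned into one clade pool per region and
each cell draws `richness` distinct taxa, each from its own region's pool
with probability $1 - \text{mixing}$, otherwise from the union of the
*other* pools.

Clade pools are built by cutting the tree at a root-to-node depth and
greedily merging the smallest resulting subtrees down to the requested
count; all depths are scanned and the shallowest cut whose merged partition
maximizes the minimum pool size (then minimizes the size spread) is kept.
Balance matters: a pool smaller than `richness` would force cells of that
region to draw foreign taxa regardless of `mixing`, silently corrupting the
planted signal. With mixing = 0 a pool smaller than `richness` is an error
for the same reason.

One subtlety of the mixing definition: because a foreign draw excludes the
cell's own clade, regions sample overlapping but *unequal* taxon unions at
mixing = 1, so a small structural between/within contrast survives full
mixing. With equal richness r the index is linear in the shared count
($\beta_{sim} = 1 - a/r$), making the expected contrast exactly computable;
the property test asserts the computed value (≈ 0.056 under its sizes)
rather than a zero gap.

Default study conditions for the recovery experiments — a 20 × 20 lattice
(400 cells), 4 regions, richness 12, mixing 0.05, and 20 replicate seeds —
with 96 tips, chosen so that clade pools (~24 taxa) are twice the cell
richness: within-region cells then share about half their taxa
(Tβsim ≈ 0.5) against near-disjoint between-region assemblages, a planted
signal that is strong but far from trivial. Since richness ≥ 5 is enforced,
every generated cell passes the small-assemblage filter (< 5 taxa), which
otherwise excludes cells before any dissimilarity is computed.

What the generator does **not** emulate: real Earth geometry (no
projection, no coastline, all cells full-area), macroevolutionary realism
(no trait evolution or dispersal kernels), occurrence sampling bias, or
topological phylogenetic uncertainty. Passing the recovery tests therefore
shows the pipeline's statistical machinery is correct and well calibrated
on clean planted structure — not that any particular empirical
regionalization is right.

## Reproducibility and problem sizes

Every stochastic function takes an explicit integer seed; pipeline-level
seeds derive stage seeds by fixed offsets, and the determinism test checks
that two runs of the full pipeline produce byte-identical CSV/JSON output.
The shipped analysis uses 400 cells with a 100-tree posterior; the test
suite and the acceptance script use the same 400-cell recovery conditions
plus smaller grids (144–200 cells, 10–25 posterior trees, 199 nulls for the
200-replicate calibration, 999 elsewhere) — sizes at which every quantity
is stable to well inside the asserted tolerances while the whole suite
stays fast on a single CPU.

## Known limitations

* Hierarchical clustering forces a nested structure; transitional cells are
  handled only by the validity rules ("unassigned"), not by fuzzy
  membership. Network- or community-detection regionalization is out of
  scope.
* The elbow is a heuristic; on curves without a pronounced kink (weak
  spatial structure, high mixing) the selected k is unstable, and the
  variance-explained definition, while standard, is one of several
  reasonable choices.
* The Voronoi null preserves region count only; schemes whose region-size
  distribution is far from Voronoi-like will see conservative or liberal
  SES depending on direction.
* Spatially autocorrelated significance corrections (e.g. modified t-tests
  for the Mantel correlation) are not implemented; p-values treat cells as
  exchangeable units.
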