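# betaregion

Quantitative biogeographic regionalization from assemblage and phylogenetic
data, with statistical comparison of independent regionalization schemes.

`betaregion` is aimed at biogeographers who want to delineate regions from a
cell × taxon presence matrix the way modern global regionalizations of
vertebrates, plants and insects are built: from the turnover component of
beta diversity, optionally weighted by evolutionary history, clustered into
a nested hierarchy of regions and realms, ordinated for visualization, and
compared across taxa with an information-theoretic map-comparison statistic
under spatial null models.

## The quantities at its core

**Simpson turnover.** For two assemblages with shared quantity *a* and
unique quantities *b*, *c*,

    βsim = 1 − a / (min(b, c) + a)

In taxonomic mode (Tβsim) *a*, *b*, *c* count shared and unique taxa; in
phylogenetic mode (Pβsim) they are summed lengths of the phylogeny's
branches incident to one or both cells (a branch is incident to a cell if
any of its descendant tips occurs there). βsim is insensitive to richness
differences: nested assemblages score 0, disjoint ones 1. Phylogenetic
uncertainty is handled by computing Pβsim over a posterior sample of trees
and taking the elementwise median.

**Regionalization.** Seven agglomerative linkages (UPGMC, WARD, SL, CL,
WPGMA, WPGMC, UPGMA) are scored by cophenetic Pearson correlation and Gower
distance (sum of squared cophenetic deviations); the best dendrogram is cut
at the elbow (maximum curvature) of the variance-explained-vs-k curve
(k ≤ 30). A cluster is a valid region only if it has more than 10 cells and
its largest connected component on the grid adjacency graph holds at least
half its cells; other cells stay "unassigned". Realms re-cut the same
dendrogram at the elbow below 15 clusters, so regions nest inside realms.

**Map comparison.** Two regionalizations are compared through the
area-weighted V-measure: with joint area fractions p_ij and Shannon
entropies, homogeneity h = 1 − H(B|A)/H(B), completeness
c = 1 − H(A|B)/H(A), and Vβ = 2hc/(h+c). Significance comes from 999 random
Voronoi regionalizations per direction (preserving each scheme's region
count), giving two directional p-values and standardized effect sizes.

Everything runs on synthetic data with known ground truth: a hexagonal
lattice, a Yule phylogeny, planted Voronoi regions, and clade-structured
assemblages with tunable cross-region mixing.

## Worked example

The `analysis/` directory holds the five-stage workflow; each stage is a
thin driver over exported functions and writes its tables under `results/`:

```sh
Rscript analysis/01_simulate.R     # grid, tree, posterior, planted truth
Rscript analysis/02_turnover.R     # Tβsim + posterior-median Pβsim
Rscript analysis/03_regionalize.R  # linkage selection, elbow, regions, realms
Rscript analysis/04_ordinate.R     # NMDS (200 starts) rotated to geography
Rscript analysis/05_compare.R      # V-measure vs truth + Voronoi nulls
```

Output of a complete run (400 cells, 96 taxa, 4 planted regions,
mixing 0.05, 100 posterior trees):

```
Simulated 400 cells x 96 taxa; 4 planted regions; 100 posterior trees.
400 cells retained by the >=5-taxa filter.
Median Pbsim range: 0.008-1.000; distinctiveness 0.594-0.795.
Mantel r between Tbsim and Pbsim: 0.944 (p = 0.001).
Best linkage: UPGMA (cophenetic r = 0.948, Gower d = 728.7).
Elbow at k = 4 regions (VE = 0.972).
4 valid regions in 4 realms; 0 cells unassigned.
Adjusted Rand index against planted truth: 1.000.
NMDS stress-1 = 0.1236 (best of 200 starts: start 165).
Recovered vs truth: V = 1.000 (h = 1.000, completeness = 1.000).
Null test: p_a = 0.001, p_b = 0.001; SES 7.6 / 7.2.
Negative control (independent Voronoi): V = 0.375, p_a = 0.706, SES -0.6.
```

Read: the pipeline recovers the planted regionalization exactly (ARI and
V-measure 1), the association with truth is far beyond the Voronoi null
(SES ≈ 7.6, p = 0.001 with 999 nulls), while an unrelated Voronoi scheme is
correctly judged non-significant; the taxonomic and phylogenetic turnover
structures agree strongly (Mantel r 0.94).

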