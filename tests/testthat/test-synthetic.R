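test_that("simulate_phylogeny produces rooted binary Yule trees deterministically", {
  expect_error(simulate_phylogeny(0), "n_tips")

  t1 <- simulate_phylogeny(1, seed = 3)
  expect_s3_class(t1, "phylo")
  expect_equal(length(t1$tip.label), 1L)

  t8 <- simulate_phylogeny(8, seed = 3)
  expect_equal(length(t8$tip.label), 8L)
  expect_equal(nrow(t8$edge), 14L)          # 2n - 2 edges, rooted binary
  expect_true(all(t8$edge.length > 0))
  expect_true(ape::is.rooted(t8))
  expect_true(ape::is.binary(t8))

  a <- ape::write.tree(simulate_phylogeny(50, seed = 1))
  b <- ape::write.tree(simulate_phylogeny(50, seed = 1))
  expect_identical(a, b)
  expect_false(identical(a, ape::write.tree(simulate_phylogeny(50, seed = 2))))
})

test_that("jitter_posterior keeps topology and matches the lognormal mean", {
  tree <- simulate_phylogeny(20, seed = 4)

  same <- jitter_posterior(tree, n_trees = 5, sd_log = 0, seed = 1)
  expect_length(same, 5L)
  for (tr in same) expect_equal(tr$edge.length, tree$edge.length)

  post <- jitter_posterior(tree, n_trees = 100, sd_log = 0.2, seed = 7)
  expect_length(post, 100L)
  for (tr in post[1:3]) expect_identical(tr$edge, tree$edge)

  # multiplicative lognormal(0, sd) noise has mean exp(sd^2/2)
  ratios <- vapply(post, function(tr) tr$edge.length / tree$edge.length,
                   numeric(length(tree$edge.length)))
  expect_equal(mean(ratios), exp(0.2^2 / 2), tolerance = 0.02)
})

test_that("plant_regions matches a brute-force nearest-seed oracle", {
  g <- build_hex_grid(20, 20, 1)
  expect_error(plant_regions(g, 401), "n_regions")

  expect_length(unique(plant_regions(g, 1, seed = 1)), 1L)
  expect_length(unique(plant_regions(g, 400, seed = 1)), 400L)

  lab <- plant_regions(g, 4, seed = 7)
  expect_setequal(unique(lab), sprintf("r%d", 1:4))

  # brute-force double loop over cells and seed cells
  set.seed(7)
  coords <- grid_centroids(g)
  seed_idx <- sample.int(400, 4)
  for (i in seq_len(nrow(coords))) {
    d <- (coords[i, 1] - coords[seed_idx, 1])^2 +
         (coords[i, 2] - coords[seed_idx, 2])^2
    expect_identical(unname(lab[i]), sprintf("r%d", which.min(d)))
  }

  # planted regions are connected on a convex lattice
  for (r in unique(lab)) {
    frac <- betaregion:::largest_component_fraction(names(lab)[lab == r], g)
    expect_equal(frac, 1)
  }
})

test_that("tree_clades gives balanced phylogenetic pools", {
  tree <- simulate_phylogeny(96, seed = 2)
  pools <- tree_clades(tree, 4)
  expect_length(pools, 4L)
  expect_setequal(unlist(pools), tree$tip.label)
  expect_gte(min(lengths(pools)), 12L)      # balanced enough for richness 12
  expect_identical(tree_clades(tree, 1), list(tree$tip.label))
})

test_that("simulate_assemblages respects mixing semantics", {
  g <- build_hex_grid(6, 6, 1)
  tree <- simulate_phylogeny(60, seed = 9)
  regions <- plant_regions(g, 3, seed = 9)

  expect_error(simulate_assemblages(tree, regions, richness = 100),
               "richness")

  pm0 <- simulate_assemblages(tree, regions, mixing = 0, richness = 10,
                              seed = 1)
  expect_true(all(rowSums(pm0) == 10L))
  # at mixing 0 every taxon occurs in cells of exactly one region
  for (tx in colnames(pm0)[colSums(pm0) > 0]) {
    expect_length(unique(regions[rownames(pm0)[pm0[, tx] == 1L]]), 1L)
  }
  # and two cells of different regions are fully disjoint
  cells <- names(regions)[!duplicated(regions)][1:2]
  expect_equal(betasim(pair_components(pm0, cells[1], cells[2], "taxonomic")),
               1)

  # determinism
  pm0b <- simulate_assemblages(tree, regions, mixing = 0, richness = 10,
                               seed = 1)
  expect_identical(pm0, pm0b)
})

test_that("mixing erodes the between/within turnover contrast", {
  # At mixing = 1 foreign draws exclude the cell's own clade, so a small
  # structural contrast survives (different regions sample overlapping but
  # unequal unions); the planted contrast must still collapse by an order of
  # magnitude relative to mixing = 0.
  g <- build_hex_grid(25, 20, 1)   # 500 cells
  tree <- simulate_phylogeny(80, seed = 5)
  regions <- plant_regions(g, 4, seed = 5)
  gap_at <- function(mixing) {
    pm <- simulate_assemblages(tree, regions, mixing = mixing, richness = 10,
                               seed = 5)
    D <- betasim_matrix(pm, "taxonomic")
    same <- outer(regions, regions, "==")[rownames(D), rownames(D)]
    off <- upper.tri(D)
    mean(D[off & !same]) - mean(D[off & same])
  }
  g0 <- gap_at(0)
  g5 <- gap_at(0.5)
  g1 <- gap_at(1)
  expect_true(g0 > g5 && g5 > g1)
  # with equal richness r = 10, bsim = 1 - a/10 is linear in the shared count,
  # so the expected gaps follow from E[a] = sum_t P(x has t) P(y has t):
  # mixing 0: within pools of 20 -> E[a] = 20*(1/2)^2 = 5; between disjoint
  # -> gap 0.5.  mixing 1: both cells draw from 60-taxon unions sharing 60
  # (within) or 40 (between) taxa -> E[a] = 60/36 vs 40/36 -> gap 5/90.
  expect_equal(g0, 0.5, tolerance = 0.05)
  expect_equal(g1, 5 / 90, tolerance = 0.15)
})

test_that("planted signal: between-region turnover exceeds within at mixing 0", {
  g <- build_hex_grid(10, 10, 1)
  tree <- simulate_phylogeny(64, seed = 11)
  regions <- plant_regions(g, 4, seed = 11)
  pm <- simulate_assemblages(tree, regions, mixing = 0, richness = 12,
                             seed = 11)
  D <- median_posterior_betasim(pm, jitter_posterior(tree, 3, 0.1, seed = 11))
  labs <- regions[rownames(D)]
  for (r1 in unique(labs)) for (r2 in unique(labs)) {
    if (r1 >= r2) next
    between <- mean(D[labs == r1, labs == r2])
    within <- mean(c(D[labs == r1, labs == r1][upper.tri(D[labs == r1, labs == r1])],
                     D[labs == r2, labs == r2][upper.tri(D[labs == r2, labs == r2])]))
    expect_gt(between, within)
  }
})

test_that("adjusted Rand index matches brute-force pair counting and mclust", {
  items <- sprintf("i%d", 1:6)
  a <- setNames(c(1, 1, 1, 2, 2, 2), items)
  b <- setNames(c(1, 1, 2, 1, 2, 2), items)   # contingency [[2,1],[1,2]]

  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(setNames(rep(1, 6), items), b), 0)
  expect_error(adjusted_rand_index(a, b[1:5]), "cell set")

  # brute-force over all C(6,2) pairs
  pairs <- combn(items, 2)
  s_ab <- s_a <- s_b <- s_n <- 0
  for (p in seq_len(ncol(pairs))) {
    sa <- a[pairs[1, p]] == a[pairs[2, p]]
    sb <- b[pairs[1, p]] == b[pairs[2, p]]
    if (sa && sb) s_ab <- s_ab + 1
    if (sa) s_a <- s_a + 1
    if (sb) s_b <- s_b + 1
    s_n <- s_n + 1
  }
  exp_idx <- s_a * s_b / s_n
  oracle <- (s_ab - exp_idx) / ((s_a + s_b) / 2 - exp_idx)
  expect_equal(adjusted_rand_index(a, b), oracle)
  expect_equal(adjusted_rand_index(a, b),
               mclust::adjustedRandIndex(a, b[names(a)]))
})

test_that("simulate_biogeography is reproducible bit-for-bit", {
  s1 <- simulate_biogeography(n_cols = 6, n_rows = 6, n_regions = 2,
                              n_tips = 30, richness = 6, mixing = 0.1,
                              n_trees = 2, seed = 42)
  s2 <- simulate_biogeography(n_cols = 6, n_rows = 6, n_regions = 2,
                              n_tips = 30, richness = 6, mixing = 0.1,
                              n_trees = 2, seed = 42)
  expect_identical(s1$pm, s2$pm)
  expect_identical(s1$truth, s2$truth)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  expect_identical(lapply(s1$trees, `[[`, "edge.length"),
                   lapply(s2$trees, `[[`, "edge.length"))
})
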