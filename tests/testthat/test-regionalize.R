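three_cell_D <- function() {
  D <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  D
}

test_that("UPGMA reproduces the hand-worked 3-cell dendrogram", {
  D <- three_cell_D()
  dend <- hierarchical_cluster(D, "UPGMA")
  expect_equal(dend$height, c(2, 6))       # (A,B) at 2, then C at 6
  expect_equal(length(dend$height), 2L)    # n - 1 merges
  coph <- as.matrix(stats::cophenetic(dend))[rownames(D), colnames(D)]
  expect_equal(coph, D)                    # ultrametric input: fixed point

  ev <- evaluate_dendrogram(dend, D)
  expect_equal(ev$cophenetic_r, 1)
  expect_equal(ev$gower_d, 0)

  expect_error(hierarchical_cluster(D, "KMEANS"), "unknown linkage")
})

test_that("evaluate_dendrogram matches explicit 3-pair Pearson computation", {
  D <- three_cell_D()
  D["A", "B"] <- D["B", "A"] <- 3          # perturb: no longer ultrametric
  dend <- hierarchical_cluster(D, "SL")
  ev <- evaluate_dendrogram(dend, D)
  coph <- as.vector(stats::cophenetic(dend))
  input <- as.vector(stats::as.dist(D))
  expect_equal(ev$cophenetic_r, stats::cor(coph, input))
  expect_equal(ev$gower_d, sum((coph - input)^2))

  Dc <- matrix(1, 3, 3); diag(Dc) <- 0
  dimnames(Dc) <- dimnames(D)
  expect_error(evaluate_dendrogram(hierarchical_cluster(Dc, "SL"), Dc),
               "constant")
})

test_that("gower distance scales quadratically with the dissimilarities", {
  set.seed(71)
  D <- as.matrix(dist(matrix(runif(20), 10, 2)))
  dimnames(D) <- list(sprintf("c%d", 1:10), sprintf("c%d", 1:10))
  ev1 <- evaluate_dendrogram(hierarchical_cluster(D, "CL"), D)
  ev2 <- evaluate_dendrogram(hierarchical_cluster(2 * D, "CL"), 2 * D)
  expect_equal(ev2$gower_d, 4 * ev1$gower_d)
  expect_equal(ev2$cophenetic_r, ev1$cophenetic_r)
})

test_that("select_algorithm maximizes cophenetic r with Gower tie-break", {
  one <- data.frame(method = "WARD", cophenetic_r = 0.5, gower_d = 1)
  expect_equal(select_algorithm(one), "WARD")
  expect_equal(select_algorithm(
    data.frame(method = c("UPGMA", "WARD"),
               cophenetic_r = c(0.9, 0.7), gower_d = c(1, 1))), "UPGMA")
  expect_equal(select_algorithm(
    data.frame(method = c("WPGMA", "UPGMA"),
               cophenetic_r = c(0.8, 0.8), gower_d = c(2, 1))), "UPGMA")
  expect_equal(select_algorithm(
    data.frame(method = c("CL", "SL"),
               cophenetic_r = c(0.8, 0.8), gower_d = c(1, 1))), "CL")
  expect_error(select_algorithm(NULL), "no algorithm")

  # on ultrametric input UPGMA is a perfect fit and wins
  D <- three_cell_D()
  expect_equal(select_algorithm(evaluate_algorithms(D)), "UPGMA")
})

test_that("variance-explained curve has its analytic endpoints and block value", {
  set.seed(72)
  X <- matrix(runif(30), 15, 2)
  D <- as.matrix(dist(X))
  dimnames(D) <- list(sprintf("c%d", 1:15), sprintf("c%d", 1:15))
  dend <- hierarchical_cluster(D, "UPGMA")
  curve <- variance_explained_curve(D, dend, k_max = 15)
  expect_equal(curve$variance_explained[1], 0)
  expect_equal(curve$variance_explained[15], 1)
  expect_true(all(diff(curve$variance_explained) >= -1e-12))

  # two perfectly separated blocks: within d = 0, between d = 1 -> VE(2) = 1
  B <- matrix(1, 6, 6)
  B[1:3, 1:3] <- 0
  B[4:6, 4:6] <- 0
  dimnames(B) <- list(letters[1:6], letters[1:6])
  dendB <- hierarchical_cluster(B, "UPGMA")
  curveB <- variance_explained_curve(B, dendB, k_max = 6)
  expect_equal(curveB$variance_explained[2], 1)
  expect_equal(elbow(curveB), 2)
})

test_that("elbow picks the maximum chord distance with degenerate fallback", {
  curve <- data.frame(k = 1:5, variance_explained = c(0, 0.8, 0.85, 0.88, 0.9))
  expect_equal(elbow(curve), 2)

  linear <- data.frame(k = 1:5, variance_explained = seq(0, 1, 0.25))
  expect_warning(k <- elbow(linear), "no elbow")
  expect_equal(k, 2)

  expect_error(elbow(data.frame(k = 1:2, variance_explained = c(0, 1))),
               "at least 3")
})

test_that("region validity: strict size rule and spatial aggregation", {
  g <- build_hex_grid(12, 12, 1)
  # hand-build a dendrogram via a block dissimilarity with three groups:
  # a compact 50-cell group, a compact 10-cell group (too small), and the rest
  ids <- g$cells$cell_id
  grp <- rep("big", 144)
  grp[1:50] <- "A"                 # first 50 lattice cells: contiguous rows
  grp[61:70] <- "S"                # exactly 10 cells: strict rule -> invalid
  names(grp) <- ids
  D <- outer(grp, grp, FUN = function(a, b) ifelse(a == b, 0, 1))
  diag(D) <- 0
  dimnames(D) <- list(ids, ids)
  dend <- hierarchical_cluster(D, "UPGMA")
  reg <- delineate_regions(dend, 3, g, min_cells = 10)
  lab <- setNames(reg$region, reg$cell_id)
  expect_true(all(lab[names(grp)[grp == "S"]] == "unassigned"))
  expect_true(all(lab[names(grp)[grp == "A"]] != "unassigned"))
  expect_equal(sort(unique(reg$region[reg$valid])),
               sort(unique(lab[lab != "unassigned"])))
})

test_that("aggregation threshold splits exactly at the component fraction", {
  g <- build_hex_grid(20, 6, 1)
  ids <- g$cells$cell_id
  # 6 cells on the left edge + 6 on the right edge: two distant components
  left <- ids[c(1, 2, 21, 22, 41, 42)]
  right <- ids[c(19, 20, 39, 40, 59, 60)]
  split_cells <- c(left, right)
  frac <- betaregion:::largest_component_fraction(split_cells, g)
  expect_equal(frac, 0.5)

  grp <- ifelse(ids %in% split_cells, "split", "rest")
  names(grp) <- ids
  D <- outer(grp, grp, FUN = function(a, b) ifelse(a == b, 0, 1))
  diag(D) <- 0; dimnames(D) <- list(ids, ids)
  dend <- hierarchical_cluster(D, "UPGMA")

  reg50 <- delineate_regions(dend, 2, g, min_cells = 10,
                             aggregation_threshold = 0.5)
  lab50 <- setNames(reg50$region, reg50$cell_id)
  expect_true(all(lab50[split_cells] != "unassigned"))  # passes at 0.5

  reg60 <- delineate_regions(dend, 2, g, min_cells = 10,
                             aggregation_threshold = 0.6)
  lab60 <- setNames(reg60$region, reg60$cell_id)
  expect_true(all(lab60[split_cells] == "unassigned"))  # fails at 0.6
})

test_that("realms nest regions and recover a planted two-tier hierarchy", {
  g <- build_hex_grid(16, 16, 1)
  ids <- g$cells$cell_id
  # 4 spatial quadrants (regions), paired into 2 realms by lower dissimilarity
  xy <- grid_centroids(g)
  qx <- xy[, 1] > stats::median(xy[, 1])
  qy <- xy[, 2] > stats::median(xy[, 2])
  region_true <- setNames(paste0("q", qx + 2 * qy), ids)
  realm_true <- setNames(ifelse(qy, "north", "south"), ids)
  dd <- function(a, b) {
    ifelse(region_true[a] == region_true[b], 0,
           ifelse(realm_true[a] == realm_true[b], 0.4, 1))
  }
  D <- outer(ids, ids, FUN = dd)
  diag(D) <- 0; dimnames(D) <- list(ids, ids)
  dend <- hierarchical_cluster(D, "UPGMA")
  k <- elbow(variance_explained_curve(D, dend, k_max = 30))
  reg <- delineate_regions(dend, k, g)
  reg <- assign_realms(dend, reg, D, max_realms = 15)

  lab <- region_labels(reg)
  expect_equal(adjusted_rand_index(lab, region_true[names(lab)]), 1)
  realm_lab <- setNames(reg$realm, reg$cell_id)[names(lab)]
  expect_equal(adjusted_rand_index(realm_lab, realm_true[names(lab)]), 1)

  # nesting: every region maps to exactly one realm
  for (r in unique(reg$region[reg$valid])) {
    expect_length(unique(reg$realm[reg$region == r]), 1L)
  }
})

test_that("regionalization CSV round-trip preserves labels", {
  g <- build_hex_grid(6, 6, 1)
  reg <- random_voronoi_regionalization(g, 3, seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_regionalization(reg, f)
  reg2 <- read_regionalization(f)
  expect_equal(reg2$region, reg$region)
  expect_equal(reg2$valid, reg$valid)
})
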