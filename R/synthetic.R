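#' Simulate a Yule (pure-birth) phylogeny
#'
#' Rooted binary tree with `n_tips` labelled tips simulated under a constant
#' birth rate and zero extinction, branch lengths in units of the birth
#' process. Stands in for a reconstructed large-scale phylogeny when testing
#' the pipeline. Deterministic given `seed`.
#'
#' @param n_tips number of tips (>= 1).
#' @param birth_rate speciation rate (> 0); scales branch lengths only.
#' @param seed integer seed.
#' @return an [ape::phylo].
#' @export
simulate_phylogeny <- function(n_tips, birth_rate = 1, seed = 1L) {
  if (length(n_tips) != 1L || n_tips < 1) {
    stop("n_tips must be >= 1", call. = FALSE)
  }
  if (birth_rate <= 0) stop("birth_rate must be positive", call. = FALSE)
  n_tips <- as.integer(n_tips)
  set.seed(seed)
  if (n_tips == 1L) {
    # degenerate single-tip tree: one edge from the root
    tr <- structure(
      list(edge = matrix(c(2L, 1L), 1L, 2L),
           edge.length = 1 / birth_rate,
           tip.label = "t1", Nnode = 1L),
      class = "phylo", order = "cladewise"
    )
    return(tr)
  }
  if (n_tips == 2L) {
    len <- stats::rexp(1L, birth_rate)
    return(ape::read.tree(text = sprintf("(t1:%.10f,t2:%.10f);", len, len)))
  }
  ape::rphylo(n_tips, birth = birth_rate, death = 0)
}

#' Emulate a posterior sample of trees by branch-length jitter
#'
#' Keeps the topology and tip set fixed and multiplies every branch length by
#' an independent lognormal(0, `sd_log`) factor, mimicking branch-length
#' uncertainty across a posterior sample. With `sd_log = 0` all trees equal
#' the input.
#'
#' @param tree an [ape::phylo].
#' @param n_trees number of trees to draw (>= 1; a posterior sample of 100 is
#'   typical).
#' @param sd_log standard deviation of the log multiplier (>= 0).
#' @param seed integer seed.
#' @return an [ape::multiPhylo] of length `n_trees`.
#' @export
jitter_posterior <- function(tree, n_trees = 100L, sd_log = 0.1, seed = 1L) {
  if (n_trees < 1) stop("n_trees must be >= 1", call. = FALSE)
  if (sd_log < 0) stop("sd_log must be >= 0", call. = FALSE)
  set.seed(seed)
  n_edge <- length(tree$edge.length)
  out <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    tr <- tree
    tr$edge.length <- tr$edge.length *
      stats::rlnorm(n_edge, meanlog = 0, sdlog = sd_log)
    out[[i]] <- tr
  }
  class(out) <- "multiPhylo"
  out
}

# sample k elements of x (safe for length-1 x, unlike sample())
sample_vec <- function(x, k) x[sample.int(length(x), k)]

# nearest-seed (Voronoi) labelling of grid cells; ties -> lowest seed index
nearest_seed_labels <- function(coords, seed_idx, labels) {
  d2 <- outer(coords[, 1L], coords[seed_idx, 1L], "-")^2 +
        outer(coords[, 2L], coords[seed_idx, 2L], "-")^2
  assign <- max.col(-d2, ties.method = "first")
  stats::setNames(labels[assign], rownames(coords))
}

#' Plant spatial regions on a grid
#'
#' Samples `n_regions` seed cells without replacement and assigns every cell
#' to the nearest seed by centroid Euclidean distance (ties to the lowest
#' seed index): a Voronoi partition used as ground truth for recovery tests.
#'
#' @param grid a `hex_grid`.
#' @param n_regions number of regions (<= number of cells).
#' @param seed integer seed.
#' @return named character vector cell_id -> region label (`"r1"`, ...).
#' @export
plant_regions <- function(grid, n_regions, seed = 1L) {
  n <- nrow(grid$cells)
  if (n_regions < 1 || n_regions > n) {
    stop("n_regions must be between 1 and the number of cells", call. = FALSE)
  }
  set.seed(seed)
  coords <- grid_centroids(grid)
  seed_idx <- sample.int(n, n_regions)
  nearest_seed_labels(coords, seed_idx, sprintf("r%d", seq_len(n_regions)))
}

#' Partition tree tips into clades
#'
#' Produces `n_clades` phylogenetically coherent, size-balanced tip pools by
#' cutting the tree at a root-to-node depth and greedily merging the
#' smallest resulting subtrees down to exactly `n_clades`. All cut depths
#' yielding at least `n_clades` subtrees are examined and the shallowest cut
#' whose merged partition is most balanced (largest minimum pool, then
#' smallest size spread) is kept, so every pool is as even as the topology
#' allows.
#'
#' @param tree an [ape::phylo].
#' @param n_clades number of pools (>= 1, <= number of tips).
#' @return list of character vectors of tip labels, ordered by first tip.
#' @export
tree_clades <- function(tree, n_clades) {
  n_tip <- length(tree$tip.label)
  if (n_clades < 1 || n_clades > n_tip) {
    stop("n_clades must be between 1 and the number of tips", call. = FALSE)
  }
  if (n_clades == 1L) return(list(tree$tip.label))
  depth <- ape::node.depth.edgelength(tree)       # root = 0
  internal <- sort(unique(depth[(n_tip + 1L):(n_tip + tree$Nnode)]))
  paths <- tip_edge_paths(tree)

  merge_to <- function(pools, k) {
    while (length(pools) > k) {
      ord <- order(lengths(pools))[1:2]
      pools[[ord[1L]]] <- c(pools[[ord[1L]]], pools[[ord[2L]]])
      pools[[ord[2L]]] <- NULL
    }
    pools
  }

  best <- NULL
  best_score <- c(-Inf, -Inf)
  for (t_cut in internal) {
    cross <- which(depth[tree$edge[, 1L]] <= t_cut &
                   depth[tree$edge[, 2L]] > t_cut)
    if (length(cross) < n_clades) next
    pools <- merge_to(
      lapply(cross, function(e) tree$tip.label[paths[, e] == 1L]),
      n_clades
    )
    score <- c(min(lengths(pools)), -stats::sd(lengths(pools)))
    if (score[1L] > best_score[1L] ||
        (score[1L] == best_score[1L] && score[2L] > best_score[2L])) {
      best <- pools
      best_score <- score
    }
  }
  if (is.null(best)) {   # fewer distinct depths than clades: cut every tip
    best <- merge_to(as.list(tree$tip.label), n_clades)
  }
  best[order(vapply(best, function(p) p[1L], ""))]
}

#' Simulate clade-structured assemblages over planted regions
#'
#' Tips are partitioned into as many clades as regions ([tree_clades()]) and
#' clades are matched one-to-one to regions (both sorted: region labels
#' alphabetically, clades by their first tip label). Every cell then receives
#' `richness` distinct taxa: each draw comes from the cell's own regional
#' clade with probability `1 - mixing` and from the union of the other clades
#' with probability `mixing`. At `mixing = 0` regional taxon pools are
#' disjoint, so between-region turnover is maximal.
#'
#' @param tree an [ape::phylo] whose tips are the taxon pool.
#' @param regions named vector cell_id -> region label (see
#'   [plant_regions()]).
#' @param mixing probability in `[0, 1]` of drawing a foreign-clade taxon.
#' @param richness taxa per cell (>= 5, so no cell is lost to the
#'   small-assemblage filter; <= total taxa).
#' @param seed integer seed.
#' @return presence matrix (cells x taxa).
#' @export
simulate_assemblages <- function(tree, regions, mixing = 0, richness = 12L,
                                 seed = 1L) {
  if (mixing < 0 || mixing > 1) stop("mixing must be in [0,1]", call. = FALSE)
  taxa <- tree$tip.label
  if (richness > length(taxa)) {
    stop("richness exceeds the number of taxa", call. = FALSE)
  }
  if (richness < 5) {
    stop("richness must be >= 5 so every cell passes the richness filter",
         call. = FALSE)
  }
  labels <- sort(unique(regions))
  pools <- tree_clades(tree, length(labels))
  names(pools) <- labels
  if (mixing == 0 && any(lengths(pools) < richness)) {
    stop("with mixing = 0 every clade pool must hold >= richness taxa",
         call. = FALSE)
  }
  set.seed(seed)
  cells <- names(regions)
  pm <- matrix(0L, nrow = length(cells), ncol = length(taxa),
               dimnames = list(cells, taxa))
  for (i in seq_along(cells)) {
    own <- pools[[regions[[i]]]]
    other <- setdiff(taxa, own)
    k_own <- stats::rbinom(1L, richness, 1 - mixing)
    k_own <- min(k_own, length(own))
    k_other <- min(richness - k_own, length(other))
    k_own <- min(richness - k_other, length(own))  # top off if other ran short
    picked <- c(sample_vec(own, k_own), sample_vec(other, k_other))
    pm[i, picked] <- 1L
  }
  pm
}

#' Adjusted Rand index between two cell labelings
#'
#' Chance-corrected agreement between two partitions of the same cell set,
#' from the pair-counting contingency table. 1 for identical partitions
#' (up to label names), approximately 0 for independent ones.
#'
#' @param labels_a,labels_b named vectors cell_id -> label over the same
#'   cells.
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (is.null(names(labels_a)) || is.null(names(labels_b)) ||
      !setequal(names(labels_a), names(labels_b))) {
    stop("labelings must share the same named cell set", call. = FALSE)
  }
  b <- labels_b[names(labels_a)]
  ct <- table(labels_a, b)
  sum_ij <- sum(choose(ct, 2))
  sum_i <- sum(choose(rowSums(ct), 2))
  sum_j <- sum(choose(colSums(ct), 2))
  n2 <- choose(sum(ct), 2)
  expected <- sum_i * sum_j / n2
  mx <- (sum_i + sum_j) / 2
  if (mx == expected) return(0)          # both partitions trivial
  (sum_ij - expected) / (mx - expected)
}

#' Simulate a complete synthetic biogeographic data set
#'
#' One call builds the full study substrate with known ground truth: a hexagon
#' lattice, a Yule phylogeny, planted Voronoi regions, clade-structured
#' assemblages and a jittered posterior tree set. Stage seeds are derived
#' from `seed` by fixed offsets, so the whole object is reproducible from a
#' single integer.
#'
#' @param n_cols,n_rows lattice dimensions.
#' @param n_regions planted region count.
#' @param n_tips taxon pool size.
#' @param richness taxa per cell.
#' @param mixing cross-region mixing probability.
#' @param birth_rate Yule speciation rate.
#' @param n_trees posterior sample size (0 to skip).
#' @param sd_log posterior branch-length jitter.
#' @param cell_area cell area, km^2.
#' @param seed master integer seed.
#' @return list with `grid`, `tree`, `trees` (or NULL), `truth` (cell ->
#'   region), `pm`, and `params`.
#' @export
simulate_biogeography <- function(n_cols = 20L, n_rows = 20L, n_regions = 4L,
                                  n_tips = 96L, richness = 12L, mixing = 0.05,
                                  birth_rate = 1, n_trees = 0L, sd_log = 0.1,
                                  cell_area = 5e4, seed = 1L) {
  grid <- build_hex_grid(n_cols, n_rows, cell_area)
  tree <- simulate_phylogeny(n_tips, birth_rate, seed = seed + 1L)
  truth <- plant_regions(grid, n_regions, seed = seed + 2L)
  pm <- simulate_assemblages(tree, truth, mixing, richness, seed = seed + 3L)
  trees <- if (n_trees > 0L) {
    jitter_posterior(tree, n_trees, sd_log, seed = seed + 4L)
  }
  list(grid = grid, tree = tree, trees = trees, truth = truth, pm = pm,
       params = list(n_cols = n_cols, n_rows = n_rows, n_regions = n_regions,
                     n_tips = n_tips, richness = richness, mixing = mixing,
                     birth_rate = birth_rate, n_trees = n_trees,
                     sd_log = sd_log, cell_area = cell_area, seed = seed))
}

#' Write a cell -> label map as CSV
#'
#' @param labels named vector cell_id -> label.
#' @param file CSV path.
#' @param value_name column name for the label column.
#' @export
write_labels <- function(labels, file, value_name = "region") {
  df <- data.frame(cell_id = names(labels), label = unname(labels),
                   stringsAsFactors = FALSE)
  names(df)[2L] <- value_name
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_labels
#' @export
read_labels <- function(file, value_name = "region") {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  stats::setNames(as.character(df[[value_name]]), df$cell_id)
}
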