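#' Branch incidence of assemblages on a phylogeny
#'
#' For every cell, the set of tree edges "present" in that cell: an edge is
#' present iff at least one of its descendant tips is present. Incidence sets
#' are closed under the ancestor relation by construction. The root edge (the
#' stem below the root node, if any was read from the Newick) is not part of
#' the edge table and therefore never contributes: it is shared by every
#' non-empty assemblage and carries no turnover information.
#'
#' Taxa in `pm` that are missing from the tree are dropped with a warning;
#' the number dropped is recorded in attribute `n_dropped_taxa`.
#'
#' @param pm presence matrix (cells x taxa).
#' @param tree an [ape::phylo] with branch lengths.
#' @return list of class `branch_incidence` with elements
#'   `incidence` (cells x edges logical matrix), `lengths` (edge lengths) and
#'   `n_dropped_taxa`.
#' @export
branch_incidence <- function(pm, tree) {
  pm <- as_presence_matrix(pm)
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  matched <- intersect(colnames(pm), tree$tip.label)
  n_dropped <- ncol(pm) - length(matched)
  if (n_dropped > 0L) {
    warning(sprintf("%d taxa absent from the tree were dropped", n_dropped),
            call. = FALSE)
  }
  if (length(matched) == 0L) {
    stop("no taxa shared between presence matrix and tree", call. = FALSE)
  }
  sub <- pm[, matched, drop = FALSE]
  empty <- rowSums(sub) == 0L
  if (any(empty)) {
    stop("degenerate assemblage(s) with zero tree-matched taxa: ",
         paste(utils::head(rownames(sub)[empty], 5L), collapse = ", "),
         call. = FALSE)
  }

  paths <- tip_edge_paths(tree)                 # tips x edges
  m <- paths[match(matched, tree$tip.label), , drop = FALSE]
  inc <- (sub %*% m) > 0L                       # cells x edges
  structure(
    list(incidence = inc, lengths = tree$edge.length,
         n_dropped_taxa = n_dropped),
    class = "branch_incidence"
  )
}

# 0/1 matrix: tip i descends through edge j (edge j lies on the root path of i)
tip_edge_paths <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_edge <- nrow(tree$edge)
  parent_edge <- integer(max(tree$edge))        # node -> edge above it
  parent_edge[tree$edge[, 2L]] <- seq_len(n_edge)
  root <- n_tip + 1L
  parent_node <- integer(max(tree$edge))
  parent_node[tree$edge[, 2L]] <- tree$edge[, 1L]
  m <- matrix(0L, nrow = n_tip, ncol = n_edge,
              dimnames = list(tree$tip.label, NULL))
  for (i in seq_len(n_tip)) {
    v <- i
    while (v != root && v != 0L) {
      m[i, parent_edge[v]] <- 1L
      v <- parent_node[v]
    }
  }
  m
}

#' Turnover components of one assemblage pair
#'
#' Computes the shared and unique quantities entering Simpson's dissimilarity:
#' in taxonomic mode `a`, `b`, `c` are counts of shared / first-only /
#' second-only taxa; in phylogenetic mode they are the summed lengths of
#' branches incident to both cells, only the first, and only the second.
#'
#' @param pm presence matrix.
#' @param cell_x,cell_y cell ids (rownames of `pm`).
#' @param mode `"taxonomic"` or `"phylogenetic"`.
#' @param tree phylogeny, required in phylogenetic mode.
#' @return named numeric vector `c(a=, b=, c=)`.
#' @examples
#' pm <- rbind(x = c(A = 1, B = 1, C = 0), y = c(A = 1, B = 0, C = 1))
#' pair_components(pm, "x", "y", "taxonomic")  # a=1 b=1 c=1
#' @export
pair_components <- function(pm, cell_x, cell_y,
                            mode = c("taxonomic", "phylogenetic"),
                            tree = NULL) {
  mode <- match.arg(mode)
  pm <- as_presence_matrix(pm)
  for (id in c(cell_x, cell_y)) {
    if (!id %in% rownames(pm)) stop("unknown cell id: ", id, call. = FALSE)
  }
  if (mode == "taxonomic") {
    x <- pm[cell_x, ] > 0L
    y <- pm[cell_y, ] > 0L
    c(a = sum(x & y), b = sum(x & !y), c = sum(!x & y))
  } else {
    if (is.null(tree)) stop("phylogenetic mode requires a tree", call. = FALSE)
    bi <- branch_incidence(pm[c(cell_x, cell_y), , drop = FALSE], tree)
    x <- bi$incidence[cell_x, ]
    y <- bi$incidence[cell_y, ]
    len <- bi$lengths
    c(a = sum(len[x & y]), b = sum(len[x & !y]), c = sum(len[!x & y]))
  }
}

#' Simpson's dissimilarity from turnover components
#'
#' `betasim = 1 - a / (min(b, c) + a)`: the turnover-only component of beta
#' diversity, insensitive to richness difference. Equals 0 for nested
#' assemblages (min(b,c) = 0 with a > 0) and 1 for disjoint ones (a = 0).
#'
#' @param components numeric vector with elements `a`, `b`, `c` (all >= 0),
#'   as returned by [pair_components()].
#' @return dissimilarity in `[0, 1]`.
#' @export
betasim <- function(components) {
  a <- components[["a"]]; b <- components[["b"]]; c <- components[["c"]]
  if (any(c(a, b, c) < 0)) stop("components must be nonnegative", call. = FALSE)
  if (a == 0 && b == 0 && c == 0) {
    stop("dissimilarity undefined for two empty assemblages", call. = FALSE)
  }
  1 - a / (min(b, c) + a)
}

#' Pairwise Simpson turnover matrix
#'
#' Computes `betasim` for every unordered cell pair. Taxonomic mode (Tbsim)
#' uses shared/unique taxon counts; phylogenetic mode (Pbsim) uses shared and
#' unique branch lengths via a branch-incidence structure built once per tree
#' (never per pair).
#'
#' @inheritParams pair_components
#' @return symmetric numeric matrix in `[0,1]` with zero diagonal and
#'   cell-id dimnames.
#' @export
betasim_matrix <- function(pm, mode = c("taxonomic", "phylogenetic"),
                           tree = NULL) {
  mode <- match.arg(mode)
  pm <- as_presence_matrix(pm)
  if (mode == "taxonomic") {
    if (any(rowSums(pm) == 0L)) {
      stop("empty assemblage(s); filter the presence matrix first",
           call. = FALSE)
    }
    shared <- pm %*% t(pm)
    tot <- rowSums(pm)
  } else {
    if (is.null(tree)) stop("phylogenetic mode requires a tree", call. = FALSE)
    bi <- branch_incidence(pm, tree)
    inc <- bi$incidence * 1
    shared <- inc %*% (bi$lengths * t(inc))
    tot <- diag(shared)
  }
  betasim_from_shared(shared, tot, rownames(pm))
}

# shared: n x n shared quantity; tot: per-cell total quantity
betasim_from_shared <- function(shared, tot, ids) {
  n <- length(tot)
  b <- matrix(tot, n, n) - shared        # b[x,y] = tot_x - a_xy
  minbc <- pmin(b, t(b))
  d <- 1 - shared / (minbc + shared)
  diag(d) <- 0
  d[d < 0] <- 0                          # guard fp noise
  dimnames(d) <- list(ids, ids)
  d
}

#' Posterior-median phylogenetic turnover matrix
#'
#' Computes the Pbsim matrix for each tree of a posterior sample and returns
#' the elementwise median. Even tree counts use the midpoint of the two
#' central order statistics.
#'
#' @param pm presence matrix.
#' @param trees a [ape::multiPhylo] or list of `phylo` trees sharing the tip
#'   set (typically a posterior sample with fixed topology).
#' @return symmetric median Pbsim matrix.
#' @export
median_posterior_betasim <- function(pm, trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) == 0L) stop("empty tree set", call. = FALSE)
  pm <- as_presence_matrix(pm)
  n <- nrow(pm)
  low <- lower.tri(matrix(0, n, n))
  vals <- vapply(
    trees,
    function(tr) betasim_matrix(pm, "phylogenetic", tr)[low],
    numeric(sum(low))
  )
  med <- apply(vals, 1L, stats::median)
  out <- matrix(0, n, n, dimnames = list(rownames(pm), rownames(pm)))
  out[low] <- med
  out + t(out)
}

#' Assemblage distinctiveness
#'
#' For each cell, the arithmetic mean of its dissimilarity to every other
#' cell: a map of biotic uniqueness.
#'
#' @param D symmetric dissimilarity matrix (zero diagonal).
#' @return named numeric vector, one value per cell, in `[0, 1]`.
#' @export
distinctiveness <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2L) stop("need at least two cells", call. = FALSE)
  stats::setNames(rowSums(D) / (n - 1), rownames(D))
}

#' Write / read a square dissimilarity matrix CSV
#'
#' Cell ids form both the header row and the first column.
#'
#' @param D symmetric matrix with cell-id dimnames.
#' @param file CSV path.
#' @export
write_dissimilarity <- function(D, file) {
  df <- data.frame(cell_id = rownames(D), D, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_dissimilarity
#' @export
read_dissimilarity <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
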