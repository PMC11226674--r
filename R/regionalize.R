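#' Linkage algorithms considered for regionalization
#'
#' Field abbreviations mapped to [stats::hclust()] methods: UPGMC (centroid),
#' WARD (ward.D2), SL (single), CL (complete), WPGMA (mcquitty), WPGMC
#' (median), UPGMA (average).
#'
#' @export
LINKAGE_METHODS <- c(
  UPGMC = "centroid", WARD = "ward.D2", SL = "single", CL = "complete",
  WPGMA = "mcquitty", WPGMC = "median", UPGMA = "average"
)

#' Agglomerative clustering of a dissimilarity matrix
#'
#' @param D symmetric dissimilarity matrix with cell-id dimnames.
#' @param method one of `names(LINKAGE_METHODS)` (e.g. `"UPGMA"`).
#' @return an [stats::hclust] dendrogram (n - 1 merges).
#' @export
hierarchical_cluster <- function(D, method = "UPGMA") {
  if (!method %in% names(LINKAGE_METHODS)) {
    stop("unknown linkage method: ", method, "; use one of ",
         paste(names(LINKAGE_METHODS), collapse = ", "), call. = FALSE)
  }
  stats::hclust(stats::as.dist(D), method = LINKAGE_METHODS[[method]])
}

#' Distortion of a dendrogram relative to the input distances
#'
#' Compares the n(n-1)/2 cophenetic distances of the dendrogram with the
#' input dissimilarities: `cophenetic_r` is their Pearson correlation and
#' `gower_d` the sum of squared deviations (a distortion measure; 0 means the
#' dendrogram reproduces the input exactly, as for ultrametric input).
#'
#' @param dend an [stats::hclust].
#' @param D the dissimilarity matrix it was built from.
#' @return list with `cophenetic_r` and `gower_d`.
#' @export
evaluate_dendrogram <- function(dend, D) {
  coph <- as.vector(stats::cophenetic(dend))
  dv <- as.vector(stats::as.dist(D))
  if (stats::sd(dv) == 0 || stats::sd(coph) == 0) {
    stop("correlation undefined for constant distance vector", call. = FALSE)
  }
  list(cophenetic_r = stats::cor(coph, dv), gower_d = sum((coph - dv)^2))
}

#' Evaluate all linkage algorithms on one dissimilarity matrix
#'
#' The default order ranks the algorithms by a-priori preference — UPGMA
#' first, as the standard choice for biogeographic regionalization — so that
#' exact ties in [select_algorithm()] resolve to the conventional method.
#'
#' @param D dissimilarity matrix.
#' @param methods linkage names to test (default: all seven, preference
#'   order).
#' @return data.frame with columns `method`, `cophenetic_r`, `gower_d`, in
#'   the order given.
#' @export
evaluate_algorithms <- function(D, methods = c("UPGMA", "WPGMA", "WARD",
                                               "CL", "SL", "UPGMC",
                                               "WPGMC")) {
  res <- lapply(methods, function(m) {
    ev <- evaluate_dendrogram(hierarchical_cluster(D, m), D)
    data.frame(method = m, cophenetic_r = ev$cophenetic_r,
               gower_d = ev$gower_d, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Pick the best-performing linkage
#'
#' Maximizes the cophenetic correlation; ties are broken by minimal Gower
#' distance, then by the row order of `evals` (the preference order of
#' [evaluate_algorithms()]). Scores equal to within 1e-12 are treated as
#' tied so floating-point noise cannot overturn the preference.
#'
#' @param evals data.frame from [evaluate_algorithms()].
#' @return the selected method name.
#' @export
select_algorithm <- function(evals) {
  if (is.null(evals) || nrow(evals) == 0L) {
    stop("no algorithm evaluations supplied", call. = FALSE)
  }
  r <- round(evals$cophenetic_r / 1e-12) * 1e-12
  g <- round(evals$gower_d / 1e-12) * 1e-12
  ord <- order(-r, g, seq_len(nrow(evals)))
  evals$method[ord[1L]]
}

#' Variance explained by dendrogram cuts
#'
#' For each cluster count k, cuts the dendrogram into k groups and reports
#' the fraction of total squared dissimilarity lying between clusters:
#' `1 - sum(within-cluster d^2) / sum(all-pair d^2)`. Because cuts of one
#' dendrogram are nested, the curve is nondecreasing, with value 0 at k = 1
#' and 1 at k = n.
#'
#' @param D dissimilarity matrix.
#' @param dend dendrogram built from `D`.
#' @param k_max largest cluster count to evaluate (default 30, capped at n).
#' @return data.frame with columns `k`, `variance_explained`.
#' @export
variance_explained_curve <- function(D, dend, k_max = 30L) {
  D <- as.matrix(D)
  n <- nrow(D)
  ks <- seq_len(min(k_max, n))
  tot <- sum(D^2) / 2
  if (tot == 0) {
    warning("all dissimilarities are zero; variance explained undefined",
            call. = FALSE)
    return(data.frame(k = ks, variance_explained = rep(1, length(ks))))
  }
  cuts <- stats::cutree(dend, k = ks)          # n x length(ks)
  ve <- vapply(seq_along(ks), function(j) {
    cl <- cuts[, j]
    within <- 0
    for (g in unique(cl)) {
      idx <- which(cl == g)
      if (length(idx) > 1L) within <- within + sum(D[idx, idx]^2) / 2
    }
    1 - within / tot
  }, numeric(1L))
  data.frame(k = ks, variance_explained = ve)
}

#' Elbow (maximum-curvature) cluster count
#'
#' Chooses the k at maximum perpendicular distance from the
#' variance-explained curve to the chord joining its endpoints, after
#' min-max normalization of both axes; ties go to the smallest k. A
#' perfectly linear curve has no elbow: the smallest interior k is returned
#' with a warning.
#'
#' @param curve data.frame from [variance_explained_curve()].
#' @return the selected cluster count k*.
#' @export
elbow <- function(curve) {
  k <- curve$k
  v <- curve$variance_explained
  if (length(k) < 3L) stop("need at least 3 curve points", call. = FALSE)
  kn <- (k - min(k)) / (max(k) - min(k))
  rng <- max(v) - min(v)
  vn <- if (rng > 0) (v - min(v)) / rng else rep(0, length(v))
  # distance from (kn, vn) to chord from first to last normalized point
  x1 <- kn[1L]; y1 <- vn[1L]
  x2 <- kn[length(kn)]; y2 <- vn[length(vn)]
  denom <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  dist <- abs((y2 - y1) * kn - (x2 - x1) * vn + x2 * y1 - y2 * x1) / denom
  interior <- 2:(length(k) - 1L)
  if (max(dist[interior]) < 1e-12) {
    warning("variance-explained curve has no elbow (linear); returning the ",
            "smallest interior k", call. = FALSE)
    return(k[2L])
  }
  k[interior][which.max(dist[interior])]
}

# fraction of `cells` lying in their largest connected component on the
# grid adjacency graph
largest_component_fraction <- function(cells, grid) {
  if (length(cells) == 1L) return(1)
  adj <- grid$adjacency
  keep <- adj$cell_id %in% cells & adj$neighbor_id %in% cells
  edges <- adj[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = cells, stringsAsFactors = FALSE)
  )
  max(igraph::components(g)$csize) / length(cells)
}

#' Delineate valid biogeographic regions from a dendrogram cut
#'
#' Cuts the dendrogram into `k` clusters and applies the validity rules: a
#' cluster is a valid region iff it contains strictly more than `min_cells`
#' cells and is spatially aggregated, i.e. its largest connected component on
#' the grid adjacency graph holds at least `aggregation_threshold` of its
#' cells. Cells of invalid clusters are labelled `"unassigned"`.
#'
#' @param dend dendrogram over the grid cells.
#' @param k cluster count (e.g. from [elbow()]).
#' @param grid the `hex_grid` carrying adjacency and areas.
#' @param min_cells strict minimum size; a cluster of exactly `min_cells`
#'   cells is invalid (default 10).
#' @param aggregation_threshold minimum largest-component fraction
#'   (default 0.5).
#' @return a `regionalization`: data.frame with columns `cell_id`, `region`,
#'   `realm` (NA until [assign_realms()]), `valid`, `area`.
#' @export
delineate_regions <- function(dend, k, grid, min_cells = 10L,
                              aggregation_threshold = 0.5) {
  cl <- stats::cutree(dend, k = k)
  cells <- names(cl)
  if (!all(cells %in% grid$cells$cell_id)) {
    stop("dendrogram cells missing from the grid", call. = FALSE)
  }
  region <- sprintf("R%02d", cl)
  valid_cluster <- vapply(sort(unique(cl)), function(g) {
    members <- cells[cl == g]
    length(members) > min_cells &&
      largest_component_fraction(members, grid) >= aggregation_threshold
  }, logical(1L))
  names(valid_cluster) <- sprintf("R%02d", sort(unique(cl)))
  valid <- valid_cluster[region]
  region[!valid] <- "unassigned"
  area <- grid$cells$area[match(cells, grid$cells$cell_id)]
  structure(
    data.frame(cell_id = cells, region = region, realm = NA_character_,
               valid = unname(valid), area = area, stringsAsFactors = FALSE,
               row.names = NULL),
    class = c("regionalization", "data.frame")
  )
}

#' Group regions into realms
#'
#' Realms are the coarser tier of the same dendrogram: the elbow is
#' recomputed over cluster counts strictly below `max_realms`, the dendrogram
#' is cut at that count, and each valid region inherits the realm of the
#' majority of its cells. With nested cuts of a single dendrogram every
#' region falls entirely inside one realm, so the majority is unanimous.
#'
#' @param dend dendrogram over the grid cells.
#' @param regions a `regionalization` from [delineate_regions()].
#' @param D the dissimilarity matrix underlying `dend`.
#' @param max_realms strict upper bound on the realm count (default 15).
#' @return the `regionalization` with the `realm` column filled for valid
#'   cells.
#' @export
assign_realms <- function(dend, regions, D, max_realms = 15L) {
  if (!any(regions$valid)) stop("no valid regions", call. = FALSE)
  curve <- variance_explained_curve(D, dend, k_max = max_realms - 1L)
  k_realm <- elbow(curve)
  cl <- stats::cutree(dend, k = k_realm)
  realm_of_cell <- stats::setNames(sprintf("K%02d", cl), names(cl))
  for (r in unique(regions$region[regions$valid])) {
    members <- regions$cell_id[regions$region == r]
    tab <- sort(table(realm_of_cell[members]), decreasing = TRUE)
    regions$realm[regions$region == r] <- names(tab)[1L]
  }
  attr(regions, "k_realm") <- k_realm
  regions
}

#' Write / read a regionalization CSV
#'
#' Columns: `cell_id`, `region`, `realm`, `valid`, `area`.
#'
#' @param reg a `regionalization`.
#' @param file CSV path.
#' @export
write_regionalization <- function(reg, file) {
  utils::write.csv(as.data.frame(reg), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_regionalization
#' @export
read_regionalization <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  df$realm <- as.character(df$realm)
  structure(df, class = c("regionalization", "data.frame"))
}
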