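#' Area cross-tabulation of two regionalizations
#'
#' Overlap areas between every region of scheme A and every region of scheme
#' B, computed cell-wise over the cells that are valid (assigned to a region)
#' in both schemes. Row sums equal A-region areas and column sums B-region
#' areas on the shared domain.
#'
#' @param regA,regB `regionalization` objects (data.frames with `cell_id`,
#'   `region`, `valid`, `area`).
#' @return numeric matrix of overlap areas with region-label dimnames.
#' @export
area_crosstab <- function(regA, regB) {
  a <- regA[regA$valid & regA$region != "unassigned", ]
  b <- regB[regB$valid & regB$region != "unassigned", ]
  shared <- intersect(a$cell_id, b$cell_id)
  if (length(shared) == 0L) {
    stop("schemes share no cells valid in both", call. = FALSE)
  }
  ia <- a$region[match(shared, a$cell_id)]
  ib <- b$region[match(shared, b$cell_id)]
  area <- a$area[match(shared, a$cell_id)]
  crosstab_core(ia, ib, area)
}

crosstab_core <- function(labels_a, labels_b, area) {
  la <- sort(unique(labels_a))
  lb <- sort(unique(labels_b))
  ia <- match(labels_a, la)
  ib <- match(labels_b, lb)
  idx <- (ia - 1L) * length(lb) + ib
  sums <- rowsum(area, idx)
  ct <- matrix(0, length(la), length(lb), dimnames = list(la, lb))
  pos <- as.integer(rownames(sums))   # row-major linear index (ia-1)*nb + ib
  ct[cbind((pos - 1L) %/% length(lb) + 1L, (pos - 1L) %% length(lb) + 1L)] <-
    sums[, 1L]
  ct
}

#' V-measure of two regionalizations
#'
#' Area-weighted information-theoretic association between two partitions of
#' the same domain. With joint area fractions `p_ij` and natural-log Shannon
#' entropies: homogeneity `h = 1 - H(B|A)/H(B)`, completeness
#' `comp = 1 - H(A|B)/H(A)`, and `v = 2*h*comp/(h + comp)` (their harmonic
#' mean). Per-region homogeneity of an A-region is 1 minus the normalized
#' Shannon entropy of the B labels inside it (normalized by `log(n_B)`):
#' 1 when the region nests inside a single B region, 0 when evenly split
#' across all of them.
#'
#' @param ct area cross-tabulation from [area_crosstab()].
#' @return object of class `v_measure`: list with `h`, `comp`, `v`,
#'   `per_region_homogeneity_a` (A regions w.r.t. scheme B) and
#'   `per_region_homogeneity_b` (B regions w.r.t. scheme A).
#' @examples
#' ct <- matrix(c(2, 0, 0, 2), 2, dimnames = list(c("a1","a2"), c("b1","b2")))
#' v_measure(ct)$v  # identical schemes: 1
#' @export
v_measure <- function(ct) {
  if (any(ct < 0)) stop("cross-tabulation entries must be >= 0", call. = FALSE)
  total <- sum(ct)
  if (total <= 0) stop("total area must be positive", call. = FALSE)
  p <- ct / total
  pa <- rowSums(p)
  pb <- colSums(p)
  ha <- shannon(pa)
  hb <- shannon(pb)
  # conditional entropies from the joint: H(B|A) = H(A,B) - H(A)
  hab <- shannon(as.vector(p))
  h_b_given_a <- hab - ha
  h_a_given_b <- hab - hb
  h <- if (hb > 0) 1 - h_b_given_a / hb else 1
  comp <- if (ha > 0) 1 - h_a_given_b / ha else 1
  v <- if (h + comp > 0) 2 * h * comp / (h + comp) else 0
  structure(
    list(h = h, comp = comp, v = v,
         per_region_homogeneity_a = per_region_h(p, nrow = TRUE),
         per_region_homogeneity_b = per_region_h(p, nrow = FALSE)),
    class = "v_measure"
  )
}

shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# 1 - normalized entropy of the compared scheme's labels inside each region
per_region_h <- function(p, nrow = TRUE) {
  if (!nrow) p <- t(p)
  n_other <- ncol(p)
  out <- apply(p, 1L, function(row) {
    if (sum(row) == 0) return(NA_real_)
    if (n_other == 1L) return(1)
    1 - shannon(row / sum(row)) / log(n_other)
  })
  stats::setNames(out, rownames(p))
}

#' @export
print.v_measure <- function(x, ...) {
  cat(sprintf("V-measure: v = %.3f (homogeneity %.3f, completeness %.3f)\n",
              x$v, x$h, x$comp))
  invisible(x)
}

#' Random Voronoi regionalization of a grid
#'
#' Samples `k` seed cells uniformly without replacement and assigns every
#' cell to its nearest seed by centroid distance (ties to the lowest seed
#' index). Used as the randomization null preserving only the region count
#' of an observed scheme.
#'
#' @param grid a `hex_grid`.
#' @param k number of regions (<= number of cells).
#' @param seed integer seed.
#' @return a `regionalization` with all regions valid.
#' @export
random_voronoi_regionalization <- function(grid, k, seed = 1L) {
  labels <- plant_regions(grid, k, seed = seed)
  structure(
    data.frame(cell_id = names(labels), region = unname(labels),
               realm = NA_character_, valid = TRUE,
               area = grid$cells$area[match(names(labels),
                                            grid$cells$cell_id)],
               stringsAsFactors = FALSE),
    class = c("regionalization", "data.frame")
  )
}

#' Voronoi-null significance test of a V-measure
#'
#' Compares the observed V-measure of two regionalizations with two null
#' distributions: scheme A against `n_null` random Voronoi regionalizations
#' with B's region count (`null_v_a`), and B against Voronoi nulls with A's
#' region count (`null_v_b`). Directional p-values use the add-one
#' permutation estimator `(#{null >= observed} + 1)/(n_null + 1)` (ties count
#' against significance); SES is `(v_obs - mean(null))/sd(null)`.
#'
#' @param regA,regB `regionalization` objects on `grid`.
#' @param grid the shared `hex_grid`.
#' @param n_null number of null regionalizations per direction (default 999).
#' @param seed integer seed.
#' @return object of class `null_comparison`: list with `v_obs`, `null_v_a`,
#'   `null_v_b`, `p_a`, `p_b`, `ses_a`, `ses_b`, `k_a`, `k_b`.
#' @export
null_comparison <- function(regA, regB, grid, n_null = 999L, seed = 1L) {
  v_obs <- v_measure(area_crosstab(regA, regB))$v
  k_a <- length(unique(regA$region[regA$valid & regA$region != "unassigned"]))
  k_b <- length(unique(regB$region[regB$valid & regB$region != "unassigned"]))

  null_vs <- function(fixed, k_null, seeds) {
    f <- fixed[fixed$valid & fixed$region != "unassigned", ]
    coords <- grid_centroids(grid)
    n <- nrow(coords)
    vapply(seeds, function(s) {
      set.seed(s)
      seed_idx <- sample.int(n, k_null)
      lab <- nearest_seed_labels(coords, seed_idx,
                                 sprintf("n%d", seq_len(k_null)))
      nb <- lab[f$cell_id]
      v_measure(crosstab_core(f$region, nb, f$area))$v
    }, numeric(1L))
  }

  set.seed(seed)
  seeds_a <- sample.int(.Machine$integer.max, n_null)
  seeds_b <- sample.int(.Machine$integer.max, n_null)
  null_v_a <- null_vs(regA, k_b, seeds_a)
  null_v_b <- null_vs(regB, k_a, seeds_b)

  ses <- function(nulls) {
    s <- stats::sd(nulls)
    if (s == 0) return(NA_real_)
    (v_obs - mean(nulls)) / s
  }
  structure(
    list(v_obs = v_obs,
         null_v_a = null_v_a, null_v_b = null_v_b,
         p_a = (sum(null_v_a >= v_obs) + 1) / (n_null + 1),
         p_b = (sum(null_v_b >= v_obs) + 1) / (n_null + 1),
         ses_a = ses(null_v_a), ses_b = ses(null_v_b),
         k_a = k_a, k_b = k_b),
    class = "null_comparison"
  )
}

#' @export
print.null_comparison <- function(x, ...) {
  cat(sprintf(
    "V-measure null test: v_obs = %.3f; p_a = %.4g (SES %.2f), p_b = %.4g (SES %.2f)\n",
    x$v_obs, x$p_a, x$ses_a, x$p_b, x$ses_b))
  invisible(x)
}

#' Mantel permutation test between two dissimilarity matrices
#'
#' Pearson correlation of the upper-triangle vectors with a two-sided
#' permutation p-value under simultaneous row/column permutation of the
#' second matrix, using the add-one estimator.
#'
#' @param D1,D2 symmetric dissimilarity matrices over the same ordered cell
#'   set.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return list with `r` and `p`.
#' @export
mantel_test <- function(D1, D2, n_perm = 999L, seed = 1L) {
  D1 <- as.matrix(D1)
  D2 <- as.matrix(D2)
  if (!identical(dim(D1), dim(D2))) {
    stop("matrices must have the same cells in the same order", call. = FALSE)
  }
  ut <- upper.tri(D1)
  v1 <- D1[ut]
  if (stats::sd(v1) == 0 || stats::sd(D2[ut]) == 0) {
    stop("correlation undefined for a constant matrix", call. = FALSE)
  }
  r <- stats::cor(v1, D2[ut])
  set.seed(seed)
  n <- nrow(D1)
  r_perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n)
    stats::cor(v1, D2[idx, idx][ut])
  }, numeric(1L))
  list(r = r, p = (sum(abs(r_perm) >= abs(r)) + 1) / (n_perm + 1))
}
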