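#' Nonmetric multidimensional scaling with random restarts
#'
#' Rank-based NMDS of a dissimilarity matrix minimizing Kruskal stress-1
#' (`sqrt(sum((dhat - fitted)^2) / sum(fitted^2))`, with monotone regression
#' of configuration distances on dissimilarity ranks). The isotonic engine is
#' [vegan::monoMDS()]; this wrapper runs it from `n_starts` random initial
#' configurations (many random starts guard against local minima; 200 is
#' typical) and keeps the lowest-stress solution. Deterministic given `seed`.
#'
#' @param D symmetric dissimilarity matrix.
#' @param dims embedding dimension (default 2).
#' @param n_starts number of random initial configurations.
#' @param max_iter iteration cap per start.
#' @param seed integer seed.
#' @param ... further arguments to [vegan::monoMDS()] (e.g. `weakties`).
#' @return object of class `nmds_fit`: list with `points` (n x dims, centered,
#'   cell-id rownames), `stress`, `best_start`, `n_starts`.
#' @export
nmds <- function(D, dims = 2L, n_starts = 200L, max_iter = 300L, seed = 1L,
                 ...) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < dims + 1L) stop("need at least dims + 1 cells", call. = FALSE)
  d <- stats::as.dist(D)
  set.seed(seed)
  best <- NULL
  best_start <- NA_integer_
  for (i in seq_len(n_starts)) {
    y0 <- matrix(stats::runif(n * dims, -1, 1), n, dims)
    fit <- try(
      vegan::monoMDS(d, y = y0, k = dims, model = "global",
                     maxit = max_iter, smin = 1e-6, sfgrmin = 1e-7, ...),
      silent = TRUE
    )
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$stress < best$stress) {
      best <- fit
      best_start <- i
    }
  }
  if (is.null(best)) stop("NMDS failed in every start", call. = FALSE)
  pts <- scale(best$points, center = TRUE, scale = FALSE)
  attr(pts, "scaled:center") <- NULL
  rownames(pts) <- rownames(D)
  colnames(pts) <- paste0("axis", seq_len(dims))
  structure(
    list(points = pts, stress = best$stress, best_start = best_start,
         n_starts = n_starts),
    class = "nmds_fit"
  )
}

#' @export
print.nmds_fit <- function(x, ...) {
  cat(sprintf("NMDS: %d cells, %d dims, stress-1 = %.4f (best of %d starts)\n",
              nrow(x$points), ncol(x$points), x$stress, x$n_starts))
  invisible(x)
}

#' Rotate an ordination to geographic space
#'
#' Orthogonal Procrustes superimposition (translation, rotation, reflection
#' and uniform scaling, via [vegan::procrustes()]) of the NMDS configuration
#' onto the cell centroids, so ordination axes align with geography. Stress
#' is unchanged: similarity transforms do not affect distance ranks.
#'
#' @param ord an `nmds_fit`.
#' @param centroids matrix of cell centroids (rownames = cell ids), e.g.
#'   [grid_centroids()].
#' @return the `nmds_fit` with rotated `points` and a `procrustes_ss`
#'   element (residual sum of squares of the superimposition).
#' @export
rotate_to_geography <- function(ord, centroids) {
  cells <- rownames(ord$points)
  if (!all(cells %in% rownames(centroids))) {
    stop("missing centroid for some ordinated cells", call. = FALSE)
  }
  target <- centroids[cells, , drop = FALSE]
  if (all(apply(target, 2L, stats::sd) == 0)) {
    stop("degenerate centroids: all cells at the same location",
         call. = FALSE)
  }
  proc <- vegan::procrustes(X = target, Y = ord$points,
                            scale = TRUE, symmetric = FALSE)
  pts <- proc$Yrot
  dimnames(pts) <- dimnames(ord$points)
  ord$points <- pts
  ord$procrustes_ss <- proc$ss
  ord
}

#' Write ordination coordinates as CSV
#'
#' @param ord an `nmds_fit`.
#' @param file CSV path.
#' @export
write_ordination <- function(ord, file) {
  df <- data.frame(cell_id = rownames(ord$points), ord$points,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
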