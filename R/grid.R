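#' Build a planar equal-area hexagonal grid
#'
#' Constructs a pointy-top hexagonal lattice of `n_cols` x `n_rows` cells with
#' uniform cell area. The lattice is a planar stand-in for an equal-area
#' Earth hexagon grid (e.g. a Behrmann-projected grid); real grids can be
#' supplied through [read_grid()] instead. Edges are not wrapped: boundary
#' cells simply have fewer than six neighbours.
#'
#' @param n_cols,n_rows lattice dimensions (>= 1).
#' @param cell_area area of every cell, in km^2. Controls the centroid
#'   spacing: a regular hexagon of area A has side `s = sqrt(2A/(3*sqrt(3)))`
#'   and neighbour distance `sqrt(3)*s`.
#' @return An object of class `hex_grid`: a list with
#'   \describe{
#'     \item{cells}{data.frame with `cell_id`, `x`, `y`, `area`}
#'     \item{adjacency}{data.frame with `cell_id`, `neighbor_id` (symmetric)}
#'   }
#' @examples
#' g <- build_hex_grid(3, 3, 100)
#' nrow(g$cells)  # 9
#' @export
build_hex_grid <- function(n_cols, n_rows, cell_area = 5e4) {
  if (length(n_cols) != 1L || length(n_rows) != 1L ||
      n_cols < 1 || n_rows < 1) {
    stop("n_cols and n_rows must be >= 1", call. = FALSE)
  }
  if (cell_area <= 0) stop("cell_area must be positive", call. = FALSE)
  n_cols <- as.integer(n_cols)
  n_rows <- as.integer(n_rows)

  side <- sqrt(2 * cell_area / (3 * sqrt(3)))
  w <- sqrt(3) * side       # horizontal neighbour spacing
  vstep <- 1.5 * side       # vertical row spacing

  row <- rep(seq_len(n_rows) - 1L, each = n_cols)
  col <- rep(seq_len(n_cols) - 1L, times = n_rows)
  cells <- data.frame(
    cell_id = sprintf("c%04d", seq_len(n_cols * n_rows)),
    x = w * (col + 0.5 * (row %% 2L)),
    y = vstep * row,
    area = cell_area,
    stringsAsFactors = FALSE
  )

  # all six hexagon neighbours sit at exactly distance w; tolerance covers fp
  adj <- grid_adjacency_by_distance(cells$x, cells$y, w * 1.001)
  adjacency <- data.frame(
    cell_id = cells$cell_id[adj[, 1L]],
    neighbor_id = cells$cell_id[adj[, 2L]],
    stringsAsFactors = FALSE
  )
  structure(list(cells = cells, adjacency = adjacency), class = "hex_grid")
}

# symmetric neighbour pairs (both directions) for points within `thresh`
grid_adjacency_by_distance <- function(x, y, thresh) {
  n <- length(x)
  if (n == 1L) return(matrix(integer(0), ncol = 2L))
  d <- as.matrix(stats::dist(cbind(x, y)))
  hit <- which(d > 0 & d <= thresh, arr.ind = TRUE)
  unname(hit)
}

#' @export
print.hex_grid <- function(x, ...) {
  cat(sprintf("hex_grid: %d cells, %d adjacency pairs, cell area %g\n",
              nrow(x$cells), nrow(x$adjacency), x$cells$area[1L]))
  invisible(x)
}

#' Neighbour lists of a grid
#'
#' @param grid a `hex_grid`.
#' @return named list: for each cell id, the character vector of neighbour ids.
#' @export
grid_neighbors <- function(grid) {
  out <- split(grid$adjacency$neighbor_id, grid$adjacency$cell_id)
  miss <- setdiff(grid$cells$cell_id, names(out))
  out[miss] <- list(character(0))
  out[grid$cells$cell_id]
}

#' Write / read a grid as two CSV files
#'
#' The on-disk format is a cell table (`cell_id,x,y,area`) plus an adjacency
#' table (`cell_id,neighbor_id`), so grids built elsewhere (e.g. on a real
#' equal-area projection) can be dropped in.
#'
#' @param grid a `hex_grid`.
#' @param cells_file,adjacency_file CSV paths.
#' @return `write_grid` returns the paths invisibly; `read_grid` a `hex_grid`.
#' @export
write_grid <- function(grid, cells_file, adjacency_file) {
  utils::write.csv(grid$cells, cells_file, row.names = FALSE, quote = FALSE)
  utils::write.csv(grid$adjacency, adjacency_file,
                   row.names = FALSE, quote = FALSE)
  invisible(c(cells_file, adjacency_file))
}

#' @rdname write_grid
#' @export
read_grid <- function(cells_file, adjacency_file) {
  cells <- utils::read.csv(cells_file, stringsAsFactors = FALSE)
  adjacency <- utils::read.csv(adjacency_file, stringsAsFactors = FALSE)
  validate_grid(cells, adjacency)
  structure(list(cells = cells, adjacency = adjacency), class = "hex_grid")
}

validate_grid <- function(cells, adjacency) {
  stopifnot(all(c("cell_id", "x", "y", "area") %in% names(cells)),
            all(c("cell_id", "neighbor_id") %in% names(adjacency)))
  if (anyDuplicated(cells$cell_id)) stop("duplicate cell ids", call. = FALSE)
  if (any(cells$area <= 0)) stop("cell areas must be positive", call. = FALSE)
  if (any(adjacency$cell_id == adjacency$neighbor_id)) {
    stop("adjacency contains self-loops", call. = FALSE)
  }
  key <- paste(adjacency$cell_id, adjacency$neighbor_id)
  rev <- paste(adjacency$neighbor_id, adjacency$cell_id)
  if (!all(rev %in% key)) stop("adjacency is not symmetric", call. = FALSE)
  invisible(TRUE)
}

#' Centroid coordinate matrix of a grid
#'
#' @param grid a `hex_grid`.
#' @return numeric matrix with rownames = cell ids and columns x, y.
#' @export
grid_centroids <- function(grid) {
  m <- cbind(x = grid$cells$x, y = grid$cells$y)
  rownames(m) <- grid$cells$cell_id
  m
}
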