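#' Presence matrices
#'
#' A presence matrix is a binary cell x taxon incidence matrix: rows are grid
#' cells (rownames = cell ids), columns are taxa (colnames = taxon names),
#' entries 0/1. Plain base matrices are used throughout so standard matrix
#' algebra applies.
#'
#' @param m a matrix coercible to 0/1 with full dimnames.
#' @return the validated binary matrix.
#' @export
as_presence_matrix <- function(m) {
  m <- as.matrix(m)
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("presence matrix needs cell rownames and taxon colnames",
         call. = FALSE)
  }
  if (!all(m %in% c(0, 1))) stop("entries must be 0/1", call. = FALSE)
  storage.mode(m) <- "integer"
  m
}

#' Aggregate fine-grid presences onto hexagon cells
#'
#' A taxon is present in a hexagon if it is present in at least one of the
#' fine cells mapped to that hexagon (a logical OR, i.e. maximum-value
#' resampling of binary range maps).
#'
#' @param fine_presence named list: for each taxon, a character vector of
#'   fine-cell ids where it is present.
#' @param fine_to_hex named character vector mapping every fine-cell id to a
#'   hexagon cell id.
#' @param all_cells optional character vector of hexagon ids fixing row order
#'   (defaults to the sorted set appearing in `fine_to_hex`).
#' @return a presence matrix (hexagons x taxa).
#' @export
aggregate_presence <- function(fine_presence, fine_to_hex, all_cells = NULL) {
  stopifnot(is.list(fine_presence), !is.null(names(fine_presence)))
  fine_ids <- unique(unlist(fine_presence, use.names = FALSE))
  unknown <- setdiff(fine_ids, names(fine_to_hex))
  if (length(unknown)) {
    stop("fine cells without hexagon assignment: ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  if (is.null(all_cells)) all_cells <- sort(unique(unname(fine_to_hex)))
  taxa <- names(fine_presence)
  pm <- matrix(0L, nrow = length(all_cells), ncol = length(taxa),
               dimnames = list(all_cells, taxa))
  for (tx in taxa) {
    hexes <- unique(unname(fine_to_hex[fine_presence[[tx]]]))
    pm[hexes, tx] <- 1L
  }
  pm
}

#' Drop species-poor cells from a presence matrix
#'
#' Cells (rows) with fewer than `min_taxa` taxa present are removed, to avoid
#' distorted dissimilarities from tiny assemblages; taxa whose column becomes
#' all-zero are then dropped. Row and column order is otherwise preserved.
#' Idempotent: filtering a filtered matrix changes nothing.
#'
#' @param pm presence matrix.
#' @param min_taxa minimum assemblage richness to retain a cell (default 5).
#' @return the filtered presence matrix.
#' @export
filter_cells <- function(pm, min_taxa = 5L) {
  pm <- as_presence_matrix(pm)
  keep_rows <- rowSums(pm) >= min_taxa
  if (!any(keep_rows)) {
    stop("no valid cells: every cell has fewer than ", min_taxa, " taxa",
         call. = FALSE)
  }
  out <- pm[keep_rows, , drop = FALSE]
  out[, colSums(out) >= 1L, drop = FALSE]
}

#' Write / read a presence matrix as dense 0/1 CSV
#'
#' The first column (`cell_id`) holds row ids; remaining columns are taxa.
#'
#' @param pm presence matrix.
#' @param file CSV path.
#' @export
write_presence <- function(pm, file) {
  df <- data.frame(cell_id = rownames(pm), pm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_presence
#' @export
read_presence <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  as_presence_matrix(m)
}
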