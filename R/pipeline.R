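#' Convert a cell -> label map to a regionalization
#'
#' All labelled cells are marked valid; areas come from the grid. Useful for
#' treating a ground-truth or externally supplied labelling as a scheme
#' comparable by [v_measure()].
#'
#' @param labels named vector cell_id -> label.
#' @param grid a `hex_grid`.
#' @return a `regionalization`.
#' @export
labels_to_regionalization <- function(labels, grid) {
  cells <- names(labels)
  structure(
    data.frame(cell_id = cells, region = unname(as.character(labels)),
               realm = NA_character_, valid = TRUE,
               area = grid$cells$area[match(cells, grid$cells$cell_id)],
               stringsAsFactors = FALSE),
    class = c("regionalization", "data.frame")
  )
}

#' Region labels of a regionalization as a named vector
#'
#' @param reg a `regionalization`.
#' @param valid_only drop unassigned/invalid cells (default TRUE).
#' @return named vector cell_id -> region label.
#' @export
region_labels <- function(reg, valid_only = TRUE) {
  if (valid_only) reg <- reg[reg$valid & reg$region != "unassigned", ]
  stats::setNames(reg$region, reg$cell_id)
}

#' Run the full regionalization pipeline on synthetic data
#'
#' Simulates a planted-region data set, computes taxonomic and
#' posterior-median phylogenetic turnover, selects the best linkage,
#' delineates regions and realms, ordinates the cells, compares the
#' recovered regionalization with the planted truth (V-measure with Voronoi
#' nulls), and runs a Mantel test between the two turnover matrices. All
#' tables are written as CSV and a run summary as JSON under `out_dir`;
#' outputs are byte-reproducible given the same configuration and seed.
#'
#' @param out_dir output directory (created if missing).
#' @param seed master seed.
#' @param n_cols,n_rows,n_regions,n_tips,richness,mixing,n_trees,sd_log
#'   passed to [simulate_biogeography()].
#' @param k_max elbow search range for regions.
#' @param max_realms strict upper bound for the realm cut.
#' @param min_cells,aggregation_threshold validity rules.
#' @param n_starts NMDS random starts.
#' @param n_null Voronoi nulls per direction.
#' @return (invisibly) list with all intermediate objects and the `report`.
#' @export
run_pipeline <- function(out_dir, seed = 1L,
                         n_cols = 12L, n_rows = 12L, n_regions = 4L,
                         n_tips = 96L, richness = 12L, mixing = 0.05,
                         n_trees = 10L, sd_log = 0.1,
                         k_max = 30L, max_realms = 15L,
                         min_cells = 10L, aggregation_threshold = 0.5,
                         n_starts = 20L, n_null = 99L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)

  sim <- simulate_biogeography(
    n_cols = n_cols, n_rows = n_rows, n_regions = n_regions, n_tips = n_tips,
    richness = richness, mixing = mixing, n_trees = n_trees, sd_log = sd_log,
    seed = seed
  )
  write_grid(sim$grid, p("grid_cells.csv"), p("grid_adjacency.csv"))
  write_presence(sim$pm, p("presence.csv"))
  write_labels(sim$truth, p("truth.csv"), "true_region")
  ape::write.tree(sim$tree, p("tree.nwk"))
  if (!is.null(sim$trees)) ape::write.tree(sim$trees, p("posterior.nwk"))

  pm <- filter_cells(sim$pm, min_taxa = 5L)
  d_tax <- betasim_matrix(pm, "taxonomic")
  d_phy <- if (!is.null(sim$trees)) {
    median_posterior_betasim(pm, sim$trees)
  } else {
    betasim_matrix(pm, "phylogenetic", sim$tree)
  }
  write_dissimilarity(d_tax, p("betasim_taxonomic.csv"))
  write_dissimilarity(d_phy, p("betasim_phylogenetic_median.csv"))
  write_labels(round(distinctiveness(d_phy), 10), p("distinctiveness.csv"),
               "mean_betasim")

  evals <- evaluate_algorithms(d_phy)
  utils::write.csv(evals, p("algorithm_evaluation.csv"), row.names = FALSE,
                   quote = FALSE)
  method <- select_algorithm(evals)
  dend <- hierarchical_cluster(d_phy, method)
  curve <- variance_explained_curve(d_phy, dend, k_max = k_max)
  utils::write.csv(curve, p("elbow_curve.csv"), row.names = FALSE,
                   quote = FALSE)
  k_star <- elbow(curve)
  regions <- delineate_regions(dend, k_star, sim$grid, min_cells = min_cells,
                               aggregation_threshold = aggregation_threshold)
  regions <- assign_realms(dend, regions, d_phy, max_realms = max_realms)
  write_regionalization(regions, p("regionalization.csv"))

  ord <- nmds(d_phy, n_starts = n_starts, seed = seed + 10L)
  ord <- rotate_to_geography(ord, grid_centroids(sim$grid))
  write_ordination(ord, p("ordination.csv"))

  truth_reg <- labels_to_regionalization(sim$truth, sim$grid)
  comp <- null_comparison(regions, truth_reg, sim$grid, n_null = n_null,
                          seed = seed + 20L)
  mt <- mantel_test(d_tax, d_phy, n_perm = n_null, seed = seed + 30L)

  rec <- region_labels(regions)
  ari <- adjusted_rand_index(rec, sim$truth[names(rec)])
  report <- list(
    seed = seed,
    n_cells = nrow(pm),
    n_taxa = ncol(pm),
    selected_method = method,
    k_regions = k_star,
    k_realms = attr(regions, "k_realm"),
    n_valid_regions = length(unique(rec)),
    ari_vs_truth = ari,
    nmds_stress = ord$stress,
    v_obs = comp$v_obs, p_a = comp$p_a, p_b = comp$p_b,
    ses_a = comp$ses_a, ses_b = comp$ses_b,
    mantel_r = mt$r, mantel_p = mt$p
  )
  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  invisible(list(sim = sim, pm = pm, d_tax = d_tax, d_phy = d_phy,
                 evals = evals, dend = dend, curve = curve,
                 regions = regions, ord = ord, comparison = comp,
                 mantel = mt, report = report))
}
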