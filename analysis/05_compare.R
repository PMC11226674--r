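#!/usr/bin/env Rscript

# Stage 5: congruence. Compares the recovered regionalization with the
# planted truth (and with an independent Voronoi scheme as a negative
# control) using the area-weighted V-measure, 999 random Voronoi
# regionalizations per direction, directional p-values and SES, plus the
# per-region homogeneity maps.

suppressMessages(library(betaregion))
suppressMessages(library(jsonlite))

out <- file.path("results", "comparison")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

grid <- read_grid(file.path("results", "data", "grid_cells.csv"),
                  file.path("results", "data", "grid_adjacency.csv"))
truth <- read_labels(file.path("results", "data", "truth.csv"), "true_region")
reg <- read_regionalization(file.path("results", "regions",
                                      "regionalization.csv"))
truth_reg <- labels_to_regionalization(truth, grid)

vm <- v_measure(area_crosstab(reg, truth_reg))
comp <- null_comparison(reg, truth_reg, grid, n_null = 999L, seed = 13L)
cat(sprintf("Recovered vs truth: V = %.3f (h = %.3f, completeness = %.3f).\n",
            vm$v, vm$h, vm$comp))
cat(sprintf("Null test: p_a = %.3g, p_b = %.3g; SES %.1f / %.1f.\n",
            comp$p_a, comp$p_b, comp$ses_a, comp$ses_b))

control <- random_voronoi_regionalization(grid, comp$k_a, seed = 99L)
ctrl <- null_comparison(reg, control, grid, n_null = 999L, seed = 14L)
cat(sprintf("Negative control (independent Voronoi): V = %.3f, p_a = %.3g, SES %.1f.\n",
            ctrl$v_obs, ctrl$p_a, ctrl$ses_a))

hom <- data.frame(
  region = names(vm$per_region_homogeneity_a),
  homogeneity = unname(vm$per_region_homogeneity_a)
)
write.csv(hom, file.path(out, "per_region_homogeneity.csv"),
          row.names = FALSE, quote = FALSE)

write_json(
  list(v = vm$v, homogeneity = vm$h, completeness = vm$comp,
       p_a = comp$p_a, p_b = comp$p_b, ses_a = comp$ses_a,
       ses_b = comp$ses_b,
       null_mean_a = mean(comp$null_v_a), null_sd_a = sd(comp$null_v_a),
       control_v = ctrl$v_obs, control_p_a = ctrl$p_a,
       control_ses_a = ctrl$ses_a),
  file.path(out, "comparison.json"), auto_unbox = TRUE, digits = 10,
  pretty = TRUE
)
cat("Wrote results/comparison/comparison.json.\n")
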