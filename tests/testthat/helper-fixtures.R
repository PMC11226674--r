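# Shared fixture builders; everything is generated in code under fixed seeds.

# random binary presence matrix with no empty rows
random_pm <- function(n_cells, taxa, seed, p = 0.5) {
  set.seed(seed)
  repeat {
    m <- matrix(rbinom(n_cells * length(taxa), 1L, p), n_cells, length(taxa),
                dimnames = list(sprintf("cell%02d", seq_len(n_cells)), taxa))
    if (all(rowSums(m) > 0)) return(m)
  }
}

# independent Pbsim oracle: per-pair enumeration of branch sets using
# phangorn::Descendants (a different tip-mapping route than the package's)
oracle_pbsim_pair <- function(pm, tree, cx, cy) {
  desc <- phangorn::Descendants(tree, tree$edge[, 2L], type = "tips")
  edge_tips <- lapply(desc, function(i) tree$tip.label[i])
  present_edges <- function(cell) {
    taxa <- colnames(pm)[pm[cell, ] == 1L]
    vapply(edge_tips, function(tp) any(tp %in% taxa), logical(1L))
  }
  ex <- present_edges(cx)
  ey <- present_edges(cy)
  len <- tree$edge.length
  a <- sum(len[ex & ey]); b <- sum(len[ex & !ey]); c <- sum(len[!ex & ey])
  1 - a / (min(b, c) + a)
}

oracle_pbsim_matrix <- function(pm, tree) {
  n <- nrow(pm)
  d <- matrix(0, n, n, dimnames = list(rownames(pm), rownames(pm)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- oracle_pbsim_pair(pm, tree,
                                            rownames(pm)[i], rownames(pm)[j])
  }
  d
}

# entropy oracle for the V-measure: conditional entropies computed directly
# as weighted within-row/column entropies (the package goes via the joint)
oracle_v_measure <- function(ct) {
  p <- ct / sum(ct)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  h_b_given_a <- sum(rowSums(p) *
                       apply(p, 1L, function(r) if (sum(r) > 0) ent(r / sum(r)) else 0))
  h_a_given_b <- sum(colSums(p) *
                       apply(p, 2L, function(r) if (sum(r) > 0) ent(r / sum(r)) else 0))
  hb <- ent(colSums(p)); ha <- ent(rowSums(p))
  h <- if (hb > 0) 1 - h_b_given_a / hb else 1
  comp <- if (ha > 0) 1 - h_a_given_b / ha else 1
  list(h = h, comp = comp,
       v = if (h + comp > 0) 2 * h * comp / (h + comp) else 0)
}

# regionalization from a plain label vector on a grid, all cells valid
reg_from_labels <- function(labels, grid) {
  betaregion::labels_to_regionalization(labels, grid)
}
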