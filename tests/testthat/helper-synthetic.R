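# Shared fixtures, built in code.

# small wild-type-like population, reused across tests
wt_population <- function(n = 400, seed = 101, ...) {
  generate_cell_population(strain_spec("WT", ...), n, seed = seed)
}

# tiny planted screen: WT bulk + 3 well-separated islands
planted_screen <- function(seed = 11, n_wt = 40, n_null = 10,
                           island_n = 10) {
  screen_truth(
    n_wt = n_wt, n_null = n_null, seed = seed,
    islands = list(
      list(n = island_n, offsets = c(mean_length = 6, cv_length = 5)),
      list(n = island_n, offsets = c(mean_width = 6,
                                     mean_nucleoid_area = -6)),
      list(n = island_n, offsets = c(rel_t_nuc = -6, rel_t_const = -6))
    )) |>
    generate_screen()
}

# scores for the planted screen, without the growth features (no fitting):
# morphological + cell-cycle separation is what the planted islands carry
planted_scores <- function(screen) {
  feats <- screen_features(screen$cells)
  sc <- compute_scores(feats, screen$truth$wt_ids)
  x <- tibble::as_tibble(sc)
  num <- vapply(x, is.numeric, logical(1))
  for (f in names(x)[num]) x[[f]][is.na(x[[f]])] <- 0
  x[, names(x) != "n_cells"]
}

# ground-truth partition labels (0 = wild-type-like) in assignment order
truth_labels <- function(screen, strain_ids) {
  info <- screen$truth$strain_info
  lab <- info$island_label[match(strain_ids, info$strain_id)]
  ifelse(is.na(lab), 0L, lab)
}

# independent DBSCAN oracle: brute-force density reachability through
# igraph connected components over core points
dbscan_oracle <- function(points, eps, min_points) {
  d <- as.matrix(dist(points))
  nb <- d <= eps
  core <- rowSums(nb) >= min_points
  n <- nrow(d)
  labels <- integer(n)
  if (!any(core)) return(labels)
  core_idx <- which(core)
  adj <- nb[core_idx, core_idx, drop = FALSE]
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  labels[core_idx] <- comp
  for (b in which(!core)) {
    reach <- core_idx[nb[b, core_idx]]
    if (length(reach)) labels[b] <- labels[reach[which.min(d[b, reach])]]
  }
  labels
}

# agreement of two labelings up to label permutation
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (any((a == 0) != (b == 0))) return(FALSE)
  ok <- a > 0
  tab <- table(a[ok], b[ok])
  all(rowSums(tab > 0) <= 1) && all(colSums(tab > 0) <= 1)
}

# noiseless Zwietering Gompertz curve (minutes, per-minute mu)
gompertz_curve_fixture <- function(A = 4.4, mu = 0.0096, lambda = 120,
                                   od0 = 0.01, by = 5, t_end = 960) {
  t <- seq(0, t_end, by = by)
  tibble::tibble(
    time_min = t,
    od600 = od0 * exp(A * exp(-exp(mu * exp(1) / A * (lambda - t) + 1))))
}
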