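# Phenotypic islands: consensus over repeated stochastic embeddings plus
# density clustering.

#' Repeated stochastic embeddings of a score matrix
#'
#' Runs [embed_tsne()] `n_maps` times with per-map seeds derived from the
#' master seed. The stochasticity of the embedding is the resource: only
#' co-membership across maps is aggregated downstream, so maps need no
#' rotational alignment. Each map is, however, rescaled to a common
#' root-mean-square radius (10 units): the absolute scale of a stochastic
#' embedding varies between runs, and a shared scale is what lets one
#' DBSCAN radius apply to every map.
#'
#' @param scores A [compute_scores()] result or any tibble with
#'   `strain_id` plus numeric columns (no missing values).
#' @param n_maps Number of embeddings.
#' @param perplexity t-SNE perplexity.
#' @param seed Master seed.
#' @param n_iter Iterations per map.
#' @return An object of class `embedding_set`: list with `maps` (list of
#'   n x 2 matrices), `strain_ids`, `perplexity`, `seed`.
#' @export
embed_consensus <- function(scores, n_maps = 100, perplexity = 30, seed = 1,
                            n_iter = 400) {
  x <- score_matrix_values(scores)
  if (nrow(x) < 10) abort("need at least 10 strains.")
  if (anyNA(x)) abort("score matrix contains missing values; impute upstream.")
  maps <- lapply(seq_len(n_maps), function(m) {
    y <- embed_tsne(x, perplexity = perplexity, n_iter = n_iter,
                    seed = derive_seed(seed, m))
    y / sqrt(mean(rowSums(y^2))) * 10
  })
  structure(list(maps = maps, strain_ids = rownames(x),
                 perplexity = perplexity, seed = seed),
            class = "embedding_set")
}

score_matrix_values <- function(scores) {
  if (is.matrix(scores)) {
    if (is.null(rownames(scores))) rownames(scores) <- seq_len(nrow(scores))
    return(scores)
  }
  check_columns(scores, "strain_id", "score matrix")
  num <- vapply(scores, is.numeric, logical(1))
  x <- as.matrix(scores[, num & names(scores) != "n_cells", drop = FALSE])
  rownames(x) <- scores$strain_id
  x
}

#' Density-based clustering (DBSCAN)
#'
#' Canonical DBSCAN: points with at least `min_points` neighbours within
#' `eps` (the point itself included) are core points; clusters are the
#' connected components of core points at distance `<= eps`; non-core
#' points within `eps` of a core point join the cluster of their nearest
#' core point (ties to the lowest index), everything else is noise. This
#' formulation is order-invariant.
#'
#' @param points n x 2 coordinate matrix (or any numeric matrix).
#' @param eps Neighbourhood radius.
#' @param min_points Core-point density threshold.
#' @return Integer labels, 0 = noise.
#' @export
dbscan_cluster <- function(points, eps, min_points = 3) {
  points <- as.matrix(points)
  n <- nrow(points)
  check_number(eps, "eps", lower = 1e-12)
  d <- as.matrix(dist(points))
  nb <- d <= eps
  core <- rowSums(nb) >= min_points
  labels <- integer(n)
  if (!any(core)) return(labels)

  # connected components of core points under eps-adjacency
  core_idx <- which(core)
  comp <- integer(n)
  cl <- 0L
  for (s in core_idx) {
    if (comp[s] != 0L) next
    cl <- cl + 1L
    queue <- s
    comp[s] <- cl
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nbrs <- core_idx[nb[v, core_idx] & comp[core_idx] == 0L]
      comp[nbrs] <- cl
      queue <- c(queue, nbrs)
    }
  }
  labels[core_idx] <- comp[core_idx]

  border <- which(!core)
  for (b in border) {
    reach <- core_idx[nb[b, core_idx]]
    if (length(reach)) {
      nearest <- reach[which.min(d[b, reach])]
      labels[b] <- labels[nearest]
    }
  }
  labels
}

#' Consensus islands from repeated embeddings
#'
#' Clusters every map with DBSCAN, counts for each strain pair the
#' fraction of maps in which the pair shares a cluster, links pairs
#' co-clustering in more than `co_threshold` of the maps, and returns the
#' connected components of that graph (of size >= `min_points`) as
#' islands. Strains not consistently associated with any island remain
#' unassigned (island 0).
#'
#' @param embeds An [embed_consensus()] result.
#' @param eps,min_points DBSCAN parameters applied to every map.
#' @param co_threshold Co-clustering frequency required to link a pair
#'   (default 0.9: together in more than 90% of the maps).
#' @return An object of class `island_partition`: tibble `assignment`
#'   (`strain_id`, `island`, `co_membership`), matrix `co_freq`, and the
#'   parameters used.
#' @export
consensus_islands <- function(embeds, eps, min_points = 3,
                              co_threshold = 0.9) {
  if (!inherits(embeds, "embedding_set")) {
    abort("`embeds` must come from embed_consensus().")
  }
  ids <- embeds$strain_ids
  n <- length(ids)
  co <- matrix(0, n, n)
  for (map in embeds$maps) {
    lab <- dbscan_cluster(map, eps = eps, min_points = min_points)
    for (l in setdiff(unique(lab), 0L)) {
      m <- which(lab == l)
      co[m, m] <- co[m, m] + 1
    }
  }
  co <- co / length(embeds$maps)
  diag(co) <- 1

  adj <- co > co_threshold
  diag(adj) <- FALSE
  comp <- graph_components(adj)
  labels <- integer(n)
  k <- 0L
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    if (length(members) >= min_points) {
      k <- k + 1L
      labels[members] <- k
    }
  }
  co_membership <- vapply(seq_len(n), function(i) {
    if (labels[i] == 0L) return(NA_real_)
    mates <- setdiff(which(labels == labels[i]), i)
    if (!length(mates)) return(1)
    mean(co[i, mates])
  }, numeric(1))

  structure(
    list(assignment = tibble(strain_id = ids, island = labels,
                             co_membership = co_membership),
         co_freq = `dimnames<-`(co, list(ids, ids)),
         eps = eps, min_points = min_points, co_threshold = co_threshold,
         n_maps = length(embeds$maps)),
    class = "island_partition")
}

# connected components of a logical adjacency matrix (BFS)
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cl <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cl <- cl + 1L
    queue <- s
    comp[s] <- cl
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nbrs <- which(adj[v, ] & comp == 0L)
      comp[nbrs] <- cl
      queue <- c(queue, nbrs)
    }
  }
  comp
}

#' Tune the DBSCAN radius on consensus islands
#'
#' Chooses, over `eps_grid`, the radius yielding the most consensus
#' islands subject to the constraint that at least `wt_bulk` of the
#' wild-type replicates share a single island (the wild-type bulk must
#' not fragment). Ties resolve to the radius with the highest wild-type
#' bulk cohesion (a too-small radius strands borderline bulk strains as
#' unassigned), then to the smaller radius.
#'
#' @param embeds An [embed_consensus()] result.
#' @param wt_ids Wild-type strain ids.
#' @param eps_grid Candidate radii.
#' @param min_points DBSCAN minimum cluster size.
#' @param wt_bulk Required fraction of wild-type ids in one island.
#' @param co_threshold Consensus threshold passed through.
#' @return A list with `eps`, `min_points` and the search `trace` tibble.
#' @export
tune_dbscan <- function(embeds, wt_ids, eps_grid, min_points = 3,
                        wt_bulk = 0.9, co_threshold = 0.9) {
  if (length(eps_grid) < 1) abort("empty eps grid.")
  rows <- lapply(sort(eps_grid), function(e) {
    part <- consensus_islands(embeds, eps = e, min_points = min_points,
                              co_threshold = co_threshold)
    wt <- filter(part$assignment, .data$strain_id %in% wt_ids)
    bulk <- if (nrow(wt) == 0) 0 else {
      assigned <- wt$island[wt$island > 0]
      if (!length(assigned)) 0 else max(tabulate(assigned)) / nrow(wt)
    }
    tibble(eps = e,
           n_islands = max(part$assignment$island),
           wt_bulk_fraction = bulk)
  })
  trace <- list_rbind(rows)
  ok <- filter(trace, .data$wt_bulk_fraction >= wt_bulk)
  if (nrow(ok) == 0) {
    abort("no eps in the grid keeps the wild-type bulk in one island.")
  }
  best <- ok[order(-ok$n_islands, -ok$wt_bulk_fraction, ok$eps), ][1, ]
  list(eps = best$eps, min_points = min_points, trace = trace)
}

#' Stability of islands under subsampling
#'
#' Cross-validation-style check of embedding convergence: strains are
#' split into `n_partitions` disjoint holdout sets of fraction `holdout`;
#' for each partition the remaining strains are re-embedded
#' `maps_per_partition` times and re-clustered, and each reference island
#' receives, per map, the maximal fraction of its surviving members that
#' still cluster together — a Jaccard-style index.
#'
#' @param scores Score matrix (as for [embed_consensus()]).
#' @param reference An [consensus_islands()] partition on the full data.
#' @param eps,min_points DBSCAN parameters (use the reference's).
#' @param n_partitions Number of disjoint holdout sets.
#' @param maps_per_partition Embeddings per subsample.
#' @param holdout Fraction held out per partition (~2%).
#' @param perplexity,seed Passed to the embeddings.
#' @return Tibble `island`, `map`, `partition`, `stability`.
#' @export
island_stability <- function(scores, reference, eps, min_points = 3,
                             n_partitions = 50, maps_per_partition = 10,
                             holdout = 0.02, perplexity = 30, seed = 1) {
  x <- score_matrix_values(scores)
  ids <- rownames(x)
  n <- length(ids)
  ref <- reference$assignment
  islands <- sort(setdiff(unique(ref$island), 0L))
  if (!length(islands)) abort("reference partition has no islands.")

  hold_size <- max(1, round(holdout * n))
  order_ids <- with_seed(seed, sample(n))
  out <- list()
  for (p in seq_len(n_partitions)) {
    # disjoint holdouts, cycling through the shuffled order
    sel <- order_ids[((p - 1) * hold_size + seq_len(hold_size) - 1) %% n + 1]
    keep <- setdiff(seq_len(n), sel)
    xk <- x[keep, , drop = FALSE]
    for (m in seq_len(maps_per_partition)) {
      y <- embed_tsne(xk, perplexity = perplexity,
                      seed = derive_seed(seed, p * 1000 + m))
      lab <- dbscan_cluster(y, eps = eps, min_points = min_points)
      for (isl in islands) {
        members <- which(ids[keep] %in% ref$strain_id[ref$island == isl])
        if (length(members) < 2) next
        labs <- lab[members]
        best <- max(tabulate(labs[labs > 0]), 0)
        out[[length(out) + 1]] <- tibble(
          island = isl, partition = p, map = m,
          stability = best / length(members))
      }
    }
  }
  list_rbind(out)
}

#' Average score profile (phenoprint) of each island
#'
#' @param partition An [consensus_islands()] result.
#' @param scores The score matrix the partition was built from.
#' @return Tibble `island`, `feature`, `mean_score`.
#' @export
island_phenoprints <- function(partition, scores) {
  x <- score_matrix_values(scores)
  a <- partition$assignment
  rows <- lapply(sort(setdiff(unique(a$island), 0L)), function(isl) {
    members <- a$strain_id[a$island == isl]
    mu <- colMeans(x[members, , drop = FALSE], na.rm = TRUE)
    tibble(island = isl, feature = names(mu), mean_score = unname(mu))
  })
  list_rbind(rows)
}

#' @export
print.island_partition <- function(x, ...) {
  k <- max(x$assignment$island)
  cat(sprintf(
    "<island_partition> %d islands over %d strains (eps %.3g, minPts %d, consensus > %.0f%% of %d maps); %d unassigned\n",
    k, nrow(x$assignment), x$eps, x$min_points, 100 * x$co_threshold,
    x$n_maps, sum(x$assignment$island == 0)))
  invisible(x)
}

#' @rdname consensus_islands
#' @param x,object An `island_partition`.
#' @param ... Unused.
#' @method tidy island_partition
#' @export
tidy.island_partition <- function(x, ...) x$assignment

#' @rdname consensus_islands
#' @method glance island_partition
#' @export
glance.island_partition <- function(x, ...) {
  tibble(n_islands = max(x$assignment$island),
         n_assigned = sum(x$assignment$island > 0),
         n_unassigned = sum(x$assignment$island == 0),
         eps = x$eps, min_points = x$min_points,
         co_threshold = x$co_threshold, n_maps = x$n_maps)
}

#' Plot one embedding coloured by island assignment
#'
#' @param partition An `island_partition`.
#' @param embeds The [embed_consensus()] set; the first map is drawn.
#' @param map Index of the map to draw.
#' @return A ggplot object.
#' @export
plot_islands <- function(partition, embeds, map = 1) {
  y <- embeds$maps[[map]]
  df <- mutate(partition$assignment,
               x = y[, 1], y = y[, 2],
               island = factor(ifelse(.data$island == 0, NA, .data$island)))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$island)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_colour_discrete(na.value = "grey80") +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2", colour = "island")
}
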