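# Embedding, DBSCAN, consensus islands.

test_that("DBSCAN handles its degenerate geometries", {
  # two blobs far apart: 2 clusters, no noise
  set.seed(51)
  pts <- rbind(matrix(rnorm(40, 0, 0.1), ncol = 2),
               matrix(rnorm(40, 100, 0.1), ncol = 2))
  lab <- dbscan_cluster(pts, eps = 1, min_points = 3)
  expect_equal(length(unique(lab)), 2)
  expect_true(all(lab > 0))

  # everything within eps: one cluster
  expect_equal(unique(dbscan_cluster(matrix(rnorm(20, 0, 0.01), ncol = 2),
                                     eps = 1, min_points = 3)), 1L)

  # isolated point is noise
  lone <- rbind(matrix(rnorm(20, 0, 0.05), ncol = 2), c(50, 50))
  expect_equal(dbscan_cluster(lone, eps = 1, min_points = 3)[11], 0L)
})

test_that("DBSCAN agrees with the brute-force reachability oracle", {
  set.seed(52)
  for (i in 1:50) {
    n <- sample(20:200, 1)
    k <- sample(1:4, 1)
    centers <- matrix(runif(2 * k, 0, 10), ncol = 2)
    pts <- centers[sample(k, n, replace = TRUE), ] +
      matrix(rnorm(2 * n, 0, runif(1, 0.1, 1)), ncol = 2)
    eps <- runif(1, 0.2, 1.5)
    mp <- sample(3:6, 1)
    expect_true(same_partition(dbscan_cluster(pts, eps, mp),
                               dbscan_oracle(pts, eps, mp)),
                info = sprintf("instance %d", i))
  }
})

test_that("DBSCAN labels are order-invariant up to permutation", {
  set.seed(53)
  pts <- matrix(rnorm(200), ncol = 2)
  perm <- sample(100)
  a <- dbscan_cluster(pts, eps = 0.4, min_points = 4)
  b <- dbscan_cluster(pts[perm, ], eps = 0.4, min_points = 4)
  expect_true(same_partition(a[perm], b))
})

test_that("consensus aggregation follows the co-clustering threshold", {
  # synthetic embedding set: 2 maps, 20 points; pair (1, 2) co-clusters in
  # only one map -> below the 0.9 threshold -> not joined
  base <- rbind(matrix(rnorm(20, 0, 0.1), ncol = 2),
                matrix(rnorm(20, 10, 0.1), ncol = 2))
  moved <- base
  moved[1, ] <- c(10, 10) # point 1 defects to the other blob in map 2
  es <- structure(list(maps = list(base, moved),
                       strain_ids = sprintf("s%02d", 1:20),
                       perplexity = 5, seed = 1),
                  class = "embedding_set")
  part <- consensus_islands(es, eps = 1, min_points = 3, co_threshold = 0.9)
  expect_equal(part$co_freq["s01", "s02"], 0.5)
  isl <- part$assignment$island
  expect_true(isl[1] == 0 || isl[1] != isl[2])

  # identical maps: partition equals the per-map clustering
  es2 <- structure(list(maps = list(base, base), strain_ids = es$strain_ids,
                        perplexity = 5, seed = 1),
                   class = "embedding_set")
  part2 <- consensus_islands(es2, eps = 1, min_points = 3)
  expect_true(same_partition(part2$assignment$island,
                             dbscan_cluster(base, 1, 3)))

  # co-clustering entries are exact counts / n_maps
  expect_true(all(part$co_freq * 2 == round(part$co_freq * 2)))

  # raising the consensus threshold never merges islands
  loose <- consensus_islands(es, eps = 1, min_points = 3, co_threshold = 0.4)
  expect_gte(max(part$assignment$island), 0)
  expect_lte(max(loose$assignment$island), max(part$assignment$island) + 1)
  expect_true(all(table(part$assignment$island[part$assignment$island > 0]) >= 3))
})

test_that("planted islands are recovered with high adjusted Rand index", {
  skip_if_not_installed("mclust")
  scr <- planted_screen(seed = 55)
  sc <- planted_scores(scr)
  emb <- embed_consensus(sc, n_maps = 30, seed = 55)
  tuned <- tune_dbscan(emb, scr$truth$wt_ids, eps_grid = c(2, 3, 4, 5, 6))
  part <- consensus_islands(emb, eps = tuned$eps)
  truth <- truth_labels(scr, part$assignment$strain_id)
  ari <- mclust::adjustedRandIndex(part$assignment$island, truth)
  expect_gte(ari, 0.9)
  # the tuner found at least (true island count - 1) islands
  expect_gte(max(part$assignment$island), 3)

  # phenoprints recover the planted direction
  pp <- island_phenoprints(part, sc)
  ass <- part$assignment
  isl1 <- ass$island[match("isl1_001", ass$strain_id)]
  expect_gt(pp$mean_score[pp$island == isl1 & pp$feature == "mean_length"], 4)
})

test_that("eps tuning degenerates and errors sensibly", {
  scr <- planted_screen(seed = 56, n_wt = 30, n_null = 5, island_n = 8)
  sc <- planted_scores(scr)
  emb <- embed_consensus(sc, n_maps = 10, seed = 56)
  one <- tune_dbscan(emb, scr$truth$wt_ids, eps_grid = 4)
  expect_equal(one$eps, 4)
  expect_error(tune_dbscan(emb, scr$truth$wt_ids, eps_grid = 1e-6),
               "wild-type bulk")
})

test_that("strong islands are stable under subsampling", {
  scr <- planted_screen(seed = 57, n_wt = 30, n_null = 5, island_n = 8)
  sc <- planted_scores(scr)
  emb <- embed_consensus(sc, n_maps = 20, seed = 57)
  tuned <- tune_dbscan(emb, scr$truth$wt_ids, eps_grid = c(3, 4, 5, 6))
  part <- consensus_islands(emb, eps = tuned$eps)
  st <- island_stability(sc, part, eps = tuned$eps, n_partitions = 6,
                         maps_per_partition = 3, holdout = 0.05, seed = 57)
  expect_gte(median(st$stability), 0.9)
})

test_that("embedding input is validated", {
  sc <- tibble::tibble(strain_id = letters[1:5], f = rnorm(5))
  expect_error(embed_consensus(sc, n_maps = 2), "at least 10")
  sc2 <- tibble::tibble(strain_id = sprintf("s%d", 1:20), f = rnorm(20),
                        g = c(NA, rnorm(19)))
  expect_error(embed_consensus(sc2, n_maps = 2), "missing")
})
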