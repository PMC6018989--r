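# Strain-level features, plate correction, scores, flags.

# hand/brute-force oracle for the 19 morphological features of two cells
two_cell_oracle <- function() {
  l <- c(4, 2); w <- c(1, 1)
  body <- l - w
  a <- w * body + pi * w^2 / 4
  p <- 2 * body + pi * w
  v <- pi * w^2 * body / 4 + pi * w^3 / 6
  s <- pi * w * body + pi * w^2
  stat <- function(x) c(mean = mean(x), cv = sd(x) / mean(x))
  list(length = stat(l), width = stat(w), area = stat(a), perimeter = stat(p),
       volume = stat(v), surface = stat(s), sv = stat(s / v),
       ar = stat(w / l), circ = stat(4 * pi * a / p^2))
}

two_cell_table <- function() {
  tibble::tibble(
    strain_id = "x", length_um = c(4, 2), width_um = c(1, 1),
    constriction_degree = c(0.5, 0.4), division_ratio = c(0.45, 0.52),
    nucleoid_count = c(2L, 1L), nucleoid_area_um2 = c(1.2, 0.8),
    nucleoid_constriction_degree = c(0.6, 0.5))
}

test_that("the 19 morphological features match a hand-computed oracle", {
  ft <- strain_features(two_cell_table())
  o <- two_cell_oracle()
  expect_equal(ft$mean_length, 3)
  expect_equal(ft$cv_length, sqrt(2) / 3) # sd of (4,2) = sqrt(2)
  expect_equal(c(ft$mean_width, ft$cv_width), unname(o$width))
  expect_equal(c(ft$mean_area, ft$cv_area), unname(o$area))
  expect_equal(c(ft$mean_perimeter, ft$cv_perimeter), unname(o$perimeter))
  expect_equal(c(ft$mean_volume, ft$cv_volume), unname(o$volume))
  expect_equal(c(ft$mean_surface, ft$cv_surface), unname(o$surface))
  expect_equal(c(ft$mean_sv_ratio, ft$cv_sv_ratio), unname(o$sv))
  expect_equal(c(ft$mean_aspect_ratio, ft$cv_aspect_ratio), unname(o$ar))
  expect_equal(c(ft$mean_circularity, ft$cv_circularity), unname(o$circ))
  # division-ratio CV over the pole-randomized set {r, 1-r}
  aug <- c(0.45, 0.52, 0.55, 0.48)
  expect_equal(ft$cv_division_ratio, sd(aug) / mean(aug))
  # the five cell-cycle features ride along
  expect_equal(ft$mean_nucleoid_area, 1)
  expect_true(ft$low_n)
})

test_that("identical cells give zero CVs and the sphere limit holds", {
  tab <- two_cell_table()[c(1, 1), ]
  ft <- strain_features(tab, min_cells = 1)
  expect_equal(ft$cv_length, 0)
  expect_equal(ft$cv_circularity, 0)

  sphere <- two_cell_table()
  sphere$length_um <- sphere$width_um
  ft <- strain_features(sphere, min_cells = 1)
  expect_equal(ft$mean_volume, pi / 6)
  expect_equal(ft$mean_surface, pi)
  expect_equal(ft$mean_circularity, 1)
})

test_that("plate bias correction inverts an injected multiplicative bias", {
  scr <- generate_screen(screen_truth(n_wt = 12, n_null = 4, seed = 41,
                                      n_cells_mean = 80, n_cells_sd = 5,
                                      plate_bias_sd = 0))
  feats <- screen_features(scr$cells)
  # already unbiased: correction against own medians is near-identity
  pm <- vapply(intersect(names(feature_classes()), names(feats)),
               function(f) median(feats[[f]], na.rm = TRUE), numeric(1))
  same <- correct_plate_bias(feats, scr$truth$plate_map,
                             parental_medians = pm)
  expect_equal(same$mean_length, feats$mean_length, tolerance = 1e-9)

  # inject a plate-wide x1.2 bias on mean length and recover it
  biased <- feats
  biased$mean_length <- biased$mean_length * 1.2
  fixed <- correct_plate_bias(biased, scr$truth$plate_map,
                              parental_medians = pm)
  expect_equal(fixed$mean_length, feats$mean_length, tolerance = 1e-9)
})

test_that("plate correction shrinks random plate biases below the iqr", {
  scr <- generate_screen(screen_truth(n_wt = 30, n_null = 60, seed = 42,
                                      n_cells_mean = 80, n_cells_sd = 5,
                                      plate_size = 30, plate_bias_sd = 0.05))
  feats <- screen_features(scr$cells)
  fixed <- correct_plate_bias(feats, scr$truth$plate_map,
                              wt_ids = scr$truth$wt_ids)
  pm <- dplyr::left_join(fixed, scr$truth$plate_map, by = "strain_id")
  plate_meds <- tapply(pm$mean_length, pm$plate, median)
  spread <- diff(range(plate_meds))
  expect_lt(spread, 0.05 * IQR(fixed$mean_length))
})

test_that("scores implement the robust 1.35 iqr transform exactly", {
  set.seed(43)
  n_wt <- 200
  feats <- tibble::tibble(
    strain_id = c(sprintf("WT_%03d", 1:n_wt), "mut"),
    mean_length = c(rnorm(n_wt, 10, 2), 0))
  wt_ids <- sprintf("WT_%03d", 1:n_wt)
  m <- median(feats$mean_length[1:n_wt])
  iq <- IQR(feats$mean_length[1:n_wt])
  feats$mean_length[n_wt + 1] <- m # F = median -> 0
  sc <- compute_scores(feats, wt_ids)
  expect_equal(sc$mean_length[n_wt + 1], 0)
  feats$mean_length[n_wt + 1] <- m + iq # F = median + iqr -> 1.35
  sc <- compute_scores(feats, wt_ids)
  expect_equal(sc$mean_length[n_wt + 1], 1.35)
})

test_that("for normal features the score reads in SD units", {
  set.seed(44)
  n <- 1e5
  feats <- tibble::tibble(
    strain_id = c(sprintf("WT_%05d", 1:n), "mut"),
    mean_length = c(rnorm(n, 10, 2), 12))
  sc <- compute_scores(feats, feats$strain_id[1:n])
  expect_equal(sc$mean_length[n + 1], 1, tolerance = 0.02)
})

test_that("scores are invariant to affine rescaling of raw features", {
  scr <- generate_screen(screen_truth(n_wt = 12, n_null = 6, seed = 45,
                                      n_cells_mean = 60, n_cells_sd = 5))
  feats <- screen_features(scr$cells)
  sc1 <- compute_scores(feats, scr$truth$wt_ids)
  rescaled <- feats
  rescaled$mean_length <- rescaled$mean_length * 1000 # nm instead of um
  sc2 <- compute_scores(rescaled, scr$truth$wt_ids)
  expect_equal(sc1$mean_length, sc2$mean_length, tolerance = 1e-9)
  # correlations between feature columns survive the transform
  ok <- complete.cases(sc1$mean_length, sc1$mean_width)
  expect_equal(cor(sc1$mean_length[ok], sc1$mean_width[ok]),
               cor(feats$mean_length[ok], feats$mean_width[ok]),
               tolerance = 1e-9)
  expect_error(compute_scores(feats, scr$truth$wt_ids[1:3]), "10 wild-type")
})

test_that("zero-iqr features are dropped with a warning", {
  feats <- tibble::tibble(
    strain_id = sprintf("WT_%02d", 1:12),
    mean_length = rnorm(12, 3), mean_width = rep(1, 12))
  expect_warning(sc <- compute_scores(feats, feats$strain_id), "zero")
  expect_false("mean_width" %in% names(sc))
})

test_that("phenotype flags are monotone in the threshold and exact on plants", {
  scr <- planted_screen(seed = 46)
  sc <- compute_scores(screen_features(scr$cells), scr$truth$wt_ids)
  counts <- vapply(c(2, 3, 4, 6, Inf), function(th) {
    sum(flag_phenotypes(sc, threshold = th)$per_class$n_flagged)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[length(counts)], 0) # threshold Inf flags nothing

  # the +6 SD morphological plants are all flagged at threshold 3
  fl <- flag_phenotypes(sc, threshold = 3)
  morph <- fl$strains$morphological
  expect_true(all(sprintf("isl1_%03d", 1:10) %in% morph))
  expect_true(all(sprintf("isl2_%03d", 1:10) %in% morph))
})
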