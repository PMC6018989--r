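# Synthetic-data generator: age law, population construction, screens.

test_that("age sampling follows the steady-state exponential age law", {
  expect_error(sample_ages(0), "count")
  # inverse-CDF endpoints
  expect_equal(-log2(1 - 0 / 2), 0)
  expect_equal(-log2(1 - 1 / 2), 1)

  a <- sample_ages(1e5, seed = 1)
  expect_true(all(a >= 0 & a <= 1))
  # closed-form CDF at 0.5: 2 * (1 - 2^-0.5)
  p_half <- 2 * (1 - 2^(-0.5))
  se <- sqrt(p_half * (1 - p_half) / 1e5)
  expect_lt(abs(mean(a <= 0.5) - p_half), 4 * se)
  # analytic mean age 1/ln2 - 1
  expect_lt(abs(mean(a) - (1 / log(2) - 1)), 4 * sqrt(0.08 / 1e5))
  # reproducibility
  expect_identical(a, sample_ages(1e5, seed = 1))
})

test_that("inverse-CDF sampling matches a rejection-sampling oracle", {
  a <- sample_ages(1e5, seed = 2)
  # oracle: rejection sampling from the density 2 ln2 2^-a on [0, 1]
  set.seed(2)
  cand <- runif(4e5)
  acc <- runif(4e5) < 2^(-cand) # proportional acceptance
  b <- cand[acc][1:1e5]
  ks <- suppressWarnings(stats::ks.test(a, b))
  expect_lt(unname(ks$statistic), 0.01)
})

test_that("nucleoid separation fractions follow the age integral", {
  sp0 <- strain_spec("s", t_nuc = 0)
  sp1 <- strain_spec("s", t_nuc = 1)
  expect_true(all(generate_cell_population(sp0, 500, seed = 1)$nucleoid_count == 2))
  expect_true(all(generate_cell_population(sp1, 500, seed = 1)$nucleoid_count == 1))

  sp <- strain_spec("s", t_nuc = 0.5)
  cells <- generate_cell_population(sp, 1e5, seed = 3)
  frac <- mean(cells$nucleoid_count == 2)
  expected <- 2^(1 - 0.5) - 1
  se <- sqrt(expected * (1 - expected) / 1e5)
  expect_lt(abs(frac - expected), 3 * se)
})

test_that("fraction of cells past any age threshold obeys 2^(1-a) - 1", {
  cells <- generate_cell_population(strain_spec("s"), 1e5, seed = 4)
  for (a in seq(0.1, 0.9, by = 0.2)) {
    p <- 2^(1 - a) - 1
    se <- sqrt(p * (1 - p) / 1e5)
    expect_lt(abs(mean(cells$age > a) - p), 3 * se)
  }
})

test_that("noise-free lengths sit exactly on the elongation curve", {
  sp <- strain_spec("s", length_cv = 0, t_const = 1)
  cells <- generate_cell_population(sp, 2e4, seed = 5)
  expect_equal(cells$length_um, sp$birth_length * 2^cells$age)
  # population CV from age spread alone, against a quadrature oracle
  mom <- function(k) {
    stats::integrate(function(a) 2 * log(2) * 2^(-a) * (2^a)^k, 0, 1,
                     rel.tol = 1e-12)$value
  }
  cv_oracle <- sqrt(mom(2) - mom(1)^2) / mom(1)
  expect_lt(abs(sd(cells$length_um) / mean(cells$length_um) - cv_oracle),
            0.005)
})

test_that("population generation is deterministic under a fixed seed", {
  a <- generate_cell_population(strain_spec("s"), 500, seed = 9)
  b <- generate_cell_population(strain_spec("s"), 500, seed = 9)
  expect_identical(a, b)
})

test_that("strain_spec validates its parameters", {
  expect_error(strain_spec("x", birth_length = -1), "birth_length")
  expect_error(strain_spec("x", t_nuc = 1.5), "t_nuc")
  expect_error(strain_spec("x", score_offsets = c(3)), "named")
})

test_that("corrupt_cells labels the requested fraction", {
  cells <- wt_population(1000)
  expect_true(all(corrupt_cells(cells, 0, seed = 1)$contour_ok))
  expect_true(all(!corrupt_cells(cells, 1, seed = 1)$contour_ok))
  bad <- sum(!corrupt_cells(cells, 0.3, seed = 2)$contour_ok)
  # binomial 99% interval around 300 (deterministic count here, but the
  # rounding contract is the point)
  expect_equal(bad, 300)
  expect_error(corrupt_cells(cells, 1.2), "fraction")
})

test_that("length-mixture CVs match a dense quadrature oracle", {
  oracle_cv <- function(stage_cv, base_cv = 0.11, amin = 0.8) {
    mom <- function(k) {
      stats::integrate(function(a) {
        cvs <- ifelse(a > amin, stage_cv, base_cv)
        2 * log(2) * 2^(-a) * (2^a)^k * (1 + cvs^2)^(k * (k - 1) / 2)
      }, 0, 1, rel.tol = 1e-12)$value
    }
    m1 <- mom(1); m2 <- mom(2)
    sqrt(m2 - m1^2) / m1
  }
  cvs <- vapply(c(0.05, 0.11, 0.2), function(scv) {
    m <- simulate_length_mixture(scv)
    expect_lt(abs(m$population_cv - oracle_cv(scv)), 5e-4)
    m$population_cv
  }, numeric(1))
  # masking: population CVs move far less than the stage CVs
  expect_lt(cvs[3] / cvs[1], 0.2 / 0.05)

  m <- simulate_length_mixture(0.11)
  # constricted-stage CV ~ stage CV (small inflation from the residual
  # age spread above 0.8)
  expect_lt(abs(m$constricted_cv - 0.11), 0.01)
  # normalization: mixture densities integrate to 1
  tz <- function(df) sum(diff(df$length) *
                           (head(df$density, -1) + tail(df$density, -1)) / 2)
  expect_equal(tz(m$population), 1, tolerance = 1e-6)
  expect_equal(tz(m$constricted), 1, tolerance = 1e-6)
  expect_error(simulate_length_mixture(-0.1), "stage_cv")
})

test_that("a screen with zero offsets gives WT-like scores everywhere", {
  scr <- generate_screen(screen_truth(n_wt = 20, n_null = 5, seed = 21))
  feats <- screen_features(scr$cells)
  sc <- compute_scores(feats, scr$truth$wt_ids)
  x <- tibble::as_tibble(sc)
  wt <- x$strain_id %in% scr$truth$wt_ids
  for (f in setdiff(names(x), c("strain_id", "n_cells"))) {
    v <- x[[f]][wt]
    if (all(is.na(v))) next
    expect_equal(median(v, na.rm = TRUE), 0, tolerance = 1e-9)
    expect_equal(IQR(v, na.rm = TRUE), 1.35, tolerance = 1e-9)
  }
})

test_that("screens are byte-identical under a fixed seed and round-trip", {
  tr <- screen_truth(n_wt = 10, n_null = 2, seed = 33, n_cells_mean = 60,
                     n_cells_sd = 10)
  s1 <- generate_screen(tr)
  s2 <- generate_screen(tr)
  expect_identical(s1$cells, s2$cells)
  expect_identical(s1$growth, s2$growth)

  dir <- withr::local_tempdir()
  write_screen(s1, dir)
  cells <- read_cells(file.path(dir, "cells.csv"))
  expect_equal(nrow(cells), nrow(s1$cells))
  expect_equal(cells$length_um, s1$cells$length_um)
  growth <- read_growth(file.path(dir, "growth.csv"))
  expect_equal(growth$od600, s1$growth$od600)
})

test_that("generate_screen rejects degenerate truths", {
  expect_error(screen_truth(n_wt = 1), "replicates")
  expect_error(generate_screen(list()), "screen_truth")
})
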