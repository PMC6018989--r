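#' Sample relative cell ages from a steady-state exponential population
#'
#' In a steadily, exponentially growing population, younger cells
#' outnumber older ones: the age density is `2 * ln(2) * 2^(-a)` on
#' \[0, 1\] (twice as many newborns as dividing cells). Sampling uses the
#' closed-form inverse CDF `a = -log2(1 - u/2)`.
#'
#' @param n Number of cells to draw (`n >= 1`).
#' @param seed Optional integer seed; when supplied the draw is
#'   reproducible and the caller's RNG state is untouched.
#' @return Numeric vector of relative ages in \[0, 1\].
#' @examples
#' mean(sample_ages(1e4, seed = 1)) # ~ 1/ln(2) - 1 = 0.4427
#' @export
sample_ages <- function(n, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    abort("`n` must be a count >= 1.")
  }
  draw <- function() -log2(1 - stats::runif(n) / 2)
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Theoretical fraction of cells older than age a under the steady-state
# age distribution; inverse of relative_event_timing().
fraction_older_than <- function(a) 2^(1 - a) - 1

#' Simulate the imaged cell population of one strain
#'
#' Draws `n` cells at steady-state ages, grows each exponentially from its
#' birth length (`length = birth_length * 2^age`, times lognormal noise
#' with CV `length_cv`), and derives every per-cell measurement the screen
#' records: spherocylinder geometry, nucleoid count and area, constriction
#' degrees, division ratio, and the intensity-type features used by
#' contour curation.
#'
#' Nucleoid separation is age-thresholded at `t_nuc` (2 nucleoids for
#' `age >= t_nuc`); the cell constriction degree is 0 before `t_const` and
#' ramps linearly to 1 at division. The division ratio exists only for
#' constricted cells. The nucleoid constriction degree of constricted
#' cells starts at `cdn_c0` at constriction onset and rises with the cell
#' degree, which couples the two degrees positively as observed in
#' wild-type populations.
#'
#' @param spec A [strain_spec()].
#' @param n Number of cells (`n >= 1`).
#' @param seed Optional integer seed.
#' @return A cell-table tibble, one row per cell, with a ground-truth
#'   `age` column in addition to the measured columns.
#' @export
generate_cell_population <- function(spec, n, seed = NULL) {
  validate_strain_spec(spec)
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    abort("`n` must be a count >= 1.")
  }
  gen <- function() {
    age <- sample_ages(n)
    length_um <- spec$birth_length * 2^age *
      rlnorm_meancv(n, 1, spec$length_cv)
    width_um <- rlnorm_meancv(n, spec$mean_width, spec$width_cv)
    width_um <- pmin(width_um, 0.95 * length_um)

    geom <- spherocylinder_geometry(length_um, width_um)

    nucleoid_count <- ifelse(age >= spec$t_nuc, 2L, 1L)
    constriction_degree <- ifelse(
      age < spec$t_const, 0,
      (age - spec$t_const) / max(1 - spec$t_const, 1e-9)
    )
    constricted <- constriction_degree > 0

    division_ratio <- rep(NA_real_, n)
    k <- sum(constricted)
    if (k > 0) {
      dr <- stats::rnorm(k, 0.5, spec$sigma_dr)
      while (any(dr <= 0 | dr >= 1)) {
        bad <- dr <= 0 | dr >= 1
        dr[bad] <- stats::rnorm(sum(bad), 0.5, spec$sigma_dr)
      }
      division_ratio[constricted] <- dr
    }

    nucleoid_constriction_degree <- rep(0, n)
    if (k > 0) {
      cdn <- spec$cdn_c0 + (1 - spec$cdn_c0) * constriction_degree[constricted] +
        stats::rnorm(k, 0, 0.08)
      nucleoid_constriction_degree[constricted] <- pmin(pmax(cdn, 0), 1)
    }

    nucleoid_area_um2 <- spec$nucleoid_area_ratio * geom$area_um2 *
      rlnorm_meancv(n, 1, 0.08)
    dapi_total <- 50 * geom$area_um2 * rlnorm_meancv(n, 1, 0.10)
    nucleoid_intensity <- dapi_total / nucleoid_area_um2 *
      rlnorm_meancv(n, 1, 0.05)
    nucleoid_variability <- ifelse(
      nucleoid_count == 2L,
      rlnorm_meancv(n, 0.10, 0.5),
      rlnorm_meancv(n, 0.02, 0.5)
    )
    phase_mean <- stats::rnorm(n, 0.45, 0.02)
    contour_phase_mean <- stats::rnorm(n, 0.55, 0.02)
    intracell_width_cv <- rlnorm_meancv(n, 0.04, 0.30)

    tibble(
      strain_id = spec$strain_id,
      cell_id = seq_len(n),
      age = age,
      length_um = length_um,
      width_um = width_um,
      area_um2 = geom$area_um2,
      perimeter_um = geom$perimeter_um,
      constriction_degree = constriction_degree,
      division_ratio = division_ratio,
      nucleoid_count = nucleoid_count,
      nucleoid_area_um2 = nucleoid_area_um2,
      nucleoid_constriction_degree = nucleoid_constriction_degree,
      nucleoid_variability = nucleoid_variability,
      nucleoid_intensity = nucleoid_intensity,
      dapi_total = dapi_total,
      phase_mean = phase_mean,
      intracell_width_cv = intracell_width_cv,
      contour_phase_mean = contour_phase_mean
    )
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Corrupt a fraction of cells into mis-detection-like outliers
#'
#' Produces labelled training data for contour curation by perturbing a
#' random subset of cells into implausible regimes that mimic real
#' segmentation failures: width exceeding length, huge intensity
#' outliers, collapsed fragments, ragged contours with inflated
#' perimeter, and near-empty phase signal.
#'
#' @param table A cell table.
#' @param fraction Fraction of rows to corrupt, in \[0, 1\].
#' @param seed Optional integer seed.
#' @return The table with features of the chosen rows perturbed and a
#'   logical `contour_ok` column (`FALSE` = corrupted).
#' @export
corrupt_cells <- function(table, fraction, seed = NULL) {
  check_number(fraction, "fraction", lower = 0, upper = 1)
  run <- function() {
    n <- nrow(table)
    out <- table
    out$contour_ok <- TRUE
    n_bad <- round(fraction * n)
    if (n_bad == 0) return(out)
    idx <- sample.int(n, n_bad)
    mode <- sample.int(5L, n_bad, replace = TRUE)
    for (j in seq_along(idx)) {
      i <- idx[j]
      switch(mode[j],
        { # width > length: swapped axes plus bloating
          l <- out$length_um[i]
          out$length_um[i] <- out$width_um[i]
          out$width_um[i] <- 1.5 * l
        },
        { # fluorescence blow-up (stuck pixel / debris)
          out$dapi_total[i] <- out$dapi_total[i] * 20
          out$nucleoid_intensity[i] <- out$nucleoid_intensity[i] * 20
        },
        { # collapsed fragment
          out$length_um[i] <- 0.3 * out$width_um[i]
          out$area_um2[i] <- out$area_um2[i] * 0.1
          out$nucleoid_area_um2[i] <- out$nucleoid_area_um2[i] * 0.05
        },
        { # ragged contour: perimeter inflated, width wobbling
          out$perimeter_um[i] <- out$perimeter_um[i] * 2.5
          out$intracell_width_cv[i] <- out$intracell_width_cv[i] * 10
        },
        { # near-empty contour (background picked up)
          out$phase_mean[i] <- out$phase_mean[i] * 0.05
          out$contour_phase_mean[i] <- out$contour_phase_mean[i] * 0.1
          out$dapi_total[i] <- out$dapi_total[i] * 0.02
        }
      )
      out$contour_ok[i] <- FALSE
    }
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
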