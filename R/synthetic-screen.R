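#' Ground truth for a synthetic deletion screen
#'
#' Assembles the full generative description of a screen: a shared
#' wild-type baseline replicated `n_wt` times, optional planted phenotype
#' islands (groups of mutants sharing large score offsets on a few
#' features), extra null mutants, and a plate layout. [generate_screen()]
#' turns this object into per-cell tables and growth curves.
#'
#' @param n_wt Number of independent wild-type replicates (>= 2). The
#'   reference screen carried 240; smaller synthetic screens keep the same
#'   replicate-based score calibration.
#' @param islands A list; each element is `list(n =, offsets = c(...))`
#'   where `offsets` is a named vector of planted shifts in wild-type SD
#'   units (see [generate_screen()] for lever names). An optional `jitter`
#'   element (default 0.5) is the SD-unit spread of offsets across the
#'   island's members.
#' @param n_null Number of mutants with no planted phenotype.
#' @param baseline The wild-type [strain_spec()].
#' @param n_cells_mean,n_cells_sd Per-strain imaged cell counts are drawn
#'   Normal(mean, sd) truncated at `min_cells`; defaults 291 and 116 match
#'   the per-strain counts of the reference screen.
#' @param min_cells Lower truncation for cell counts.
#' @param plate_size Wells per plate.
#' @param plate_bias_sd Lognormal SD of the per-plate multiplicative bias
#'   applied to linear cell dimensions (plate-to-plate variability).
#' @param growth_cv Replicate-level lognormal CV on the realised growth
#'   parameters (max growth rate and saturation density).
#' @param od_noise_sd Gaussian OD600 noise added to growth curves.
#' @param seed Master seed; the whole screen is a deterministic function
#'   of this object.
#' @return An object of class `screen_truth`.
#' @export
screen_truth <- function(n_wt = 40,
                         islands = list(),
                         n_null = 20,
                         baseline = strain_spec("WT"),
                         n_cells_mean = 291,
                         n_cells_sd = 116,
                         min_cells = 30,
                         plate_size = 96,
                         plate_bias_sd = 0.02,
                         growth_cv = 0.02,
                         od_noise_sd = 0.003,
                         seed = 1L) {
  if (n_wt < 2) abort("at least 2 wild-type replicates are required.")
  validate_strain_spec(baseline)

  specs <- list()
  for (i in seq_len(n_wt)) {
    s <- baseline
    s$strain_id <- sprintf("WT_%03d", i)
    specs[[s$strain_id]] <- s
  }
  for (i in seq_len(n_null)) {
    s <- baseline
    s$strain_id <- sprintf("null_%03d", i)
    specs[[s$strain_id]] <- s
  }
  for (k in seq_along(islands)) {
    isl <- islands[[k]]
    if (is.null(isl$n) || is.null(isl$offsets)) {
      abort("each island needs `n` and a named `offsets` vector.")
    }
    jitter <- isl$jitter %||% 0.5
    for (i in seq_len(isl$n)) {
      s <- baseline
      s$strain_id <- sprintf("isl%d_%03d", k, i)
      s$score_offsets <- isl$offsets
      attr(s$score_offsets, "jitter") <- jitter
      s$island_label <- as.integer(k)
      specs[[s$strain_id]] <- s
    }
  }

  ids <- names(specs)
  plate_map <- tibble(
    strain_id = ids,
    plate = (seq_along(ids) - 1L) %/% plate_size + 1L,
    well = (seq_along(ids) - 1L) %% plate_size + 1L
  )

  structure(
    list(
      specs = specs,
      wt_ids = ids[startsWith(ids, "WT_")],
      plate_map = plate_map,
      n_cells_mean = n_cells_mean, n_cells_sd = n_cells_sd,
      min_cells = min_cells,
      plate_bias_sd = plate_bias_sd,
      growth_cv = growth_cv, od_noise_sd = od_noise_sd,
      seed = as.integer(seed)
    ),
    class = "screen_truth"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Strain-level summaries used to calibrate planted offsets in units of the
# wild-type replicate spread.
lever_summary <- function(cells, alpha_max, od_max) {
  constr <- cells$constriction_degree > 0
  dr <- cells$division_ratio[constr & !is.na(cells$division_ratio)]
  dr_aug <- c(dr, 1 - dr)
  onset <- onset_band_cells(cells)
  c(
    mean_length = mean(cells$length_um),
    cv_length = cv(cells$length_um),
    mean_width = mean(cells$width_um),
    cv_width = cv(cells$width_um),
    rel_t_nuc = relative_event_timing(mean(cells$nucleoid_count >= 2)),
    rel_t_const = relative_event_timing(mean(cells$constriction_degree > 0.15)),
    mean_nucleoid_area = mean(cells$nucleoid_area_um2),
    cv_division_ratio = if (length(dr)) stats::sd(dr_aug) / 0.5 else NA_real_,
    cdn_c0 = if (length(onset)) mean(cells$nucleoid_constriction_degree[onset]) else NA_real_,
    alpha_max = alpha_max,
    od_max = od_max
  )
}

# age-spread-induced squared CV of length under exponential elongation:
# Var(2^a)/E(2^a)^2 with a ~ steady-state age density.
age_cv2 <- function() 2 / (2 * log(2))^2 - 1

apply_offsets <- function(spec, offsets, wt_mean, wt_sd) {
  unknown <- setdiff(names(offsets), names(wt_mean))
  if (length(unknown)) {
    abort(paste0("unknown score-offset lever(s): ",
                 paste(unknown, collapse = ", ")))
  }
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  for (f in names(offsets)) {
    s <- offsets[[f]]
    sdf <- wt_sd[[f]]
    mf <- wt_mean[[f]]
    switch(f,
      mean_length = {
        spec$birth_length <- spec$birth_length * max(0.1, 1 + s * sdf / mf)
      },
      cv_length = {
        target <- max(mf + s * sdf, 0.01)
        spec$length_cv <- sqrt(max((1 + target^2) / (1 + age_cv2()) - 1, 0))
      },
      mean_width = {
        spec$mean_width <- spec$mean_width * max(0.1, 1 + s * sdf / mf)
      },
      cv_width = {
        spec$width_cv <- max(0.001, mf + s * sdf)
      },
      rel_t_nuc = {
        spec$t_nuc <- clamp(spec$t_nuc + s * sdf, 0.02, 0.98)
      },
      rel_t_const = {
        spec$t_const <- clamp(spec$t_const + s * sdf, 0.05, 0.98)
      },
      mean_nucleoid_area = {
        spec$nucleoid_area_ratio <-
          clamp(spec$nucleoid_area_ratio * max(0.1, 1 + s * sdf / mf),
                0.02, 0.95)
      },
      cv_division_ratio = {
        target <- max(mf + s * sdf, 0.005)
        spec$sigma_dr <- spec$sigma_dr * target / mf
      },
      cdn_c0 = {
        spec$cdn_c0 <- clamp(spec$cdn_c0 + s * sdf, 0.02, 0.98)
      },
      alpha_max = {
        spec$growth_mu <- spec$growth_mu * max(0.05, 1 + s * sdf / mf)
      },
      od_max = {
        spec$growth_A <- spec$growth_A + log(max(0.05, 1 + s * sdf / mf))
      }
    )
  }
  spec
}

# Zwietering Gompertz curve on log-relative OD, evaluated at `times` (min).
gompertz_od <- function(times, A, mu, lambda, od0) {
  y <- A * exp(-exp(mu * exp(1) / A * (lambda - times) + 1))
  od0 * exp(y)
}

# time at which the noiseless curve reaches od_max / ratio
gompertz_time_at_fraction <- function(A, mu, lambda, ratio = 4.5,
                                      t_max = Inf) {
  frac <- 1 - log(ratio) / A
  if (frac <= 0) return(lambda)
  z <- log(-log(frac))
  t <- lambda - (z - 1) * A / (mu * exp(1))
  min(max(t, 0), t_max)
}

#' Generate a full synthetic screen with known ground truth
#'
#' Simulates every strain of a [screen_truth()]: per-cell measurement
#' tables (with plate, well and imaging metadata), growth curves, and the
#' realised ground-truth parameters. Wild-type replicates share one
#' baseline specification, so their strain-level feature spread reflects
#' sampling noise plus replicate-level growth jitter only; planted mutant
#' offsets are calibrated against that empirical wild-type spread, so an
#' offset of +6 moves the corresponding feature by about six wild-type
#' standard deviations.
#'
#' Available offset levers: `mean_length`, `cv_length`, `mean_width`,
#' `cv_width`, `rel_t_nuc`, `rel_t_const`, `mean_nucleoid_area`,
#' `cv_division_ratio`, `cdn_c0`, `alpha_max`, `od_max`.
#'
#' @param truth A [screen_truth()].
#' @param times Growth-curve sampling times in minutes.
#' @return A list of class `synthetic_screen`: `cells` (tibble of all
#'   cells with plate/well/imaging metadata), `growth` (tibble
#'   strain_id/time_min/od600), and `truth` (the input plus realised
#'   per-strain parameters in `$strain_info` and the calibration SDs in
#'   `$wt_sd`).
#' @export
generate_screen <- function(truth, times = seq(0, 960, by = 5)) {
  if (!inherits(truth, "screen_truth")) abort("`truth` must be a screen_truth.")
  if (length(truth$specs) == 0) abort("empty screen_truth.")
  if (length(truth$wt_ids) < 2) abort("at least 2 wild-type replicates required.")

  with_seed(truth$seed, {
    ids <- names(truth$specs)
    n_cells <- pmax(truth$min_cells,
                    round(stats::rnorm(length(ids), truth$n_cells_mean,
                                       truth$n_cells_sd)))
    names(n_cells) <- ids

    # realised growth parameters (replicate-level jitter for all strains)
    realized <- lapply(truth$specs, function(sp) {
      mu <- sp$growth_mu * rlnorm_meancv(1, 1, truth$growth_cv)
      odmax <- sp$od0 * exp(sp$growth_A) * rlnorm_meancv(1, 1, truth$growth_cv)
      lambda <- sp$growth_lambda * rlnorm_meancv(1, 1, 0.05)
      list(mu = mu, A = log(odmax / sp$od0), lambda = lambda, od0 = sp$od0,
           alpha_max = mu * 60, od_max = odmax)
    })

    # 1) wild-type populations first: they calibrate the offset levers
    wt_cells <- lapply(truth$wt_ids, function(id) {
      generate_cell_population(truth$specs[[id]], n_cells[[id]])
    })
    names(wt_cells) <- truth$wt_ids
    wt_stats <- vapply(truth$wt_ids, function(id) {
      lever_summary(wt_cells[[id]],
                    realized[[id]]$alpha_max, realized[[id]]$od_max)
    }, numeric(11))
    wt_mean <- apply(wt_stats, 1, mean, na.rm = TRUE)
    wt_sd <- apply(wt_stats, 1, stats::sd, na.rm = TRUE)

    # 2) mutants, with offsets mapped onto generative parameters
    strain_info <- list()
    all_cells <- vector("list", length(ids))
    names(all_cells) <- ids
    for (id in ids) {
      sp <- truth$specs[[id]]
      offs <- sp$score_offsets
      if (length(offs) > 0) {
        jit <- attr(offs, "jitter") %||% 0
        offs <- offs + stats::rnorm(length(offs), 0, jit)
        sp <- apply_offsets(sp, offs, wt_mean, wt_sd)
        # growth levers modify the strain specification; refresh the
        # realised growth parameters accordingly
        mu <- sp$growth_mu * rlnorm_meancv(1, 1, truth$growth_cv)
        odmax <- sp$od0 * exp(sp$growth_A) *
          rlnorm_meancv(1, 1, truth$growth_cv)
        realized[[id]]$mu <- mu
        realized[[id]]$A <- log(odmax / sp$od0)
        realized[[id]]$alpha_max <- mu * 60
        realized[[id]]$od_max <- odmax
      }
      all_cells[[id]] <- if (id %in% truth$wt_ids) {
        wt_cells[[id]]
      } else {
        generate_cell_population(sp, n_cells[[id]])
      }
      strain_info[[id]] <- tibble(
        strain_id = id,
        island_label = truth$specs[[id]]$island_label,
        is_wt = id %in% truth$wt_ids,
        n_cells = n_cells[[id]],
        true_alpha_max = realized[[id]]$alpha_max,
        true_od_max = realized[[id]]$od_max,
        true_t_nuc = sp$t_nuc,
        true_t_const = sp$t_const
      )
    }

    # 3) plate biases on linear dimensions
    plates <- sort(unique(truth$plate_map$plate))
    bias <- rlnorm_meancv(length(plates), 1, truth$plate_bias_sd)
    names(bias) <- as.character(plates)

    # 4) growth curves + imaging metadata
    growth <- vector("list", length(ids))
    meta <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      id <- ids[i]
      rp <- realized[[id]]
      od <- gompertz_od(times, rp$A, rp$mu, rp$lambda, rp$od0) +
        stats::rnorm(length(times), 0, truth$od_noise_sd)
      growth[[i]] <- tibble(strain_id = id, time_min = times,
                            od600 = pmax(od, 1e-4))
      t_img <- gompertz_time_at_fraction(rp$A, rp$mu, rp$lambda,
                                         t_max = max(times))
      meta[[i]] <- tibble(strain_id = id,
                          image_time_min = t_img,
                          od_imaging = rp$od_max / 4.5)
    }

    cells <- list_rbind(unname(all_cells)) |>
      left_join(truth$plate_map, by = "strain_id") |>
      left_join(list_rbind(meta), by = "strain_id")
    b <- unname(bias[as.character(cells$plate)])
    cells$length_um <- cells$length_um * b
    cells$width_um <- cells$width_um * b
    geom <- spherocylinder_geometry(cells$length_um, cells$width_um)
    cells$area_um2 <- geom$area_um2
    cells$perimeter_um <- geom$perimeter_um
    cells$nucleoid_area_um2 <- cells$nucleoid_area_um2 * b^2
    cells$dapi_total <- cells$dapi_total * b^2

    truth$strain_info <- list_rbind(strain_info)
    truth$wt_sd <- wt_sd
    truth$wt_mean <- wt_mean
    truth$plate_bias <- bias

    structure(
      list(cells = cells, growth = list_rbind(growth), truth = truth),
      class = "synthetic_screen"
    )
  })
}

#' @export
print.synthetic_screen <- function(x, ...) {
  cat(sprintf(
    "<synthetic_screen> %d strains (%d WT replicates), %d cells, seed %d\n",
    nrow(x$truth$plate_map), length(x$truth$wt_ids), nrow(x$cells),
    x$truth$seed))
  invisible(x)
}
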