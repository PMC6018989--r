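#' Define the generative parameters of one strain
#'
#' A strain specification holds everything needed to simulate one strain's
#' imaged cell population and growth curve: newborn cell size, size noise,
#' relative cell-cycle timings, nucleoid size, and Gompertz growth
#' parameters. The defaults describe a plausible wild-type-like rod growing
#' in minimal medium at 30 C (doubling time ~72 min); they are synthetic
#' reference values, not measurements.
#'
#' @param strain_id Strain identifier.
#' @param birth_length Mean newborn cell length, µm.
#' @param length_cv Arithmetic CV of length at fixed cell age (lognormal
#'   noise multiplying the exponential elongation curve). The wild-type
#'   value 0.11 was determined experimentally for *E. coli*.
#' @param mean_width,width_cv Mean cell width (µm) and its arithmetic CV.
#' @param t_nuc Relative cell age (0 birth, 1 division) at which the two
#'   sister nucleoids become resolvable.
#' @param t_const Relative age at onset of cell constriction.
#' @param nucleoid_area_ratio Fraction of the projected cell area occupied
#'   by the nucleoid(s) (summed over nucleoids).
#' @param sigma_dr Standard deviation of the division-ratio ground truth,
#'   Normal(0.5, sigma_dr) truncated to (0, 1).
#' @param cdn_c0 Mean degree of nucleoid separation at the onset of cell
#'   constriction, in \[0, 1\].
#' @param growth_A Gompertz amplitude `A = ln(OD_max / OD_0)`
#'   (dimensionless log-relative density).
#' @param growth_mu Maximal specific growth rate, 1/min.
#' @param growth_lambda Lag time, min.
#' @param od0 Inoculation density, OD600.
#' @param score_offsets Named numeric vector of planted phenotype shifts in
#'   wild-type standard-deviation units; names must be levers understood by
#'   [generate_screen()] (see its help).
#' @param island_label Integer ground-truth island id, or `NA` for
#'   wild-type-like strains.
#'
#' @return An object of class `strain_spec` (a named list).
#' @examples
#' strain_spec("WT_001")
#' strain_spec("longboi", score_offsets = c(mean_length = 6), island_label = 1L)
#' @export
strain_spec <- function(strain_id,
                        birth_length = 2.0,
                        length_cv = 0.11,
                        mean_width = 0.9,
                        width_cv = 0.04,
                        t_nuc = 0.55,
                        t_const = 0.75,
                        nucleoid_area_ratio = 0.35,
                        sigma_dr = 0.03,
                        cdn_c0 = 0.5,
                        growth_A = 4.4,
                        growth_mu = 0.0096,
                        growth_lambda = 120,
                        od0 = 0.01,
                        score_offsets = numeric(0),
                        island_label = NA_integer_) {
  spec <- list(
    strain_id = as.character(strain_id),
    birth_length = birth_length, length_cv = length_cv,
    mean_width = mean_width, width_cv = width_cv,
    t_nuc = t_nuc, t_const = t_const,
    nucleoid_area_ratio = nucleoid_area_ratio,
    sigma_dr = sigma_dr, cdn_c0 = cdn_c0,
    growth_A = growth_A, growth_mu = growth_mu,
    growth_lambda = growth_lambda, od0 = od0,
    score_offsets = score_offsets,
    island_label = as.integer(island_label)
  )
  class(spec) <- "strain_spec"
  validate_strain_spec(spec)
}

validate_strain_spec <- function(spec) {
  if (!inherits(spec, "strain_spec")) abort("not a strain_spec.")
  check_number(spec$birth_length, "birth_length", lower = 1e-6)
  check_number(spec$length_cv, "length_cv", lower = 0)
  check_number(spec$mean_width, "mean_width", lower = 1e-6)
  check_number(spec$width_cv, "width_cv", lower = 0)
  check_number(spec$t_nuc, "t_nuc", lower = 0, upper = 1)
  check_number(spec$t_const, "t_const", lower = 0, upper = 1)
  check_number(spec$nucleoid_area_ratio, "nucleoid_area_ratio",
               lower = 1e-6, upper = 1 - 1e-6)
  check_number(spec$sigma_dr, "sigma_dr", lower = 1e-6)
  check_number(spec$cdn_c0, "cdn_c0", lower = 0, upper = 1)
  check_number(spec$growth_A, "growth_A", lower = 1e-6)
  check_number(spec$growth_mu, "growth_mu", lower = 1e-9)
  check_number(spec$growth_lambda, "growth_lambda", lower = 0)
  check_number(spec$od0, "od0", lower = 1e-9)
  if (length(spec$score_offsets) > 0 &&
      (is.null(names(spec$score_offsets)) ||
       any(!is.finite(spec$score_offsets)))) {
    abort("score_offsets must be a named, finite numeric vector.")
  }
  invisible(spec)
}

#' @export
print.strain_spec <- function(x, ...) {
  cat("<strain_spec> ", x$strain_id, "\n", sep = "")
  cat(sprintf("  birth length %.2f um (cv %.3f), width %.2f um (cv %.3f)\n",
              x$birth_length, x$length_cv, x$mean_width, x$width_cv))
  cat(sprintf("  t_nuc %.2f, t_const %.2f, nucleoid area ratio %.2f\n",
              x$t_nuc, x$t_const, x$nucleoid_area_ratio))
  if (length(x$score_offsets)) {
    cat("  planted offsets:",
        paste(names(x$score_offsets), x$score_offsets, sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}
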