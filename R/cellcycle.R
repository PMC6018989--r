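#' Assign relative cell ages from the length rank of snapshot cells
#'
#' In a steady-state exponential population, a cell's rank in the length
#' distribution determines its relative cell-cycle age: with `F` the
#' fraction of cells with length at or below the cell's own,
#' `age(F) = -ln(1 - F/2) / ln(2)`. Ties share the average rank and hence
#' the same age. The assignment is rank-based, so it is invariant to any
#' monotone rescaling of length.
#'
#' @param lengths Numeric vector of cell lengths (µm), `n >= 2`.
#' @return A tibble with columns `length_um`, `rank_fraction` (F) and
#'   `age`, in input order.
#' @examples
#' age_from_rank(c(2, 3, 4))$age # longest cell has age 1
#' @export
age_from_rank <- function(lengths) {
  if (!is.numeric(lengths) || length(lengths) < 2) {
    abort("`lengths` must be a numeric vector with n >= 2.")
  }
  f <- rank(lengths, ties.method = "average") / length(lengths)
  tibble(length_um = lengths,
         rank_fraction = f,
         age = -log(1 - f / 2) / log(2))
}

#' Relative cell-cycle timing of an event from its population fraction
#'
#' Under the steady-state age distribution, the fraction of cells older
#' than age `a` is `2^(1 - a) - 1`. If a fraction `p` of snapshot cells
#' lies past a cell-cycle event (e.g. has two separate nucleoids), the
#' event occurs at relative age `T = 1 - log2(1 + p)`. This converts
#' single-snapshot population fractions into relative timings without any
#' time-lapse data; only steady state is assumed.
#'
#' @param fraction_past Fraction of cells past the event, in \[0, 1\].
#' @return Relative age in \[0, 1\].
#' @examples
#' relative_event_timing(sqrt(2) - 1) # 0.5
#' @export
relative_event_timing <- function(fraction_past) {
  if (any(!is.finite(fraction_past)) ||
      any(fraction_past < 0 | fraction_past > 1)) {
    abort("`fraction_past` must lie in [0, 1].")
  }
  1 - log2(1 + fraction_past)
}

#' Cumulative event curves over inferred cell age
#'
#' Computes, on a grid of relative ages, the cumulative fraction of cells
#' past nucleoid separation (2+ nucleoids) and past constriction onset
#' (constriction degree above the threshold), with per-cell ages inferred
#' by [age_from_rank()]. These are the snapshot analogues of the
#' event-progression curves of time-lapse experiments.
#'
#' @param table Cell table with `length_um`, `nucleoid_count`,
#'   `constriction_degree`.
#' @param constriction_threshold Degree above which a cell counts as
#'   constricting (default 0.15).
#' @param grid Age grid.
#' @return Tibble with columns `age`, `event`
#'   (`"nucleoid_separation"` / `"constriction"`), `fraction`.
#' @export
event_curves <- function(table, constriction_threshold = 0.15,
                         grid = seq(0, 1, by = 0.02)) {
  check_columns(table, c("length_um", "nucleoid_count", "constriction_degree"),
                "cell table")
  ages <- age_from_rank(table$length_um)$age
  two_nuc <- table$nucleoid_count >= 2
  constr <- table$constriction_degree > constriction_threshold
  frac_at <- function(flag) {
    f <- vapply(grid, function(a) {
      sel <- ages <= a
      if (!any(sel)) NA_real_ else mean(flag[sel])
    }, numeric(1))
    # grid ages younger than the youngest cell carry the first defined value
    if (anyNA(f)) f[is.na(f)] <- f[which(!is.na(f))[1]]
    f
  }
  # cummax enforces the monotonicity the underlying process guarantees but
  # finite-sample noise can violate
  bind_rows(
    tibble(age = grid, event = "nucleoid_separation",
           fraction = cummax(frac_at(two_nuc))),
    tibble(age = grid, event = "constriction",
           fraction = cummax(frac_at(constr)))
  )
}

# cells in the constriction-onset band: lowest decile (by default) of
# strictly positive cell constriction degrees
onset_band_cells <- function(table, band = 0.1) {
  pos <- table$constriction_degree > 0
  if (!any(pos)) return(integer(0))
  cut <- stats::quantile(table$constriction_degree[pos], band, names = FALSE)
  which(pos & table$constriction_degree <= cut)
}

#' Coupling between nucleoid separation and cell constriction
#'
#' Two per-strain statistics describing how tightly nucleoid constriction
#' tracks cell constriction: `rho_cd`, the Pearson correlation between the
#' cell and nucleoid constriction degrees across constricting cells, and
#' `cdn_c0`, the mean degree of nucleoid separation among cells at the
#' very onset of constriction (lowest decile of positive cell degrees).
#'
#' @param table Cell table with `constriction_degree` and
#'   `nucleoid_constriction_degree`.
#' @param min_cells Minimum number of constricting cells below which both
#'   statistics are returned as `NA`.
#' @param onset_band Quantile width of the onset band (default lowest
#'   decile).
#' @return A one-row tibble with `rho_cd`, `cdn_c0` and `n_constricting`.
#' @export
coupling_stats <- function(table, min_cells = 10, onset_band = 0.1) {
  check_columns(table, c("constriction_degree", "nucleoid_constriction_degree"),
                "cell table")
  constr <- which(table$constriction_degree > 0)
  if (length(constr) < min_cells) {
    return(tibble(rho_cd = NA_real_, cdn_c0 = NA_real_,
                  n_constricting = length(constr)))
  }
  x <- table$constriction_degree[constr]
  y <- table$nucleoid_constriction_degree[constr]
  rho <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else cor(x, y)
  onset <- onset_band_cells(table, onset_band)
  tibble(
    rho_cd = rho,
    cdn_c0 = mean(table$nucleoid_constriction_degree[onset]),
    n_constricting = length(constr)
  )
}

#' Per-strain cell-cycle feature set
#'
#' The five cell-cycle features of the screen: relative timing of nucleoid
#' separation (from the fraction of cells with two nucleoids), relative
#' timing of constriction onset (fraction with degree above the
#' threshold), mean nucleoid area (sum over nucleoids per cell), and the
#' two coupling statistics of [coupling_stats()].
#'
#' @inheritParams event_curves
#' @inheritParams coupling_stats
#' @return One-row tibble: `rel_t_nuc`, `rel_t_const`,
#'   `mean_nucleoid_area`, `rho_cd`, `cdn_c0`.
#' @export
cellcycle_features <- function(table, constriction_threshold = 0.15,
                               min_cells = 10, onset_band = 0.1) {
  check_columns(table, c("nucleoid_count", "constriction_degree",
                         "nucleoid_area_um2"), "cell table")
  cs <- coupling_stats(table, min_cells = min_cells, onset_band = onset_band)
  tibble(
    rel_t_nuc = relative_event_timing(mean(table$nucleoid_count >= 2)),
    rel_t_const = relative_event_timing(
      mean(table$constriction_degree > constriction_threshold)),
    mean_nucleoid_area = mean(table$nucleoid_area_um2),
    rho_cd = cs$rho_cd,
    cdn_c0 = cs$cdn_c0
  )
}
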