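#' Fit a Gompertz growth curve to a microplate OD600 series
#'
#' Fits the modified (Zwietering) Gompertz model for the log-relative
#' density, `ln(OD(t) / OD_0) = A * exp(-exp(mu * e / A * (lambda - t) + 1))`,
#' by nonlinear least squares with five data-driven starts (best residual
#' sum of squares wins). Residuals are taken on the measured OD scale,
#' where plate-reader noise is additive — log-scale residuals would let
#' the noisy low-density points dominate the fit. The baseline `OD_0` is a
#' free parameter. `mu` is the maximal specific growth rate — the slope of
#' `ln(OD)` at the inflection — so `alpha_max` is directly comparable
#' across strains regardless of inoculum or saturation level.
#'
#' @param curve A data frame with columns `time_min` (strictly
#'   increasing) and `od600`, at least 8 points spanning >= 2 h.
#' @param strain_id Optional label stored in the result.
#' @return An object of class `gompertz_fit` with elements `alpha_max`
#'   (1/h), `od_max` (mean OD over the last hour, via [od_max()]),
#'   `lag` (min), `amplitude` (dimensionless `A`), `rss`, `converged`,
#'   `n`, `strain_id`. Flat or non-increasing curves yield
#'   `converged = FALSE` rather than an error.
#' @examples
#' t <- seq(0, 960, 5)
#' od <- 0.01 * exp(2 * exp(-exp(0.008 * exp(1) / 2 * (120 - t) + 1)))
#' fit_gompertz(data.frame(time_min = t, od600 = od))
#' @export
fit_gompertz <- function(curve, strain_id = NA_character_) {
  check_columns(curve, c("time_min", "od600"), "growth curve")
  t <- curve$time_min
  od <- curve$od600
  if (length(t) < 8) abort("a growth curve needs at least 8 points.")
  if (any(diff(t) <= 0)) abort("`time_min` must be strictly increasing.")
  if (max(t) - min(t) < 120) abort("a growth curve must span at least 2 h.")

  failed <- function() {
    structure(list(alpha_max = NA_real_, od_max = od_max(curve),
                   lag = NA_real_, amplitude = NA_real_, rss = NA_real_,
                   converged = FALSE, n = length(t), strain_id = strain_id,
                   model = NULL, curve = as_tibble(curve)),
              class = "gompertz_fit")
  }
  if (max(od) <= min(od) || max(od) / max(min(od), 1e-9) < 1.2) {
    return(failed())
  }

  # data-driven heuristics: baseline from the smallest readings, amplitude
  # from the plateau, mu from the steepest smoothed slope of ln(OD), lag
  # from where the curve first clears 5% of the amplitude
  od0_0 <- max(stats::median(head(sort(od), 5)), 1e-4)
  a0 <- max(log(max(od) / od0_0), 0.1)
  ylog <- log(pmax(od, od0_0 / 2))
  dy <- diff(ylog) / diff(t)
  mu0 <- max(stats::filter(dy, rep(1 / 5, 5), sides = 2), na.rm = TRUE)
  mu0 <- max(mu0, 1e-5)
  lag0 <- t[which(ylog - log(od0_0) > 0.05 * a0)[1]]
  if (is.na(lag0)) lag0 <- t[2]

  starts <- list(
    c(A = a0, mu = mu0, lambda = lag0, od0 = od0_0),
    c(A = a0 * 1.2, mu = mu0 * 2, lambda = lag0 * 0.5, od0 = od0_0),
    c(A = a0 * 0.9, mu = mu0 * 0.5, lambda = lag0 * 1.5, od0 = od0_0 * 2),
    c(A = a0, mu = mu0 * 4, lambda = max(t) / 4, od0 = od0_0),
    c(A = a0 * 1.1, mu = mu0, lambda = 0, od0 = od0_0 / 2)
  )

  dat <- data.frame(t = t, od = od)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        od ~ od0 * exp(A * exp(-exp(mu * exp(1) / A * (lambda - t) + 1))),
        data = dat, start = as.list(st),
        lower = c(A = 1e-3, mu = 1e-7, lambda = -max(t), od0 = 1e-6),
        upper = c(A = 10 * max(a0, 1), mu = 1, lambda = 2 * max(t),
                  od0 = max(od)),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) return(failed())

  p <- coef(best$fit)
  structure(
    list(alpha_max = unname(p["mu"]) * 60, od_max = od_max(curve),
         lag = unname(p["lambda"]), amplitude = unname(p["A"]),
         rss = best$rss, converged = TRUE, n = length(t),
         strain_id = strain_id, model = best$fit, curve = as_tibble(curve)),
    class = "gompertz_fit")
}

#' Saturating density from the tail of a growth curve
#'
#' Mean OD600 over the final `window` minutes of the curve.
#'
#' @inheritParams fit_gompertz
#' @param window Averaging window in minutes (default: the last hour).
#' @return A single OD600 value.
#' @export
od_max <- function(curve, window = 60) {
  check_columns(curve, c("time_min", "od600"), "growth curve")
  span <- max(curve$time_min) - min(curve$time_min)
  if (span < window) abort("curve shorter than the averaging window.")
  mean(curve$od600[curve$time_min >= max(curve$time_min) - window])
}

#' Fit growth curves for every strain of a screen
#'
#' @param growth Long tibble with `strain_id`, `time_min`, `od600`.
#' @return Tibble with one row per strain: `strain_id`, `alpha_max`,
#'   `od_max`, `lag`, `amplitude`, `rss`, `converged`.
#' @export
fit_growth_curves <- function(growth) {
  check_columns(growth, c("strain_id", "time_min", "od600"), "growth table")
  growth |>
    group_by(.data$strain_id) |>
    group_modify_fit() |>
    ungroup()
}

group_modify_fit <- function(grouped) {
  dplyr::group_modify(grouped, function(df, key) {
    f <- fit_gompertz(df, strain_id = key$strain_id)
    tibble(alpha_max = f$alpha_max, od_max = f$od_max, lag = f$lag,
           amplitude = f$amplitude, rss = f$rss, converged = f$converged)
  })
}

#' @export
print.gompertz_fit <- function(x, ...) {
  cat("<gompertz_fit>",
      if (!is.na(x$strain_id)) x$strain_id else "", "\n")
  if (x$converged) {
    cat(sprintf("  alpha_max %.4f /h, od_max %.3f, lag %.1f min, A %.3f (rss %.3g, n %d)\n",
                x$alpha_max, x$od_max, x$lag, x$amplitude, x$rss, x$n))
  } else {
    cat(sprintf("  not converged (flat curve?); od_max %.3f, n %d\n",
                x$od_max, x$n))
  }
  invisible(x)
}

#' @rdname fit_gompertz
#' @param x,object A `gompertz_fit`.
#' @param ... Unused.
#' @method tidy gompertz_fit
#' @export
tidy.gompertz_fit <- function(x, ...) {
  tibble(
    term = c("alpha_max", "od_max", "lag", "amplitude"),
    estimate = c(x$alpha_max, x$od_max, x$lag, x$amplitude),
    unit = c("1/h", "OD600", "min", "ln(OD/OD0)")
  )
}

#' @rdname fit_gompertz
#' @method glance gompertz_fit
#' @export
glance.gompertz_fit <- function(x, ...) {
  tibble(alpha_max = x$alpha_max, od_max = x$od_max, lag = x$lag,
         amplitude = x$amplitude, rss = x$rss, converged = x$converged,
         n = x$n)
}

#' @rdname fit_gompertz
#' @method autoplot gompertz_fit
#' @export
autoplot.gompertz_fit <- function(object, ...) {
  df <- object$curve
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_min, .data$od600)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (min)", y = "OD600")
  if (object$converged) {
    pred <- tibble(
      time_min = seq(min(df$time_min), max(df$time_min), length.out = 200))
    pred$od600 <- stats::predict(object$model,
                                 newdata = data.frame(t = pred$time_min))
    p <- p + ggplot2::geom_line(data = pred, colour = "firebrick")
  }
  p
}
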