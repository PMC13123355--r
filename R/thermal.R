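#' Boltzmann sigmoid fit of a thermal-unfolding curve
#'
#' Least-squares fit of
#' \code{F(T) = f_min + (f_max - f_min) / (1 + exp((Tm - T)/slope))} to a
#' fluorescence melt curve. Plateaus are initialised from the first/last
#' temperature deciles and Tm from the half-height crossing. Descending
#' curves (signal falling on unfolding) are auto-detected and fitted with
#' the plateaus swapped.
#'
#' @param temperature temperature grid, degrees C, strictly increasing
#'   (>= 10 points). A two-column data frame
#'   (\code{temperature, fluorescence}) may be passed as the single
#'   argument.
#' @param fluorescence fluorescence intensities.
#' @param t_max optional upper-temperature cutoff excluding post-plateau
#'   quench points (default none).
#' @return an object of class \code{"melt_fit"} with \code{tm},
#'   \code{slope}, \code{f_min}, \code{f_max}, standard errors \code{se},
#'   \code{r_squared}, \code{direction} ("ascending"/"descending"), and
#'   the underlying \code{nls} fit.
#' @examples
#' curve <- simulate_melt_curve(melt_sim_config(tm = 59.7, seed = 1))
#' fit_boltzmann(curve)
#' @export
fit_boltzmann <- function(temperature, fluorescence = NULL, t_max = NULL) {
  if (is.data.frame(temperature)) {
    fluorescence <- temperature$fluorescence
    temperature <- temperature$temperature
  }
  stopifnot(length(temperature) == length(fluorescence),
            length(temperature) >= 10L, all(diff(temperature) > 0))
  if (!is.null(t_max)) {
    keep <- temperature <= t_max
    temperature <- temperature[keep]
    fluorescence <- fluorescence[keep]
  }
  tt <- temperature; ff <- fluorescence
  n <- length(tt)
  dec <- max(2L, n %/% 10L)
  lo <- mean(ff[seq_len(dec)])
  hi <- mean(ff[(n - dec + 1L):n])
  descending <- hi < lo
  y <- if (descending) -ff else ff
  y_lo <- mean(y[seq_len(dec)])
  y_hi <- mean(y[(n - dec + 1L):n])
  # transition-span check against residual scatter around a running trend
  sm <- stats::smooth.spline(tt, y, df = min(10, n - 2))
  res_sd <- stats::sd(y - stats::predict(sm, tt)$y)
  if (!is.finite(res_sd)) res_sd <- stats::sd(y) * 0.05
  if ((y_hi - y_lo) <= 3 * res_sd)
    stop("no unfolding transition: curve does not span two plateaus")
  mid <- (y_lo + y_hi) / 2
  cross <- which(y >= mid)[1]
  tm0 <- if (is.na(cross)) stats::median(tt) else tt[cross]
  fit <- minpack.lm::nlsLM(
    y ~ fmin + (fmax - fmin) / (1 + exp((tm - tt) / slope)),
    start = list(fmin = y_lo, fmax = y_hi, tm = tm0, slope = 2),
    lower = c(-Inf, -Inf, min(tt), 1e-3),
    upper = c(Inf, Inf, max(tt), diff(range(tt))),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  sm2 <- summary(fit)$coefficients
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  f_min <- if (descending) -cf[["fmax"]] else cf[["fmin"]]
  f_max <- if (descending) -cf[["fmin"]] else cf[["fmax"]]
  structure(list(tm = cf[["tm"]], slope = cf[["slope"]],
                 f_min = min(f_min, f_max), f_max = max(f_min, f_max),
                 se = c(tm = sm2["tm", 2], slope = sm2["slope", 2],
                        f_min = sm2["fmin", 2], f_max = sm2["fmax", 2]),
                 r_squared = r2,
                 direction = if (descending) "descending" else "ascending",
                 fit = fit, temperature = tt, fluorescence = ff),
            class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("Boltzmann melt fit (%s): Tm = %.1f +/- %.1f C, slope = %.2f C, R^2 = %.4f\n",
              x$direction, x$tm, x$se["tm"], x$slope, x$r_squared))
  invisible(x)
}

#' @export
coef.melt_fit <- function(object, ...) {
  c(tm = object$tm, slope = object$slope,
    f_min = object$f_min, f_max = object$f_max)
}

#' @export
predict.melt_fit <- function(object, temperature = NULL, ...) {
  if (is.null(temperature)) temperature <- object$temperature
  s <- if (object$direction == "descending") -1 else 1
  object$f_min + (object$f_max - object$f_min) /
    (1 + exp(s * (object$tm - temperature) / object$slope))
}

#' @export
plot.melt_fit <- function(x, ...) {
  graphics::plot(x$temperature, x$fluorescence, xlab = "temperature (C)",
                 ylab = "fluorescence", ...)
  tt <- seq(min(x$temperature), max(x$temperature), length.out = 300)
  graphics::lines(tt, predict(x, tt), lwd = 2)
  graphics::abline(v = x$tm, lty = 2)
  invisible(x)
}

#' Melting-temperature shift between two conditions
#'
#' \code{delta_Tm = Tm_b - Tm_a} with propagated (quadrature-summed)
#' uncertainty.
#'
#' @param fit_a,fit_b \code{\link{fit_boltzmann}} results (reference first).
#' @return list of class \code{"delta_tm"} with \code{delta_tm} (C) and
#'   \code{se}.
#' @export
delta_tm <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "melt_fit"), inherits(fit_b, "melt_fit"))
  d <- fit_b$tm - fit_a$tm
  s <- sqrt(fit_a$se[["tm"]]^2 + fit_b$se[["tm"]]^2)
  structure(list(delta_tm = d, se = s,
                 tm_a = fit_a$tm, tm_b = fit_b$tm),
            class = "delta_tm")
}

#' @export
print.delta_tm <- function(x, ...) {
  cat(sprintf("Delta Tm = %.1f +/- %.1f C (%.1f -> %.1f C)\n",
              x$delta_tm, x$se, x$tm_a, x$tm_b))
  invisible(x)
}
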