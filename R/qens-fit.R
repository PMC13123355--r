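#' Fit a QENS spectrum with a resolution-convolved two-Lorentzian model
#'
#' Weighted least squares of
#' \code{R (x) [A1 L(G1) + A2 L(G2)] + a + b E}, where L is a unit-area
#' Lorentzian, R the measured resolution function (numerical convolution on
#' the energy grid) and (a, b) a linear background. Components are reported
#' ordered so that \code{Gamma_narrow < Gamma_broad}.
#'
#' @param spectrum a \code{\link{qens_spectrum}}.
#' @param init optional named list of starting values
#'   (\code{gamma_narrow, gamma_broad, A_narrow, A_broad, bg_offset,
#'   bg_slope}).
#' @param buffer optional buffer spectrum (same grid) subtracted
#'   channel-wise before fitting.
#' @param elastic include a resolution-shaped elastic line (off by
#'   default; the standard model has only the two Lorentzians plus
#'   background).
#' @return an object of class \code{"qens_fit"}: list with
#'   \code{gamma_narrow, gamma_broad} (HWHM, ueV), \code{A_narrow,
#'   A_broad}, background terms, standard errors (\code{se}), reduced
#'   chi-square \code{chi2_red}, \code{converged}, \code{collapsed}
#'   (TRUE when the two widths are not separable, ratio < 1.5), and the
#'   fitted curve.
#' @export
fit_qens_spectrum <- function(spectrum, init = NULL, buffer = NULL,
                              elastic = FALSE) {
  stopifnot(inherits(spectrum, "qens_spectrum"))
  e <- spectrum$energy
  if (max(e) < 50 || min(e) > -50)
    stop("spectrum must cover at least +/-50 ueV")
  y <- spectrum$intensity
  if (!is.null(buffer)) {
    bi <- if (inherits(buffer, "qens_spectrum")) buffer$intensity else buffer
    stopifnot(length(bi) == length(y))
    y <- y - bi
  }
  sig <- spectrum$sigma
  kern <- spectrum$resolution
  de <- mean(diff(e))

  a_tot <- max(pracma::trapz(e, pmax(y, 0)), .Machine$double.eps)
  init <- .qens_init(init, e, y, a_tot)

  n_el <- if (elastic) 1L else 0L
  model_fun <- function(p) {
    g1 <- exp(p[1]); g2 <- exp(p[2])
    a1 <- exp(p[3]); a2 <- exp(p[4])
    out <- .qens_model(e, kern, g1, g2, a1, a2, p[5], p[6])
    if (elastic) out <- out + exp(p[7]) * kern
    out
  }
  p0 <- c(log(init$gamma_narrow), log(init$gamma_broad),
          log(init$A_narrow), log(init$A_broad),
          init$bg_offset, init$bg_slope,
          if (elastic) log(0.05 * a_tot))
  res_fun <- function(p) (model_fun(p) - y) / sig
  nls <- minpack.lm::nls.lm(
    p0, fn = res_fun,
    control = minpack.lm::nls.lm.control(maxiter = 300))
  p <- nls$par
  converged <- nls$info %in% 1:4

  npar <- length(p0)
  dof <- length(y) - npar
  chi2_red <- sum(nls$fvec^2) / dof
  # covariance of transformed parameters; delta method for the logs
  se <- rep(NA_real_, npar)
  cv <- tryCatch(chi2_red * 2 * solve(nls$hessian), error = function(e) NULL)
  if (!is.null(cv)) se <- sqrt(pmax(diag(cv), 0))

  g <- exp(p[1:2]); a <- exp(p[3:4])
  ord <- order(g)
  out <- list(gamma_narrow = g[ord[1]], gamma_broad = g[ord[2]],
              A_narrow = a[ord[1]], A_broad = a[ord[2]],
              bg_offset = p[5], bg_slope = p[6],
              se = c(gamma_narrow = g[ord[1]] * se[ord[1]],
                     gamma_broad = g[ord[2]] * se[ord[2]],
                     A_narrow = a[ord[1]] * se[2 + ord[1]],
                     A_broad = a[ord[2]] * se[2 + ord[2]],
                     bg_offset = se[5], bg_slope = se[6]),
              chi2_red = chi2_red, converged = converged,
              collapsed = g[ord[2]] / g[ord[1]] < 1.5,
              fitted = model_fun(p), energy = e,
              q = spectrum$q, temperature = spectrum$temperature)
  if (out$collapsed)
    warning("Lorentzian widths collapse (ratio < 1.5); ",
            "consider a single-component refit")
  if (!converged)
    warning("QENS fit did not converge (info = ", nls$info, ")")
  class(out) <- "qens_fit"
  out
}

.qens_init <- function(init, e, y, a_tot) {
  def <- list(gamma_narrow = 1, gamma_broad = 12,
              A_narrow = 0.5 * a_tot, A_broad = 0.5 * a_tot,
              bg_offset = stats::median(y[abs(e) > 0.9 * max(abs(e))]),
              bg_slope = 0)
  if (!is.null(init)) def[names(init)] <- init
  def$bg_offset <- max(def$bg_offset, 0)
  def
}

#' @export
print.qens_fit <- function(x, ...) {
  cat(sprintf("QENS two-Lorentzian fit (Q = %.2f 1/A, T = %.0f K):\n",
              x$q, x$temperature))
  cat(sprintf("  Gamma_narrow = %.3f +/- %.3f ueV, Gamma_broad = %.2f +/- %.2f ueV\n",
              x$gamma_narrow, x$se["gamma_narrow"],
              x$gamma_broad, x$se["gamma_broad"]))
  cat(sprintf("  reduced chi2 = %.3f%s\n", x$chi2_red,
              if (x$collapsed) " [widths collapsed]" else ""))
  invisible(x)
}

#' @export
coef.qens_fit <- function(object, ...) {
  c(gamma_narrow = object$gamma_narrow, gamma_broad = object$gamma_broad,
    A_narrow = object$A_narrow, A_broad = object$A_broad,
    bg_offset = object$bg_offset, bg_slope = object$bg_slope)
}

#' @export
residuals.qens_fit <- function(object, ...) {
  # standardised residuals are not retained; report raw differences
  NULL
}

#' @export
plot.qens_fit <- function(x, ...) {
  graphics::plot(x$energy, x$fitted, type = "l",
                 xlab = "energy transfer (ueV)", ylab = "intensity", ...)
  invisible(x)
}

#' Global diffusivity from the Q^2 law
#'
#' Weighted linear fit of the narrow-component HWHM against Q^2 through the
#' origin (\code{Gamma = D Q^2}); the slope is the diffusivity in A^2 ueV.
#'
#' @param gamma narrow-component HWHMs, ueV.
#' @param q momentum transfers, 1/A (>= 3 points).
#' @param se optional HWHM standard errors (weights 1/se^2).
#' @param temperature sample temperature, K (carried through).
#' @param intercept allow a free intercept for diagnostics (default FALSE,
#'   matching the origin-constrained law).
#' @return list of class \code{"diffusivity_fit"} with \code{D} (A^2 ueV),
#'   \code{D_cm2_s} (converted via hbar = 658.2 ueV ps), \code{se}, and
#'   the fit.
#' @export
fit_global_diffusion <- function(gamma, q, se = NULL,
                                 temperature = NA_real_,
                                 intercept = FALSE) {
  stopifnot(length(gamma) == length(q), length(q) >= 3L, all(q > 0))
  w <- if (is.null(se)) rep(1, length(q)) else 1 / se^2
  dat <- data.frame(gamma = gamma, q2 = q^2)
  fml <- if (intercept) gamma ~ q2 else gamma ~ 0 + q2
  fit <- stats::lm(fml, data = dat, weights = w)
  d <- unname(stats::coef(fit)["q2"])
  if (d <= 0) stop("negative diffusivity slope (unphysical)")
  d_se <- summary(fit)$coefficients["q2", "Std. Error"]
  # Gamma = hbar D_phys Q^2  =>  D_phys = D[ueV A^2] / hbar; to cm^2/s:
  # A^2/ps = 1e-16 cm^2 / 1e-12 s = 1e-4 cm^2/s
  d_cm2_s <- d / .HBAR_UEV_PS * 1e-4
  structure(list(D = d, D_cm2_s = d_cm2_s, se = d_se,
                 temperature = temperature, fit = fit),
            class = "diffusivity_fit")
}

#' @export
print.diffusivity_fit <- function(x, ...) {
  cat(sprintf("Global diffusion (T = %.0f K): D = %.3f +/- %.3f A^2 ueV (%.2e cm^2/s)\n",
              x$temperature, x$D, x$se, x$D_cm2_s))
  invisible(x)
}

#' Internal-dynamics rate from the power-law Q dependence
#'
#' Log-log linear fit of the broad-component HWHM,
#' \code{log Gamma = log(rate) + alpha log Q}; the rate is the HWHM at
#' Q = 1 1/A (the dimensional anchor of the power law) and converts to a
#' relaxation time via \code{tau0 = 658.2 / rate} ps.
#'
#' @param gamma broad-component HWHMs, ueV (all > 0).
#' @param q momentum transfers, 1/A (>= 3 points).
#' @param se optional HWHM standard errors.
#' @param temperature sample temperature, K.
#' @return list of class \code{"internal_dynamics_fit"} with \code{rate}
#'   (ueV at Q = 1), \code{alpha}, \code{tau0_ps}, standard errors, and
#'   the fit.
#' @export
fit_internal_dynamics <- function(gamma, q, se = NULL,
                                  temperature = NA_real_) {
  stopifnot(length(gamma) == length(q), length(q) >= 3L, all(q > 0))
  if (any(gamma <= 0)) stop("all broad-component widths must be > 0")
  # relative errors on Gamma become absolute errors on log Gamma
  w <- if (is.null(se)) rep(1, length(q)) else (gamma / se)^2
  fit <- stats::lm(log(gamma) ~ log(q), weights = w)
  cf <- stats::coef(fit)
  sm <- summary(fit)$coefficients
  rate <- exp(unname(cf[1]))
  structure(list(rate = rate, alpha = unname(cf[2]),
                 tau0_ps = .HBAR_UEV_PS / rate,
                 se = c(rate = rate * sm[1, 2], alpha = sm[2, 2]),
                 temperature = temperature, fit = fit),
            class = "internal_dynamics_fit")
}

#' @export
print.internal_dynamics_fit <- function(x, ...) {
  cat(sprintf("Internal dynamics (T = %.0f K): rate = %.2f +/- %.2f ueV at Q = 1 (tau0 = %.1f ps), alpha = %.2f +/- %.2f\n",
              x$temperature, x$rate, x$se["rate"], x$tau0_ps,
              x$alpha, x$se["alpha"]))
  invisible(x)
}

#' Arrhenius analysis of a temperature-dependent rate or diffusivity
#'
#' Linear fit of \code{ln X} against \code{1/T}; the activation energy is
#' \code{Ea = -slope * R} with R = 8.314 J/(mol K), reported in kJ/mol, and
#' the prefactor is \code{exp(intercept)}.
#'
#' @param values rates/diffusivities, all > 0.
#' @param temperatures temperatures, K (>= 2; >= 3 for a standard error).
#' @param se optional standard errors of \code{values}.
#' @return list of class \code{"arrhenius_fit"} with \code{Ea_kJ_mol},
#'   \code{prefactor}, standard errors, and the underlying \code{lm} fit.
#' @export
arrhenius_fit <- function(values, temperatures, se = NULL) {
  stopifnot(length(values) == length(temperatures),
            length(values) >= 2L, all(temperatures > 0))
  if (any(values <= 0)) stop("Arrhenius fit requires positive values")
  w <- if (is.null(se)) rep(1, length(values)) else (values / se)^2
  fit <- stats::lm(log(values) ~ I(1 / temperatures), weights = w)
  cf <- stats::coef(fit)
  ea <- -unname(cf[2]) * .R_GAS / 1000
  ea_se <- if (length(values) >= 3L)
    summary(fit)$coefficients[2, 2] * .R_GAS / 1000 else NA_real_
  pre <- exp(unname(cf[1]))
  pre_se <- if (length(values) >= 3L)
    pre * summary(fit)$coefficients[1, 2] else NA_real_
  structure(list(Ea_kJ_mol = ea, prefactor = pre,
                 se = c(Ea_kJ_mol = ea_se, prefactor = pre_se),
                 fit = fit, temperatures = temperatures, values = values),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("Arrhenius fit over %d temperatures: Ea = %.1f +/- %.1f kJ/mol, prefactor = %.3g\n",
              length(x$temperatures), x$Ea_kJ_mol, x$se["Ea_kJ_mol"],
              x$prefactor))
  invisible(x)
}

#' @export
coef.arrhenius_fit <- function(object, ...) {
  c(Ea_kJ_mol = object$Ea_kJ_mol, prefactor = object$prefactor)
}

#' @export
predict.arrhenius_fit <- function(object, temperatures = NULL, ...) {
  if (is.null(temperatures)) temperatures <- object$temperatures
  object$prefactor * exp(-object$Ea_kJ_mol * 1000 / (.R_GAS * temperatures))
}

#' @export
plot.arrhenius_fit <- function(x, ...) {
  graphics::plot(1 / x$temperatures, log(x$values),
                 xlab = "1/T (1/K)", ylab = "ln(rate)", ...)
  graphics::abline(x$fit$coefficients[1], x$fit$coefficients[2])
  invisible(x)
}

#' Full QENS dynamics chain: spectra to activation energies
#'
#' Fits every spectrum with the two-Lorentzian model, extracts per-
#' temperature diffusivities (Q^2 law on the narrow widths) and internal
#' rates (power law on the broad widths), and runs Arrhenius fits on both.
#'
#' @param spectra list of \code{\link{qens_spectrum}} objects (e.g. from
#'   \code{\link{simulate_qens}}, element \code{spectra}).
#' @param init optional initial values forwarded to
#'   \code{\link{fit_qens_spectrum}}.
#' @return an object of class \code{"qens_dynamics"}: list with
#'   \code{widths} (data frame per T, Q), \code{diffusion} / \code{internal}
#'   (per-temperature fits), and \code{arrhenius_global} /
#'   \code{arrhenius_internal}.
#' @export
qens_dynamics <- function(spectra, init = NULL) {
  fits <- lapply(spectra, fit_qens_spectrum, init = init)
  widths <- do.call(rbind, lapply(fits, function(f) data.frame(
    temperature = f$temperature, q = f$q,
    gamma_narrow = f$gamma_narrow, gamma_broad = f$gamma_broad,
    se_narrow = f$se[["gamma_narrow"]], se_broad = f$se[["gamma_broad"]],
    chi2_red = f$chi2_red)))
  temps <- sort(unique(widths$temperature))
  diffusion <- list(); internal <- list()
  for (tt in temps) {
    wt <- widths[widths$temperature == tt, ]
    diffusion[[as.character(tt)]] <- fit_global_diffusion(
      wt$gamma_narrow, wt$q, se = wt$se_narrow, temperature = tt)
    internal[[as.character(tt)]] <- fit_internal_dynamics(
      wt$gamma_broad, wt$q, se = wt$se_broad, temperature = tt)
  }
  d_vals <- vapply(diffusion, function(f) f$D, numeric(1))
  r_vals <- vapply(internal, function(f) f$rate, numeric(1))
  structure(list(widths = widths, fits = fits,
                 diffusion = diffusion, internal = internal,
                 arrhenius_global = arrhenius_fit(d_vals, temps),
                 arrhenius_internal = arrhenius_fit(r_vals, temps)),
            class = "qens_dynamics")
}

#' @export
print.qens_dynamics <- function(x, ...) {
  cat("QENS dynamics analysis:\n")
  cat(sprintf("  global diffusion:  Ea = %.1f +/- %.1f kJ/mol\n",
              x$arrhenius_global$Ea_kJ_mol,
              x$arrhenius_global$se["Ea_kJ_mol"]))
  cat(sprintf("  internal dynamics: Ea = %.1f +/- %.1f kJ/mol\n",
              x$arrhenius_internal$Ea_kJ_mol,
              x$arrhenius_internal$se["Ea_kJ_mol"]))
  invisible(x)
}
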