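#' One-dimensional small-angle scattering curve
#'
#' @param q momentum transfer, 1/A, strictly increasing and > 0.
#' @param intensity scattered intensity (arbitrary units).
#' @param sigma per-point uncertainties, > 0.
#' @param label optional species/sample label.
#' @return an object of class \code{"sas_curve"} (list with q, intensity,
#'   sigma, label).
#' @export
scattering_curve <- function(q, intensity, sigma = NULL, label = NULL) {
  stopifnot(length(q) == length(intensity), all(q > 0), all(diff(q) > 0),
            all(is.finite(intensity)))
  if (is.null(sigma)) sigma <- pmax(0.01 * abs(intensity), 1e-12)
  stopifnot(length(sigma) == length(q), all(sigma > 0))
  structure(list(q = q, intensity = intensity, sigma = sigma,
                 label = label),
            class = "sas_curve")
}

#' @export
print.sas_curve <- function(x, ...) {
  cat(sprintf("Scattering curve%s: %d points, q in [%.4g, %.4g] 1/A\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              length(x$q), min(x$q), max(x$q)))
  invisible(x)
}

#' @export
plot.sas_curve <- function(x, ...) {
  graphics::plot(x$q, x$intensity, log = "y", xlab = "q (1/A)",
                 ylab = "I(q)", ...)
  invisible(x)
}

#' Guinier analysis of the low-q regime
#'
#' Iterative fit of \code{ln I = ln I0 - (Rg^2/3) q^2} with the fitted
#' range restricted so that \code{qmax * Rg <= qrg_limit}; the range is
#' re-selected and the fit repeated until Rg changes by less than 1%.
#'
#' @param curve a \code{\link{scattering_curve}}.
#' @param qrg_limit upper bound on q * Rg in the fitted window
#'   (default 1.3).
#' @param min_points minimum points in the fitted window (default 5).
#' @return an object of class \code{"guinier_fit"} with \code{Rg} (A),
#'   \code{I0}, their standard errors, \code{q_range}, \code{qrg_max},
#'   \code{n_points}, and an \code{aggregation_flag} raised on upward
#'   curvature at the lowest q.
#' @export
guinier_fit <- function(curve, qrg_limit = 1.3, min_points = 5L) {
  stopifnot(inherits(curve, "sas_curve"))
  pos <- curve$intensity > 0
  q <- curve$q[pos]; i <- curve$intensity[pos]; s <- curve$sigma[pos]
  if (length(q) < min_points) stop("not enough positive-intensity points")
  n_use <- max(min_points, min(10L, length(q)))
  rg_old <- Inf
  fit <- NULL
  for (iter in 1:30) {
    idx <- seq_len(n_use)
    w <- (i[idx] / s[idx])^2       # errors on ln I
    fit <- stats::lm(log(i[idx]) ~ I(q[idx]^2), weights = w)
    slope <- stats::coef(fit)[2]
    if (slope >= 0) stop("no Guinier decay at low q (non-negative slope)")
    rg <- sqrt(-3 * slope)
    if (is.finite(rg_old) && abs(rg - rg_old) / rg < 0.01) break
    rg_old <- rg
    n_use2 <- max(min_points, sum(q * rg <= qrg_limit))
    if (n_use2 == n_use) break
    n_use <- n_use2
  }
  idx <- seq_len(n_use)
  cf <- stats::coef(fit)
  sm <- summary(fit)$coefficients
  rg <- sqrt(-3 * cf[2])
  rg_se <- 3 * sm[2, 2] / (2 * rg)
  i0 <- exp(cf[1])
  # aggregation signature: systematic positive residuals at the lowest q
  res <- stats::residuals(fit)
  k <- max(3L, n_use %/% 4L)
  agg <- mean(res[seq_len(k)]) > 2 * stats::sd(res) / sqrt(k)
  if (agg) warning("upward curvature at low q: possible aggregation")
  structure(list(Rg = unname(rg), I0 = unname(i0),
                 se = c(Rg = unname(rg_se), I0 = unname(i0 * sm[1, 2])),
                 q_range = range(q[idx]), qrg_max = max(q[idx]) * rg,
                 n_points = n_use, aggregation_flag = agg, fit = fit),
            class = "guinier_fit")
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf("Guinier fit: Rg = %.1f +/- %.1f A, I(0) = %.4g (%d points, max qRg = %.2f)%s\n",
              x$Rg, x$se["Rg"], x$I0, x$n_points, x$qrg_max,
              if (x$aggregation_flag) " [aggregation?]" else ""))
  invisible(x)
}

#' @export
coef.guinier_fit <- function(object, ...) c(Rg = object$Rg, I0 = object$I0)

#' Pair-distance distribution by regularized indirect Fourier transform
#'
#' Represents P(r) on an n_r-point grid over [0, Dmax] with
#' \code{P(0) = P(Dmax) = 0} and solves the smoothness-regularized weighted
#' least-squares problem
#' \deqn{\min_P \left\|\frac{I - K P}{\sigma}\right\|^2 +
#'   \lambda \|P''\|^2, \qquad
#'   K_{jk} = 4\pi\,\Delta r\,\frac{\sin(q_j r_k)}{q_j r_k}.}
#' The regularization weight is dimensionless (scaled internally by the
#' ratio of the data and smoothness operator norms). When not given it is
#' chosen automatically: the smoothest solution whose data misfit stays
#' within 25% of the best attainable misfit over a wide weight grid (an
#' L-curve-style trade-off with a transparent selection rule).
#'
#' @param curve a \code{\link{scattering_curve}}.
#' @param dmax maximum intraparticle distance, A.
#' @param n_r number of r-grid points (default 101).
#' @param reg_weight dimensionless regularization weight (default NULL =
#'   automatic choice).
#' @return an object of class \code{"pr_function"} with \code{r},
#'   \code{P}, \code{dmax}, \code{Rg} and \code{I0} moments, the
#'   \code{reg_weight} used, the data-space \code{chi2_red}, and a
#'   \code{negativity_flag}.
#' @export
pr_transform <- function(curve, dmax, n_r = 101L, reg_weight = NULL) {
  stopifnot(inherits(curve, "sas_curve"), dmax > 0, n_r >= 10L)
  q <- curve$q; i <- curve$intensity
  # floor the uncertainties: weights spanning many decades (e.g. tiny
  # relative errors at deep form-factor minima) otherwise dominate the fit
  s <- pmax(curve$sigma, 1e-5 * max(abs(i)))
  if (min(q) > pi / dmax)
    warning("qmin > pi/dmax: the curve may not resolve the assumed dmax")
  r <- seq(0, dmax, length.out = n_r)
  dr <- r[2] - r[1]
  K <- 4 * pi * dr * outer(q, r, function(qq, rr) .sinc(qq * rr))
  interior <- 2:(n_r - 1L)            # endpoint constraints P(0)=P(Dmax)=0
  A <- K[, interior, drop = FALSE] / s
  b <- i / s
  # second-difference operator acting on the full (zero-padded) P
  D2 <- matrix(0, n_r - 2L, length(interior))
  for (k in seq_len(n_r - 2L)) {
    for (jj in (k - 1L):(k + 1L)) {
      if (jj >= 1L && jj <= length(interior))
        D2[k, jj] <- c(1, -2, 1)[jj - k + 2L]
    }
  }
  D2 <- D2 / dr^2
  # dimensionless weight scaled by the operator norms; solved by QR on the
  # augmented system (normal equations are numerically unusable here: the
  # error weighting spans several decades)
  scale0 <- sum(A^2) / sum(D2^2)
  solve_p <- function(lam_rel) {
    lam <- max(lam_rel, 1e-10) * scale0
    M <- rbind(A, sqrt(lam) * D2)
    rhs <- c(b, numeric(nrow(D2)))
    p <- numeric(n_r)
    p[interior] <- qr.coef(qr(M), rhs)
    p[!is.finite(p)] <- 0
    p
  }
  misfit <- function(p) sum((A %*% p[interior] - b)^2)
  if (is.null(reg_weight)) {
    lams <- 10^seq(-7, 0, length.out = 25)
    chis <- vapply(lams, function(l) misfit(solve_p(l)), numeric(1))
    # smoothest solution whose misfit is within 25% of the best
    ok <- chis <= 1.25 * min(chis) + 1e-12
    reg_weight <- max(lams[ok])
  }
  p <- solve_p(reg_weight)
  neg <- sum(abs(pmin(p, 0))) > 0.1 * sum(abs(p))
  if (neg) warning("P(r) is substantially negative; increase reg_weight")
  ptot <- pracma::trapz(r, p)
  if (ptot <= 0) warning("P(r) integrates to a non-positive total")
  rg <- sqrt(pracma::trapz(r, r^2 * p) / (2 * ptot))
  i0 <- 4 * pi * ptot
  chi2 <- misfit(p) / max(length(q) - 1L, 1L)
  structure(list(r = r, P = p, dmax = dmax, Rg = rg, I0 = i0,
                 reg_weight = reg_weight, chi2_red = chi2,
                 negativity_flag = neg),
            class = "pr_function")
}

#' @export
print.pr_function <- function(x, ...) {
  cat(sprintf("P(r): Dmax = %.0f A, Rg = %.1f A, I(0) = %.4g, lambda = %.3g%s\n",
              x$dmax, x$Rg, x$I0, x$reg_weight,
              if (x$negativity_flag) " [negative lobes]" else ""))
  invisible(x)
}

#' @export
plot.pr_function <- function(x, ...) {
  graphics::plot(x$r, x$P, type = "l", xlab = "r (A)", ylab = "P(r)", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

# interpolate a basis curve onto the target q grid (monotone cubic; no
# extrapolation)
.basis_on_grid <- function(basis, q_target) {
  mat <- vapply(basis, function(b) {
    if (length(b$q) == length(q_target) &&
        max(abs(b$q - q_target)) < 1e-9) return(b$intensity)
    if (min(b$q) > min(q_target) + 1e-12 ||
        max(b$q) < max(q_target) - 1e-12)
      stop("basis curve '", b$label,
           "' does not cover the target q range (extrapolation forbidden)")
    stats::splinefun(b$q, b$intensity, method = "monoH.FC")(q_target)
  }, numeric(length(q_target)))
  interp <- !all(vapply(basis, function(b)
    length(b$q) == length(q_target) && max(abs(b$q - q_target)) < 1e-9,
    logical(1)))
  attr(mat, "interpolated") <- interp
  mat
}

#' Non-negative least-squares decomposition of a scattering curve
#'
#' Fits the target intensity as a non-negative linear combination of basis
#' curves in the error-weighted metric and reports normalised weights, the
#' overall scale, and the reduced chi-square with
#' \code{n_q - n_members} degrees of freedom.
#'
#' @param basis list of \code{\link{scattering_curve}}s (interpolated onto
#'   the target grid when needed; flagged).
#' @param target the measured \code{\link{scattering_curve}} (must carry
#'   uncertainties).
#' @return an object of class \code{"nnls_fit"} with \code{weights}
#'   (non-negative, sum 1), \code{scale}, \code{chi2_red},
#'   \code{interpolated} and \code{degenerate} flags, and \code{fitted}.
#' @export
nnls_weights <- function(basis, target) {
  stopifnot(inherits(target, "sas_curve"), length(basis) >= 1L)
  B <- .basis_on_grid(basis, target$q)
  A <- B / target$sigma
  b <- target$intensity / target$sigma
  sol <- pracma::lsqnonneg(A, b)
  coefs <- sol$x
  scale <- sum(coefs)
  w <- if (scale > 0) coefs / scale else coefs
  dof <- length(b) - ncol(A)
  chi2 <- sum((b - A %*% coefs)^2) / max(dof, 1L)
  degenerate <- FALSE
  if (ncol(B) > 1L) {
    cc <- suppressWarnings(stats::cor(B))
    degenerate <- any(cc[upper.tri(cc)] > 0.9999, na.rm = TRUE)
  }
  labs <- vapply(seq_along(basis), function(k) {
    if (is.null(basis[[k]]$label)) sprintf("member_%d", k)
    else basis[[k]]$label
  }, character(1))
  names(w) <- labs
  structure(list(weights = w, scale = scale, chi2_red = chi2,
                 fitted = as.numeric(B %*% coefs),
                 interpolated = isTRUE(attr(B, "interpolated")),
                 degenerate = degenerate),
            class = "nnls_fit")
}

#' @export
print.nnls_fit <- function(x, ...) {
  cat(sprintf("NNLS decomposition: reduced chi2 = %.3f, scale = %.4g%s\n",
              x$chi2_red, x$scale,
              if (x$degenerate) " [degenerate basis]" else ""))
  nz <- x$weights[x$weights > 1e-6]
  print(round(nz, 4))
  invisible(x)
}
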