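#' Forster radius from donor/acceptor spectral properties
#'
#' Computes the spectral overlap integral
#' \deqn{J = \frac{\int F_D(\lambda)\,\varepsilon_A(\lambda)\,\lambda^4\,
#'   d\lambda}{\int F_D(\lambda)\, d\lambda}}
#' (units M^-1 cm^-1 nm^4, wavelengths in nm) by trapezoidal quadrature and
#' the Forster radius
#' \deqn{R_0 = 0.211\,[\kappa^2\,\eta^{-4}\,Q_D\,J]^{1/6}\ \mathrm{(A)}.}
#'
#' @param donor_emission data frame with columns \code{lambda} (nm) and
#'   \code{intensity}: donor emission spectrum (any normalisation; the
#'   definition of J is normalisation-free).
#' @param acceptor_extinction data frame with columns \code{lambda} (nm)
#'   and \code{epsilon} (M^-1 cm^-1): acceptor molar extinction.
#' @param quantum_yield donor fluorescence quantum yield Q_D.
#' @param kappa2 dipole orientation factor (default 2/3, isotropic).
#' @param refractive_index medium refractive index (default 1.4).
#' @return list of class \code{"forster_radius"} with \code{R0} (A) and
#'   \code{J} (M^-1 cm^-1 nm^4).
#' @export
forster_radius <- function(donor_emission, acceptor_extinction,
                           quantum_yield, kappa2 = 2 / 3,
                           refractive_index = 1.4) {
  stopifnot(quantum_yield >= 0, kappa2 >= 0, kappa2 <= 4,
            refractive_index > 1)
  stopifnot(all(c("lambda", "intensity") %in% names(donor_emission)),
            all(c("lambda", "epsilon") %in% names(acceptor_extinction)))
  stopifnot(all(donor_emission$intensity >= 0),
            all(acceptor_extinction$epsilon >= 0))
  # common grid: overlap of the two wavelength ranges, on the donor grid
  lo <- max(min(donor_emission$lambda), min(acceptor_extinction$lambda))
  hi <- min(max(donor_emission$lambda), max(acceptor_extinction$lambda))
  lam_d <- donor_emission$lambda
  keep <- lam_d >= lo & lam_d <= hi
  denom <- pracma::trapz(lam_d, donor_emission$intensity)
  if (hi <= lo || !any(keep)) stop("donor and acceptor spectra do not overlap")
  lam <- lam_d[keep]
  fd <- donor_emission$intensity[keep]
  eps <- stats::approx(acceptor_extinction$lambda,
                       acceptor_extinction$epsilon, xout = lam)$y
  num <- pracma::trapz(lam, fd * eps * lam^4)
  if (denom <= 0) stop("donor spectrum has zero integral")
  J <- num / denom
  if (J <= 0) stop("zero spectral overlap (J = 0)")
  r0 <- 0.211 * (kappa2 * refractive_index^-4 * quantum_yield * J)^(1 / 6)
  structure(list(R0 = r0, J = J, kappa2 = kappa2,
                 refractive_index = refractive_index,
                 quantum_yield = quantum_yield),
            class = "forster_radius")
}

#' @export
print.forster_radius <- function(x, ...) {
  cat(sprintf("Forster radius R0 = %.1f A (J = %.3g M^-1 cm^-1 nm^4, QD = %.2f, kappa2 = %.3f, n = %.2f)\n",
              x$R0, x$J, x$quantum_yield, x$kappa2, x$refractive_index))
  invisible(x)
}

#' Inter-fluorophore distance from a FRET efficiency
#'
#' Inverts the Forster relation: \code{r = R0 * (1/E - 1)^(1/6)}, so that
#' \code{r = R0} at E = 0.5.
#'
#' @param E FRET efficiency, strictly inside (0, 1).
#' @param R0 Forster radius, A (a \code{forster_radius} object also works).
#' @return distance in A (vectorised over E).
#' @examples
#' fret_to_distance(0.5, 54.8)            # r = R0 at the half point
#' fret_to_distance(c(0.33, 0.49, 0.63, 0.78), 54.8)
#' @export
fret_to_distance <- function(E, R0) {
  if (inherits(R0, "forster_radius")) R0 <- R0$R0
  stopifnot(R0 > 0)
  if (any(E <= 0 | E >= 1))
    stop("E must be strictly inside (0, 1): distance is unbounded/degenerate at the ends")
  R0 * (1 / E - 1)^(1 / 6)
}

#' Distance change between two FRET states
#'
#' \code{delta_r = r(E_state) - r(E_reference)}; positive values mean the
#' state is more open (longer dye separation) than the reference. By
#' convention the reference is the highest-FRET (most compact, inactive)
#' state.
#'
#' @param E_state efficiency of the state of interest.
#' @param E_reference efficiency of the reference state.
#' @param R0 Forster radius, A.
#' @return displacement in A.
#' @export
fret_displacement <- function(E_state, E_reference, R0) {
  fret_to_distance(E_state, R0) - fret_to_distance(E_reference, R0)
}
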