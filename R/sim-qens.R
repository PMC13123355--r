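#' Configuration for the quasi-elastic neutron spectrum generator
#'
#' Encodes the measurement model used throughout the QENS stage: at each
#' temperature T and momentum transfer Q the quasi-elastic signal is the sum
#' of a narrow Lorentzian (global diffusion, HWHM \code{Gamma = D(T) Q^2})
#' and a broad Lorentzian (internal dynamics,
#' \code{Gamma = rate(T) Q^alpha}, with the rate anchored at Q = 1 1/A),
#' both with Arrhenius temperature dependence
#' \code{X(T) = X0 exp(-Ea / (R T))}, convolved with a Gaussian instrument
#' resolution and sitting on a linear background.
#'
#' @param temperatures sample temperatures, K.
#' @param q_values momentum transfers, 1/Angstrom.
#' @param energy_grid symmetric energy-transfer grid, ueV.
#' @param resolution_fwhm Gaussian resolution full width at half maximum,
#'   ueV (default 3.4).
#' @param D0 Arrhenius prefactor of the diffusivity, A^2 ueV.
#' @param Ea_global activation energy of global diffusion, kJ/mol.
#' @param rate0 Arrhenius prefactor of the internal relaxation rate
#'   (broad-component HWHM at Q = 1 1/A), ueV.
#' @param Ea_internal activation energy of the internal rate, kJ/mol.
#' @param alpha power-law exponent of the broad component's Q dependence.
#' @param A_narrow,A_broad integrated areas of the two components.
#' @param bg_offset,bg_slope linear background, intensity units and
#'   intensity per ueV.
#' @param noise_rel relative (multiplicative) Gaussian noise level.
#' @param seed optional RNG seed.
#' @return an object of class \code{"qens_sim_config"}.
#' @export
qens_sim_config <- function(temperatures = c(280, 290, 300, 310),
                            q_values = c(0.7, 0.9, 1.1, 1.3, 1.5),
                            energy_grid = seq(-100, 100, by = 0.4),
                            resolution_fwhm = 3.4,
                            D0 = 9500, Ea_global = 21.1,
                            rate0 = 288, Ea_internal = 8.2,
                            alpha = 1.4,
                            A_narrow = 0.6, A_broad = 0.4,
                            bg_offset = 0.002, bg_slope = 2e-6,
                            noise_rel = 0.03,
                            seed = NULL) {
  stopifnot(all(temperatures > 0), all(q_values > 0),
            resolution_fwhm > 0, D0 > 0, rate0 > 0,
            A_narrow >= 0, A_broad >= 0, noise_rel >= 0)
  e <- sort(energy_grid)
  if (max(abs(e + rev(e))) > 1e-9 * max(abs(e)))
    stop("energy_grid must be symmetric about 0")
  de <- diff(e)
  if (max(de) - min(de) > 1e-9 * mean(de))
    stop("energy_grid must be uniform")
  if (mean(de) > resolution_fwhm / 5)
    stop("energy grid too coarse: need >= 5 points per resolution FWHM")
  structure(list(temperatures = temperatures, q_values = q_values,
                 energy_grid = e, resolution_fwhm = resolution_fwhm,
                 D0 = D0, Ea_global = Ea_global,
                 rate0 = rate0, Ea_internal = Ea_internal, alpha = alpha,
                 A_narrow = A_narrow, A_broad = A_broad,
                 bg_offset = bg_offset, bg_slope = bg_slope,
                 noise_rel = noise_rel, seed = seed),
            class = "qens_sim_config")
}

# Arrhenius law, Ea in kJ/mol, T in K
.arrhenius <- function(x0, ea_kj, temp) {
  x0 * exp(-ea_kj * 1000 / (.R_GAS * temp))
}

# Gaussian resolution kernel sampled on the energy grid (unit area)
.resolution_kernel <- function(energy, fwhm) {
  sd <- fwhm / (2 * sqrt(2 * log(2)))
  k <- stats::dnorm(energy, 0, sd)
  k / (sum(k) * mean(diff(energy)))
}

# resolution-convolved two-Lorentzian + linear background on `energy`;
# components are computed on a padded grid so convolution edges are clean
.qens_model <- function(energy, kernel, g1, g2, a1, a2, bg0, bg1) {
  de <- mean(diff(energy))
  n <- length(energy)
  pad <- ceiling(n / 4)
  e_ext <- c(energy[1] - rev(seq_len(pad)) * de, energy,
             energy[n] + seq_len(pad) * de)
  y <- a1 * .lorentzian(e_ext, g1) + a2 * .lorentzian(e_ext, g2)
  conv <- .conv_kernel(y, kernel, de)
  conv[(pad + 1):(pad + n)] + bg0 + bg1 * energy
}

#' Simulate quasi-elastic neutron spectra
#'
#' Generates one spectrum per (temperature, Q) pair from the two-Lorentzian
#' model described in \code{\link{qens_sim_config}}, with multiplicative
#' Gaussian noise and per-point uncertainties \code{sigma = noise_rel * I}.
#' Ground-truth component widths are attached to each spectrum.
#'
#' @param config a \code{\link{qens_sim_config}}.
#' @return an object of class \code{"qens_sim"}: list with \code{spectra}
#'   (list of \code{qens_spectrum} objects), \code{truth} (data frame of
#'   true widths per T, Q), \code{resolution} (kernel on the grid) and the
#'   \code{config}.
#' @export
simulate_qens <- function(config) {
  stopifnot(inherits(config, "qens_sim_config"))
  .with_seed(config$seed)
  e <- config$energy_grid
  kern <- .resolution_kernel(e, config$resolution_fwhm)
  spectra <- list()
  truth <- NULL
  for (temp in config$temperatures) {
    d_t <- .arrhenius(config$D0, config$Ea_global, temp)
    r_t <- .arrhenius(config$rate0, config$Ea_internal, temp)
    for (q in config$q_values) {
      g1 <- d_t * q^2
      g2 <- r_t * q^config$alpha
      ideal <- .qens_model(e, kern, g1, g2,
                           config$A_narrow, config$A_broad,
                           config$bg_offset, config$bg_slope)
      noise <- if (config$noise_rel > 0)
        stats::rnorm(length(e), 0, config$noise_rel) else 0
      intensity <- ideal * (1 + noise)
      sigma <- if (config$noise_rel > 0) config$noise_rel * abs(ideal)
               else rep(1, length(e))
      spectra[[length(spectra) + 1L]] <- qens_spectrum(
        energy = e, intensity = intensity, sigma = sigma,
        resolution = kern, q = q, temperature = temp)
      truth <- rbind(truth, data.frame(
        temperature = temp, q = q, gamma_narrow = g1, gamma_broad = g2,
        D = d_t, rate = r_t))
    }
  }
  structure(list(spectra = spectra, truth = truth, resolution = kern,
                 config = config),
            class = "qens_sim")
}

#' Construct a QENS spectrum object
#'
#' @param energy energy-transfer grid, ueV (uniform).
#' @param intensity measured intensities.
#' @param sigma per-point uncertainties (positive).
#' @param resolution resolution function sampled on the same grid
#'   (normalised internally to unit area).
#' @param q momentum transfer, 1/A.
#' @param temperature sample temperature, K.
#' @return an object of class \code{"qens_spectrum"}.
#' @export
qens_spectrum <- function(energy, intensity, sigma = NULL, resolution,
                          q = NA_real_, temperature = NA_real_) {
  stopifnot(length(energy) == length(intensity),
            length(energy) == length(resolution),
            all(is.finite(intensity)))
  if (is.null(sigma)) sigma <- rep(1, length(energy))
  stopifnot(length(sigma) == length(energy), all(sigma > 0))
  de <- mean(diff(energy))
  resolution <- resolution / (sum(resolution) * de)
  structure(list(energy = energy, intensity = intensity, sigma = sigma,
                 resolution = resolution, q = q, temperature = temperature),
            class = "qens_spectrum")
}

#' @export
print.qens_spectrum <- function(x, ...) {
  cat(sprintf("QENS spectrum: Q = %.2f 1/A, T = %.0f K, %d points over [%g, %g] ueV\n",
              x$q, x$temperature, length(x$energy),
              min(x$energy), max(x$energy)))
  invisible(x)
}

#' @export
print.qens_sim <- function(x, ...) {
  cat("Synthetic QENS set:", length(x$spectra), "spectra;",
      "T =", paste(x$config$temperatures, collapse = ", "), "K;",
      "Q =", paste(x$config$q_values, collapse = ", "), "1/A\n")
  invisible(x)
}
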