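#' Configuration for the thermal-melt curve generator
#'
#' Boltzmann sigmoid unfolding signal
#' \code{F(T) = f_min + (f_max - f_min) / (1 + exp((tm - T)/slope))}
#' with additive Gaussian noise, emulating a CPM dye thermal-shift readout
#' on a 20-90 C ramp.
#'
#' @param tm midpoint (melting temperature), degrees C.
#' @param slope transition width parameter, degrees C (> 0).
#' @param f_min,f_max folded/unfolded fluorescence plateaus
#'   (\code{f_max > f_min} for the rising convention).
#' @param temp_range temperature grid, degrees C (default 20-90 at 0.5).
#' @param noise_sd additive noise sd, fluorescence units (default 1% of the
#'   plateau span).
#' @param seed optional RNG seed.
#' @return an object of class \code{"melt_sim_config"}.
#' @export
melt_sim_config <- function(tm = 55, slope = 2, f_min = 0.1, f_max = 1,
                            temp_range = seq(20, 90, by = 0.5),
                            noise_sd = 0.01 * (f_max - f_min),
                            seed = NULL) {
  stopifnot(f_max > f_min, slope > 0, length(temp_range) >= 10L,
            all(diff(temp_range) > 0), noise_sd >= 0)
  structure(list(tm = tm, slope = slope, f_min = f_min, f_max = f_max,
                 temp_range = temp_range, noise_sd = noise_sd, seed = seed),
            class = "melt_sim_config")
}

#' Simulate a thermal-unfolding fluorescence curve
#'
#' @param config a \code{\link{melt_sim_config}}.
#' @return a data frame with columns \code{temperature} (C) and
#'   \code{fluorescence}; the noiseless truth is attached as attribute
#'   \code{"truth"}.
#' @export
simulate_melt_curve <- function(config) {
  stopifnot(inherits(config, "melt_sim_config"))
  .with_seed(config$seed)
  tt <- config$temp_range
  ideal <- config$f_min + (config$f_max - config$f_min) /
    (1 + exp((config$tm - tt) / config$slope))
  out <- data.frame(temperature = tt,
                    fluorescence = ideal +
                      stats::rnorm(length(tt), 0, config$noise_sd))
  attr(out, "truth") <- ideal
  out
}
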