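# Internal numerical helpers shared across modules.

# hbar in ueV * ps; converts a Lorentzian HWHM (ueV) to a relaxation time (ps)
.HBAR_UEV_PS <- 658.2

# Gas constant, J/(mol K)
.R_GAS <- 8.314

#' Convert a Lorentzian half-width to a relaxation time
#'
#' Uses the reduced Planck constant hbar = 658.2 ueV ps, so that
#' \code{tau[ps] = 658.2 / Gamma[ueV]}.
#'
#' @param gamma_ueV half-width at half-maximum in ueV.
#' @return relaxation time in picoseconds.
#' @export
hwhm_to_tau <- function(gamma_ueV) {
  stopifnot(all(gamma_ueV > 0))
  .HBAR_UEV_PS / gamma_ueV
}

# unit-area Lorentzian, HWHM gamma
.lorentzian <- function(e, gamma) {
  gamma / (pi * (e^2 + gamma^2))
}

# sin(x)/x with the analytic limit at 0
.sinc <- function(x) {
  out <- rep(1, length(x))
  nz <- x != 0
  out[nz] <- sin(x[nz]) / x[nz]
  out
}

# Linear convolution of y with a kernel sampled on the same uniform grid,
# kernel centred on its middle element; returns a vector aligned with y.
# de is the grid step (the kernel is treated as a density: sum * de ~ area).
.conv_kernel <- function(y, kernel, de) {
  m <- length(kernel)
  n <- length(y)
  L <- stats::nextn(n + m - 1L)
  Y <- stats::fft(c(y, numeric(L - n)))
  K <- stats::fft(c(kernel, numeric(L - m)))
  full <- Re(stats::fft(Y * K, inverse = TRUE)) / L
  c0 <- (m + 1L) %/% 2L
  full[c0:(c0 + n - 1L)] * de
}

# running median with edge replication
.running_median <- function(x, k = 15L) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  k <- min(k, if (n %% 2L == 1L) n else n - 1L)
  if (k < 3L) return(x)
  sm <- stats::runmed(x, k, endrule = "median")
  as.numeric(sm)
}

# draw from a discrete distribution (normalised internally)
.rcat <- function(n, prob) {
  sample.int(length(prob), size = n, replace = TRUE, prob = prob)
}

# lightweight checksum for provenance stamping (not cryptographic)
.config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  v <- as.integer(raw)
  h <- 5381
  # fold in strides to keep this O(1)-ish for big configs
  idx <- seq(1L, length(v), by = max(1L, length(v) %/% 2048L))
  for (b in v[idx]) h <- (h * 33 + b) %% 1e9
  sprintf("%09.0f", h)
}

# set seed only when given; keep derived seeds under 2^31
.with_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed %% 2147483647))
  invisible(NULL)
}

.derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}
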