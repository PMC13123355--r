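#' Configuration for the single-molecule FRET trace generator
#'
#' Describes a continuous-time Markov model over discrete conformational
#' states, each with a characteristic FRET efficiency, observed through
#' donor/acceptor photon counting at a fixed frame time with additive
#' Gaussian channel noise and single-step photobleaching.
#'
#' @param state_means FRET efficiencies of the states, strictly increasing,
#'   all in (0, 1). Default: the four-state set 0.33/0.49/0.63/0.78.
#' @param rate_matrix transition-rate matrix (per second) between states:
#'   off-diagonals are non-negative, each diagonal equals minus its row's
#'   off-diagonal sum. If \code{NULL}, an equilibrium exchange matrix is
#'   built from \code{occupancies} and \code{k_ex} via
#'   \code{\link{equilibrium_rate_matrix}}.
#' @param occupancies target stationary state probabilities (used only when
#'   \code{rate_matrix} is NULL). Default uniform.
#' @param k_ex overall exchange rate (1/s) used to build the default rate
#'   matrix. Default 0.2/s, i.e. dwell times of several seconds -- slow
#'   exchange relative to the 100-ms frame, consistent with molecules
#'   sampling only a subset of states over an observation window.
#' @param frame_time camera exposure per frame, seconds (default 0.1).
#' @param total_intensity mean summed donor+acceptor photons per frame.
#' @param noise_sd per-channel additive Gaussian noise sd, photons.
#' @param bleach_rate per-frame probability of acceptor photobleaching;
#'   donor bleaching follows with the same per-frame rate.
#' @param n_traces number of molecules to simulate.
#' @param n_frames_max frames per trace before truncation.
#' @param stratify_initial allocate initial states by largest-remainder
#'   quotas from the stationary distribution instead of independent draws
#'   (default TRUE). With slow exchange the cohort's realised occupancy
#'   then tracks the stationary law closely, which is what an
#'   occupancy-matched simulated condition is meant to deliver.
#' @param seed optional RNG seed.
#' @return an object of class \code{"fret_sim_config"}.
#' @export
fret_sim_config <- function(state_means = c(0.33, 0.49, 0.63, 0.78),
                            rate_matrix = NULL,
                            occupancies = NULL,
                            k_ex = 0.2,
                            frame_time = 0.1,
                            total_intensity = 1000,
                            noise_sd = 50,
                            bleach_rate = 0.002,
                            n_traces = 200L,
                            n_frames_max = 500L,
                            stratify_initial = TRUE,
                            seed = NULL) {
  stopifnot(length(state_means) >= 1L,
            all(state_means > 0), all(state_means < 1),
            all(diff(state_means) > 0),
            frame_time > 0, total_intensity > 0, noise_sd >= 0,
            bleach_rate >= 0, bleach_rate <= 1,
            n_traces >= 1L, n_frames_max >= 1L)
  m <- length(state_means)
  if (is.null(rate_matrix)) {
    if (is.null(occupancies)) occupancies <- rep(1 / m, m)
    rate_matrix <- equilibrium_rate_matrix(occupancies, k_ex)
  }
  .check_rate_matrix(rate_matrix, m)
  structure(list(state_means = state_means, rate_matrix = rate_matrix,
                 frame_time = frame_time, total_intensity = total_intensity,
                 noise_sd = noise_sd, bleach_rate = bleach_rate,
                 n_traces = as.integer(n_traces),
                 n_frames_max = as.integer(n_frames_max),
                 stratify_initial = isTRUE(stratify_initial), seed = seed),
            class = "fret_sim_config")
}

#' Exchange-rate matrix with a prescribed stationary distribution
#'
#' Builds the rate matrix with off-diagonals \code{k[i, j] = k_ex * pi[j]},
#' whose stationary distribution is exactly \code{pi} for any overall
#' exchange rate \code{k_ex}.
#'
#' @param occupancies stationary probabilities (normalised internally).
#' @param k_ex overall exchange rate, 1/s.
#' @return a square rate matrix with rows summing to zero.
#' @export
equilibrium_rate_matrix <- function(occupancies, k_ex = 0.5) {
  stopifnot(all(occupancies >= 0), sum(occupancies) > 0, k_ex >= 0)
  p <- occupancies / sum(occupancies)
  m <- length(p)
  K <- k_ex * matrix(p, nrow = m, ncol = m, byrow = TRUE)
  diag(K) <- 0
  diag(K) <- -rowSums(K)
  K
}

.check_rate_matrix <- function(K, m) {
  if (!is.matrix(K) || nrow(K) != m || ncol(K) != m)
    stop("rate_matrix must be a ", m, "x", m, " matrix")
  off <- K; diag(off) <- 0
  if (any(off < 0)) stop("rate_matrix off-diagonals must be >= 0")
  if (any(abs(rowSums(K)) > 1e-8 * (1 + max(abs(K)))))
    stop("rate_matrix rows must sum to zero (conservative generator)")
  invisible(TRUE)
}

# Exact continuous-time Markov path over n_frames * dt seconds.
# Returns per-frame occupancy matrix (n_frames x m) and the majority state.
.sim_ctmc_frames <- function(K, n_frames, dt, init_prob,
                             init_state = NULL) {
  m <- nrow(K)
  occ <- matrix(0, n_frames, m)
  state <- if (is.null(init_state)) .rcat(1L, init_prob) else init_state
  t_now <- 0
  t_end <- n_frames * dt
  rates <- -diag(K)
  while (t_now < t_end) {
    r <- rates[state]
    t_next <- if (r <= 0) t_end else t_now + stats::rexp(1L, r)
    t_stop <- min(t_next, t_end)
    # credit occupancy of `state` over [t_now, t_stop)
    f0 <- floor(t_now / dt) + 1
    f1 <- ceiling(t_stop / dt)
    for (f in f0:f1) {
      lo <- (f - 1) * dt
      hi <- f * dt
      ov <- max(0, min(hi, t_stop) - max(lo, t_now))
      if (ov > 0) occ[f, state] <- occ[f, state] + ov / dt
    }
    if (t_next >= t_end) break
    p <- K[state, ]
    p[state] <- 0
    state <- .rcat(1L, p)
    t_now <- t_next
  }
  list(occupancy = occ, state = max.col(occ, ties.method = "first"))
}

#' Simulate single-molecule FRET intensity traces
#'
#' Each molecule follows a continuous-time Markov path over the configured
#' states, discretised at the frame time; the per-frame acceptor fraction is
#' the occupancy-weighted mean of the state efficiencies. Channel intensities
#' are \code{donor = total * (1 - E) + noise} and
#' \code{acceptor = total * E + noise}. After a geometric acceptor-bleach
#' time the acceptor drops to background and the donor recovers the full
#' intensity; a later geometric donor bleach drops both channels to
#' background. Ground truth (state path, per-frame ideal efficiency, bleach
#' frames) is carried alongside each trace.
#'
#' @param config a \code{\link{fret_sim_config}}.
#' @return an object of class \code{"fret_sim"}: a list with elements
#'   \code{traces} (list of per-molecule data frames with columns
#'   \code{frame, donor, acceptor, state_id, true_E, bleached}),
#'   \code{bleach_frame} (first acceptor-bleach frame per trace, NA if
#'   none), and the \code{config}.
#' @export
simulate_fret_traces <- function(config) {
  stopifnot(inherits(config, "fret_sim_config"))
  .with_seed(config$seed)
  m <- length(config$state_means)
  pi0 <- .stationary_dist(config$rate_matrix)
  traces <- vector("list", config$n_traces)
  bleach_frame <- rep(NA_integer_, config$n_traces)
  init_states <- if (isTRUE(config$stratify_initial))
    sample(.quota_states(pi0, config$n_traces)) else NULL
  for (i in seq_len(config$n_traces)) {
    nf <- config$n_frames_max
    path <- .sim_ctmc_frames(config$rate_matrix, nf, config$frame_time, pi0,
                             init_state = init_states[i])
    e_true <- as.numeric(path$occupancy %*% config$state_means)
    # single-step bleaching: acceptor first, then donor
    fa <- if (config$bleach_rate > 0)
      stats::rgeom(1L, config$bleach_rate) + 1L else NA_integer_
    fd <- if (config$bleach_rate > 0 && !is.na(fa) && fa <= nf)
      fa + stats::rgeom(1L, config$bleach_rate) + 1L else NA_integer_
    e_obs <- e_true
    donor_frac <- 1 - e_true
    if (!is.na(fa) && fa <= nf) {
      idx <- fa:nf
      e_obs[idx] <- 0
      donor_frac[idx] <- 1
      bleach_frame[i] <- fa
      if (!is.na(fd) && fd <= nf) {
        idx2 <- fd:nf
        donor_frac[idx2] <- 0
      }
    }
    donor <- config$total_intensity * donor_frac +
      stats::rnorm(nf, 0, config$noise_sd)
    acceptor <- config$total_intensity * e_obs +
      stats::rnorm(nf, 0, config$noise_sd)
    traces[[i]] <- data.frame(
      frame = seq_len(nf),
      donor = donor,
      acceptor = acceptor,
      state_id = path$state,
      true_E = e_true,
      bleached = !is.na(fa) & seq_len(nf) >= fa)
  }
  structure(list(traces = traces, bleach_frame = bleach_frame,
                 config = config),
            class = "fret_sim")
}

# largest-remainder allocation of n initial states to the law p
.quota_states <- function(p, n) {
  exact <- p * n
  base <- floor(exact)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  rep(seq_along(p), times = base)
}

.stationary_dist <- function(K) {
  m <- nrow(K)
  if (all(K == 0)) return(rep(1 / m, m))
  # solve pi K = 0, sum(pi) = 1
  A <- rbind(t(K), rep(1, m))
  b <- c(rep(0, m), 1)
  p <- stats::lm.fit(A, b)$coefficients
  p <- pmax(p, 0)
  p / sum(p)
}

#' @export
print.fret_sim <- function(x, ...) {
  cat("Synthetic smFRET data:", length(x$traces), "traces,",
      x$config$n_frames_max, "frames max,",
      length(x$config$state_means), "states at",
      paste(format(x$config$state_means), collapse = "/"), "\n")
  invisible(x)
}
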