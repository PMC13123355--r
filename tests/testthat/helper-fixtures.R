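# Shared fixtures, built in code at test time.

four_state_means <- c(0.33, 0.49, 0.63, 0.78)

# small four-state smFRET simulation with ground truth
small_fret_sim <- function(n_traces = 40, n_frames = 300, seed = 1, ...) {
  simulate_fret_traces(fret_sim_config(n_traces = n_traces,
                                       n_frames_max = n_frames,
                                       seed = seed, ...))
}

valid_fret_traces <- function(sim) {
  fts <- lapply(sim$traces, compute_fret)
  fts[vapply(fts, function(f) f$valid && f$n_valid >= 10L, logical(1))]
}

# rectangular toy spectra for the overlap-integral closed form
rect_donor <- function() data.frame(lambda = seq(540, 610, by = 0.5),
                                    intensity = as.numeric(
                                      seq(540, 610, by = 0.5) >= 550 &
                                      seq(540, 610, by = 0.5) <= 600))
rect_acceptor <- function(eps = 1e5) {
  lam <- seq(540, 610, by = 0.5)
  data.frame(lambda = lam, epsilon = eps * (lam >= 550 & lam <= 600))
}

default_q_grid <- seq(0.006, 0.25, by = 0.0015)

oligomer_basis <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- lapply(oligomer_bead_models(), debye_curve,
                       q_values = default_q_grid)
    cache
  }
})
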