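#' Gaussian decomposition of a pooled FRET-efficiency histogram
#'
#' Pools valid frames across molecules into a population histogram and fits
#' a sum of Gaussian components by least squares. Component means are by
#' default fixed at the supplied state efficiencies (e.g. from
#' \code{\link{stasi}}); widths are free but bounded below by a shot-noise
#' floor; state populations are the component areas normalised to 100%.
#' Per-bin standard errors are estimated by bootstrap over molecules.
#'
#' @param traces list of \code{\link{compute_fret}} results or numeric
#'   vectors of per-frame efficiencies.
#' @param state_means component means (>= 2 states).
#' @param n_bins number of histogram bins over [0, 1] (default 50).
#' @param fix_means keep component means fixed (default TRUE); otherwise
#'   they are initialised at \code{state_means} and refined.
#' @param weight_by "frame" pools every frame with equal weight (default);
#'   "molecule" gives every molecule equal total weight.
#' @param sd_floor lower bound on component sd (default 0.01).
#' @param sd_init initial component sd (default 0.05).
#' @param n_boot bootstrap replicates for per-bin standard errors
#'   (default 100; 0 disables).
#' @param seed optional RNG seed for the bootstrap.
#' @return an object of class \code{"fret_hist_fit"}: list with
#'   \code{breaks}, \code{mids}, \code{density}, \code{se} (per-bin),
#'   \code{components} (data frame mean/sd/weight/population_pct),
#'   \code{populations} (named %, summing to 100), \code{fitted}, and the
#'   fit object.
#' @export
fit_fret_histogram <- function(traces, state_means, n_bins = 50L,
                               fix_means = TRUE,
                               weight_by = c("frame", "molecule"),
                               sd_floor = 0.01, sd_init = 0.05,
                               n_boot = 100L, seed = NULL) {
  weight_by <- match.arg(weight_by)
  stopifnot(length(state_means) >= 2L, all(diff(state_means) > 0))
  ys <- .as_trace_list(traces)
  ys <- ys[lengths(ys) > 0L]
  if (!length(ys)) stop("no valid frames supplied")
  m <- length(state_means)
  n_par <- if (fix_means) 2L * m else 3L * m
  if (sum(lengths(ys)) < 5L * n_par)
    stop("fewer frames than 5x parameter count; fit refused")

  breaks <- seq(0, 1, length.out = n_bins + 1L)
  dens <- .pooled_density(ys, breaks, weight_by)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2

  fit <- .fit_gauss_sum(mids, dens, state_means, fix_means,
                        sd_floor, sd_init)
  comp <- fit$components
  pops <- 100 * comp$weight / sum(comp$weight)
  comp$population_pct <- pops
  names(pops) <- sprintf("%.2f", comp$mean)

  se <- rep(NA_real_, n_bins)
  if (n_boot > 0L && length(ys) > 1L) {
    .with_seed(seed)
    boot <- matrix(NA_real_, n_boot, n_bins)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(length(ys), replace = TRUE)
      boot[b, ] <- .pooled_density(ys[idx], breaks, weight_by)
    }
    se <- apply(boot, 2, stats::sd)
  }

  structure(list(breaks = breaks, mids = mids, density = dens, se = se,
                 components = comp, populations = pops,
                 fitted = fit$fitted, n_frames = sum(lengths(ys)),
                 n_molecules = length(ys), converged = fit$converged),
            class = "fret_hist_fit")
}

.pooled_density <- function(ys, breaks, weight_by) {
  nb <- length(breaks) - 1L
  if (weight_by == "frame") {
    y <- unlist(ys, use.names = FALSE)
    y <- pmin(pmax(y, 0), 1)
    h <- graphics::hist(y, breaks = breaks, plot = FALSE)
    h$density
  } else {
    acc <- numeric(nb)
    for (y in ys) {
      y <- pmin(pmax(y, 0), 1)
      h <- graphics::hist(y, breaks = breaks, plot = FALSE)
      acc <- acc + h$density
    }
    acc / length(ys)
  }
}

.fit_gauss_sum <- function(x, dens, means, fix_means, sd_floor, sd_init) {
  m <- length(means)
  # weight initialisation: mass nearest each component mean
  near <- apply(abs(outer(x, means, "-")), 1, which.min)
  dx <- mean(diff(x))
  w0 <- vapply(seq_len(m), function(k) sum(dens[near == k]) * dx, numeric(1))
  w0 <- pmax(w0, 1e-3)
  model_fun <- function(p) {
    w <- exp(p[seq_len(m)])
    s <- sd_floor + exp(p[m + seq_len(m)])
    mu <- if (fix_means) means else p[2L * m + seq_len(m)]
    rowSums(vapply(seq_len(m),
                   function(k) w[k] * stats::dnorm(x, mu[k], s[k]),
                   numeric(length(x))))
  }
  p0 <- c(log(w0), rep(log(max(sd_init - sd_floor, 1e-3)), m),
          if (!fix_means) means)
  res_fun <- function(p) model_fun(p) - dens
  nls <- minpack.lm::nls.lm(p0, fn = res_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200))
  p <- nls$par
  w <- exp(p[seq_len(m)])
  s <- sd_floor + exp(p[m + seq_len(m)])
  mu <- if (fix_means) means else p[2L * m + seq_len(m)]
  list(components = data.frame(mean = mu, sd = s, weight = w),
       fitted = model_fun(p),
       converged = nls$info %in% 1:4)
}

#' @export
print.fret_hist_fit <- function(x, ...) {
  cat(sprintf("FRET histogram fit: %d molecules, %d frames, %d components\n",
              x$n_molecules, x$n_frames, nrow(x$components)))
  tab <- x$components
  tab$population_pct <- round(tab$population_pct, 1)
  print(tab, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
coef.fret_hist_fit <- function(object, ...) object$populations

#' @export
plot.fret_hist_fit <- function(x, ...) {
  graphics::plot(x$mids, x$density, type = "h", xlab = "FRET efficiency",
                 ylab = "density", ...)
  graphics::lines(x$mids, x$fitted, lwd = 2)
  for (k in seq_len(nrow(x$components)))
    graphics::lines(x$mids, x$components$weight[k] *
                      stats::dnorm(x$mids, x$components$mean[k],
                                   x$components$sd[k]), lty = 2)
  invisible(x)
}
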