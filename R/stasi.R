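#' Step transition and state identification (STaSI)
#'
#' Identifies discrete states in piecewise-constant, noisy single-molecule
#' trajectories. The procedure: (i) the noise sd is estimated from the
#' robust scale of first differences (median absolute deviation of Haar
#' detail coefficients divided by 0.6745 * sqrt(2)); (ii) each trace is
#' split recursively at the frame maximising the two-sample t statistic
#' between the left and right means, accepted while the statistic exceeds
#' the critical value (by default the 99.9th percentile of the null t
#' distribution for the segment length); (iii) segment means are pooled
#' across traces and merged agglomeratively (minimum within-group
#' sum-of-squares increase, adjacent in mean); (iv) for each candidate
#' number of states m the minimum description length
#' \deqn{MDL(m) = \frac{\sum r^2}{2 \sigma^2 \ln 2} +
#'   \frac{p}{2} \log_2 n, \quad p = m + \#\mathrm{change\ points}}
#' is evaluated and the m minimising it is returned.
#'
#' @param traces list of \code{\link{compute_fret}} results, or a list of
#'   numeric vectors (one trajectory each), or a single numeric vector.
#' @param max_states largest candidate state count (default 8).
#' @param alpha tail probability of the change-point acceptance test
#'   (default 0.001, i.e. the 99.9th percentile).
#' @param min_seg minimum segment length in frames (default 2).
#' @return an object of class \code{"stasi_fit"}: list with
#'   \code{n_states}, \code{means} (ascending), \code{sigma},
#'   \code{mdl} (data frame of MDL per candidate m), \code{segments}
#'   (trace, start, end, mean, state), and \code{assignments} (list of
#'   per-frame state indices per trace).
#' @export
stasi <- function(traces, max_states = 8L, alpha = 0.001, min_seg = 2L) {
  ys <- .as_trace_list(traces)
  ys <- ys[vapply(ys, length, integer(1)) >= 10L]
  if (!length(ys)) stop("need at least one trace with >= 10 valid frames")
  n_total <- sum(lengths(ys))

  sigma <- .haar_sigma(ys)
  if (sigma < .Machine$double.eps^0.5) {
    return(.stasi_degenerate(ys, n_total))
  }

  # -- change-point segmentation per trace -------------------------------
  segs <- NULL
  for (i in seq_along(ys)) {
    y <- ys[[i]]
    cps <- sort(.split_recursive(y, 1L, length(y), sigma, alpha, min_seg))
    bounds <- c(0L, cps, length(y))
    for (k in seq_len(length(bounds) - 1L)) {
      a <- bounds[k] + 1L
      b <- bounds[k + 1L]
      seg_y <- y[a:b]
      segs <- rbind(segs, data.frame(
        trace = i, start = a, end = b, n = b - a + 1L,
        mean = mean(seg_y), ss = sum((seg_y - mean(seg_y))^2)))
    }
  }

  # -- agglomerative merging of segment means ----------------------------
  merge_path <- .merge_levels(segs$mean, segs$n, max_states)

  # -- MDL model selection ----------------------------------------------
  cand <- sort(as.integer(names(merge_path)))
  mdl <- data.frame(m = cand, mdl = NA_real_)
  n_traces <- max(segs$trace)
  for (j in seq_along(cand)) {
    lab <- merge_path[[as.character(cand[j])]]
    mu <- vapply(split(segs$mean * segs$n, lab$group[lab$member]),
                 sum, numeric(1)) /
      vapply(split(segs$n, lab$group[lab$member]), sum, numeric(1))
    seg_state <- lab$group[lab$member]
    rss <- sum(segs$ss + segs$n * (segs$mean - mu[seg_state])^2)
    # change points: transitions between distinct states within a trace
    ncp <- 0L
    for (tr in seq_len(n_traces)) {
      st <- seg_state[segs$trace == tr]
      if (length(st) > 1L) ncp <- ncp + sum(diff(st) != 0L)
    }
    p <- cand[j] + ncp
    # two-part code: parameter cost for the state means and change-point
    # locations, plus the assignment cost of mapping each segment to one
    # of m states (log2 m bits per segment; zero for m = 1). Without the
    # assignment term the criterion keeps splitting states when many
    # traces are pooled, because a split costs O(log n) bits but explains
    # the sampling scatter of hundreds of segment means.
    mdl$mdl[j] <- rss / (2 * sigma^2 * log(2)) +
      (p / 2) * log2(n_total) + nrow(segs) * log2(cand[j])
  }
  m_best <- mdl$m[which.min(mdl$mdl)]

  lab <- merge_path[[as.character(m_best)]]
  seg_state0 <- lab$group[lab$member]
  mu0 <- vapply(split(segs$mean * segs$n, seg_state0), sum, numeric(1)) /
    vapply(split(segs$n, seg_state0), sum, numeric(1))
  ord <- order(mu0)
  relabel <- match(seq_along(mu0), ord)
  means <- as.numeric(mu0[ord])
  segs$state <- relabel[seg_state0]

  assignments <- vector("list", length(ys))
  for (i in seq_along(ys)) {
    a <- integer(length(ys[[i]]))
    si <- segs[segs$trace == i, ]
    for (k in seq_len(nrow(si))) a[si$start[k]:si$end[k]] <- si$state[k]
    assignments[[i]] <- a
  }

  structure(list(n_states = as.integer(m_best), means = means,
                 sigma = sigma, mdl = mdl,
                 segments = segs[, c("trace", "start", "end", "n",
                                     "mean", "state")],
                 assignments = assignments, n_frames = n_total),
            class = "stasi_fit")
}

.as_trace_list <- function(traces) {
  if (is.numeric(traces)) traces <- list(traces)
  if (inherits(traces, "fret_trace")) traces <- list(traces)
  lapply(traces, function(tr) {
    if (inherits(tr, "fret_trace")) tr$E else as.numeric(tr)
  })
}

# robust noise scale from pooled first differences
.haar_sigma <- function(ys) {
  d <- unlist(lapply(ys, diff), use.names = FALSE)
  if (!length(d)) return(0)
  stats::median(abs(d - stats::median(d))) / (0.6745 * sqrt(2))
}

# recursive binary segmentation; returns change-point indices (end of left
# segment, absolute within the trace)
.split_recursive <- function(y, lo, hi, sigma, alpha, min_seg) {
  n <- hi - lo + 1L
  if (n < 2L * min_seg) return(integer(0))
  seg <- y[lo:hi]
  cs <- cumsum(seg)
  tot <- cs[n]
  k <- min_seg:(n - min_seg)          # split after local index k
  mean_l <- cs[k] / k
  mean_r <- (tot - cs[k]) / (n - k)
  tstat <- abs(mean_l - mean_r) / (sigma * sqrt(1 / k + 1 / (n - k)))
  kb <- k[which.max(tstat)]
  if (max(tstat) <= stats::qt(1 - alpha, df = max(n - 2L, 1L)))
    return(integer(0))
  cp <- lo + kb - 1L
  c(cp,
    .split_recursive(y, lo, cp, sigma, alpha, min_seg),
    .split_recursive(y, cp + 1L, hi, sigma, alpha, min_seg))
}

# bottom-up merging of 1-D levels (weighted); returns, for each candidate
# state count m <= max_states, the mapping segment -> group
.merge_levels <- function(mu, w, max_states) {
  ord <- order(mu)
  cl_mu <- mu[ord]
  cl_w <- as.numeric(w[ord])
  member <- integer(length(mu))      # segment -> cluster id (current)
  member[ord] <- seq_along(ord)
  active <- seq_along(cl_mu)
  out <- list()
  snapshot <- function() {
    # map cluster id -> dense group index among active
    grp <- integer(length(cl_mu))
    grp[active] <- seq_along(active)
    list(member = member, group = grp)
  }
  if (length(active) <= max_states)
    out[[as.character(length(active))]] <- snapshot()
  while (length(active) > 1L) {
    am <- cl_mu[active]
    aw <- cl_w[active]
    cost <- (aw[-length(aw)] * aw[-1]) / (aw[-length(aw)] + aw[-1]) *
      diff(am)^2
    j <- which.min(cost)              # merge active[j] and active[j+1]
    a <- active[j]; b <- active[j + 1L]
    new_w <- cl_w[a] + cl_w[b]
    cl_mu[a] <- (cl_mu[a] * cl_w[a] + cl_mu[b] * cl_w[b]) / new_w
    cl_w[a] <- new_w
    member[member == b] <- a
    active <- active[active != b]
    if (length(active) <= max_states)
      out[[as.character(length(active))]] <- snapshot()
  }
  out
}

# noiseless degenerate input: unique-level counting
.stasi_degenerate <- function(ys, n_total) {
  all_y <- unlist(ys, use.names = FALSE)
  lv <- sort(unique(round(all_y, 12)))
  assignments <- lapply(ys, function(y) match(round(y, 12), lv))
  segs <- NULL
  for (i in seq_along(ys)) {
    a <- assignments[[i]]
    r <- rle(a)
    e <- cumsum(r$lengths)
    s <- e - r$lengths + 1L
    segs <- rbind(segs, data.frame(trace = i, start = s, end = e,
                                   n = r$lengths, mean = lv[r$values],
                                   state = r$values))
  }
  structure(list(n_states = length(lv), means = lv, sigma = 0,
                 mdl = data.frame(m = length(lv), mdl = NA_real_),
                 segments = segs, assignments = assignments,
                 n_frames = n_total),
            class = "stasi_fit")
}

#' @export
print.stasi_fit <- function(x, ...) {
  cat(sprintf("STaSI fit: %d states over %d frames (sigma = %.4f)\n",
              x$n_states, x$n_frames, x$sigma))
  cat("State means:", paste(sprintf("%.3f", x$means), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.stasi_fit <- function(object, ...) {
  occ <- table(factor(unlist(object$assignments),
                      levels = seq_len(object$n_states)))
  tab <- data.frame(state = seq_len(object$n_states),
                    mean_E = object$means,
                    frames = as.integer(occ),
                    fraction = as.numeric(occ) / object$n_frames)
  cat(sprintf("STaSI fit: %d states, MDL-selected out of m = %s\n",
              object$n_states,
              paste(range(object$mdl$m), collapse = "..")))
  print(tab, row.names = FALSE)
  invisible(tab)
}

#' @export
coef.stasi_fit <- function(object, ...) object$means

#' @export
plot.stasi_fit <- function(x, ...) {
  graphics::plot(x$mdl$m, x$mdl$mdl, type = "b", xlab = "number of states",
                 ylab = "MDL (bits)", ...)
  graphics::abline(v = x$n_states, lty = 2)
  invisible(x)
}
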