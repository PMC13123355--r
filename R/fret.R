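#' FRET efficiency trace from donor/acceptor intensities
#'
#' Converts a raw intensity trace to a per-frame FRET efficiency
#' \code{E = I_A / (I_D + I_A)} up to the detected photobleaching point,
#' after per-channel background subtraction.
#'
#' Bleach detection combines two tests on running medians (window
#' \code{med_window}): the terminal donor bleach is the first frame where
#' the summed intensity falls below \code{sum_threshold} times its running
#' median; the acceptor bleach (which leaves the sum unchanged because the
#' donor recovers the transferred photons) is the first frame where the
#' acceptor channel falls below \code{acceptor_floor} times the running
#' median of the sum, sustained for at least 3 frames. The efficiency trace
#' ends at the earlier of the two. Backgrounds are the post-bleach channel
#' means when a bleach is found, else the modal bin of the lowest intensity
#' decile.
#'
#' @param trace data frame with columns \code{donor} and \code{acceptor}
#'   (a member of \code{\link{simulate_fret_traces}}'s \code{traces} works
#'   directly), or a two-column matrix.
#' @param frame_time frame duration, s.
#' @param sum_threshold fraction of the running-median total below which the
#'   molecule counts as fully bleached (default 0.5).
#' @param acceptor_floor fraction of the running-median total below which
#'   the acceptor counts as bleached (default 0.15).
#' @param med_window running-median window, frames.
#' @param clip clip efficiencies into [0, 1] (default TRUE).
#' @return an object of class \code{"fret_trace"}: list with \code{E}
#'   (efficiency per valid frame), \code{n_valid}, \code{bleach_frame}
#'   (NA if no bleach found), \code{background} (donor, acceptor), and
#'   \code{valid} flag.
#' @export
compute_fret <- function(trace, frame_time = 0.1, sum_threshold = 0.5,
                         acceptor_floor = 0.15, med_window = 15L,
                         clip = TRUE) {
  if (is.matrix(trace)) trace <- data.frame(donor = trace[, 1],
                                            acceptor = trace[, 2])
  stopifnot(all(c("donor", "acceptor") %in% names(trace)),
            nrow(trace) >= 1L, frame_time > 0)
  don <- trace$donor
  acc <- trace$acceptor
  total <- don + acc
  if (all(abs(total) < .Machine$double.eps)) {
    return(structure(list(E = numeric(0), n_valid = 0L,
                          bleach_frame = NA_integer_,
                          background = c(donor = 0, acceptor = 0),
                          frame_time = frame_time, valid = FALSE),
                     class = "fret_trace"))
  }
  med_tot <- .running_median(total, med_window)
  # terminal (donor) bleach: total collapses
  donor_bleach <- .first_sustained(total < sum_threshold * med_tot, 1L)
  # acceptor bleach: acceptor near zero while total persists
  acc_bleach <- .first_sustained(acc < acceptor_floor * med_tot, 3L)
  if (!is.na(acc_bleach)) {
    # extend a confirmed bleach backwards over adjacent low frames, so
    # noisy edge frames just above the floor do not leak into the trace
    while (acc_bleach > 1L &&
           acc[acc_bleach - 1L] < 2 * acceptor_floor * med_tot[acc_bleach - 1L])
      acc_bleach <- acc_bleach - 1L
  }
  cand <- c(donor_bleach, acc_bleach)
  bleach <- if (all(is.na(cand))) NA_integer_ else min(cand, na.rm = TRUE)
  n <- nrow(trace)
  bg <- .trace_background(don, acc, bleach, n)
  don_c <- don - bg["donor"]
  acc_c <- acc - bg["acceptor"]
  last <- if (is.na(bleach)) n else bleach - 1L
  if (last < 1L) {
    return(structure(list(E = numeric(0), n_valid = 0L,
                          bleach_frame = bleach, background = bg,
                          frame_time = frame_time, valid = FALSE),
                     class = "fret_trace"))
  }
  idx <- seq_len(last)
  e <- acc_c[idx] / (don_c[idx] + acc_c[idx])
  e[!is.finite(e)] <- NA_real_
  if (clip) e <- pmin(pmax(e, 0), 1)
  e <- e[!is.na(e)]
  structure(list(E = e, n_valid = length(e), bleach_frame = bleach,
                 background = bg, frame_time = frame_time,
                 valid = length(e) > 0L),
            class = "fret_trace")
}

.first_sustained <- function(flag, run = 3L) {
  flag[is.na(flag)] <- FALSE
  if (!any(flag)) return(NA_integer_)
  if (run <= 1L) return(which(flag)[1])
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # a shorter run is accepted when it reaches the end of the trace: the
  # sustain requirement cannot be checked past the last frame
  hit <- which(r$values & (r$lengths >= run | ends == length(flag)))
  if (!length(hit)) NA_integer_ else starts[hit[1]]
}

.trace_background <- function(don, acc, bleach, n) {
  if (!is.na(bleach) && bleach < n) {
    # donor background only after full bleach; detect via post-bleach total
    post <- bleach:n
    tot_post <- don[post] + acc[post]
    full <- post[tot_post < 0.25 * stats::median(don + acc)]
    bg_d <- if (length(full) >= 3L) mean(don[full]) else .modal_low(don)
    bg_a <- mean(acc[post])
    # acceptor post-bleach mean can sit on donor-only frames; keep it if
    # small, else fall back to the modal low bin
    if (!is.finite(bg_a) || bg_a > 0.25 * stats::median(don + acc))
      bg_a <- .modal_low(acc)
    c(donor = bg_d, acceptor = bg_a)
  } else {
    c(donor = .modal_low(don), acceptor = .modal_low(acc))
  }
}

# modal bin of the lowest-decile intensities, a crude dark-level estimate;
# only trusted when that mode is genuinely dark (well below the typical
# signal) -- otherwise the trace never bleached and the low decile is
# signal, so the baseline is taken as already corrected (zero)
.modal_low <- function(x) {
  lo <- x[x <= stats::quantile(x, 0.1, names = FALSE)]
  if (length(lo) < 3L) return(0)
  h <- graphics::hist(lo, breaks = "FD", plot = FALSE)
  mode_lo <- h$mids[which.max(h$counts)]
  if (is.finite(mode_lo) && abs(mode_lo) < 0.15 * abs(stats::median(x)))
    mode_lo else 0
}

#' @export
print.fret_trace <- function(x, ...) {
  cat(sprintf("FRET trace: %d valid frames%s, mean E = %.3f\n",
              x$n_valid,
              if (is.na(x$bleach_frame)) " (no bleach detected)"
              else sprintf(" (bleach at frame %d)", x$bleach_frame),
              if (x$n_valid) mean(x$E) else NA_real_))
  invisible(x)
}

#' @export
plot.fret_trace <- function(x, ...) {
  graphics::plot(seq_along(x$E) * x$frame_time, x$E, type = "s",
                 xlab = "time (s)", ylab = "FRET efficiency",
                 ylim = c(0, 1), ...)
  invisible(x)
}
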