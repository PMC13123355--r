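#' Bead models and Debye-formula scattering curves
#'
#' A bead model is a set of point scatterers (bead centres in Angstrom with
#' a scattering length each) used to compute theoretical small-angle curves
#' through the Debye formula. Coarse sphere-packing models of the monomer
#' and of loosely associated oligomers stand in for atomistic conformers.
#'
#' @param coordinates numeric matrix, one bead per row, columns x/y/z in A.
#' @param f scattering length per bead (scalar or per-bead vector).
#' @param label species name, e.g. "monomer".
#' @return an object of class \code{"bead_model"}.
#' @export
bead_model <- function(coordinates, f = 1, label = "model") {
  coordinates <- as.matrix(coordinates)
  stopifnot(nrow(coordinates) >= 1L, ncol(coordinates) == 3L,
            all(is.finite(coordinates)))
  f <- rep_len(f, nrow(coordinates))
  structure(list(coordinates = coordinates, f = f, label = label),
            class = "bead_model")
}

#' @export
print.bead_model <- function(x, ...) {
  cat(sprintf("Bead model '%s': %d beads, Rg = %.1f A\n",
              x$label, nrow(x$coordinates), bead_rg(x)))
  invisible(x)
}

#' Radius of gyration of a bead model
#'
#' Scattering-length-weighted Rg about the centre of mass.
#'
#' @param model a \code{\link{bead_model}}.
#' @return Rg in Angstrom.
#' @export
bead_rg <- function(model) {
  w <- model$f / sum(model$f)
  ctr <- colSums(model$coordinates * w)
  d2 <- rowSums(sweep(model$coordinates, 2, ctr)^2)
  sqrt(sum(w * d2))
}

#' Filled-sphere bead model
#'
#' Beads on a cubic lattice inside a sphere; the continuous sphere of radius
#' R has Rg = R * sqrt(3/5), which the lattice model approaches as the
#' spacing shrinks.
#'
#' @param radius sphere radius, A.
#' @param spacing lattice spacing, A (default radius/5.5).
#' @param center sphere centre (length-3).
#' @param f scattering length per bead.
#' @param label species name.
#' @return a \code{\link{bead_model}}.
#' @export
sphere_bead_model <- function(radius, spacing = radius / 5.5,
                              center = c(0, 0, 0), f = 1,
                              label = "sphere") {
  stopifnot(radius > 0, spacing > 0)
  g <- seq(-radius, radius, by = spacing)
  xyz <- as.matrix(expand.grid(x = g, y = g, z = g))
  keep <- rowSums(xyz^2) <= radius^2
  xyz <- sweep(xyz[keep, , drop = FALSE], 2, -center)
  bead_model(xyz, f = f, label = label)
}

#' Oligomer bead-model fixtures
#'
#' Coarse models of the species classes used in ensemble decomposition:
#' a monomer (filled sphere), a dimer and a square-planar tetramer whose
#' subunit surfaces are separated by a configurable gap (default 30 A,
#' i.e. loosely associated, micelle-like organisation rather than tight
#' interfaces), and a compact trimer of touching spheres.
#'
#' @param subunit_radius radius of one subunit sphere, A (default 30).
#' @param gap surface-to-surface separation of dimer/tetramer subunits, A.
#' @param spacing bead lattice spacing, A.
#' @return named list of \code{\link{bead_model}}s:
#'   monomer, dimer, trimer, tetramer.
#' @export
oligomer_bead_models <- function(subunit_radius = 30, gap = 30,
                                 spacing = subunit_radius / 5) {
  r <- subunit_radius
  d_loose <- 2 * r + gap   # centre-to-centre with a gap
  d_tight <- 2 * r         # touching spheres
  place <- function(centers, label) {
    parts <- lapply(seq_len(nrow(centers)), function(i)
      sphere_bead_model(r, spacing, center = centers[i, ])$coordinates)
    bead_model(do.call(rbind, parts), label = label)
  }
  list(
    monomer = sphere_bead_model(r, spacing, label = "monomer"),
    dimer = place(rbind(c(-d_loose / 2, 0, 0), c(d_loose / 2, 0, 0)),
                  "dimer"),
    trimer = place(d_tight / sqrt(3) * rbind(
      c(1, 0, 0),
      c(-0.5, sqrt(3) / 2, 0),
      c(-0.5, -sqrt(3) / 2, 0)), "trimer"),
    tetramer = place(rbind(
      c(-d_loose / 2, -d_loose / 2, 0), c(d_loose / 2, -d_loose / 2, 0),
      c(-d_loose / 2, d_loose / 2, 0), c(d_loose / 2, d_loose / 2, 0)),
      "tetramer"))
}

#' Random decoy bead models
#'
#' Generates plausible but wrong candidate species for ensemble-selection
#' searches: random triaxial ellipsoids and random two/three-blob composites
#' spanning a range of sizes.
#'
#' @param n number of decoys.
#' @param size_range range of characteristic semi-axis / blob radius, A.
#' @param seed optional RNG seed.
#' @return list of \code{\link{bead_model}}s labelled decoy_1..decoy_n.
#' @export
decoy_bead_models <- function(n, size_range = c(18, 70), seed = NULL) {
  .with_seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    if (stats::runif(1) < 0.5) {
      ax <- stats::runif(3, size_range[1], size_range[2])
      sp <- max(ax) / 6
      g <- seq(-max(ax), max(ax), by = sp)
      xyz <- as.matrix(expand.grid(x = g, y = g, z = g))
      keep <- (xyz[, 1] / ax[1])^2 + (xyz[, 2] / ax[2])^2 +
        (xyz[, 3] / ax[3])^2 <= 1
      out[[i]] <- bead_model(xyz[keep, , drop = FALSE],
                             label = sprintf("decoy_%d", i))
    } else {
      k <- sample(2:3, 1)
      r <- stats::runif(1, size_range[1], size_range[2] / 2)
      sep <- stats::runif(1, 2 * r, 2 * r + 60)
      centers <- matrix(stats::rnorm(3 * k), k, 3)
      centers <- centers / sqrt(rowSums(centers^2)) * sep / 2
      parts <- lapply(seq_len(k), function(j)
        sphere_bead_model(r, r / 5, center = centers[j, ])$coordinates)
      out[[i]] <- bead_model(do.call(rbind, parts),
                             label = sprintf("decoy_%d", i))
    }
  }
  names(out) <- vapply(out, function(m) m$label, character(1))
  out
}

#' Theoretical scattering curve of a bead model (Debye formula)
#'
#' \deqn{I(q) = \sum_i \sum_j f_i f_j \frac{\sin(q r_{ij})}{q r_{ij}}}
#' with the self term equal to \eqn{f_i^2}, so \eqn{I(0) = (\sum_i f_i)^2};
#' the q -> 0 limit is handled analytically.
#'
#' @param model a \code{\link{bead_model}}.
#' @param q_values momentum transfer grid, 1/A (q = 0 allowed).
#' @param rel_error relative uncertainty assigned to the sigma column.
#' @return a \code{\link{scattering_curve}} (points with q > 0; the exact
#'   I(0) is stored as attribute \code{"I0"}).
#' @examples
#' # two beads at 30 A: I(q) = 2 (1 + sinc(30 q))
#' pair <- bead_model(rbind(c(0, 0, 0), c(30, 0, 0)))
#' debye_curve(pair, c(0.05, 0.1, 0.2))$intensity
#' @export
debye_curve <- function(model, q_values, rel_error = 0.01) {
  stopifnot(inherits(model, "bead_model"), all(q_values >= 0))
  f <- model$f
  # equal scattering lengths dominate in practice; keep the general case
  d <- as.vector(stats::dist(model$coordinates))
  equal_f <- length(unique(f)) == 1L
  i0 <- sum(f)^2
  q_pos <- sort(unique(q_values[q_values > 0]))
  # large models: histogram the pair distances (bin width chosen so that
  # q * delta stays ~0.02, i.e. sinc discretisation error < 1e-4)
  if (equal_f && length(d) > 2e5) {
    delta <- min(0.02 / max(q_pos), max(d) / 200)
    bins <- floor(d / delta) + 1L
    cnt <- tabulate(bins)
    r_mid <- (seq_along(cnt) - 0.5) * delta
    keep <- cnt > 0L
    cnt <- cnt[keep]; r_mid <- r_mid[keep]
    intens <- vapply(q_pos, function(q)
      f[1]^2 * (length(f) + 2 * sum(cnt * .sinc(q * r_mid))),
      numeric(1))
  } else {
    intens <- vapply(q_pos, function(q) {
      if (equal_f) {
        f[1]^2 * (length(f) + 2 * sum(.sinc(q * d)))
      } else {
        idx <- utils::combn(length(f), 2L)
        sum(f^2) + 2 * sum(f[idx[1, ]] * f[idx[2, ]] * .sinc(q * d))
      }
    }, numeric(1))
  }
  # the orientational average is non-negative; clamp tiny negative
  # excursions from the binned pair-distance approximation
  intens <- pmax(intens, i0 * 1e-12)
  curve <- scattering_curve(q_pos, intens, rel_error * intens,
                            label = model$label)
  attr(curve, "I0") <- i0
  curve
}

#' Mix basis scattering curves into a noisy composite
#'
#' \code{I_mix(q) = sum_k w_k I_k(q)} with multiplicative Gaussian noise of
#' sd \code{noise_rel * I}; the sigma column is set to \code{noise_rel * I}.
#'
#' @param basis list of \code{\link{scattering_curve}}s on a common q grid.
#' @param weights non-negative mixing weights, one per basis member.
#' @param noise_rel relative noise level (0 for a noiseless mixture).
#' @param seed optional RNG seed.
#' @return a \code{\link{scattering_curve}}.
#' @export
simulate_sas_mixture <- function(basis, weights, noise_rel = 0.01,
                                 seed = NULL) {
  stopifnot(length(basis) == length(weights), all(weights >= 0))
  q0 <- basis[[1]]$q
  for (b in basis)
    if (length(b$q) != length(q0) || max(abs(b$q - q0)) > 1e-9)
      stop("all basis curves must share one q grid")
  .with_seed(seed)
  imix <- Reduce(`+`, Map(function(b, w) w * b$intensity, basis, weights))
  noisy <- imix * (1 + stats::rnorm(length(imix), 0, noise_rel))
  sig <- if (noise_rel > 0) noise_rel * abs(imix)
         else pmax(1e-12 * max(abs(imix)), abs(imix) * 1e-12)
  scattering_curve(q0, noisy, sig, label = "mixture")
}
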