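#' Genetic-algorithm minimal-ensemble selection
#'
#' Searches, for each ensemble size 1..n_max, for the subset of candidate
#' curves whose non-negative linear combination (weights from exact NNLS,
#' \code{\link{nnls_weights}}) best fits the target curve by reduced
#' chi-square. The GA uses tournament selection, uniform crossover on
#' member slots, per-slot mutation swapping in random pool members,
#' elitism, and duplicate-free chromosomes; each size is restarted
#' \code{iterations} times from randomised parents and the best of all
#' restarts kept. The overall best across sizes is reported with
#' species-class fractions aggregated from member labels and weights.
#'
#' @param pool named list of candidate \code{\link{scattering_curve}}s.
#' @param target measured \code{\link{scattering_curve}} with
#'   uncertainties.
#' @param species character vector assigning each pool member to a class
#'   (monomer/dimer/...); defaults to the label text before the first
#'   underscore.
#' @param n_max largest ensemble size (default 5).
#' @param generations generations per restart (default 100).
#' @param iterations randomised restarts per size (default 5).
#' @param population_size GA population (default 64).
#' @param mutation_rate per-slot mutation probability (default 0.1).
#' @param stall_generations stop a restart early once the best fitness has
#'   not improved for this many generations (default 25; set to
#'   \code{generations} to disable). Elitism makes the early exit safe:
#'   the incumbent best cannot be lost.
#' @param seed optional RNG seed.
#' @return an object of class \code{"ensemble_fit"}: list with
#'   \code{members} (labels), \code{weights} (sum 1), \code{scale},
#'   \code{chi2_red}, \code{size}, \code{class_fractions},
#'   \code{by_size} (best chi2 per ensemble size) and \code{history}
#'   (best fitness per generation for the winning restart).
#' @export
ga_select <- function(pool, target, species = NULL, n_max = 5L,
                      generations = 100L, iterations = 5L,
                      population_size = 64L, mutation_rate = 0.1,
                      stall_generations = 25L, seed = NULL) {
  np <- length(pool)
  if (np < n_max) stop("candidate pool smaller than requested ensemble size")
  stopifnot(inherits(target, "sas_curve"))
  .with_seed(seed)
  labs <- vapply(seq_along(pool), function(k) {
    if (!is.null(names(pool)) && nzchar(names(pool)[k])) names(pool)[k]
    else if (!is.null(pool[[k]]$label)) pool[[k]]$label
    else sprintf("member_%d", k)
  }, character(1))
  if (is.null(species)) species <- sub("_.*$", "", labs)
  stopifnot(length(species) == np)

  B <- .basis_on_grid(pool, target$q)
  A <- B / target$sigma
  b <- target$intensity / target$sigma
  nq <- length(b)

  memo <- new.env(parent = emptyenv())
  subset_fit <- function(idx) {
    idx <- sort(idx)
    key <- paste(idx, collapse = ",")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    sol <- pracma::lsqnonneg(A[, idx, drop = FALSE], b)
    chi2 <- sum((b - A[, idx, drop = FALSE] %*% sol$x)^2) /
      max(nq - length(idx), 1L)
    out <- list(chi2 = chi2, coefs = sol$x)
    memo[[key]] <- out
    out
  }

  best_by_size <- vector("list", n_max)
  for (m in seq_len(n_max)) {
    size_best <- NULL
    for (it in seq_len(iterations)) {
      run <- .ga_run(np, m, subset_fit, generations, population_size,
                     mutation_rate, stall_generations)
      if (is.null(size_best) || run$chi2 < size_best$chi2) size_best <- run
    }
    best_by_size[[m]] <- size_best
  }
  chis <- vapply(best_by_size, function(x) x$chi2, numeric(1))
  # minimal ensemble: the smallest size whose best fit ties the overall
  # optimum (within numerical tolerance)
  m_star <- which(chis <= min(chis) * (1 + 1e-6) + 1e-12)[1]
  win <- best_by_size[[m_star]]
  coefs <- win$coefs
  scale <- sum(coefs)
  w <- if (scale > 0) coefs / scale else coefs
  keep <- w > 1e-8
  members <- labs[win$idx]
  cf <- tapply(w, species[win$idx], sum)
  class_fractions <- as.numeric(cf)
  names(class_fractions) <- names(cf)
  structure(list(members = members[keep], weights = stats::setNames(
                   w[keep], members[keep]),
                 scale = scale, chi2_red = win$chi2,
                 size = as.integer(sum(keep)),
                 class_fractions = class_fractions,
                 by_size = data.frame(size = seq_len(n_max),
                                      chi2_red = chis),
                 history = win$history),
            class = "ensemble_fit")
}

# one GA restart at fixed ensemble size m
.ga_run <- function(np, m, subset_fit, generations, pop_size, mut_rate,
                    stall = generations) {
  # population: m x pop_size matrix of distinct member indices per column
  pop <- vapply(seq_len(pop_size),
                function(...) sort(sample.int(np, m)), integer(m))
  pop <- matrix(pop, nrow = m)
  eval_pop <- function(P)
    vapply(seq_len(ncol(P)), function(k) subset_fit(P[, k])$chi2,
           numeric(1))
  fitness <- eval_pop(pop)
  history <- rep(NA_real_, generations)
  best_so_far <- min(fitness)
  stalled <- 0L
  g_last <- 0L
  for (g in seq_len(generations)) {
    g_last <- g
    elite_i <- which.min(fitness)
    # tournament selection (size 2), two parents per child
    nc <- pop_size - 1L
    t1 <- sample.int(pop_size, 2L * nc, replace = TRUE)
    t2 <- sample.int(pop_size, 2L * nc, replace = TRUE)
    parents <- ifelse(fitness[t1] <= fitness[t2], t1, t2)
    pa <- pop[, parents[seq_len(nc) * 2L - 1L], drop = FALSE]
    pb <- pop[, parents[seq_len(nc) * 2L], drop = FALSE]
    # uniform crossover on slots
    take <- matrix(stats::runif(m * nc) < 0.5, m, nc)
    child <- ifelse(take, pa, pb)
    # per-slot mutation: swap in a random pool member
    mut <- matrix(stats::runif(m * nc) < mut_rate, m, nc)
    child[mut] <- sample.int(np, sum(mut), replace = TRUE)
    # repair duplicate members within a chromosome
    for (k in seq_len(nc)) {
      ck <- unique(child[, k])
      while (length(ck) < m)
        ck <- unique(c(ck, sample.int(np, m - length(ck))))
      child[, k] <- sort(ck)
    }
    pop <- cbind(pop[, elite_i], child)                 # elitism
    fitness <- eval_pop(pop)
    fbest <- min(fitness)
    history[g] <- fbest
    if (fbest < best_so_far - .Machine$double.eps) {
      best_so_far <- fbest
      stalled <- 0L
    } else {
      stalled <- stalled + 1L
      if (stalled >= stall) break
    }
  }
  besti <- which.min(fitness)
  idx <- pop[, besti]
  res <- subset_fit(idx)
  list(idx = idx, chi2 = res$chi2, coefs = res$coefs,
       history = cummin(history[seq_len(g_last)]))
}

#' Exhaustive minimal-ensemble search
#'
#' Enumerates every candidate subset of size 1..n_max and returns the
#' reduced-chi-square optimum. Used as the brute-force reference for the
#' stochastic GA search; practical only for small pools.
#'
#' @inheritParams ga_select
#' @return list with \code{idx}, \code{members}, \code{weights},
#'   \code{chi2_red} and \code{size} of the best subset.
#' @export
ensemble_exhaustive <- function(pool, target, n_max = 3L) {
  np <- length(pool)
  stopifnot(np >= n_max)
  B <- .basis_on_grid(pool, target$q)
  A <- B / target$sigma
  b <- target$intensity / target$sigma
  nq <- length(b)
  best <- list(chi2_red = Inf)
  for (m in seq_len(n_max)) {
    combos <- utils::combn(np, m)
    for (j in seq_len(ncol(combos))) {
      idx <- combos[, j]
      sol <- pracma::lsqnonneg(A[, idx, drop = FALSE], b)
      chi2 <- sum((b - A[, idx, drop = FALSE] %*% sol$x)^2) /
        max(nq - m, 1L)
      if (chi2 < best$chi2_red) {
        w <- sol$x / max(sum(sol$x), .Machine$double.eps)
        best <- list(idx = idx, weights = w, chi2_red = chi2, size = m)
      }
    }
  }
  labs <- vapply(seq_along(pool), function(k) {
    if (!is.null(names(pool)) && nzchar(names(pool)[k])) names(pool)[k]
    else if (!is.null(pool[[k]]$label)) pool[[k]]$label
    else sprintf("member_%d", k)
  }, character(1))
  best$members <- labs[best$idx]
  best
}

#' @export
print.ensemble_fit <- function(x, ...) {
  cat(sprintf("GA ensemble: %d members, reduced chi2 = %.3f\n",
              x$size, x$chi2_red))
  print(round(x$weights, 4))
  cat("Class fractions:\n")
  print(round(x$class_fractions, 4))
  invisible(x)
}

#' @export
summary.ensemble_fit <- function(object, ...) {
  print(object)
  cat("Best reduced chi2 by ensemble size:\n")
  print(object$by_size, row.names = FALSE, digits = 4)
  invisible(object)
}

#' @export
coef.ensemble_fit <- function(object, ...) object$weights
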