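#' Run the simulate-analyze-report pipeline from one configuration
#'
#' Executes the requested stages (any of \code{"fret"}, \code{"qens"},
#' \code{"sas"}, \code{"melt"}) in order: each stage simulates its inputs
#' from the stage's generator configuration, runs the corresponding
#' analysis chain, optionally writes its outputs under \code{out_dir}, and
#' contributes its headline numbers to the run report. The global seed
#' fans out to independent per-stage substreams, so rerunning a single
#' stage in isolation reproduces its in-pipeline output, and identical
#' config + seed give identical reports.
#'
#' The per-stage blocks of \code{config} are argument lists for the
#' generator configs (\code{\link{fret_sim_config}},
#' \code{\link{qens_sim_config}}, \code{\link{melt_sim_config}}) plus, for
#' \code{sas}, \code{weights} (mixing fractions over
#' monomer/dimer/trimer/tetramer), \code{noise_rel}, \code{n_decoys}, and
#' GA settings; and for \code{fret}, \code{R0} (A) for the distance table.
#'
#' @param config named list with elements \code{seed} (integer) and
#'   \code{stages} (named list of per-stage parameter blocks; stage order
#'   is the execution order).
#' @param out_dir optional output directory for stage files and the JSON
#'   report.
#' @return an object of class \code{"confokit_report"}: per-stage results,
#'   headline numbers, and provenance (config hash, seed, package
#'   version).
#' @export
confokit_run <- function(config, out_dir = NULL) {
  stopifnot(is.list(config), !is.null(config$stages))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  known <- c("fret", "qens", "sas", "melt")
  bad <- setdiff(names(config$stages), known)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(stages = list(),
                 provenance = list(
                   config_hash = .config_hash(config),
                   seed = seed,
                   package_version = as.character(
                     utils::packageVersion("confokit"))))
  offs <- stats::setNames(seq_along(known), known)
  for (stage in names(config$stages)) {
    blk <- config$stages[[stage]]
    sseed <- .derive_seed(seed, offs[[stage]])
    res <- tryCatch(
      switch(stage,
             fret = .stage_fret(blk, sseed, out_dir),
             qens = .stage_qens(blk, sseed, out_dir),
             sas = .stage_sas(blk, sseed, out_dir),
             melt = .stage_melt(blk, sseed, out_dir)),
      error = function(e) {
        structure(list(error = conditionMessage(e)), class = "stage_error")
      })
    report$stages[[stage]] <- res
    if (inherits(res, "stage_error")) {
      warning("stage '", stage, "' failed: ", res$error,
              "; downstream stages skipped")
      break
    }
  }
  class(report) <- "confokit_report"
  if (!is.null(out_dir)) {
    jsonlite::write_json(.report_numbers(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

.stage_fret <- function(blk, seed, out_dir) {
  r0 <- if (is.null(blk$R0)) 54.8 else blk$R0
  cfg_args <- blk[setdiff(names(blk), "R0")]
  cfg_args$seed <- seed
  cfg <- do.call(fret_sim_config, cfg_args)
  sim <- simulate_fret_traces(cfg)
  fts <- lapply(sim$traces, compute_fret, frame_time = cfg$frame_time)
  fts <- fts[vapply(fts, function(f) f$valid && f$n_valid >= 10L,
                    logical(1))]
  st <- stasi(fts)
  hist_fit <- fit_fret_histogram(fts, st$means,
                                 seed = .derive_seed(seed, 101L))
  e_ref <- max(st$means)
  displacements <- vapply(
    st$means[st$means < e_ref],
    function(e) fret_displacement(e, e_ref, r0), numeric(1))
  if (!is.null(out_dir)) {
    write_traces(sim, file.path(out_dir, "fret_traces.tsv"))
    utils::write.csv(
      data.frame(state = seq_along(st$means), mean_E = st$means,
                 population_pct = hist_fit$populations),
      file.path(out_dir, "fret_states.csv"), row.names = FALSE)
  }
  list(n_states = st$n_states, state_means = st$means,
       populations = hist_fit$populations,
       displacements_A = displacements, R0 = r0,
       n_molecules = length(fts))
}

.stage_qens <- function(blk, seed, out_dir) {
  blk$seed <- seed
  cfg <- do.call(qens_sim_config, blk)
  sim <- simulate_qens(cfg)
  dyn <- qens_dynamics(sim$spectra)
  if (!is.null(out_dir)) {
    utils::write.csv(dyn$widths, file.path(out_dir, "qens_widths.csv"),
                     row.names = FALSE)
  }
  list(Ea_global_kJ_mol = dyn$arrhenius_global$Ea_kJ_mol,
       Ea_internal_kJ_mol = dyn$arrhenius_internal$Ea_kJ_mol,
       widths = dyn$widths)
}

.stage_sas <- function(blk, seed, out_dir) {
  weights <- if (is.null(blk$weights)) c(monomer = 0.821, dimer = 0.037,
                                         trimer = 0.037, tetramer = 0.105)
             else blk$weights
  noise_rel <- if (is.null(blk$noise_rel)) 0.01 else blk$noise_rel
  n_decoys <- if (is.null(blk$n_decoys)) 20L else blk$n_decoys
  q <- if (is.null(blk$q_values)) seq(0.006, 0.25, by = 0.0015)
       else blk$q_values
  olig <- oligomer_bead_models()
  basis <- lapply(olig, debye_curve, q_values = q)
  target <- simulate_sas_mixture(basis, weights / sum(weights),
                                 noise_rel = noise_rel, seed = seed)
  pool <- c(basis, lapply(decoy_bead_models(
    n_decoys, seed = .derive_seed(seed, 201L)), debye_curve,
    q_values = q))
  gfit <- guinier_fit(target)
  ens <- ga_select(pool, target, seed = .derive_seed(seed, 202L))
  if (!is.null(out_dir)) {
    write_sas_dat(target, file.path(out_dir, "sas_mixture.dat"))
    jsonlite::write_json(
      list(members = ens$members, weights = as.list(ens$weights),
           chi2_red = ens$chi2_red,
           class_fractions = as.list(ens$class_fractions)),
      file.path(out_dir, "ensemble.json"), auto_unbox = TRUE, digits = NA)
  }
  list(Rg_guinier = gfit$Rg, chi2_red = ens$chi2_red,
       class_fractions = ens$class_fractions,
       true_weights = weights / sum(weights))
}

.stage_melt <- function(blk, seed, out_dir) {
  conditions <- if (is.null(blk$conditions))
    list(unliganded = list(tm = 55), liganded = list(tm = 59.7))
  else blk$conditions
  fits <- list()
  for (k in seq_along(conditions)) {
    args <- conditions[[k]]
    args$seed <- .derive_seed(seed, 300L + k)
    cfg <- do.call(melt_sim_config, args)
    curve <- simulate_melt_curve(cfg)
    fits[[names(conditions)[k]]] <- fit_boltzmann(curve)
  }
  tms <- vapply(fits, function(f) f$tm, numeric(1))
  out <- list(tm = tms)
  if (length(fits) >= 2L)
    out$delta_tm <- delta_tm(fits[[1]], fits[[2]])$delta_tm
  if (!is.null(out_dir))
    utils::write.csv(data.frame(condition = names(tms), tm = tms),
                     file.path(out_dir, "melt_tm.csv"), row.names = FALSE)
  out
}

.report_numbers <- function(report) {
  num <- list()
  st <- report$stages
  if (!is.null(st$fret) && !inherits(st$fret, "stage_error")) {
    num$fret <- list(n_states = st$fret$n_states,
                     state_means = st$fret$state_means,
                     populations_pct = as.list(st$fret$populations),
                     displacements_A = as.list(st$fret$displacements_A))
  }
  if (!is.null(st$qens) && !inherits(st$qens, "stage_error")) {
    num$qens <- list(Ea_global_kJ_mol = st$qens$Ea_global_kJ_mol,
                     Ea_internal_kJ_mol = st$qens$Ea_internal_kJ_mol)
  }
  if (!is.null(st$sas) && !inherits(st$sas, "stage_error")) {
    num$sas <- list(Rg_guinier = st$sas$Rg_guinier,
                    chi2_red = st$sas$chi2_red,
                    class_fractions = as.list(st$sas$class_fractions))
  }
  if (!is.null(st$melt) && !inherits(st$melt, "stage_error")) {
    num$melt <- list(tm = as.list(st$melt$tm),
                     delta_tm = st$melt$delta_tm)
  }
  c(num, list(provenance = report$provenance))
}

#' @export
print.confokit_report <- function(x, ...) {
  cat("confokit run (seed", x$provenance$seed, ", config",
      x$provenance$config_hash, "):\n")
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    if (inherits(s, "stage_error")) {
      cat(sprintf("  %s: FAILED (%s)\n", nm, s$error))
      next
    }
    msg <- switch(nm,
      fret = sprintf("%d states at %s; populations %s %%",
                     s$n_states,
                     paste(sprintf("%.2f", s$state_means), collapse = "/"),
                     paste(sprintf("%.1f", s$populations), collapse = "/")),
      qens = sprintf("Ea(global) = %.1f, Ea(internal) = %.1f kJ/mol",
                     s$Ea_global_kJ_mol, s$Ea_internal_kJ_mol),
      sas = sprintf("Rg = %.1f A, chi2 = %.2f, fractions %s",
                    s$Rg_guinier, s$chi2_red,
                    paste(sprintf("%s %.3f", names(s$class_fractions),
                                  s$class_fractions), collapse = ", ")),
      melt = sprintf("Tm = %s C%s",
                     paste(sprintf("%.1f", s$tm), collapse = ", "),
                     if (is.null(s$delta_tm)) ""
                     else sprintf(" (shift %.1f C)", s$delta_tm)))
    cat("  ", nm, ": ", msg, "\n", sep = "")
  }
  invisible(x)
}

#' Compare a run report against target values
#'
#' Each target names a number in the report (dotted \code{key} into the
#' stage results), the expected \code{value}, a comparison mode
#' (\code{"eq"}, \code{"le"}, \code{"ge"}, \code{"le_abs"},
#' \code{"mag_eq"}) and a tolerance. Missing report values are marked
#' unevaluable rather than failed.
#'
#' @param report a \code{\link{confokit_run}} result.
#' @param targets data frame (or list of lists) with columns
#'   \code{id, key, value, cmp, tol}.
#' @return data frame with per-target observed value and verdict
#'   (\code{"pass"}, \code{"fail"}, \code{"unevaluable"}); overall pass
#'   as attribute \code{"pass"}.
#' @export
acceptance_check <- function(report, targets) {
  if (!is.data.frame(targets)) {
    targets <- do.call(rbind, lapply(targets, function(t)
      data.frame(id = t$id, key = t$key, value = t$value,
                 cmp = if (is.null(t$cmp)) "eq" else t$cmp,
                 tol = if (is.null(t$tol)) 0 else t$tol)))
  }
  if (is.null(targets) || nrow(targets) == 0L) {
    out <- data.frame(id = character(0), observed = numeric(0),
                      expected = numeric(0), verdict = character(0))
    attr(out, "pass") <- TRUE
    return(out)
  }
  rows <- lapply(seq_len(nrow(targets)), function(j) {
    key <- strsplit(targets$key[j], ".", fixed = TRUE)[[1]]
    obs <- tryCatch(Reduce(function(acc, k) acc[[k]],
                           key, report$stages),
                    error = function(e) NULL)
    if (is.null(obs) || !is.numeric(obs) || !length(obs)) {
      verdict <- "unevaluable"; obs <- NA_real_
    } else {
      obs <- obs[[1]]
      v <- targets$value[j]; tol <- targets$tol[j]
      ok <- switch(targets$cmp[j],
                   eq = abs(obs - v) <= tol,
                   le = obs <= v + tol,
                   ge = obs >= v - tol,
                   le_abs = abs(obs) <= abs(v) + tol,
                   mag_eq = abs(abs(obs) - abs(v)) <= tol,
                   stop("unknown cmp: ", targets$cmp[j]))
      verdict <- if (ok) "pass" else "fail"
    }
    data.frame(id = targets$id[j], observed = obs,
               expected = targets$value[j], cmp = targets$cmp[j],
               tol = targets$tol[j], verdict = verdict)
  })
  out <- do.call(rbind, rows)
  attr(out, "pass") <- !any(out$verdict == "fail")
  out
}
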