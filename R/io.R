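# Plain-text readers/writers for the formats the toolkit exchanges.

#' Write and read single-molecule intensity traces
#'
#' One tab-separated file per run with columns
#' \code{trace, frame, donor, acceptor} plus the ground-truth columns
#' \code{state_id, bleached} when present.
#'
#' @param sim a \code{fret_sim} object (or a bare list of per-trace data
#'   frames with donor/acceptor columns).
#' @param path output file path.
#' @return \code{write_traces}: the path, invisibly.
#'   \code{read_traces}: list of per-trace data frames.
#' @export
write_traces <- function(sim, path) {
  traces <- if (inherits(sim, "fret_sim")) sim$traces else sim
  rows <- lapply(seq_along(traces), function(i)
    cbind(trace = i, traces[[i]]))
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  tab <- utils::read.delim(path)
  stopifnot(all(c("trace", "donor", "acceptor") %in% names(tab)))
  split(tab[setdiff(names(tab), "trace")], tab$trace)
}

#' Read a plain two-column donor/acceptor trace
#'
#' Whitespace-delimited text, donor in column 1 and acceptor in column 2;
#' lines starting with '#' are skipped.
#'
#' @param path file path.
#' @return data frame with columns \code{donor} and \code{acceptor}.
#' @export
read_trace_pair <- function(path) {
  tab <- utils::read.table(path, comment.char = "#")
  stopifnot(ncol(tab) >= 2L)
  data.frame(donor = tab[[1]], acceptor = tab[[2]])
}

#' Write and read a QENS spectrum set
#'
#' Each spectrum goes to a two/three-column energy/intensity(/sigma) text
#' table; one resolution table and a CSV manifest listing temperature, Q
#' and file name tie the set together.
#'
#' @param sim a \code{qens_sim} object or list of \code{qens_spectrum}s.
#' @param dir output directory (created if missing).
#' @return \code{write_qens_set}: the manifest path, invisibly.
#'   \code{read_qens_set}: list of \code{\link{qens_spectrum}} objects.
#' @export
write_qens_set <- function(sim, dir) {
  spectra <- if (inherits(sim, "qens_sim")) sim$spectra else sim
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- NULL
  for (k in seq_along(spectra)) {
    sp <- spectra[[k]]
    fn <- sprintf("spectrum_T%03.0f_Q%04.2f.dat", sp$temperature, sp$q)
    utils::write.table(
      data.frame(energy = sp$energy, intensity = sp$intensity,
                 sigma = sp$sigma),
      file.path(dir, fn), sep = " ", row.names = FALSE, quote = FALSE)
    man <- rbind(man, data.frame(temperature = sp$temperature, q = sp$q,
                                 file = fn))
  }
  res <- spectra[[1]]$resolution
  utils::write.table(
    data.frame(energy = spectra[[1]]$energy, intensity = res),
    file.path(dir, "resolution.dat"), sep = " ", row.names = FALSE,
    quote = FALSE)
  man_path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, man_path, row.names = FALSE)
  invisible(man_path)
}

#' @rdname write_qens_set
#' @param manifest path to the manifest CSV written by
#'   \code{write_qens_set}.
#' @export
read_qens_set <- function(manifest) {
  man <- utils::read.csv(manifest)
  dir <- dirname(manifest)
  res_tab <- utils::read.table(file.path(dir, "resolution.dat"),
                               header = TRUE)
  lapply(seq_len(nrow(man)), function(k) {
    tab <- utils::read.table(file.path(dir, man$file[k]), header = TRUE)
    qens_spectrum(energy = tab$energy, intensity = tab$intensity,
                  sigma = if ("sigma" %in% names(tab)) tab$sigma else NULL,
                  resolution = res_tab$intensity,
                  q = man$q[k], temperature = man$temperature[k])
  })
}

#' Write and read 3-column scattering curves
#'
#' Whitespace-delimited q/I/sigma text in the common small-angle
#' \code{.dat} dialect; '#' comment lines are ignored on read.
#'
#' @param curve a \code{\link{scattering_curve}}.
#' @param path file path.
#' @return \code{write_sas_dat}: the path, invisibly.
#'   \code{read_sas_dat}: a \code{\link{scattering_curve}}.
#' @export
write_sas_dat <- function(curve, path) {
  stopifnot(inherits(curve, "sas_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(curve$label)) writeLines(paste("#", curve$label), con)
  writeLines("# q(1/A) I(q) sigma", con)
  utils::write.table(
    data.frame(curve$q, curve$intensity, curve$sigma), con,
    sep = " ", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sas_dat
#' @param label optional label for the curve read in.
#' @export
read_sas_dat <- function(path, label = NULL) {
  tab <- utils::read.table(path, comment.char = "#")
  stopifnot(ncol(tab) >= 2L)
  scattering_curve(tab[[1]], tab[[2]],
                   sigma = if (ncol(tab) >= 3L) tab[[3]] else NULL,
                   label = label)
}

#' Write a P(r) function as 2-column text
#'
#' @param pr a \code{pr_function} from \code{\link{pr_transform}}.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_pr <- function(pr, path) {
  stopifnot(inherits(pr, "pr_function"))
  utils::write.table(data.frame(r = pr$r, P = pr$P), path, sep = " ",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a melt-curve table
#'
#' CSV or whitespace text with temperature and fluorescence columns and an
#' optional condition column; returns one data frame per condition.
#'
#' @param path file path.
#' @return named list of data frames with columns
#'   \code{temperature, fluorescence}.
#' @export
read_melt_curves <- function(path) {
  tab <- if (grepl("\\.csv$", path)) utils::read.csv(path)
         else utils::read.table(path, header = TRUE)
  names(tab) <- tolower(names(tab))
  stopifnot(all(c("temperature", "fluorescence") %in% names(tab)))
  if ("condition" %in% names(tab)) {
    split(tab[c("temperature", "fluorescence")], tab$condition)
  } else {
    list(curve = tab[c("temperature", "fluorescence")])
  }
}
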