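# Derived quantities ------------------------------------------------------------

#' Simulation duration from time step and step count
#'
#' The run length is not stored as a single field in the run input; it is the
#' product of the integration time step and the number of steps. Note that
#' for continuation runs this is the length of the final segment only, not
#' the total simulated time.
#'
#' @param dt Time step in ps (> 0).
#' @param nsteps Number of integration steps (>= 0).
#' @return `list(duration_ps, duration_ns)`.
#' @export
#' @examples
#' simulation_time(0.002, 50000000)  # 100000 ps = 100 ns
simulation_time <- function(dt, nsteps) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be a positive time step in ps")
  if (!is.numeric(nsteps) || nsteps < 0) stop("nsteps must be non-negative")
  ps <- dt * nsteps
  list(duration_ps = ps, duration_ns = ps / 1000)
}

#' Convert a time step from ps to fs
#'
#' @param dt Time step in ps (> 0).
#' @return Time step in fs.
#' @export
convert_timestep <- function(dt) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be a positive time step in ps")
  dt * 1000
}

#' Version series of a software version string
#'
#' GROMACS switched to year-based version numbers in 2016. For year-based
#' versions the series is the year ("2024.3" -> "2024"); for older versions
#' the series is the major number ("GROMACS 5.1.4" -> "5"), with major.minor
#' additionally available for finer grouping. Unparseable strings map to
#' "unknown".
#'
#' @param version_string Version string, e.g. "GROMACS 5.1.4" or "2024.3".
#' @return `list(series, major_minor)`; `major_minor` is `NULL` for
#'   year-based or unparseable versions.
#' @export
version_series <- function(version_string) {
  if (is.null(version_string) || !nzchar(trimws(version_string))) {
    return(list(series = "unknown", major_minor = NULL))
  }
  m <- regmatches(version_string,
                  regexec("([0-9]+)(\\.([0-9]+))?(\\.[0-9]+)*", version_string))[[1]]
  if (length(m) < 2) return(list(series = "unknown", major_minor = NULL))
  major <- as.integer(m[2])
  if (is.na(major)) return(list(series = "unknown", major_minor = NULL))
  if (major >= 2016) return(list(series = as.character(major), major_minor = NULL))
  mm <- if (length(m) >= 4 && nzchar(m[4])) paste(m[2], m[4], sep = ".") else NULL
  list(series = as.character(major), major_minor = mm)
}

#' Add derived fields to a metadata record
#'
#' Computes segment duration (from `dt` and `nsteps`), the time step in fs
#' and the software version series, and stores them under the `derived`
#' section with `derived` provenance tags. Derived fields never overwrite
#' parsed fields.
#'
#' @param record A [metadata_record()].
#' @return The record with a populated `derived` section.
#' @export
add_derived <- function(record) {
  stopifnot(is_metadata_record(record))
  sim <- record$simulation
  der <- list()
  prov <- record$provenance
  tag <- function(path) {
    prov[[path]] <<- provenance_tag("(computed)", "derived")
  }
  if (!is.null(sim$dt) && !is.null(sim$nsteps) && sim$dt > 0 && sim$nsteps >= 0) {
    st <- simulation_time(sim$dt, sim$nsteps)
    der$duration_ps <- st$duration_ps
    der$duration_ns <- st$duration_ns
    tag("derived.duration_ps"); tag("derived.duration_ns")
  }
  if (!is.null(sim$dt) && sim$dt > 0) {
    der$dt_fs <- convert_timestep(sim$dt)
    tag("derived.dt_fs")
  }
  if (!is.null(sim$software_information)) {
    vs <- version_series(sim$software_information)
    der$version_series <- vs$series
    tag("derived.version_series")
    if (!is.null(vs$major_minor)) {
      der$version_major_minor <- vs$major_minor
      tag("derived.version_major_minor")
    }
  }
  record$derived <- der
  record$provenance <- prov
  canonicalize_record(record)
}
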