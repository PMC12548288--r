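#' @importFrom stats setNames
NULL

# Dotted field paths that extraction can populate; used for provenance
# bookkeeping and for ordering emitted documents.
SECTION_ORDER <- c("system", "simulation", "simulated_object",
                   "administrative", "derived", "extra", "notes", "provenance")

SIMULATION_FIELD_ORDER <- c("forcefield", "software_information", "dt",
                            "nsteps", "ensemble_temperature", "tcoupl",
                            "pcoupl", "pcoupltype", "continuation",
                            "raw_parameters")

#' Known water models
#'
#' Canonical lowercase names of water models recognised when inferring the
#' model from topology include filenames. Matching is exact on the lowercased
#' filename stem, so e.g. `tip4pew` never matches a `tip4p` include.
#'
#' @return Character vector of canonical model names.
#' @export
water_model_dictionary <- function() {
  c("spc", "spce", "tip3p", "tip4p", "tip4pew", "tip4p2005", "tip5p",
    "opc", "opc3", "opc4")
}

#' Create a provenance tag
#'
#' Each populated extracted field carries one tag recording where the value
#' came from and how reliable the extraction route is. Values inferred from
#' filenames (force field, water model) always carry a warning because file
#' contents are never inspected.
#'
#' @param source_file Filename the value was extracted from.
#' @param method One of `"parsed"`, `"filename_inference"`, `"user_supplied"`,
#'   `"derived"`.
#' @param warning Optional warning text; required for `filename_inference`.
#' @return A `provenance_tag` list.
#' @export
provenance_tag <- function(source_file, method, warning = NULL) {
  method <- match.arg(method,
                      c("parsed", "filename_inference", "user_supplied", "derived"))
  if (method == "filename_inference" && (is.null(warning) || !nzchar(warning))) {
    stop("filename_inference tags must carry a non-empty warning")
  }
  tag <- list(source_file = as.character(source_file), method = method)
  if (!is.null(warning) && nzchar(warning)) tag$warning <- as.character(warning)
  structure(tag, class = "provenance_tag")
}

#' Construct a metadata record
#'
#' The record has four logical parts: `system` (water model, box geometry),
#' `simulation` (force field, software version and all run parameters),
#' `simulated_object` (external database identifiers) and `administrative`
#' (creators, institution, dates). Two service parts may be added later:
#' `derived` (quantities computed from other fields, e.g. simulation time)
#' and `extra` (free-form user keys). `provenance` maps dotted field paths to
#' [provenance_tag()]s; `notes` collects cross-check and merge-conflict notes.
#'
#' Empty sections and `NULL` fields are pruned so that a record compares
#' `identical()` after a JSON or YAML round trip.
#'
#' @param system,simulation,simulated_object,administrative,derived,extra
#'   Named lists for each part (see the field lists in the package vignette).
#' @param notes Character vector of free-text notes.
#' @param provenance Named list mapping dotted paths to [provenance_tag()]s.
#' @return A `metadata_record`.
#' @export
metadata_record <- function(system = list(), simulation = list(),
                            simulated_object = list(), administrative = list(),
                            derived = list(), extra = list(),
                            notes = character(), provenance = list()) {
  rec <- list(system = system, simulation = simulation,
              simulated_object = simulated_object,
              administrative = administrative, derived = derived,
              extra = extra, notes = notes, provenance = provenance)
  canonicalize_record(rec)
}

is_metadata_record <- function(x) inherits(x, "metadata_record")

prune_empty <- function(x) {
  if (!is.list(x)) return(x)
  x <- lapply(x, prune_empty)
  keep <- !vapply(x, function(e) is.null(e) || (is.list(e) && length(e) == 0) ||
                    (is.atomic(e) && length(e) == 0), logical(1))
  x[keep]
}

order_names <- function(x, order) {
  if (is.null(names(x))) return(x)
  known <- intersect(order, names(x))
  rest <- sort(setdiff(names(x), order))
  x[c(known, rest)]
}

# Bring a (possibly re-parsed) record structure into canonical form: fixed
# key order, doubles for all numerics, character/numeric vectors for the
# known vector-valued fields, pruned empties.
canonicalize_record <- function(rec) {
  rec <- as.list(rec)

  sys <- as.list(rec$system)
  if (!is.null(sys$water_model)) sys$water_model <- as.character(sys$water_model)[1]
  if (!is.null(sys$box)) sys$box <- canonicalize_box(sys$box)
  sys <- order_names(sys, c("water_model", "box"))

  sim <- as.list(rec$simulation)
  for (f in c("dt", "nsteps")) {
    if (!is.null(sim[[f]])) sim[[f]] <- as.numeric(sim[[f]])[1]
  }
  if (!is.null(sim$ensemble_temperature)) {
    sim$ensemble_temperature <- as.numeric(unlist(sim$ensemble_temperature))
  }
  if (!is.null(sim$continuation)) {
    sim$continuation <- as.logical(sim$continuation)[1]
  }
  for (f in c("forcefield", "software_information", "tcoupl", "pcoupl",
              "pcoupltype")) {
    if (!is.null(sim[[f]])) sim[[f]] <- as.character(sim[[f]])[1]
  }
  if (!is.null(sim$raw_parameters)) {
    rp <- lapply(sim$raw_parameters, function(v) as.character(v)[1])
    sim$raw_parameters <- rp[order(names(rp))]
  }
  sim <- order_names(sim, SIMULATION_FIELD_ORDER)

  so <- as.list(rec$simulated_object)
  if (!is.null(so$identifiers)) {
    so$identifiers <- lapply(so$identifiers, function(id) {
      list(database = as.character(id$database)[1], id = as.character(id$id)[1])
    })
  }

  adm <- as.list(rec$administrative)
  if (!is.null(adm$creators)) adm$creators <- as.character(unlist(adm$creators))
  for (f in c("institution", "creation_date", "gromacs_version")) {
    if (!is.null(adm[[f]])) adm[[f]] <- as.character(adm[[f]])[1]
  }
  adm <- order_names(adm, c("creators", "institution", "creation_date",
                            "gromacs_version"))

  der <- as.list(rec$derived)
  for (f in c("duration_ps", "duration_ns", "dt_fs")) {
    if (!is.null(der[[f]])) der[[f]] <- as.numeric(der[[f]])[1]
  }
  for (f in c("version_series", "version_major_minor")) {
    if (!is.null(der[[f]])) der[[f]] <- as.character(der[[f]])[1]
  }
  der <- order_names(der, c("duration_ps", "duration_ns", "dt_fs",
                            "version_series", "version_major_minor"))

  prov <- lapply(as.list(rec$provenance), function(tag) {
    tag <- as.list(tag)
    out <- list(source_file = as.character(tag$source_file)[1],
                method = as.character(tag$method)[1])
    if (!is.null(tag$warning)) out$warning <- as.character(tag$warning)[1]
    structure(out, class = "provenance_tag")
  })
  if (length(prov)) prov <- prov[order(names(prov))]

  out <- list(system = sys, simulation = sim, simulated_object = so,
              administrative = adm, derived = der,
              extra = canonicalize_free(rec$extra),
              notes = unique(as.character(unlist(rec$notes))),
              provenance = prov)
  out <- prune_empty(out)
  structure(out, class = "metadata_record")
}

# Free-form user payloads: integers -> double, homogeneous scalar arrays ->
# atomic vectors (so JSON- and YAML-parsed forms agree), key order kept.
canonicalize_free <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.list(x)) {
    x <- lapply(x, canonicalize_free)
    if (is.null(names(x)) && length(x) &&
        all(vapply(x, function(e) is.atomic(e) && length(e) == 1, logical(1))) &&
        length(unique(vapply(x, typeof, ""))) == 1) {
      return(canonicalize_free(unlist(x, use.names = FALSE)))
    }
    return(x)
  }
  if (is.integer(x)) return(as.numeric(x))
  x
}

#' @export
print.metadata_record <- function(x, ...) {
  cat("<metadata_record>\n")
  for (sec in intersect(SECTION_ORDER, names(x))) {
    n <- if (sec == "notes") length(x[[sec]]) else length(names(x[[sec]]))
    cat(sprintf("  %-17s %d field(s)\n", sec, n))
  }
  invisible(x)
}

# Flatten populated extractable leaves to dotted paths (used by the
# provenance-completeness invariant). 'derived' leaves are included;
# raw_parameters counts as a single field.
populated_field_paths <- function(rec) {
  paths <- character()
  add <- function(sec, fields) {
    present <- intersect(fields, names(rec[[sec]]))
    paths <<- c(paths, if (length(present)) paste(sec, present, sep = "."))
  }
  add("system", c("water_model", "box"))
  add("simulation", SIMULATION_FIELD_ORDER)
  add("derived", c("duration_ps", "duration_ns", "dt_fs", "version_series",
                   "version_major_minor"))
  paths
}
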