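# Dump-text parsing ------------------------------------------------------------
#
# Binary .tpr run-input files are consumed through their human-readable dump
# rendering (the text the native dump utility prints). The dialect accepted
# here is a tolerant superset of that layout:
#
#   document   := line*
#   line       := pair | array | indexed | boxrow | block | version | other
#   pair       := key "=" value                (leading whitespace ignored)
#   array      := key ":" value (" " value)+   (e.g. "ref-t: 298 298 310")
#   indexed    := key "[" digits "]" "=" value (aggregated in index order)
#   boxrow     := "box[" i "] = { x, y, z }"   (collected into a 3x3 matrix)
#   block      := key ":"                      (grouping only; members are
#                                               ordinary pairs)
#   version    := "VERSION <string>" or a "version = ..." pair
#
# Key spellings drift across version series; synonyms are normalised
# (pcoupl-type -> pcoupltype, ref-t/ref_t -> ref_t, unconstrained-start ->
# continuation). Binary input is rejected with instructions to supply the
# dump text instead.

TYPED_DUMP_KEYS <- c("dt", "nsteps", "tcoupl", "pcoupl", "pcoupltype",
                     "continuation", "ref_t")

normalize_dump_key <- function(key) {
  key <- trimws(key)
  low <- tolower(key)
  if (low %in% c("pcoupl-type", "pcoupl_type")) return("pcoupltype")
  if (low %in% c("ref-t", "ref_t")) return("ref_t")
  if (low %in% c("continuation", "unconstrained-start", "unconstrained_start")) {
    return("continuation")
  }
  if (low %in% TYPED_DUMP_KEYS) return(low)
  key
}

parse_dump_boolean <- function(value) {
  v <- tolower(trimws(value))
  if (v %in% c("yes", "true", "1")) return(TRUE)
  if (v %in% c("no", "false", "0")) return(FALSE)
  NA
}

#' Parse the dump-text rendering of a run-input file
#'
#' Captures every `key = value` pair in order, coerces the known keys to
#' typed fields (`dt` in ps, `nsteps`, coupling algorithm names, the
#' `continuation` flag, per-group reference temperatures `ref_t` in K),
#' collects `box[i] = { ... }` rows into a 3x3 box matrix and picks up the
#' software version string. Unknown keys are preserved verbatim.
#'
#' @param text Character scalar (file content) or vector of lines.
#' @return A `dump_parameters` list with `version_string`, `params` (ordered
#'   named list of raw string values), `typed` (coerced known fields) and
#'   `box` (3x3 matrix in nm, or `NULL`).
#' @export
parse_dump <- function(text) {
  lines <- split_lines(text)
  if (any(!validUTF8(lines)) ||
      any(grepl("[^\t[:print:]]", lines, useBytes = TRUE))) {
    stop(paste("input looks binary, not dump text: render the .tpr with the",
               "dump utility first and supply the resulting text"))
  }
  if (!length(lines) || !any(nzchar(trimws(lines)))) {
    stop("empty dump text")
  }

  params <- list()
  version_string <- NULL
  box <- NULL
  indexed <- list()  # key -> named values by index

  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line)) next

    if (grepl("^VERSION\\s+\\S", line)) {
      if (is.null(version_string)) version_string <- line
      next
    }
    # box rows: box[0] = { 5.00000, 0.00000, 0.00000 }
    mb <- regmatches(line, regexec(
      "^box\\[([0-2])\\]\\s*=\\s*\\{([^}]*)\\}\\s*$", line))[[1]]
    if (length(mb) == 3) {
      row <- as.integer(mb[2]) + 1L
      vals <- suppressWarnings(as.numeric(strsplit(trimws(mb[3]), ",")[[1]]))
      if (length(vals) != 3 || anyNA(vals)) {
        stop(sprintf("malformed box row at line %d: '%s'", i, line))
      }
      if (is.null(box)) box <- matrix(NA_real_, 3, 3)
      box[row, ] <- vals
      next
    }
    # indexed array element: ref-t[0] = 298
    mi <- regmatches(line, regexec(
      "^([A-Za-z0-9_.-]+)\\[([0-9]+)\\]\\s*=\\s*(.*)$", line))[[1]]
    if (length(mi) == 4) {
      key <- normalize_dump_key(mi[2])
      indexed[[key]] <- c(indexed[[key]],
                          stats::setNames(trimws(mi[4]), mi[3]))
      next
    }
    # plain pair: key = value
    mp <- regmatches(line, regexec("^([^=:]+?)\\s*=\\s*(.*)$", line, perl = TRUE))[[1]]
    if (length(mp) == 3) {
      key <- normalize_dump_key(mp[2])
      value <- trimws(mp[3])
      if (identical(tolower(key), "version")) {
        if (is.null(version_string)) version_string <- value
        next
      }
      if (!key %in% names(params)) params[[key]] <- value
      next
    }
    # array pair: key: v1 v2 v3   (a bare "key:" is a block introducer)
    ma <- regmatches(line, regexec("^([^=:]+?):\\s*(.*)$", line, perl = TRUE))[[1]]
    if (length(ma) == 3) {
      key <- normalize_dump_key(ma[2])
      value <- trimws(ma[3])
      if (nzchar(value) && !key %in% names(params)) params[[key]] <- value
      next
    }
  }

  for (key in names(indexed)) {
    vals <- indexed[[key]][order(as.integer(names(indexed[[key]])))]
    if (!key %in% names(params)) params[[key]] <- paste(vals, collapse = " ")
  }
  if (!is.null(box) && anyNA(box)) {
    stop("incomplete box block in dump text: need rows box[0..2]")
  }

  typed <- list()
  coerce_num <- function(key, what) {
    v <- suppressWarnings(as.numeric(params[[key]]))
    if (anyNA(v)) {
      stop(sprintf("typed dump key '%s' has uncoercible %s value '%s'",
                   key, what, params[[key]]))
    }
    v
  }
  if (!is.null(params$dt)) typed$dt <- coerce_num("dt", "numeric")
  if (!is.null(params$nsteps)) typed$nsteps <- coerce_num("nsteps", "integer")
  if (!is.null(params$ref_t)) {
    vals <- suppressWarnings(as.numeric(strsplit(params$ref_t, "[[:space:],]+")[[1]]))
    if (!length(vals) || anyNA(vals)) {
      stop(sprintf("typed dump key 'ref_t' has uncoercible value '%s'", params$ref_t))
    }
    typed$ref_t <- vals
  }
  if (!is.null(params$continuation)) {
    b <- parse_dump_boolean(params$continuation)
    if (is.na(b)) {
      stop(sprintf("typed dump key 'continuation' has non-boolean value '%s'",
                   params$continuation))
    }
    typed$continuation <- b
  }
  for (key in c("tcoupl", "pcoupl", "pcoupltype")) {
    if (!is.null(params[[key]])) typed[[key]] <- params[[key]]
  }

  structure(list(version_string = version_string, params = params,
                 typed = typed, box = box),
            class = "dump_parameters")
}

#' Map parsed dump parameters onto a partial metadata record
#'
#' Typed fields land in the simulation section (`ref_t` becomes the sorted
#' unique `ensemble_temperature` list), the version string becomes
#' `software_information` ("VERSION 5.1.4" is rendered "GROMACS 5.1.4"), a
#' box block becomes the system box, and every remaining key is preserved in
#' `raw_parameters`. Each populated field gets a `parsed` provenance tag.
#'
#' @param dump A [parse_dump()] result.
#' @param source_file Filename used in provenance tags.
#' @return A partial [metadata_record()].
#' @export
map_to_record <- function(dump, source_file = "runinput.tpr.dump") {
  sim <- list()
  prov <- list()
  tag <- function(path) prov[[path]] <<- provenance_tag(source_file, "parsed")

  if (!is.null(dump$version_string)) {
    v <- sub("^VERSION\\s+", "GROMACS ", dump$version_string)
    if (!grepl("GROMACS", v, ignore.case = TRUE)) v <- paste("GROMACS", v)
    sim$software_information <- v
    tag("simulation.software_information")
  }
  typed <- dump$typed
  if (!is.null(typed$dt)) { sim$dt <- typed$dt; tag("simulation.dt") }
  if (!is.null(typed$nsteps)) { sim$nsteps <- typed$nsteps; tag("simulation.nsteps") }
  if (!is.null(typed$ref_t)) {
    sim$ensemble_temperature <- sort(unique(typed$ref_t))
    tag("simulation.ensemble_temperature")
  }
  for (key in c("tcoupl", "pcoupl", "pcoupltype")) {
    if (!is.null(typed[[key]])) {
      sim[[key]] <- typed[[key]]
      tag(paste0("simulation.", key))
    }
  }
  if (!is.null(typed$continuation)) {
    sim$continuation <- typed$continuation
    tag("simulation.continuation")
  }

  raw <- dump$params[setdiff(names(dump$params), TYPED_DUMP_KEYS)]
  if (length(raw)) {
    sim$raw_parameters <- raw
    tag("simulation.raw_parameters")
  }

  sys <- list()
  if (!is.null(dump$box)) {
    sys$box <- box_geometry(dump$box)
    tag("system.box")
  }
  metadata_record(system = sys, simulation = sim, provenance = prov)
}
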