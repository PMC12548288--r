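# Record validation and the machine-readable schema ----------------------------

IDENTIFIER_PATTERNS <- c(
  PDB       = "^[0-9][A-Za-z0-9]{3}$",
  UniProt   = "^([OPQ][0-9][A-Z0-9]{3}[0-9]|[A-NR-Z][0-9]([A-Z][A-Z0-9]{2}[0-9]){1,2})$",
  PubChem   = "^[0-9]+$",
  ChEMBL    = "^CHEMBL[0-9]+$",
  DrugBank  = "^DB[0-9]{5}$",
  LIPIDMAPS = "^LM[A-Z]{2}[A-Z0-9]{8}$"
)

#' Validate an external database identifier
#'
#' Checks an identifier against the accession format its registry publishes:
#' PDB (1 digit + 3 alphanumerics), UniProt (official accession pattern),
#' PubChem CID (digits), ChEMBL (`CHEMBL` + digits), DrugBank (`DB` + 5
#' digits) and LIPID MAPS (`LM` + 2 letters + 8 alphanumerics).
#'
#' @param database Registry name (one of the above).
#' @param id Identifier string.
#' @return `TRUE` iff `id` matches the registry pattern.
#' @export
#' @examples
#' validate_identifier("PDB", "6fip")
validate_identifier <- function(database, id) {
  if (!database %in% names(IDENTIFIER_PATTERNS)) {
    stop(sprintf("unsupported identifier database '%s'; supported: %s",
                 database, paste(names(IDENTIFIER_PATTERNS), collapse = ", ")))
  }
  is.character(id) && length(id) == 1 &&
    grepl(IDENTIFIER_PATTERNS[[database]], id)
}

#' Validate a metadata record
#'
#' Checks every record invariant and returns a report of violations (an empty
#' report means the record is valid). Problems are reported, never raised,
#' and the record is not modified. Checked: presence of the simulation
#' section; water model in the known dictionary (or "unknown"); box
#' lower-triangular convention, shape label and volume consistency; `dt > 0`;
#' `nsteps >= 0`; ensemble temperatures > 0; raw parameter values are
#' strings; identifier formats; creation date parses as a calendar date;
#' provenance tag methods, warning pairing, and one tag per populated
#' extracted field.
#'
#' @param record A [metadata_record()].
#' @param water_models Accepted water-model names (extensible via CLI config).
#' @return A data frame (class `validation_report`) with columns `field`
#'   (dotted path) and `message`; zero rows iff valid.
#' @export
validate_record <- function(record, water_models = water_model_dictionary()) {
  violations <- list()
  flag <- function(field, message) {
    violations[[length(violations) + 1L]] <<- list(field = field, message = message)
  }

  if (is.null(record$simulation) || !length(record$simulation)) {
    flag("simulation", "simulation section is required")
  }

  wm <- record$system$water_model
  if (!is.null(wm) && !wm %in% c(water_models, "unknown")) {
    flag("system.water_model",
         sprintf("'%s' is not a known water model (or 'unknown')", wm))
  }
  box <- record$system$box
  if (!is.null(box)) {
    v <- box$vectors
    upper <- c(v[1, 2], v[1, 3], v[2, 3])
    if (any(abs(upper) > BOX_SHAPE_TOL)) {
      flag("system.box.vectors", "box vectors are not lower-triangular")
    } else {
      if (!identical(box$shape, classify_box(v))) {
        flag("system.box.shape", sprintf("shape '%s' does not match the vectors", box$shape))
      }
      if (abs(box$volume - v[1, 1] * v[2, 2] * v[3, 3]) >
            1e-9 * max(1, abs(box$volume))) {
        flag("system.box.volume", "volume does not equal the diagonal product")
      }
      if (any(diag(v) <= 0)) flag("system.box.vectors", "box diagonal must be positive")
    }
  }

  sim <- record$simulation
  if (!is.null(sim$dt) && (!is.numeric(sim$dt) || sim$dt <= 0)) {
    flag("simulation.dt", "time step must be a positive number of ps")
  }
  if (!is.null(sim$nsteps) &&
        (!is.numeric(sim$nsteps) || sim$nsteps < 0 || sim$nsteps != round(sim$nsteps))) {
    flag("simulation.nsteps", "step count must be a non-negative integer")
  }
  et <- sim$ensemble_temperature
  if (!is.null(et) && (!is.numeric(et) || any(et <= 0))) {
    flag("simulation.ensemble_temperature", "temperatures must be positive (K)")
  }
  if (!is.null(et) && is.numeric(et) && is.unsorted(et, strictly = TRUE) ) {
    flag("simulation.ensemble_temperature", "temperatures must be sorted and unique")
  }
  if (!is.null(sim$continuation) && !is.logical(sim$continuation)) {
    flag("simulation.continuation", "continuation must be a boolean")
  }
  if (!is.null(sim$raw_parameters)) {
    bad <- !vapply(sim$raw_parameters, is.character, logical(1))
    if (any(bad)) {
      flag(paste0("simulation.raw_parameters.", names(sim$raw_parameters)[bad][1]),
           "raw parameter values must be strings")
    }
  }

  ids <- record$simulated_object$identifiers
  for (i in seq_along(ids)) {
    db <- ids[[i]]$database
    if (is.null(db) || !db %in% names(IDENTIFIER_PATTERNS)) {
      flag(sprintf("simulated_object.identifiers[%d].database", i),
           "unsupported identifier database")
    } else if (!validate_identifier(db, ids[[i]]$id)) {
      flag(sprintf("simulated_object.identifiers[%d].id", i),
           sprintf("'%s' does not match the %s format", ids[[i]]$id, db))
    }
  }

  cd <- record$administrative$creation_date
  if (!is.null(cd)) {
    ok <- grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", cd) &&
      !is.na(suppressWarnings(as.Date(cd, format = "%Y-%m-%d")))
    if (!ok) flag("administrative.creation_date", "not an ISO-8601 calendar date")
  }

  for (path in names(record$provenance)) {
    tag <- record$provenance[[path]]
    if (!tag$method %in% c("parsed", "filename_inference", "user_supplied", "derived")) {
      flag(paste0("provenance.", path), "unknown provenance method")
    }
    if (identical(tag$method, "filename_inference") &&
          (is.null(tag$warning) || !nzchar(tag$warning))) {
      flag(paste0("provenance.", path),
           "filename_inference tags must carry a warning")
    }
  }
  for (path in populated_field_paths(record)) {
    if (!path %in% names(record$provenance)) {
      flag(paste0("provenance.", path), "populated extracted field has no provenance tag")
    }
  }

  report <- if (length(violations)) {
    data.frame(field = vapply(violations, `[[`, "", "field"),
               message = vapply(violations, `[[`, "", "message"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(field = character(), message = character(),
               stringsAsFactors = FALSE)
  }
  class(report) <- c("validation_report", class(report))
  report
}

# JSON Schema document ----------------------------------------------------------

schema_number <- function(min = NULL, exmin = NULL) {
  s <- list(type = "number")
  if (!is.null(min)) s$minimum <- min
  if (!is.null(exmin)) s$exclusiveMinimum <- exmin
  s
}

#' Emit the metadata schema
#'
#' Builds the machine-readable JSON Schema (draft-07) for metadata records.
#' It has exactly four top-level sections — `system`, `simulation`,
#' `simulated_object`, `administrative` — of which `simulation` is required;
#' service keys (`derived`, `extra`, `notes`, `provenance`) are permitted as
#' additional properties. The document encodes the same field-level
#' constraints that [validate_record()] checks.
#'
#' @param path Optional file path; when given, the schema JSON is written
#'   there.
#' @return The schema as a nested list (invisibly when `path` is given).
#' @export
emit_schema <- function(path = NULL) {
  id_schemas <- lapply(names(IDENTIFIER_PATTERNS), function(db) {
    list(type = "object",
         required = c("database", "id"),
         properties = list(
           database = list(const = db),
           id = list(type = "string", pattern = IDENTIFIER_PATTERNS[[db]])))
  })
  zero <- list(const = 0)
  pos <- schema_number(exmin = 0)
  num <- list(type = "number")
  schema <- list(
    "$schema" = "http://json-schema.org/draft-07/schema#",
    title = "MD simulation metadata record",
    type = "object",
    required = list("simulation"),
    additionalProperties = TRUE,
    properties = list(
      system = list(
        type = "object",
        properties = list(
          water_model = list(enum = as.list(c(water_model_dictionary(), "unknown"))),
          box = list(
            type = "object",
            required = c("vectors", "shape", "dimensions", "volume"),
            properties = list(
              vectors = list(
                type = "array",
                items = list(
                  list(type = "array", items = list(pos, zero, zero)),
                  list(type = "array", items = list(num, pos, zero)),
                  list(type = "array", items = list(num, num, pos)))),
              shape = list(enum = list("cubic", "rectangular", "triclinic")),
              dimensions = list(type = "array",
                                items = pos, minItems = 3, maxItems = 3),
              volume = pos)))),
      simulation = list(
        type = "object",
        properties = list(
          forcefield = list(type = "string"),
          software_information = list(type = "string"),
          dt = pos,
          nsteps = list(type = "integer", minimum = 0),
          ensemble_temperature = list(type = "array", items = pos),
          tcoupl = list(type = "string"),
          pcoupl = list(type = "string"),
          pcoupltype = list(type = "string"),
          continuation = list(type = "boolean"),
          raw_parameters = list(type = "object",
                                additionalProperties = list(type = "string")))),
      simulated_object = list(
        type = "object",
        properties = list(
          identifiers = list(type = "array", items = list(oneOf = id_schemas)))),
      administrative = list(
        type = "object",
        properties = list(
          creators = list(type = "array", items = list(type = "string")),
          institution = list(type = "string"),
          creation_date = list(type = "string",
                               pattern = "^[0-9]{4}-[0-9]{2}-[0-9]{2}$"),
          gromacs_version = list(type = "string")))))
  if (!is.null(path)) {
    jsonlite::write_json(schema, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    return(invisible(schema))
  }
  schema
}

# Generic schema applier ---------------------------------------------------------
#
# A small data-driven interpreter for the draft-07 subset emit_schema() uses:
# type, enum, const, pattern, minimum, exclusiveMinimum, minLength,
# minItems/maxItems, required, properties, additionalProperties, items
# (single schema or positional list), oneOf. It walks a JSON-shaped structure
# (named lists = objects, unnamed lists = arrays, atomics = scalars), i.e.
# what jsonlite::fromJSON(..., simplifyVector = FALSE) returns, and shares no
# logic with validate_record().

#' Validate a JSON-shaped instance against a schema document
#'
#' @param instance A JSON-shaped structure (as returned by
#'   `jsonlite::fromJSON(txt, simplifyVector = FALSE)`).
#' @param schema A schema document, e.g. from [emit_schema()].
#' @param path Instance path for error messages (internal).
#' @return Character vector of violations; empty iff the instance conforms.
#' @export
schema_validate <- function(instance, schema, path = "$") {
  errs <- character()
  say <- function(msg) errs <<- c(errs, sprintf("%s: %s", path, msg))

  is_object <- function(x) is.list(x) && !is.null(names(x)) && all(nzchar(names(x)))
  is_array <- function(x) (is.list(x) && is.null(names(x))) ||
    (is.atomic(x) && length(x) != 1)
  json_type <- function(x) {
    if (is_object(x)) return("object")
    if (is_array(x)) return("array")
    if (is.logical(x)) return("boolean")
    if (is.numeric(x)) return("number")
    if (is.character(x)) return("string")
    "null"
  }
  as_items <- function(x) if (is.list(x)) x else as.list(x)

  if (!is.null(schema$oneOf)) {
    ok <- vapply(schema$oneOf,
                 function(s) length(schema_validate(instance, s, path)) == 0,
                 logical(1))
    if (sum(ok) != 1) say(sprintf("matches %d of the oneOf alternatives", sum(ok)))
    return(errs)
  }
  if (!is.null(schema$const)) {
    if (!(length(instance) == 1 && !is.list(instance) && instance == schema$const)) {
      say(sprintf("must equal the constant '%s'", format(schema$const)))
    }
    return(errs)
  }
  if (!is.null(schema$enum)) {
    ok <- length(instance) == 1 && !is.list(instance) &&
      any(vapply(schema$enum, function(e) isTRUE(instance == e), logical(1)))
    if (!ok) say("value is not in the enumeration")
    return(errs)
  }

  t <- schema$type
  if (!is.null(t)) {
    it <- json_type(instance)
    # a length-1 atomic is also a valid singleton array
    type_ok <- it == t || (t == "array" && is.atomic(instance)) ||
      (t == "integer" && it == "number")
    if (!type_ok) { say(sprintf("expected %s, got %s", t, it)); return(errs) }
  }

  if (identical(t, "integer")) {
    if (instance != round(instance)) { say("not an integer"); return(errs) }
    t <- "number"
  }
  if (identical(t, "number")) {
    if (!is.null(schema$minimum) && instance < schema$minimum) {
      say(sprintf("%g is below the minimum %g", instance, schema$minimum))
    }
    if (!is.null(schema$exclusiveMinimum) && instance <= schema$exclusiveMinimum) {
      say(sprintf("%g is not above %g", instance, schema$exclusiveMinimum))
    }
  }
  if (identical(t, "string")) {
    if (!is.null(schema$pattern) && !grepl(schema$pattern, instance)) {
      say(sprintf("'%s' does not match pattern %s", instance, schema$pattern))
    }
    if (!is.null(schema$minLength) && nchar(instance) < schema$minLength) {
      say("string shorter than minLength")
    }
  }
  if (identical(t, "object")) {
    for (req in unlist(schema$required)) {
      if (!req %in% names(instance)) say(sprintf("missing required key '%s'", req))
    }
    for (key in names(schema$properties)) {
      if (key %in% names(instance)) {
        errs <- c(errs, schema_validate(instance[[key]], schema$properties[[key]],
                                        paste(path, key, sep = ".")))
      }
    }
    ap <- schema$additionalProperties
    if (is.list(ap)) {
      for (key in setdiff(names(instance), names(schema$properties))) {
        errs <- c(errs, schema_validate(instance[[key]], ap,
                                        paste(path, key, sep = ".")))
      }
    }
  }
  if (identical(t, "array")) {
    elems <- as_items(instance)
    if (!is.null(schema$minItems) && length(elems) < schema$minItems) {
      say("fewer items than minItems")
    }
    if (!is.null(schema$maxItems) && length(elems) > schema$maxItems) {
      say("more items than maxItems")
    }
    items <- schema$items
    if (!is.null(items)) {
      positional <- is.list(items) && is.null(names(items))
      for (i in seq_along(elems)) {
        s <- if (positional) {
          if (i <= length(items)) items[[i]] else NULL
        } else {
          items
        }
        if (!is.null(s)) {
          errs <- c(errs, schema_validate(elems[[i]], s,
                                          sprintf("%s[%d]", path, i)))
        }
      }
    }
  }
  errs
}

#' Validate a record against the emitted schema
#'
#' Serialises the record to JSON, re-parses it into a JSON-shaped structure
#' and applies the emitted schema document with the generic
#' [schema_validate()] interpreter. This is an independent route from
#' [validate_record()].
#'
#' @param record A [metadata_record()].
#' @param schema Schema document (defaults to [emit_schema()]).
#' @return Character vector of violations; empty iff the record conforms.
#' @export
schema_validate_record <- function(record, schema = emit_schema()) {
  txt <- emit_record(record, format = "json", validate = FALSE)
  schema_validate(jsonlite::fromJSON(txt, simplifyVector = FALSE), schema)
}
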