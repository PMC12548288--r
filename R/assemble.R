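# Assembly, user-metadata merging and deterministic emission --------------------

BOX_CROSSCHECK_TOL <- 1e-3  # nm; disagreement beyond this between sources is noted

#' Assemble partial records into one metadata record
#'
#' Performs a field-level union of the partial records extracted from the
#' run-input dump text (required), the topology and the structure file. When
#' two sources provide the same field the run-input value wins, and if the
#' values disagree beyond tolerance (boxes: `1e-3` nm) a cross-check note is
#' recorded. Derived quantities are computed last.
#'
#' @param dump_record Partial record from [map_to_record()] (required).
#' @param top_record Optional partial record from the topology.
#' @param gro_record Optional partial record from the structure file.
#' @param derive Compute the `derived` section (default `TRUE`).
#' @return A [metadata_record()].
#' @export
assemble <- function(dump_record = NULL, top_record = NULL, gro_record = NULL,
                     derive = TRUE) {
  if (is.null(dump_record)) {
    stop("run-input metadata required: supply the dump-text partial record")
  }
  rec <- dump_record
  notes <- rec$notes

  merge_partial <- function(rec, part) {
    if (is.null(part)) return(rec)
    for (sec in c("system", "simulation")) {
      for (field in names(part[[sec]])) {
        if (is.null(rec[[sec]][[field]])) {
          rec[[sec]][[field]] <- part[[sec]][[field]]
          path <- paste(sec, field, sep = ".")
          rec$provenance[[path]] <- part$provenance[[path]]
        }
      }
    }
    notes <<- c(notes, part$notes)
    rec
  }

  # cross-check the box when both the dump text and the .gro provide one
  if (!is.null(gro_record$system$box) && !is.null(rec$system$box)) {
    d <- abs(rec$system$box$vectors - gro_record$system$box$vectors)
    if (max(d) > BOX_CROSSCHECK_TOL) {
      notes <- c(notes, sprintf(
        "system.box: run-input and structure boxes disagree (max |diff| %.4g nm); run-input value kept",
        max(d)))
    }
  }
  rec <- merge_partial(rec, top_record)
  rec <- merge_partial(rec, gro_record)
  rec$notes <- notes
  rec <- canonicalize_record(rec)
  if (derive) rec <- add_derived(rec)
  rec
}

#' Merge user-supplied metadata into a record
#'
#' User metadata may populate the `simulated_object` and `administrative`
#' sections and arbitrary keys under `extra`. Extracted fields (`system.*`,
#' `simulation.*`) are machine ground truth: attempts to set them are
#' rejected and recorded as conflict notes. Merging is idempotent.
#'
#' @param record A [metadata_record()].
#' @param user Named list, typically read from a JSON file: keys
#'   `simulated_object`, `administrative`, `extra`.
#' @param source_file Filename for provenance tags.
#' @return The merged [metadata_record()].
#' @export
merge_user <- function(record, user, source_file = "user-metadata.json") {
  stopifnot(is_metadata_record(record))
  if (is.null(user)) return(record)
  if (!is.list(user) || (length(user) && is.null(names(user)))) {
    stop("user metadata must be a JSON object (named keys)")
  }
  notes <- record$notes
  for (sec in names(user)) {
    if (sec %in% c("system", "simulation")) {
      for (field in names(user[[sec]])) {
        notes <- c(notes, sprintf(
          "user metadata may not set extracted field %s.%s; value ignored",
          sec, field))
      }
      next
    }
    if (sec %in% c("simulated_object", "administrative")) {
      if (!is.list(user[[sec]]) || is.null(names(user[[sec]]))) {
        stop(sprintf("user metadata section '%s' must be an object", sec))
      }
      for (field in names(user[[sec]])) {
        record[[sec]][[field]] <- user[[sec]][[field]]
        record$provenance[[paste(sec, field, sep = ".")]] <-
          provenance_tag(source_file, "user_supplied")
      }
      next
    }
    if (sec == "extra") {
      for (field in names(user$extra)) {
        record$extra[[field]] <- user$extra[[field]]
      }
      next
    }
    notes <- c(notes, sprintf(
      "user metadata key '%s' is not a recognised section; value ignored", sec))
  }
  record$notes <- notes
  canonicalize_record(record)
}

# Emission -----------------------------------------------------------------------

# Record -> plain JSON-shaped list in the deterministic emission order.
record_to_document <- function(record) {
  doc <- list()
  for (sec in SECTION_ORDER) {
    if (!is.null(record[[sec]]) && length(record[[sec]])) {
      doc[[sec]] <- record[[sec]]
    }
  }
  if (!is.null(doc$system$box)) {
    box <- doc$system$box
    doc$system$box <- list(
      vectors = lapply(1:3, function(i) box$vectors[i, ]),
      shape = box$shape, dimensions = box$dimensions, volume = box$volume)
  }
  if (!is.null(doc$provenance)) {
    doc$provenance <- lapply(doc$provenance, unclass)
  }
  doc
}

# Mark which leaves must serialise as JSON arrays even when length 1.
ARRAY_FIELDS <- c("ensemble_temperature", "dimensions", "creators",
                  "identifiers", "notes", "vectors")

document_to_json_ready <- function(x, name = "") {
  if (is.list(x)) {
    if (name == "vectors") return(lapply(x, function(r) I(as.numeric(r))))
    out <- lapply(seq_along(x), function(i) {
      document_to_json_ready(x[[i]], if (is.null(names(x))) "" else names(x)[i])
    })
    names(out) <- names(x)
    return(out)
  }
  if (name %in% ARRAY_FIELDS) return(I(x))
  if (length(x) == 1) return(jsonlite::unbox(x))
  I(x)
}

#' Emit a metadata record as JSON or YAML
#'
#' Output is deterministic: sections appear in schema order (system,
#' simulation, simulated_object, administrative, derived), known fields in
#' schema-declared order, and `raw_parameters` keys alphabetically. By
#' default the record is validated first and nothing is emitted for an
#' invalid record.
#'
#' @param record A [metadata_record()].
#' @param format `"json"` or `"yaml"`.
#' @param path Optional output file; when given, text is written there.
#' @param validate Refuse to emit an invalid record (default `TRUE`).
#' @return The serialised text (invisibly when `path` is given).
#' @export
emit_record <- function(record, format = c("json", "yaml"), path = NULL,
                        validate = TRUE) {
  format <- match.arg(format)
  stopifnot(is_metadata_record(record))
  if (validate) {
    report <- validate_record(record)
    if (nrow(report)) {
      stop(structure(class = c("mdmeta_validation_error", "error", "condition"),
                     list(message = paste0(
                       "record failed validation (", nrow(report), " problem(s)):\n",
                       paste(sprintf("  %s: %s", report$field, report$message),
                             collapse = "\n")),
                       call = sys.call(-1), report = report)))
    }
  }
  doc <- record_to_document(record)
  text <- if (format == "json") {
    as.character(jsonlite::toJSON(document_to_json_ready(doc),
                                  digits = I(17), pretty = TRUE,
                                  null = "null"))
  } else {
    yaml::as.yaml(doc, precision = 17L)
  }
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

#' Parse an emitted metadata document back into a record
#'
#' Accepts the JSON or YAML text produced by [emit_record()] (format is
#' auto-detected from the content when not given) and restores the canonical
#' in-memory record, so that `parse_record(emit_record(r)) == r`.
#'
#' @param text Serialised record text, or a file path to one.
#' @param format `"json"`, `"yaml"` or `"auto"`.
#' @return A [metadata_record()].
#' @export
parse_record <- function(text, format = c("auto", "json", "yaml")) {
  format <- match.arg(format)
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    if (format == "auto") {
      format <- if (grepl("\\.ya?ml$", text, ignore.case = TRUE)) "yaml" else "json"
    }
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  }
  if (format == "auto") {
    format <- if (grepl("^\\s*\\{", text)) "json" else "yaml"
  }
  doc <- if (format == "json") {
    jsonlite::fromJSON(text, simplifyVector = FALSE)
  } else {
    yaml::yaml.load(text)
  }
  if (!is.list(doc)) stop("not a metadata document")
  canonicalize_record(doc)
}
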