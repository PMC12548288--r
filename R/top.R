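# .top topology parsing and filename-based inference --------------------------

#' Parse a GROMACS .top topology file
#'
#' Captures every `#include "..."` path in order, the `[ system ]` name and
#' the `[ molecules ]` composition. Comment lines (leading `;`) and blank
#' lines are ignored; unknown bracketed sections are skipped untouched.
#' Preprocessor conditionals (`#ifdef`) are not evaluated: includes inside
#' inactive branches are still listed, and a note flags their presence.
#'
#' @param text Character scalar (file content) or vector of lines.
#' @return A `topology_info` list with `includes` (character), `system_name`,
#'   `molecules` (list of `list(name, count)`) and `has_ifdef` (logical).
#' @export
parse_top <- function(text) {
  lines <- split_lines(text)
  includes <- character()
  system_name <- NULL
  molecules <- list()
  has_ifdef <- FALSE
  section <- NA_character_

  for (i in seq_along(lines)) {
    raw <- lines[[i]]
    line <- trimws(sub(";.*$", "", raw))
    if (!nzchar(line)) next
    if (grepl("^#ifdef\\b|^#ifndef\\b", line)) { has_ifdef <- TRUE; next }
    if (grepl("^#", line)) {
      m <- regmatches(line, regexec('^#include\\s+"([^"]+)"', line))[[1]]
      if (length(m) == 2) includes <- c(includes, m[2])
      next
    }
    sec <- regmatches(line, regexec("^\\[\\s*([^][:space:]]+)\\s*\\]$", line))[[1]]
    if (length(sec) == 2) { section <- tolower(sec[2]); next }
    if (identical(section, "system")) {
      if (is.null(system_name)) system_name <- line
    } else if (identical(section, "molecules")) {
      parts <- strsplit(line, "[[:space:]]+")[[1]]
      count <- suppressWarnings(as.numeric(parts[length(parts)]))
      if (length(parts) < 2 || is.na(count) || count != round(count) || count <= 0) {
        stop(sprintf("malformed [ molecules ] entry at line %d: '%s'", i, raw))
      }
      name <- paste(parts[-length(parts)], collapse = " ")
      molecules[[length(molecules) + 1L]] <- list(name = name, count = as.numeric(count))
    }
  }
  structure(list(includes = includes, system_name = system_name,
                 molecules = molecules, has_ifdef = has_ifdef),
            class = "topology_info")
}

#' Infer the force field from topology includes
#'
#' GROMACS force fields are distributed as `<name>.ff/` directories; the
#' first include path containing a directory component ending in `.ff` names
#' the force field (suffix stripped, lowercased). This is filename inference:
#' the contents of the included files are never inspected, so the result
#' always carries a warning.
#'
#' @param info A [parse_top()] result.
#' @param source_file Filename used in the provenance tag.
#' @return `list(name, tag)` where `name` is the force-field name or
#'   `"unknown"` and `tag` is a [provenance_tag()].
#' @export
infer_forcefield <- function(info, source_file = "topology.top") {
  name <- "unknown"
  for (inc in info$includes) {
    comps <- strsplit(inc, "/", fixed = TRUE)[[1]]
    ff <- grep("\\.ff$", comps, value = TRUE)
    if (length(ff)) {
      name <- tolower(sub("\\.ff$", "", basename(ff[[1]])))
      break
    }
  }
  warn <- if (identical(name, "unknown")) {
    "no .ff include found in the topology; force field unknown"
  } else {
    sprintf("force field '%s' inferred from the include filename; file contents were not inspected", name)
  }
  list(name = name, tag = provenance_tag(source_file, "filename_inference", warn))
}

#' Infer the water model from topology includes
#'
#' Matches the lowercased filename stem of each include against the
#' [water_model_dictionary()]; the first exact stem match wins (so
#' `tip4pew.itp` is tip4pew, never tip4p). Always filename inference with a
#' warning: a file named `opc.itp` may well contain a different model.
#'
#' @inheritParams infer_forcefield
#' @param dictionary Character vector of canonical model names.
#' @return `list(name, tag)` as in [infer_forcefield()].
#' @export
infer_water_model <- function(info, source_file = "topology.top",
                              dictionary = water_model_dictionary()) {
  name <- "unknown"
  for (inc in info$includes) {
    stem <- tolower(tools::file_path_sans_ext(basename(inc)))
    if (stem %in% dictionary) { name <- stem; break }
  }
  warn <- if (identical(name, "unknown")) {
    "no include filename matched a known water model"
  } else {
    sprintf("water model '%s' inferred from the include filename only; the .itp contents were not inspected", name)
  }
  list(name = name, tag = provenance_tag(source_file, "filename_inference", warn))
}

#' Partial metadata record from a parsed topology
#'
#' Wraps [infer_forcefield()] and [infer_water_model()] into the partial
#' record a topology contributes to [assemble()].
#'
#' @param info A [parse_top()] result.
#' @param source_file Filename used in provenance tags.
#' @param dictionary Water-model dictionary.
#' @return A partial [metadata_record()].
#' @export
top_to_record <- function(info, source_file = "topology.top",
                          dictionary = water_model_dictionary()) {
  ff <- infer_forcefield(info, source_file)
  wm <- infer_water_model(info, source_file, dictionary)
  notes <- if (isTRUE(info$has_ifdef)) {
    sprintf("%s contains #ifdef blocks; includes inside inactive branches are still listed", source_file)
  } else character()
  metadata_record(
    system = list(water_model = wm$name),
    simulation = list(forcefield = ff$name),
    notes = notes,
    provenance = list("system.water_model" = wm$tag,
                      "simulation.forcefield" = ff$tag))
}
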