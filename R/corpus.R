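# Corpus-level summary statistics -------------------------------------------------

BOX_DIM_BREAKS <- 0:30                       # nm, 1 nm bins, overflow above
DT_FS_BREAKS <- c(0, 0.5, 1, 1.5, 2, 2.5, 3, 4, 5)  # fs, overflow above
TEMP_BREAKS <- seq(250, 400, by = 5)         # K, 5 K bins, under/overflow

COUPLING_CANONICAL <- c("parrinello-rahman" = "Parrinello-Rahman",
                        "berendsen" = "Berendsen",
                        "c-rescale" = "C-rescale",
                        "v-rescale" = "V-rescale",
                        "nose-hoover" = "Nose-Hoover",
                        "no" = "no")

normalize_coupling <- function(name) {
  key <- tolower(trimws(name))
  if (key %in% names(COUPLING_CANONICAL)) COUPLING_CANONICAL[[key]] else name
}

bin_counts <- function(values, breaks, underflow = FALSE) {
  if (!length(values)) return(stats::setNames(numeric(), character()))
  lab <- function(a, b) paste0("[", a, ",", b, ")")
  labels <- c(if (underflow) paste0("<", breaks[1]),
              lab(breaks[-length(breaks)], breaks[-1]),
              paste0(">=", breaks[length(breaks)]))
  full <- c(if (underflow) -Inf, breaks, Inf)
  idx <- cut(values, breaks = full, labels = labels, right = FALSE)
  tab <- table(idx)
  out <- as.numeric(tab)
  names(out) <- names(tab)
  out[out > 0]
}

count_table <- function(values) {
  if (!length(values)) return(stats::setNames(numeric(), character()))
  tab <- table(values)
  stats::setNames(as.numeric(tab), names(tab))
}

# Which source files contributed to a record, judged from provenance tags.
record_file_presence <- function(record) {
  src <- vapply(record$provenance, `[[`, "", "source_file")
  present <- c(
    if (any(grepl("\\.(tpr|dump|txt)(\\.|$)", src, ignore.case = TRUE))) "tpr",
    if (any(grepl("\\.top$", src, ignore.case = TRUE))) "top",
    if (any(grepl("\\.gro$", src, ignore.case = TRUE))) "gro")
  if (!length(present)) "none" else paste(present, collapse = "+")
}

#' Summarise a corpus of metadata records
#'
#' Aggregates many records into the distributions a corpus overview needs:
#' box dimensions per axis (1 nm bins, 0-30 nm with overflow), time steps
#' (fs bins at 0.5-5 fs with overflow), ensemble temperatures (5 K bins,
#' 250-400 K with under/overflow), pressure- and temperature-coupling
#' algorithm counts (names normalised case-insensitively to canonical
#' spellings), software version series, creation years and source-file
#' presence combinations. Records missing a field are counted in that
#' statistic's `missing` bucket, so counts + missing = `n_records` for every
#' statistic. For records coupling groups at several temperatures the lowest
#' ensemble temperature represents the record.
#'
#' @param records List of [metadata_record()]s.
#' @return A `corpus_summary` list.
#' @export
summarize_corpus <- function(records) {
  n <- as.numeric(length(records))
  get <- function(f) lapply(records, f)
  drop_null <- function(x) x[!vapply(x, is.null, logical(1))]

  boxes <- drop_null(get(function(r) r$system$box$dimensions))
  dts <- unlist(drop_null(get(function(r) r$simulation$dt)))
  temps <- unlist(drop_null(get(function(r) {
    et <- r$simulation$ensemble_temperature
    if (is.null(et)) NULL else min(et)
  })))
  pc <- unlist(drop_null(get(function(r) r$simulation$pcoupl)))
  tc <- unlist(drop_null(get(function(r) r$simulation$tcoupl)))
  vs <- unlist(drop_null(get(function(r) {
    if (!is.null(r$derived$version_series)) return(r$derived$version_series)
    si <- r$simulation$software_information
    if (is.null(si)) NULL else version_series(si)$series
  })))
  years <- unlist(drop_null(get(function(r) {
    cd <- r$administrative$creation_date
    if (is.null(cd)) NULL else substr(cd, 1, 4)
  })))

  dim_axis <- function(i) {
    vals <- vapply(boxes, `[`, 0, i)
    bin_counts(vals, BOX_DIM_BREAKS)
  }
  summary <- list(
    n_records = as.numeric(n),
    box_dim_histogram = list(x = dim_axis(1), y = dim_axis(2), z = dim_axis(3)),
    dt_histogram = bin_counts(if (length(dts)) dts * 1000 else numeric(),
                              DT_FS_BREAKS),
    temperature_histogram = bin_counts(temps, TEMP_BREAKS, underflow = TRUE),
    pcoupl_counts = count_table(vapply(pc, normalize_coupling, "")),
    tcoupl_counts = count_table(vapply(tc, normalize_coupling, "")),
    version_series_counts = count_table(vs),
    year_counts = count_table(years),
    file_presence_counts = count_table(
      vapply(records, record_file_presence, "")),
    missing = c(box_dim = n - length(boxes),
                dt = n - length(dts),
                temperature = n - length(temps),
                pcoupl = n - length(pc),
                tcoupl = n - length(tc),
                version_series = n - length(vs),
                year = n - length(years))
  )
  structure(summary, class = "corpus_summary")
}

summary_rows <- function(summary) {
  rows <- list()
  add <- function(stat, counts) {
    for (bin in names(counts)) {
      rows[[length(rows) + 1L]] <<- list(statistic = stat, bin = bin,
                                         count = counts[[bin]])
    }
  }
  if (summary$n_records > 0) {
    rows[[1]] <- list(statistic = "n_records", bin = "", count = summary$n_records)
  }
  for (ax in c("x", "y", "z")) add(paste0("box_dim_", ax),
                                   summary$box_dim_histogram[[ax]])
  add("dt_fs", summary$dt_histogram)
  add("temperature_K", summary$temperature_histogram)
  add("pcoupl", summary$pcoupl_counts)
  add("tcoupl", summary$tcoupl_counts)
  add("version_series", summary$version_series_counts)
  add("year", summary$year_counts)
  add("file_presence", summary$file_presence_counts)
  miss <- summary$missing[summary$missing > 0]
  for (stat in names(miss)) {
    rows[[length(rows) + 1L]] <- list(statistic = stat, bin = "(missing)",
                                      count = miss[[stat]])
  }
  rows
}

named_to_object <- function(x) {
  if (!length(x)) return(stats::setNames(list(), character()))
  lapply(as.list(x), jsonlite::unbox)
}

#' Export a corpus summary
#'
#' `"json"` produces a document that [parse_summary()] restores to an equal
#' summary; `"tsv"` produces one row per (statistic, bin, count) with a fixed
#' column order and a header line (header-only for an empty corpus).
#'
#' @param summary A [summarize_corpus()] result.
#' @param format `"json"` or `"tsv"`.
#' @param path Optional output file.
#' @return The export text (invisibly when `path` is given).
#' @export
export_summary <- function(summary, format = c("json", "tsv"), path = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(summary, "corpus_summary"))
  text <- if (format == "json") {
    doc <- list(
      n_records = jsonlite::unbox(summary$n_records),
      box_dim_histogram = lapply(summary$box_dim_histogram, named_to_object),
      dt_histogram = named_to_object(summary$dt_histogram),
      temperature_histogram = named_to_object(summary$temperature_histogram),
      pcoupl_counts = named_to_object(summary$pcoupl_counts),
      tcoupl_counts = named_to_object(summary$tcoupl_counts),
      version_series_counts = named_to_object(summary$version_series_counts),
      year_counts = named_to_object(summary$year_counts),
      file_presence_counts = named_to_object(summary$file_presence_counts),
      missing = named_to_object(summary$missing))
    as.character(jsonlite::toJSON(doc, digits = NA, pretty = TRUE))
  } else {
    rows <- summary_rows(summary)
    lines <- c("statistic\tbin\tcount",
               vapply(rows, function(r) {
                 sprintf("%s\t%s\t%s", r$statistic, r$bin,
                         format(r$count, scientific = FALSE))
               }, ""))
    paste(lines, collapse = "\n")
  }
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

#' Parse an exported JSON corpus summary
#'
#' @param text JSON text from [export_summary()], or a path to it.
#' @return A `corpus_summary` equal to the exported one.
#' @export
parse_summary <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  }
  doc <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  as_counts <- function(x) {
    if (!length(x)) return(stats::setNames(numeric(), character()))
    stats::setNames(as.numeric(unlist(x)), names(x))
  }
  structure(list(
    n_records = as.numeric(doc$n_records),
    box_dim_histogram = lapply(doc$box_dim_histogram, as_counts),
    dt_histogram = as_counts(doc$dt_histogram),
    temperature_histogram = as_counts(doc$temperature_histogram),
    pcoupl_counts = as_counts(doc$pcoupl_counts),
    tcoupl_counts = as_counts(doc$tcoupl_counts),
    version_series_counts = as_counts(doc$version_series_counts),
    year_counts = as_counts(doc$year_counts),
    file_presence_counts = as_counts(doc$file_presence_counts),
    missing = as_counts(doc$missing)), class = "corpus_summary")
}
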