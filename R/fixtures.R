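# Synthetic fixture generation ----------------------------------------------------
#
# Generates mutually consistent .gro / .top / dump-text file sets with known
# ground truth, so every extraction stage is testable without real simulation
# data. Water coordinates are placeholder lattice points: extraction never
# reads coordinates, only counts atoms and parses the box line.

#' Define a synthetic fixture specification
#'
#' All physical values use GROMACS native units (nm, ps, K, bar).
#'
#' @param dt Time step in ps.
#' @param nsteps Step count.
#' @param ref_t Reference temperatures per coupling group (K).
#' @param tcoupl,pcoupl,pcoupltype Coupling algorithm names.
#' @param continuation Continuation flag.
#' @param version_string Software version, e.g. `"VERSION 5.1.4"`.
#' @param forcefield Force-field name (becomes the `.ff` include directory).
#' @param water_model Water-model name (becomes the water `.itp` include).
#' @param box 3x3 lower-triangular box matrix in nm, or a length-3 diagonal.
#' @param n_water Number of water molecules in the .gro file.
#' @param creation_date Optional ISO date for administrative metadata.
#' @param has_top,has_gro Whether the fileset includes those files.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(dt = 0.002, nsteps = 500000, ref_t = 298,
                         tcoupl = "V-rescale", pcoupl = "Parrinello-Rahman",
                         pcoupltype = "Isotropic", continuation = FALSE,
                         version_string = "VERSION 2024.3",
                         forcefield = "amber99sb-ildn", water_model = "tip3p",
                         box = c(5, 5, 5), n_water = 10,
                         creation_date = NULL, has_top = TRUE, has_gro = TRUE) {
  if (length(box) == 3) box <- diag(as.numeric(box))
  box <- matrix(as.numeric(box), 3, 3)
  spec <- list(dt = dt, nsteps = nsteps, ref_t = as.numeric(ref_t),
               tcoupl = tcoupl, pcoupl = pcoupl, pcoupltype = pcoupltype,
               continuation = isTRUE(continuation),
               version_string = version_string, forcefield = forcefield,
               water_model = water_model, box = box,
               n_water = as.integer(n_water), creation_date = creation_date,
               has_top = isTRUE(has_top), has_gro = isTRUE(has_gro))
  problems <- character()
  if (!is.numeric(dt) || dt <= 0) problems <- c(problems, "dt must be > 0 ps")
  if (!is.numeric(nsteps) || nsteps < 0 || nsteps != round(nsteps)) {
    problems <- c(problems, "nsteps must be a non-negative integer")
  }
  if (any(spec$ref_t <= 0)) problems <- c(problems, "ref_t values must be > 0 K")
  if (any(diag(box) <= 0)) problems <- c(problems, "box diagonal must be > 0 nm")
  if (any(abs(c(box[1, 2], box[1, 3], box[2, 3])) > 0)) {
    problems <- c(problems, "box must be lower-triangular")
  }
  if (spec$n_water < 0) problems <- c(problems, "n_water must be >= 0")
  if (length(problems)) {
    stop(paste(c("invalid fixture spec:", problems), collapse = "\n  "))
  }
  structure(spec, class = "fixture_spec")
}

fmt_box_num <- function(x) sprintf("%.5f", x)

generate_gro_text <- function(spec) {
  n_atoms <- spec$n_water * 3L
  lines <- c("Synthetic water box", sprintf("%5d", n_atoms))
  box <- spec$box
  # deterministic placeholder lattice; coordinates are never read back
  side <- max(1L, ceiling(spec$n_water^(1 / 3)))
  atom <- 0L
  atoms <- character(n_atoms)
  names3 <- c("OW", "HW1", "HW2")
  for (i in seq_len(spec$n_water)) {
    base <- c((i - 1) %% side, ((i - 1) %/% side) %% side,
              (i - 1) %/% (side * side)) * 0.3 + 0.15
    for (j in 1:3) {
      atom <- atom + 1L
      xyz <- base + (j - 1) * 0.05
      atoms[atom] <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                             i %% 100000L, "SOL", names3[j], atom %% 100000L,
                             xyz[1], xyz[2], xyz[3])
    }
  }
  off <- c(box[2, 1], box[3, 1], box[3, 2])
  box_line <- if (all(off == 0)) {
    paste0("   ", paste(fmt_box_num(diag(box)), collapse = "   "))
  } else {
    paste0("   ", paste(fmt_box_num(c(box[1, 1], box[2, 2], box[3, 3],
                                      box[1, 2], box[1, 3], box[2, 1],
                                      box[2, 3], box[3, 1], box[3, 2])),
                        collapse = "   "))
  }
  paste(c(lines, atoms, box_line), collapse = "\n")
}

generate_top_text <- function(spec) {
  ff <- spec$forcefield
  paste(c(
    "; synthetic topology",
    sprintf('#include "%s.ff/forcefield.itp"', ff),
    sprintf('#include "%s.ff/%s.itp"', ff, spec$water_model),
    sprintf('#include "%s.ff/ions.itp"', ff),
    "",
    "[ system ]",
    "Synthetic water box",
    "",
    "[ molecules ]",
    sprintf("SOL %16d", spec$n_water)),
    collapse = "\n")
}

generate_dump_text <- function(spec) {
  box <- spec$box
  ref_t <- paste(format(spec$ref_t, trim = TRUE, scientific = FALSE),
                 collapse = " ")
  paste(c(
    "dump rendering of run-input parameters",
    "header:",
    sprintf("   version = %s", spec$version_string),
    "inputrec:",
    sprintf("   integrator = md"),
    sprintf("   dt = %s", format(spec$dt, scientific = FALSE)),
    sprintf("   nsteps = %s", format(spec$nsteps, scientific = FALSE)),
    "   init-step = 0",
    "   cutoff-scheme = Verlet",
    "   coulombtype = PME",
    "   rcoulomb = 1.2",
    "   vdwtype = Cut-off",
    "   rvdw = 1.2",
    sprintf("   tcoupl = %s", spec$tcoupl),
    sprintf("   ref-t: %s", ref_t),
    sprintf("   tau-t: %s", paste(rep("0.1", length(spec$ref_t)), collapse = " ")),
    sprintf("   pcoupl = %s", spec$pcoupl),
    sprintf("   pcoupltype = %s", spec$pcoupltype),
    "   tau-p = 2",
    "   ref-p = 1",
    sprintf("   continuation = %s", if (spec$continuation) "true" else "false"),
    "   constraints = h-bonds",
    "   constraint-algorithm = Lincs",
    "box:",
    sprintf("   box[%d] = { %s }", 0:2,
            vapply(1:3, function(i) paste(fmt_box_num(box[i, ]), collapse = ", "), ""))),
    collapse = "\n")
}

#' Generate a mutually consistent synthetic fileset
#'
#' Produces the texts of a .gro structure file, a .top topology and the
#' dump-text rendering of the run input, all encoding the same spec: the box
#' appears identically in the .gro and the dump text, and the force field and
#' water model appear as include filenames in the topology. Output is a pure
#' function of the spec (byte-identical for identical specs).
#'
#' @param spec A [fixture_spec()].
#' @return Named list of texts: `dump`, plus `top` and `gro` when the spec
#'   includes them.
#' @export
generate_fileset <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  out <- list(dump = generate_dump_text(spec))
  if (spec$has_top) out$top <- generate_top_text(spec)
  if (spec$has_gro) out$gro <- generate_gro_text(spec)
  out
}

#' Built-in fixture presets
#'
#' `tonb_ctd` mirrors the annotation profile of a deposited bacterial
#' TonB C-terminal-domain simulation set: GROMACS 5.1.4, force field
#' amber99sb-ildn, Parrinello-Rahman isotropic pressure coupling, dt 0.002 ps
#' and nsteps 50000000 (a 100 ns segment), with three variants pairing the
#' water models tip3p / tip4pew / opc with ensemble temperatures
#' 298 / 303 / 310 K and `continuation = true`.
#'
#' @param name Preset name; currently `"tonb_ctd"`.
#' @return A list of [fixture_spec()] variants.
#' @export
fixture_preset <- function(name = "tonb_ctd") {
  presets <- list(
    tonb_ctd = function() {
      wm <- c("tip3p", "tip4pew", "opc")
      tt <- c(298, 303, 310)
      lapply(1:3, function(i) {
        fixture_spec(dt = 0.002, nsteps = 50000000, ref_t = tt[i],
                     tcoupl = "V-rescale", pcoupl = "Parrinello-Rahman",
                     pcoupltype = "Isotropic", continuation = TRUE,
                     version_string = "VERSION 5.1.4",
                     forcefield = "amber99sb-ildn", water_model = wm[i],
                     box = c(8, 8, 8), n_water = 100)
      })
    })
  if (!name %in% names(presets)) {
    stop(sprintf("unknown preset '%s'; available: %s", name,
                 paste(names(presets), collapse = ", ")))
  }
  presets[[name]]()
}

#' Default corpus distribution configuration
#'
#' Ground-truth distributions for synthetic corpora: box edges uniform on
#' 5-15 nm (the typical protein-in-water range), time steps 1 or 2 fs with
#' 2 fs dominant, ensemble temperatures around room and body temperature,
#' and coupling algorithms drawn from the common category sets with
#' Parrinello-Rahman / V-rescale / Nose-Hoover dominant.
#'
#' @return Named list of distribution settings.
#' @export
corpus_config <- function() {
  list(
    box_range = c(5, 15),
    dt_choices = c(0.001, 0.002), dt_weights = c(0.15, 0.85),
    ref_t_choices = c(298, 303, 310), ref_t_weights = c(0.5, 0.15, 0.35),
    pcoupl_choices = c("Parrinello-Rahman", "Berendsen", "C-rescale", "no"),
    pcoupl_weights = c(0.6, 0.2, 0.1, 0.1),
    tcoupl_choices = c("V-rescale", "Nose-Hoover", "Berendsen", "no"),
    tcoupl_weights = c(0.45, 0.35, 0.15, 0.05),
    version_choices = c("VERSION 4.6.7", "VERSION 5.1.4", "VERSION 2021.5",
                        "VERSION 2024.3"),
    version_weights = c(0.25, 0.2, 0.25, 0.3),
    forcefield_choices = c("amber99sb-ildn", "charmm36-jul2022", "oplsaa",
                           "gromos54a7"),
    water_choices = c("tip3p", "tip4pew", "spce", "opc"),
    nsteps_range = c(1e5, 5e7),
    p_top = 0.8, p_gro = 0.7)
}

#' Generate a corpus of random fixture specs
#'
#' Draws `n` independent specs from the configured distributions; fully
#' reproducible from the seed.
#'
#' @param n Number of specs.
#' @param config Distribution configuration, see [corpus_config()].
#' @param seed Integer RNG seed.
#' @return List of [fixture_spec()]s.
#' @export
generate_corpus <- function(n, config = corpus_config(), seed = 1L) {
  stopifnot(n >= 0)
  if (n == 0) return(list())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pick <- function(choices, weights = NULL) {
    sample(choices, 1, prob = weights)
  }
  lapply(seq_len(n), function(i) {
    fixture_spec(
      dt = pick(config$dt_choices, config$dt_weights),
      nsteps = round(stats::runif(1, config$nsteps_range[1], config$nsteps_range[2])),
      ref_t = pick(config$ref_t_choices, config$ref_t_weights),
      tcoupl = pick(config$tcoupl_choices, config$tcoupl_weights),
      pcoupl = pick(config$pcoupl_choices, config$pcoupl_weights),
      pcoupltype = "Isotropic",
      continuation = stats::runif(1) < 0.3,
      version_string = pick(config$version_choices, config$version_weights),
      forcefield = pick(config$forcefield_choices),
      water_model = pick(config$water_choices),
      box = round(stats::runif(3, config$box_range[1], config$box_range[2]), 5),
      n_water = sample(5:20, 1),
      creation_date = sprintf("20%02d-%02d-%02d", sample(18:25, 1),
                              sample(1:12, 1), sample(1:28, 1)),
      has_top = stats::runif(1) < config$p_top,
      has_gro = stats::runif(1) < config$p_gro)
  })
}

#' Build the metadata record a fixture spec should extract to
#'
#' Runs the full pipeline (generate the fileset, parse each file, assemble)
#' on an in-memory spec. This is the extraction ground-truth path used by the
#' recovery tests and corpus studies.
#'
#' @param spec A [fixture_spec()].
#' @return A [metadata_record()].
#' @export
extract_fileset <- function(spec) {
  fs <- generate_fileset(spec)
  rec <- assemble(
    dump_record = map_to_record(parse_dump(fs$dump), "runinput.tpr.dump"),
    top_record = if (!is.null(fs$top)) top_to_record(parse_top(fs$top), "topol.top"),
    gro_record = if (!is.null(fs$gro)) gro_to_record(parse_gro(fs$gro), "conf.gro"))
  if (!is.null(spec$creation_date)) {
    rec <- merge_user(rec, list(administrative = list(
      creation_date = spec$creation_date)))
  }
  rec
}
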