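# Shared generators: random fixture specs, fully populated records and
# targeted corruptions, all deterministic under set.seed().

VALID_IDS <- list(
  list(database = "PDB", id = "5lw8"),
  list(database = "PDB", id = "6fip"),
  list(database = "UniProt", id = "P12345"),
  list(database = "PubChem", id = "2244"),
  list(database = "ChEMBL", id = "CHEMBL25"),
  list(database = "DrugBank", id = "DB00945"),
  list(database = "LIPIDMAPS", id = "LMGP01010005"))

random_spec <- function() {
  cfg <- corpus_config()
  tric <- runif(1) < 0.3
  d <- round(runif(3, 5, 15), 5)
  box <- diag(d)
  if (tric) box[2, 1] <- round(d[1] / 2, 5)
  fixture_spec(
    dt = sample(c(0.001, 0.002, 0.0025), 1),
    nsteps = sample.int(5e7, 1),
    ref_t = sort(sample(c(298, 303, 310, 323), sample(1:2, 1))),
    tcoupl = sample(cfg$tcoupl_choices, 1),
    pcoupl = sample(cfg$pcoupl_choices, 1),
    pcoupltype = sample(c("Isotropic", "Semiisotropic"), 1),
    continuation = runif(1) < 0.5,
    version_string = sample(cfg$version_choices, 1),
    forcefield = sample(cfg$forcefield_choices, 1),
    water_model = sample(cfg$water_choices, 1),
    box = box,
    n_water = sample(3:12, 1),
    has_top = runif(1) < 0.9,
    has_gro = runif(1) < 0.9)
}

random_user_metadata <- function() {
  user <- list()
  if (runif(1) < 0.7) {
    user$simulated_object <- list(
      identifiers = sample(VALID_IDS, sample(1:2, 1)))
  }
  if (runif(1) < 0.7) {
    user$administrative <- list(
      creators = sample(c("A. Author", "B. Builder", "C. Curator"),
                        sample(1:2, 1)),
      institution = "Example Institute",
      creation_date = sprintf("202%d-0%d-1%d", sample(0:5, 1),
                              sample(1:9, 1), sample(0:9, 1)),
      gromacs_version = "2024.3")
  }
  if (runif(1) < 0.5) {
    user$extra <- list(project = "synthetic-benchmark",
                       replicate = sample(1:5, 1))
  }
  user
}

# A fully populated record that passes validate_record().
random_valid_record <- function() {
  rec <- extract_fileset(random_spec())
  merge_user(rec, random_user_metadata())
}

CORRUPTION_CLASSES <- c("negative_dt", "negative_nsteps", "negative_temperature",
                        "unknown_water_model", "bad_identifier",
                        "missing_simulation", "bad_creation_date",
                        "bad_box_shape", "nonstring_raw_parameter")

# Direct structural surgery (no re-canonicalisation), so the defect survives
# into the emitted JSON exactly as planted.
corrupt_record <- function(rec, class = sample(CORRUPTION_CLASSES, 1)) {
  switch(class,
    negative_dt = { rec$simulation$dt <- -0.002; rec },
    negative_nsteps = { rec$simulation$nsteps <- -5; rec },
    negative_temperature = { rec$simulation$ensemble_temperature <- -300; rec },
    unknown_water_model = { rec$system$water_model <- "notawater"; rec },
    bad_identifier = {
      rec$simulated_object$identifiers <- list(list(database = "PDB", id = "x"))
      rec
    },
    missing_simulation = { rec$simulation <- NULL; rec },
    bad_creation_date = { rec$administrative$creation_date <- "someday"; rec },
    bad_box_shape = {
      if (is.null(rec$system$box)) {
        rec$system$box <- box_geometry(diag(c(5, 6, 7)))
        rec$provenance[["system.box"]] <- provenance_tag("conf.gro", "parsed")
      }
      rec$system$box$shape <- "spherical"
      rec
    },
    nonstring_raw_parameter = { rec$simulation$raw_parameters$integrator <- 5; rec },
    stop("unknown corruption class"))
}
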