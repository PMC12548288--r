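DUMP_EXAMPLE <- "
header:
   version = VERSION 5.1.4
inputrec:
   integrator = md
   dt = 0.002
   nsteps = 50000000
   tcoupl = V-rescale
   ref-t: 298 298
   pcoupl = Parrinello-Rahman
   pcoupltype = Isotropic
   continuation = true
box:
   box[0] = { 5.00000, 0.00000, 0.00000 }
   box[1] = { 0.00000, 5.00000, 0.00000 }
   box[2] = { 0.00000, 0.00000, 5.00000 }
"

test_that("key = value lines are captured and known keys typed", {
  d <- parse_dump(DUMP_EXAMPLE)
  expect_equal(d$typed$dt, 0.002)
  expect_equal(d$typed$nsteps, 50000000)
  expect_equal(d$typed$pcoupl, "Parrinello-Rahman")
  expect_equal(d$typed$tcoupl, "V-rescale")
  expect_equal(d$typed$ref_t, c(298, 298))
  expect_true(d$typed$continuation)
  expect_equal(d$version_string, "VERSION 5.1.4")
  expect_equal(d$params$integrator, "md")
  expect_equal(unname(diag(d$box)), c(5, 5, 5))
})

test_that("key synonyms across version series are normalised", {
  d <- parse_dump(c("pcoupl-type = Semiisotropic",
                    "unconstrained-start = no",
                    "ref-t[0] = 298", "ref-t[1] = 310"))
  expect_equal(d$typed$pcoupltype, "Semiisotropic")
  expect_false(d$typed$continuation)
  expect_equal(d$typed$ref_t, c(298, 310))
})

test_that("uncoercible typed values, empty and binary input are rejected", {
  expect_error(parse_dump("dt = abc"), "dt.*abc")
  expect_error(parse_dump(""), "empty dump text")
  expect_error(parse_dump("   \n  "), "empty dump text")
  expect_error(parse_dump(rawToChar(as.raw(c(137, 80, 78, 71)))), "binary")
  expect_error(parse_dump("nsteps = soon"), "nsteps")
})

test_that("map_to_record fills the simulation section with provenance", {
  rec <- map_to_record(parse_dump(DUMP_EXAMPLE), "run.tpr.dump")
  expect_equal(rec$simulation$software_information, "GROMACS 5.1.4")
  expect_true(rec$simulation$continuation)
  expect_equal(rec$simulation$ensemble_temperature, 298)  # sorted unique
  expect_equal(rec$system$box$shape, "cubic")
  expect_equal(rec$provenance[["simulation.dt"]]$method, "parsed")
  expect_equal(rec$provenance[["simulation.dt"]]$source_file, "run.tpr.dump")

  empty <- structure(list(version_string = NULL, params = list(),
                          typed = list(), box = NULL),
                     class = "dump_parameters")
  rec <- map_to_record(empty)
  expect_null(rec$simulation$dt)
  expect_length(rec$provenance, 0)
})

test_that("no key is lost or duplicated between typed fields and raw parameters", {
  set.seed(3)
  for (i in 1:50) {
    d <- parse_dump(generate_fileset(random_spec())$dump)
    rec <- map_to_record(d)
    n_typed <- sum(c("dt", "nsteps", "ref_t", "continuation", "tcoupl",
                     "pcoupl", "pcoupltype") %in% names(d$params))
    expect_equal(n_typed + length(rec$simulation$raw_parameters),
                 length(d$params))
    expect_false(any(names(rec$simulation$raw_parameters) %in%
                       c("dt", "nsteps", "ref_t", "continuation")))
  }
})

test_that("parse recovers every generated parameter exactly", {
  set.seed(9)
  for (i in 1:100) {
    spec <- random_spec()
    d <- parse_dump(generate_fileset(spec)$dump)
    expect_identical(d$typed$dt, spec$dt)
    expect_identical(d$typed$nsteps, as.numeric(spec$nsteps))
    expect_identical(d$typed$ref_t, spec$ref_t)
    expect_identical(d$typed$tcoupl, spec$tcoupl)
    expect_identical(d$typed$pcoupl, spec$pcoupl)
    expect_identical(d$typed$pcoupltype, spec$pcoupltype)
    expect_identical(d$typed$continuation, spec$continuation)
    expect_equal(d$version_string, spec$version_string)
    expect_true(all(abs(d$box - spec$box) < 1e-4))
  }
})
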