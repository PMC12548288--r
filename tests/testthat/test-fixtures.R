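test_that("filesets are byte-identical for identical specs", {
  spec <- fixture_preset()[[1]]
  expect_identical(generate_fileset(spec), generate_fileset(spec))
  expect_identical(generate_corpus(25, seed = 99), generate_corpus(25, seed = 99))
})

test_that("invalid specs are rejected with the violations listed", {
  expect_error(fixture_spec(dt = -1), "dt must be")
  expect_error(fixture_spec(nsteps = -1, ref_t = -3), "nsteps.*\n.*ref_t")
  m <- diag(c(5, 5, 5)); m[1, 2] <- 1
  expect_error(fixture_spec(box = m), "lower-triangular")
})

test_that("the full pipeline reproduces the preset annotation values", {
  specs <- fixture_preset("tonb_ctd")
  water <- character(); temps <- numeric()
  for (spec in specs) {
    rec <- extract_fileset(spec)
    expect_identical(rec$simulation$software_information, "GROMACS 5.1.4")
    expect_identical(rec$simulation$forcefield, "amber99sb-ildn")
    expect_identical(rec$simulation$pcoupl, "Parrinello-Rahman")
    expect_identical(rec$simulation$pcoupltype, "Isotropic")
    expect_identical(rec$simulation$dt, 0.002)
    expect_identical(rec$simulation$nsteps, 50000000)
    expect_true(rec$simulation$continuation)
    expect_identical(rec$derived$duration_ns, 100)
    water <- c(water, rec$system$water_model)
    temps <- c(temps, rec$simulation$ensemble_temperature)
  }
  expect_setequal(water, c("tip3p", "tip4pew", "opc"))
  expect_setequal(temps, c(298, 303, 310))
  expect_error(fixture_preset("nope"), "tonb_ctd")
})

test_that("an opc include is reported as opc with a filename-inference warning", {
  spec <- fixture_preset()[[3]]
  rec <- extract_fileset(spec)
  expect_identical(rec$system$water_model, "opc")
  tag <- rec$provenance[["system.water_model"]]
  expect_identical(tag$method, "filename_inference")
  expect_match(tag$warning, "not inspected")
  expect_match(generate_fileset(spec)$top, '"amber99sb-ildn.ff/opc.itp"',
               fixed = TRUE)
})

test_that("end-to-end extraction recovers every spec field", {
  set.seed(61)
  for (i in 1:60) {
    spec <- random_spec()
    rec <- extract_fileset(spec)
    expect_identical(rec$simulation$dt, spec$dt)
    expect_identical(rec$simulation$nsteps, as.numeric(spec$nsteps))
    expect_identical(rec$simulation$ensemble_temperature,
                     sort(unique(spec$ref_t)))
    expect_identical(rec$simulation$tcoupl, spec$tcoupl)
    expect_identical(rec$simulation$pcoupl, spec$pcoupl)
    expect_identical(rec$simulation$continuation, spec$continuation)
    expect_true(all(abs(rec$system$box$vectors - spec$box) < 1e-4))
    if (spec$has_top) {
      expect_identical(rec$system$water_model, spec$water_model)
      expect_identical(rec$simulation$forcefield, spec$forcefield)
    } else {
      expect_null(rec$system$water_model)
    }
  }
})

test_that("corpus draws follow the configured distributions", {
  expect_identical(generate_corpus(0), list())
  specs <- generate_corpus(1000, seed = 62)
  dts <- vapply(specs, `[[`, 0, "dt")
  # dt = 2 fs is drawn with weight 0.85; its empirical mode is certain
  # far beyond 3 sigma (sd ~ 11 records around a mean of 850)
  expect_gt(sum(dts == 0.002), 850 - 3 * sqrt(1000 * 0.85 * 0.15))
  expect_equal(names(which.max(table(dts))), "0.002")
  temps <- vapply(specs, function(s) s$ref_t[1], 0)
  expect_true(all(temps %in% c(298, 303, 310)))
  boxes <- t(vapply(specs, function(s) diag(s$box), numeric(3)))
  expect_true(all(boxes >= 5 & boxes <= 15))
})
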