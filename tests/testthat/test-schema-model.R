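test_that("identifier formats follow the registry patterns", {
  expect_true(validate_identifier("PDB", "6fip"))
  expect_true(validate_identifier("PDB", "5lw8"))
  expect_false(validate_identifier("PDB", "x"))
  expect_false(validate_identifier("PDB", "abcd"))  # must start with a digit
  expect_true(validate_identifier("ChEMBL", "CHEMBL25"))
  expect_false(validate_identifier("ChEMBL", "CHEMBL"))
  expect_true(validate_identifier("UniProt", "P12345"))
  expect_true(validate_identifier("UniProt", "A0A024R161"))
  expect_false(validate_identifier("UniProt", "12345"))
  expect_true(validate_identifier("PubChem", "2244"))
  expect_true(validate_identifier("DrugBank", "DB00945"))
  expect_false(validate_identifier("DrugBank", "DB1"))
  expect_true(validate_identifier("LIPIDMAPS", "LMGP01010005"))
  expect_error(validate_identifier("KEGG", "C00001"), "PDB")
})

test_that("a fully populated extracted record validates cleanly", {
  set.seed(31)
  rec <- merge_user(extract_fileset(fixture_preset()[[1]]),
                    list(simulated_object = list(identifiers = list(
                           list(database = "PDB", id = "5lw8"))),
                         administrative = list(creators = c("A. Author"),
                                               creation_date = "2025-04-15")))
  report <- validate_record(rec)
  expect_s3_class(report, "validation_report")
  expect_equal(nrow(report), 0)
  # validation is pure
  expect_identical(validate_record(rec), validate_record(rec))
})

test_that("violations are reported at their dotted field paths", {
  rec <- extract_fileset(fixture_preset()[[1]])
  bad <- rec
  bad$simulation$dt <- -0.002
  report <- validate_record(bad)
  expect_equal(report$field, "simulation.dt")
  expect_equal(nrow(report), 1)
  # the record passed in is not modified
  expect_identical(bad$simulation$dt, -0.002)

  report <- validate_record(corrupt_record(rec, "negative_temperature"))
  expect_true("simulation.ensemble_temperature" %in% report$field)
  report <- validate_record(corrupt_record(rec, "bad_identifier"))
  expect_match(report$field, "identifiers", all = FALSE)
})

test_that("the emitted schema has exactly four top-level sections", {
  schema <- emit_schema()
  expect_length(schema$properties, 4)
  expect_setequal(names(schema$properties),
                  c("system", "simulation", "simulated_object", "administrative"))
  expect_equal(unlist(schema$required), "simulation")
  expect_match(schema[["$schema"]], "json-schema.org")
  # writing the document produces valid JSON
  path <- tempfile(fileext = ".json")
  emit_schema(path)
  expect_length(jsonlite::fromJSON(path, simplifyVector = FALSE)$properties, 4)
})

test_that("the schema accepts the preset record and rejects section-less records", {
  rec <- extract_fileset(fixture_preset()[[1]])
  expect_length(schema_validate_record(rec), 0)
  nosim <- corrupt_record(rec, "missing_simulation")
  errs <- schema_validate_record(nosim)
  expect_match(errs, "simulation", all = FALSE)
})

test_that("hand-rolled validation and the schema document agree record by record", {
  set.seed(33)
  for (i in 1:60) {
    rec <- random_valid_record()
    if (i %% 2 == 0) rec <- corrupt_record(rec)
    by_rules <- nrow(validate_record(rec)) == 0
    by_schema <- length(schema_validate_record(rec)) == 0
    expect_identical(by_rules, by_schema)
  }
})
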