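dump_rec_for <- function(spec) {
  map_to_record(parse_dump(generate_fileset(spec)$dump), "run.tpr.dump")
}

test_that("assembly requires the run-input partial record", {
  expect_error(assemble(NULL), "run-input metadata required")
  spec <- fixture_preset()[[1]]
  rec <- assemble(dump_rec_for(spec))
  expect_equal(rec$simulation$dt, 0.002)
  expect_null(rec$system$water_model)  # no topology supplied
})

test_that("the run-input box wins and disagreements are noted", {
  spec <- fixture_preset()[[1]]
  dump_rec <- dump_rec_for(spec)

  same_gro <- gro_to_record(parse_gro(generate_fileset(spec)$gro), "conf.gro")
  rec <- assemble(dump_rec, gro_record = same_gro)
  expect_length(rec$notes, 0)
  expect_equal(rec$provenance[["system.box"]]$source_file, "run.tpr.dump")

  other <- fixture_spec(box = c(8, 8, 8.2))
  other_gro <- gro_to_record(parse_gro(generate_fileset(other)$gro), "conf.gro")
  rec <- assemble(dump_rec, gro_record = other_gro)
  expect_match(rec$notes, "system.box", all = FALSE)
  expect_equal(rec$system$box$dimensions, c(8, 8, 8))  # dump value kept
})

test_that("assembly is insensitive to which optional sources are present first", {
  spec <- fixture_preset()[[2]]
  fs <- generate_fileset(spec)
  dump_rec <- map_to_record(parse_dump(fs$dump), "run.tpr.dump")
  top_rec <- top_to_record(parse_top(fs$top), "topol.top")
  gro_rec <- gro_to_record(parse_gro(fs$gro), "conf.gro")
  a <- assemble(dump_rec, top_record = top_rec, gro_record = gro_rec)
  b <- assemble(dump_rec, gro_record = gro_rec, top_record = top_rec)
  expect_identical(a, b)
})

test_that("user metadata fills its own sections and never extracted fields", {
  rec <- assemble(dump_rec_for(fixture_preset()[[1]]))
  merged <- merge_user(rec, list(administrative = list(creators = list("A. Author"))))
  expect_equal(merged$administrative$creators, "A. Author")
  expect_equal(merged$provenance[["administrative.creators"]]$method,
               "user_supplied")

  expect_identical(merge_user(rec, list()), rec)

  conflicted <- merge_user(rec, list(simulation = list(dt = 0.001)))
  expect_equal(conflicted$simulation$dt, rec$simulation$dt)
  expect_match(conflicted$notes, "simulation.dt", all = FALSE)

  expect_error(merge_user(rec, list(administrative = "notanobject")),
               "administrative")
})

test_that("merging the same user metadata twice changes nothing", {
  set.seed(41)
  for (i in 1:20) {
    rec <- extract_fileset(random_spec())
    user <- random_user_metadata()
    user$simulation <- list(dt = 999)  # provokes a conflict note
    once <- merge_user(rec, user)
    twice <- merge_user(once, user)
    expect_identical(once, twice)
  }
})

test_that("emission is deterministic and ordered by schema section", {
  rec <- extract_fileset(fixture_preset()[[1]])
  y <- emit_record(rec, "yaml")
  top_keys <- sub(":.*", "", grep("^[a-z_]+:", strsplit(y, "\n")[[1]], value = TRUE))
  expect_identical(top_keys, c("system", "simulation", "derived", "provenance"))
  rp <- names(rec$simulation$raw_parameters)
  expect_identical(rp, sort(rp))
  expect_identical(emit_record(rec, "json"), emit_record(rec, "json"))
})

test_that("invalid records are not emitted", {
  bad <- corrupt_record(extract_fileset(fixture_preset()[[1]]), "negative_dt")
  err <- tryCatch(emit_record(bad, "json"), error = function(e) e)
  expect_s3_class(err, "mdmeta_validation_error")
  expect_equal(err$report$field, "simulation.dt")
})

test_that("records survive JSON and YAML round trips unchanged", {
  set.seed(43)
  for (i in 1:40) {
    rec <- random_valid_record()
    expect_identical(parse_record(emit_record(rec, "json"), "json"), rec)
    expect_identical(parse_record(emit_record(rec, "yaml"), "yaml"), rec)
  }
})
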