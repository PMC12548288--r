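TOP_EXAMPLE <- '
; generated topology
#include "amber99sb-ildn.ff/forcefield.itp"
#include "amber99sb-ildn.ff/tip4pew.itp"
#include "amber99sb-ildn.ff/ions.itp"

[ system ]
Protein in water

[ molecules ]
Protein_chain_A 1
SOL 12000
'

test_that("includes, system name and molecule composition are parsed in order", {
  info <- parse_top(TOP_EXAMPLE)
  expect_equal(info$includes[1], "amber99sb-ildn.ff/forcefield.itp")
  expect_length(info$includes, 3)
  expect_equal(info$system_name, "Protein in water")
  expect_equal(info$molecules,
               list(list(name = "Protein_chain_A", count = 1),
                    list(name = "SOL", count = 12000)))

  empty <- parse_top("")
  expect_length(empty$includes, 0)
  expect_null(empty$system_name)
  expect_length(empty$molecules, 0)
})

test_that("malformed molecule counts raise an error naming the line", {
  bad <- "[ molecules ]\nSOL twelve"
  expect_error(parse_top(bad), "line 2")
})

test_that("parsing ignores comments and blank lines", {
  set.seed(11)
  for (i in 1:20) {
    spec <- random_spec()
    txt <- generate_fileset(fixture_spec(forcefield = spec$forcefield,
                                         water_model = spec$water_model,
                                         n_water = spec$n_water))$top
    lines <- strsplit(txt, "\n")[[1]]
    stripped <- lines[!grepl("^\\s*(;.*)?$", lines)]
    expect_identical(parse_top(txt), parse_top(stripped))
  }
})

test_that("force field is inferred from the first .ff include directory", {
  ff <- infer_forcefield(parse_top(TOP_EXAMPLE))
  expect_equal(ff$name, "amber99sb-ildn")
  expect_equal(ff$tag$method, "filename_inference")

  ff <- infer_forcefield(parse_top('#include "charmm36-jul2022.ff/forcefield.itp"'))
  expect_equal(ff$name, "charmm36-jul2022")

  ff <- infer_forcefield(parse_top('#include "posre.itp"'))
  expect_equal(ff$name, "unknown")
  expect_match(ff$tag$warning, "unknown")
})

test_that("water-model inference is exact on the filename stem", {
  wm <- infer_water_model(parse_top(TOP_EXAMPLE))
  expect_equal(wm$name, "tip4pew")  # never collapses to tip4p
  expect_equal(infer_water_model(parse_top('#include "ff.ff/tip4p.itp"'))$name,
               "tip4p")
  opc <- infer_water_model(parse_top('#include "custom/opc.itp"'))
  expect_equal(opc$name, "opc")
  expect_match(opc$tag$warning, "not inspected")
  expect_equal(infer_water_model(parse_top('#include "mywater_custom.itp"'))$name,
               "unknown")
})

test_that("every inferred value carries filename_inference and a warning", {
  set.seed(5)
  for (i in 1:100) {
    spec <- random_spec()
    spec$has_top <- TRUE
    rec <- top_to_record(parse_top(generate_fileset(spec)$top))
    for (path in c("system.water_model", "simulation.forcefield")) {
      tag <- rec$provenance[[path]]
      expect_equal(tag$method, "filename_inference")
      expect_gt(nchar(tag$warning), 0)
    }
  }
})

test_that("#ifdef blocks are flagged but their includes are still listed", {
  txt <- '#ifdef POSRES\n#include "posre.itp"\n#endif'
  info <- parse_top(txt)
  expect_true(info$has_ifdef)
  expect_equal(info$includes, "posre.itp")
  rec <- top_to_record(info, "topol.top")
  expect_match(rec$notes, "#ifdef")
})
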