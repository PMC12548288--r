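Package: mdmeta
Title: Metadata Extraction and Annotation for GROMACS Molecular Dynamics Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parses GROMACS simulation input files (structure .gro files,
    topology .top files, and dump-text renderings of binary .tpr run-input
    files) and assembles a validated, four-part metadata record covering the
    simulated system, the simulation parameters, the simulated object, and
    administrative information. Force fields and water models are inferred
    from topology include filenames with explicit provenance tagging.
    Records are emitted as deterministic JSON or YAML, validated against a
    machine-readable JSON Schema, and can be aggregated into corpus-level
    summary statistics (box dimensions, time steps, temperatures, coupling
    algorithms, version series). A synthetic fixture generator produces
    mutually consistent file sets and whole corpora for testing.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
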