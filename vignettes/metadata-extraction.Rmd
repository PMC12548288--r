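---
title: "Extracting and validating molecular-dynamics simulation metadata"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting and validating molecular-dynamics simulation metadata}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdmeta)
```

## The problem

Molecular-dynamics (MD) simulations produced with GROMACS are increasingly
deposited in generalist repositories, usually as bare file bundles with
little or no structured description. Yet the input files themselves carry
almost everything a reader needs to judge whether a deposited simulation is
relevant: the binary run-input file (`.tpr`) holds every run parameter, the
topology (`.top`) names the force field and water model through its
`#include` directives, and the structure file (`.gro`) carries the periodic
box. `mdmeta` turns those files into a validated, machine-readable metadata
record (JSON or YAML) and aggregates many records into corpus-level summary
statistics.

The binary `.tpr` format is deliberately not decoded here. GROMACS ships a
dump utility that renders the run input as human-readable text; `mdmeta`
consumes that dump text. This keeps the package pure R, keeps it stable
across the long series of run-input format revisions, and matches how
practitioners already inspect `.tpr` files.

## The metadata model

A record has four logical parts:

* **system** — the physical setup: the water model and the box geometry
  (3×3 lower-triangular vectors in nm, classified as cubic, rectangular or
  triclinic, with dimensions and volume).
* **simulation** — the force field, the software version and the run
  parameters: time step `dt` (ps), step count `nsteps`, temperature and
  pressure coupling algorithms, the `continuation` flag, the sorted unique
  ensemble temperatures (K), and every remaining parsed key verbatim in
  `raw_parameters`.
* **simulated_object** — external identifiers of what was simulated (PDB,
  UniProt, PubChem, ChEMBL, DrugBank, LIPID MAPS), each checked against the
  accession pattern its registry publishes.
* **administrative** — creators, institution, creation date, software
  version used for deposition.

Two service parts complete a record: `derived` holds quantities computed
from other fields, and every populated extracted field carries a
**provenance tag** (`source_file`, `method`, optional `warning`). Methods
are `parsed` (read directly from a file), `filename_inference` (guessed
from a filename — always with a warning), `user_supplied` and `derived`.

Units are GROMACS native throughout: nm, ps, K, bar.

## Extraction routes and their reliability

Run parameters are parsed from the dump text dialect documented in
`?parse_dump`: one `key = value` pair per line, `key: v1 v2` arrays,
indexed `key[0] = v` lines, and `box[i] = { x, y, z }` rows. Key spellings
that drift across version series are normalised (`pcoupl-type` →
`pcoupltype`, `unconstrained-start` → `continuation`, `ref-t`/`ref_t` →
`ref_t`). These values are trustworthy: they come from the file that
actually drove the simulation.

The force field and water model are different. They are inferred from the
*filenames* of topology includes: the first directory component ending in
`.ff` names the force field, and the first include whose lowercased stem
matches the water-model dictionary (`spc`, `spce`, `tip3p`, `tip4p`,
`tip4pew`, `tip4p2005`, `tip5p`, `opc`, `opc3`, `opc4`) names the water
model. Matching is exact on the stem, never substring, so `tip4pew.itp` is
reported as tip4pew and can never collapse to tip4p — a distinction that
matters because tip4pew is reparameterised for Ewald electrostatics.
Filename inference can still be wrong in a way no parser can detect: a file
named `opc.itp` may contain a different model entirely. That is why every
inferred value carries `method = "filename_inference"` and a warning that
the file contents were not inspected, and why the contents of `.itp` files
are deliberately never analysed. Preprocessor conditionals are not
evaluated either; includes inside `#ifdef` branches are listed, with a note
when conditionals are present.

When both the dump text and a `.gro` file provide the box, the run-input
value wins and a cross-check note is recorded if they disagree by more than
1e-3 nm (the `.gro` box is printed at 1e-5 nm resolution, so genuine
disagreement is visible well above noise).

## Derived quantities

The segment length is `dt × nsteps` (reported in ps and ns); for a
`continuation = true` run this is the final segment only, not the total
simulated time, which would require trajectory files. The time step is also
reported in fs (`dt × 1000`). Software versions are grouped into series:
major version for the pre-2016 numbering ("GROMACS 5.1.4" → series "5",
with "5.1" retained for finer grouping) and the year for year-based
versions ("2024.3" → "2024"). Derived values never overwrite parsed ones;
they live in their own section with `derived` provenance.

## Validation: two independent routes

`validate_record()` checks every invariant directly (positivity of `dt` and
temperatures, non-negative integer `nsteps`, box convention and volume
consistency, identifier formats, calendar dates, provenance completeness
and warning pairing) and returns a report of dotted field paths — problems
are reported, never raised. Independently, `emit_schema()` produces a JSON
Schema (draft-07) document with exactly four top-level sections, and
`schema_validate()` is a small generic interpreter of the draft-07 subset
the document uses (type, enum, const, pattern, bounds, required,
properties, items including positional forms, oneOf). The two routes share
no code; the test suite asserts they accept and reject the same records.
Record-level cross-field rules (one provenance tag per populated extracted
field, warnings on inferred values) are expressible only in the rule-based
route and are checked there alone.

Emission is deterministic — sections in schema order, known fields in
declared order, `raw_parameters` alphabetical — and a record that passes
validation round-trips through both JSON and YAML bit-for-bit
(`parse_record(emit_record(r)) == r`). JSON numbers are written at 17
significant digits and YAML at precision 17 so that doubles survive the
round trip exactly.

## Merging user metadata

Extracted values are machine ground truth; published descriptions of the
same data are regularly wrong about water models and run lengths. User
metadata (a JSON document) may therefore populate only `simulated_object`,
`administrative` and the free-form `extra` namespace. Attempts to set
`system.*` or `simulation.*` fields are rejected and recorded as conflict
notes rather than silently dropped, and merging is idempotent.

## Synthetic fixtures and what they do (not) show

`fixture_spec()` + `generate_fileset()` produce mutually consistent
`.gro`/`.top`/dump-text file sets from a known ground truth: the same box
appears in the `.gro` and the dump text, and the force field and water
model appear as include filenames. Water coordinates are placeholder
lattice points because extraction never reads coordinates — only the atom
count and the box line. `generate_corpus()` draws whole corpora from
configurable distributions; the defaults emulate the broad usage patterns
seen in public deposits: box edges uniform on 5–15 nm (typical
protein-in-water cells), time steps of 1 or 2 fs with 2 fs dominant (the
standard constraint-enabled compromise), ensemble temperatures clustered at
298/303/310 K (room and body temperature), Parrinello-Rahman the dominant
barostat and V-rescale/Nose-Hoover the dominant thermostats, and a version
mix spanning the 4.x series through year-based releases. Topology and
structure files are each present with probability 0.8 and 0.7, reflecting
that public deposits often ship the run input alone.

A built-in preset, `fixture_preset("tonb_ctd")`, mirrors the annotation
profile of a deposited bacterial TonB C-terminal-domain simulation set
(GROMACS 5.1.4, amber99sb-ildn, Parrinello-Rahman isotropic coupling,
dt 0.002 ps, 50 000 000 steps — a 100 ns segment) in three variants pairing
water models tip3p/tip4pew/opc with temperatures 298/303/310 K; the
pairing of water model to temperature across the variants is a package
choice. The preset's box (8 nm cube, 100 waters) is
likewise nominal: extraction reads only the box line and atom count, so
these values do not affect any recovered annotation field.

Passing the fixture-based tests shows that the parsers and the assembly
logic are faithful to the formats the generator emits — a tolerant superset
of real dump text and standard `.gro`/`.top` layouts. It does not show
robustness to every formatting quirk of two decades of real GROMACS
output, to hand-edited topologies, or to custom `.itp` files whose names
lie about their contents; the provenance warnings exist precisely because
that last failure is undetectable.

## Corpus statistics

`summarize_corpus()` aggregates records into the distributions a corpus
overview needs: per-axis box-dimension histograms (1 nm bins, 0–30 nm with
overflow), time steps (bins at 0.5–5 fs with overflow), ensemble
temperatures (5 K bins, 250–400 K with under- and overflow), coupling
algorithm counts (names normalised case-insensitively to canonical
spellings), version series, creation years and source-file presence. Bin
edges are package choices sized to resolve the known modes (5–15 nm boxes,
2 fs steps, 298/310 K clusters). Records missing a field are counted in a
per-field `missing` bucket, so counts + missing = corpus size for every
statistic. Records coupling groups at several temperatures are represented
by their lowest ensemble temperature, keeping the histogram one-per-record.

## Numerical and design choices

* Shape classification tolerance is 1e-5 nm — below the `.gro` print
  precision of 1e-5 nm per field, far above double-precision noise; labels
  are stable under perturbations an order of magnitude smaller.
* Box volume is the diagonal product, valid for the lower-triangular
  convention and tested against the full determinant.
* When several includes match water models, the first match wins and the
  provenance warning stands; the same first-match rule applies to `.ff`
  directories.
* Duplicate keys in dump text keep the first occurrence.
* The empty record, empty topology and zero-atom `.gro` are all legal
  inputs; the empty dump text is not (a run input always has parameters).
* Problem sizes in the test suite (up to 200 random file sets and a
  1000-record corpus) were chosen as the smallest sizes at which the
  property-based checks are statistically meaningful.

## Worked example

```{r example}
specs <- fixture_preset("tonb_ctd")
rec <- extract_fileset(specs[[2]])
rec$simulation$software_information
rec$system$water_model
rec$derived$duration_ns
validate_record(rec)
```

## Limitations

Binary `.tpr` decoding, trajectory analysis (total simulated time across
continuations), force-field parameter extraction (charges, Lennard-Jones
parameters), nested include resolution and `.itp` content inspection are
out of scope. Named non-orthorhombic cells (rhombic dodecahedron, truncated
octahedron) are reported as `triclinic` together with their raw vectors,
from which the named shape can be recovered if needed.
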