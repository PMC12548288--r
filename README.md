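# mdmeta

Structured, validated metadata for GROMACS molecular-dynamics simulations.

MD simulations deposited in generalist repositories usually arrive as bare
file bundles. The inputs themselves, however, describe the experiment
completely: the run-input file (`.tpr`, consumed here through its dump-text
rendering) holds every run parameter, the topology (`.top`) names the force
field and water model through its `#include` directives, and the structure
file (`.gro`) carries the periodic box. `mdmeta` parses these files,
assembles a four-part metadata record — **system** (water model, box
geometry), **simulation** (force field, software version, run parameters),
**simulated_object** (PDB/UniProt/PubChem/ChEMBL/DrugBank/LIPID MAPS
identifiers) and **administrative** (creators, dates) — validates it against
a machine-readable JSON Schema, and emits deterministic JSON or YAML. It is
aimed at people who share, curate or mine simulation data and need
machine-readable annotations rather than prose.

Every populated field carries a provenance tag. Values read from the run
input are `parsed`; the force field and water model are
`filename_inference` — matched exactly on include-filename stems against a
water-model dictionary (so `tip4pew.itp` never collapses to `tip4p`) — and
always carry a warning, because a file named `opc.itp` may contain a
different model and file contents are deliberately never inspected.

Quantities not stored in any single field are derived explicitly: the
segment length is

    duration = dt × nsteps        (ps; ÷ 1000 for ns)

so `dt = 0.002 ps` and `nsteps = 50,000,000` give 100,000 ps = 100 ns — the
length of this run segment, not of the whole study when
`continuation = true`. Box volume is the diagonal product of the
lower-triangular box vectors, `V = v1x · v2y · v3z` (nm³), and boxes are
classified cubic / rectangular / triclinic at a 1e-5 nm tolerance.

A synthetic fixture generator (`fixture_spec()`, `generate_fileset()`,
`generate_corpus()`) produces mutually consistent file sets and whole
corpora with known ground truth, and `summarize_corpus()` aggregates many
records into the distributions a corpus overview needs (box dimensions,
time steps, temperatures, coupling algorithms, version series).

## Worked example

```r
library(mdmeta)

specs <- fixture_preset("tonb_ctd")   # three preset variants
rec   <- extract_fileset(specs[[2]])     # generate + parse + assemble
cat(emit_record(rec, "yaml"))
```

```yaml
system:
  water_model: tip4pew
  box:
    shape: cubic
    dimensions:
    - 8.0
    - 8.0
    - 8.0
    volume: 512.0
simulation:
  forcefield: amber99sb-ildn
  software_information: GROMACS 5.1.4
  dt: 0.002
  nsteps: 50000000.0
  ensemble_temperature: 303.0
  tcoupl: V-rescale
  pcoupl: Parrinello-Rahman
  pcoupltype: Isotropic
  continuation: yes
derived:
  duration_ps: 100000.0
  duration_ns: 100.0
  dt_fs: 2.0
  version_series: '5'
```

(abridged: the full document also carries `raw_parameters` — every
remaining run parameter verbatim — and the per-field provenance map). The
water model is `tip4pew` because the topology includes `tip4pew.itp`; its
provenance tag warns that the name was inferred from the filename only.
`duration_ns: 100.0` is the derived segment length; `version_series: '5'`
groups `GROMACS 5.1.4` into its major series. `validate_record(rec)`
returns a zero-row report, i.e. the record satisfies every invariant, and
the same record is accepted by the emitted JSON Schema (`emit_schema()`,
four top-level sections).

A command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/mdmeta", package="mdmeta"))')" \
    extract run.tpr.dump topol.top conf.gro --format yaml --output meta.yaml
```

with subcommands `extract | validate | stats | fixture` (exit codes:
0 success, 1 validation failure, 2 input error).

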