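# leukotype

Logical immunophenotype definitions and automated classification of
hematologic malignancies.

## What this is for

Acute leukemias are routinely diagnosed from the *immunophenotype* of the
malignant blast population — the pattern of surface and cytoplasmic
marker expression (CD19, CD10, cytoplasmic CD3, MPO, ...) measured by
flow cytometry. The EGIL scheme classifies acute lymphoblastic and
myeloid leukemias purely from such marker profiles. `leukotype` turns
that scheme into machine-reasoning material, for ontologists and
informaticians building diagnostic annotation pipelines:

* a curated **knowledge base** of cell classes defined genus-differentia
  style: each class is a named parent (*genus*) plus
  necessary-and-sufficient marker conditions (*differentia*),
  e.g. `B-II = B-lineage-ALL ⊓ CD10+`;
* a bespoke, **sound and complete reasoner** for this fragment:
  entailment, satisfiability, automatic class-hierarchy derivation and
  instance classification;
* a deterministic **OWL functional-syntax** exporter/parser using
  OBO-style relations (`has_plasma_membrane_part`, `has_cytoplasm_part`,
  `lacks_plasma_membrane_part`, `lacks_cytoplasm_part`, ...);
* a **patient-data pipeline**: CSV input of categorical statuses or
  percent-positive values (classical 20 % positivity cutoff), a seeded
  sample simulator, and a CLI.

## The model

A *literal* asserts one status for one marker at one location, with
statuses `absent | present | high | low`; `high`/`low` refine `present`,
`absent` contradicts all three. A *phenotype* is a conjunction of
disjunctive clauses over literals (the table's "and/or" is one clause).
A class definition expands to the conjunction of its own differentia and
everything along its genus chain. Entailment between phenotypes is
decided by a small exhaustive constraint solver over *marker worlds*
(total assignments of concrete statuses), verified in the test suite
against brute-force enumeration of all 4^k worlds.

For a patient sample, a class is **definite** when every clause of its
expanded definition is witnessed by a measured status (then closed
upward under subsumption), **compatible** when nothing contradicts it.
Under the `open` policy only measurements can contradict; under `closed`,
unmeasured markers count as absent and rule classes out.

## Worked example

```r
library(leukotype)
kb <- builtin_egil_kb()
#> <knowledge base 'egil_table1' v1.0.0: 26 classes, 28 markers>

render_textual_definition("B-III", kb)
#> A B-lineage ALL that is cytoplasmic Ig mu positive.

s <- patient_sample("patient-01",
                    c(CD19 = "present", CD10 = "present", CD3 = "absent"))
classify_instance(s, kb)
#> <classification of patient-01 [open-world]>
#>   most specific: B-II
#>   definite:      abnormal-cell, ALL, B-II, B-lineage-ALL,
#>                  hematologic-malignant-cell, malignant-cell, neoplastic-cell
#>   compatible:    22 classes
```

CD19+ establishes the B-lineage clause, CD10+ the common-B differentia,
so the most specific diagnosis is **B-II (common B) ALL**; every
ancestor up to the root is definite too, and 22 classes are not yet
ruled out (open world: cytoplasmic Ig mu was never measured, so pre-B
remains compatible). Simulation and export:

```r
ss <- simulate_samples(simulation_spec("T-III", n_samples = 3, seed = 7), kb)
ss[[1]]
#> <sample T-III-001: CD1a+, cyCD3-, CD3+>

export_ontology(kb, owl_render_plan(), "egil.ofn")
#> <ontology stats: 54 classes (54 native, 0 imported), 4 object properties>
```

## Command line

```sh
RS='Rscript -e "leukotype::run_cli(commandArgs(TRUE))" --args'
$RS build    --out egil.ofn                      # OWL export + stats
$RS validate                                     # KB consistency findings
$RS simulate --class B-II --n 20 --seed 7 --out sim.csv
$RS classify --samples sim.csv --policy closed --out report.csv
```

Patient CSV schema: `sample_id,marker,location,status` or
`sample_id,marker,location,percent_positive` (one of the two per row;
percent values are thresholded at `--cutoff`, default 20, boundary
inclusive).

## Layout

* `R/` — model, knowledge base, reasoner, OWL I/O, pipeline, CLI
* `inst/extdata/egil_table1.json` — the shipped KB (human-editable JSON)
* `vignettes/leukotype-methods.Rmd` — methods and design notes
* `tests/testthat/` — unit, property and acceptance suites
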