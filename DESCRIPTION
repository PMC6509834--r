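Package: leukotype
Title: Logical Immunophenotype Definitions and Classification of
    Hematologic Malignancies
Version: 0.1.0
Authors@R:
    person("Ada", "Whitfield", email = "ada.whitfield@example.org",
           role = c("aut", "cre"))
Description: Compiles immunophenotype-based definitions of leukemic cell
    types (the EGIL scheme) into genus-differentia logical class
    definitions, reasons over them (entailment, satisfiability, class
    hierarchy), and classifies patient surface/cytoplasmic marker data
    into diagnostic classes.  Ships a curated knowledge base of acute
    lymphoblastic and myeloid leukemia immunophenotypes, a deterministic
    OWL functional-syntax exporter/parser, a seeded patient-sample
    simulator, and a command-line interface for building, validating,
    simulating and classifying.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
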