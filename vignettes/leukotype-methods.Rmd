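---
title: "leukotype: model, reasoning semantics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{leukotype: model, reasoning semantics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leukotype)
```

## The model

`leukotype` represents diagnostic cell classes of acute leukemias the way
modern bio-ontologies represent hematopoietic cell types: each class is a
*genus* (named parent) plus *differentia* given purely as marker
expression. The literal model has two locations (`surface`,
`cytoplasmic`) and four statuses. `high` and `low` are refinements of
`present` — they encode expression above or below the population mean in
flow cytometry — so the status lattice is

```
absent  ⟂  present ⊒ {high, low}
```

A phenotype is a conjunction of clauses, each clause a disjunction of
literals (CNF). This normal form was chosen because the EGIL table's
rows are literally of that shape ("CD19+ and/or CD79a+ and/or CD22+" is
one disjunctive clause; separate row conditions are separate clauses).
Phenotypes are canonicalised (literals sorted by marker label, location,
status; duplicates removed) so structural equality coincides with
syntactic equality, and `make_phenotype` is idempotent.

## Reasoning semantics

A *marker world* totally assigns each (marker, location) pair one
concrete status. A `present` literal is satisfied by any of
present/high/low; `absent`, `high` and `low` only by themselves.
Entailment `p ⊨ q` holds when every world satisfying `p` satisfies `q`,
over the union universe.

Deciding entailment clause-by-clause via clause subsumption plus unit
propagation alone is *incomplete* for this fragment: e.g.
`{CD19+ ∨ CD5+} ∧ {CD19+ ∨ CD5−} ⊨ {CD19+}` requires case analysis on
CD5. The reasoner therefore reduces `p ⊨ q` to unsatisfiability of
`p ∧ ¬c` for each clause `c` of `q`, decided by a small constraint
solver over status domains: negating `c` restricts the domains of its
variables, then unit propagation (dead-literal pruning, certainly-true
clause elimination, unit domain intersection) runs to fixpoint and the
solver branches over the concrete statuses of a live variable. Because
branching enumerates concrete statuses exhaustively and propagation only
removes impossible options, the procedure is sound and complete; the
test suite additionally verifies it against brute-force enumeration of
all `4^k` worlds on ≥ 1000 random phenotype pairs (≤ 6 marker-locations)
rather than trusting the argument a priori.

Class-level subsumption: a child's expansion always contains its
ancestors' clauses, so asserted edges to *defining* parents are
automatically derivable; *non-defining* classes (lineage stubs like
"acute lymphoblastic leukemic cell") carry only necessary conditions and
subsume solely via the asserted genus chain. `classify_hierarchy`
computes the full subsumption matrix, merges mutual subsumptions into
equivalence groups, and returns the transitive reduction, flagging
asserted-only edges.

## Knowledge-base encoding decisions

The shipped KB (`inst/extdata/egil_table1.json`, identical to
`builtin_egil_kb()`) encodes the EGIL scheme with these genuinely open
points decided as follows:

* **B-lineage membership** is encoded as printed — *any* of CD19/CD79a/
  CD22 suffices. (Earlier EGIL literature requires ≥ 2 of the three; a
  cardinality extension is deliberately not guessed into the default KB.)
* **B-I "no B-cell differentiation antigens"** becomes explicit negative
  literals for the sibling-defining markers (CD10−, cytoplasmic Ig mu−,
  sIg−): the only machine-checkable reading, and the one that makes
  B-I ⊑ B-lineage derivable while keeping B-I and B-II/III/IV mutually
  incompatible on measured data.
* **B-IV (mature B)** is encoded as light-chain restriction: one clause
  {kappa+ ∨ lambda+} at surface or cytoplasmic location. Folding
  cytoplasmic Ig mu itself into that clause (a possible reading of the
  garbled printed row) would make B-III logically subsumed by B-IV and
  collapse the maturation series into a chain, contradicting the
  scheme's sibling layout; the light-chain reading is the standard
  clinical criterion.
* **AML-M0** constrains only the enzymatic myeloperoxidase assay
  (enzymatic MPO−): the "MPO ±" immunologic call contributes no literal.
  Immunologic and enzymatic MPO are distinct markers.
* **Myelo/monocytic AML** is one disjunctive clause
  {CD13+ ∨ CD33+ ∨ CD65+ ∨ CD117+} plus cytoplasmic MPO+; the printed
  slash notation is ambiguous between "all" and "any", and "any" matches
  how such panels are used.
* **Undifferentiated AML** carries only a `typical_profile` annotation
  (CD34/HLA-DR/CD38/CD7): "often positive" is not a necessary condition,
  so the class is non-defining.
* **Sibling stages are not disjoint.** EGIL profiles overlap (a CD10+,
  cyIg mu+ sample satisfies both B-II and B-III); no disjointness axioms
  are asserted. An optional *maturation-stage precedence* policy
  (`classify_instance(..., precedence = TRUE)`) keeps only the latest
  stage among most-specific same-series results, emulating clinical
  staging; it is off by default.

The KB file format is a single human-editable JSON document (markers
with synonyms and optional external CURIEs; one record per class with
explicit clause lists). JSON was chosen over a spreadsheet so clause
structure stays explicit, and over YAML because the target environment
ships no YAML parser for R. `load_kb ∘ save_kb` is the identity.

## Instance classification semantics

`classify_instance` distinguishes ruling *in* from ruling *out*:

* a class is **definite** only when every clause of its expansion has a
  literal witnessed by a *measured* status; definiteness then propagates
  upward under subsumption (ancestors, including non-defining lineage
  stubs, become definite).
* a class is **compatible** when no clause is falsified. Under the
  `open` policy only measured statuses falsify; under `closed`,
  unmeasured markers count as absent and can falsify.

The asymmetry is deliberate. If closed-world absence could also *witness*
negative literals, every B-lineage panel lacking CD10/cyIg mu/sIg
measurements would be auto-diagnosed as B-I (pro-B), and the
generate-and-recover property (below) would be unattainable for non-leaf
classes; requiring measured evidence for definiteness keeps "we did not
look" distinct from "we looked and it was negative", while the closed
policy still lets a fixed panel rule out classes whose positive
requirements were never seen. Unsatisfiable class definitions would
subsume everything vacuously, so they are excluded from classification
outright and surfaced by `validate_kb`. Ties among incomparable
most-specific classes are all returned, sorted by class id.

The empty sample is therefore definite in nothing (and compatible with
every satisfiable class under `open`): with no measurements there is no
evidence, and the lineage stubs' trivially-true expansions are necessary
conditions only, not grounds for membership.

## Thresholding and parameters

* `threshold_percent(value, cutoff = 20, inclusive = TRUE)` implements
  the classical "≥ 20 % of the population bears the marker" positivity
  rule. The boundary is inclusive (20 → positive); strictness is a flag
  because the historical rule does not state it. Units: percent of
  gated population, range [0, 100].
* Percent input never yields `high`/`low`: relative-amount calls need a
  population context a single percentage lacks; those statuses enter
  only via explicit categorical input.

## The simulator: what it emulates, what it does not

`simulate_samples` is a reproducibility stand-in for unpublished patient
test instances. Its stated world: for each sample it picks one literal
per clause of the target's expanded definition uniformly at random,
draws every remaining panel marker-location absent/present with equal
probability (this cannot falsify a clause that already holds), flips
each measured status with probability `noise_rate` (positivity toggles),
and, when emitting percents, draws positives uniformly from
[cutoff, 100] and negatives from [0, cutoff) — values deliberately
straddling the cutoff. The default panel is *closed*: exactly the
target's expanded marker-locations, matching how a directed panel is
run. Everything is determined by the spec's seed, and the caller's RNG
state is untouched.

What a green generate-and-recover test establishes: the definitional
pipeline (encode → expand → simulate → threshold → classify) is
self-consistent at 100 % in the noise-free closed-panel case, and
degrades monotonically with marker-flip noise. What it does not
establish: anything about real flow cytometry — no spillover, no gating
error, no continuous fluorescence distributions, no correlated marker
noise, no doublets. The simulator draws free markers independently and
uniformly, which real co-expression patterns are not.

## OWL export choices

* Primary dialect is functional-style syntax, written line-oriented and
  deterministically (byte-identical re-export; exercised by tests).
  RDF/XML is accepted on input for statistics only.
* Disjunctive clauses render as `ObjectUnionOf` of existential
  restrictions inside the defining `ObjectIntersectionOf`.
* Negative literals render as restrictions over the *lacks* relations
  (`lacks_plasma_membrane_part`, `lacks_cytoplasm_part`) rather than
  `ObjectComplementOf`, keeping the export EL-friendly (the profile an
  ELK-style reasoner consumes).
* Four relations carry Relation-Ontology CURIEs; the two cytoplasmic
  relations and generic `lacks_part` are minted natively, since they do
  not exist in the imported vocabularies. The export declares exactly
  the relations the KB references — for the shipped KB that is four
  (surface/cytoplasmic × present/absent; the EGIL table has no high/low
  literals).
* IRIs are minted as zero-padded 7-digit ids in KB order, classes then
  markers: stable across re-export of an unchanged KB without mutating
  the KB document. Marker terms are tagged with a `term_type`
  annotation so a parsed export can separate them from cell classes
  even when a marker appears only in annotations.

## Known limitations

* The reasoner covers exactly this fragment (conjunction, disjunction,
  four-status literals); no role chains, cardinality restrictions or
  nominals — deliberately, as the definitions need none of them.
* The multiple-myeloma branch is an empty extension point: the KB format
  supports adding its panels, but no consensus marker content is
  shipped.
* `load_ontology_stats` does not resolve `owl:imports` (offline by
  design); imported-term counts on files with import closures reflect
  local declarations only unless the closure is merged beforehand.
* Textual definitions are generated from class labels; renaming a genus
  changes its children's sentences (determinism is per-KB-state).
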