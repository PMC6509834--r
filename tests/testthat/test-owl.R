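kb <- builtin_egil_kb()
plan <- owl_render_plan()

test_that("class axioms render genus-differentia structure", {
  ax <- render_class_axioms(kb$classes[["B-II"]], plan, kb)
  eq <- grep("^EquivalentClasses", ax, value = TRUE)
  expect_length(eq, 1L)
  expect_match(eq, "ObjectIntersectionOf")
  # single-literal clause: a bare existential restriction over the
  # surface-presence relation, aimed at the CD10 marker class
  iris <- leukotype:::mint_iris(kb, plan)
  expect_match(eq, sprintf("ObjectSomeValuesFrom\\(obo:RO_0002104 %s\\)",
                           iris$marker[["CD10"]]), fixed = FALSE)
  expect_match(eq, iris$class[["B-lineage-ALL"]], fixed = TRUE)
  expect_false(any(grepl("^SubClassOf", ax)))

  # cytoplasmic literal renders over has_cytoplasm_part
  ax3 <- render_class_axioms(kb$classes[["B-III"]], plan, kb)
  expect_match(grep("^EquivalentClasses", ax3, value = TRUE),
               "ccl:CCLREL_0000001")

  # multi-literal clause renders as a union inside the intersection
  ax_b <- render_class_axioms(kb$classes[["B-lineage-ALL"]], plan, kb)
  expect_match(grep("^EquivalentClasses", ax_b, value = TRUE),
               "ObjectUnionOf")

  # non-defining class: subclass axiom only, profile as annotation
  ax_u <- render_class_axioms(kb$classes[["AML-undifferentiated"]], plan, kb)
  expect_true(any(grepl("^SubClassOf", ax_u)))
  expect_false(any(grepl("^EquivalentClasses", ax_u)))
  expect_match(grep("rdfs:comment", ax_u, value = TRUE), "Typical profile")

  # negative literals use the lacks relations, never complements
  ax_m0 <- render_class_axioms(kb$classes[["AML-M0"]], plan, kb)
  expect_match(grep("^EquivalentClasses", ax_m0, value = TRUE),
               "ccl:CCLREL_0000002")
  expect_false(any(grepl("ObjectComplementOf",
                         unlist(lapply(kb$classes, render_class_axioms,
                                       plan = plan, kb = kb)))))
})

test_that("cytoplasmic high/low literals are unrenderable", {
  bad <- kb$classes[["B-III"]]
  bad$differentia$clauses[[1]]$status <- "high"  # cytoplasmic Ig mu high
  expect_error(render_class_axioms(bad, plan, kb), "no relation")
})

test_that("export is deterministic and round-trips byte-identically", {
  f1 <- tempfile(fileext = ".ofn")
  f2 <- tempfile(fileext = ".ofn")
  f3 <- tempfile(fileext = ".ofn")
  export_ontology(kb, plan, f1)
  export_ontology(kb, plan, f2)
  expect_identical(readBin(f1, "raw", file.size(f1) + 10),
                   readBin(f2, "raw", file.size(f2) + 10))
  write_ofn(parse_ofn(f1), f3)
  expect_identical(readBin(f1, "raw", file.size(f1) + 10),
                   readBin(f3, "raw", file.size(f3) + 10))
})

test_that("export declares exactly the relations the KB uses", {
  f <- tempfile(fileext = ".ofn")
  export_ontology(kb, plan, f)
  doc <- parse_ofn(f)
  declared <- regmatches(doc$axioms,
    regexec("^Declaration\\(ObjectProperty\\((.*)\\)\\)$", doc$axioms))
  declared <- vapply(Filter(function(m) length(m) == 2L, declared),
                     `[[`, character(1), 2L)
  used <- leukotype:::kb_relations_used(kb)
  expect_setequal(declared, unname(plan$relation_iris[used]))
  # Table 1 uses surface/cytoplasmic x present/absent only
  expect_setequal(used, c("has_plasma_membrane_part",
                          "lacks_plasma_membrane_part",
                          "has_cytoplasm_part",
                          "lacks_cytoplasm_part"))
})

test_that("export stats conserve the KB term counts", {
  f <- tempfile(fileext = ".ofn")
  st <- export_ontology(kb, plan, f)
  expect_s3_class(st, "ontology_stats")
  # every KB cell class and marker becomes one native OWL class
  expect_equal(st$native_class_count,
               length(kb$classes) + length(kb$markers))
  expect_equal(st$imported_class_count, 0L)
  expect_equal(st$total_class_count, st$native_class_count)
  expect_equal(st$object_property_count, 4L)
  expect_equal(unname(st$axiom_counts[["EquivalentClasses"]]),
               sum(vapply(kb$classes, function(d) {
                 d$defining && !is_trivially_true(d$differentia)
               }, logical(1))))
})

test_that("a parsed export reproduces the reasoned hierarchy", {
  f <- tempfile(fileext = ".ofn")
  export_ontology(kb, plan, f)
  kb2 <- ofn_to_kb(parse_ofn(f), plan)
  h1 <- classify_hierarchy(kb)
  h2 <- classify_hierarchy(kb2)
  expect_identical(h2$direct_edges, h1$direct_edges)
  expect_identical(h2$equivalence_groups, h1$equivalence_groups)
})

test_that("functional-syntax stats work on a hand-built fixture", {
  f <- tempfile(fileext = ".ofn")
  writeLines(c(
    "Prefix(ex:=<http://example.org/onto/>)",
    "Prefix(owl:=<http://www.w3.org/2002/07/owl#>)",
    "Prefix(ext:=<http://example.org/other/>)",
    "Ontology(<http://example.org/onto/fixture.owl>",
    "Declaration(Class(ex:C_0000001))",
    "Declaration(Class(ex:C_0000002))",
    "Declaration(Class(ext:D_0000001))",
    "Declaration(Class(ext:D_0000002))",
    "Declaration(ObjectProperty(ex:rel))",
    "AnnotationAssertion(owl:deprecated ext:D_0000002 \"true\")",
    "SubClassOf(ex:C_0000002 ex:C_0000001)",
    ")"), f)
  st <- load_ontology_stats(f, native_prefix = "http://example.org/onto/")
  expect_equal(st$total_class_count, 3L)  # deprecated class excluded
  expect_equal(st$native_class_count, 2L)
  expect_equal(st$imported_class_count, 1L)
  expect_equal(st$object_property_count, 1L)
})

test_that("RDF/XML stats count classes with a native/imported split", {
  f <- tempfile(fileext = ".owl")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    '         xmlns:owl="http://www.w3.org/2002/07/owl#">',
    '  <owl:Ontology rdf:about="http://example.org/onto/fixture.owl">',
    '    <owl:imports rdf:resource="http://example.org/elsewhere.owl"/>',
    '  </owl:Ontology>',
    '  <owl:Class rdf:about="http://example.org/onto/C1"/>',
    '  <owl:Class rdf:about="http://example.org/onto/C2"/>',
    '  <owl:Class rdf:about="http://example.org/other/D1"/>',
    '  <owl:Class rdf:about="http://example.org/onto/Cdep">',
    '    <owl:deprecated>true</owl:deprecated>',
    '  </owl:Class>',
    '  <owl:ObjectProperty rdf:about="http://example.org/onto/r1"/>',
    '</rdf:RDF>'), f)
  expect_warning(
    st <- load_ontology_stats(f, native_prefix = "http://example.org/onto/"),
    "unresolved import")
  expect_equal(st$total_class_count, 3L)
  expect_equal(st$native_class_count, 2L)
  expect_equal(st$imported_class_count, 1L)
  expect_equal(st$object_property_count, 1L)
  expect_error(
    suppressWarnings(load_ontology_stats(
      f, native_prefix = "http://example.org/onto/",
      on_unresolved_import = "fail")),
    "imports")
})
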