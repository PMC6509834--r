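kb <- builtin_egil_kb()

lit <- function(m, l, s) c(m, l, s)

test_that("literal_implies follows the status lattice", {
  expect_true(literal_implies(lit("CD10", "surface", "high"),
                              lit("CD10", "surface", "present")))
  expect_true(literal_implies(lit("CD10", "surface", "low"),
                              lit("CD10", "surface", "present")))
  expect_false(literal_implies(lit("CD3", "surface", "present"),
                               lit("CD3", "cytoplasmic", "present")))
  expect_false(literal_implies(lit("CD19", "surface", "absent"),
                               lit("CD19", "surface", "present")))
  expect_false(literal_implies(lit("CD19", "surface", "present"),
                               lit("CD19", "surface", "high")))
  expect_true(literal_implies(lit("CD19", "surface", "absent"),
                              lit("CD19", "surface", "absent")))
})

test_that("satisfies evaluates clauses over concrete worlds", {
  blin <- expand_definition("B-lineage-ALL", kb)
  w <- marker_world(c("CD19|surface" = "high",
                      "CD22|surface" = "absent",
                      "CD79a|surface" = "absent"))
  expect_true(satisfies(w, blin))   # high entails present

  expect_true(satisfies(marker_world(c("CD19|surface" = "absent")),
                        make_phenotype(list(), kb)))

  p10 <- make_phenotype(list(list(lit("CD10", "surface", "present"))), kb)
  expect_false(satisfies(marker_world(c("CD10|surface" = "absent")), p10))
  expect_error(satisfies(marker_world(c("CD19|surface" = "present")), p10),
               "universe")
})

test_that("entails handles the textbook cases", {
  cd19 <- make_phenotype(list(list(lit("CD19", "surface", "present"))), kb)
  blin <- expand_definition("B-lineage-ALL", kb)
  triv <- make_phenotype(list(), kb)
  expect_true(entails(cd19, blin))
  expect_false(entails(blin, cd19))
  expect_true(entails(triv, triv))
  expect_true(entails(cd19, triv))
  expect_false(entails(triv, cd19))
  # an unsatisfiable premise entails anything
  contra <- make_phenotype(list(list(lit("CD19", "surface", "present")),
                                list(lit("CD19", "surface", "absent"))), kb)
  expect_false(is_satisfiable(contra))
  expect_true(entails(contra, cd19))
  # resolution-style case needing more than clause subsumption:
  # {CD19+ v CD5+} & {CD19+ v CD5-} entails {CD19+}
  p <- make_phenotype(list(list(lit("CD19", "surface", "present"),
                                lit("CD5", "surface", "present")),
                           list(lit("CD19", "surface", "present"),
                                lit("CD5", "surface", "absent"))), kb)
  expect_true(entails(p, cd19))
  # tautological clause is entailed by anything
  taut <- make_phenotype(list(list(lit("CD5", "surface", "present"),
                                   lit("CD5", "surface", "absent"))), kb)
  expect_true(entails(triv, taut))
})

test_that("is_satisfiable matches the obvious cases", {
  expect_false(is_satisfiable(make_phenotype(
    list(list(lit("CD19", "surface", "present")),
         list(lit("CD19", "surface", "absent"))), kb)))
  expect_true(is_satisfiable(expand_definition("AML-M0", kb)))
  # high and low on the same marker-location cannot both hold
  expect_false(is_satisfiable(make_phenotype(
    list(list(lit("CD19", "surface", "high")),
         list(lit("CD19", "surface", "low"))), kb)))
})

test_that("solver agrees with world enumeration on random phenotypes", {
  set.seed(73)
  toy <- toy_marker_kb(3L)  # up to 6 marker-locations
  for (i in 1:300) {
    p <- random_phenotype(toy, max_vars = 3L)
    q <- random_phenotype(toy, max_vars = 3L)
    expect_identical(is_satisfiable(p), oracle_satisfiable(p), info = i)
    expect_identical(entails(p, q), oracle_entails(p, q), info = i)
  }
})

test_that("entailment is monotone in the premise", {
  set.seed(74)
  toy <- toy_marker_kb(3L)
  for (i in 1:60) {
    p <- random_phenotype(toy, max_vars = 3L)
    q <- random_phenotype(toy, max_vars = 3L)
    extra <- random_phenotype(toy, max_vars = 3L, max_clauses = 1L)
    if (!entails(p, q)) next
    p2 <- leukotype:::canonical_phenotype(
      leukotype:::new_phenotype(c(p$clauses, extra$clauses)))
    expect_true(entails(p2, q), info = i)
  }
})

test_that("subsumes respects the asserted and logical hierarchy", {
  expect_true(subsumes("B-lineage-ALL", "B-II", kb))
  expect_false(subsumes("B-II", "B-lineage-ALL", kb))
  expect_false(subsumes("B-II", "B-III", kb))
  expect_false(subsumes("B-III", "B-II", kb))
  for (id in c("B-II", "ALL", "AML-erythroid-early")) {
    expect_true(subsumes(id, id, kb))  # reflexivity
  }
  # non-defining classes subsume only via the asserted chain
  expect_true(subsumes("ALL", "B-II", kb))
  expect_false(subsumes("AML", "B-II", kb))
  expect_error(subsumes("B-II", "nope", kb), "unknown class")
})

test_that("subsumption is transitive on the builtin KB", {
  sub <- classify_hierarchy(kb)$subsumption
  ids <- rownames(sub)
  for (i in ids) for (j in ids) for (k in ids) {
    if (sub[i, j] && sub[j, k]) expect_true(sub[i, k])
  }
})

test_that("classify_hierarchy merges duplicated definitions", {
  kb_dup <- kb
  twin <- kb_dup$classes[["B-II"]]
  twin$id <- "B-II-copy"
  twin$label <- "B-II copy"
  kb_dup$classes[["B-II-copy"]] <- twin
  h <- classify_hierarchy(kb_dup)
  expect_length(h$equivalence_groups, 1L)
  expect_setequal(h$equivalence_groups[[1]], c("B-II", "B-II-copy"))
})

test_that("classify_hierarchy agrees with the oracle on random KBs", {
  set.seed(99)
  for (i in 1:12) {
    rkb <- random_kb(n_classes = 5L, n_markers = 3L)
    h <- classify_hierarchy(rkb)
    sub_oracle <- oracle_subsumption_matrix(rkb)
    expect_identical(h$subsumption, sub_oracle, info = i)
    expect_identical(h$direct_edges[, c("child", "parent")],
                     oracle_direct_edges(sub_oracle), info = i)
  }
})

test_that("classify_instance reproduces the worked examples", {
  h <- classify_hierarchy(kb)
  r1 <- classify_instance(patient_sample("S1", c(CD19 = "present",
                                                 CD10 = "present")),
                          kb, "open", h)
  expect_identical(r1$most_specific_definite, "B-II")
  expect_true(all(c("B-lineage-ALL", "ALL", "hematologic-malignant-cell")
                  %in% r1$definite))

  r2 <- classify_instance(patient_sample("S2", c(CD3 = "present",
                                                 CD1a = "present")),
                          kb, "open", h)
  expect_identical(r2$most_specific_definite, "T-III")
  # surface CD3+ with CD1a+ contradicts mature-T (requires CD1a-)
  expect_false("T-IV" %in% r2$compatible)

  r3 <- classify_instance(patient_sample("S3", c(CD41 = "present")),
                          kb, "open", h)
  expect_identical(r3$most_specific_definite, "AML-megakaryocytic")
})

test_that("the empty sample is definite in nothing, compatible with all", {
  h <- classify_hierarchy(kb)
  empty <- patient_sample("E", c(CD19 = "present"))
  empty$measurements <- empty$measurements[0, , drop = FALSE]
  r <- classify_instance(empty, kb, "open", h)
  expect_identical(r$definite, character(0))
  defn <- names(kb$classes)[vapply(kb$classes, `[[`, logical(1), "defining")]
  expect_true(all(defn %in% r$compatible))
})

test_that("definite sets are upward-closed and inside compatible", {
  h <- classify_hierarchy(kb)
  sub <- h$subsumption
  set.seed(17)
  defn <- names(kb$classes)[vapply(kb$classes, `[[`, logical(1), "defining")]
  for (cl in sample(defn, 6L)) {
    ss <- simulate_samples(simulation_spec(cl, 4L, seed = 5L), kb)
    for (s in ss) {
      for (policy in c("open", "closed")) {
        r <- classify_instance(s, kb, policy, h)
        expect_true(all(r$definite %in% r$compatible))
        expect_true(all(r$most_specific_definite %in% r$definite))
        for (d in r$definite) {
          ups <- rownames(sub)[sub[d, ]]
          expect_true(all(ups %in% r$definite))
        }
      }
    }
  }
})

test_that("open vs closed world differ only in what gets ruled out", {
  h <- classify_hierarchy(kb)
  s <- patient_sample("S", c(CD19 = "present"))
  open <- classify_instance(s, kb, "open", h)
  closed <- classify_instance(s, kb, "closed", h)
  expect_identical(open$definite, closed$definite)
  expect_true(all(closed$compatible %in% open$compatible))
  # closed world rules out classes whose positive requirements are unmeasured
  expect_true("T-lineage-ALL" %in% open$compatible)
  expect_false("T-lineage-ALL" %in% closed$compatible)
})

test_that("unknown markers are skipped with a warning or fail", {
  h <- classify_hierarchy(kb)
  s <- patient_sample("S", c(CD19 = "present", FOOBAR = "present"))
  expect_warning(r <- classify_instance(s, kb, "open", h), "FOOBAR")
  expect_true("B-lineage-ALL" %in% r$definite)
  expect_error(classify_instance(s, kb, "open", h,
                                 on_unknown_marker = "fail"), "FOOBAR")
})

test_that("maturation-stage precedence keeps only the latest stage", {
  h <- classify_hierarchy(kb)
  s <- patient_sample("S", c(CD19 = "present", CD10 = "present",
                             cyIgM = "present"))
  r <- classify_instance(s, kb, "open", h)
  expect_setequal(r$most_specific_definite, c("B-II", "B-III"))
  rp <- classify_instance(s, kb, "open", h, precedence = TRUE)
  expect_identical(rp$most_specific_definite, "B-III")
})

test_that("unsatisfiable classes never absorb instances", {
  kb_bad <- kb
  boot <- kb
  kb_bad$classes[["impossible"]] <- leukotype:::new_classdef(
    "impossible", "impossible class", "B-lineage-ALL", TRUE,
    make_phenotype(list(list(lit("CD10", "surface", "present")),
                        list(lit("CD10", "surface", "absent"))), boot))
  h <- classify_hierarchy(kb_bad)
  r <- classify_instance(patient_sample("S", c(CD19 = "present",
                                               CD10 = "present")),
                         kb_bad, "open", h)
  expect_false("impossible" %in% r$definite)
  expect_false("impossible" %in% r$compatible)
  expect_true("unsatisfiable-class" %in% validate_kb(kb_bad)$code)
})
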