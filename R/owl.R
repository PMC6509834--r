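# OWL functional-style syntax export and parsing.
#
# The writer is strictly line-oriented and deterministic: two exports of
# an identical knowledge base are byte-identical.  Negative literals are
# rendered as existential restrictions over the "lacks" relations (not as
# complements), keeping the export in an EL-friendly profile.  RDF/XML is
# accepted on input for statistics only.

#' Create an OWL render plan
#'
#' Governs IRI minting and relation IRIs for [export_ontology].  Class
#' and marker IRIs are minted as zero-padded 7-digit numeric local ids in
#' knowledge-base order (classes first, then markers), which is stable
#' across re-export of an unchanged KB.
#'
#' @param iri_prefix base IRI for natively minted terms.
#' @param ontology_iri IRI of the ontology document itself.
#' @param relation_iris named character vector mapping the relation names
#'   of [relation_vocabulary] to CURIEs.
#' @return an `owl_render_plan`.
#' @export
owl_render_plan <- function(
    iri_prefix = "http://purl.example.org/ccl/",
    ontology_iri = paste0(iri_prefix, "egil.owl"),
    relation_iris = c(
      has_plasma_membrane_part        = "obo:RO_0002104",
      lacks_plasma_membrane_part      = "obo:RO_0002105",
      has_high_plasma_membrane_amount = "obo:RO_0015015",
      has_low_plasma_membrane_amount  = "obo:RO_0015016",
      has_cytoplasm_part              = "ccl:CCLREL_0000001",
      lacks_cytoplasm_part            = "ccl:CCLREL_0000002",
      lacks_part                      = "ccl:CCLREL_0000003")) {
  missing <- setdiff(relation_vocabulary(), names(relation_iris))
  if (length(missing)) {
    stop("relation_iris missing entries for: ",
         paste(missing, collapse = ", "))
  }
  structure(list(iri_prefix = iri_prefix,
                 ontology_iri = ontology_iri,
                 relation_iris = relation_iris,
                 prefixes = c(
                   ccl  = iri_prefix,
                   obo  = "http://purl.obolibrary.org/obo/",
                   owl  = "http://www.w3.org/2002/07/owl#",
                   rdfs = "http://www.w3.org/2000/01/rdf-schema#",
                   xsd  = "http://www.w3.org/2001/XMLSchema#")),
            class = "owl_render_plan")
}

mint_iris <- function(kb, plan) {
  n_classes <- length(kb$classes)
  class_iri <- stats::setNames(
    sprintf("ccl:CCL_%07d", seq_len(n_classes)), names(kb$classes))
  marker_iri <- stats::setNames(
    sprintf("ccl:CCL_%07d", n_classes + seq_along(kb$markers)),
    vapply(kb$markers, `[[`, character(1), "label"))
  list(class = class_iri, marker = marker_iri)
}

quote_owl_string <- function(x) {
  paste0("\"", gsub("\"", "\\\\\"", x), "\"")
}

restriction_expr <- function(marker, location, status, plan, iris) {
  rel <- plan$relation_iris[[relation_for(location, status)]]
  sprintf("ObjectSomeValuesFrom(%s %s)", rel, iris$marker[[marker]])
}

clause_expr <- function(cl, plan, iris) {
  parts <- mapply(restriction_expr, cl$marker, cl$location, cl$status,
                  MoreArgs = list(plan = plan, iris = iris))
  if (length(parts) > 1L) {
    sprintf("ObjectUnionOf(%s)", paste(parts, collapse = " "))
  } else {
    parts
  }
}

#' Render the OWL axioms for one class definition
#'
#' Defining classes with differentia render an equivalence axiom
#' `Class == Genus and (per-clause expressions)`: single-literal clauses
#' become existential restrictions over the mapped relation, multi-literal
#' clauses become unions of restrictions.  Non-defining classes render a
#' plain subclass axiom, with the typical profile (if any) carried as an
#' annotation.  Annotations carry the label, the class id and the textual
#' definition.
#'
#' @param classdef a class definition from a `leuko_kb`.
#' @param plan an [owl_render_plan].
#' @param kb the knowledge base the definition belongs to.
#' @return character vector of functional-syntax axiom lines.
#' @export
render_class_axioms <- function(classdef, plan, kb) {
  stopifnot(inherits(plan, "owl_render_plan"), inherits(kb, "leuko_kb"))
  iris <- mint_iris(kb, plan)
  iri <- iris$class[[classdef$id]]
  out <- c(
    sprintf("Declaration(Class(%s))", iri),
    sprintf("AnnotationAssertion(rdfs:label %s %s)", iri,
            quote_owl_string(classdef$label)),
    sprintf("AnnotationAssertion(ccl:id %s %s)", iri,
            quote_owl_string(classdef$id)),
    sprintf("AnnotationAssertion(obo:IAO_0000115 %s %s)", iri,
            quote_owl_string(render_textual_definition(classdef$id, kb)))
  )
  if (!is.null(classdef$typical_profile)) {
    out <- c(out, sprintf(
      "AnnotationAssertion(rdfs:comment %s %s)", iri,
      quote_owl_string(paste("Typical profile:",
                             format(classdef$typical_profile)))))
  }
  genus_iri <- if (!is.null(classdef$genus)) iris$class[[classdef$genus]]
  if (classdef$defining && !is_trivially_true(classdef$differentia)) {
    exprs <- vapply(classdef$differentia$clauses, clause_expr,
                    character(1), plan = plan, iris = iris)
    out <- c(out, sprintf(
      "EquivalentClasses(%s ObjectIntersectionOf(%s))",
      iri, paste(c(genus_iri, exprs), collapse = " ")))
  } else if (!is.null(genus_iri)) {
    out <- c(out, sprintf("SubClassOf(%s %s)", iri, genus_iri))
  }
  out
}

kb_relations_used <- function(kb) {
  rels <- character(0)
  for (d in kb$classes) {
    for (cl in d$differentia$clauses) {
      rels <- c(rels, mapply(relation_for, cl$location, cl$status))
    }
  }
  sort(unique(rels))
}

#' Export a knowledge base as OWL functional-style syntax
#'
#' Writes a deterministic, line-oriented functional-syntax document:
#' declarations for every class, marker and referenced object property,
#' annotation assertions, and one equivalence or subclass axiom per
#' class.  Output is byte-identical across runs on the same KB and plan.
#'
#' @param kb a validated `leuko_kb`.
#' @param plan an [owl_render_plan].
#' @param path output file path.
#' @return the [load_ontology_stats] of the written file, invisibly.
#' @export
export_ontology <- function(kb, plan = owl_render_plan(), path) {
  stopifnot(inherits(kb, "leuko_kb"))
  iris <- mint_iris(kb, plan)
  lines <- c(
    sprintf("Prefix(%s:=<%s>)", names(plan$prefixes), plan$prefixes),
    sprintf("Ontology(<%s>", plan$ontology_iri),
    "Declaration(AnnotationProperty(ccl:id))",
    "Declaration(AnnotationProperty(ccl:term_type))",
    "Declaration(AnnotationProperty(obo:IAO_0000115))"
  )
  rels <- kb_relations_used(kb)
  lines <- c(lines, sprintf("Declaration(ObjectProperty(%s))",
                            plan$relation_iris[rels]))
  lines <- c(lines, sprintf("AnnotationAssertion(rdfs:label %s %s)",
                            plan$relation_iris[rels],
                            vapply(rels, quote_owl_string, character(1))))
  for (d in kb$classes) {
    lines <- c(lines, render_class_axioms(d, plan, kb))
  }
  for (m in kb$markers) {
    iri <- iris$marker[[m$label]]
    lines <- c(lines,
      sprintf("Declaration(Class(%s))", iri),
      sprintf("AnnotationAssertion(rdfs:label %s %s)", iri,
              quote_owl_string(m$label)),
      sprintf("AnnotationAssertion(ccl:id %s %s)", iri,
              quote_owl_string(m$id)),
      sprintf("AnnotationAssertion(ccl:term_type %s \"marker\")", iri))
    if (!is.null(m$external_ref)) {
      lines <- c(lines, sprintf(
        "AnnotationAssertion(ccl:xref %s %s)", iri,
        quote_owl_string(m$external_ref)))
    }
  }
  lines <- c(lines, ")")
  con <- file(path, open = "wb")
  writeLines(lines, con, useBytes = TRUE)
  close(con)
  invisible(load_ontology_stats(path, native_prefix = plan$iri_prefix))
}

# -- parsing: functional syntax -----------------------------------------

#' Parse an OWL functional-syntax document (line-oriented subset)
#'
#' Reads documents produced by [export_ontology] (and any functional
#' syntax file with one axiom per line).  Re-serialising the result with
#' [write_ofn] reproduces the input bytes.
#'
#' @param path file path.
#' @return an `ofn_document`: list with `prefixes` (named character),
#'   `ontology_iri` and `axioms` (character vector of axiom lines).
#' @export
parse_ofn <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  pref_idx <- grepl("^Prefix\\(", lines)
  prefixes <- character(0)
  for (l in lines[pref_idx]) {
    m <- regmatches(l, regexec("^Prefix\\(([A-Za-z0-9._-]*):=<([^>]*)>\\)$", l))[[1]]
    if (length(m) != 3L) stop("malformed Prefix line: ", l)
    prefixes[m[2]] <- m[3]
  }
  body <- lines[!pref_idx]
  ont_idx <- grep("^Ontology\\(", body)
  if (length(ont_idx) != 1L) stop("expected exactly one Ontology( line")
  ont_line <- body[ont_idx]
  m <- regmatches(ont_line, regexec("^Ontology\\(<([^>]*)>$", ont_line))[[1]]
  if (length(m) != 2L) stop("malformed Ontology line: ", ont_line)
  axioms <- body[-ont_idx]
  if (length(axioms) == 0L || axioms[length(axioms)] != ")") {
    stop("functional-syntax document must end with a ')' line")
  }
  axioms <- axioms[-length(axioms)]
  structure(list(prefixes = prefixes, ontology_iri = m[2], axioms = axioms),
            class = "ofn_document")
}

#' Serialise a parsed functional-syntax document
#'
#' @param doc an `ofn_document` from [parse_ofn].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ofn <- function(doc, path) {
  stopifnot(inherits(doc, "ofn_document"))
  lines <- c(sprintf("Prefix(%s:=<%s>)", names(doc$prefixes), doc$prefixes),
             sprintf("Ontology(<%s>", doc$ontology_iri),
             doc$axioms,
             ")")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

# tokenizing recursive-descent parser for one functional-syntax axiom:
# returns list(head = keyword, args = list of strings / nested nodes)
parse_axiom <- function(line) {
  pos <- 1L
  n <- nchar(line)
  peek <- function() if (pos <= n) substr(line, pos, pos) else ""
  skip_ws <- function() while (pos <= n && peek() == " ") pos <<- pos + 1L
  read_node <- function() {
    skip_ws()
    if (peek() == "\"") {
      # quoted string
      j <- pos + 1L
      out <- character(0)
      while (j <= n) {
        ch <- substr(line, j, j)
        if (ch == "\\") { out <- c(out, substr(line, j + 1L, j + 1L)); j <- j + 2L }
        else if (ch == "\"") break
        else { out <- c(out, ch); j <- j + 1L }
      }
      pos <<- j + 1L
      return(list(type = "string", value = paste(out, collapse = "")))
    }
    start <- pos
    while (pos <= n && !(peek() %in% c("(", ")", " "))) pos <<- pos + 1L
    tok <- substr(line, start, pos - 1L)
    skip_ws()
    if (peek() == "(") {
      pos <<- pos + 1L
      args <- list()
      repeat {
        skip_ws()
        if (peek() == ")") { pos <<- pos + 1L; break }
        if (pos > n) stop("unbalanced parentheses in axiom: ", line)
        args[[length(args) + 1L]] <- read_node()
      }
      return(list(type = "call", head = tok, args = args))
    }
    list(type = "name", value = tok)
  }
  node <- read_node()
  skip_ws()
  if (pos <= n) stop("trailing content in axiom: ", line)
  node
}

node_name <- function(x) {
  if (!identical(x$type, "name")) stop("expected a name node")
  x$value
}

# -- reconstructing a KB from a parsed export ---------------------------

#' Rebuild a knowledge base from a parsed ontology export
#'
#' Inverts [export_ontology] far enough to re-derive the class hierarchy:
#' class/marker identities come from the `ccl:id` annotations, genus and
#' differentia from the equivalence/subclass axioms, and literals from
#' the relation IRIs in `plan`.  Annotation-only content (typical
#' profiles, lineage sentences) is not reconstructed.
#'
#' @param doc an `ofn_document` from [parse_ofn].
#' @param plan the [owl_render_plan] the document was exported with.
#' @return a `leuko_kb` suitable for [classify_hierarchy].
#' @export
ofn_to_kb <- function(doc, plan = owl_render_plan()) {
  stopifnot(inherits(doc, "ofn_document"))
  rel_by_iri <- stats::setNames(names(plan$relation_iris),
                                plan$relation_iris)
  loc_status <- list()
  for (k in names(RELATION_MAP)) {
    loc_status[[RELATION_MAP[[k]]]] <- strsplit(k, "|", fixed = TRUE)[[1]]
  }

  declared <- character(0)
  ids <- list()       # iri -> ccl:id annotation
  labels <- list()    # iri -> rdfs:label
  sub_of <- list()    # iri -> genus iri
  equiv <- list()     # iri -> intersection node
  tagged_markers <- character(0)
  filler_iris <- character(0)

  collect_fillers <- function(node) {
    if (identical(node$type, "call")) {
      if (node$head == "ObjectSomeValuesFrom") {
        filler_iris <<- c(filler_iris, node_name(node$args[[2]]))
      }
      for (a in node$args) collect_fillers(a)
    }
  }

  for (line in doc$axioms) {
    node <- parse_axiom(line)
    if (node$type != "call") next
    if (node$head == "Declaration") {
      inner <- node$args[[1]]
      if (inner$head == "Class") {
        declared <- c(declared, node_name(inner$args[[1]]))
      }
    } else if (node$head == "AnnotationAssertion") {
      prop <- node_name(node$args[[1]])
      subj <- node_name(node$args[[2]])
      val <- node$args[[3]]$value
      if (prop == "ccl:id") ids[[subj]] <- val
      if (prop == "rdfs:label") labels[[subj]] <- val
      if (prop == "ccl:term_type" && identical(val, "marker")) {
        tagged_markers <- c(tagged_markers, subj)
      }
    } else if (node$head == "SubClassOf") {
      sub_of[[node_name(node$args[[1]])]] <- node_name(node$args[[2]])
    } else if (node$head == "EquivalentClasses") {
      equiv[[node_name(node$args[[1]])]] <- node$args[[2]]
      collect_fillers(node$args[[2]])
    }
  }

  # markers: tagged as such on export, or (untagged files) any declared
  # class used as a restriction filler
  marker_iris <- intersect(declared,
                           unique(c(tagged_markers, filler_iris)))
  markers <- lapply(marker_iris, function(iri) {
    new_marker(ids[[iri]] %||% iri, labels[[iri]] %||% iri)
  })
  class_iris <- setdiff(declared, marker_iris)
  boot <- new_kb(list(), markers, list(name = "reparsed"))

  restriction_to_literal <- function(node) {
    stopifnot(node$head == "ObjectSomeValuesFrom")
    rel <- rel_by_iri[[node_name(node$args[[1]])]]
    ls <- loc_status[[rel]]
    marker_label <- labels[[node_name(node$args[[2]])]]
    c(marker_label, ls[1], ls[2])
  }

  classes <- lapply(class_iris, function(iri) {
    id <- ids[[iri]] %||% iri
    if (!is.null(equiv[[iri]])) {
      node <- equiv[[iri]]
      stopifnot(node$head == "ObjectIntersectionOf")
      genus_iri <- NULL
      clauses <- list()
      for (a in node$args) {
        if (a$type == "name") {
          genus_iri <- a$value
        } else if (a$head == "ObjectUnionOf") {
          clauses[[length(clauses) + 1L]] <-
            lapply(a$args, restriction_to_literal)
        } else {
          clauses[[length(clauses) + 1L]] <- list(restriction_to_literal(a))
        }
      }
      genus <- if (!is.null(genus_iri)) ids[[genus_iri]] %||% genus_iri
      new_classdef(id, labels[[iri]] %||% id, genus, TRUE,
                   make_phenotype(clauses, boot))
    } else {
      genus_iri <- sub_of[[iri]]
      genus <- if (!is.null(genus_iri)) ids[[genus_iri]] %||% genus_iri
      new_classdef(id, labels[[iri]] %||% id, genus, FALSE,
                   new_phenotype(list()))
    }
  })
  new_kb(classes, markers, list(name = "reparsed", version = "0"))
}

# -- statistics ----------------------------------------------------------

resolve_curie <- function(x, prefixes) {
  m <- regmatches(x, regexec("^([A-Za-z0-9._-]*):(.*)$", x))[[1]]
  if (length(m) == 3L && m[2] %in% names(prefixes)) {
    paste0(prefixes[[m[2]]], m[3])
  } else {
    gsub("^<|>$", "", x)
  }
}

#' Count classes, properties and axioms of an ontology file
#'
#' Supports the line-oriented OWL functional syntax written by
#' [export_ontology] and RDF/XML.  Named, non-deprecated classes are
#' counted and split into native vs imported by IRI prefix.  Import
#' statements are not resolved over the network: by default unresolved
#' imports are reported via a warning and local counts returned.
#'
#' @param path ontology file path.
#' @param native_prefix IRI prefix of natively minted terms.
#' @param on_unresolved_import `"count-local-only"` (default) or `"fail"`.
#' @return an `ontology_stats`: list with `total_class_count`,
#'   `native_class_count`, `imported_class_count`,
#'   `object_property_count` and `axiom_counts` (named table by axiom
#'   type).
#' @export
load_ontology_stats <- function(path, native_prefix,
                                on_unresolved_import =
                                  c("count-local-only", "fail")) {
  on_unresolved_import <- match.arg(on_unresolved_import)
  head <- readLines(path, n = 5L, warn = FALSE)
  is_xml <- any(grepl("^\\s*<\\?xml|^\\s*<rdf:RDF", head))
  if (is_xml) {
    stats_rdfxml(path, native_prefix, on_unresolved_import)
  } else {
    stats_ofn(path, native_prefix, on_unresolved_import)
  }
}

new_ontology_stats <- function(class_iris, native_prefix, deprecated,
                               n_objprop, axiom_counts) {
  class_iris <- setdiff(unique(class_iris), deprecated)
  native <- sum(startsWith(class_iris, native_prefix))
  structure(list(total_class_count = length(class_iris),
                 native_class_count = native,
                 imported_class_count = length(class_iris) - native,
                 object_property_count = n_objprop,
                 axiom_counts = axiom_counts),
            class = "ontology_stats")
}

stats_ofn <- function(path, native_prefix, on_unresolved_import) {
  doc <- parse_ofn(path)
  class_iris <- character(0)
  objprops <- character(0)
  deprecated <- character(0)
  kinds <- character(0)
  for (line in doc$axioms) {
    node <- parse_axiom(line)
    if (node$type != "call") next
    kinds <- c(kinds, node$head)
    if (node$head == "Declaration") {
      inner <- node$args[[1]]
      iri <- resolve_curie(node_name(inner$args[[1]]), doc$prefixes)
      if (inner$head == "Class") class_iris <- c(class_iris, iri)
      if (inner$head == "ObjectProperty") objprops <- c(objprops, iri)
    } else if (node$head == "AnnotationAssertion" &&
               node_name(node$args[[1]]) == "owl:deprecated") {
      deprecated <- c(deprecated,
                      resolve_curie(node_name(node$args[[2]]), doc$prefixes))
    } else if (node$head == "Import") {
      if (on_unresolved_import == "fail") {
        stop("ontology has imports; resolution is not supported: ", line)
      }
      warning("unresolved import ignored (counting local terms only): ",
              line)
    }
  }
  new_ontology_stats(class_iris, native_prefix, deprecated,
                     length(unique(objprops)), table(kinds))
}

stats_rdfxml <- function(path, native_prefix, on_unresolved_import) {
  x <- xml2::read_xml(path)
  ns <- c(owl = "http://www.w3.org/2002/07/owl#",
          rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#")
  classes <- xml2::xml_find_all(x, "//owl:Class[@rdf:about]", ns)
  class_iris <- xml2::xml_attr(classes, "about")
  dep_nodes <- xml2::xml_find_all(
    x, "//owl:Class[owl:deprecated='true']", ns)
  deprecated <- xml2::xml_attr(dep_nodes, "about")
  objprops <- xml2::xml_find_all(x, "//owl:ObjectProperty[@rdf:about]", ns)
  imports <- xml2::xml_find_all(x, "//owl:imports", ns)
  if (length(imports)) {
    if (on_unresolved_import == "fail") {
      stop("ontology has imports; resolution is not supported")
    }
    warning("unresolved imports ignored (counting local terms only)")
  }
  kinds <- table(c(rep("Class", length(classes)),
                   rep("ObjectProperty", length(objprops))))
  new_ontology_stats(class_iris, native_prefix, deprecated,
                     length(unique(xml2::xml_attr(objprops, "about"))),
                     kinds)
}

#' @export
print.ontology_stats <- function(x, ...) {
  cat(sprintf("<ontology stats: %d classes (%d native, %d imported), %d object properties>\n",
              x$total_class_count, x$native_class_count,
              x$imported_class_count, x$object_property_count))
  invisible(x)
}
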