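# Knowledge base: marker dictionary, genus-differentia class definitions,
# relation vocabulary, validation, textual definitions, and the shipped
# EGIL encoding.

# -- relation vocabulary -------------------------------------------------

# (location, status) -> OBO-style relation name.  There is deliberately no
# cytoplasmic analogue of the high/low plasma-membrane-amount relations:
# relative-amount calls are defined against surface fluorescence only.
RELATION_MAP <- list(
  "surface|present"     = "has_plasma_membrane_part",
  "surface|absent"      = "lacks_plasma_membrane_part",
  "surface|high"        = "has_high_plasma_membrane_amount",
  "surface|low"         = "has_low_plasma_membrane_amount",
  "cytoplasmic|present" = "has_cytoplasm_part",
  "cytoplasmic|absent"  = "lacks_cytoplasm_part"
)

#' Relation vocabulary of the literal model
#'
#' @return named character vector: the relation names used to axiomatise
#'   marker literals, including the generic absence relation `lacks_part`.
#' @export
relation_vocabulary <- function() {
  c(unlist(RELATION_MAP, use.names = FALSE), "lacks_part")
}

#' Map a (location, status) pair to its relation name
#'
#' Errors for (cytoplasmic, high/low): no such relation exists in the
#' vocabulary.
#'
#' @param location `"surface"` or `"cytoplasmic"`.
#' @param status one of [STATUSES].
#' @export
relation_for <- function(location, status) {
  assert_location(location)
  assert_status(status)
  rel <- RELATION_MAP[[paste(location, status, sep = "|")]]
  if (is.null(rel)) {
    stop(sprintf("unsupported relation: no relation for (%s, %s)",
                 location, status))
  }
  rel
}

# -- construction --------------------------------------------------------

new_marker <- function(id, label, synonyms = character(0),
                       external_ref = NULL) {
  list(id = id, label = label, synonyms = as.character(synonyms),
       external_ref = external_ref)
}

new_classdef <- function(id, label, genus, defining, differentia,
                         typical_profile = NULL, lineage_text = NULL,
                         stage_group = NULL, stage_rank = NULL) {
  list(id = id, label = label, genus = genus, defining = defining,
       differentia = differentia, typical_profile = typical_profile,
       lineage_text = lineage_text, stage_group = stage_group,
       stage_rank = stage_rank)
}

build_marker_index <- function(markers) {
  idx <- list()
  for (m in markers) {
    for (k in unique(normalize_key(c(m$label, m$synonyms)))) {
      if (!is.null(idx[[k]]) && idx[[k]] != m$id) {
        stop(sprintf("marker label/synonym '%s' maps to both %s and %s",
                     k, idx[[k]], m$id))
      }
      idx[[k]] <- m$id
    }
  }
  idx
}

new_kb <- function(classes, markers, metadata) {
  names(markers) <- vapply(markers, `[[`, character(1), "id")
  names(classes) <- vapply(classes, `[[`, character(1), "id")
  roots <- names(classes)[vapply(classes, function(d) is.null(d$genus),
                                 logical(1))]
  structure(list(classes = classes,
                 markers = markers,
                 marker_index = build_marker_index(markers),
                 roots = roots,
                 metadata = metadata),
            class = "leuko_kb")
}

#' @export
print.leuko_kb <- function(x, ...) {
  cat(sprintf("<knowledge base '%s' v%s: %d classes, %d markers>\n",
              x$metadata$name, x$metadata$version,
              length(x$classes), length(x$markers)))
  invisible(x)
}

# -- the built-in EGIL knowledge base -----------------------------------

egil_markers <- function() {
  list(
    new_marker("M01", "CD19", external_ref = "PR:000001002"),
    new_marker("M02", "CD79a"),
    new_marker("M03", "CD22"),
    new_marker("M04", "CD10"),
    new_marker("M05", "Ig mu",
               synonyms = c("IgM", "Igmu", "IgM heavy chain", "cyIgmu")),
    new_marker("M06", "sIg",
               synonyms = c("surface immunoglobulin", "smIg")),
    new_marker("M07", "kappa light chain",
               synonyms = c("kappa", "Ig kappa")),
    new_marker("M08", "lambda light chain",
               synonyms = c("lambda", "Ig lambda")),
    new_marker("M09", "CD3"),
    new_marker("M10", "CD7"),
    new_marker("M11", "CD2"),
    new_marker("M12", "CD5"),
    new_marker("M13", "CD8"),
    new_marker("M14", "CD1a"),
    new_marker("M15", "TCR alpha/beta",
               synonyms = c("TCRab", "TCR a/b")),
    new_marker("M16", "TCR gamma/delta",
               synonyms = c("TCRgd", "TCR g/d")),
    new_marker("M17", "MPO", synonyms = "myeloperoxidase"),
    new_marker("M18", "enzymatic MPO", synonyms = "enzMPO"),
    new_marker("M19", "CD13"),
    new_marker("M20", "CD33"),
    new_marker("M21", "CD65"),
    new_marker("M22", "CD117", synonyms = "KIT"),
    new_marker("M23", "CD41"),
    new_marker("M24", "CD61"),
    new_marker("M25", "GPA", synonyms = c("glycophorin A", "CD235a")),
    new_marker("M26", "CD34"),
    new_marker("M27", "HLA-DR"),
    new_marker("M28", "CD38")
  )
}

#' The built-in EGIL knowledge base
#'
#' Curated genus-differentia encoding of the EGIL immunophenotyping scheme
#' for acute leukemias: B-lineage ALL with maturation stages B-I..B-IV,
#' T-lineage ALL with stages T-I..T-IV (and the TCR alpha/beta vs
#' gamma/delta subgroups of T-IV), and the AML lineages (early myeloid
#' AML-M0, myelo/monocytic, megakaryocytic, erythroid, undifferentiated).
#' The domain root `hematologic-malignant-cell` sits under a stub upper
#' chain (malignant / neoplastic / abnormal cell), and a non-defining
#' `multiple-myeloma` class is included as an extension point.
#'
#' @return a `leuko_kb` object.
#' @examples
#' kb <- builtin_egil_kb()
#' expand_definition("B-II", kb)
#' @export
builtin_egil_kb <- function() {
  markers <- egil_markers()
  # bootstrap KB with markers only, so make_phenotype can resolve labels
  boot <- new_kb(list(), markers, list(name = "egil_table1"))
  ph <- function(...) make_phenotype(list(...), boot)
  none <- new_phenotype(list())

  s <- function(m, st = "present") c(m, "surface", st)
  cy <- function(m, st = "present") c(m, "cytoplasmic", st)

  classes <- list(
    new_classdef("abnormal-cell", "abnormal cell", NULL, FALSE, none,
      lineage_text = "A cell that deviates from its expected normal state."),
    new_classdef("neoplastic-cell", "neoplastic cell", "abnormal-cell",
      FALSE, none,
      lineage_text = "An abnormal cell arising from clonal proliferation."),
    new_classdef("malignant-cell", "malignant cell", "neoplastic-cell",
      FALSE, none,
      lineage_text = "A neoplastic cell with invasive potential."),
    new_classdef("hematologic-malignant-cell", "hematologic malignant cell",
      "malignant-cell", FALSE, none,
      lineage_text = "A malignant cell of hematopoietic origin."),

    new_classdef("ALL", "acute lymphoblastic leukemic cell",
      "hematologic-malignant-cell", FALSE, none,
      lineage_text = paste("A hematologic malignant cell whose precursor",
                           "is of lymphoid lineage.")),
    new_classdef("AML", "acute myeloid leukemic cell",
      "hematologic-malignant-cell", FALSE, none,
      lineage_text = paste("A hematologic malignant cell whose precursor",
                           "is of myeloid lineage.")),

    # --- B lineage ------------------------------------------------------
    new_classdef("B-lineage-ALL", "B-lineage ALL", "ALL", TRUE,
      ph(list(s("CD19"), s("CD79a"), s("CD22")))),
    # "No B-cell differentiation antigens": explicit negatives for the
    # sibling-defining maturation markers.
    new_classdef("B-I", "B-I (pro-B)", "B-lineage-ALL", TRUE,
      ph(list(s("CD10", "absent")),
         list(cy("Ig mu", "absent")),
         list(s("sIg", "absent"))),
      stage_group = "B", stage_rank = 1L),
    new_classdef("B-II", "B-II (common B)", "B-lineage-ALL", TRUE,
      ph(list(s("CD10"))),
      stage_group = "B", stage_rank = 2L),
    new_classdef("B-III", "B-III (pre-B)", "B-lineage-ALL", TRUE,
      ph(list(cy("Ig mu"))),
      stage_group = "B", stage_rank = 3L),
    # mature B: cytoplasmic or surface light-chain restriction
    new_classdef("B-IV", "B-IV (mature B)", "B-lineage-ALL", TRUE,
      ph(list(s("kappa light chain"), cy("kappa light chain"),
              s("lambda light chain"), cy("lambda light chain"))),
      stage_group = "B", stage_rank = 4L),

    # --- T lineage ------------------------------------------------------
    new_classdef("T-lineage-ALL", "T-lineage ALL", "ALL", TRUE,
      ph(list(cy("CD3"), s("CD3")))),
    new_classdef("T-I", "T-I (pro-T)", "T-lineage-ALL", TRUE,
      ph(list(s("CD7"))),
      stage_group = "T", stage_rank = 1L),
    new_classdef("T-II", "T-II (pre-T)", "T-lineage-ALL", TRUE,
      ph(list(s("CD2"), s("CD5"), s("CD8"))),
      stage_group = "T", stage_rank = 2L),
    new_classdef("T-III", "T-III (cortical T)", "T-lineage-ALL", TRUE,
      ph(list(s("CD1a"))),
      stage_group = "T", stage_rank = 3L),
    new_classdef("T-IV", "T-IV (mature T)", "T-lineage-ALL", TRUE,
      ph(list(s("CD3")), list(s("CD1a", "absent"))),
      stage_group = "T", stage_rank = 4L),
    new_classdef("T-IV-a", "T-IV group a (TCR alpha/beta+)", "T-IV", TRUE,
      ph(list(s("TCR alpha/beta")))),
    new_classdef("T-IV-b", "T-IV group b (TCR gamma/delta+)", "T-IV", TRUE,
      ph(list(s("TCR gamma/delta")))),

    # --- AML ------------------------------------------------------------
    # AML-M0: immunologic MPO is unconstrained ("+/-"); the row constrains
    # only the enzymatic assay, which must be negative.
    new_classdef("AML-M0", "early myeloid AML (AML-M0)", "AML", TRUE,
      ph(list(cy("enzymatic MPO", "absent")),
         list(s("CD13"), s("CD33"), s("CD65"), s("CD117")))),
    new_classdef("AML-myelomonocytic", "myelo/monocytic lineage AML",
      "AML", TRUE,
      ph(list(cy("MPO")),
         list(s("CD13"), s("CD33"), s("CD65"), s("CD117")))),
    new_classdef("AML-megakaryocytic", "megakaryocytic lineage AML",
      "AML", TRUE,
      ph(list(s("CD41"), cy("CD41"), s("CD61"), cy("CD61")))),
    new_classdef("AML-erythroid", "erythroid lineage AML", "AML", FALSE,
      none,
      lineage_text = "An acute myeloid leukemic cell of erythroid lineage."),
    new_classdef("AML-erythroid-early", "early/immature erythroid AML",
      "AML-erythroid", FALSE, none,
      lineage_text = paste("An early immature erythroid leukemic cell,",
                           "unclassified by markers.")),
    new_classdef("AML-erythroid-late", "late/mature erythroid AML",
      "AML-erythroid", TRUE,
      ph(list(s("GPA")))),
    new_classdef("AML-undifferentiated", "undifferentiated AML", "AML",
      FALSE, none,
      typical_profile = ph(list(s("CD34")), list(s("HLA-DR")),
                           list(s("CD38")), list(s("CD7"))),
      lineage_text = paste("An acute myeloid leukemic cell lacking",
                           "lineage-committed marker expression.")),

    # extension point, empty by default
    new_classdef("multiple-myeloma", "multiple myeloma cell",
      "hematologic-malignant-cell", FALSE, none,
      lineage_text = paste("A hematologic malignant cell whose precursor",
                           "is a plasma cell."))
  )

  new_kb(classes, markers,
         list(name = "egil_table1", version = "1.0.0",
              description = paste("EGIL immunophenotype classification of",
                                  "acute leukemias, genus-differentia",
                                  "encoding")))
}

# -- validation ----------------------------------------------------------

finding <- function(level, code, class_id, message) {
  data.frame(level = level, code = code, class_id = class_id,
             message = message, stringsAsFactors = FALSE)
}

no_findings <- function() {
  data.frame(level = character(0), code = character(0),
             class_id = character(0), message = character(0),
             stringsAsFactors = FALSE)
}

#' Validate a knowledge base
#'
#' Automated consistency review: genus cycles and dangling references,
#' literals with no relation in the vocabulary (cytoplasmic high/low),
#' unsatisfiable expanded definitions, pairs of distinct defining classes
#' with logically equivalent expanded definitions, duplicate labels, and
#' markers never used.
#'
#' @param kb a `leuko_kb`.
#' @return data frame of findings with columns `level` (`"error"`,
#'   `"warning"`, `"info"`), `code`, `class_id`, `message`; zero rows for
#'   a clean KB.
#' @export
validate_kb <- function(kb) {
  stopifnot(inherits(kb, "leuko_kb"))
  f <- no_findings()
  ids <- names(kb$classes)

  # duplicate labels (case-insensitive)
  labs <- tolower(vapply(kb$classes, `[[`, character(1), "label"))
  for (l in unique(labs[duplicated(labs)])) {
    f <- rbind(f, finding("error", "duplicate-label",
                          paste(ids[labs == l], collapse = ","),
                          sprintf("label '%s' used by multiple classes", l)))
  }

  # genus chains: dangling references and cycles
  expansions <- list()
  for (id in ids) {
    res <- tryCatch(expand_definition(id, kb), error = function(e) e)
    if (inherits(res, "error")) {
      code <- if (grepl("cycle", conditionMessage(res))) "genus-cycle"
              else "dangling-genus"
      f <- rbind(f, finding("error", code, id, conditionMessage(res)))
    } else {
      expansions[[id]] <- res
    }
  }

  # unsupported relations
  for (id in ids) {
    for (cl in kb$classes[[id]]$differentia$clauses) {
      bad <- cl$location == "cytoplasmic" & cl$status %in% c("high", "low")
      if (any(bad)) {
        f <- rbind(f, finding("error", "unsupported-relation", id,
          sprintf("no relation for cytoplasmic %s (marker %s)",
                  cl$status[bad][1L], cl$marker[bad][1L])))
      }
    }
  }

  # unsatisfiable expansions
  for (id in names(expansions)) {
    if (!is_satisfiable(expansions[[id]])) {
      f <- rbind(f, finding("error", "unsatisfiable-class", id,
        sprintf("expanded definition of '%s' admits no marker world", id)))
    }
  }

  # logically equivalent pairs among defining classes
  defn <- ids[vapply(kb$classes, `[[`, logical(1), "defining")]
  defn <- intersect(defn, names(expansions))
  if (length(defn) > 1L) {
    for (i in seq_len(length(defn) - 1L)) {
      for (j in seq(i + 1L, length(defn))) {
        a <- expansions[[defn[i]]]; b <- expansions[[defn[j]]]
        if (entails(a, b) && entails(b, a)) {
          f <- rbind(f, finding("warning", "equivalent-classes",
            paste(defn[i], defn[j], sep = ","),
            sprintf("'%s' and '%s' have logically equivalent definitions",
                    defn[i], defn[j])))
        }
      }
    }
  }

  # markers never used (differentia or typical profile)
  used <- character(0)
  for (d in kb$classes) {
    for (p in list(d$differentia, d$typical_profile)) {
      if (!is.null(p)) {
        used <- c(used, unlist(lapply(p$clauses, `[[`, "marker")))
      }
    }
  }
  unused <- setdiff(vapply(kb$markers, `[[`, character(1), "label"),
                    unique(used))
  for (m in unused) {
    f <- rbind(f, finding("info", "unused-marker", NA_character_,
                          sprintf("marker '%s' is never used", m)))
  }

  rownames(f) <- NULL
  f
}

# -- textual definitions -------------------------------------------------

status_word <- function(status) {
  c(absent = "negative", present = "positive",
    high = "high", low = "low")[status]
}

literal_phrase <- function(marker, location, status) {
  if (location == "cytoplasmic") {
    paste("cytoplasmic", marker, status_word(status))
  } else {
    paste0(marker, "-", status_word(status))
  }
}

article_for <- function(label) {
  if (grepl("^[AEIOUaeiou]", label)) "An" else "A"
}

#' Render the human-readable textual definition of a class
#'
#' Defining classes render deterministically as "A/An {genus label} that
#' is {marker phrases}.", with disjunctive clauses joined by "or" and
#' cytoplasmic literals phrased as "cytoplasmic X positive/negative".
#' Non-defining classes (and classes without differentia) return their
#' stored lineage sentence.
#'
#' @param class_id identifier of a class in `kb`.
#' @param kb a `leuko_kb`.
#' @return a single sentence.
#' @export
render_textual_definition <- function(class_id, kb) {
  stopifnot(inherits(kb, "leuko_kb"))
  def <- kb$classes[[class_id]]
  if (is.null(def)) stop("unknown class: ", class_id)
  if (!def$defining || is_trivially_true(def$differentia)) {
    if (!is.null(def$lineage_text)) return(def$lineage_text)
    genus_label <- if (!is.null(def$genus)) kb$classes[[def$genus]]$label
                   else "cell"
    return(paste0(article_for(genus_label), " ", genus_label, "."))
  }
  genus_label <- kb$classes[[def$genus]]$label
  phrases <- vapply(def$differentia$clauses, function(cl) {
    paste(mapply(literal_phrase, cl$marker, cl$location, cl$status),
          collapse = " or ")
  }, character(1))
  paste0(article_for(genus_label), " ", genus_label, " that is ",
         paste(phrases, collapse = ", "), ".")
}

# -- load / save ---------------------------------------------------------

phenotype_to_schema <- function(p) {
  lapply(p$clauses, function(cl) {
    lapply(seq_len(nrow(cl)), function(i) {
      list(marker = cl$marker[i], location = cl$location[i],
           status = cl$status[i])
    })
  })
}

#' Save a knowledge base to its structured-text (JSON) schema
#'
#' The on-disk schema is a single human-editable JSON document with
#' `metadata`, a `markers` dictionary (id, label, synonyms, external_ref)
#' and one record per class: `id`, `label`, `genus`, `defining`, `clauses`
#' as lists of marker/location/status triples, optional `typical_profile`,
#' `lineage_text` and maturation-stage annotations.  Saving then loading
#' yields an identical knowledge base.
#'
#' @param kb a `leuko_kb`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_kb <- function(kb, path) {
  stopifnot(inherits(kb, "leuko_kb"))
  doc <- list(
    format = "leukotype-kb",
    schema_version = 1L,
    metadata = kb$metadata,
    markers = lapply(unname(kb$markers), function(m) {
      out <- list(id = m$id, label = m$label)
      if (length(m$synonyms)) out$synonyms <- as.list(m$synonyms)
      if (!is.null(m$external_ref)) out$external_ref <- m$external_ref
      out
    }),
    classes = lapply(unname(kb$classes), function(d) {
      out <- list(id = d$id, label = d$label)
      if (!is.null(d$genus)) out$genus <- d$genus
      out$defining <- d$defining
      out$clauses <- phenotype_to_schema(d$differentia)
      if (!is.null(d$typical_profile)) {
        out$typical_profile <- phenotype_to_schema(d$typical_profile)
      }
      if (!is.null(d$lineage_text)) out$lineage_text <- d$lineage_text
      if (!is.null(d$stage_group)) {
        out$stage_group <- d$stage_group
        out$stage_rank <- d$stage_rank
      }
      out
    })
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

schema_clauses <- function(raw, kb, context) {
  lapply(raw, function(cl) {
    if (length(cl) == 0L) {
      stop(sprintf("%s: empty clause", context))
    }
    lapply(cl, function(lit) {
      for (fld in c("marker", "location", "status")) {
        if (is.null(lit[[fld]])) {
          stop(sprintf("%s: literal missing field '%s'", context, fld))
        }
      }
      c(lit$marker, lit$location, lit$status)
    })
  })
}

#' Load a knowledge base from its structured-text schema
#'
#' @param path path to a KB JSON document (see [save_kb]).
#' @param strict if `TRUE` (default), error-level validation findings
#'   abort the load; otherwise they are reported as warnings.
#' @return a validated `leuko_kb`.
#' @export
load_kb <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("KB file not found: ", path)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("KB file does not parse as JSON: ",
                         conditionMessage(e))
                  })
  if (!identical(doc$format, "leukotype-kb")) {
    stop("not a leukotype KB document (missing format tag)")
  }
  markers <- lapply(doc$markers, function(m) {
    if (is.null(m$id) || is.null(m$label)) {
      stop("marker record missing id or label")
    }
    new_marker(m$id, m$label,
               synonyms = unlist(m$synonyms %||% list()),
               external_ref = m$external_ref)
  })
  boot <- new_kb(list(), markers, doc$metadata)
  classes <- lapply(seq_along(doc$classes), function(i) {
    rec <- doc$classes[[i]]
    ctx <- sprintf("class record %d (id '%s')", i, rec$id %||% "?")
    if (is.null(rec$id) || is.null(rec$label)) {
      stop(ctx, ": missing id or label")
    }
    diff <- make_phenotype(schema_clauses(rec$clauses %||% list(),
                                          boot, ctx), boot)
    # relation-vocabulary check at load time, with record context
    for (cl in diff$clauses) {
      for (k in seq_len(nrow(cl))) {
        tryCatch(relation_for(cl$location[k], cl$status[k]),
                 error = function(e) {
                   stop(ctx, ": ", conditionMessage(e), call. = FALSE)
                 })
      }
    }
    tp <- if (!is.null(rec$typical_profile)) {
      make_phenotype(schema_clauses(rec$typical_profile, boot, ctx), boot)
    }
    new_classdef(rec$id, rec$label, rec$genus, isTRUE(rec$defining), diff,
                 typical_profile = tp, lineage_text = rec$lineage_text,
                 stage_group = rec$stage_group,
                 stage_rank = if (!is.null(rec$stage_rank))
                   as.integer(rec$stage_rank))
  })
  kb <- new_kb(classes, markers, doc$metadata)
  findings <- validate_kb(kb)
  errs <- findings[findings$level == "error", , drop = FALSE]
  if (nrow(errs)) {
    msg <- paste(sprintf("[%s] %s", errs$code, errs$message),
                 collapse = "; ")
    if (strict) stop("KB validation failed: ", msg) else warning(msg)
  }
  kb
}

`%||%` <- function(a, b) if (is.null(a)) b else a
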