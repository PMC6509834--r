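# Core vocabulary: markers, expression literals, phenotypes.
#
# A literal asserts one expression status for one marker at one cellular
# location.  A phenotype is a conjunction of clauses, each clause a
# disjunction of literals (conjunctive normal form); this houses the
# "and/or" rows of immunophenotyping tables directly.

#' Cellular locations recognised by the literal model
#' @export
LOCATIONS <- c("surface", "cytoplasmic")

#' Expression statuses recognised by the literal model
#'
#' `high` and `low` each entail `present` (relative amounts refine
#' presence); `absent` is incompatible with all three.
#' @export
STATUSES <- c("absent", "present", "high", "low")

# Concrete statuses a world may assign that make a literal of the given
# status true.  This is the semantic core shared by the reasoner and the
# instance classifier.
status_allowed <- function(status) {
  switch(status,
    present = c("present", "high", "low"),
    absent  = "absent",
    high    = "high",
    low     = "low",
    stop("unknown expression status: ", status)
  )
}

assert_location <- function(location) {
  if (!is.character(location) || length(location) != 1L ||
      !(location %in% LOCATIONS)) {
    stop("location must be one of: ", paste(LOCATIONS, collapse = ", "))
  }
  location
}

assert_status <- function(status) {
  if (!is.character(status) || length(status) != 1L ||
      !(status %in% STATUSES)) {
    stop("status must be one of: ", paste(STATUSES, collapse = ", "))
  }
  status
}

# Normalised lookup key for a marker label or synonym: case-folded,
# all whitespace removed (so "CD 117" and "cd117 " both resolve).
normalize_key <- function(x) {
  gsub("[[:space:]]+", "", tolower(trimws(x)))
}

#' Resolve a raw marker label against a knowledge base
#'
#' Matching is case-insensitive and whitespace-insensitive, over both
#' canonical labels and synonyms.  Location prefixes such as `"cy"` in
#' `"cyCD3"` are the caller's concern: this resolves the bare marker name.
#'
#' @param raw a single marker label as written (e.g. `"CD19"`, `"cd19 "`).
#' @param kb a [KnowledgeBase][builtin_egil_kb] object.
#' @return the matching marker record: a list with `id`, `label`,
#'   `synonyms`, `external_ref`.
#' @export
normalize_marker_label <- function(raw, kb) {
  stopifnot(inherits(kb, "leuko_kb"))
  if (!is.character(raw) || length(raw) != 1L || !nzchar(trimws(raw))) {
    stop("marker label must be a non-empty string")
  }
  key <- normalize_key(raw)
  hit <- kb$marker_index[[key]]
  if (is.null(hit)) {
    cand <- names(kb$marker_index)
    d <- utils::adist(key, cand)
    near <- unique(unlist(lapply(cand[order(d)][seq_len(min(3L, length(cand)))],
                                 function(k) kb$marker_index[[k]])))
    near_labels <- vapply(kb$markers[near], function(m) m$label, character(1))
    stop(sprintf("unknown marker '%s' (nearest candidates: %s)",
                 raw, paste(unique(near_labels), collapse = ", ")))
  }
  kb$markers[[hit]]
}

# -- phenotype construction ---------------------------------------------

literal_key <- function(clause) {
  paste(clause$marker, clause$location, clause$status, sep = "\x1f")
}

canonical_clause <- function(df) {
  df <- df[!duplicated(literal_key(df)), , drop = FALSE]
  df <- df[order(df$marker, df$location, df$status), , drop = FALSE]
  rownames(df) <- NULL
  df
}

clause_key <- function(df) {
  paste(literal_key(df), collapse = "\x1e")
}

new_phenotype <- function(clauses) {
  structure(list(clauses = clauses), class = "leuko_phenotype")
}

#' Build a canonical phenotype from clause triples
#'
#' Each clause is a list of `(marker, location, status)` triples and is
#' read as a disjunction; the clause list is a conjunction.  Marker names
#' are resolved through the knowledge base dictionary.  Duplicate literals
#' within a clause and duplicate clauses are removed; literals are sorted
#' by marker label, then location, then status, so equal phenotypes
#' compare equal.  An empty clause list is the trivially true phenotype.
#'
#' @param clauses list of clauses; each clause a non-empty list of triples
#'   (character vectors or lists of length 3: marker, location, status).
#' @param kb a knowledge base supplying the marker dictionary.
#' @return a `leuko_phenotype` object.
#' @examples
#' kb <- builtin_egil_kb()
#' make_phenotype(list(list(
#'   c("CD19", "surface", "present"),
#'   c("CD79a", "surface", "present"),
#'   c("CD22", "surface", "present"))), kb)
#' @export
make_phenotype <- function(clauses, kb) {
  stopifnot(is.list(clauses))
  out <- lapply(clauses, function(cl) {
    if (length(cl) == 0L) stop("empty clause in phenotype")
    lits <- lapply(cl, function(lit) {
      lit <- as.character(unlist(lit, use.names = FALSE))
      if (length(lit) != 3L) {
        stop("each literal must be a (marker, location, status) triple")
      }
      marker <- normalize_marker_label(lit[[1L]], kb)$label
      data.frame(marker = marker,
                 location = assert_location(lit[[2L]]),
                 status = assert_status(lit[[3L]]),
                 stringsAsFactors = FALSE)
    })
    canonical_clause(do.call(rbind, lits))
  })
  keys <- vapply(out, clause_key, character(1))
  out <- out[!duplicated(keys)]
  out <- out[order(vapply(out, clause_key, character(1)))]
  new_phenotype(out)
}

# Re-canonicalise a phenotype without touching marker resolution
# (used internally after concatenating clause lists).
canonical_phenotype <- function(p) {
  clauses <- lapply(p$clauses, canonical_clause)
  keys <- vapply(clauses, clause_key, character(1))
  clauses <- clauses[!duplicated(keys)]
  clauses <- clauses[order(vapply(clauses, clause_key, character(1)))]
  new_phenotype(clauses)
}

#' Is a phenotype trivially true (the empty conjunction)?
#' @param p a `leuko_phenotype`.
#' @export
is_trivially_true <- function(p) {
  stopifnot(inherits(p, "leuko_phenotype"))
  length(p$clauses) == 0L
}

# Marker-location universe of a phenotype, as "marker|location" keys.
phenotype_universe <- function(p) {
  if (is_trivially_true(p)) return(character(0))
  sort(unique(unlist(lapply(p$clauses, function(cl) {
    paste(cl$marker, cl$location, sep = "|")
  }))))
}

format_literal <- function(marker, location, status) {
  suffix <- c(absent = "-", present = "+", high = "++", low = "+(dim)")[status]
  loc <- if (location == "cytoplasmic") "cy" else ""
  paste0(loc, marker, suffix)
}

#' @export
format.leuko_phenotype <- function(x, ...) {
  if (is_trivially_true(x)) return("TRUE (empty conjunction)")
  paste(vapply(x$clauses, function(cl) {
    lits <- mapply(format_literal, cl$marker, cl$location, cl$status)
    if (length(lits) > 1L) paste0("{", paste(lits, collapse = " | "), "}")
    else paste0("{", lits, "}")
  }, character(1)), collapse = " & ")
}

#' @export
print.leuko_phenotype <- function(x, ...) {
  cat("<phenotype> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Expand a class definition along its genus chain
#'
#' Returns the conjunction of the class's own differentia with the
#' differentia of every ancestor along its genus chain, canonicalised.
#' Child classes thereby inherit all necessary marker conditions of their
#' parents; the domain root expands to the trivially true phenotype.
#'
#' @param class_id identifier of a class in `kb`.
#' @param kb a knowledge base.
#' @return a `leuko_phenotype`.
#' @export
expand_definition <- function(class_id, kb) {
  stopifnot(inherits(kb, "leuko_kb"))
  if (is.null(kb$classes[[class_id]])) {
    stop("unknown class: ", class_id)
  }
  clauses <- list()
  seen <- character(0)
  cur <- class_id
  while (!is.null(cur)) {
    if (cur %in% seen) {
      stop("cycle in genus chain at class: ", cur)
    }
    seen <- c(seen, cur)
    def <- kb$classes[[cur]]
    if (is.null(def)) stop("dangling genus reference: ", cur)
    clauses <- c(clauses, def$differentia$clauses)
    cur <- def$genus
  }
  canonical_phenotype(new_phenotype(clauses))
}
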