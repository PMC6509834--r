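# Sound-and-complete reasoning over marker phenotypes.
#
# Semantics: a marker world totally assigns each (marker, location) pair
# one concrete status in {absent, present(-unspecified), high, low}.  A
# literal with status `present` is satisfied by any of present/high/low
# (relative amounts refine presence); absent/high/low are satisfied only
# by themselves.  Entailment and satisfiability are decided by a small
# constraint solver (unit propagation + branching over concrete statuses),
# which is exhaustive over worlds and therefore complete; the test suite
# checks it against brute-force world enumeration.

#' Construct a marker world
#'
#' @param assignment named character vector: names are
#'   `"marker|location"` keys, values concrete statuses
#'   (`"present"` meaning present-unspecified).
#' @return a `leuko_world`.
#' @export
marker_world <- function(assignment) {
  stopifnot(is.character(assignment), !is.null(names(assignment)))
  bad <- setdiff(assignment, STATUSES)
  if (length(bad)) stop("unknown status in world: ", bad[1])
  structure(assignment, class = "leuko_world")
}

#' Does one literal imply another?
#'
#' True iff both literals concern the same marker and location, and the
#' statuses coincide or the first is a refinement (`high`/`low`) of
#' `present`.
#'
#' @param a,b literals: lists or character vectors with `marker`,
#'   `location`, `status` in that order (named or positional).
#' @export
literal_implies <- function(a, b) {
  a <- as.character(unlist(a, use.names = FALSE))
  b <- as.character(unlist(b, use.names = FALSE))
  stopifnot(length(a) == 3L, length(b) == 3L)
  a[1] == b[1] && a[2] == b[2] &&
    (a[3] == b[3] || (a[3] %in% c("high", "low") && b[3] == "present"))
}

# internal: clause data.frame -> list(vars = "marker|location", allowed)
clause_constraints <- function(cl) {
  list(vars = paste(cl$marker, cl$location, sep = "|"),
       allowed = lapply(cl$status, status_allowed))
}

#' Does a marker world satisfy a phenotype?
#'
#' Every clause must have at least one satisfied literal.  The world's
#' universe must cover the phenotype's marker-locations.
#'
#' @param world a [marker_world].
#' @param p a `leuko_phenotype`.
#' @export
satisfies <- function(world, p) {
  stopifnot(inherits(p, "leuko_phenotype"))
  uni <- phenotype_universe(p)
  missing <- setdiff(uni, names(world))
  if (length(missing)) {
    stop("world universe does not cover phenotype marker-locations: ",
         paste(missing, collapse = ", "))
  }
  for (cl in p$clauses) {
    cc <- clause_constraints(cl)
    hit <- FALSE
    for (k in seq_along(cc$vars)) {
      if (world[[cc$vars[k]]] %in% cc$allowed[[k]]) { hit <- TRUE; break }
    }
    if (!hit) return(FALSE)
  }
  TRUE
}

# -- CSP solver ----------------------------------------------------------

# Satisfiability of a set of disjunctive constraints under per-variable
# domain restrictions.  clauses: list of clause_constraints(); domains:
# named list var -> character vector of still-possible statuses.
csp_solve <- function(clauses, domains) {
  repeat {
    changed <- FALSE
    keep <- rep(TRUE, length(clauses))
    for (i in seq_along(clauses)) {
      cc <- clauses[[i]]
      live <- integer(0)
      satisfied <- FALSE
      for (k in seq_along(cc$vars)) {
        dom <- domains[[cc$vars[k]]]
        inter <- intersect(dom, cc$allowed[[k]])
        if (length(inter) == 0L) next
        if (length(inter) == length(dom)) { satisfied <- TRUE; break }
        live <- c(live, k)
      }
      if (satisfied) { keep[i] <- FALSE; next }
      if (length(live) == 0L) return(FALSE)
      if (length(live) == 1L) {
        k <- live
        v <- cc$vars[k]
        domains[[v]] <- intersect(domains[[v]], cc$allowed[[k]])
        keep[i] <- FALSE
        changed <- TRUE
      } else if (length(live) < length(cc$vars)) {
        # drop dead literals so branching always picks a live variable
        clauses[[i]] <- list(vars = cc$vars[live],
                             allowed = cc$allowed[live])
        changed <- TRUE
      }
    }
    clauses <- clauses[keep]
    if (!changed) break
  }
  if (length(clauses) == 0L) return(TRUE)
  # branch on the first variable of the shortest clause
  sizes <- vapply(clauses, function(cc) length(cc$vars), integer(1))
  v <- clauses[[which.min(sizes)]]$vars[1L]
  for (s in domains[[v]]) {
    d2 <- domains
    d2[[v]] <- s
    if (csp_solve(clauses, d2)) return(TRUE)
  }
  FALSE
}

full_domains <- function(vars) {
  stats::setNames(rep(list(STATUSES), length(vars)), vars)
}

#' Is a phenotype satisfiable?
#'
#' True iff some marker world satisfies every clause.
#'
#' @param p a `leuko_phenotype`.
#' @export
is_satisfiable <- function(p) {
  stopifnot(inherits(p, "leuko_phenotype"))
  if (is_trivially_true(p)) return(TRUE)
  csp_solve(lapply(p$clauses, clause_constraints),
            full_domains(phenotype_universe(p)))
}

#' Does one phenotype entail another?
#'
#' True iff every marker world over the union universe satisfying `p`
#' also satisfies `q`.  Decided clause by clause: `p` entails a clause
#' `c` iff `p` conjoined with the negation of `c` is unsatisfiable.
#'
#' @param p,q `leuko_phenotype` objects.
#' @export
entails <- function(p, q) {
  stopifnot(inherits(p, "leuko_phenotype"), inherits(q, "leuko_phenotype"))
  if (is_trivially_true(q)) return(TRUE)
  p_clauses <- lapply(p$clauses, clause_constraints)
  vars <- union(phenotype_universe(p), phenotype_universe(q))
  for (cl in q$clauses) {
    cc <- clause_constraints(cl)
    domains <- full_domains(vars)
    empty <- FALSE
    for (k in seq_along(cc$vars)) {
      v <- cc$vars[k]
      domains[[v]] <- setdiff(domains[[v]], cc$allowed[[k]])
      if (length(domains[[v]]) == 0L) { empty <- TRUE; break }
    }
    if (empty) next                      # clause is tautological
    if (csp_solve(p_clauses, domains)) return(FALSE)  # countermodel found
  }
  TRUE
}

# -- class-level reasoning ----------------------------------------------

kb_expansions <- function(kb) {
  ids <- names(kb$classes)
  stats::setNames(lapply(ids, expand_definition, kb = kb), ids)
}

# asserted ancestor ids of a class (genus chain, excluding itself)
genus_chain <- function(class_id, kb) {
  out <- character(0)
  cur <- kb$classes[[class_id]]$genus
  while (!is.null(cur)) {
    if (cur %in% out) stop("cycle in genus chain at class: ", cur)
    out <- c(out, cur)
    cur <- kb$classes[[cur]]$genus
  }
  out
}

#' Does one class subsume another?
#'
#' `parent_id` subsumes `child_id` iff they coincide, `parent_id` lies on
#' the child's asserted genus chain, or (for defining parents) the
#' child's expanded definition entails the parent's.  Non-defining
#' classes carry only necessary conditions, so they subsume only via the
#' asserted hierarchy.
#'
#' @param parent_id,child_id class identifiers in `kb`.
#' @param kb a `leuko_kb`.
#' @export
subsumes <- function(parent_id, child_id, kb) {
  stopifnot(inherits(kb, "leuko_kb"))
  for (id in c(parent_id, child_id)) {
    if (is.null(kb$classes[[id]])) stop("unknown class: ", id)
  }
  if (parent_id == child_id) return(TRUE)
  if (parent_id %in% genus_chain(child_id, kb)) return(TRUE)
  if (!kb$classes[[parent_id]]$defining) return(FALSE)
  entails(expand_definition(child_id, kb),
          expand_definition(parent_id, kb))
}

subsumption_matrix <- function(kb, expansions = kb_expansions(kb)) {
  ids <- names(kb$classes)
  n <- length(ids)
  defining <- vapply(kb$classes, `[[`, logical(1), "defining")
  sub <- matrix(FALSE, n, n, dimnames = list(child = ids, parent = ids))
  chains <- lapply(ids, genus_chain, kb = kb)
  names(chains) <- ids
  for (i in ids) {
    sub[i, i] <- TRUE
    for (j in ids) {
      if (i == j) next
      if (j %in% chains[[i]]) {
        sub[i, j] <- TRUE
      } else if (defining[[j]]) {
        sub[i, j] <- entails(expansions[[i]], expansions[[j]])
      }
    }
  }
  sub
}

# transitive reduction of a reflexive-transitive boolean relation whose
# equivalence groups have been collapsed to representatives
reduce_dag <- function(sub, reps) {
  edges <- NULL
  for (i in reps) {
    for (j in reps) {
      if (i == j || !sub[i, j]) next
      between <- any(vapply(setdiff(reps, c(i, j)), function(k) {
        sub[i, k] && sub[k, j]
      }, logical(1)))
      if (!between) edges <- rbind(edges, c(i, j))
    }
  }
  edges
}

#' Compute the inferred class hierarchy of a knowledge base
#'
#' Derives all pairwise subsumptions among classes, merges mutual
#' subsumptions into equivalence groups, and returns the transitive
#' reduction as direct child-parent edges.  Each edge is flagged
#' `derivable` when it follows logically from the expanded definitions
#' (parent defining and entailed); edges to non-defining parents are
#' retained from the asserted genus graph and flagged asserted-only
#' (`derivable = FALSE`).
#'
#' @param kb a `leuko_kb`.
#' @return a `leuko_hierarchy`: list with `direct_edges` (data frame
#'   `child`, `parent`, `derivable`), `equivalence_groups` (list of
#'   character vectors, groups of size >= 2 only), and the full boolean
#'   `subsumption` matrix (children in rows, parents in columns).
#' @export
classify_hierarchy <- function(kb) {
  stopifnot(inherits(kb, "leuko_kb"))
  ids <- names(kb$classes)
  expansions <- kb_expansions(kb)
  sub <- subsumption_matrix(kb, expansions)
  defining <- vapply(kb$classes, `[[`, logical(1), "defining")

  # equivalence groups: mutual subsumption
  rep_of <- stats::setNames(ids, ids)
  groups <- list()
  assigned <- character(0)
  for (i in ids) {
    if (i %in% assigned) next
    grp <- ids[sub[i, ] & sub[, i]]
    if (length(grp) > 1L) {
      groups[[length(groups) + 1L]] <- sort(grp)
      rep_of[grp] <- sort(grp)[1L]
      assigned <- c(assigned, grp)
    }
  }
  reps <- unique(unname(rep_of))

  edges <- reduce_dag(sub, reps)
  if (is.null(edges)) {
    direct <- data.frame(child = character(0), parent = character(0),
                         derivable = logical(0), stringsAsFactors = FALSE)
  } else {
    derivable <- vapply(seq_len(nrow(edges)), function(k) {
      child <- edges[k, 1]; parent <- edges[k, 2]
      defining[[parent]] && entails(expansions[[child]],
                                    expansions[[parent]])
    }, logical(1))
    direct <- data.frame(child = edges[, 1], parent = edges[, 2],
                         derivable = derivable, stringsAsFactors = FALSE)
    direct <- direct[order(direct$child, direct$parent), , drop = FALSE]
    rownames(direct) <- NULL
  }
  structure(list(direct_edges = direct,
                 equivalence_groups = groups,
                 subsumption = sub),
            class = "leuko_hierarchy")
}

#' @export
print.leuko_hierarchy <- function(x, ...) {
  cat(sprintf("<class hierarchy: %d direct edges, %d equivalence group(s)>\n",
              nrow(x$direct_edges), length(x$equivalence_groups)))
  invisible(x)
}

# -- instance classification --------------------------------------------

sample_known_statuses <- function(sample, kb, on_unknown_marker) {
  m <- sample$measurements
  keys <- character(0)
  vals <- character(0)
  for (i in seq_len(nrow(m))) {
    res <- tryCatch(normalize_marker_label(m$marker[i], kb),
                    error = function(e) e)
    if (inherits(res, "error")) {
      if (on_unknown_marker == "fail") stop(conditionMessage(res))
      warning(sprintf("sample %s: skipping unknown marker '%s'",
                      sample$sample_id, m$marker[i]))
      next
    }
    keys <- c(keys, paste(res$label, m$location[i], sep = "|"))
    vals <- c(vals, m$status[i])
  }
  stats::setNames(vals, keys)
}

# clause evaluation against a partial assignment:
#  "satisfied"  -- some literal holds under a measured status
#  "falsified"  -- every literal is contradicted (closed world: an
#                  unmeasured marker counts as absent)
#  "indeterminate" otherwise
eval_clause <- function(cc, known, closed) {
  sat <- FALSE
  fal <- TRUE
  for (k in seq_along(cc$vars)) {
    v <- cc$vars[k]
    if (v %in% names(known)) {
      if (known[[v]] %in% cc$allowed[[k]]) { sat <- TRUE; fal <- FALSE }
    } else if (closed) {
      if ("absent" %in% cc$allowed[[k]]) fal <- FALSE
    } else {
      fal <- FALSE
    }
  }
  if (sat) "satisfied" else if (fal) "falsified" else "indeterminate"
}

#' Classify a patient sample against the knowledge base
#'
#' A class is *definite* when every clause of its expanded definition has
#' a literal satisfied by a measured status and the class carries a full
#' (necessary-and-sufficient) definition; definite membership is then
#' closed upward under subsumption, so asserted non-defining ancestors are
#' included.  A class is *compatible* when no clause of its expansion is
#' contradicted: under the open-world policy only measured statuses can
#' contradict, under the closed-world policy unmeasured markers count as
#' absent and can rule classes out.  Unsatisfiable classes are excluded
#' so they never absorb instances vacuously.
#'
#' @param sample a `leuko_sample` (see [read_samples]).
#' @param kb a `leuko_kb`.
#' @param policy `"open"` (default) or `"closed"`.
#' @param hierarchy optional precomputed [classify_hierarchy] result for
#'   `kb`; computed on the fly when `NULL`.
#' @param on_unknown_marker `"skip"` (warn and drop the measurement,
#'   default) or `"fail"`.
#' @param precedence if `TRUE`, apply the maturation-stage precedence
#'   policy: among most-specific classes of the same EGIL stage series,
#'   keep only the latest stage.  Off by default.
#' @return a `leuko_classification`: list with `sample_id`, `definite`,
#'   `compatible`, `most_specific_definite` (sorted class ids) and
#'   `policy`.
#' @export
classify_instance <- function(sample, kb, policy = c("open", "closed"),
                              hierarchy = NULL,
                              on_unknown_marker = c("skip", "fail"),
                              precedence = FALSE) {
  stopifnot(inherits(sample, "leuko_sample"), inherits(kb, "leuko_kb"))
  policy <- match.arg(policy)
  on_unknown_marker <- match.arg(on_unknown_marker)
  if (is.null(hierarchy)) hierarchy <- classify_hierarchy(kb)
  sub <- hierarchy$subsumption
  closed <- policy == "closed"

  known <- sample_known_statuses(sample, kb, on_unknown_marker)
  expansions <- kb_expansions(kb)
  ids <- names(kb$classes)
  defining <- vapply(kb$classes, `[[`, logical(1), "defining")
  satisfiable <- vapply(expansions, is_satisfiable, logical(1))

  definite_base <- character(0)
  compatible <- character(0)
  for (id in ids) {
    if (!satisfiable[[id]]) next
    states <- vapply(expansions[[id]]$clauses, function(cl) {
      eval_clause(clause_constraints(cl), known, closed)
    }, character(1))
    if (!any(states == "falsified")) compatible <- c(compatible, id)
    if (defining[[id]] && (length(states) == 0L || all(states == "satisfied"))) {
      definite_base <- c(definite_base, id)
    }
  }

  # upward closure under subsumption
  definite <- character(0)
  for (c_id in definite_base) {
    definite <- union(definite, ids[sub[c_id, ]])
  }
  definite <- sort(intersect(definite, ids[satisfiable]))
  compatible <- sort(union(compatible, definite))

  strictly_below <- function(a, b) sub[a, b] && !sub[b, a]
  most_specific <- definite[vapply(definite, function(d) {
    !any(vapply(setdiff(definite, d), strictly_below, logical(1), b = d))
  }, logical(1))]

  if (precedence && length(most_specific) > 1L) {
    grp <- vapply(most_specific, function(id) {
      kb$classes[[id]]$stage_group %||% NA_character_
    }, character(1))
    rank <- vapply(most_specific, function(id) {
      kb$classes[[id]]$stage_rank %||% NA_integer_
    }, integer(1))
    keep <- rep(TRUE, length(most_specific))
    for (g in unique(grp[!is.na(grp)])) {
      in_g <- which(grp == g & !is.na(rank))
      if (length(in_g) > 1L) keep[in_g[rank[in_g] < max(rank[in_g])]] <- FALSE
    }
    most_specific <- most_specific[keep]
  }

  structure(list(sample_id = sample$sample_id,
                 definite = definite,
                 compatible = compatible,
                 most_specific_definite = sort(most_specific),
                 policy = policy),
            class = "leuko_classification")
}

#' @export
print.leuko_classification <- function(x, ...) {
  cat(sprintf("<classification of %s [%s-world]>\n", x$sample_id, x$policy))
  cat("  most specific:", paste(x$most_specific_definite, collapse = ", "),
      "\n")
  cat("  definite:     ", paste(x$definite, collapse = ", "), "\n")
  cat("  compatible:   ", length(x$compatible), "classes\n")
  invisible(x)
}
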