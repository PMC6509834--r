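# Brute-force oracles: exhaustive enumeration of marker worlds.
# Deliberately independent of the package's constraint solver.

ALL_STATUSES <- c("absent", "present", "high", "low")

oracle_allowed <- function(status) {
  switch(status,
    present = c("present", "high", "low"),
    absent  = "absent",
    high    = "high",
    low     = "low")
}

# matrix of all |STATUSES|^k worlds over the given variables (columns)
oracle_worlds <- function(vars) {
  if (length(vars) == 0L) {
    return(matrix(character(0), nrow = 1L, ncol = 0L))
  }
  g <- expand.grid(rep(list(ALL_STATUSES), length(vars)),
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  m <- as.matrix(g)
  colnames(m) <- vars
  m
}

# logical vector: which rows of `worlds` satisfy phenotype p
oracle_sat_rows <- function(worlds, p) {
  sat <- rep(TRUE, nrow(worlds))
  for (cl in p$clauses) {
    clause_sat <- rep(FALSE, nrow(worlds))
    for (k in seq_len(nrow(cl))) {
      v <- paste(cl$marker[k], cl$location[k], sep = "|")
      clause_sat <- clause_sat |
        (worlds[, v] %in% oracle_allowed(cl$status[k]))
    }
    sat <- sat & clause_sat
  }
  sat
}

oracle_universe <- function(...) {
  sort(unique(unlist(lapply(list(...), function(p) {
    unlist(lapply(p$clauses, function(cl) {
      paste(cl$marker, cl$location, sep = "|")
    }))
  }))))
}

oracle_satisfiable <- function(p) {
  any(oracle_sat_rows(oracle_worlds(oracle_universe(p)), p))
}

oracle_entails <- function(p, q) {
  worlds <- oracle_worlds(oracle_universe(p, q))
  all(!oracle_sat_rows(worlds, p) | oracle_sat_rows(worlds, q))
}

# -- random generators ---------------------------------------------------

# KB holding only a generic marker dictionary, for building phenotypes
toy_marker_kb <- function(n_markers = 4L) {
  markers <- lapply(seq_len(n_markers), function(i) {
    list(id = sprintf("X%02d", i), label = sprintf("X%d", i),
         synonyms = character(0), external_ref = NULL)
  })
  leukotype:::new_kb(list(), markers, list(name = "toy", version = "0"))
}

# random phenotype over at most `max_vars` marker-locations
random_phenotype <- function(kb, max_vars = 3L, max_clauses = 3L,
                             max_literals = 3L) {
  labels <- vapply(kb$markers, `[[`, character(1), "label")
  labels <- labels[seq_len(min(max_vars, length(labels)))]
  n_clauses <- sample(0:max_clauses, 1L)
  if (n_clauses == 0L) {
    return(make_phenotype(list(), kb))
  }
  clauses <- lapply(seq_len(n_clauses), function(i) {
    n_lit <- sample.int(max_literals, 1L)
    lapply(seq_len(n_lit), function(j) {
      c(sample(labels, 1L),
        sample(c("surface", "cytoplasmic"), 1L),
        sample(ALL_STATUSES, 1L))
    })
  })
  make_phenotype(clauses, kb)
}

# random small KB: a root plus defining classes chained at random
random_kb <- function(n_classes = 6L, n_markers = 4L) {
  marker_kb <- toy_marker_kb(n_markers)
  markers <- unname(marker_kb$markers)
  classes <- list(leukotype:::new_classdef(
    "root", "root cell", NULL, FALSE, leukotype:::new_phenotype(list()),
    lineage_text = "A root cell."))
  for (i in seq_len(n_classes)) {
    repeat {
      p <- random_phenotype(marker_kb, max_vars = n_markers,
                            max_clauses = 2L, max_literals = 2L)
      if (!is_trivially_true(p)) break
    }
    genus <- sample(vapply(classes, `[[`, character(1), "id"), 1L)
    classes[[length(classes) + 1L]] <- leukotype:::new_classdef(
      sprintf("C%02d", i), sprintf("class %d", i), genus, TRUE, p)
  }
  leukotype:::new_kb(classes, markers, list(name = "random", version = "0"))
}

# oracle subsumption matrix over a KB: same interface contract as the
# reasoner (asserted chain for non-defining parents, entailment for
# defining parents) but entailment decided by world enumeration
oracle_subsumption_matrix <- function(kb) {
  ids <- names(kb$classes)
  exps <- lapply(ids, expand_definition, kb = kb)
  names(exps) <- ids
  defining <- vapply(kb$classes, `[[`, logical(1), "defining")
  chain <- function(id) {
    out <- character(0)
    cur <- kb$classes[[id]]$genus
    while (!is.null(cur)) { out <- c(out, cur); cur <- kb$classes[[cur]]$genus }
    out
  }
  sub <- matrix(FALSE, length(ids), length(ids),
                dimnames = list(child = ids, parent = ids))
  for (i in ids) {
    for (j in ids) {
      sub[i, j] <- i == j || j %in% chain(i) ||
        (defining[[j]] && oracle_entails(exps[[i]], exps[[j]]))
    }
  }
  sub
}

# independent transitive reduction: edge i->j direct iff i strictly below
# j with no representative strictly between
oracle_direct_edges <- function(sub) {
  ids <- rownames(sub)
  rep_of <- vapply(ids, function(i) {
    grp <- ids[sub[i, ] & sub[, i]]
    sort(grp)[1L]
  }, character(1))
  reps <- unique(rep_of)
  edges <- data.frame(child = character(0), parent = character(0),
                      stringsAsFactors = FALSE)
  for (i in reps) {
    for (j in reps) {
      if (i == j || !sub[i, j]) next
      mid <- setdiff(reps, c(i, j))
      if (!any(sub[i, mid] & sub[mid, j])) {
        edges <- rbind(edges, data.frame(child = i, parent = j,
                                         stringsAsFactors = FALSE))
      }
    }
  }
  edges <- edges[order(edges$child, edges$parent), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}
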