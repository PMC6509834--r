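# Patient-data I/O, positivity thresholding and synthetic-sample
# generation.

#' Threshold a percent-positive value into an expression status
#'
#' The classical flow-cytometry rule: a population is called positive for
#' a marker when at least `cutoff` percent of cells bear it (boundary
#' inclusive).  A single percentage carries no population context, so
#' this never returns `high`/`low`.
#'
#' @param value numeric vector of percent-positive values in \[0, 100\].
#' @param cutoff positivity cutoff in percent (default 20).
#' @param inclusive if `TRUE` (default) a value exactly at the cutoff is
#'   positive.
#' @return character vector of `"present"`/`"absent"`.
#' @examples
#' threshold_percent(c(5, 20, 25))
#' @export
threshold_percent <- function(value, cutoff = 20, inclusive = TRUE) {
  if (!is.numeric(value) || any(is.na(value)) ||
      any(value < 0 | value > 100)) {
    stop("percent-positive values must be numeric in [0, 100]")
  }
  pos <- if (inclusive) value >= cutoff else value > cutoff
  ifelse(pos, "present", "absent")
}

new_sample <- function(sample_id, measurements) {
  key <- paste(measurements$marker, measurements$location, sep = "|")
  if (anyDuplicated(key)) {
    stop(sprintf("sample %s: duplicate measurement for %s",
                 sample_id, key[duplicated(key)][1]))
  }
  rownames(measurements) <- NULL
  structure(list(sample_id = sample_id, measurements = measurements),
            class = "leuko_sample")
}

#' Construct a patient sample from marker statuses
#'
#' Convenience constructor for programmatic use; file input goes through
#' [read_samples].
#'
#' @param sample_id specimen identifier.
#' @param statuses named character vector; names are markers (optionally
#'   `"cy"`-prefixed meaning cytoplasmic, e.g. `"cyCD3"`), values are
#'   statuses from [STATUSES].
#' @return a `leuko_sample`.
#' @examples
#' patient_sample("S1", c(CD19 = "present", CD10 = "present"))
#' @export
patient_sample <- function(sample_id, statuses) {
  stopifnot(is.character(statuses), !is.null(names(statuses)))
  marker <- names(statuses)
  cyto <- grepl("^cy", marker) & !grepl("^cyt", marker)
  marker[cyto] <- sub("^cy", "", marker[cyto])
  m <- data.frame(marker = marker,
                  location = ifelse(cyto, "cytoplasmic", "surface"),
                  status = vapply(unname(statuses), assert_status,
                                  character(1)),
                  percent = NA_real_,
                  stringsAsFactors = FALSE)
  new_sample(sample_id, m)
}

#' @export
print.leuko_sample <- function(x, ...) {
  lits <- mapply(format_literal, x$measurements$marker,
                 x$measurements$location, x$measurements$status)
  cat(sprintf("<sample %s: %s>\n", x$sample_id,
              paste(lits, collapse = ", ")))
  invisible(x)
}

#' Read patient samples from a CSV file
#'
#' Expected header: `sample_id`, `marker`, `location`, and `status`
#' and/or `percent_positive`; each data row must fill exactly one of the
#' latter two.  Percent rows are thresholded with [threshold_percent].
#' Samples are grouped by `sample_id`, preserving file order.
#'
#' @param path CSV file path.
#' @param cutoff positivity cutoff passed to [threshold_percent].
#' @return list of `leuko_sample` objects.
#' @export
read_samples <- function(path, cutoff = 20) {
  if (!file.exists(path)) stop("sample file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = TRUE)
  need <- c("sample_id", "marker", "location")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("sample CSV missing column(s): ", paste(missing, collapse = ", "))
  }
  has_status <- "status" %in% names(df)
  has_pct <- "percent_positive" %in% names(df)
  if (!has_status && !has_pct) {
    stop("sample CSV needs a 'status' or 'percent_positive' column")
  }
  n <- nrow(df)
  status <- character(n)
  pct <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    line <- i + 1L  # header is line 1
    st <- if (has_status) trimws(df$status[i]) else ""
    pp <- if (has_pct) trimws(df$percent_positive[i]) else ""
    if (nzchar(st) && nzchar(pp)) {
      stop(sprintf("line %d: both status and percent_positive set", line))
    }
    if (!nzchar(st) && !nzchar(pp)) {
      stop(sprintf("line %d: neither status nor percent_positive set", line))
    }
    if (!df$location[i] %in% LOCATIONS) {
      stop(sprintf("line %d: unknown location '%s'", line, df$location[i]))
    }
    if (nzchar(st)) {
      if (!st %in% STATUSES) {
        stop(sprintf("line %d: unknown status '%s'", line, st))
      }
      status[i] <- st
    } else {
      v <- suppressWarnings(as.numeric(pp))
      if (is.na(v) || v < 0 || v > 100) {
        stop(sprintf("line %d: percent_positive '%s' not in [0, 100]",
                     line, pp))
      }
      pct[i] <- v
      status[i] <- threshold_percent(v, cutoff)
    }
  }
  out <- list()
  for (sid in unique(df$sample_id)) {
    rows <- which(df$sample_id == sid)
    m <- data.frame(marker = df$marker[rows],
                    location = df$location[rows],
                    status = status[rows],
                    percent = pct[rows],
                    stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- new_sample(sid, m)
  }
  out
}

#' Write patient samples to CSV
#'
#' Inverse of [read_samples]: rows carry `percent_positive` where a
#' percent value is recorded, otherwise the categorical `status`.
#'
#' @param samples list of `leuko_sample` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  rows <- do.call(rbind, lapply(samples, function(s) {
    m <- s$measurements
    data.frame(sample_id = s$sample_id, marker = m$marker,
               location = m$location,
               status = ifelse(is.na(m$percent), m$status, ""),
               percent_positive = ifelse(is.na(m$percent), "",
                                         format(m$percent, digits = 6,
                                                trim = TRUE)),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Specify a simulation of patient samples
#'
#' @param target_class class id whose expanded definition the samples
#'   must satisfy.
#' @param n_samples number of samples.
#' @param seed RNG seed; the output is fully determined by it.
#' @param noise_rate probability in \[0, 1\] that a measured status is
#'   flipped (positivity toggled) after generation.
#' @param panel optional character vector of `"marker|location"` keys to
#'   report; defaults to the closed panel, i.e. exactly the
#'   marker-locations of the target's expanded definition.  Must cover
#'   the target's markers.
#' @param emit_percent if `TRUE`, emit percent-positive values straddling
#'   the cutoff instead of categorical statuses.
#' @param cutoff positivity cutoff used when `emit_percent` is `TRUE`.
#' @return a `leuko_simspec`.
#' @export
simulation_spec <- function(target_class, n_samples, seed,
                            noise_rate = 0, panel = NULL,
                            emit_percent = FALSE, cutoff = 20) {
  stopifnot(is.numeric(n_samples), n_samples >= 1,
            is.numeric(seed), length(seed) == 1L)
  if (!is.numeric(noise_rate) || noise_rate < 0 || noise_rate > 1) {
    stop("noise_rate must be in [0, 1]")
  }
  structure(list(target_class = target_class,
                 n_samples = as.integer(n_samples),
                 seed = as.integer(seed),
                 noise_rate = noise_rate,
                 panel = panel,
                 emit_percent = isTRUE(emit_percent),
                 cutoff = cutoff),
            class = "leuko_simspec")
}

flip_status <- function(status) {
  ifelse(status == "absent", "present", "absent")
}

#' Simulate patient samples consistent with a class definition
#'
#' For each sample, one literal per clause of the target's expanded
#' definition is picked uniformly at random and asserted; the remaining
#' panel marker-locations are drawn absent/present with equal
#' probability (which cannot falsify any clause, since each clause
#' already holds).  Measured statuses are then flipped independently
#' with probability `noise_rate`.  With `emit_percent`, positive calls
#' draw a percent uniformly from \[cutoff, 100\] and negative calls from
#' \[0, cutoff).  Output is fully determined by the spec's seed.
#'
#' @param spec a [simulation_spec].
#' @param kb a `leuko_kb`.
#' @return list of `leuko_sample` objects.
#' @export
simulate_samples <- function(spec, kb) {
  stopifnot(inherits(spec, "leuko_simspec"), inherits(kb, "leuko_kb"))
  if (is.null(kb$classes[[spec$target_class]])) {
    stop("unknown target class: ", spec$target_class)
  }
  expansion <- expand_definition(spec$target_class, kb)
  if (!is_satisfiable(expansion)) {
    stop("unsatisfiable target class: ", spec$target_class)
  }
  required <- phenotype_universe(expansion)
  panel <- if (is.null(spec$panel)) required else sort(unique(spec$panel))
  missing <- setdiff(required, panel)
  if (length(missing)) {
    stop("panel missing required marker-location(s): ",
         paste(missing, collapse = ", "))
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(spec$seed)

  constraints <- lapply(expansion$clauses, clause_constraints)
  samples <- vector("list", spec$n_samples)
  for (i in seq_len(spec$n_samples)) {
    # choose one literal per clause; retry on conflicting choices
    assignment <- NULL
    for (try in seq_len(50L)) {
      chosen <- list()
      ok <- TRUE
      for (cl in expansion$clauses) {
        k <- if (nrow(cl) == 1L) 1L else sample.int(nrow(cl), 1L)
        v <- paste(cl$marker[k], cl$location[k], sep = "|")
        st <- cl$status[k]
        prev <- chosen[[v]]
        if (is.null(prev)) {
          chosen[[v]] <- st
        } else if (prev == st) {
          # consistent repeat
        } else if (st %in% c("high", "low") && prev == "present") {
          chosen[[v]] <- st          # refine presence
        } else if (prev %in% c("high", "low") && st == "present") {
          # already refined
        } else {
          ok <- FALSE; break         # contradictory picks, redraw
        }
      }
      if (ok) { assignment <- chosen; break }
    }
    if (is.null(assignment)) {
      stop("could not draw a consistent literal choice for class ",
           spec$target_class)
    }
    free <- setdiff(panel, names(assignment))
    for (v in free) {
      assignment[[v]] <- sample(c("absent", "present"), 1L)
    }
    vars <- sort(names(assignment))
    status <- vapply(vars, function(v) assignment[[v]], character(1))
    if (spec$noise_rate > 0) {
      flip <- stats::runif(length(vars)) < spec$noise_rate
      status[flip] <- flip_status(status[flip])
    }
    pct <- rep(NA_real_, length(vars))
    if (spec$emit_percent) {
      pos <- status != "absent"
      pct[pos] <- stats::runif(sum(pos), spec$cutoff, 100)
      pct[!pos] <- stats::runif(sum(!pos), 0, spec$cutoff)
      status <- threshold_percent(pct, spec$cutoff)
    }
    parts <- strsplit(vars, "|", fixed = TRUE)
    m <- data.frame(marker = vapply(parts, `[[`, character(1), 1L),
                    location = vapply(parts, `[[`, character(1), 2L),
                    status = unname(status),
                    percent = pct,
                    stringsAsFactors = FALSE)
    samples[[i]] <- new_sample(sprintf("%s-%03d", spec$target_class, i), m)
  }
  samples
}
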