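# Order-time alert decisions for exam pairs and exam histories, per
# terminology backend. A backend resolves an exam code to SANOPS regions at
# a chosen utility-class threshold (`max_class`); the "unaltered state" of a
# terminology corresponds to max_class = 1 (only region-grade attributes and
# concepts usable without extra computing steps), while higher thresholds
# model lookup tables (2-3) and custom traversal algorithms (4).

#' Construct an exam record
#'
#' @param patient_id,site_id Opaque identifiers.
#' @param exam_code Exam-name terminology code (non-empty).
#' @param timestamp ISO-8601 datetime string or `POSIXct`.
#' @return An object of class `exam_record`.
#' @export
exam_record <- function(patient_id, site_id, exam_code, timestamp) {
  if (!nzchar(exam_code)) stop("`exam_code` must be non-empty", call. = FALSE)
  ts <- .parse_timestamp(timestamp)
  structure(list(patient_id = as.character(patient_id),
                 site_id = as.character(site_id),
                 exam_code = as.character(exam_code),
                 timestamp = ts),
            class = "exam_record")
}

.parse_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  ts <- tryCatch(
    as.POSIXct(x, tz = "UTC",
               tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                              "%Y-%m-%d")),
    error = function(e) NA)
  if (is.na(ts)) stop("unparseable timestamp: ", x, call. = FALSE)
  ts
}

#' Read an exam-history CSV
#'
#' Expected columns: `patient_id`, `site_id`, `exam_code`, `timestamp`.
#'
#' @param path CSV path.
#' @return List of [exam_record()] objects.
#' @export
read_exam_history <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("patient_id", "site_id", "exam_code", "timestamp")
  if (!all(need %in% names(df))) {
    stop("exam history needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    exam_record(df$patient_id[i], df$site_id[i], df$exam_code[i],
                df$timestamp[i])
  })
}

#' Construct a terminology backend
#'
#' Bundles one terminology graph with its exam mappings and SANOPS
#' correspondence table; the unit the alert engine operates on.
#'
#' @param graph A `terminology_graph`.
#' @param mappings List of [exam_mapping()] objects (named by exam code, or
#'   names are derived from the mappings).
#' @param correspondence A [correspondence_table()].
#' @return An object of class `terminology_backend`.
#' @export
terminology_backend <- function(graph, mappings, correspondence) {
  stopifnot(inherits(graph, "terminology_graph"),
            inherits(correspondence, "correspondence_table"))
  if (is.null(names(mappings)) || any(!nzchar(names(mappings)))) {
    names(mappings) <- vapply(mappings, `[[`, character(1), "exam_code")
  }
  for (m in mappings) .check_mapping_concepts(graph, m)
  marked <- correspondence$concept_id[correspondence$terminology == graph$name]
  missing <- setdiff(marked, graph$concepts$id)
  if (length(missing)) {
    stop("correspondence marks concept(s) absent from graph: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(graph = graph, mappings = mappings,
                 correspondence = correspondence,
                 cache = new.env(parent = emptyenv())),
            class = "terminology_backend")
}

.backend_mapping <- function(backend, exam_code) {
  m <- backend$mappings[[exam_code]]
  if (is.null(m)) {
    stop("exam code not mapped in backend '", backend$graph$name, "': ",
         exam_code, call. = FALSE)
  }
  m
}

#' Per-region utility classes for one exam in a backend
#'
#' Marker-carrying attribute concepts contribute their regions at class 1;
#' each target region named by the exam additionally gets the path-structure
#' class (2-5) from the focus concept(s), when the region's concept is
#' resolvable in the correspondence table.
#'
#' @param backend A [terminology_backend()].
#' @param exam_code Mapped exam code.
#' @param max_length Walk-length bound.
#' @return `data.frame` with columns `region`, `class` (one row per region,
#'   minimum class per region; zero rows if nothing resolves).
#' @export
region_classes <- function(backend, exam_code, max_length = 15L) {
  mapping <- .backend_mapping(backend, exam_code)
  # per-backend memo: graphs are immutable once bundled
  key <- paste0(exam_code, "#", max_length)
  hit <- get0(key, envir = backend$cache, ifnotfound = NULL)
  if (!is.null(hit)) return(hit)
  graph <- backend$graph
  table <- backend$correspondence
  term <- graph$name

  rows <- list()
  attrs <- unique(c(mapping$region_attribute, mapping$focus_attribute))
  for (a in attrs) {
    mk <- .concept_marker(table, term, a)
    if (!is.na(mk)) {
      for (r in marker_regions(mk)) {
        rows[[length(rows) + 1L]] <- data.frame(region = r, class = 1L)
      }
    }
  }

  starts <- mapping$focus_attribute
  if (is.null(starts)) starts <- mapping$region_attribute
  for (r in mapping$target_regions) {
    R <- .region_concept(table, term, r)
    if (is.na(R)) next
    cls <- min(vapply(starts, function(s) {
      .path_class_one(graph, s, R, max_length)$value
    }, integer(1)))
    rows[[length(rows) + 1L]] <- data.frame(region = r, class = cls)
  }
  if (!length(rows)) {
    out <- data.frame(region = character(), class = integer(),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    out <- do.call(rbind, lapply(split(out, out$region), function(d) {
      data.frame(region = d$region[1L], class = min(d$class),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out <- out[order(out$region), , drop = FALSE]
  }
  assign(key, out, envir = backend$cache)
  out
}

#' Resolve an exam code to SANOPS regions at a utility-class threshold
#'
#' @param backend A [terminology_backend()].
#' @param exam_code Mapped exam code (unmapped codes are an error).
#' @param max_class Highest utility class the caller is willing to "pay
#'   for"; 1 is the terminology's unaltered state, 2-3 admit lookup-table
#'   remedies, 4 admits custom mixed-relation traversal.
#' @param max_length Walk-length bound.
#' @return Character vector of region codes (possibly empty).
#' @export
resolve_regions <- function(backend, exam_code, max_class = 1L,
                            max_length = 15L) {
  stopifnot(max_class >= 1L, max_class <= 5L)
  rc <- region_classes(backend, exam_code, max_length)
  # Class 5 means unreachable: never resolvable at any threshold.
  sort(unique(rc$region[rc$class <= min(max_class, 4L)]))
}

#' Decide the alert relation for a pair of exams
#'
#' `same` when the codes are equal; otherwise both exams are resolved to
#' SANOPS regions at `max_class` and the SANOPS rule [alert_relation()] is
#' applied. An empty resolved region set yields `none` -- an unusable
#' mapping is a missed alert, not an error.
#'
#' @param backend A [terminology_backend()].
#' @param current,prior [exam_record()] objects.
#' @param max_class Utility-class threshold (see [resolve_regions()]).
#' @param table SANOPS adjacency table.
#' @param max_length Walk-length bound.
#' @return An object of class `alert_decision` with fields `alert`,
#'   `current`, `prior`, `regions_current`, `regions_prior`,
#'   `max_class_used`, `terminology`.
#' @export
decide_alert <- function(backend, current, prior, max_class = 1L,
                         table = sanops_adjacency(), max_length = 15L) {
  stopifnot(inherits(current, "exam_record"), inherits(prior, "exam_record"))
  same <- identical(current$exam_code, prior$exam_code)
  rc <- resolve_regions(backend, current$exam_code, max_class, max_length)
  rp <- resolve_regions(backend, prior$exam_code, max_class, max_length)
  alert <- if (same) {
    "same"
  } else if (length(rc) == 0L || length(rp) == 0L) {
    "none"
  } else {
    alert_relation(rc, rp, same_code = FALSE, table = table)
  }
  structure(list(alert = alert, current = current, prior = prior,
                 regions_current = rc, regions_prior = rp,
                 max_class_used = as.integer(max_class),
                 terminology = backend$graph$name),
            class = "alert_decision")
}

#' @export
print.alert_decision <- function(x, ...) {
  cat(sprintf("[%s] %s: current %s {%s} vs prior %s {%s} (max_class=%d)\n",
              x$terminology, toupper(x$alert),
              x$current$exam_code, paste(x$regions_current, collapse = ","),
              x$prior$exam_code, paste(x$regions_prior, collapse = ","),
              x$max_class_used))
  invisible(x)
}

#' Rank alert decisions for a history of prior exams
#'
#' One decision per prior exam, ordered by alert precedence (same >
#' similar > proximate > none), ties broken by descending prior timestamp
#' (most recent first). An optional lookback window drops priors older than
#' `lookback_days` before the current exam; the default is unlimited.
#'
#' @param backend A [terminology_backend()].
#' @param current An [exam_record()].
#' @param priors List of [exam_record()] objects.
#' @param max_class Utility-class threshold.
#' @param table SANOPS adjacency table.
#' @param lookback_days Window in days (default `Inf`).
#' @return List of `alert_decision` objects, strongest and most recent first.
#' @export
alert_history <- function(backend, current, priors, max_class = 1L,
                          table = sanops_adjacency(), lookback_days = Inf) {
  if (!length(priors)) return(list())
  if (is.finite(lookback_days)) {
    cutoff <- current$timestamp - lookback_days * 86400
    priors <- Filter(function(p) p$timestamp >= cutoff, priors)
    if (!length(priors)) return(list())
  }
  decisions <- lapply(priors, function(p) {
    decide_alert(backend, current, p, max_class, table)
  })
  prec <- match(vapply(decisions, `[[`, character(1), "alert"), alert_classes())
  ts <- vapply(decisions, function(d) as.numeric(d$prior$timestamp), numeric(1))
  decisions[order(prec, -ts)]
}

#' Reproduce the hypothetical alert firing matrix
#'
#' Runs every scenario exam pair against every supplied backend and records
#' whether an appropriate alert (similar or proximate) fires. At the default
#' `max_class = 1` this is each terminology's unaltered state.
#'
#' @param backends Named list of [terminology_backend()] objects; defaults
#'   to the five standard fixture terminologies.
#' @param scenarios Scenario table, see [scenario_table()].
#' @param max_class Utility-class threshold.
#' @param table SANOPS adjacency table.
#' @return `data.frame`: one row per scenario, one column per backend with
#'   cells in `{"same","similar","proximate","-"}`, preceded by scenario
#'   metadata columns.
#' @export
run_scenarios <- function(backends = NULL, scenarios = scenario_table(),
                          max_class = 1L, table = sanops_adjacency()) {
  if (is.null(backends)) {
    nm <- c("loinc", "loinc_rsna", "radlex", "fma", "snomed")
    backends <- lapply(nm, function(n) build_fixture(n)$backend)
    names(backends) <- nm
  }
  out <- scenarios[, c("scenario", "prior_name", "current_name")]
  for (bn in names(backends)) {
    cells <- character(nrow(scenarios))
    for (i in seq_len(nrow(scenarios))) {
      cur <- exam_record("pt", "site-a", scenarios$current_code[i],
                         "2016-02-01T12:00:00")
      pri <- exam_record("pt", "site-b", scenarios$prior_code[i],
                         "2016-01-01T12:00:00")
      d <- decide_alert(backends[[bn]], cur, pri, max_class, table)
      cells[i] <- if (d$alert %in% c("similar", "proximate")) d$alert
                  else if (d$alert == "same") "same" else "-"
    }
    out[[bn]] <- cells
  }
  out
}
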