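# Ordinal 1-5 terminology-utility classification of one exam's anatomic
# mapping, measured against the SANOPS body regions. The class approximates
# how much machinery beyond a plain SANOPS lookup a terminology needs before
# it can support a similar/proximate alert for that exam:
#   1  region(-attribute) is already a SANOPS-grade region (or joint / whole
#      extremity), usable as-is;
#   2  focus sits under the region via one uniform relation chain and no
#      alternative rootward path -- a lookup table suffices;
#   3  uniform chain exists but the polyhierarchy also offers rootward paths
#      bypassing the region -- lookup plus verification needed;
#   4  region reachable only by mixing relation types (e.g. down has_part
#      then back up part_of) -- a custom traversal algorithm needed;
#   5  region unreachable: the terminology cannot support the alert unmodified.

#' Construct an exam anatomic mapping
#'
#' One exam code's anatomic assignment within one terminology. Attribute
#' fields hold concept ids of that terminology's graph: `region_attribute`
#' for body-region / region-imaged style attributes (present in RadLex and
#' Playbook style terminologies), `focus_attribute` for the anatomic focus
#' or organ-level concept. Either may name several concepts (bilateral
#' exams, multi-region exams). `target_regions` are the SANOPS region codes
#' named by the exam's long common name; they select the region concept(s)
#' the path criteria are evaluated against.
#'
#' @param exam_code Exam-name terminology code (LOINC-style string).
#' @param exam_name Long common name.
#' @param terminology Owning terminology name.
#' @param region_attribute,focus_attribute Character vectors of concept ids
#'   (either may be `NULL`, not both).
#' @param target_regions Character vector of SANOPS region codes (may be
#'   empty only if an attribute carries a marker).
#' @return An object of class `exam_mapping`.
#' @export
exam_mapping <- function(exam_code, exam_name, terminology,
                         region_attribute = NULL, focus_attribute = NULL,
                         target_regions = character()) {
  if (!nzchar(exam_code)) stop("`exam_code` must be non-empty", call. = FALSE)
  if (is.null(region_attribute) && is.null(focus_attribute)) {
    stop("mapping needs at least one of region_attribute / focus_attribute",
         call. = FALSE)
  }
  if (length(target_regions)) .check_region_codes(target_regions)
  structure(list(exam_code = exam_code, exam_name = exam_name,
                 terminology = terminology,
                 region_attribute = region_attribute,
                 focus_attribute = focus_attribute,
                 target_regions = target_regions),
            class = "exam_mapping")
}

#' Construct a correspondence table
#'
#' Links terminology concepts to SANOPS. A marker is one of: a plain SANOPS
#' region code (the concept *is* that body region), `JOINT:<code>` (the
#' concept is a major joint corresponding to that extremity region), or
#' `WHOLE_EXTREMITY:<limb>` with limb in LUE/RUE/LLE/RLE (the concept is an
#' entire extremity, corresponding to all three of its regions). Each
#' concept carries at most one marker.
#'
#' @param df `data.frame` with columns `terminology`, `concept_id`, `marker`.
#' @return An object of class `correspondence_table`.
#' @export
correspondence_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  stopifnot(all(c("terminology", "concept_id", "marker") %in% names(df)))
  df[] <- lapply(df[, c("terminology", "concept_id", "marker")], as.character)
  key <- paste(df$terminology, df$concept_id)
  if (anyDuplicated(key)) {
    stop("concept(s) with more than one marker: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  for (m in df$marker) marker_regions(m)  # validates
  structure(df, class = c("correspondence_table", "data.frame"))
}

#' SANOPS regions implied by a correspondence marker
#'
#' @param marker A marker string (see [correspondence_table()]).
#' @return Character vector of region codes (three for a whole-extremity
#'   marker, one otherwise).
#' @export
marker_regions <- function(marker) {
  if (grepl("^JOINT:", marker)) {
    code <- sub("^JOINT:", "", marker)
    .check_region_codes(code)
    return(code)
  }
  if (grepl("^WHOLE_EXTREMITY:", marker)) {
    return(limb_regions(sub("^WHOLE_EXTREMITY:", "", marker)))
  }
  .check_region_codes(marker)
  marker
}

# Marker for one concept, or NA_character_.
.concept_marker <- function(table, terminology, concept_id) {
  hit <- table$terminology == terminology & table$concept_id == concept_id
  if (any(hit)) table$marker[which(hit)[1L]] else NA_character_
}

# The region concept carrying the plain-region marker `code`, or NA.
.region_concept <- function(table, terminology, code) {
  hit <- table$terminology == terminology & table$marker == code
  if (any(hit)) table$concept_id[which(hit)[1L]] else NA_character_
}

.utility_rationales <- c(
  "1" = "region or attribute maps directly to a SANOPS region, joint, or whole extremity",
  "2" = "focus nested under the SANOPS region via a uniform relation without alternative paths",
  "3" = "uniform links to the SANOPS region plus polyhierarchy paths bypassing it",
  "4" = "SANOPS region reachable only through mixed relation types",
  "5" = "focus not nested under the SANOPS region")

.utility_class <- function(value, witness = NULL, regions = character(),
                           per_region = NULL) {
  structure(list(value = as.integer(value),
                 rationale = .utility_rationales[[as.character(value)]],
                 witness = witness, regions = regions,
                 per_region = per_region),
            class = "utility_class")
}

#' @export
print.utility_class <- function(x, ...) {
  cat(sprintf("utility class %d: %s\n", x$value, x$rationale))
  if (!is.null(x$witness)) cat("  witness:", format(x$witness), "\n")
  invisible(x)
}

.no_target_error <- function(mapping) {
  stop(errorCondition(
    paste0("no target region: no SANOPS-marked concept resolvable for exam ",
           mapping$exam_code, " (", mapping$terminology,
           ") and no marker on its attributes"),
    class = c("sanops_no_target_region", "sanopsError")))
}

.check_mapping_concepts <- function(graph, mapping) {
  for (cid in c(mapping$region_attribute, mapping$focus_attribute)) {
    .check_concept(graph, cid, "mapping concept")
  }
}

# Path-structure class (2..5) for one start concept against one region
# concept, using the package's traversal engine.
.path_class_one <- function(graph, start, region_concept, max_length) {
  paths <- find_paths(graph, start, region_concept, max_length)
  uniform <- Filter(function(p) p$uniform, paths)
  if (length(uniform)) {
    if (rootward_closure_avoiding(graph, start, region_concept)) {
      list(value = 3L, witness = uniform[[1L]])
    } else {
      list(value = 2L, witness = uniform[[1L]])
    }
  } else if (length(paths)) {
    list(value = 4L, witness = paths[[1L]])
  } else {
    list(value = 5L, witness = NULL)
  }
}

#' Classify a terminology's anatomic mapping for one exam
#'
#' Evaluates the five ordered criteria of the utility scale, first match
#' wins. Criterion 1 fires when any mapped attribute concept carries a
#' correspondence marker (region, joint, or whole extremity). Otherwise each
#' target region named by the exam is resolved to the concept carrying its
#' marker and scored by path structure from the focus concept(s); an exam
#' naming several regions is reported at the worst (highest) per-region
#' class, with per-region detail retained. Classes 2-4 return the
#' qualifying walk as a witness.
#'
#' @param graph The terminology graph.
#' @param mapping An [exam_mapping()].
#' @param table A [correspondence_table()].
#' @param max_length Walk-length bound passed to [find_paths()].
#' @return A `utility_class` object with fields `value` (1-5), `rationale`,
#'   `witness`, `regions` (regions usable at this class), `per_region`.
#' @export
classify <- function(graph, mapping, table, max_length = 15L) {
  stopifnot(inherits(mapping, "exam_mapping"),
            inherits(table, "correspondence_table"))
  .check_mapping_concepts(graph, mapping)
  term <- graph$name

  attrs <- unique(c(mapping$region_attribute, mapping$focus_attribute))
  markers <- vapply(attrs, function(a) .concept_marker(table, term, a),
                    character(1))
  if (any(!is.na(markers))) {
    regions <- unique(unlist(lapply(markers[!is.na(markers)], marker_regions)))
    return(.utility_class(1L, regions = regions))
  }

  targets <- mapping$target_regions
  region_concepts <- vapply(targets, function(r) .region_concept(table, term, r),
                            character(1))
  keep <- !is.na(region_concepts)
  if (!any(keep)) .no_target_error(mapping)

  starts <- mapping$focus_attribute
  if (is.null(starts)) starts <- mapping$region_attribute

  per <- lapply(which(keep), function(i) {
    best <- list(value = 5L, witness = NULL)
    for (s in starts) {
      res <- .path_class_one(graph, s, region_concepts[[i]], max_length)
      if (res$value < best$value) best <- res
    }
    list(region = targets[[i]], value = best$value, witness = best$witness)
  })
  per_df <- data.frame(region = vapply(per, `[[`, character(1), "region"),
                       class = vapply(per, `[[`, integer(1), "value"),
                       stringsAsFactors = FALSE)
  worst <- which.max(per_df$class)
  value <- per_df$class[worst]
  .utility_class(value,
                 witness = if (value %in% 2:4) per[[worst]]$witness,
                 regions = per_df$region[per_df$class == value & value < 5L],
                 per_region = per_df)
}

#' Brute-force reference classifier
#'
#' Independent implementation of the same five criteria by exhaustive
#' enumeration built on igraph's simple-path machinery (with parallel typed
#' edges expanded), with no pruning and no shared traversal code with
#' [classify()]. Intended as a test oracle; refuses graphs over 40 concepts.
#'
#' @inheritParams classify
#' @return A `utility_class` (no witness retained).
#' @export
classify_oracle <- function(graph, mapping, table, max_length = 15L) {
  if (nrow(graph$concepts) > 40L) {
    stop("classify_oracle is restricted to graphs of at most 40 concepts",
         call. = FALSE)
  }
  stopifnot(inherits(mapping, "exam_mapping"),
            inherits(table, "correspondence_table"))
  .check_mapping_concepts(graph, mapping)
  term <- graph$name

  attrs <- unique(c(mapping$region_attribute, mapping$focus_attribute))
  markers <- vapply(attrs, function(a) .concept_marker(table, term, a),
                    character(1))
  if (any(!is.na(markers))) {
    regions <- unique(unlist(lapply(markers[!is.na(markers)], marker_regions)))
    return(.utility_class(1L, regions = regions))
  }

  targets <- mapping$target_regions
  region_concepts <- vapply(targets, function(r) .region_concept(table, term, r),
                            character(1))
  keep <- !is.na(region_concepts)
  if (!any(keep)) .no_target_error(mapping)

  starts <- mapping$focus_attribute
  if (is.null(starts)) starts <- mapping$region_attribute

  classes <- vapply(which(keep), function(i) {
    R <- region_concepts[[i]]
    min(vapply(starts, function(s) {
      rels <- .oracle_walk_relsets(graph, s, R, max_length)
      has_uniform <- any(vapply(rels, length, integer(1)) == 1L)
      if (has_uniform) {
        if (.oracle_bypass(graph, s, R)) 3L else 2L
      } else if (length(rels)) 4L else 5L
    }, integer(1)))
  }, integer(1))
  value <- max(classes)
  .utility_class(value,
                 regions = targets[keep][classes == value & value < 5L],
                 per_region = data.frame(region = targets[keep],
                                         class = classes,
                                         stringsAsFactors = FALSE))
}

# igraph handle on the full asserted-direction graph; edge attribute
# `relation` preserved (parallel edges kept).
.igraph_of <- function(g, rootward_only = FALSE) {
  e <- g$edges
  if (rootward_only && nrow(e)) e <- e[e$relation %in% rootward_relations(), ]
  igraph::graph_from_data_frame(
    d = data.frame(from = e$source, to = e$target, relation = e$relation,
                   stringsAsFactors = FALSE),
    directed = TRUE, vertices = g$concepts$id)
}

# Relation sets of all simple typed walks start -> goal (parallel edges with
# different relations expanded into distinct walks).
.oracle_walk_relsets <- function(g, start, goal, max_length) {
  if (start == goal) return(list())
  ig <- .igraph_of(g)
  vpaths <- igraph::all_simple_paths(ig, from = start, to = goal,
                                     mode = "out", cutoff = max_length)
  out <- list()
  e <- g$edges
  for (vp in vpaths) {
    nodes <- names(vp)
    step_rels <- lapply(seq_len(length(nodes) - 1L), function(i) {
      unique(e$relation[e$source == nodes[i] & e$target == nodes[i + 1L]])
    })
    combos <- expand.grid(step_rels, stringsAsFactors = FALSE)
    for (j in seq_len(nrow(combos))) {
      out[[length(out) + 1L]] <- sort(unique(unlist(combos[j, ])))
    }
  }
  out
}

# Bypass oracle: after removing `forbidden`, is any original root (concept
# without outgoing rootward edges) reachable from `start` rootward-only?
.oracle_bypass <- function(g, start, forbidden) {
  if (start == forbidden) return(FALSE)
  e <- g$edges
  e <- e[e$relation %in% rootward_relations(), , drop = FALSE]
  roots <- setdiff(g$concepts$id, unique(e$source))
  if (start %in% roots) return(TRUE)
  ig <- .igraph_of(g, rootward_only = TRUE)
  ig <- igraph::delete_vertices(ig, forbidden)
  roots <- setdiff(roots, forbidden)
  if (!length(roots)) return(FALSE)
  d <- igraph::distances(ig, v = start, to = roots, mode = "out")
  any(is.finite(d))
}

#' Classify a batch of exam mappings
#'
#' Order-preserving; classification errors (e.g. "no target region") are
#' collected per row rather than aborting the batch.
#'
#' @param graph The terminology graph.
#' @param mappings List of [exam_mapping()] objects.
#' @param table A [correspondence_table()].
#' @param max_length Walk-length bound.
#' @return `data.frame` with columns `exam_code`, `terminology`, `class`
#'   (`NA` on error), `rationale` (error message on error), `ok`. The full
#'   `utility_class` objects are attached as attribute `"results"`.
#' @export
classify_batch <- function(graph, mappings, table, max_length = 15L) {
  empty <- data.frame(exam_code = character(), terminology = character(),
                      class = integer(), rationale = character(),
                      ok = logical(), stringsAsFactors = FALSE)
  if (!length(mappings)) {
    attr(empty, "results") <- list()
    return(empty)
  }
  results <- vector("list", length(mappings))
  rows <- lapply(seq_along(mappings), function(i) {
    m <- mappings[[i]]
    res <- tryCatch(classify(graph, m, table, max_length), error = identity)
    results[[i]] <<- res
    if (inherits(res, "error")) {
      data.frame(exam_code = m$exam_code, terminology = m$terminology,
                 class = NA_integer_, rationale = conditionMessage(res),
                 ok = FALSE, stringsAsFactors = FALSE)
    } else {
      data.frame(exam_code = m$exam_code, terminology = m$terminology,
                 class = res$value, rationale = res$rationale, ok = TRUE,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "results") <- results
  out
}
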