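# Typed-edge anatomic terminology graphs: containers, validation, JSON I/O,
# and the rootward path analysis the utility classifier and alert engine
# are built on.

#' Relation types recognised in terminology graphs
#'
#' Anatomic terminologies express nesting either as subsumption (`is_a`) or
#' as partonomy (`part_of` and its FMA refinements `regional_part_of` /
#' `constitutional_part_of`), plus the inverse `has_part`. All relations are
#' stored in their asserted direction: the four "rootward" relations point
#' child/part -> parent/whole, while `has_part` points whole -> part.
#'
#' @return Character vector of the five relation type names.
#' @export
relation_types <- function() {
  c("is_a", "part_of", "has_part", "regional_part_of", "constitutional_part_of")
}

#' Rootward relation types
#'
#' The subset of [relation_types()] asserted from a concept toward the
#' ontology roots. The subgraph restricted to these relations must be
#' acyclic in a valid terminology graph.
#'
#' @return Character vector of the four rootward relation names.
#' @export
rootward_relations <- function() {
  c("is_a", "part_of", "regional_part_of", "constitutional_part_of")
}

#' Construct a terminology graph
#'
#' A terminology graph is a named set of concepts plus typed directed edges.
#' Edges are stored in asserted direction (see [relation_types()]). The
#' constructor validates all structural invariants: unique concept ids,
#' non-empty labels, resolvable edge endpoints, no self-loops, known
#' relation types, and acyclicity of the rootward subgraph.
#'
#' @param name Terminology name (scalar character).
#' @param concepts `data.frame` with columns `id`, `label`.
#' @param edges `data.frame` with columns `source`, `target`, `relation`
#'   (may have zero rows).
#' @return An object of class `terminology_graph`.
#' @export
terminology_graph <- function(name, concepts, edges = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("`name` must be a non-empty string", call. = FALSE)
  }
  concepts <- as.data.frame(concepts, stringsAsFactors = FALSE)
  if (!all(c("id", "label") %in% names(concepts))) {
    stop("`concepts` needs columns `id` and `label`", call. = FALSE)
  }
  concepts <- concepts[, c("id", "label")]
  concepts[] <- lapply(concepts, as.character)
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- data.frame(source = character(), target = character(),
                        relation = character(), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (!all(c("source", "target", "relation") %in% names(edges))) {
      stop("`edges` needs columns `source`, `target`, `relation`", call. = FALSE)
    }
    edges <- edges[, c("source", "target", "relation")]
    edges[] <- lapply(edges, as.character)
  }
  g <- structure(list(name = name, concepts = concepts, edges = edges),
                 class = "terminology_graph")
  validate_graph(g)
  g
}

#' Validate a terminology graph
#'
#' @param g A `terminology_graph`.
#' @return `g`, invisibly, if valid; otherwise an error describing the first
#'   violated invariant (dangling endpoints name the offending edge; a
#'   rootward cycle is listed concept by concept).
#' @export
validate_graph <- function(g) {
  stopifnot(inherits(g, "terminology_graph"))
  ids <- g$concepts$id
  if (anyDuplicated(ids)) {
    stop("duplicate concept id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(g$concepts$label)) || anyNA(g$concepts$label)) {
    stop("every concept needs a non-empty label", call. = FALSE)
  }
  e <- g$edges
  if (nrow(e)) {
    bad_rel <- setdiff(unique(e$relation), relation_types())
    if (length(bad_rel)) {
      stop("unknown relation type(s): ", paste(bad_rel, collapse = ", "),
           call. = FALSE)
    }
    if (any(e$source == e$target)) {
      i <- which(e$source == e$target)[1L]
      stop("self-loop edge: ", e$source[i], " -[", e$relation[i], "]-> ",
           e$target[i], call. = FALSE)
    }
    dangling <- !(e$source %in% ids) | !(e$target %in% ids)
    if (any(dangling)) {
      i <- which(dangling)[1L]
      stop("edge references unknown concept: ", e$source[i], " -[",
           e$relation[i], "]-> ", e$target[i], call. = FALSE)
    }
  }
  cyc <- .rootward_cycle(g)
  if (!is.null(cyc)) {
    stop("rootward subgraph contains a cycle: ",
         paste(cyc, collapse = " -> "), call. = FALSE)
  }
  invisible(g)
}

# Detect a directed cycle in the rootward subgraph; returns the cycle as a
# character vector of concept ids (closed: first == last) or NULL.
.rootward_cycle <- function(g) {
  adj <- .adjacency(g, rootward_only = TRUE)
  color <- new.env(parent = emptyenv())
  found <- NULL
  visit <- function(v, stack) {
    state <- get0(v, envir = color, ifnotfound = "white")
    if (state == "grey") {
      i <- match(v, stack)
      found <<- c(stack[i:length(stack)], v)
      return(TRUE)
    }
    if (state == "black") return(FALSE)
    assign(v, "grey", envir = color)
    for (w in adj[[v]]$target) {
      if (visit(w, c(stack, v))) return(TRUE)
    }
    assign(v, "black", envir = color)
    FALSE
  }
  for (v in g$concepts$id) {
    if (visit(v, character())) break
  }
  found
}

# Outgoing-edge lookup: list keyed by concept id, each element a data.frame
# with columns target, relation. Concepts with no outgoing edges map to a
# zero-row data.frame.
.adjacency <- function(g, rootward_only = FALSE) {
  e <- g$edges
  if (rootward_only && nrow(e)) e <- e[e$relation %in% rootward_relations(), ]
  empty <- data.frame(target = character(), relation = character(),
                      stringsAsFactors = FALSE)
  adj <- rep(list(empty), nrow(g$concepts))
  names(adj) <- g$concepts$id
  if (nrow(e)) {
    sp <- split(seq_len(nrow(e)), e$source)
    for (src in names(sp)) {
      adj[[src]] <- e[sp[[src]], c("target", "relation"), drop = FALSE]
    }
  }
  adj
}

.check_concept <- function(g, id, arg = "concept") {
  if (length(id) != 1L || !id %in% g$concepts$id) {
    stop("unknown ", arg, ": ", paste(id, collapse = ", "),
         " (terminology '", g$name, "')", call. = FALSE)
  }
  invisible(id)
}

#' Read a terminology graph from its JSON file dialect
#'
#' The dialect is a single object
#' `{"name": ..., "concepts": [{"id","label"}...],
#'   "edges": [{"source","target","relation"}...]}`.
#' The file is fully validated on load.
#'
#' @param path Path to a UTF-8 JSON file.
#' @return A `terminology_graph`.
#' @export
load_graph <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE),
    error = function(e) stop("malformed JSON in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (!is.list(raw) || is.null(raw$name) || is.null(raw$concepts)) {
    stop("not a terminology graph file (need `name` and `concepts`): ", path,
         call. = FALSE)
  }
  terminology_graph(raw$name, raw$concepts, raw$edges)
}

#' Write a terminology graph to the JSON dialect
#'
#' Output ordering is stable (concepts by id, edges by source/target/relation)
#' so that saved files are byte-comparable.
#'
#' @param g A `terminology_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_graph <- function(g, path) {
  validate_graph(g)
  concepts <- g$concepts[order(g$concepts$id), , drop = FALSE]
  e <- g$edges
  e <- e[order(e$source, e$target, e$relation), , drop = FALSE]
  rownames(concepts) <- rownames(e) <- NULL
  payload <- list(name = jsonlite::unbox(g$name), concepts = concepts, edges = e)
  txt <- jsonlite::toJSON(payload, dataframe = "rows", pretty = TRUE)
  ok <- tryCatch({ writeLines(txt, path, useBytes = TRUE); TRUE },
                 error = function(e) FALSE,
                 warning = function(w) FALSE)
  if (!ok) stop("cannot write to ", path, call. = FALSE)
  invisible(path)
}

#' Concepts one rootward step from a concept
#'
#' Rootward neighbors are the targets of `is_a`/`part_of`/`regional_part_of`/
#' `constitutional_part_of` edges asserted *from* the concept. In a
#' polyhierarchy a concept may have several, possibly leading to ancestors
#' that bypass one another.
#'
#' @param g A `terminology_graph`.
#' @param concept Concept id.
#' @return `data.frame` with columns `id`, `relation` (zero rows if none).
#' @export
rootward_neighbors <- function(g, concept) {
  .check_concept(g, concept)
  adj <- .adjacency(g, rootward_only = TRUE)[[concept]]
  out <- data.frame(id = adj$target, relation = adj$relation,
                    stringsAsFactors = FALSE)
  out[!duplicated(out), , drop = FALSE]
}

#' Enumerate typed connecting walks between two concepts
#'
#' Finds every simple directed walk (no repeated concept) from `start` to
#' `goal` of length at most `max_length`, traversing each edge in its
#' asserted direction only: rootward relations child -> parent, `has_part`
#' whole -> part. Mixing `has_part` with partonomy edges is what produces
#' the "travel down then back up" routes some terminologies need to reach a
#' body region from an organ.
#'
#' Each walk carries a `uniform` flag (all edges share one relation type) and
#' its `relation_set`. `has_part` edges can close directed cycles with
#' `part_of`, so the simple-walk restriction is what guarantees termination.
#'
#' @param g A `terminology_graph`.
#' @param start,goal Concept ids; must differ for a non-empty result.
#' @param max_length Maximum number of edges per walk (default 15, ample for
#'   the shallow fixture terminologies while bounding generated graphs).
#' @return List of `typed_path` objects (possibly empty), each a list with
#'   `concepts`, `relations`, `uniform`, `relation_set`.
#' @export
find_paths <- function(g, start, goal, max_length = 15L) {
  .check_concept(g, start, "start")
  .check_concept(g, goal, "goal")
  stopifnot(max_length >= 1L)
  adj <- .adjacency(g)
  paths <- list()
  walk <- function(v, via_concepts, via_relations) {
    if (length(via_relations) >= max_length) return(invisible())
    out <- adj[[v]]
    for (i in seq_len(nrow(out))) {
      w <- out$target[i]
      if (w %in% via_concepts) next
      rels <- c(via_relations, out$relation[i])
      if (w == goal) {
        paths[[length(paths) + 1L]] <<- .typed_path(c(via_concepts, w), rels)
      } else {
        walk(w, c(via_concepts, w), rels)
      }
    }
    invisible()
  }
  if (start != goal) walk(start, start, character())
  paths
}

.typed_path <- function(concepts, relations) {
  structure(list(concepts = concepts,
                 relations = relations,
                 uniform = length(unique(relations)) == 1L,
                 relation_set = sort(unique(relations))),
            class = "typed_path")
}

#' @export
format.typed_path <- function(x, ...) {
  n <- length(x$relations)
  parts <- character(2L * n + 1L)
  parts[seq(1L, 2L * n + 1L, by = 2L)] <- x$concepts
  parts[seq(2L, 2L * n, by = 2L)] <- paste0("-[", x$relations, "]->")
  paste(parts, collapse = " ")
}

#' @export
print.typed_path <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Can the rootward closure of a concept bypass a given ancestor?
#'
#' Tests whether some maximal rootward walk from `start` — one ending at a
#' root, i.e. a concept with no outgoing rootward edges — never visits
#' `forbidden`. This is the polyhierarchy "bypass" condition that separates
#' utility class 2 (no alternative paths) from class 3 (alternative paths to
#' other superclasses exist). A `start` that is itself a root vacuously
#' bypasses any `forbidden` other than itself.
#'
#' @param g A `terminology_graph`.
#' @param start Concept id.
#' @param forbidden Concept id the walk must avoid.
#' @return `TRUE` or `FALSE`.
#' @export
rootward_closure_avoiding <- function(g, start, forbidden) {
  .check_concept(g, start, "start")
  .check_concept(g, forbidden, "forbidden")
  if (start == forbidden) return(FALSE)
  adj <- .adjacency(g, rootward_only = TRUE)
  memo <- new.env(parent = emptyenv())
  # Rootward subgraph is a validated DAG, so plain memoised recursion.
  reach <- function(v) {
    if (v == forbidden) return(FALSE)
    hit <- get0(v, envir = memo, ifnotfound = NULL)
    if (!is.null(hit)) return(hit)
    out <- adj[[v]]
    res <- if (nrow(out) == 0L) TRUE else any(vapply(out$target, reach, logical(1)))
    assign(v, res, envir = memo)
    res
  }
  reach(start)
}

#' @export
print.terminology_graph <- function(x, ...) {
  cat(sprintf("<terminology_graph '%s': %d concepts, %d edges>\n",
              x$name, nrow(x$concepts), nrow(x$edges)))
  invisible(x)
}

#' Structural equality of two terminology graphs
#'
#' Order-insensitive comparison of name, concept set and edge multiset; used
#' by the serialization round-trip tests.
#'
#' @param a,b `terminology_graph` objects.
#' @return `TRUE` or `FALSE`.
#' @export
graphs_identical <- function(a, b) {
  norm <- function(g) {
    co <- g$concepts[order(g$concepts$id), , drop = FALSE]
    ed <- g$edges[order(g$edges$source, g$edges$target, g$edges$relation), ,
                  drop = FALSE]
    rownames(co) <- rownames(ed) <- NULL
    list(g$name, co, ed)
  }
  isTRUE(all.equal(norm(a), norm(b), check.attributes = FALSE))
}

#' Concept label lookup
#'
#' @param g A `terminology_graph`.
#' @param concept Concept id.
#' @return The concept's label.
#' @export
concept_label <- function(g, concept) {
  .check_concept(g, concept)
  g$concepts$label[match(concept, g$concepts$id)]
}
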