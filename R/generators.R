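# Random terminology generators with planted utility classes, and random
# ordinal class samples. These emulate, at desk scale, the structural
# situations the classifier has to recognise (uniform nesting, bypassing
# polyhierarchy branches, mixed-relation detours, missing links) and the
# shape of utility-class samples drawn over many exam codes. They do not
# emulate real terminology size, label semantics, or the correlation of
# classes across exams within one terminology.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification for a planted-class random terminology
#'
#' @param seed Integer RNG seed.
#' @param n_concepts Total concepts (>= 3; the planted structure uses up to
#'   6, the rest become decoys).
#' @param planted_class Utility class 1-5 the construction guarantees.
#' @param relations Relation palette. Classes 2-3 need at least one rootward
#'   relation; class 4 additionally needs `has_part` plus a rootward type --
#'   an infeasible palette is an error.
#' @param region_code SANOPS region the synthetic exam targets.
#' @return A `planted_graph_spec` list.
#' @export
planted_graph_spec <- function(seed, n_concepts = 12L, planted_class,
                               relations = c("is_a", "part_of", "has_part"),
                               region_code = "4") {
  stopifnot(n_concepts >= 3L, planted_class %in% 1:5)
  bad <- setdiff(relations, relation_types())
  if (length(bad)) stop("unknown relation(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  root_pal <- intersect(relations, rootward_relations())
  if (planted_class %in% 2:3 && !length(root_pal)) {
    stop("infeasible spec: classes 2-3 need a rootward relation in the palette",
         call. = FALSE)
  }
  if (planted_class == 4L && (!"has_part" %in% relations || !length(root_pal))) {
    stop("infeasible spec: class 4 needs has_part plus a rootward relation",
         call. = FALSE)
  }
  .check_region_codes(region_code)
  structure(list(seed = as.integer(seed), n_concepts = as.integer(n_concepts),
                 planted_class = as.integer(planted_class),
                 relations = relations, region_code = region_code),
            class = "planted_graph_spec")
}

#' Generate a random terminology with a planted utility class
#'
#' Builds a small random graph around a focus concept `F` and a marked
#' region concept `R` such that [classify()] provably returns
#' `planted_class`: class 1 plants a marker on the focus; class 2 a uniform
#' rootward chain F -> ... -> R with no alternative rootward path; class 3
#' that chain plus a bypassing branch to a separate root; class 4 a
#' has_part-then-rootward detour and no uniform walk; class 5 no connection
#' at all. Remaining concepts are decoys wired so they cannot alter the
#' planted class (rootward edges above R, or a side component).
#'
#' @param spec A [planted_graph_spec()] (or the arguments to build one,
#'   passed via `...` for convenience is not supported -- build the spec).
#' @return List with elements `graph`, `mapping`, `table`, `spec`, and
#'   `witness_edge` (for class 2: the chain edge out of the focus, whose
#'   deletion must raise the class).
#' @export
random_terminology <- function(spec) {
  stopifnot(inherits(spec, "planted_graph_spec"))
  .with_seed(spec$seed, .random_terminology_impl(spec))
}

.random_terminology_impl <- function(spec) {
  term <- sprintf("rand%d", spec$seed)
  k <- spec$planted_class
  root_pal <- intersect(spec$relations, rootward_relations())
  n <- spec$n_concepts

  ids <- c("F", "R")
  edges <- list()
  add_edge <- function(s, t, r) edges[[length(edges) + 1L]] <<- c(s, t, r)
  witness_edge <- NULL
  markers <- data.frame(terminology = term, concept_id = "R",
                        marker = spec$region_code, stringsAsFactors = FALSE)

  chain_rel <- if (length(root_pal)) sample(root_pal, 1L) else NA_character_
  if (k == 1L) {
    # marker on the focus itself; any structure beyond that is irrelevant
    markers <- rbind(markers, data.frame(terminology = term,
                                         concept_id = "F", marker = "JOINT:9b",
                                         stringsAsFactors = FALSE))
    if (!is.na(chain_rel) && stats::runif(1) < 0.5) add_edge("F", "R", chain_rel)
  } else if (k %in% c(2L, 3L)) {
    len <- sample(1:3, 1L)
    chain <- if (len > 1L) paste0("C", seq_len(len - 1L)) else character()
    ids <- c(ids, chain)
    nodes <- c("F", chain, "R")
    for (i in seq_len(length(nodes) - 1L)) {
      add_edge(nodes[i], nodes[i + 1L], chain_rel)
    }
    witness_edge <- c("F", nodes[2L], chain_rel)
    if (k == 3L) {
      ids <- c(ids, "B")  # bypass root: separate superclass, no out-edges
      from <- sample(c("F", chain), 1L)
      add_edge(from, "B", sample(root_pal, 1L))
    }
  } else if (k == 4L) {
    len <- sample(1:2, 1L)
    tail <- if (len > 1L) "C1" else character()
    ids <- c(ids, "X", tail)
    add_edge("F", "X", "has_part")
    nodes <- c("X", tail, "R")
    for (i in seq_len(length(nodes) - 1L)) {
      add_edge(nodes[i], nodes[i + 1L], chain_rel)
    }
  }
  # k == 5: F stays disconnected from R (side decoys may hang off F below)

  n_decoy <- max(0L, n - length(ids))
  if (n_decoy > 0L) {
    decoys <- paste0("D", seq_len(n_decoy))
    ids <- c(ids, decoys)
    half <- n_decoy %/% 2L
    upper <- decoys[seq_len(half)]            # strictly above R
    side <- decoys[setdiff(seq_len(n_decoy), seq_len(half))]  # own component
    for (u in upper) {
      if (length(root_pal)) add_edge("R", u, sample(root_pal, 1L))
    }
    if (length(side) > 1L && length(root_pal)) {
      for (i in seq_len(length(side) - 1L)) {
        if (stats::runif(1) < 0.6) {
          add_edge(side[i], side[i + 1L], sample(root_pal, 1L))
        }
      }
    }
    # class 5 (and only class 5) may hook the focus into the side component:
    # side decoys have no route to R, so no walk F -> R can appear
    if (k == 5L && length(side) && length(root_pal) && stats::runif(1) < 0.7) {
      add_edge("F", side[1L], sample(root_pal, 1L))
    }
  }

  edf <- if (length(edges)) {
    as.data.frame(do.call(rbind, edges), stringsAsFactors = FALSE)
  } else {
    data.frame(source = character(), target = character(),
               relation = character())
  }
  names(edf) <- c("source", "target", "relation")
  qual <- function(x) paste0(term, ":", x)
  graph <- terminology_graph(term,
                             data.frame(id = qual(ids),
                                        label = paste("concept", ids)),
                             data.frame(source = qual(edf$source),
                                        target = qual(edf$target),
                                        relation = edf$relation))
  markers$concept_id <- qual(markers$concept_id)
  mapping <- exam_mapping("RND-1", "Synthetic exam", term,
                          focus_attribute = qual("F"),
                          target_regions = spec$region_code)
  list(graph = graph, mapping = mapping,
       table = correspondence_table(markers), spec = spec,
       witness_edge = if (!is.null(witness_edge)) {
         data.frame(source = qual(witness_edge[1L]),
                    target = qual(witness_edge[2L]),
                    relation = witness_edge[3L], stringsAsFactors = FALSE)
       })
}

#' Random ordinal utility-class samples
#'
#' Draws, per terminology, `n` independent classes from a categorical
#' distribution over `{1..5}`. Used to emulate the shape of utility-class
#' samples over many exam codes when exercising the comparison statistics.
#'
#' @param seed Integer RNG seed.
#' @param n Sample size per terminology.
#' @param class_probabilities Named list: terminology -> length-5 probability
#'   vector over classes 1..5 (each must sum to 1).
#' @return A [class_sample()]: named list of integer vectors.
#' @export
random_class_sample <- function(seed, n, class_probabilities) {
  stopifnot(n >= 1L, length(class_probabilities) >= 1L,
            !is.null(names(class_probabilities)))
  for (p in class_probabilities) {
    if (length(p) != 5L || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("each probability vector must be length 5, nonnegative, sum to 1",
           call. = FALSE)
    }
  }
  .with_seed(seed, {
    class_sample(lapply(class_probabilities, function(p) {
      sample(1:5, n, replace = TRUE, prob = p)
    }))
  })
}
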