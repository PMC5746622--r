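# Independent brute-force oracles for the path machinery and the rank
# statistics, plus small random-graph builders. These deliberately share no
# code with the package internals: walk enumeration is a queue-based
# breadth-first expansion over the raw edge table.

# All simple typed walks start -> goal, length <= max_length, as lists of
# relation vectors (one entry per walk). Parallel typed edges are distinct.
bf_walks <- function(g, start, goal, max_length = 15L) {
  e <- g$edges
  done <- list()
  queue <- list(list(nodes = start, rels = character()))
  head <- 1L
  while (head <= length(queue)) {
    w <- queue[[head]]; head <- head + 1L
    if (length(w$rels) >= max_length) next
    tip <- w$nodes[length(w$nodes)]
    out <- which(e$source == tip)
    for (i in out) {
      tgt <- e$target[i]
      if (tgt %in% w$nodes) next
      nxt <- list(nodes = c(w$nodes, tgt), rels = c(w$rels, e$relation[i]))
      if (tgt == goal) done[[length(done) + 1L]] <- nxt
      else queue[[length(queue) + 1L]] <- nxt
    }
  }
  done
}

# All maximal rootward walks from start (each ends at a concept with no
# outgoing rootward edge), as lists of node vectors.
bf_maximal_rootward_walks <- function(g, start) {
  e <- g$edges[g$edges$relation %in% rootward_relations(), , drop = FALSE]
  done <- list()
  queue <- list(start)
  head <- 1L
  while (head <= length(queue)) {
    nodes <- queue[[head]]; head <- head + 1L
    tip <- nodes[length(nodes)]
    out <- which(e$source == tip)
    # rootward subgraph is acyclic so walks cannot revisit; guard anyway
    out <- out[!(e$target[out] %in% nodes)]
    if (!length(out)) {
      done[[length(done) + 1L]] <- nodes
    } else {
      for (i in out) queue[[length(queue) + 1L]] <- c(nodes, e$target[i])
    }
  }
  done
}

bf_bypass <- function(g, start, forbidden) {
  if (start == forbidden) return(FALSE)
  walks <- bf_maximal_rootward_walks(g, start)
  any(vapply(walks, function(w) !(forbidden %in% w), logical(1)))
}

# Random valid terminology graph: DAG rootward edges over an ordered concept
# set plus a few has_part edges (which may close directed cycles with the
# rootward edges -- legal, since only the rootward subgraph must be acyclic).
# Density is calibrated to mean degree ~3 so that exhaustive simple-walk
# enumeration stays tractable at n = 25.
random_valid_graph <- function(seed, n = 10L, p_edge = 3 / n,
                               p_haspart = 0.6 / n) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  src <- tgt <- rel <- character()
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (runif(1) < p_edge) {
        src <- c(src, ids[i]); tgt <- c(tgt, ids[j])
        rel <- c(rel, sample(rootward_relations(), 1L))
      }
      if (runif(1) < p_haspart) {
        # has_part in either orientation; may create cycles in the full graph
        if (runif(1) < 0.5) { src <- c(src, ids[i]); tgt <- c(tgt, ids[j]) }
        else { src <- c(src, ids[j]); tgt <- c(tgt, ids[i]) }
        rel <- c(rel, "has_part")
      }
    }
  }
  ed <- data.frame(source = src, target = tgt, relation = rel,
                   stringsAsFactors = FALSE)
  ed <- ed[!duplicated(ed), , drop = FALSE]
  terminology_graph(sprintf("rv%d", seed),
                    data.frame(id = ids, label = paste("concept", ids)), ed)
}

# Two-sided permutation test of group difference via the rank-sum statistic
# (for two groups) or the between-group rank variance (for k groups).
perm_rank_test <- function(groups, n_perm = 2000L, seed = 1L) {
  set.seed(seed)
  values <- unlist(groups, use.names = FALSE)
  sizes <- lengths(groups)
  idx <- rep(seq_along(groups), sizes)
  stat <- function(lab) {
    r <- rank(values)
    ms <- tapply(r, lab, mean)
    sum(sizes * (ms - mean(r))^2)
  }
  obs <- stat(idx)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    if (stat(sample(idx)) >= obs - 1e-12) hits <- hits + 1L
  }
  (hits + 1L) / (n_perm + 1L)
}

std_fixture_names <- function() c("loinc", "loinc_rsna", "radlex", "fma", "snomed")

fixture_code <- function(key) {
  defs <- fixture_exams()
  defs$code[defs$key == key]
}

classify_fixture <- function(term, key, ...) {
  b <- build_fixture(term)$backend
  classify(b$graph, b$mappings[[fixture_code(key)]], b$correspondence, ...)
}

rec <- function(code, ts = "2016-02-01T09:00:00", pt = "p1", site = "s1") {
  exam_record(pt, site, code, ts)
}
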