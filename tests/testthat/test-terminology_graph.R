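test_that("minimal graphs construct, round-trip, and identity cases hold", {
  g <- terminology_graph("mini", data.frame(id = "a", label = "A"))
  expect_s3_class(g, "terminology_graph")
  expect_equal(nrow(g$concepts), 1L)

  path <- withr::local_tempfile(fileext = ".json")
  save_graph(g, path)
  expect_true(graphs_identical(g, load_graph(path)))
})

test_that("load-time validation rejects malformed input", {
  bad_json <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", bad_json)
  expect_error(load_graph(bad_json), "malformed JSON")

  expect_error(
    terminology_graph("t", data.frame(id = "a", label = "A"),
                      data.frame(source = "a", target = "ghost",
                                 relation = "is_a")),
    "unknown concept.*ghost")
  expect_error(
    terminology_graph("t", data.frame(id = c("a", "b"), label = c("A", "B")),
                      data.frame(source = c("a", "b"), target = c("b", "a"),
                                 relation = "is_a")),
    "cycle")
  # has_part may close cycles with part_of: full graph cyclic, rootward DAG
  expect_s3_class(
    terminology_graph("t", data.frame(id = c("a", "b"), label = c("A", "B")),
                      data.frame(source = c("a", "b"), target = c("b", "a"),
                                 relation = c("part_of", "has_part"))),
    "terminology_graph")
  expect_error(
    terminology_graph("t", data.frame(id = c("a", "a"), label = "A")),
    "duplicate")
  expect_error(
    terminology_graph("t", data.frame(id = "a", label = "")),
    "label")
})

test_that("round-trip serialization preserves all fixture graphs", {
  for (nm in fixture_names()) {
    g <- build_fixture(nm)$backend$graph
    path <- withr::local_tempfile(fileext = ".json")
    save_graph(g, path)
    g2 <- load_graph(path)
    expect_true(graphs_identical(g, g2), label = paste("round-trip", nm))
    expect_setequal(unique(g2$edges$relation), unique(g$edges$relation))
  }
})

test_that("rootward_neighbors returns one-step rootward concepts only", {
  g <- terminology_graph(
    "t", data.frame(id = c("a", "b", "c"), label = c("A", "B", "C")),
    data.frame(source = c("a", "b", "a"), target = c("b", "c", "c"),
               relation = c("is_a", "is_a", "has_part")))
  nb <- rootward_neighbors(g, "a")
  expect_equal(nb$id, "b")  # has_part is not rootward
  expect_equal(nrow(rootward_neighbors(g, "c")), 0L)
  expect_error(rootward_neighbors(g, "zzz"), "unknown")
})

test_that("SNOMED fixture temporal bone has both head-path and bypassing neighbors", {
  g <- build_fixture("snomed")$backend$graph
  nb <- rootward_neighbors(g, "SNOMED:TemporalBone")
  to_head <- vapply(nb$id, function(v) {
    length(bf_walks(g, v, "SNOMED:Head")) > 0L || v == "SNOMED:Head"
  }, logical(1))
  avoiding <- vapply(nb$id, function(v) bf_bypass(g, v, "SNOMED:Head") ||
                       (v != "SNOMED:Head" && nrow(rootward_neighbors(g, v)) == 0L),
                     logical(1))
  expect_true(any(to_head))
  expect_true(any(avoiding))
})

test_that("fixture path structure matches the cited terminology facts", {
  loinc <- build_fixture("loinc")$backend$graph
  # paranasal sinuses: rootward is_a toward skeletal system, none toward head
  nb <- rootward_neighbors(loinc, "LOINC:ParanasalSinuses")
  expect_true("LOINC:SkeletalSystem" %in% nb$id)
  expect_length(find_paths(loinc, "LOINC:ParanasalSinuses", "LOINC:Head"), 0L)
  # no walk from cervical spine to neck, no links kidney -> abdomen
  expect_length(find_paths(loinc, "LOINC:CervicalSpine", "LOINC:Neck"), 0L)
  expect_length(find_paths(loinc, "LOINC:Kidney", "LOINC:Abdomen"), 0L)

  fma <- build_fixture("fma")$backend$graph
  paths <- find_paths(fma, "FMA:Esophagus", "FMA:Chest")
  expect_gt(length(paths), 0L)
  for (p in paths) {
    expect_false(p$uniform)
    expect_true(all(c("has_part", "part_of") %in% p$relation_set))
  }
})

test_that("find_paths flags and adjacency basics", {
  g <- terminology_graph(
    "t", data.frame(id = c("a", "b"), label = c("A", "B")),
    data.frame(source = "a", target = "b", relation = "part_of"))
  p <- find_paths(g, "a", "b")
  expect_length(p, 1L)
  expect_true(p[[1L]]$uniform)
  expect_equal(p[[1L]]$relation_set, "part_of")
  expect_error(find_paths(g, "a", "zzz"), "unknown")
})

test_that("find_paths agrees with the brute-force enumeration oracle", {
  for (seed in 1:30) {
    g <- random_valid_graph(seed, n = sample(4:25, 1L))
    ids <- g$concepts$id
    for (rep in 1:4) {
      pair <- sample(ids, 2L)
      for (ml in c(3L, 15L)) {
        mine <- find_paths(g, pair[1L], pair[2L], ml)
        ref <- bf_walks(g, pair[1L], pair[2L], ml)
        expect_equal(length(mine), length(ref),
                     label = sprintf("seed %d pair %s->%s ml=%d", seed,
                                     pair[1L], pair[2L], ml))
        canon <- function(ps, f) sort(vapply(ps, f, character(1)))
        expect_equal(canon(mine, function(p) paste(p$concepts, collapse = "|")),
                     canon(ref, function(p) paste(p$nodes, collapse = "|")))
      }
    }
  }
})

test_that("rootward_closure_avoiding matches maximal-walk enumeration", {
  # trivial cases first
  chain <- terminology_graph(
    "t", data.frame(id = c("s", "f", "r"), label = c("S", "F", "R")),
    data.frame(source = c("s", "f"), target = c("f", "r"), relation = "is_a"))
  expect_false(rootward_closure_avoiding(chain, "s", "f"))
  expect_true(rootward_closure_avoiding(chain, "r", "s"))   # root itself
  expect_false(rootward_closure_avoiding(chain, "s", "s"))  # self is visited

  for (seed in 31:55) {
    g <- random_valid_graph(seed, n = sample(4:25, 1L))
    ids <- g$concepts$id
    for (rep in 1:5) {
      pair <- sample(ids, 2L)
      expect_equal(rootward_closure_avoiding(g, pair[1L], pair[2L]),
                   bf_bypass(g, pair[1L], pair[2L]),
                   label = sprintf("seed %d %s avoid %s", seed, pair[1L],
                                   pair[2L]))
    }
  }
})

test_that("adding an edge never removes a found path", {
  for (seed in 101:115) {
    g <- random_valid_graph(seed, n = 10L)
    ids <- g$concepts$id
    pair <- sample(ids, 2L)
    before <- find_paths(g, pair[1L], pair[2L], 6L)
    # add a rootward edge consistent with the DAG order (i < j)
    i <- sort(sample(seq_along(ids), 2L))
    new_edge <- data.frame(source = ids[i[1L]], target = ids[i[2L]],
                           relation = "regional_part_of")
    g2 <- terminology_graph(g$name, g$concepts, rbind(g$edges, new_edge))
    after <- find_paths(g2, pair[1L], pair[2L], 6L)
    key <- function(p) paste(p$concepts, collapse = "|")
    expect_true(all(vapply(before, key, character(1)) %in%
                      vapply(after, key, character(1))),
                label = paste("monotonicity seed", seed))
  }
})
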