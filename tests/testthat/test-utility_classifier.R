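# Frozen expected classes for the worked fixture examples. Values 2/3/4/5/1
# below are the published scale assignments these fixtures encode.
worked_examples <- function() {
  rbind(
    data.frame(term = "loinc", key = "angio_abd", class = 2L),
    data.frame(term = "snomed", key = "temporal", class = 3L),
    data.frame(term = "fma", key = "esoph", class = 4L),
    data.frame(term = "loinc", key = "cspine", class = 5L),
    data.frame(term = "radlex", key = "cspine", class = 5L),
    data.frame(term = "loinc_rsna", key = "neck_angio", class = 1L),
    data.frame(term = "radlex", key = "neck_angio", class = 1L),
    data.frame(term = "fma", key = "cspine", class = 3L),
    data.frame(term = "snomed", key = "liver", class = 3L),
    data.frame(term = "snomed", key = "sinus", class = 3L),
    data.frame(term = std_fixture_names(), key = "abd_pelvis", class = 1L),
    data.frame(term = std_fixture_names(), key = "rknee", class = 1L))
}

test_that("classify reproduces every worked fixture example, with witnesses", {
  ex <- worked_examples()
  for (i in seq_len(nrow(ex))) {
    res <- classify_fixture(ex$term[i], ex$key[i])
    expect_equal(res$value, ex$class[i],
                 label = paste(ex$term[i], ex$key[i]))
    expect_true(nzchar(res$rationale))
    if (res$value %in% 2:4) {
      expect_s3_class(res$witness, "typed_path")
    } else {
      expect_null(res$witness)
    }
  }
  # class-4 witness is the mixed has_part/part_of detour
  w <- classify_fixture("fma", "esoph")$witness
  expect_setequal(w$relation_set, c("has_part", "part_of"))
})

test_that("criterion order puts attribute markers above pathological focus paths", {
  # sinus exam: region attribute head (class 1) even though the focus concept
  # has no usable path in the graph
  for (term in c("loinc_rsna", "radlex")) {
    res <- classify_fixture(term, "sinus")
    expect_equal(res$value, 1L)
    expect_equal(res$regions, "1")
  }
  # without the attribute, the same structure is class 5 (loinc/fma)
  expect_equal(classify_fixture("loinc", "sinus")$value, 5L)
  expect_equal(classify_fixture("fma", "sinus")$value, 5L)
})

test_that("multi-region exams report the worst per-region class with detail", {
  b <- build_fixture("loinc")$backend
  m <- exam_mapping("TST-1", "Abdomen and pelvis angio", "loinc",
                    focus_attribute = c("LOINC:AbdominalVessels",
                                        "LOINC:Kidney"),
                    target_regions = c("4"))
  # abdominal vessels give class 2 on region 4; kidney alone would be 5,
  # but any focus reaching the region suffices per region
  expect_equal(classify(b$graph, m, b$correspondence)$value, 2L)

  m2 <- exam_mapping("TST-2", "Abdominal vessels and pelvis", "loinc",
                     focus_attribute = "LOINC:AbdominalVessels",
                     target_regions = c("4", "5"))
  res <- classify(b$graph, m2, b$correspondence)
  expect_equal(res$value, 5L)  # worst region (pelvis unreachable) dominates
  expect_equal(sort(res$per_region$class), c(2L, 5L))
})

test_that("classification error 'no target region' is distinct from class 5", {
  g <- terminology_graph("bare", data.frame(id = "x", label = "X"))
  tbl <- correspondence_table(data.frame(terminology = "other",
                                         concept_id = "y", marker = "1"))
  m <- exam_mapping("TST-3", "Unmappable", "bare", focus_attribute = "x",
                    target_regions = "1")
  expect_error(classify(g, m, tbl), class = "sanops_no_target_region")
  expect_error(classify_oracle(g, m, tbl), class = "sanops_no_target_region")
})

test_that("classify agrees with the brute-force oracle on planted graphs", {
  set.seed(99)
  n_cases <- 120L
  specs <- lapply(seq_len(n_cases), function(i) {
    planted_graph_spec(seed = 1000L + i, n_concepts = sample(6:20, 1L),
                       planted_class = sample(1:5, 1L))
  })
  for (sp in specs) {
    rt <- random_terminology(sp)
    a <- classify(rt$graph, rt$mapping, rt$table)$value
    b <- classify_oracle(rt$graph, rt$mapping, rt$table)$value
    expect_equal(a, b, label = paste("seed", sp$seed))
    expect_equal(a, sp$planted_class, label = paste("planted seed", sp$seed))
  }
})

test_that("classify agrees with the oracle on unconstrained random graphs", {
  for (seed in 200:249) {
    g <- random_valid_graph(seed, n = sample(5:20, 1L))
    ids <- g$concepts$id
    set.seed(seed + 5000L)
    R <- sample(ids, 1L)
    FF <- sample(setdiff(ids, R), 1L)
    tbl <- correspondence_table(data.frame(terminology = g$name,
                                           concept_id = R, marker = "4"))
    m <- exam_mapping("RND-X", "random exam", g$name, focus_attribute = FF,
                      target_regions = "4")
    expect_equal(classify(g, m, tbl)$value,
                 classify_oracle(g, m, tbl)$value,
                 label = paste("random graph seed", seed))
  }
})

test_that("oracle refuses oversized graphs; trivial single-concept case is class 1", {
  big <- terminology_graph("big",
                           data.frame(id = sprintf("c%02d", 1:41),
                                      label = "x"))
  tbl <- correspondence_table(data.frame(terminology = "big",
                                         concept_id = "c01", marker = "1"))
  m <- exam_mapping("B-1", "big exam", "big", focus_attribute = "c02",
                    target_regions = "1")
  expect_error(classify_oracle(big, m, tbl), "40 concepts")

  one <- terminology_graph("one", data.frame(id = "r", label = "Region"))
  tbl1 <- correspondence_table(data.frame(terminology = "one",
                                          concept_id = "r", marker = "4"))
  m1 <- exam_mapping("O-1", "region exam", "one", focus_attribute = "r",
                     target_regions = "4")
  expect_equal(classify_oracle(one, m1, tbl1)$value, 1L)
  expect_equal(classify(one, m1, tbl1)$value, 1L)
})

test_that("deleting a class-2 witness edge can only raise the class", {
  for (i in 1:25) {
    sp <- planted_graph_spec(seed = 3000L + i, n_concepts = 10L,
                             planted_class = 2L)
    rt <- random_terminology(sp)
    expect_equal(classify(rt$graph, rt$mapping, rt$table)$value, 2L)
    we <- rt$witness_edge
    e <- rt$graph$edges
    keep <- !(e$source == we$source & e$target == we$target &
                e$relation == we$relation)
    g2 <- terminology_graph(rt$graph$name, rt$graph$concepts, e[keep, ])
    expect_gt(classify(g2, rt$mapping, rt$table)$value, 2L)
  }
})

test_that("classify_batch preserves order, collects errors, matches elementwise", {
  b <- build_fixture("radlex")$backend
  sc <- scenario_table()
  codes <- unique(c(sc$prior_code, sc$current_code))
  mappings <- b$mappings[codes]
  res <- classify_batch(b$graph, unname(mappings), b$correspondence)
  expect_equal(nrow(res), length(mappings))
  expect_equal(res$exam_code, codes)
  expect_true(all(res$class[res$ok] %in% 1:5))
  for (i in seq_along(mappings)) {
    expect_equal(res$class[i],
                 classify(b$graph, mappings[[i]], b$correspondence)$value)
  }

  # empty batch and per-row error collection
  empty <- classify_batch(b$graph, list(), b$correspondence)
  expect_equal(nrow(empty), 0L)
  bad <- exam_mapping("NOPE-1", "orphan", "radlex",
                      focus_attribute = "RADLEX:Esophagus",
                      target_regions = "9c")  # no 9c-marked concept
  mixed <- classify_batch(b$graph, list(bad, mappings[[1L]]),
                          b$correspondence)
  expect_false(mixed$ok[1L])
  expect_true(is.na(mixed$class[1L]))
  expect_true(mixed$ok[2L])
})
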