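test_that("resolve_regions honours the utility-class threshold", {
  radlex <- build_fixture("radlex")$backend
  loinc <- build_fixture("loinc")$backend
  snomed <- build_fixture("snomed")$backend
  kidney <- fixture_code("kidney")
  sinus <- fixture_code("sinus")

  expect_equal(resolve_regions(radlex, kidney, 1L), "4")   # abdomen attribute
  expect_equal(resolve_regions(loinc, kidney, 1L), character())
  expect_equal(resolve_regions(loinc, kidney, 5L), character())  # class 5 never resolves
  expect_equal(resolve_regions(snomed, sinus, 1L), character())
  expect_equal(resolve_regions(snomed, sinus, 3L), "1")  # lookup-table remedy
  expect_equal(resolve_regions(loinc, fixture_code("liver"), 2L), "4")
  expect_error(resolve_regions(loinc, "UNMAPPED-1"), "not mapped")
})

test_that("decide_alert applies SANOPS semantics over resolved regions", {
  radlex <- build_fixture("radlex")$backend
  fma <- build_fixture("fma")$backend

  same <- decide_alert(radlex, rec(fixture_code("liver")),
                       rec(fixture_code("liver"), "2016-01-01"))
  expect_equal(same$alert, "same")

  sim <- decide_alert(radlex, rec(fixture_code("kidney")),
                      rec(fixture_code("liver"), "2016-01-01"))
  expect_equal(sim$alert, "similar")
  expect_equal(sim$regions_current, "4")

  # FMA esophagus: nothing at the unaltered state, similar once the
  # mixed-relation walk (class 4) is paid for
  esoph_pair <- function(k) decide_alert(fma, rec(fixture_code("chest")),
                                         rec(fixture_code("esoph"),
                                             "2016-01-01"), max_class = k)
  expect_equal(esoph_pair(1L)$alert, "none")
  expect_equal(esoph_pair(4L)$alert, "similar")
})

test_that("decide_alert is symmetric for non-same outcomes", {
  for (term in std_fixture_names()) {
    b <- build_fixture(term)$backend
    codes <- names(b$mappings)
    set.seed(7)
    for (i in 1:10) {
      pair <- sample(codes, 2L)
      for (k in c(1L, 3L)) {
        d1 <- decide_alert(b, rec(pair[1L]), rec(pair[2L], "2016-01-01"), k)
        d2 <- decide_alert(b, rec(pair[2L]), rec(pair[1L], "2016-01-01"), k)
        expect_equal(d1$alert, d2$alert,
                     label = sprintf("%s %s/%s k=%d", term, pair[1L],
                                     pair[2L], k))
      }
    }
  }
})

test_that("the full 35-cell scenario matrix reproduces at max_class = 1", {
  m <- run_scenarios()
  sc <- scenario_table()
  expect_equal(nrow(m), 7L)
  for (term in std_fixture_names()) {
    fired <- m[[term]] %in% c("similar", "proximate")
    expect_equal(fired, sc[[term]], label = paste("column", term))
  }
  # alert types where the narrative states them (rows 1-5)
  expect_equal(unname(unlist(m[1, std_fixture_names()])), rep("similar", 5))
  expect_equal(unname(unlist(m[2, std_fixture_names()])), rep("proximate", 5))
  expect_equal(unname(unlist(m[3, std_fixture_names()])), rep("proximate", 5))
  expect_equal(unname(unlist(m[4, c("loinc_rsna", "radlex")])),
               rep("similar", 2))
  expect_equal(m$radlex[5], "similar")
})

test_that("SANOPS as its own backend fires an appropriate alert in all 7 scenarios", {
  b <- build_fixture("sanops")$backend
  m <- run_scenarios(backends = list(sanops = b))
  sc <- scenario_table()
  expect_true(all(m$sanops %in% c("similar", "proximate")))
  stated <- !is.na(sc$type)
  expect_equal(m$sanops[stated], sc$type[stated])
})

test_that("raising max_class never downgrades an alert", {
  strength <- function(a) match(a, rev(alert_classes()))  # none lowest
  violations <- character()
  for (term in c("loinc", "fma", "snomed")) {  # full sweep in acceptance
    b <- build_fixture(term)$backend
    codes <- names(b$mappings)
    pairs <- expand.grid(cur = codes, pri = codes, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(pairs))) {
      prev_regions <- character()
      prev_strength <- 0L
      for (k in 1:5) {
        rk <- resolve_regions(b, pairs$cur[i], k)
        if (!all(prev_regions %in% rk)) {
          violations <- c(violations, sprintf("%s %s regions k=%d", term,
                                              pairs$cur[i], k))
        }
        prev_regions <- rk
        d <- decide_alert(b, rec(pairs$cur[i]),
                          rec(pairs$pri[i], "2016-01-01"), k)
        s <- strength(d$alert)
        if (s < prev_strength) {
          violations <- c(violations, sprintf("%s %s/%s alert k=%d", term,
                                              pairs$cur[i], pairs$pri[i], k))
        }
        prev_strength <- s
      }
    }
  }
  expect_identical(violations, character())
})

test_that("alert_history ranks by precedence then recency and honours lookback", {
  b <- build_fixture("radlex")$backend
  current <- rec(fixture_code("neck"), "2016-02-01T09:00:00")
  priors <- list(
    rec(fixture_code("head_iv"), "2016-01-20T09:00:00"),   # proximate
    rec(fixture_code("neck"), "2014-01-01T09:00:00"),      # same, old
    rec(fixture_code("esoph"), "2016-01-25T09:00:00"),     # none
    rec(fixture_code("head_noiv"), "2016-01-28T09:00:00")) # proximate, newer
  h <- alert_history(b, current, priors)
  expect_equal(vapply(h, `[[`, character(1), "alert"),
               c("same", "proximate", "proximate", "none"))
  # among equal precedence, most recent prior first
  expect_equal(h[[2L]]$prior$exam_code, fixture_code("head_noiv"))

  expect_equal(alert_history(b, current, list()), list())

  short <- alert_history(b, current, priors, lookback_days = 30)
  expect_false(fixture_code("neck") %in%
                 vapply(short, function(d) d$prior$exam_code, character(1)))

  none_only <- alert_history(b, current, priors[3L])
  expect_equal(length(none_only), 1L)
  expect_equal(none_only[[1L]]$alert, "none")
})

test_that("exam records validate timestamps and histories load from CSV", {
  expect_error(exam_record("p", "s", "C-1", "not-a-date"), "timestamp")
  expect_error(exam_record("p", "s", "", "2016-01-01"), "non-empty")
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,site_id,exam_code,timestamp",
               "p1,sA,X0001-1,2016-01-02T10:00:00",
               "p1,sB,X0003-7,2016-01-05"), csv)
  h <- read_exam_history(csv)
  expect_length(h, 2L)
  expect_s3_class(h[[1L]], "exam_record")
})
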