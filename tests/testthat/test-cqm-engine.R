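# Decision-tree CQM engine: load-time validation, evaluation semantics,
# scorecards.

write_ruleset <- function(doc) {
  path <- withr::local_tempfile(fileext = ".json",
                                .local_envir = parent.frame())
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  path
}

valid_doc <- function() {
  list(
    ruleset_id = "t", version = "1",
    feature_dictionary = list("record.risk_group", "record.hormone_therapy"),
    measures = list(list(
      measure_id = "M1", title = "t", category = "EXPECTED", root = "n1",
      nodes = list(
        n1 = list(field = "record.risk_group", op = "EQ", value = "HIGH",
                  true = "n2", false = "leaf_na"),
        n2 = list(field = "record.hormone_therapy", op = "EXISTS",
                  true = "leaf_pass", false = "leaf_fail"),
        leaf_pass = list(result = "PASS"),
        leaf_fail = list(result = "FAIL"),
        leaf_na = list(result = "NOT_APPLICABLE")))))
}

test_that("a valid tree loads; cycles, dangling branches and typos are rejected", {
  rs <- load_ruleset(write_ruleset(valid_doc()))
  expect_s3_class(rs, "rt_cqm_ruleset")
  expect_length(rs$measures, 1L)

  doc <- valid_doc()
  doc$measures[[1]]$nodes$n2$true <- "n1"  # cycle back to the root
  err <- expect_error(load_ruleset(write_ruleset(doc)),
                      class = "rtqa_ruleset_error")
  expect_match(conditionMessage(err), "cycle")

  doc <- valid_doc()
  doc$measures[[1]]$nodes$n2$true <- "nowhere"
  err <- expect_error(load_ruleset(write_ruleset(doc)),
                      class = "rtqa_ruleset_error")
  expect_match(conditionMessage(err), "does not resolve")

  doc <- valid_doc()
  doc$measures[[1]]$nodes$n1$field <- "record.rsk_group"
  err <- expect_error(load_ruleset(write_ruleset(doc)),
                      class = "rtqa_ruleset_error")
  expect_match(conditionMessage(err), "nearest.*record.risk_group")

  doc <- valid_doc()
  doc$measures[[1]]$nodes$n1$op <- "XOR"
  expect_error(load_ruleset(write_ruleset(doc)), class = "rtqa_ruleset_error")
})

test_that("the two-node hand-traced tree evaluates per the stated semantics", {
  rs <- load_ruleset(write_ruleset(valid_doc()))
  m <- rs$measures$M1

  res <- evaluate_measure(list(record.risk_group = "HIGH",
                               record.hormone_therapy = TRUE), m)
  expect_identical(res$result, "PASS")
  expect_identical(res$score, 1L)
  expect_length(res$path_trace, 3L)  # n1, n2, leaf

  res2 <- evaluate_measure(list(record.risk_group = "LOW"), m)
  expect_identical(res2$result, "NOT_APPLICABLE")
  expect_true(is.na(res2$score))

  # EXISTS never fails on missing: it takes the false branch
  res3 <- evaluate_measure(list(record.risk_group = "HIGH"), m)
  expect_identical(res3$result, "FAIL")
  expect_identical(res3$score, 0L)

  # a non-EXISTS predicate on a missing field halts with NOT_EVALUABLE
  m2 <- m
  m2$nodes$n2 <- list(field = "record.hormone_therapy", op = "EQ",
                      value = TRUE, true = "leaf_pass", false = "leaf_fail")
  res4 <- evaluate_measure(list(record.risk_group = "HIGH"), m2)
  expect_identical(res4$result, "NOT_EVALUABLE")
  expect_identical(res4$missing_fields, "record.hormone_therapy")
  expect_true(is.na(res4$score))
})

test_that("random trees agree with the brute-force evaluator on all assignments", {
  set.seed(1234)
  for (t in 1:12) {
    m <- random_measure(paste0("R", t))
    for (f in feature_assignments(m)) {
      got <- evaluate_measure(f, m)
      want <- oracle_tree_eval(m, f)
      expect_identical(got$result, want,
                       info = paste("tree", t, "features",
                                    paste(names(f), unlist(f),
                                          collapse = ",")))
      # the recorded path replays to the reported leaf
      final <- replay_trace(m, got$path_trace)
      if (got$result == "NOT_EVALUABLE") {
        expect_null(m$nodes[[final]]$result)
      } else {
        expect_identical(m$nodes[[final]]$result, got$result)
      }
    }
  }
})

test_that("scorecards are deterministic byte-for-byte and summaries add up", {
  co <- make_cohort(3, sites = "A", seed = 21)
  rs <- load_ruleset(system.file("extdata", "cqm", "prostate.json",
                                 package = "rtqa"))
  e <- co[[1]]
  sc1 <- score_patient(e$record, e$plan, e$constraint_report, rs)
  sc2 <- score_patient(e$record, e$plan, e$constraint_report, rs)
  expect_identical(jsonlite::serializeJSON(sc1), jsonlite::serializeJSON(sc2))
  expect_identical(sum(unlist(sc1$summary$by_result)),
                   sc1$summary$n_measures)
  expect_identical(sum(unlist(sc1$summary$by_category)),
                   sc1$summary$n_measures)
})

test_that("flipping one feature changes exactly the measures that read it", {
  co <- make_cohort(1, sites = "A", seed = 8)
  e <- co[[1]]
  rs <- load_ruleset(system.file("extdata", "cqm", "prostate.json",
                                 package = "rtqa"))
  base <- score_patient(e$record, e$plan, e$constraint_report, rs)

  rec2 <- e$record
  rec2$encounters$EOT$fields$treatment_completed <-
    !rec2$encounters$EOT$fields$treatment_completed
  flipped <- score_patient(rec2, e$plan, e$constraint_report, rs)

  for (mid in names(base$results)) {
    touched <- any(vapply(rs$measures[[mid]]$nodes, function(n)
      identical(n$field, "record.treatment_completed"), logical(1)))
    same <- identical(base$results[[mid]]$result,
                      flipped$results[[mid]]$result)
    if (touched) expect_false(same, info = mid) else expect_true(same, info = mid)
  }
})

test_that("an empty ruleset yields an empty scorecard with zero counts", {
  doc <- list(ruleset_id = "empty", version = "1",
              feature_dictionary = list("record.x"), measures = list())
  rs <- load_ruleset(write_ruleset(doc))
  co <- make_cohort(1, sites = "A", seed = 2)
  e <- co[[1]]
  sc <- score_patient(e$record, e$plan, e$constraint_report, rs)
  expect_length(sc$results, 0L)
  expect_identical(sc$summary$n_measures, 0L)
  expect_identical(sum(unlist(sc$summary$by_result)), 0L)
})
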