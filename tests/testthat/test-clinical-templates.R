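# Template validation, NCCN derivation, auto-population, narrative
# round-tripping.

test_that("validation flags missing required fields and range violations", {
  r <- make_patient_record("PROSTATE", seed = 1)
  cat <- load_template_catalogue()
  schema <- template_schema("PROSTATE", "CONSULT", cat)

  expect_identical(nrow(validate_record(r, schema, cat)), 0L)

  r_bad <- r
  r_bad$encounters$CONSULT$fields$psa <- -1
  iss <- validate_record(r_bad, schema, cat)
  expect_identical(iss$severity, "ERROR")
  expect_match(iss$message, "psa out of range")

  r_missing <- r
  r_missing$encounters$CONSULT$fields$t_stage <- NULL
  iss2 <- validate_record(r_missing, schema, cat)
  expect_true(any(iss2$severity == "ERROR" & iss2$field == "t_stage"))

  r_opt <- r
  r_opt$encounters$CONSULT$fields$comorbidity <- NULL
  iss3 <- validate_record(r_opt, schema, cat)
  expect_identical(iss3$severity, "WARNING")
  expect_identical(iss3$field, "comorbidity")

  r_vocab <- r
  r_vocab$encounters$CONSULT$fields$t_stage <- "T9"
  iss4 <- validate_record(r_vocab, schema, cat)
  expect_true(any(iss4$severity == "ERROR" & grepl("vocabulary",
                                                   iss4$message)))
  # validation is pure
  expect_identical(validate_record(r_bad, schema, cat),
                   validate_record(r_bad, schema, cat))

  expect_error(template_schema("PROSTATE", "NOPE", cat),
               class = "rtqa_config_error")
})

test_that("NCCN risk matches the published table on the exhaustive cross product", {
  for (t in c("T1c", "T2a", "T2b", "T2c", "T3a"))
    for (gsum in 6:9)
      for (psa in c(5, 15, 25)) {
        gp <- if (gsum <= 7) 3L else 4L
        gs <- as.integer(gsum - gp)
        expect_identical(compute_nccn_risk(t, gp, gs, psa),
                         oracle_nccn(t, gp, gs, psa),
                         info = sprintf("%s %d+%d psa=%g", t, gp, gs, psa))
      }
})

test_that("NCCN risk spot values and domain errors behave as specified", {
  expect_identical(compute_nccn_risk("T1c", 3, 3, 8.0), "LOW")
  expect_identical(compute_nccn_risk("T2b", 3, 4, 12.0), "INTERMEDIATE")
  expect_identical(compute_nccn_risk("T2a", 4, 4, 5.0), "HIGH")
  expect_error(compute_nccn_risk("T2x", 3, 3, 8), class = "rtqa_domain_error")
  expect_error(compute_nccn_risk("T2a", 2, 3, 8), class = "rtqa_domain_error")
  expect_error(compute_nccn_risk("T2a", 3, 6, 8), class = "rtqa_domain_error")
})

test_that("autopopulate copies along the flow map, marks provenance, is idempotent", {
  r <- make_patient_record("PROSTATE", seed = 9)
  r$encounters$EOT$fields$t_stage <- NULL
  r$encounters$EOT$provenance$t_stage <- NULL
  out <- autopopulate(r, "EOT")
  expect_identical(out$encounters$EOT$fields$t_stage,
                   r$encounters$CONSULT$fields$t_stage)
  expect_identical(out$encounters$EOT$provenance$t_stage, "AUTO_POPULATED")

  out2 <- autopopulate(out, "EOT")
  attr(out, "warnings") <- NULL; attr(out2, "warnings") <- NULL
  expect_identical(out, out2)

  # manual edits win over re-population
  out$encounters$EOT$fields$t_stage <- "T3b"
  out$encounters$EOT$provenance$t_stage <- "ENTERED"
  out3 <- autopopulate(out, "EOT")
  expect_identical(out3$encounters$EOT$fields$t_stage, "T3b")

  # missing source: target left absent, warning recorded
  r2 <- r
  r2$encounters$CONSULT$fields$t_stage <- NULL
  out4 <- autopopulate(r2, "EOT")
  expect_null(out4$encounters$EOT$fields$t_stage)
  expect_match(attr(out4, "warnings"), "CONSULT.t_stage", all = FALSE)

  # unknown fields in the flow map are a configuration error
  expect_error(autopopulate(r, "EOT",
                            flows = list(list(site = "PROSTATE",
                                              from = "CONSULT.bogus",
                                              to = "EOT.t_stage"))),
               class = "rtqa_config_error")
})

test_that("render_narrative substitutes values, sentinels absent optionals", {
  r <- make_patient_record("PROSTATE", seed = 3,
                           overrides = list(psa = 8.0))
  expect_identical(render_narrative(r, "PSA was {psa} ng/mL."),
                   "PSA was 8 ng/mL.")
  r$encounters$CONSULT$fields$comorbidity <- NULL
  expect_identical(render_narrative(r, "Comorbidity: {comorbidity}."),
                   "Comorbidity: [not recorded].")
  expect_error(render_narrative(r, "Value {no_such_field}."),
               class = "rtqa_config_error")
  # deterministic
  bp <- read_text(system.file("extdata", "boilerplates",
                              "prostate_consult.txt", package = "rtqa"))
  expect_identical(render_narrative(r, bp), render_narrative(r, bp))
})

test_that("render/extract round trip recovers all fields over random records", {
  bp <- read_text(system.file("extdata", "boilerplates",
                              "prostate_consult.txt", package = "rtqa"))
  for (seed in 1:40) {
    r <- make_patient_record("PROSTATE", seed = seed)
    nar <- render_narrative(r, bp)
    vals <- extract_discrete(nar, bp, record_site = "PROSTATE")
    cf <- r$encounters$CONSULT$fields
    for (nm in names(vals))
      expect_identical(vals[[nm]], cf[[nm]],
                       info = paste("seed", seed, "field", nm))
  }
})

test_that("sentinel values map back to absent on extraction", {
  r <- make_patient_record("PROSTATE", seed = 2)
  r$encounters$CONSULT$fields$comorbidity <- NULL
  bp <- "Age {age}. Comorbidity: {comorbidity}. PSA {psa}."
  vals <- extract_discrete(render_narrative(r, bp), bp,
                           record_site = "PROSTATE")
  expect_false("comorbidity" %in% names(vals))
  expect_identical(vals$psa, r$encounters$CONSULT$fields$psa)
})

test_that("tampered narratives raise a parse error naming a position", {
  r <- make_patient_record("PROSTATE", seed = 4)
  bp <- "Stage {t_stage}. Gleason {gleason_primary}+{gleason_secondary}. PSA {psa} ng/mL."
  nar <- render_narrative(r, bp)
  err <- expect_error(extract_discrete(sub("Gleason.*PSA", "PSA", nar), bp),
                      class = "rtqa_parse_error")
  expect_match(conditionMessage(err), "position [0-9]+")
  expect_error(extract_discrete(paste0(nar, " extra"), bp),
               class = "rtqa_parse_error")
})

test_that("a boilerplate without placeholders extracts an empty map", {
  r <- make_patient_record("PROSTATE", seed = 5)
  bp <- "Nothing discrete here."
  expect_identical(render_narrative(r, bp), bp)
  expect_identical(extract_discrete(bp, bp), list())
})
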