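test_that("imputation fills unreported events and never overwrites reports", {
  schema <- toy_schema()
  models <- list(
    imputation_model("DX_002", -1, c(DX_001 = 0.5)),
    imputation_model("RX_002", 0.3, c(DX_002 = -2)))
  prof <- patient_profile(c(DX_001 = "present", RX_001 = "absent"),
                          severity = "moderate", schema = schema)
  # assume-absent: all unreported coordinates are 0
  va <- impute_missing(prof, schema, models, mode = "assume-absent")
  expect_equal(unname(va[c("DX_001", "RX_001", "DX_002", "RX_002", "PX_001")]),
               c(1, 0, 0, 0, 0))
  # expected: logistic chain in topological order
  ve <- impute_missing(prof, schema, models, mode = "expected")
  expect_equal(unname(ve["DX_002"]), stats::plogis(-1 + 0.5 * 1))
  expect_equal(unname(ve["RX_002"]),
               stats::plogis(0.3 - 2 * stats::plogis(-0.5)))
  expect_equal(unname(ve["DX_001"]), 1)
  expect_equal(unname(ve["RX_001"]), 0)
  # single documented example: intercept -1, one present predictor at 0.5
  m1 <- list(imputation_model("DX_002", -1, c(DX_001 = 0.5)))
  v1 <- impute_missing(prof, schema, m1, mode = "expected")
  expect_equal(unname(v1["DX_002"]), stats::plogis(-0.5), tolerance = 1e-12)
  expect_equal(round(unname(v1["DX_002"]), 4), 0.3775)
})

test_that("fully reported profiles pass through unchanged in both modes", {
  schema <- toy_schema()
  ev <- stats::setNames(rep(c("present", "absent"), c(2, 3)),
                        schema$event_id)
  prof <- patient_profile(ev, severity = "severe", schema = schema)
  models <- list(imputation_model("DX_002", 5, c(DX_001 = 5)))
  expect_equal(impute_missing(prof, schema, models, "expected"),
               impute_missing(prof, schema, models, "assume-absent"))
})

test_that("imputation output is invariant to model storage order", {
  schema <- toy_schema()
  models <- list(
    imputation_model("RX_002", 0.3, c(DX_002 = -2)),
    imputation_model("DX_002", -1, c(DX_001 = 0.5)),
    imputation_model("PX_001", 0.1, c(RX_002 = 1, DX_002 = 1)))
  prof <- patient_profile(c(DX_001 = "present"), severity = "moderate",
                          schema = schema)
  base <- impute_missing(prof, schema, models, "expected")
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_equal(impute_missing(prof, schema, models[perm], "expected"), base)
  }
})

test_that("predicted probabilities match closed-form hand evaluation", {
  kb <- toy_kb_two_drug()
  v <- stats::setNames(c(1, 0, 1, 0, 0), kb$schema$event_id)
  p <- predict_responses(v, kb)
  expect_equal(unname(p["A"]), stats::plogis(0.2 + 0.5), tolerance = 1e-12)
  expect_equal(unname(p["B"]), stats::plogis(-0.1 + 2.0 + 0.3),
               tolerance = 1e-12)
  # all-zero vector: logistic of the intercepts
  z <- stats::setNames(rep(0, 5), kb$schema$event_id)
  pz <- predict_responses(z, kb)
  expect_equal(unname(pz), stats::plogis(c(0.2, -0.1)), tolerance = 1e-12)
  # monotonicity in a positively weighted event
  v2 <- z; v2["RX_001"] <- 1
  expect_gt(predict_responses(v2, kb)["B"], pz["B"])
})

test_that("routing resolves population-specific models and errors when absent", {
  kb <- toy_kb_two_drug()
  kb$subgroups <- list(aa = list(A = toy_model("A", -3, numeric(0),
                                               "subgroup:aa")))
  kb$routing <- data.frame(drug = "A", subgroup = "aa",
                           population_tag = "subgroup:aa",
                           stringsAsFactors = FALSE)
  z <- stats::setNames(rep(0, 5), kb$schema$event_id)
  p_general <- predict_responses(z, kb)
  p_aa <- predict_responses(z, kb, subgroups = "aa")
  expect_equal(unname(p_aa["A"]), stats::plogis(-3))
  expect_equal(unname(p_general["A"]), stats::plogis(0.2))
  expect_equal(p_aa["B"], p_general["B"])
  kb$routing$population_tag <- "subgroup:missing"
  expect_error(predict_responses(z, kb, subgroups = "aa"), "routes drug")
})

test_that("recommendation rules fire in precedence order", {
  # low severity always wins
  r <- recommend(c(A = 0.9, B = 0.8), "low")
  expect_equal(r$branch, "no_antidepressant_low_severity")
  expect_length(r$drugs, 0)
  # 10% floor forces non-drug options
  r2 <- recommend(c(A = 0.10, B = 0.05), "moderate")
  expect_equal(r2$branch, "non_drug_options")
  # 5% tie window recommends either of the top two
  r3 <- recommend(c(A = 0.42, B = 0.39, C = 0.12), "moderate")
  expect_equal(r3$branch, "either_of_two")
  expect_equal(r3$drugs, c("A", "B"))
  # otherwise the single top drug
  r4 <- recommend(c(A = 0.42, B = 0.30), "severe")
  expect_equal(r4$branch, "single_drug")
  expect_equal(r4$drugs, "A")
  expect_error(recommend(numeric(0), "moderate"), "empty")
})

test_that("recommend is deterministic under exact ties", {
  p <- c(B = 0.4, A = 0.4, C = 0.1)
  r1 <- recommend(p, "moderate")
  r2 <- recommend(p[c(2, 1, 3)], "moderate")
  expect_equal(r1$branch, "either_of_two")
  expect_equal(r1$drugs, r2$drugs)
  expect_equal(r1$drugs, c("A", "B"))
})

test_that("a relative floor compares against the baseline rate", {
  p <- c(A = 0.25, B = 0.12)
  abs_r <- recommend(p, "moderate")
  rel_r <- recommend(p, "moderate", relative_floor = TRUE, baseline = 0.2)
  expect_equal(abs_r$branch, "single_drug")
  expect_equal(rel_r$branch, "non_drug_options")  # no drug beats 0.2 by 0.1
})

test_that("zero-coefficient knowledgebases produce empty explanations", {
  kb <- toy_kb_zero()
  prof <- patient_profile(severity = "moderate", schema = kb$schema)
  expl <- explain_recommendation(prof, kb, mode = "assume-absent")
  expect_equal(nrow(expl$presence_flips), 0L)
  expect_equal(nrow(expl$absence_flips), 0L)
})

test_that("explanation lists match an exhaustive flip oracle and are sound", {
  kb <- toy_kb_two_drug()
  prof <- patient_profile(c(DX_001 = "present"), severity = "moderate",
                          schema = kb$schema)
  expl <- explain_recommendation(prof, kb, mode = "assume-absent")
  base <- expl$baseline
  # independent exhaustive flip scan
  flips_presence <- character(0); flips_absence <- character(0)
  for (e in kb$schema$event_id) {
    status <- unname(prof$events[e])
    p2 <- prof
    p2$events[e] <- if (identical(status, "present")) "absent" else "present"
    v <- impute_missing(p2, kb$schema, kb$imputation, "assume-absent")
    rec <- recommend(predict_responses(v, kb), p2$severity)
    changed <- !(identical(rec$branch, base$branch) &&
                   setequal(rec$drugs, base$drugs))
    if (changed) {
      if (identical(status, "present")) {
        flips_absence <- c(flips_absence, e)
      } else {
        flips_presence <- c(flips_presence, e)
      }
    }
  }
  expect_setequal(expl$presence_flips$event_id, flips_presence)
  expect_setequal(expl$absence_flips$event_id, flips_absence)
  # RX_001 carries +2 for B only and must appear among presence flips
  expect_true("RX_001" %in% expl$presence_flips$event_id)
  # soundness: every listed flip, applied, changes the recommendation;
  # flipping twice returns to baseline
  for (e in expl$presence_flips$event_id) {
    p2 <- prof; p2$events[e] <- "present"
    v <- impute_missing(p2, kb$schema, kb$imputation, "assume-absent")
    rec <- recommend(predict_responses(v, kb), p2$severity)
    expect_false(identical(rec$branch, base$branch) &&
                   setequal(rec$drugs, base$drugs))
    p3 <- p2; p3$events[e] <- "absent"
    v3 <- impute_missing(p3, kb$schema, kb$imputation, "assume-absent")
    rec3 <- recommend(predict_responses(v3, kb), p3$severity)
    expect_true(identical(rec3$branch, base$branch) &&
                  setequal(rec3$drugs, base$drugs))
  }
})

test_that("assume-absent mode gives identical advice to all silent patients", {
  kb <- toy_kb_two_drug()
  profs <- list(
    patient_profile(severity = "moderate", schema = kb$schema),
    patient_profile(severity = "moderate", schema = kb$schema))
  recs <- lapply(profs, function(p)
    recommend(predict_responses(
      impute_missing(p, kb$schema, kb$imputation, "assume-absent"), kb),
      p$severity))
  expect_equal(recs[[1]], recs[[2]])
})

test_that("advice documents have the four-section structure", {
  kb <- toy_kb_two_drug()
  prof <- patient_profile(c(DX_001 = "present", RX_001 = "present"),
                          severity = "moderate", schema = kb$schema)
  doc <- render_advice(prof, kb, mode = "assume-absent",
                       links = c(B = "https://example.org/b"))
  expect_s3_class(doc, "advice_document")
  expect_true(all(c("history_summary", "recommendation", "explanation",
                    "information_links", "bar_chart") %in% names(doc)))
  expect_true(doc$recommendation$branch %in%
                c("no_antidepressant_low_severity", "non_drug_options",
                  "either_of_two", "single_drug"))
  # bar chart covers every drug in the kb
  expect_setequal(doc$bar_chart$drug, names(kb$general))
  # relevant reported events carry nonzero coefficients somewhere
  expect_setequal(doc$history_summary$relevant_reported,
                  c("DX_001", "RX_001"))
})

test_that("either-of-two documents name two drugs; non-drug branch has empty link slots", {
  kb <- toy_kb_two_drug()
  # force a tie: no events reported, intercepts 0.2 vs -0.1 -> plogis gap > 5%
  kb$general$A$intercept <- 0.0
  kb$general$B$intercept <- 0.05
  prof <- patient_profile(severity = "moderate", schema = kb$schema)
  doc <- render_advice(prof, kb, mode = "assume-absent")
  expect_equal(doc$recommendation$branch, "either_of_two")
  expect_length(doc$recommendation$drugs, 2)
  lowkb <- toy_kb_two_drug()
  lowkb$general$A$intercept <- -4
  lowkb$general$B$intercept <- -4
  lowkb$general$B$coefficients <- c(RX_001 = 0.1, DX_001 = 0.1)
  doc2 <- render_advice(patient_profile(severity = "severe",
                                        schema = lowkb$schema),
                        lowkb, mode = "assume-absent")
  expect_equal(doc2$recommendation$branch, "non_drug_options")
  expect_length(doc2$information_links, 0)
})

test_that("advice documents survive a JSON round trip", {
  kb <- toy_kb_two_drug()
  prof <- patient_profile(c(DX_001 = "present"), severity = "moderate",
                          schema = kb$schema)
  doc <- render_advice(prof, kb, mode = "assume-absent")
  path <- withr::local_tempfile(fileext = ".json")
  advice_to_json(doc, path)
  doc2 <- advice_from_json(path)
  expect_equal(doc2$recommendation$branch, doc$recommendation$branch)
  expect_equal(doc2$recommendation$drugs, doc$recommendation$drugs)
  expect_equal(doc2$bar_chart$predicted_response,
               doc$bar_chart$predicted_response)
  expect_equal(doc2$explanation$presence_flips$event_id,
               doc$explanation$presence_flips$event_id)
})

test_that("profile validation rejects unknown statuses and events", {
  schema <- toy_schema()
  expect_error(patient_profile(c(DX_001 = "maybe"), "moderate",
                               schema = schema),
               "present/absent/unreported")
  expect_error(patient_profile(c(NOPE = "present"), "moderate",
                               schema = schema),
               "outside the schema")
})
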