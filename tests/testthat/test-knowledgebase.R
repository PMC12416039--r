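test_that("screening ranks a perfect predictor first and drops constants", {
  set.seed(1)
  y <- rbinom(40, 1, 0.5)
  x <- cbind(perfect = y,
             noise1 = rbinom(40, 1, 0.5),
             constant = rep(1L, 40),
             noise2 = rbinom(40, 1, 0.3))
  sel <- safe_screen(x, y, k = 4)
  expect_equal(sel[1], "perfect")
  expect_false("constant" %in% sel)
  expect_warning(safe_screen(matrix(1L, 10, 2,
                                    dimnames = list(NULL, c("a", "b"))),
                             rbinom(10, 1, 0.5)),
                 "constant")
})

test_that("screening ranking equals brute-force univariate scoring", {
  set.seed(2)
  x <- matrix(rbinom(30 * 5, 1, 0.4), 30, 5,
              dimnames = list(NULL, paste0("E", 1:5)))
  y <- rbinom(30, 1, 0.5)
  scores <- oracle_screen_scores(x, y)
  expected <- names(sort(-scores[is.finite(scores)]))
  # tie-break lexicographic: re-sort equal scores by id
  expected <- names(scores)[order(-scores, names(scores))]
  expected <- expected[is.finite(scores[expected])]
  expect_equal(safe_screen(x, y, k = 5), expected)
  expect_equal(safe_screen(x, y, k = 2), expected[1:2])
})

test_that("screening is invariant to column order up to the tie-break", {
  set.seed(3)
  x <- matrix(rbinom(50 * 6, 1, 0.4), 50, 6,
              dimnames = list(NULL, paste0("E", 1:6)))
  y <- rbinom(50, 1, 0.5)
  perm <- sample(ncol(x))
  expect_equal(safe_screen(x, y, k = 6), safe_screen(x[, perm], y, k = 6))
})

test_that("the exact SAFE discard mode never drops the top-ranked predictor", {
  set.seed(4)
  x <- matrix(rbinom(60 * 8, 1, 0.4), 60, 8,
              dimnames = list(NULL, paste0("E", 1:8)))
  y <- as.integer(x[, 1] == 1 | rbinom(60, 1, 0.2) == 1)
  assoc <- safe_screen(x, y, k = 8)
  safe <- safe_screen(x, y, k = 8, method = "safe")
  expect_true(length(safe) <= length(assoc))
  expect_equal(safe[1], assoc[1])
})

test_that("an infinite penalty shrinks everything to the intercept", {
  set.seed(5)
  x <- matrix(rbinom(100 * 4, 1, 0.5), 100, 4,
              dimnames = list(NULL, paste0("E", 1:4)))
  y <- rbinom(100, 1, 0.4)
  fit <- mddaid:::fit_lasso_logistic(x, y, lambda = 10)
  expect_true(all(fit$coefficients == 0))
  expect_equal(stats::plogis(fit$intercept), mean(y), tolerance = 1e-6)
})

test_that("penalized coefficients match an independent coordinate descent", {
  # small problems, fixed penalties, glmnet parametrization
  set.seed(6)
  cases <- list(
    list(n = 6, p = 2, lambda = 0.15),
    list(n = 10, p = 3, lambda = 0.10),
    list(n = 8, p = 2, lambda = 0.20))
  for (cs in cases) {
    x <- matrix(rbinom(cs$n * cs$p, 1, 0.5), cs$n, cs$p,
                dimnames = list(NULL, paste0("E", seq_len(cs$p))))
    y <- rbinom(cs$n, 1, 0.5)
    if (length(unique(y)) < 2) y[1] <- 1 - y[1]
    got <- suppressWarnings(mddaid:::fit_lasso_logistic(x, y, cs$lambda))
    want <- oracle_lasso_logistic_cd(x, y, cs$lambda)
    expect_equal(got$intercept, want$intercept, tolerance = 1e-6)
    expect_equal(unname(got$coefficients), unname(want$coefficients),
                 tolerance = 1e-6)
  }
})

test_that("stability selection input validation", {
  x <- matrix(rbinom(40, 1, 0.5), 20, 2,
              dimnames = list(NULL, c("a", "b")))
  expect_error(fit_lasso_stability(x, rep(1L, 20), "d"), "single-class")
  expect_error(fit_lasso_stability(x, rbinom(20, 1, 0.5), "d",
                                   n_subsets = 1),
               "n_subsets")
})

test_that("retained set shrinks weakly as the retention threshold rises", {
  coh <- planted_cohort(n = 1500, seed = 33)
  fm <- cohort_feature_matrix(coh)
  keep <- safe_screen(fm$x, fm$y, k = 50)
  m <- fit_lasso_stability(fm$x[, keep], fm$y, "sertraline",
                           n_subsets = 20, seed = 2, metrics_folds = 0)
  sizes <- vapply(c(0.25, 0.5, 0.75, 1.0), function(th)
    sum(m$retained_fraction >= th), numeric(1))
  expect_true(all(diff(sizes) <= 0))
  expect_true(all(m$retained_fraction >= 0 & m$retained_fraction <= 1))
})

test_that("AUC equals the exhaustive pair-counting oracle", {
  expect_equal(
    mddaid:::auc_rank(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0)), 0.75)
  set.seed(7)
  for (rep in 1:10) {
    scores <- round(runif(12), 1)  # force some ties
    labels <- rbinom(12, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1] <- 1 - labels[1]
    expect_equal(mddaid:::auc_rank(scores, labels),
                 oracle_auc_pairs(scores, labels))
  }
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  scores <- runif(60)
  labels <- rbinom(60, 1, 0.5)
  expect_equal(
    mddaid:::auc_rank(scores, labels),
    as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                   direction = "<"))))
})

test_that("evaluation metrics behave at the boundaries", {
  m <- toy_model("A", -2.5, c(DX_001 = 5))
  x <- matrix(c(1, 1, 0, 0), 4, 1, dimnames = list(NULL, "DX_001"))
  y <- c(1, 1, 0, 0)
  met <- evaluate_model(m, x, y)
  expect_equal(met$auc, 1.0)
  expect_equal(met$sensitivity, 1.0)
  expect_equal(met$specificity, 1.0)
  expect_gt(met$mcfadden_r2, 0.5)  # near-perfect model
  # null model has McFadden R^2 exactly 0
  null_m <- toy_model("A", stats::qlogis(0.5), numeric(0))
  met0 <- evaluate_model(null_m, x, y)
  expect_equal(met0$mcfadden_r2, 0, tolerance = 1e-10)
  expect_equal(met0$auc, 0.5)
  expect_error(evaluate_model(m, x, rep(1, 4)), "single class")
})

test_that("uninformative scores give AUC near one half at large n", {
  set.seed(9)
  n <- 4000
  scores <- runif(n)
  labels <- rbinom(n, 1, 0.5)
  expect_lt(abs(mddaid:::auc_rank(scores, labels) - 0.5), 0.03)
})

test_that("McFadden R^2 matches a first-principles computation", {
  set.seed(10)
  p <- runif(50, 0.05, 0.95)
  y <- rbinom(50, 1, p)
  met <- mddaid:::compute_metrics(p, y)
  expect_equal(met$mcfadden_r2, oracle_mcfadden(p, y))
})

test_that("knowledgebase JSON round-trip is lossless and validated", {
  kb <- toy_kb_two_drug()
  kb$imputation <- list(
    imputation_model("DX_002", -1, c(DX_001 = 0.5)),
    imputation_model("RX_002", 0.2, c(DX_002 = -0.4)))
  kb$routing <- data.frame(drug = "A", subgroup = "aa",
                           population_tag = "general",
                           stringsAsFactors = FALSE)
  validate_kb(kb)
  path <- withr::local_tempfile(fileext = ".json")
  save_kb(kb, path)
  kb2 <- load_kb(path)
  expect_equal(kb2$schema, kb$schema)
  expect_equal(kb2$general$B$coefficients, kb$general$B$coefficients)
  expect_equal(kb2$general$A$intercept, kb$general$A$intercept)
  expect_equal(kb2$routing, kb$routing)
  expect_equal(length(kb2$imputation), 2L)
  expect_equal(kb2$imputation[[1]]$coefficients, c(DX_001 = 0.5))
})

test_that("schema vocabulary totals validate at the catalog sizes", {
  s <- event_schema(1499)
  kb <- knowledgebase(schema = s, general = list())
  counts <- schema_summary(kb)
  expect_equal(unname(counts["total"]),
               unname(sum(counts[c("DX", "RX", "PX", "ADR")])))
  expect_equal(unname(counts["total"]), 1499L)
})

test_that("tampered knowledgebases are rejected by name", {
  kb <- toy_kb_two_drug()
  kb$routing <- data.frame(drug = "A", subgroup = "aa",
                           population_tag = "subgroup:missing",
                           stringsAsFactors = FALSE)
  expect_error(validate_kb(kb), "routing")
  kb2 <- toy_kb_two_drug()
  kb2$version <- "9.9"
  expect_error(validate_kb(kb2), "version")
  path <- withr::local_tempfile(fileext = ".json")
  kb3 <- toy_kb_two_drug()
  save_kb(kb3, path)
  doc <- jsonlite::read_json(path)
  doc$version <- "0.0"
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  expect_error(load_kb(path), "version")
})

test_that("cyclic imputation models are rejected at validation time", {
  kb <- toy_kb_two_drug()
  kb$imputation <- list(
    imputation_model("DX_001", 0, c(DX_002 = 1)),
    imputation_model("DX_002", 0, c(DX_001 = 1)))
  expect_error(validate_kb(kb), "cyclic")
  expect_error(imputation_model("DX_001", 0, c(DX_001 = 1)), "itself")
})
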