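# Per-drug response models: association screening, L1-penalized logistic
# fits with stability selection over random subsamples, evaluation metrics,
# and a versioned JSON knowledgebase.

KB_VERSION <- "1.0"

#' Build a binary patient-by-event feature matrix
#'
#' Pivots long-format medical-history event records into the 0/1 design
#' matrix the response models are fit on, with one row per episode.
#'
#' @param events data.frame with `patient_id` and `code` (event id) columns.
#' @param episodes episode data.frame from [build_episodes()] (uses
#'   `patient_id` and `response`).
#' @param schema event schema data.frame (`event_id`, `vocabulary`); defines
#'   the column set and order.
#' @return list with `x` (0/1 matrix, rows = episodes, columns = schema
#'   events), `y` (integer response vector), `patient_id`.
#' @export
feature_matrix <- function(events, episodes, schema) {
  x <- matrix(0L, nrow(episodes), nrow(schema),
              dimnames = list(episodes$patient_id, schema$event_id))
  keep <- events$patient_id %in% episodes$patient_id &
    events$code %in% schema$event_id
  ev <- events[keep, , drop = FALSE]
  x[cbind(match(ev$patient_id, episodes$patient_id),
          match(ev$code, schema$event_id))] <- 1L
  list(x = x, y = as.integer(episodes$response),
       patient_id = episodes$patient_id)
}

#' Screen candidate events down to the most relevant k
#'
#' Safe screening before a penalized fit: each binary column is scored by its
#' absolute centered inner product with the centered outcome, normalized by
#' the column norm (the magnitude of the univariate association that the
#' SAFE discard test for the lasso bounds). The top `k` columns are kept.
#' Zero-variance columns are always discarded; ties break by event id.
#'
#' @param x 0/1 matrix with named columns.
#' @param y binary outcome vector.
#' @param k number of events to keep (default 1000).
#' @param method `"association"` (default, rank by normalized association) or
#'   `"safe"` (apply the exact SAFE discard inequality
#'   `|x_j'y| < lambda - ||x_j|| ||y|| (lambda_max - lambda)/lambda_max` at
#'   penalty `lambda`, then rank the survivors; at most `k` returned).
#' @param lambda penalty for `method = "safe"`; defaults to
#'   `0.5 * lambda_max`.
#' @return character vector of selected event ids, ranked most relevant
#'   first.
#' @export
safe_screen <- function(x, y, k = 1000L, method = c("association", "safe"),
                        lambda = NULL) {
  method <- match.arg(method)
  stopifnot(k >= 1, nrow(x) == length(y))
  xc <- scale(x, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  norms <- sqrt(colSums(xc^2))
  ip <- abs(drop(crossprod(xc, yc)))
  ok <- norms > 0
  if (!any(ok)) {
    warning("all columns are constant; nothing to screen")
    return(character(0))
  }
  score <- ifelse(ok, ip / pmax(norms, .Machine$double.eps), -Inf)
  if (method == "safe") {
    lambda_max <- max(ip[ok])
    lambda <- lambda %||% (0.5 * lambda_max)
    ynorm <- sqrt(sum(yc^2))
    keep <- ok & ip >= lambda - norms * ynorm * (lambda_max - lambda) / lambda_max
    score[!keep] <- -Inf
    ok <- keep
  }
  ids <- colnames(x)[ok][order(-score[ok], colnames(x)[ok])]
  utils::head(ids, k)
}

# L1-penalized logistic fit at a fixed penalty. glmnet minimizes
# -(1/n) loglik + lambda ||beta||_1 (unstandardized columns, intercept free);
# a descending warm-start path ending at the target penalty is supplied
# because single-lambda calls are poorly conditioned.
fit_lasso_logistic <- function(x, y, lambda) {
  path <- sort(unique(c(lambda * 50, lambda * 10, lambda * 3, lambda)),
               decreasing = TRUE)
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                        lambda = path, standardize = FALSE, thresh = 1e-12)
  co <- as.matrix(stats::coef(fit, s = lambda, exact = TRUE, x = x, y = y))
  list(intercept = co[1, 1],
       coefficients = stats::setNames(co[-1, 1], rownames(co)[-1]))
}

#' Fit a per-drug response model with stability selection
#'
#' The L1 penalty is chosen by cross-validated binomial deviance on the full
#' data, then the penalized fit is repeated on random subsamples; an event is
#' retained if its coefficient is nonzero in at least `retain_threshold` of
#' the subsamples. Final coefficients come from an unpenalized logistic refit
#' on the retained set (falling back to a lightly ridged fit when the refit
#' does not converge, e.g. under separation).
#'
#' @param x screened 0/1 feature matrix.
#' @param y binary response vector (both classes must be present).
#' @param drug drug name recorded on the model.
#' @param n_subsets number of random subsamples (default 40).
#' @param subsample_fraction fraction of rows drawn without replacement per
#'   subsample (default 0.8).
#' @param retain_threshold minimum fraction of subsamples in which an event
#'   must be selected (default 0.5).
#' @param seed master seed; subsample seeds are derived by fixed offsets.
#' @param lambda_choice `"1se"` (default; the sparsest penalty within one
#'   standard error of the minimum cross-validated deviance, the
#'   conventional pairing with stability selection) or `"min"`.
#' @param population_tag `"general"` or `"subgroup:<name>"`.
#' @param metrics_folds folds for the cross-validated metrics stored on the
#'   model (default 5); set to 0 to skip metric computation.
#' @return object of class `drug_model`: `drug`, `intercept`,
#'   `coefficients` (sparse named vector over retained events),
#'   `retained_fraction` (over all screened events), `metrics`
#'   (`auc`, `sensitivity`, `specificity`, `mcfadden_r2`), `population_tag`,
#'   `settings`.
#' @export
fit_lasso_stability <- function(x, y, drug,
                                n_subsets = 40L,
                                subsample_fraction = 0.8,
                                retain_threshold = 0.5,
                                seed = 1L,
                                lambda_choice = c("1se", "min"),
                                population_tag = "general",
                                metrics_folds = 5L) {
  lambda_choice <- match.arg(lambda_choice)
  y <- as.integer(y)
  if (length(unique(y)) < 2) {
    stop("single-class outcome: cannot fit a response model for ", drug)
  }
  if (n_subsets < 2) stop("n_subsets must be at least 2")
  stopifnot(subsample_fraction > 0, subsample_fraction <= 1,
            retain_threshold >= 0, retain_threshold <= 1)
  n <- nrow(x)

  set.seed(seed)
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                          type.measure = "deviance", nfolds = 5,
                          standardize = FALSE)
  lambda <- if (lambda_choice == "min") cv$lambda.min else cv$lambda.1se

  m <- ncol(x)
  nonzero <- matrix(FALSE, n_subsets, m, dimnames = list(NULL, colnames(x)))
  n_sub <- max(2L, floor(subsample_fraction * n))
  for (b in seq_len(n_subsets)) {
    set.seed(seed + b)
    rows <- sample.int(n, n_sub)
    if (length(unique(y[rows])) < 2) next
    fit <- glmnet::glmnet(x[rows, , drop = FALSE], y[rows],
                          family = "binomial", alpha = 1,
                          lambda = cv$lambda, standardize = FALSE)
    co <- as.matrix(stats::coef(fit, s = lambda))[-1, 1]
    nonzero[b, names(co)] <- co != 0
  }
  retained_fraction <- colMeans(nonzero)
  retained <- names(retained_fraction)[retained_fraction >= retain_threshold]

  refit <- refit_logistic(x[, retained, drop = FALSE], y)
  model <- structure(
    list(drug = drug, intercept = refit$intercept,
         coefficients = refit$coefficients,
         retained_fraction = retained_fraction,
         metrics = NULL, population_tag = population_tag,
         settings = list(lambda = lambda, n_subsets = n_subsets,
                         subsample_fraction = subsample_fraction,
                         retain_threshold = retain_threshold, seed = seed)),
    class = "drug_model")
  if (metrics_folds > 0) {
    model$metrics <- cv_model_metrics(x, y, retained, metrics_folds,
                                      seed = seed)
  }
  model
}

# Unpenalized logistic refit on the retained columns; ridge fallback with a
# tiny penalty when glm fails to converge (separation).
refit_logistic <- function(x, y) {
  if (ncol(x) == 0) {
    p <- mean(y)
    return(list(intercept = stats::qlogis(min(max(p, 1e-12), 1 - 1e-12)),
                coefficients = stats::setNames(numeric(0), character(0))))
  }
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, x), y, family = stats::binomial()))
  if (fit$converged && all(abs(fit$coefficients) < 30)) {
    co <- fit$coefficients
    return(list(intercept = co[1],
                coefficients = stats::setNames(co[-1], colnames(x))))
  }
  rf <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                       lambda = c(1, 0.1, 1e-3), standardize = FALSE)
  co <- as.matrix(stats::coef(rf, s = 1e-3))
  list(intercept = co[1, 1],
       coefficients = stats::setNames(co[-1, 1], colnames(x)))
}

# K-fold cross-validated metrics for the stability-selected event set:
# per fold, the retained set is refit unpenalized on the training rows and
# scored on the held-out rows; metrics are computed on pooled out-of-fold
# predictions, with the null likelihood from the pooled training-fold means.
cv_model_metrics <- function(x, y, retained, folds = 5L, seed = 1L) {
  set.seed(seed + 1000L)
  fold <- sample(rep_len(seq_len(folds), nrow(x)))
  pred <- numeric(nrow(x))
  null_pred <- numeric(nrow(x))
  for (k in seq_len(folds)) {
    test <- fold == k
    refit <- refit_logistic(x[!test, retained, drop = FALSE], y[!test])
    eta <- refit$intercept +
      drop(x[test, retained, drop = FALSE] %*% refit$coefficients)
    pred[test] <- stats::plogis(eta)
    null_pred[test] <- mean(y[!test])
  }
  compute_metrics(pred, y, null_prob = null_pred)
}

# Rank-statistic AUC over all response/non-response pairs; ties count 1/2.
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUC undefined: outcome has a single class")
  }
  n1 <- as.numeric(n1); n0 <- as.numeric(n0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

bernoulli_loglik <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

compute_metrics <- function(pred, y, threshold = 0.5, null_prob = NULL) {
  null_prob <- null_prob %||% mean(y)
  ll <- bernoulli_loglik(pred, y)
  ll0 <- bernoulli_loglik(rep_len(null_prob, length(y)), y)
  hard <- as.integer(pred > threshold)
  list(auc = auc_rank(pred, y),
       sensitivity = if (sum(y == 1)) mean(hard[y == 1] == 1) else NA_real_,
       specificity = if (sum(y == 0)) mean(hard[y == 0] == 0) else NA_real_,
       mcfadden_r2 = 1 - ll / ll0)
}

#' Evaluate a drug model on a feature matrix
#'
#' In-sample evaluation: AUC by the rank statistic over all
#' response/non-response pairs (ties count one half), sensitivity and
#' specificity at a 0.5 probability threshold, and McFadden's pseudo-R²
#' (1 − ℓ_model/ℓ_null with the null the intercept-only fit on the same
#' rows). Models fit through [fit_lasso_stability()] additionally carry
#' 5-fold cross-validated versions of these metrics.
#'
#' @param model a `drug_model`.
#' @param x 0/1 feature matrix whose columns cover the model's coefficients.
#' @param y binary response vector.
#' @return list with `auc`, `sensitivity`, `specificity`, `mcfadden_r2`.
#' @export
evaluate_model <- function(model, x, y) {
  missing_cols <- setdiff(names(model$coefficients), colnames(x))
  if (length(missing_cols)) {
    stop("feature matrix lacks model columns: ",
         paste(missing_cols, collapse = ", "))
  }
  pred <- predict_drug_model(model, x)
  compute_metrics(pred, as.integer(y))
}

# Predicted response probabilities from a sparse logistic drug model.
predict_drug_model <- function(model, x) {
  beta <- model$coefficients
  eta <- rep(model$intercept, nrow(x)) +
    if (length(beta)) drop(x[, names(beta), drop = FALSE] %*% beta) else 0
  stats::plogis(eta)
}

#' Assemble a knowledgebase
#'
#' @param schema event schema data.frame (`event_id`, `vocabulary`).
#' @param general named list of `drug_model`s (the general-population models).
#' @param subgroups named list (subgroup name → named list of `drug_model`s).
#' @param imputation list of imputation models (see [imputation_model()]);
#'   must be acyclic.
#' @param routing data.frame (`drug`, `subgroup`, `population_tag`); empty
#'   default routes every drug to the general model.
#' @param provenance list of free-form provenance metadata (seeds, settings).
#' @return object of class `knowledgebase`.
#' @export
knowledgebase <- function(schema, general, subgroups = list(),
                          imputation = list(), routing = NULL,
                          provenance = list()) {
  kb <- structure(
    list(version = KB_VERSION, schema = schema, general = general,
         subgroups = subgroups, imputation = imputation,
         routing = routing %||% data.frame(
           drug = character(0), subgroup = character(0),
           population_tag = character(0), stringsAsFactors = FALSE),
         provenance = provenance),
    class = "knowledgebase")
  validate_kb(kb)
  kb
}

#' Validate knowledgebase invariants
#'
#' Checks the version, the schema (unique event ids, vocabulary totals
#' consistent), that every model coefficient references a schema event, that
#' routing targets exist, and that the imputation models form an acyclic
#' dependency graph.
#'
#' @param kb a `knowledgebase`.
#' @return the knowledgebase, invisibly; errors name the offending field.
#' @export
validate_kb <- function(kb) {
  if (!identical(kb$version, KB_VERSION)) {
    stop("knowledgebase validation failed: unknown version '", kb$version, "'")
  }
  if (anyDuplicated(kb$schema$event_id)) {
    stop("knowledgebase validation failed: schema has duplicate event ids")
  }
  counts <- table(kb$schema$vocabulary)
  if (sum(counts) != nrow(kb$schema)) {
    stop("knowledgebase validation failed: schema vocabulary counts inconsistent")
  }
  check_model <- function(m, where) {
    bad <- setdiff(names(m$coefficients), kb$schema$event_id)
    if (length(bad)) {
      stop("knowledgebase validation failed: ", where,
           " references unknown events: ", paste(bad, collapse = ", "))
    }
  }
  for (d in names(kb$general)) check_model(kb$general[[d]], paste0("general$", d))
  for (s in names(kb$subgroups)) {
    for (d in names(kb$subgroups[[s]])) {
      check_model(kb$subgroups[[s]][[d]], paste0("subgroups$", s, "$", d))
    }
  }
  if (nrow(kb$routing)) {
    for (i in seq_len(nrow(kb$routing))) {
      tag <- kb$routing$population_tag[i]
      drug <- kb$routing$drug[i]
      ok <- if (tag == "general") {
        drug %in% names(kb$general)
      } else if (startsWith(tag, "subgroup:")) {
        sg <- sub("^subgroup:", "", tag)
        drug %in% names(kb$subgroups[[sg]] %||% list())
      } else FALSE
      if (!ok) {
        stop("knowledgebase validation failed: routing entry (", drug, ", ",
             kb$routing$subgroup[i], ") targets missing model '", tag, "'")
      }
    }
  }
  if (length(kb$imputation)) check_imputation_acyclic(kb$imputation)
  invisible(kb)
}

#' Summarize the event schema by vocabulary
#'
#' @param kb a `knowledgebase` (or an event schema data.frame).
#' @return named integer vector of per-vocabulary counts plus `total`.
#' @export
schema_summary <- function(kb) {
  schema <- if (inherits(kb, "knowledgebase")) kb$schema else kb
  counts <- table(factor(schema$vocabulary, levels = c("DX", "RX", "PX", "ADR")))
  c(stats::setNames(as.integer(counts), names(counts)),
    total = nrow(schema))
}

model_to_list <- function(m) {
  list(drug = m$drug, intercept = m$intercept,
       coefficients = as.list(m$coefficients),
       retained_fraction = as.list(m$retained_fraction),
       metrics = m$metrics, population_tag = m$population_tag,
       settings = m$settings)
}

model_from_list <- function(l) {
  structure(
    list(drug = l$drug, intercept = l$intercept,
         coefficients = unlist_named(l$coefficients),
         retained_fraction = unlist_named(l$retained_fraction),
         metrics = l$metrics, population_tag = l$population_tag,
         settings = l$settings),
    class = "drug_model")
}

unlist_named <- function(l) {
  if (length(l) == 0) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(vapply(l, as.numeric, numeric(1)), names(l))
}

#' Save / load a knowledgebase as JSON
#'
#' The JSON round-trip is lossless; [load_kb()] re-validates all invariants
#' and rejects unknown versions.
#'
#' @param kb a `knowledgebase`.
#' @param path file path for the JSON document.
#' @return `save_kb` returns `path` invisibly; `load_kb` returns the
#'   `knowledgebase`.
#' @export
save_kb <- function(kb, path) {
  validate_kb(kb)
  doc <- list(
    version = kb$version,
    schema = kb$schema,
    general = lapply(kb$general, model_to_list),
    subgroups = lapply(kb$subgroups, function(s) lapply(s, model_to_list)),
    imputation = lapply(kb$imputation, function(m)
      list(target = m$target, intercept = m$intercept,
           coefficients = as.list(m$coefficients))),
    routing = kb$routing,
    provenance = kb$provenance)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_kb
#' @export
load_kb <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$version, KB_VERSION)) {
    stop("cannot load knowledgebase: unknown version '",
         doc$version %||% "<missing>", "'")
  }
  schema <- data.frame(
    event_id = vapply(doc$schema, function(r) r$event_id, character(1)),
    vocabulary = vapply(doc$schema, function(r) r$vocabulary, character(1)),
    stringsAsFactors = FALSE)
  routing <- if (length(doc$routing)) {
    data.frame(
      drug = vapply(doc$routing, function(r) r$drug, character(1)),
      subgroup = vapply(doc$routing, function(r) r$subgroup, character(1)),
      population_tag = vapply(doc$routing, function(r) r$population_tag,
                              character(1)),
      stringsAsFactors = FALSE)
  } else NULL
  imputation <- lapply(doc$imputation, function(m)
    imputation_model(m$target, m$intercept, unlist_named(m$coefficients)))
  kb <- knowledgebase(
    schema = schema,
    general = lapply(doc$general, model_from_list),
    subgroups = lapply(doc$subgroups, function(s) lapply(s, model_from_list)),
    imputation = imputation,
    routing = routing,
    provenance = doc$provenance)
  kb
}

#' Build a knowledgebase from a cohort
#'
#' Convenience pipeline: screen candidate events, fit one stability-selected
#' model per drug, and assemble the knowledgebase with provenance.
#'
#' @param cohort output of [generate_cohort()], or a list with `events`,
#'   `dispensings`, `schema`.
#' @param drugs drugs to model; default all drugs with episodes.
#' @param windows an [episode_windows()].
#' @param screen_k events kept by screening per drug (default 1000).
#' @param seed master seed.
#' @param ... passed to [fit_lasso_stability()].
#' @return a `knowledgebase`.
#' @export
build_kb <- function(cohort, drugs = NULL, windows = episode_windows(),
                     screen_k = 1000L, seed = 1L, ...) {
  episodes <- build_episodes(cohort$dispensings, windows)
  # first episode per patient indexes the cohort outcome
  episodes <- episodes[!duplicated(episodes$patient_id), , drop = FALSE]
  drugs <- drugs %||% sort(unique(episodes$index_drug))
  general <- list()
  for (d in drugs) {
    ep_d <- episodes[episodes$index_drug == d, , drop = FALSE]
    fm <- feature_matrix(cohort$events, ep_d, cohort$schema)
    keep <- safe_screen(fm$x, fm$y, k = screen_k)
    general[[d]] <- fit_lasso_stability(
      fm$x[, keep, drop = FALSE], fm$y, drug = d, seed = seed, ...)
  }
  knowledgebase(
    schema = cohort$schema, general = general,
    provenance = list(seed = seed, screen_k = screen_k,
                      windows = unclass(windows),
                      created = "build_kb"))
}
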