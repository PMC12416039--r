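# Subgroup bias audit: compare the general model against a subgroup-specific
# refit on held-out subgroup data, and update the knowledgebase routing.
#
# A model can be accurate on average yet systematically worse in a minority
# subgroup. The audit fits a population-specific model (same screening +
# stability-selection pipeline, restricted to subgroup rows), compares
# McFadden pseudo-R-squared of both models on out-of-fold subgroup
# predictions, and routes the subgroup to whichever model explains more.

#' Audit one drug's model on a subgroup
#'
#' @param kb a `knowledgebase` holding the general model for `drug`.
#' @param x 0/1 feature matrix of the subgroup's episodes for this drug.
#' @param y binary response vector for those episodes.
#' @param drug drug name.
#' @param subgroup subgroup name (e.g. `"african_american"`).
#' @param min_cases minimum number of treatment episodes required; below
#'   this the drug is skipped with status `"insufficient_cases"` (default 68).
#' @param decision_margin the held-out R² improvement the specific model
#'   must exceed to be adopted; the default 0.05 (five pseudo-R² points)
#'   keeps noise-level improvements from spawning subgroup models.
#' @param folds cross-validation folds for the held-out comparison.
#' @param screen_k events kept when screening the subgroup fit.
#' @param n_subsets stability-selection subsamples for the subgroup fit.
#' @param seed seed for fold assignment and subgroup fits.
#' @param fit_final when the decision is `population_specific`, also fit the
#'   specific model on all subgroup rows and attach it as `$model`, so
#'   [apply_routing()] can store it (default TRUE).
#' @return object of class `audit_result`: `drug`, `subgroup`, `r2_general`,
#'   `r2_specific`, `n_trials`, `n_response`, `margin`, `decision`
#'   (`"general"` or `"population_specific"`), `status` (`"ok"` or
#'   `"insufficient_cases"`), and optionally `model`.
#' @export
audit_drug <- function(kb, x, y, drug, subgroup,
                       min_cases = 68L, decision_margin = 0.05,
                       folds = 5L, screen_k = 1000L, n_subsets = 40L,
                       seed = 1L, fit_final = TRUE) {
  if (!drug %in% names(kb$general)) {
    stop("drug '", drug, "' is absent from the knowledgebase")
  }
  y <- as.integer(y)
  n <- nrow(x)
  res <- list(drug = drug, subgroup = subgroup,
              r2_general = NA_real_, r2_specific = NA_real_,
              n_trials = n, n_response = sum(y),
              margin = NA_real_, decision = NA_character_, status = "ok")
  if (n < min_cases) {
    res$status <- "insufficient_cases"
    res$decision <- "general"
    return(structure(res, class = "audit_result"))
  }

  general <- kb$general[[drug]]
  set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), n))
  pred_g <- predict_drug_model(general, x)
  pred_s <- numeric(n)
  null_pred <- numeric(n)
  for (k in seq_len(folds)) {
    test <- fold == k
    xt <- x[!test, , drop = FALSE]
    yt <- y[!test]
    keep <- safe_screen(xt, yt, k = screen_k)
    spec <- fit_lasso_stability(
      xt[, keep, drop = FALSE], yt, drug = drug,
      n_subsets = n_subsets, seed = seed + k,
      population_tag = paste0("subgroup:", subgroup), metrics_folds = 0)
    pred_s[test] <- predict_drug_model(spec, x[test, , drop = FALSE])
    null_pred[test] <- mean(yt)
  }
  ll0 <- bernoulli_loglik(null_pred, y)
  res$r2_general <- 1 - bernoulli_loglik(pred_g, y) / ll0
  res$r2_specific <- 1 - bernoulli_loglik(pred_s, y) / ll0
  res$margin <- res$r2_specific - res$r2_general
  res$decision <- if (res$margin > decision_margin) "population_specific"
                  else "general"
  if (fit_final && res$decision == "population_specific") {
    keep <- safe_screen(x, y, k = screen_k)
    res$model <- fit_lasso_stability(
      x[, keep, drop = FALSE], y, drug = drug,
      n_subsets = n_subsets, seed = seed,
      population_tag = paste0("subgroup:", subgroup), metrics_folds = 0)
  }
  structure(res, class = "audit_result")
}

#' Decide between general and population-specific R² values
#'
#' The comparison rule of the audit in isolation: adopt the
#' population-specific model only when its held-out McFadden R² exceeds the
#' general model's by more than `decision_margin` (ties keep the parsimonious
#' general default).
#'
#' @param r2_general,r2_specific held-out McFadden R² of the two models.
#' @param decision_margin required improvement (default 0.05).
#' @return `"population_specific"` or `"general"`.
#' @export
#' @examples
#' audit_decision(0.09, 0.30)  # large subgroup improvement
#' audit_decision(0.23, 0.19)  # general model ahead
audit_decision <- function(r2_general, r2_specific, decision_margin = 0.05) {
  if (r2_specific - r2_general > decision_margin) "population_specific"
  else "general"
}

#' Apply audit results to the knowledgebase routing table
#'
#' Each `population_specific` result routes (drug, subgroup) to the subgroup
#' model; `general` results route explicitly to the general model; unaudited
#' drugs keep their default general routing. Applying the same results twice
#' leaves the knowledgebase unchanged.
#'
#' @param kb a `knowledgebase`; subgroup models referenced by
#'   `population_specific` decisions must already be stored under
#'   `kb$subgroups`.
#' @param results list of `audit_result`s (or a single one).
#' @return the updated `knowledgebase`.
#' @export
apply_routing <- function(kb, results) {
  if (inherits(results, "audit_result")) results <- list(results)
  if (length(results) == 0) return(kb)
  key <- vapply(results, function(r) paste(r$drug, r$subgroup), character(1))
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    decisions <- vapply(results, function(r) r$decision %||% NA_character_,
                        character(1))
    for (k in unique(key[dup])) {
      if (length(unique(decisions[key == k])) > 1) {
        stop("conflicting audit results for (", k, ")")
      }
    }
    results <- results[!duplicated(key)]
  }
  routing <- kb$routing
  for (r in results) {
    tag <- if (identical(r$decision, "population_specific")) {
      paste0("subgroup:", r$subgroup)
    } else "general"
    if (tag != "general" && !is.null(r$model)) {
      if (is.null(kb$subgroups[[r$subgroup]])) kb$subgroups[[r$subgroup]] <- list()
      kb$subgroups[[r$subgroup]][[r$drug]] <- r$model
    }
    hit <- routing$drug == r$drug & routing$subgroup == r$subgroup
    if (any(hit)) {
      routing$population_tag[hit] <- tag
    } else {
      routing <- rbind(routing, data.frame(
        drug = r$drug, subgroup = r$subgroup, population_tag = tag,
        stringsAsFactors = FALSE))
    }
  }
  kb$routing <- routing
  validate_kb(kb)
  kb
}

#' Format audit results as a report table
#'
#' @param results list of `audit_result`s.
#' @return data.frame with one row per audited drug (trials, responses, the
#'   two R² values as percentages, margin, decision, status).
#' @export
audit_report <- function(results) {
  if (inherits(results, "audit_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r) data.frame(
    drug = r$drug, subgroup = r$subgroup,
    n_trials = r$n_trials, n_response = r$n_response,
    r2_general_pct = round_half_up(100 * r$r2_general, 0),
    r2_specific_pct = round_half_up(100 * r$r2_specific, 0),
    margin = r$margin, decision = r$decision, status = r$status,
    stringsAsFactors = FALSE)))
}
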