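# Rule-based, explained treatment advice.
#
# Given a patient's reported medical-history events, the advice pipeline
# (1) completes the event vector — either assuming unmentioned events absent
# or imputing them through a network of linked logistic regressions,
# (2) predicts the probability of response to every antidepressant via the
# routed knowledgebase model, (3) applies fixed recommendation rules
# (severity gate, 10% response floor, 5% top-two tie window), (4) lists the
# single event flips that would change the recommendation, and (5) renders a
# four-section advice document from pre-set, non-generative templates.

#' A patient profile
#'
#' @param events named character vector over schema event ids with values
#'   `"present"`, `"absent"`, or `"unreported"`; events not mentioned default
#'   to `"unreported"`.
#' @param severity depression severity, one of `"low"`, `"moderate"`,
#'   `"severe"`; must be set before advising.
#' @param subgroups character vector of subgroup tags used for model routing.
#' @param schema optional event schema to validate event ids against.
#' @return object of class `patient_profile`.
#' @export
patient_profile <- function(events = character(0),
                            severity = c("low", "moderate", "severe"),
                            subgroups = character(0),
                            schema = NULL) {
  severity <- match.arg(severity)
  if (length(events)) {
    bad_val <- setdiff(unique(events), c("present", "absent", "unreported"))
    if (length(bad_val)) {
      stop("event status must be present/absent/unreported, got: ",
           paste(bad_val, collapse = ", "))
    }
    if (is.null(names(events)) || any(names(events) == "")) {
      stop("events must be a named vector keyed by event id")
    }
    if (!is.null(schema)) {
      bad <- setdiff(names(events), schema$event_id)
      if (length(bad)) {
        stop("profile references events outside the schema: ",
             paste(bad, collapse = ", "))
      }
    }
  }
  structure(list(events = events, severity = severity, subgroups = subgroups),
            class = "patient_profile")
}

#' An imputation model for one medical-history event
#'
#' One node of the linked-regression (structured-equation) network: a
#' logistic regression predicting the target event from other events.
#'
#' @param target event id being imputed.
#' @param intercept intercept of the logistic model.
#' @param coefficients named numeric vector over predictor event ids; must
#'   not include the target itself.
#' @return object of class `imputation_model`.
#' @export
imputation_model <- function(target, intercept, coefficients = numeric(0)) {
  if (target %in% names(coefficients)) {
    stop("imputation model for ", target, " may not predict from itself")
  }
  structure(list(target = target, intercept = intercept,
                 coefficients = coefficients),
            class = "imputation_model")
}

# Errors (at load/validation time, not at imputation time) if the imputation
# models' dependency graph has a cycle; returns the topological order.
check_imputation_acyclic <- function(models) {
  targets <- vapply(models, function(m) m$target, character(1))
  if (anyDuplicated(targets)) {
    stop("duplicate imputation models for: ",
         paste(unique(targets[duplicated(targets)]), collapse = ", "))
  }
  from <- character(0); to <- character(0)
  for (m in models) {
    preds <- intersect(names(m$coefficients), targets)
    from <- c(from, preds)
    to <- c(to, rep(m$target, length(preds)))
  }
  ord <- topo_order(targets, from, to)
  if (is.null(ord)) {
    stop("imputation models form a cyclic dependency graph")
  }
  ord
}

#' Complete a patient's event vector
#'
#' Reported events map to 1 (`present`) or 0 (`absent`) and are never
#' overwritten. Unreported events are filled either with 0
#' (`mode = "assume-absent"`, matching a deployed prototype that treats
#' unmentioned events as not having occurred) or, in `mode = "expected"`,
#' with the logistic expectation from the imputation network, evaluated in
#' topological order so upstream imputations feed downstream ones.
#' Unreported events with no imputation model are 0 in both modes.
#'
#' @param profile a [patient_profile()].
#' @param schema event schema data.frame defining the vector's coordinates.
#' @param imputation list of [imputation_model()]s (acyclic).
#' @param mode `"expected"` or `"assume-absent"`.
#' @return named numeric vector in \[0, 1\] over all schema events.
#' @export
impute_missing <- function(profile, schema, imputation = list(),
                           mode = c("expected", "assume-absent")) {
  mode <- match.arg(mode)
  v <- stats::setNames(rep(0, nrow(schema)), schema$event_id)
  reported <- names(profile$events)[profile$events != "unreported"]
  v[reported] <- as.numeric(profile$events[reported] == "present")
  if (mode == "assume-absent" || length(imputation) == 0) return(v)
  ord <- check_imputation_acyclic(imputation)
  targets <- vapply(imputation, function(m) m$target, character(1))
  for (t in ord) {
    if (t %in% reported) next          # never overwrite reported events
    m <- imputation[[match(t, targets)]]
    eta <- m$intercept +
      sum(m$coefficients * v[names(m$coefficients)])
    v[t] <- stats::plogis(eta)
  }
  v
}

# Resolve the model for (drug, patient subgroups) through the routing table.
route_model <- function(kb, drug, subgroups) {
  tag <- "general"
  for (sg in subgroups) {
    hit <- kb$routing$drug == drug & kb$routing$subgroup == sg
    if (any(hit)) tag <- kb$routing$population_tag[which(hit)[1]]
  }
  if (tag == "general") {
    m <- kb$general[[drug]]
  } else {
    sg <- sub("^subgroup:", "", tag)
    m <- kb$subgroups[[sg]][[drug]]
  }
  if (is.null(m)) {
    stop("no model routes drug '", drug, "' for subgroups [",
         paste(subgroups, collapse = ", "), "]")
  }
  m
}

#' Predict response probabilities for every drug
#'
#' @param values completed event vector from [impute_missing()].
#' @param kb a `knowledgebase`.
#' @param subgroups patient subgroup tags; routing picks the
#'   population-specific model where the routing table directs it.
#' @return named numeric vector of response probabilities in (0, 1), one
#'   per drug in the knowledgebase.
#' @export
predict_responses <- function(values, kb, subgroups = character(0)) {
  drugs <- names(kb$general)
  vapply(drugs, function(d) {
    m <- route_model(kb, d, subgroups)
    beta <- m$coefficients
    eta <- m$intercept + sum(beta * values[names(beta)])
    stats::plogis(eta)
  }, numeric(1))
}

#' Apply the recommendation rules
#'
#' Rules, in fixed precedence order:
#' 1. severity `low` → no antidepressant; refer to low-severity treatments
#'    such as exercise;
#' 2. no drug reaches the response floor (predicted probability > 0.10) →
#'    recommend options other than common oral antidepressants;
#' 3. top two drugs within 0.05 of each other → recommend either of the two;
#' 4. otherwise → the single drug with the highest predicted response.
#' Ties inside rules 3–4 break deterministically by drug name.
#'
#' @param probabilities named numeric vector of per-drug predicted response
#'   probabilities.
#' @param severity `"low"`, `"moderate"`, or `"severe"`.
#' @param response_floor minimum predicted probability for an oral
#'   antidepressant to be recommendable (default 0.10).
#' @param tie_window top-two probability difference treated as a tie
#'   (default 0.05).
#' @param relative_floor if TRUE the floor is applied to the improvement
#'   over `baseline` rather than the absolute probability (off by default).
#' @param baseline baseline probability for `relative_floor`.
#' @return object of class `recommendation`: `branch` (one of
#'   `"no_antidepressant_low_severity"`, `"non_drug_options"`,
#'   `"either_of_two"`, `"single_drug"`), `drugs` (length 0, 1 or 2),
#'   `probabilities`.
#' @export
#' @examples
#' recommend(c(A = 0.42, B = 0.39, C = 0.12), "moderate")
recommend <- function(probabilities, severity,
                      response_floor = 0.10, tie_window = 0.05,
                      relative_floor = FALSE, baseline = 0) {
  if (length(probabilities) == 0) stop("empty probability map")
  severity <- match.arg(severity, c("low", "moderate", "severe"))
  o <- order(-probabilities, names(probabilities))
  p <- probabilities[o]
  eligible <- if (relative_floor) p - baseline > response_floor
              else p > response_floor
  rec <- if (severity == "low") {
    list(branch = "no_antidepressant_low_severity", drugs = character(0))
  } else if (!any(eligible)) {
    list(branch = "non_drug_options", drugs = character(0))
  } else if (length(p) >= 2 && p[1] - p[2] <= tie_window) {
    list(branch = "either_of_two", drugs = names(p)[1:2])
  } else {
    list(branch = "single_drug", drugs = names(p)[1])
  }
  rec$probabilities <- probabilities
  structure(rec, class = "recommendation")
}

# Two recommendations are the same advice iff branch and named drugs agree.
same_recommendation <- function(a, b) {
  identical(a$branch, b$branch) && setequal(a$drugs, b$drugs)
}

# Full pipeline from profile to recommendation; shared by explain/render.
advise_pipeline <- function(profile, kb, mode, ...) {
  values <- impute_missing(profile, kb$schema, kb$imputation, mode)
  probabilities <- predict_responses(values, kb, profile$subgroups)
  rec <- recommend(probabilities, profile$severity, ...)
  list(values = values, probabilities = probabilities, recommendation = rec)
}

#' Counterfactual one-flip explanation
#'
#' Scans schema events and lists those whose single flip changes the
#' recommendation: events not reported present whose presence would change
#' it, and reported-present events whose absence would. Each flip is applied
#' to the *profile* (as if the patient had reported it), the imputation
#' network re-run, probabilities re-predicted and the rules re-applied, so
#' downstream imputed events move with the flip.
#'
#' @param profile a [patient_profile()].
#' @param kb a `knowledgebase`.
#' @param mode imputation mode, as in [impute_missing()].
#' @param max_events optional cap on the number of schema events scanned (in
#'   schema order); NULL scans all (the default). When capped, the scan is
#'   truncated and the result carries `truncated = TRUE`.
#' @param ... recommendation rule parameters passed to [recommend()].
#' @return list with `presence_flips` and `absence_flips` (data.frames with
#'   `event_id`, `new_branch`, `new_drugs`, `delta_top` = change in the top
#'   predicted probability, sorted by `|delta_top|` descending), `baseline`
#'   (the unflipped recommendation), and `truncated`.
#' @export
explain_recommendation <- function(profile, kb,
                                   mode = c("expected", "assume-absent"),
                                   max_events = NULL, ...) {
  mode <- match.arg(mode)
  base <- advise_pipeline(profile, kb, mode, ...)
  events <- kb$schema$event_id
  truncated <- FALSE
  if (!is.null(max_events) && length(events) > max_events) {
    events <- events[seq_len(max_events)]
    truncated <- TRUE
  }
  empty <- data.frame(event_id = character(0), new_branch = character(0),
                      new_drugs = character(0), delta_top = numeric(0),
                      stringsAsFactors = FALSE)
  presence <- empty; absence <- empty
  for (e in events) {
    status <- unname(profile$events[e])
    is_present <- identical(status, "present")
    flipped <- profile
    flipped$events[e] <- if (is_present) "absent" else "present"
    alt <- advise_pipeline(flipped, kb, mode, ...)
    if (!same_recommendation(alt$recommendation, base$recommendation)) {
      row <- data.frame(
        event_id = e,
        new_branch = alt$recommendation$branch,
        new_drugs = paste(alt$recommendation$drugs, collapse = "|"),
        delta_top = max(alt$probabilities) - max(base$probabilities),
        stringsAsFactors = FALSE)
      if (is_present) absence <- rbind(absence, row)
      else presence <- rbind(presence, row)
    }
  }
  presence <- presence[order(-abs(presence$delta_top), presence$event_id), ]
  absence <- absence[order(-abs(absence$delta_top), absence$event_id), ]
  rownames(presence) <- rownames(absence) <- NULL
  list(presence_flips = presence, absence_flips = absence,
       baseline = base$recommendation, truncated = truncated)
}

recommendation_text <- function(rec) {
  switch(rec$branch,
    no_antidepressant_low_severity = paste(
      "No antidepressant is recommended for low-severity depression.",
      "Established non-drug treatments, including exercise, are advised."),
    non_drug_options = paste(
      "No common oral antidepressant reaches the minimum predicted chance",
      "of response. Treatment options besides common oral antidepressants",
      "are advised."),
    either_of_two = sprintf(
      "The top two antidepressants have predicted response rates within the tie window; either %s or %s is recommended.",
      rec$drugs[1], rec$drugs[2]),
    single_drug = sprintf(
      "%s has the highest predicted response rate and is recommended.",
      rec$drugs[1]))
}

#' Render the four-section advice document
#'
#' Sections: (1) summary of relevant reported history (reported-present
#' events carrying a nonzero coefficient in any drug model), (2) the
#' recommendation with predicted rates, (3) the counterfactual explanation
#' lists, (4) per-drug information links. All text comes from pre-set
#' templates; nothing is generated. Bar-chart data covers every drug routed
#' for this patient.
#'
#' @param profile a [patient_profile()].
#' @param kb a `knowledgebase`.
#' @param mode imputation mode.
#' @param links named character vector drug → information URL (configuration
#'   data; missing drugs get an empty slot).
#' @param max_events cap forwarded to [explain_recommendation()].
#' @param ... recommendation rule parameters.
#' @return object of class `advice_document` with `history_summary`,
#'   `recommendation` (incl. `text`), `explanation`, `information_links`,
#'   `bar_chart` (data.frame drug/predicted_response).
#' @export
render_advice <- function(profile, kb, mode = c("expected", "assume-absent"),
                          links = character(0), max_events = NULL, ...) {
  mode <- match.arg(mode)
  base <- advise_pipeline(profile, kb, mode, ...)
  expl <- explain_recommendation(profile, kb, mode, max_events = max_events,
                                 ...)
  relevant <- unique(unlist(lapply(kb$general, function(m)
    names(m$coefficients)[m$coefficients != 0])))
  reported_present <- names(profile$events)[profile$events == "present"]
  rec <- base$recommendation
  link_slots <- stats::setNames(rep("", length(rec$drugs)), rec$drugs)
  have <- intersect(rec$drugs, names(links))
  link_slots[have] <- links[have]
  structure(list(
    history_summary = list(
      reported_present = reported_present,
      relevant_reported = intersect(reported_present, relevant),
      severity = profile$severity),
    recommendation = list(
      branch = rec$branch, drugs = rec$drugs,
      text = recommendation_text(rec),
      predicted_rates = base$probabilities[rec$drugs]),
    explanation = list(
      presence_flips = expl$presence_flips,
      absence_flips = expl$absence_flips,
      truncated = expl$truncated),
    information_links = as.list(link_slots),
    bar_chart = data.frame(drug = names(base$probabilities),
                           predicted_response = unname(base$probabilities),
                           stringsAsFactors = FALSE)),
    class = "advice_document")
}

#' Serialize / deserialize an advice document as JSON
#'
#' @param doc an `advice_document`.
#' @param path file path.
#' @return `advice_to_json` returns `path` invisibly; `advice_from_json`
#'   the `advice_document`.
#' @export
advice_to_json <- function(doc, path) {
  jsonlite::write_json(unclass(doc), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname advice_to_json
#' @export
advice_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (s in c("presence_flips", "absence_flips")) {
    if (!is.data.frame(doc$explanation[[s]])) {
      doc$explanation[[s]] <- data.frame(
        event_id = character(0), new_branch = character(0),
        new_drugs = character(0), delta_top = numeric(0),
        stringsAsFactors = FALSE)
    }
  }
  doc$recommendation$predicted_rates <- unlist(doc$recommendation$predicted_rates)
  doc$recommendation$drugs <- as.character(unlist(doc$recommendation$drugs))
  structure(doc, class = "advice_document")
}
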