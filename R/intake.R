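# Information-gain adaptive intake over a prototype table.
#
# A prototype is a combination of the most important medical-history feature
# values, describing at least min_support patients, with empirical per-drug
# response rates. The intake keeps the set of prototypes consistent with the
# answers so far, and greedily asks the unasked question with the largest
# expected reduction in entropy of the recommendation label, stopping once
# all surviving prototypes imply the same advice. This mirrors how a
# clinician prunes a history: male patients are never asked about pregnancy,
# because no surviving prototype differs on it.

#' A prototype table
#'
#' @param rows data.frame of feature-value combinations, one column per
#'   feature (character; `NA` is recoded to `"unknown"`), plus a `count`
#'   column of patients described by the combination.
#' @param rates matrix (rows × drugs) of empirical per-drug response rates in
#'   \[0, 1\]; `NA` where the drug was not observed within the combination.
#' @param min_support minimum patient count per row (default 100).
#' @return object of class `prototype_table` with `rows`, `count`, `rates`,
#'   `features` (named list of answer domains), `drugs`.
#' @export
prototype_table <- function(rows, rates, min_support = 100L) {
  stopifnot(is.data.frame(rows), "count" %in% names(rows))
  count <- as.integer(rows$count)
  feat <- rows[setdiff(names(rows), "count")]
  feat[] <- lapply(feat, function(col) {
    col <- as.character(col)
    col[is.na(col)] <- "unknown"
    col
  })
  if (any(count < min_support)) {
    stop("prototype rows below min_support = ", min_support)
  }
  if (anyDuplicated(feat)) stop("duplicate prototype rows")
  rates <- as.matrix(rates)
  if (nrow(rates) != nrow(feat)) stop("rates rows must match prototype rows")
  if (any(rates < 0 | rates > 1, na.rm = TRUE)) {
    stop("response rates must lie in [0, 1]")
  }
  structure(list(
    rows = feat, count = count, rates = rates,
    features = lapply(feat, function(col) sort(unique(col))),
    drugs = colnames(rates), min_support = as.integer(min_support)),
    class = "prototype_table")
}

#' Derive a prototype table from patient-level data
#'
#' Groups patients by their combination of feature values, keeps the
#' combinations describing at least `min_support` patients, and tabulates
#' per-drug response rates (responders / treated) within each.
#'
#' @param data data.frame with one row per treated patient: the feature
#'   columns named in `features`, plus `drug` and binary `response`.
#' @param features character vector of feature column names (finite domains).
#' @param min_support minimum patients per combination (default 100).
#' @return a [prototype_table()].
#' @export
derive_prototypes <- function(data, features, min_support = 100L) {
  stopifnot(all(c(features, "drug", "response") %in% names(data)))
  key <- do.call(paste, c(lapply(data[features], function(col) {
    col <- as.character(col); col[is.na(col)] <- "unknown"; col
  }), sep = "\r"))
  counts <- table(key)
  keep_keys <- names(counts)[counts >= min_support]
  if (length(keep_keys) == 0) {
    stop("no feature combination reaches min_support = ", min_support,
         "; use fewer or coarser features")
  }
  drugs <- sort(unique(data$drug))
  rows <- as.data.frame(
    do.call(rbind, strsplit(keep_keys, "\r", fixed = TRUE)),
    stringsAsFactors = FALSE)
  names(rows) <- features
  rates <- matrix(NA_real_, length(keep_keys), length(drugs),
                  dimnames = list(NULL, drugs))
  for (i in seq_along(keep_keys)) {
    sub <- data[key == keep_keys[i], , drop = FALSE]
    for (d in drugs) {
      trt <- sub$response[sub$drug == d]
      if (length(trt)) rates[i, d] <- mean(trt)
    }
  }
  rows$count <- as.integer(counts[keep_keys])
  prototype_table(rows, rates, min_support = min_support)
}

#' Recommendation label induced on a prototype row
#'
#' The default intake objective: the advice branch (and named drugs) that
#' the recommendation rules produce from a row's per-drug response rates.
#' Drugs unobserved in the row are dropped.
#'
#' @param rates named numeric vector of per-drug response rates (may contain
#'   `NA`).
#' @param severity severity assumed for labeling (default `"moderate"`).
#' @param ... rule parameters passed to [recommend()].
#' @return single character label, e.g. `"single_drug:sertraline"`.
#' @export
recommendation_label <- function(rates, severity = "moderate", ...) {
  rates <- rates[!is.na(rates)]
  if (length(rates) == 0) return("non_drug_options")
  rec <- recommend(rates, severity, ...)
  if (length(rec$drugs)) {
    paste0(rec$branch, ":", paste(sort(rec$drugs), collapse = "|"))
  } else {
    rec$branch
  }
}

# Labels for every row of the table, memoized on the table object.
table_labels <- function(table, label_fun = recommendation_label) {
  vapply(seq_len(nrow(table$rows)), function(i)
    label_fun(table$rates[i, ]), character(1))
}

#' Start an intake interview
#'
#' @param table a [prototype_table()].
#' @param question_budget hard cap on the number of questions (default 25).
#' @return object of class `intake_state`: `answers`, `asked`, `surviving`
#'   (row indices), `question_budget`.
#' @export
intake_state <- function(table, question_budget = 25L) {
  structure(list(answers = list(), asked = character(0),
                 surviving = seq_len(nrow(table$rows)),
                 question_budget = as.integer(question_budget)),
            class = "intake_state")
}

#' Expected information gain of asking a feature
#'
#' The target variable is the recommendation label induced on each surviving
#' prototype row. Prior entropy is computed over the count-weighted label
#' distribution of the survivors; the answer distribution is proportional to
#' surviving counts, with rows whose value is unrecorded grouped under an
#' explicit `"unknown"` answer branch. Gain is prior entropy minus expected
#' conditional entropy, in bits, and is always nonnegative.
#'
#' @param state an [intake_state()].
#' @param feature unasked feature name.
#' @param table a [prototype_table()].
#' @param label_fun row-labeling objective (default [recommendation_label()];
#'   pluggable).
#' @return expected entropy reduction in bits.
#' @export
information_gain <- function(state, feature, table,
                             label_fun = recommendation_label) {
  if (feature %in% state$asked) stop("feature already asked: ", feature)
  if (!feature %in% names(table$rows)) stop("unknown feature: ", feature)
  if (length(state$surviving) == 0) stop("no surviving prototypes")
  rows <- state$surviving
  labels <- table_labels(table, label_fun)[rows]
  counts <- table$count[rows]
  values <- table$rows[[feature]][rows]
  prior <- entropy_bits(tapply(counts, labels, sum))
  cond <- 0
  for (a in unique(values)) {
    sel <- values == a
    cond <- cond + sum(counts[sel]) / sum(counts) *
      entropy_bits(tapply(counts[sel], labels[sel], sum))
  }
  max(0, prior - cond)
}

#' Choose the next question, or stop
#'
#' Greedy policy: among unasked features taking at least two distinct values
#' across the surviving prototypes (features precluded by earlier answers —
#' constant among survivors — are never proposed), pick the one with maximal
#' expected information gain, breaking ties lexicographically. Stops when the
#' induced recommendation label is constant across survivors, when no
#' informative feature remains, or when the question budget is exhausted.
#'
#' @param state an [intake_state()].
#' @param table a [prototype_table()].
#' @param label_fun row-labeling objective.
#' @return list with `action` = `"ask"` (plus `feature`, `gain`) or
#'   `"stop"` (plus `reason` and the surviving `label`s).
#' @export
next_question <- function(state, table, label_fun = recommendation_label) {
  if (length(state$surviving) == 0) {
    stop("contradictory answers: no surviving prototypes")
  }
  labels <- unique(table_labels(table, label_fun)[state$surviving])
  if (length(labels) == 1) {
    return(list(action = "stop", reason = "label_constant", label = labels))
  }
  if (length(state$answers) >= state$question_budget) {
    return(list(action = "stop", reason = "budget_exhausted", label = labels))
  }
  candidates <- setdiff(names(table$rows), state$asked)
  candidates <- candidates[vapply(candidates, function(f)
    length(unique(table$rows[[f]][state$surviving])) > 1, logical(1))]
  if (length(candidates) == 0) {
    return(list(action = "stop", reason = "no_informative_feature",
                label = labels))
  }
  gains <- vapply(candidates, function(f)
    information_gain(state, f, table, label_fun), numeric(1))
  if (max(gains) <= 0) {
    return(list(action = "stop", reason = "no_informative_feature",
                label = labels))
  }
  best <- sort(candidates[gains == max(gains)])[1]
  list(action = "ask", feature = best, gain = max(gains))
}

#' Record an answer and prune the surviving prototypes
#'
#' @param state an [intake_state()].
#' @param feature the feature that was asked (must not have been asked
#'   before).
#' @param value the answer; must be in the feature's domain or `"unknown"`.
#' @param table a [prototype_table()].
#' @return the new `intake_state`; the surviving set never grows, and equals
#'   a one-shot filter on all answers given so far.
#' @export
apply_answer <- function(state, feature, value, table) {
  if (feature %in% state$asked) {
    stop("feature already answered: ", feature)
  }
  if (!feature %in% names(table$rows)) stop("unknown feature: ", feature)
  domain <- c(table$features[[feature]], "unknown")
  if (!value %in% domain) {
    stop("value '", value, "' not in domain of ", feature)
  }
  surviving <- state$surviving[table$rows[[feature]][state$surviving] == value]
  if (length(surviving) == 0) {
    stop("no prototype consistent with ", feature, " = ", value)
  }
  state$answers[[feature]] <- value
  state$asked <- c(state$asked, feature)
  state$surviving <- surviving
  state
}

#' Simulate a full interview against a fixed respondent
#'
#' Runs the greedy policy to completion, drawing each answer from
#' `answer_fun(feature)`.
#'
#' @param table a [prototype_table()].
#' @param answer_fun function(feature) → answer value.
#' @param question_budget forwarded to [intake_state()].
#' @param label_fun row-labeling objective.
#' @return list with `n_questions`, `answers`, `stop_reason`, final
#'   `label`(s) among survivors.
#' @export
run_intake <- function(table, answer_fun, question_budget = 25L,
                       label_fun = recommendation_label) {
  state <- intake_state(table, question_budget)
  repeat {
    q <- next_question(state, table, label_fun)
    if (q$action == "stop") {
      return(list(n_questions = length(state$answers),
                  answers = state$answers, stop_reason = q$reason,
                  label = q$label))
    }
    state <- apply_answer(state, q$feature, answer_fun(q$feature), table)
  }
}

#' Expected interview length of the greedy policy
#'
#' Averages the number of questions over all prototype rows, weighting each
#' row by its patient count and answering every question with the row's own
#' value.
#'
#' @param table a [prototype_table()].
#' @param label_fun row-labeling objective.
#' @param question_budget forwarded to [intake_state()].
#' @return expected number of questions.
#' @export
expected_interview_length <- function(table,
                                      label_fun = recommendation_label,
                                      question_budget = 25L) {
  lens <- vapply(seq_len(nrow(table$rows)), function(i) {
    res <- run_intake(table, function(f) table$rows[[f]][i],
                      question_budget, label_fun)
    res$n_questions
  }, numeric(1))
  sum(lens * table$count) / sum(table$count)
}
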