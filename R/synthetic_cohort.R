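# Synthetic claims-like cohorts with known ground-truth response models.
#
# Real antidepressant knowledgebases are built from proprietary claims data.
# This module generates dispensing streams and binary medical-history events
# from declared logistic response models, so every downstream stage (episode
# construction, screening, LASSO stability selection, bias audit, intake,
# advice) can be tested against a known truth.

#' Build an event schema across the four medical-history vocabularies
#'
#' Events are allocated to diagnoses (DX), medications (RX), procedures (PX),
#' and prior antidepressant responses (ADR) in proportion to the 700/550/151/98
#' split of the 1499-event catalog the response models draw on, with
#' largest-remainder rounding so the counts sum to `n_events`.
#'
#' @param n_events number of candidate history events.
#' @return data.frame with columns `event_id`, `vocabulary`.
#' @export
#' @examples
#' event_schema(20)
event_schema <- function(n_events) {
  stopifnot(n_events >= 1)
  split <- largest_remainder(
    c(DX = 700, RX = 550, PX = 151, ADR = 98) / 1499, n_events)
  vocab <- rep(names(split), split)
  width <- max(3L, nchar(as.character(n_events)))
  ids <- sprintf(paste0("%s_%0", width, "d"), vocab,
                 unlist(lapply(split, seq_len), use.names = FALSE))
  data.frame(event_id = ids, vocabulary = vocab, stringsAsFactors = FALSE)
}

#' Configuration for a synthetic cohort
#'
#' @param n_patients number of patients (one treatment episode each).
#' @param drugs character vector of antidepressant names.
#' @param n_events number of candidate binary history events; the schema is
#'   produced by [event_schema()].
#' @param event_prevalence per-event probability of occurrence, scalar or
#'   length `n_events`, all in \[0, 1\].
#' @param true_models named list (one entry per drug) of ground-truth logistic
#'   response models: `list(intercept = , coefficients = )` where
#'   `coefficients` is a named numeric vector keyed by event id.
#' @param subgroup_fraction proportion of patients assigned to the designated
#'   subgroup, in \[0, 1\].
#' @param subgroup_shifts named list per drug of coefficient deltas (named
#'   numeric vectors, keyed by event id) applied inside the subgroup; an
#'   optional `"(Intercept)"` entry shifts the intercept.
#' @param event_correlation equicorrelation of the latent Gaussian used to
#'   threshold events into binaries; 0 (default) samples events
#'   independently. Correlated events exercise screening under collinearity.
#' @param nonresponse_dispositions weights over `switched`, `discontinued`,
#'   `augmented` used to assign a disposition to non-responders; responders
#'   are always `continued`. Defaults follow the conditional split of the
#'   observed 46.3/12.8/35.1/5.9 four-way disposition mix.
#' @param seed integer seed; fixing it fixes all outputs.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients, drugs, n_events,
                          event_prevalence = 0.2,
                          true_models,
                          subgroup_fraction = 0,
                          subgroup_shifts = NULL,
                          event_correlation = 0,
                          nonresponse_dispositions = c(
                            switched = 0.238, discontinued = 0.654,
                            augmented = 0.108),
                          seed = 1L) {
  if (length(drugs) == 0) stop("configuration error: drug list is empty")
  if (anyDuplicated(drugs)) stop("configuration error: duplicate drug names")
  stopifnot(n_patients >= 1, n_events >= 1)
  schema <- event_schema(n_events)
  prev <- rep_len(event_prevalence, n_events)
  if (any(prev < 0 | prev > 1)) {
    stop("configuration error: event_prevalence outside [0, 1]")
  }
  if (subgroup_fraction < 0 || subgroup_fraction > 1) {
    stop("configuration error: subgroup_fraction outside [0, 1]")
  }
  if (event_correlation < 0 || event_correlation >= 1) {
    stop("configuration error: event_correlation outside [0, 1)")
  }
  if (!all(drugs %in% names(true_models))) {
    stop("configuration error: true_models missing drugs: ",
         paste(setdiff(drugs, names(true_models)), collapse = ", "))
  }
  check_keys <- function(v, what) {
    keys <- setdiff(names(v), "(Intercept)")
    bad <- setdiff(keys, schema$event_id)
    if (length(bad)) {
      stop("configuration error: ", what, " references undeclared events: ",
           paste(bad, collapse = ", "))
    }
  }
  for (d in drugs) check_keys(true_models[[d]]$coefficients, paste0("true_models$", d))
  for (d in names(subgroup_shifts)) check_keys(subgroup_shifts[[d]], paste0("subgroup_shifts$", d))
  nonresponse_dispositions <-
    nonresponse_dispositions / sum(nonresponse_dispositions)
  structure(
    list(n_patients = as.integer(n_patients), drugs = drugs,
         n_events = as.integer(n_events), event_prevalence = prev,
         true_models = true_models, subgroup_fraction = subgroup_fraction,
         subgroup_shifts = subgroup_shifts,
         event_correlation = event_correlation,
         nonresponse_dispositions = nonresponse_dispositions,
         schema = schema, seed = as.integer(seed)),
    class = "cohort_config")
}

# Dispensing-stream templates realizing each disposition under the default
# windows (response 70 d, disposition 100 d, gap tolerance 15 d):
#   continued    — 30-day fills at days 0/28/56/84; gap-tolerant coverage [0,114)
#   discontinued — single 30-day fill; coverage lapses, no new antidepressant
#   switched     — 30-day fill, then another antidepressant at day 50, after
#                  index coverage has lapsed beyond the 15-day tolerance
#   augmented    — 30-day fills at days 0/28/56/84 plus another antidepressant
#                  at day 40 while index coverage persists
disposition_template <- function(disposition, patient_id, index_drug, alt_drug) {
  idx <- function(days) data.frame(
    patient_id = patient_id, drug = index_drug, fill_date = days,
    days_supply = 30L, stringsAsFactors = FALSE)
  alt <- function(day) data.frame(
    patient_id = patient_id, drug = alt_drug, fill_date = day,
    days_supply = 30L, stringsAsFactors = FALSE)
  switch(disposition,
    continued    = idx(c(0L, 28L, 56L, 84L)),
    discontinued = idx(0L),
    switched     = rbind(idx(0L), alt(50L)),
    augmented    = rbind(idx(c(0L, 28L, 56L, 84L)), alt(40L)),
    stop("unknown disposition: ", disposition))
}

#' Generate a synthetic cohort
#'
#' Samples binary event histories at the configured prevalences (optionally
#' equicorrelated through a latent Gaussian), assigns each patient one drug
#' uniformly at random, draws the binary response from the ground-truth
#' logistic model (with subgroup coefficient shifts applied to subgroup
#' members), and lays down a dispensing stream whose episode reconstruction
#' recovers the intended disposition: responders continue their index drug
#' through the disposition window, non-responders switch, discontinue, or
#' augment.
#'
#' @param config a [cohort_config()].
#' @return list with `events` (patient_id, vocabulary, code, date),
#'   `dispensings` (patient_id, drug, fill_date, days_supply), `labels`
#'   (patient_id, drug, subgroup, linear_predictor, p_response, response,
#'   disposition), `features` (patient-by-event 0/1 matrix, rows named by
#'   patient id), and `schema`.
#' @export
#' @examples
#' cfg <- cohort_config(
#'   n_patients = 50, drugs = "sertraline", n_events = 5,
#'   true_models = list(sertraline = list(
#'     intercept = -0.2, coefficients = c(DX_001 = 1))),
#'   seed = 7)
#' coh <- generate_cohort(cfg)
#' head(coh$labels)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  m <- config$n_events
  schema <- config$schema
  width <- max(6L, nchar(as.character(n)))
  pid <- sprintf(paste0("P%0", width, "d"), seq_len(n))

  # event matrix: latent equicorrelated Gaussian thresholded at the
  # prevalence quantile; rho = 0 reduces to independent Bernoulli draws
  rho <- config$event_correlation
  if (rho > 0) {
    w <- stats::rnorm(n)
    z <- sqrt(rho) * w + sqrt(1 - rho) * matrix(stats::rnorm(n * m), n, m)
    x <- sweep(z, 2, stats::qnorm(1 - config$event_prevalence), ">") * 1L
  } else {
    x <- matrix(stats::rbinom(n * m, 1L,
                              rep(config$event_prevalence, each = n)), n, m)
  }
  dimnames(x) <- list(pid, schema$event_id)

  subgroup <- stats::runif(n) < config$subgroup_fraction
  drug <- sample(config$drugs, n, replace = TRUE)

  eta <- numeric(n)
  for (d in config$drugs) {
    rows <- which(drug == d)
    if (!length(rows)) next
    tm <- config$true_models[[d]]
    beta <- tm$coefficients %||% numeric(0)
    eta[rows] <- tm$intercept +
      if (length(beta)) drop(x[rows, names(beta), drop = FALSE] %*% beta) else 0
    sh <- config$subgroup_shifts[[d]]
    if (!is.null(sh)) {
      srows <- rows[subgroup[rows]]
      if (length(srows)) {
        b <- sh[setdiff(names(sh), "(Intercept)")]
        ish <- if ("(Intercept)" %in% names(sh)) sh[["(Intercept)"]] else 0
        eta[srows] <- eta[srows] + ish +
          if (length(b)) drop(x[srows, names(b), drop = FALSE] %*% b) else 0
      }
    }
  }
  p <- stats::plogis(eta)
  response <- stats::rbinom(n, 1L, p)

  ndw <- config$nonresponse_dispositions
  disposition <- ifelse(response == 1L, "continued",
                        sample(names(ndw), n, replace = TRUE, prob = ndw))

  # alternate drug for switch/augment streams: any other declared drug,
  # or the catch-all category when only one drug is declared
  alt_pool <- if (length(config$drugs) > 1) config$drugs else c(config$drugs, "other")
  alt <- vapply(seq_len(n), function(i) {
    pool <- setdiff(alt_pool, drug[i])
    pool[1 + (i %% length(pool))]
  }, character(1))

  disp_list <- lapply(seq_len(n), function(i)
    disposition_template(disposition[i], pid[i], drug[i], alt[i]))
  dispensings <- do.call(rbind, disp_list)
  rownames(dispensings) <- NULL

  idx <- which(x == 1L, arr.ind = TRUE)
  events <- data.frame(
    patient_id = pid[idx[, 1]],
    vocabulary = schema$vocabulary[idx[, 2]],
    code = schema$event_id[idx[, 2]],
    date = as.integer((idx[, 1] * 13L + idx[, 2] * 7L) %% 180L),
    stringsAsFactors = FALSE)
  events <- events[order(events$patient_id, events$code), ]
  rownames(events) <- NULL

  labels <- data.frame(
    patient_id = pid, drug = drug, subgroup = subgroup,
    linear_predictor = eta, p_response = p,
    response = as.integer(response), disposition = disposition,
    stringsAsFactors = FALSE)

  list(events = events, dispensings = dispensings, labels = labels,
       features = x, schema = schema)
}

#' Plant an exact mix of episode dispositions
#'
#' Apportions `n` single-episode patients over the four dispositions by
#' largest-remainder rounding (so realized counts are exact) and emits the
#' dispensing stream realizing each one. Applying [build_episodes()] with the
#' default windows to the output recovers the planted counts exactly.
#'
#' @param proportions named nonnegative weights over a subset of
#'   `continued`, `switched`, `discontinued`, `augmented`, summing to 1
#'   (printed-percentage slack of 0.005 is normalized away).
#' @param n number of patients.
#' @param seed integer seed controlling the (shuffled) assignment order.
#' @param index_drug,alt_drug drug names used for the index and the
#'   switch/augment antidepressant.
#' @return data.frame of dispensing records with a `disposition` attribute
#'   giving the planted per-patient labels.
#' @export
#' @examples
#' d <- plant_disposition_mix(c(continued = 0.5, discontinued = 0.5), 4, seed = 1)
#' table(attr(d, "disposition")$disposition)
plant_disposition_mix <- function(proportions, n, seed = 1L,
                                  index_drug = "sertraline",
                                  alt_drug = "bupropion") {
  allowed <- c("continued", "switched", "discontinued", "augmented")
  if (!all(names(proportions) %in% allowed)) {
    stop("unknown disposition in proportions: ",
         paste(setdiff(names(proportions), allowed), collapse = ", "))
  }
  counts <- largest_remainder(proportions, n)
  set.seed(seed)
  disposition <- sample(rep(names(counts), counts))
  width <- max(6L, nchar(as.character(n)))
  pid <- sprintf(paste0("P%0", width, "d"), seq_len(n))
  out <- do.call(rbind, lapply(seq_len(n), function(i)
    disposition_template(disposition[i], pid[i], index_drug, alt_drug)))
  rownames(out) <- NULL
  attr(out, "disposition") <- data.frame(
    patient_id = pid, disposition = disposition, stringsAsFactors = FALSE)
  out
}
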