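# Treatment-episode construction from dispensing records.
#
# An episode is one antidepressant treatment attempt. Within the first
# disposition_window_days (default 100) of the index fill it is classified
# four ways: continued, switched, discontinued, or augmented. The binary
# surrogate response is persistence on the index drug through the response
# window (default 70 days = 10 weeks): premature abandonment stands in for
# lack of remission, which claims data do not record.

#' Episode window parameters
#'
#' @param response_window_days days of gap-tolerant index-drug coverage
#'   required for response = 1; default 70 (10 weeks).
#' @param disposition_window_days horizon within which the four-way
#'   disposition is determined; default 100. All intervals are half-open
#'   `[start, end)` in integer days from the index fill.
#' @param gap_tolerance_days refill gaps up to this many days do not break
#'   coverage; default 15.
#' @return object of class `episode_windows`.
#' @export
episode_windows <- function(response_window_days = 70L,
                            disposition_window_days = 100L,
                            gap_tolerance_days = 15L) {
  stopifnot(response_window_days > 0, disposition_window_days > 0,
            gap_tolerance_days > 0)
  if (response_window_days > disposition_window_days) {
    stop("response_window_days must not exceed disposition_window_days")
  }
  structure(list(response_window_days = as.integer(response_window_days),
                 disposition_window_days = as.integer(disposition_window_days),
                 gap_tolerance_days = as.integer(gap_tolerance_days)),
            class = "episode_windows")
}

# Classify one episode's fills. `fills` holds this episode's records only
# (index fill first); returns disposition, response, covered_days.
classify_episode <- function(fills, index_drug, start, windows,
                             response_rule) {
  dw <- windows$disposition_window_days
  gap <- windows$gap_tolerance_days
  idx <- fills[fills$drug == index_drug, , drop = FALSE]
  oth <- fills[fills$drug != index_drug, , drop = FALSE]

  # gap-tolerant merged coverage of the index drug, clipped to the window
  s <- pmax(idx$fill_date, start)
  e <- pmin(idx$fill_date + idx$days_supply, start + dw)
  keep <- e > s
  merged <- merge_intervals(s[keep], e[keep], bridge = gap)
  covered <- merge_intervals(s[keep], e[keep], bridge = 0)
  covered_days <- sum(covered$end - covered$start)
  # the merged run that starts at the index fill
  lead <- merged[merged$start <= start, , drop = FALSE]
  lead_end <- if (nrow(lead)) max(lead$end) else start

  t_other <- if (nrow(oth)) min(oth$fill_date) else Inf

  decide <- function(horizon) {
    if (t_other < start + horizon) {
      # another antidepressant starts inside the window: augmentation if
      # gap-tolerant index coverage persists at that moment, else a switch
      alive <- any(merged$start <= t_other & t_other < merged$end)
      if (alive) "augmented" else "switched"
    } else if (lead_end + gap >= start + horizon) {
      # coverage never lapses beyond tolerance inside the window
      "continued"
    } else {
      "discontinued"
    }
  }

  disposition <- decide(dw)
  response <- switch(response_rule,
    # default: response requires the full episode to be classified continued
    # (a switch or augmentation anywhere in the disposition window is a
    # failed treatment choice) plus coverage spanning the response window
    disposition = as.integer(
      disposition == "continued" &&
        lead_end >= start + windows$response_window_days),
    # alternative: evaluate persistence at the response window only, so a
    # switch or augmentation between the two windows does not cancel response
    response_window = as.integer(
      decide(windows$response_window_days) == "continued"),
    stop("unknown response_rule: ", response_rule))

  list(disposition = disposition, response = response,
       covered_days = as.integer(covered_days))
}

#' Build treatment episodes from dispensing records
#'
#' For each patient, the first fill opens an episode indexed on that drug;
#' every fill within the disposition window belongs to it (refills sustain
#' coverage, a different antidepressant triggers a switch or augmentation),
#' and the first fill at or beyond the window end opens the next episode.
#'
#' Disposition rules within `[start, start + disposition_window)`:
#' * **continued** — gap-tolerant index coverage from the index fill reaches
#'   the end of the window, with no other antidepressant starting;
#' * **switched** — another antidepressant starts after index coverage has
#'   lapsed beyond the gap tolerance;
#' * **augmented** — another antidepressant starts while gap-tolerant index
#'   coverage persists;
#' * **discontinued** — coverage lapses and no other antidepressant starts.
#'
#' @param dispensings data.frame with `patient_id`, `drug`, `fill_date`
#'   (integer day offset, day 0 = cohort start), `days_supply` (>= 1).
#'   Records with nonpositive `days_supply` or negative `fill_date` are
#'   dropped with a warning.
#' @param windows an [episode_windows()].
#' @param response_rule `"disposition"` (default: response = 1 only for
#'   continued episodes with coverage through the response window) or
#'   `"response_window"` (persistence judged at the response window alone, so
#'   a switch or augmentation after it does not cancel response).
#' @return data.frame with one row per episode: `patient_id`, `index_drug`,
#'   `start_day`, `disposition`, `response`, `covered_days`.
#' @export
#' @examples
#' d <- data.frame(patient_id = "P1", drug = "sertraline",
#'                 fill_date = c(0, 28, 56), days_supply = 30)
#' build_episodes(d)
build_episodes <- function(dispensings, windows = episode_windows(),
                           response_rule = c("disposition", "response_window")) {
  response_rule <- match.arg(response_rule)
  need <- c("patient_id", "drug", "fill_date", "days_supply")
  if (!all(need %in% names(dispensings))) {
    stop("dispensings must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(dispensings) == 0) {
    return(data.frame(patient_id = character(0), index_drug = character(0),
                      start_day = integer(0), disposition = character(0),
                      response = integer(0), covered_days = integer(0),
                      stringsAsFactors = FALSE))
  }
  bad <- dispensings$days_supply < 1 | dispensings$fill_date < 0
  if (any(bad)) {
    warning(sum(bad), " dispensing record(s) rejected: days_supply < 1 ",
            "or fill_date < 0")
    dispensings <- dispensings[!bad, , drop = FALSE]
  }
  dispensings <- dispensings[order(dispensings$patient_id,
                                   dispensings$fill_date), , drop = FALSE]
  out <- lapply(split(dispensings, dispensings$patient_id), function(f) {
    eps <- list()
    i <- 1L
    while (i <= nrow(f)) {
      start <- f$fill_date[i]
      index_drug <- f$drug[i]
      in_ep <- f$fill_date < start + windows$disposition_window_days &
        f$fill_date >= start
      cls <- classify_episode(f[in_ep, , drop = FALSE], index_drug, start,
                              windows, response_rule)
      eps[[length(eps) + 1L]] <- data.frame(
        patient_id = f$patient_id[i], index_drug = index_drug,
        start_day = as.integer(start), disposition = cls$disposition,
        response = cls$response, covered_days = cls$covered_days,
        stringsAsFactors = FALSE)
      nxt <- which(!in_ep & f$fill_date >= start)
      i <- if (length(nxt)) min(nxt) else nrow(f) + 1L
    }
    do.call(rbind, eps)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Four-way disposition summary
#'
#' @param episodes episode data.frame from [build_episodes()], or any
#'   data.frame with a `disposition` column.
#' @return data.frame with `disposition`, `count`, `percent`; all four
#'   dispositions always appear, percentages are half-up rounded to one
#'   decimal and sum to 100 within rounding slack.
#' @export
summarize_dispositions <- function(episodes) {
  if (is.null(episodes) || nrow(episodes) == 0) {
    stop("cannot summarize an empty episode list")
  }
  lev <- c("continued", "switched", "discontinued", "augmented")
  counts <- table(factor(episodes$disposition, levels = lev))
  data.frame(disposition = lev, count = as.integer(counts),
             percent = round_half_up(as.integer(counts) / nrow(episodes) * 100, 1),
             stringsAsFactors = FALSE)
}

#' Treatment frequency table
#'
#' Per-treatment episode counts and percentages, sorted by count descending,
#' mirroring the frequency-of-treatments layout of published claims analyses.
#'
#' @param x episode data.frame (counted by `index_drug`) or a named integer
#'   vector of per-treatment episode counts.
#' @return data.frame with `treatment`, `count`, `percent` (half-up, two
#'   decimals), rows sorted by count descending (ties by name).
#' @export
#' @examples
#' treatment_frequency_table(c(sertraline = 3, bupropion = 1))
treatment_frequency_table <- function(x) {
  if (is.data.frame(x)) {
    if (nrow(x) == 0) stop("cannot tabulate an empty episode list")
    counts <- table(x$index_drug)
    counts <- stats::setNames(as.integer(counts), names(counts))
  } else {
    if (length(x) == 0) stop("cannot tabulate an empty count vector")
    counts <- x
  }
  total <- sum(counts)
  o <- order(-counts, names(counts))
  data.frame(treatment = names(counts)[o],
             count = as.integer(counts[o]),
             percent = round_half_up(as.integer(counts[o]) / total * 100, 2),
             stringsAsFactors = FALSE, row.names = NULL)
}
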