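# Suicide-risk triage from detected risk-factor categories.
#
# Upstream detection (mapping conversation text to categories) is out of
# scope; this module consumes category ids, deduplicates them, and maps the
# count to one of three referral pathways. A count exceeding three factors
# near-perfectly separates high/moderate- from low-risk presentations, so
# the default crisis boundary is count > 3.

#' The 14-category suicide-risk-factor taxonomy
#'
#' @return data.frame with `id` (1–14) and `label`.
#' @export
#' @examples
#' risk_taxonomy()
risk_taxonomy <- function() {
  data.frame(
    id = 1:14,
    label = c(
      "active suicidal ideation with a particular method and a plan for when and how",
      "passive suicidal ideation: wishing to be dead without a specific plan",
      "history of suicidal behavior: prior attempt, interrupted attempt, or emergency visits for an attempt",
      "non-suicidal or non-life-threatening self-injury",
      "thwarted belongingness or burden to others: rejection, negative self-worth, hopelessness",
      "persistent intolerable pain or acute exacerbation of mental illness",
      "new episode of eating disorder or borderline/antisocial personality disorder",
      "preparatory suicidal actions: new access to means, giving away cherished belongings",
      "significant and severe lack of sleep, nightmares, lack of REM sleep",
      "adverse life events: death in the family, peer suicide attempt, terminal diagnosis",
      "victimization: sexual abuse, physical punishment, peer bullying",
      "new indications of poor attachment to parents or nuclear family",
      "sexual or gender confusion, including regrets over new experimentation or online outing",
      "increase in recklessness or impulsivity, including illicit substance use"),
    stringsAsFactors = FALSE)
}

#' Triage detected suicide-risk factors into a referral pathway
#'
#' Duplicate mentions of one category count once. With the default
#' thresholds: a count above `crisis_threshold` (3) routes to the crisis
#' line; a count of at least `referral_threshold` (1) but not above the
#' crisis boundary routes to a Safety Plan supporter; zero detected factors
#' need no referral.
#'
#' @param detected integer vector of category ids in 1–14; duplicates are
#'   collapsed.
#' @param crisis_threshold counts strictly above this go to `crisis_line`.
#' @param referral_threshold counts at or above this (and not above the
#'   crisis boundary) go to `safety_plan_supporter`.
#' @return object of class `risk_assessment`: `detected` (sorted unique
#'   ids), `count`, `pathway` (one of `"crisis_line"`,
#'   `"safety_plan_supporter"`, `"no_referral"`).
#' @export
#' @examples
#' triage_risk(c(1, 1, 3, 8, 9, 14))
triage_risk <- function(detected, crisis_threshold = 3L,
                        referral_threshold = 1L) {
  detected <- as.integer(detected)
  bad <- setdiff(detected, risk_taxonomy()$id)
  if (length(bad)) {
    stop("unknown risk-factor category id(s): ", paste(bad, collapse = ", "))
  }
  detected <- sort(unique(detected))
  count <- length(detected)
  pathway <- if (count > crisis_threshold) "crisis_line"
             else if (count >= referral_threshold) "safety_plan_supporter"
             else "no_referral"
  structure(list(detected = detected, count = count, pathway = pathway),
            class = "risk_assessment")
}
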