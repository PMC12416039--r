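---
title: "Methods: persistence-based antidepressant response models and the decision-aid pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: persistence-based antidepressant response models and the decision-aid pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mddaid)
```

## The problem

Antidepressant choice for major depressive disorder (MDD) is largely
trial-and-error: response rates differ across drugs and across patients, and
a failed first choice costs weeks. `mddaid` implements the analytical core
of a decision aid that learns per-drug response models from claims-like
dispensing data, audits them for subgroup bias, collects a patient's history
through an adaptive questionnaire, screens for suicide risk, and emits a
rule-based, explained recommendation.

Claims data do not record remission, so the models use a **surrogate
outcome**: persistence on the index antidepressant. Premature abandonment of
a prescription within the first ten weeks — whether for inefficacy or side
effects — marks the prescription as an incorrect choice; sustained use marks
a (possible) response. The package encodes this as a binary response derived
from treatment episodes.

## Treatment episodes

An episode starts at a patient's first fill of an antidepressant (a later
fill opens a new episode only after the current episode's observation window
has closed). Within the first `disposition_window_days` (default 100) the
episode is classified:

* **continued** — gap-tolerant coverage of the index drug never lapses
  beyond `gap_tolerance_days` (default 15) inside the window and no other
  antidepressant starts;
* **switched** — another antidepressant starts after index coverage has
  lapsed beyond tolerance;
* **augmented** — another antidepressant starts while index coverage
  persists;
* **discontinued** — coverage lapses and nothing replaces it.

`response = 1` requires the episode to be *continued* and the merged
coverage run to span `response_window_days` (default 70, i.e. ten weeks).
All intervals are half-open `[start, end)` in integer days with day 0 the
cohort start; integer days avoid calendar parsing throughout.

Two readings of the outcome are defensible when a switch or augmentation
falls between day 70 and day 100: the default (`response_rule =
"disposition"`) counts it as non-response, on the argument that the whole
episode revealed an incorrect choice; `response_rule = "response_window"`
judges persistence at day 70 only. The default is a documented choice, not
an inference — the two differ only on that corner.

Disposition and frequency summaries use half-up decimal rounding (one
decimal for the four-way split, two for per-treatment percentages), matching
the convention of published claims tables; `round()`'s round-half-even would
disagree on boundary values.

## Synthetic cohorts as the study conditions

Real knowledgebases of this kind are fit on proprietary claims (millions of
episodes). The `synthetic_cohort` module generates cohorts with *declared*
ground truth so that every downstream stage is testable: each drug has a
logistic response model over binary history events (diagnoses, medications,
procedures, prior antidepressant responses, allocated 700/550/151/98 as in
the 1499-event intake catalog); events are sampled at configurable
prevalence, optionally equicorrelated through a latent Gaussian threshold
model to exercise screening under collinearity; responders receive
dispensing streams that reconstruct as *continued*, non-responders as
switched/discontinued/augmented in configurable proportions (defaults follow
the conditional split of the observed 46.3/12.8/35.1/5.9 mix).

`plant_disposition_mix()` apportions an exact disposition mix by
largest-remainder rounding, so episode building recovers planted counts
exactly. Weights are normalized when they sum to within 0.005 of 1, because
mixes are often read off printed percentage tables that round to 100.1%.

The package's recovery experiments fix one set of conditions, chosen once:
cohorts of n = 5000 (support recovery) or n = 2800 with a 55% subgroup
(bias audit), 50 candidate events at prevalence 0.3, a true model with
intercept −0.5 and coefficients +1.2/−1.0/+1.0 on three events, and 20
replications. Under these conditions the generating model's theoretical AUC
is ≈ 0.70 — the same moderate-accuracy regime reported for real per-drug
persistence models. What these experiments show is that the pipeline
recovers a sparse truth *of this kind*; synthetic events are (by default)
independent and binary, with none of the coding noise, temporal drift, or
confounding of real claims, so passing them does not certify performance on
real data.

## Screening and stability selection

With tens of thousands of candidate events, fitting starts with a screen.
`safe_screen()` ranks columns by `|⟨x_c, y_c⟩| / ‖x_c‖` (centered inner
product normalized by column norm — the univariate association magnitude
that safe-discard rules for the lasso bound) and keeps the top k (default
1000). Zero-variance columns are always dropped; ties break by event id so
the ranking is order-invariant. The exact SAFE discard inequality
(`|x'y| < λ − ‖x‖‖y‖(λmax − λ)/λmax`) is available as `method = "safe"` for
a given penalty; the default ranking mode reproduces the "k most relevant
variables" behavior while remaining penalty-free.

`fit_lasso_stability()` then:

1. chooses the L1 penalty by 5-fold cross-validated binomial deviance on the
   full data (`cv.glmnet`), taking `lambda.1se` by default — the sparsest
   penalty within one standard error of the minimum. Stability selection
   pairs naturally with the sparser choice; `lambda.min` keeps many
   noise coefficients alive in individual subsamples and inflates the
   retained set;
2. refits the penalized model on `n_subsets = 40` random 80% subsamples
   (without replacement, seeds derived from the master seed by fixed
   offsets) and records, per event, the fraction of subsamples with a
   nonzero coefficient;
3. retains events with fraction ≥ `retain_threshold` (default 0.5 — a
   documented default, since "robust across subsets" admits several
   operationalizations);
4. reports final coefficients from an unpenalized logistic refit on the
   retained set (a lightly ridged refit is the fallback under separation or
   non-convergence).

Metrics stored on the model are 5-fold cross-validated: per fold the
retained set is refit on the training rows and scored out-of-fold; AUC is
the rank statistic over all response/non-response pairs (ties count ½),
sensitivity/specificity use a fixed 0.5 probability threshold (a documented
convention — the threshold is not tuned), and McFadden's pseudo-R² is
`1 − ℓ_model/ℓ_null` with the null the intercept-only fit (the training-fold
response mean).

## Bias audit and routing

A model accurate on average can be systematically worse in a subgroup.
`audit_drug()` fits a population-specific model (same screening +
stability-selection pipeline, restricted to subgroup rows, cross-validated)
and compares held-out McFadden R² of the general and specific models on the
same subgroup rows. Drugs with fewer than `min_cases = 68` subgroup episodes
are skipped with an explicit `insufficient_cases` status rather than
audited on noise.

The adoption criterion is an explicit margin: the specific model is adopted
only when its held-out R² exceeds the general model's by more than
`decision_margin`. The default margin is **0.05** (five pseudo-R² points).
A zero margin is tempting ("any improvement wins") but wrong in practice:
under a true null, held-out R² differences between the two models are
symmetric noise of a few points, so margin 0 adopts a spurious subgroup
model roughly half the time. Five points sits well above that noise floor at
the audit's sample sizes while remaining far below the improvement a real
coefficient shift produces (tens of points in the planted-shift
experiments). The margin is a parameter precisely because no published
criterion pins it down; ties keep the parsimonious general model.

`apply_routing()` records decisions in a (drug, subgroup) → model routing
table; unaudited combinations route to the general model, updates are
idempotent, and conflicting duplicate results are an error.

## Adaptive intake

The intake works over a **prototype table**: feature-value combinations
describing at least `min_support = 100` patients each, with empirical
per-drug response rates. The interview maintains the set of prototypes
consistent with the answers so far and greedily asks the unasked feature
with the largest expected information gain, in bits, over the
**recommendation label** — the advice branch the recommendation rules induce
on each surviving row. Making the label (not prototype identity) the target
is a design choice: the interview exists to pin down the advice, and it
yields a principled stopping rule — stop as soon as every surviving
prototype implies the same recommendation. The labeling objective is
pluggable (`label_fun`) since other targets (e.g. response-probability
variance) are defensible.

Answer probabilities are proportional to surviving patient counts.
"Unknown" is a first-class answer value: rows with an unrecorded feature
value form an explicit `unknown` branch, and partitioning on it keeps gain
nonnegative and the interview order-independent (a sequence of answers
filters to exactly the one-shot filter). Features constant among survivors
are never proposed — this is how logical preclusion emerges: once sex =
male has been answered, no surviving prototype varies on pregnancy, so the
question cannot be asked. A `question_budget` (default 25) is a hard stop
for degenerate tables.

The greedy policy is not optimal in general; the test suite compares its
expected question count against an exhaustive search over adaptive policies
of depth ≤ 4 on 16-row tables and requires agreement within one expected
question.

## Suicide-risk triage

Risk detection (mapping conversation text to categories) is out of scope;
the triage consumes detected category ids from a fixed 14-category taxonomy
(active ideation, passive ideation, prior suicidal behavior, non-suicidal
self-injury, thwarted belongingness/burden, intolerable pain or acute
exacerbation, eating/personality-disorder episode, preparatory actions,
severe sleep loss, adverse life events, victimization, poor attachment,
sexual/gender confusion, recklessness/impulsivity). Duplicate mentions
collapse. A count **above three** routes to a crisis line — the boundary at
which factor counts near-perfectly separate high/moderate from low risk —
one to three factors to a Safety Plan supporter, zero to no referral. Only
the upper boundary is externally anchored; the ≥1 lower boundary is a
conservative default, and both are configurable. Adding a factor never
lowers acuity.

## Advice

`impute_missing()` completes the patient's event vector. Two modes:
`assume-absent` treats unmentioned events as not having occurred (the
deployed-prototype behavior — conversational respondents do not enumerate
negatives); `expected` fills unreported events with logistic expectations
from a network of linked regressions (one regression per event, predicting
it from other events — a structured-equation view of the history). The
model set must be acyclic; this is validated at load time, and evaluation in
topological order makes the result independent of storage order. Reported
events are never overwritten; unreported events with no imputation model
default to 0.

`predict_responses()` evaluates the routed model per drug;
`recommend()` applies fixed rules in precedence order:

1. severity low → no antidepressant, non-drug referral (e.g. exercise);
2. no drug's predicted probability exceeds **0.10** → options other than
   common oral antidepressants;
3. top two within **0.05** of each other → either of the two;
4. otherwise the single top drug.

The 10% rule is read as an absolute predicted-probability floor (the two
published statements of the rule only cohere under the absolute reading); a
relative-to-baseline mode exists but is off by default. Ties break by drug
name, so the function is pure.

`explain_recommendation()` produces the counterfactual lists: every schema
event is flipped one at a time *in the profile* (so expected-mode imputation
propagates downstream), the pipeline re-run, and the event listed iff the
advice branch or named drug set changes — absent/unreported events whose
presence would flip the advice, and present events whose absence would.
Lists are sorted by the magnitude of the induced change in the top predicted
probability. The scan is exhaustive by default (`max_events` caps it with a
truncation flag for very large schemas). Section 1 of the rendered document
lists reported events carrying a nonzero coefficient in *any* drug model
("relevant to any drug" rather than "to the recommended drug" — flagged as a
choice). All four sections come from pre-set templates; nothing is
generated.

## Dialogue topics

`build_topic_network()` derives a directed acyclic topic graph from the
knowledgebase: events are grouped into named topics, edge weights accumulate
cross-topic imputation dependencies (absolute coefficients) and co-retention
of events within drug models, and every edge is oriented from the
higher-priority topic to the lower, which guarantees acyclicity by
construction (a cycle check runs anyway). The real network behind deployed
systems of this kind is not public, so this derivation is a reproducible
stand-in, not a reconstruction; the priority order and co-relevance
threshold are the tunable surface. The controller (`next_topic()`)
redirects on digressions, stays on an open topic up to `per_topic_cap = 6`
turns, advances only to topics whose predecessors are resolved (visit order
is always a topological order), and terminates within
`topics × (cap + 1)` decisions.

## Numerical and testing notes

* Determinism: every stochastic step takes an explicit seed; subsample and
  fold seeds derive from it by fixed offsets. Identical configuration ⇒
  byte-identical pipeline artifacts.
* The penalized-fit oracle in the tests is an independent IRLS coordinate
  descent on glmnet's objective (`−(1/n)·loglik + λ‖β‖₁`, unstandardized,
  free intercept); agreement is required to 1e-6 on ≤10-row problems away
  from separation.
* Problem sizes in the test suite: toy fixtures for oracle equivalence
  (≤ 16 rows), n = 1500–2800 cohorts for behavioral checks, and
  20-replication experiments at n = 5000 (recovery) and n = 2800 (audit) —
  sizes chosen so the full suite completes in minutes while leaving the
  Monte-Carlo margins comfortably above their thresholds.
* Known limitations: synthetic dispensing streams realize each disposition
  with one fixed template (no stockpiling, dose tapering, or eligibility
  gaps); event semantics are anonymous ids, not real ICD/NDC/CPT codes; the
  imputation network is user-supplied rather than learned; and published
  headline accuracies from proprietary cohorts are not reproduction targets
  — the package's claims are about recovering known synthetic truth.
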