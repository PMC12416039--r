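# Fixtures built in code: toy knowledgebases, cohorts, prototype tables.

toy_schema <- function(ids = c("DX_001", "DX_002", "RX_001", "RX_002", "PX_001")) {
  data.frame(event_id = ids,
             vocabulary = sub("_.*", "", ids),
             stringsAsFactors = FALSE)
}

toy_model <- function(drug, intercept, coefficients,
                      population_tag = "general") {
  structure(list(drug = drug, intercept = intercept,
                 coefficients = coefficients,
                 retained_fraction =
                   stats::setNames(rep(1, length(coefficients)),
                                   names(coefficients)),
                 metrics = NULL, population_tag = population_tag,
                 settings = list()),
            class = "drug_model")
}

# Two-drug knowledgebase where event RX_001 carries weight +2 for drug B
# only; used for counterfactual-explanation oracles.
toy_kb_two_drug <- function() {
  schema <- toy_schema()
  knowledgebase(
    schema = schema,
    general = list(
      A = toy_model("A", intercept = 0.2,
                    coefficients = c(DX_001 = 0.5)),
      B = toy_model("B", intercept = -0.1,
                    coefficients = c(RX_001 = 2.0, DX_001 = 0.3))))
}

toy_kb_zero <- function() {
  schema <- toy_schema()
  knowledgebase(
    schema = schema,
    general = list(
      A = toy_model("A", intercept = 0.3, coefficients = c(DX_001 = 0)),
      B = toy_model("B", intercept = -0.4, coefficients = numeric(0))))
}

# Standard small cohort with three planted coefficients.
planted_cohort <- function(n = 2000, seed = 11, prevalence = 0.3,
                           betas = c(DX_001 = 1.2, RX_001 = -1.0,
                                     PX_001 = 1.0),
                           subgroup_fraction = 0, subgroup_shifts = NULL) {
  cfg <- cohort_config(
    n_patients = n, drugs = "sertraline", n_events = 50,
    event_prevalence = prevalence,
    true_models = list(sertraline = list(intercept = -0.5,
                                         coefficients = betas)),
    subgroup_fraction = subgroup_fraction,
    subgroup_shifts = subgroup_shifts,
    seed = seed)
  generate_cohort(cfg)
}

cohort_feature_matrix <- function(cohort) {
  ep <- build_episodes(cohort$dispensings)
  ep <- ep[!duplicated(ep$patient_id), , drop = FALSE]
  feature_matrix(cohort$events, ep, cohort$schema)
}

# Small prototype table with hand-set per-drug rates. Labels under the
# default moderate-severity recommendation rules differ across rows.
toy_prototype_table <- function() {
  rows <- expand.grid(sex = c("female", "male"),
                      prior_ssri = c("no", "yes"),
                      insomnia = c("no", "yes"),
                      stringsAsFactors = FALSE)
  rows$count <- c(400L, 300L, 250L, 150L, 200L, 120L, 180L, 100L)
  # drug A dominates unless prior_ssri = yes, where B pulls clearly ahead
  rates <- cbind(
    A = ifelse(rows$prior_ssri == "yes", 0.20, 0.45),
    B = ifelse(rows$prior_ssri == "yes", 0.40, 0.25))
  prototype_table(rows, rates, min_support = 100L)
}

# Theoretical AUC of a generating logistic model, by large-sample simulation
# from the model itself (independent of any fitting code).
theoretical_auc <- function(intercept, betas, prevalence, n = 200000,
                            seed = 999) {
  set.seed(seed)
  x <- matrix(rbinom(n * length(betas), 1, prevalence), n, length(betas))
  p <- 1 / (1 + exp(-(intercept + drop(x %*% betas))))
  y <- rbinom(n, 1, p)
  r <- rank(p)
  n1 <- sum(y); n0 <- n - n1
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
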