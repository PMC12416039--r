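# Configuration, pipeline orchestration, and on-disk artifacts.
#
# Ties the stages together: simulate -> episodes -> build-kb ->
# prototypes, with every artifact written as plain text (CSV / JSON / YAML)
# and stamped with provenance (seed, settings, package version), so a rerun
# with an identical configuration reproduces identical artifacts.

#' Read and validate a run configuration
#'
#' @param path YAML file, or a list with the same structure. Recognized
#'   keys: `seed` (required), `n_patients`, `drugs`, `n_events`,
#'   `event_prevalence`, `subgroup_fraction`, `windows`
#'   (`response_window_days`, `disposition_window_days`,
#'   `gap_tolerance_days`), `thresholds` (`retain_threshold`,
#'   `decision_margin`, `response_floor`, `tie_window`), `screen_k`,
#'   `n_subsets`, `true_models`, `min_support`, `intake_features`.
#' @return validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(cfg$seed)) stop("config error: seed is required")
  cfg$seed <- as.integer(cfg$seed)
  th <- cfg$thresholds %||% list()
  th$retain_threshold <- th$retain_threshold %||% 0.5
  th$decision_margin <- th$decision_margin %||% 0
  th$response_floor <- th$response_floor %||% 0.10
  th$tie_window <- th$tie_window %||% 0.05
  if (th$retain_threshold < 0 || th$retain_threshold > 1) {
    stop("config error: retain_threshold outside [0, 1]")
  }
  if (th$response_floor < 0 || th$response_floor > 1 ||
      th$tie_window < 0 || th$tie_window > 1) {
    stop("config error: recommendation floors outside [0, 1]")
  }
  cfg$thresholds <- th
  w <- cfg$windows %||% list()
  cfg$windows <- episode_windows(
    w$response_window_days %||% 70L,
    w$disposition_window_days %||% 100L,
    w$gap_tolerance_days %||% 15L)
  cfg$n_patients <- as.integer(cfg$n_patients %||% 1000L)
  cfg$n_events <- as.integer(cfg$n_events %||% 50L)
  cfg$drugs <- cfg$drugs %||% c("sertraline", "bupropion", "citalopram")
  cfg$screen_k <- as.integer(cfg$screen_k %||% 1000L)
  cfg$n_subsets <- as.integer(cfg$n_subsets %||% 40L)
  cfg$min_support <- as.integer(cfg$min_support %||% 100L)
  structure(cfg, class = "run_config")
}

# Default ground-truth models when a config does not declare any: each drug
# gets three moderate planted coefficients on distinct events.
default_true_models <- function(drugs, schema, intercept = -0.3) {
  models <- list()
  for (i in seq_along(drugs)) {
    picks <- schema$event_id[((i - 1) * 3 + 1:3 - 1) %% nrow(schema) + 1]
    models[[drugs[i]]] <- list(
      intercept = intercept,
      coefficients = stats::setNames(c(1.0, -0.9, 0.8), picks))
  }
  models
}

parse_true_models <- function(tm) {
  lapply(tm, function(m) list(
    intercept = as.numeric(m$intercept),
    coefficients = unlist_named(m$coefficients)))
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full pipeline
#'
#' Stages, in dependency order: simulate a cohort, build episodes and
#' summaries, fit the per-drug knowledgebase, derive the intake prototype
#' table. All artifacts are written under `out_dir`; a `provenance.json`
#' records the configuration, seed, and package version. Rerunning with an
#' identical configuration reproduces identical artifacts.
#'
#' @param config a [read_run_config()] result, a path to a YAML config, or a
#'   plain list.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory artifacts (`cohort`,
#'   `episodes`, `kb`, `prototypes`) and `paths`.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  stage_log("simulate", "generating cohort of ", cfg$n_patients, " patients")
  schema <- event_schema(cfg$n_events)
  true_models <- if (is.null(cfg$true_models)) {
    default_true_models(cfg$drugs, schema)
  } else parse_true_models(cfg$true_models)
  ccfg <- cohort_config(
    n_patients = cfg$n_patients, drugs = cfg$drugs, n_events = cfg$n_events,
    event_prevalence = cfg$event_prevalence %||% 0.2,
    true_models = true_models,
    subgroup_fraction = cfg$subgroup_fraction %||% 0,
    seed = cfg$seed)
  cohort <- generate_cohort(ccfg)
  paths$events <- file.path(out_dir, "events.csv")
  paths$dispensings <- file.path(out_dir, "dispensings.csv")
  paths$labels <- file.path(out_dir, "ground_truth_labels.csv")
  utils::write.csv(cohort$events, paths$events, row.names = FALSE)
  utils::write.csv(cohort$dispensings, paths$dispensings, row.names = FALSE)
  utils::write.csv(cohort$labels, paths$labels, row.names = FALSE)

  stage_log("episodes", "building treatment episodes")
  episodes <- build_episodes(cohort$dispensings, cfg$windows)
  paths$episodes <- file.path(out_dir, "episodes.csv")
  utils::write.csv(episodes, paths$episodes, row.names = FALSE)
  paths$dispositions <- file.path(out_dir, "disposition_summary.csv")
  utils::write.csv(summarize_dispositions(episodes), paths$dispositions,
                   row.names = FALSE)
  paths$frequency <- file.path(out_dir, "treatment_frequency.csv")
  utils::write.csv(treatment_frequency_table(episodes), paths$frequency,
                   row.names = FALSE)

  stage_log("build-kb", "fitting per-drug response models")
  kb <- build_kb(cohort, drugs = cfg$drugs, windows = cfg$windows,
                 screen_k = cfg$screen_k, seed = cfg$seed,
                 n_subsets = cfg$n_subsets,
                 retain_threshold = cfg$thresholds$retain_threshold)
  kb$provenance$config <- cfg[c("seed", "n_patients", "n_events", "drugs",
                                "screen_k", "n_subsets")]
  paths$kb <- file.path(out_dir, "knowledgebase.json")
  save_kb(kb, paths$kb)
  paths$coefficients <- file.path(out_dir, "coefficients.csv")
  utils::write.csv(kb_coefficient_table(kb), paths$coefficients,
                   row.names = FALSE)

  stage_log("prototypes", "deriving intake prototype table")
  feats <- cfg$intake_features %||%
    utils::head(unique(unlist(lapply(kb$general, function(m)
      names(m$coefficients)[m$coefficients != 0]))), 3)
  prototypes <- NULL
  if (length(feats)) {
    ep1 <- build_episodes(cohort$dispensings, cfg$windows)
    ep1 <- ep1[!duplicated(ep1$patient_id), , drop = FALSE]
    pd <- as.data.frame(cohort$features[ep1$patient_id, feats, drop = FALSE])
    pd$drug <- ep1$index_drug
    pd$response <- ep1$response
    prototypes <- tryCatch(
      derive_prototypes(pd, feats, min_support = cfg$min_support),
      error = function(e) {
        stage_log("prototypes", "skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(prototypes)) {
      paths$prototypes <- file.path(out_dir, "prototypes.csv")
      utils::write.csv(
        cbind(prototypes$rows, count = prototypes$count, prototypes$rates),
        paths$prototypes, row.names = FALSE)
    }
  }

  prov <- list(seed = cfg$seed, package_version = "0.1.0",
               thresholds = cfg$thresholds, windows = unclass(cfg$windows),
               n_patients = cfg$n_patients, n_events = cfg$n_events,
               drugs = cfg$drugs)
  paths$provenance <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, paths$provenance, auto_unbox = TRUE, digits = NA)

  invisible(list(cohort = cohort, episodes = episodes, kb = kb,
                 prototypes = prototypes, paths = paths))
}

#' Coefficient export table
#'
#' @param kb a `knowledgebase`.
#' @return data.frame (drug, event, coefficient, retained_fraction) over all
#'   nonzero model coefficients.
#' @export
kb_coefficient_table <- function(kb) {
  out <- lapply(names(kb$general), function(d) {
    m <- kb$general[[d]]
    if (length(m$coefficients) == 0) return(NULL)
    data.frame(drug = d, event = names(m$coefficients),
               coefficient = unname(m$coefficients),
               retained_fraction =
                 unname(m$retained_fraction[names(m$coefficients)]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out %||% data.frame(drug = character(0), event = character(0),
                      coefficient = numeric(0),
                      retained_fraction = numeric(0))
}
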