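# End-to-end orchestration: ingest -> clean -> metrics -> cognition ->
# models -> network, with a run manifest accounting for every exclusion.

#' Default pipeline configuration
#'
#' @param logs,clinical,norms,corpus Input paths (ignored when
#'   `simulate = TRUE`).
#' @param simulate Generate a synthetic study instead of reading inputs.
#' @param seed Seed for the synthetic study.
#' @param window_days Evaluation window half-width in days.
#' @param engines Canonical engine labels to keep.
#' @param unique_terms_mode Passed to [subject_profiles()].
#' @param exclude_terms Hub terms removed from the co-occurrence graph.
#' @param composite_mode Passed to [composite_scores()].
#' @return A named list; can also be written/read as YAML.
#' @export
pipeline_config <- function(logs = NULL, clinical = NULL, norms = NULL,
                            corpus = NULL, simulate = is.null(logs),
                            seed = 1L, window_days = 91,
                            engines = default_engines(),
                            unique_terms_mode = "distinct_vocab",
                            exclude_terms = character(0),
                            composite_mode = "tests") {
  list(logs = logs, clinical = clinical, norms = norms, corpus = corpus,
       simulate = simulate, seed = seed, window_days = window_days,
       engines = engines, unique_terms_mode = unique_terms_mode,
       exclude_terms = exclude_terms, composite_mode = composite_mode)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the [pipeline_config()]
#'   fields.
#' @return A pipeline configuration list.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  cfg[names(raw)] <- raw
  if (!is.null(raw$logs)) cfg$simulate <- isTRUE(raw$simulate)
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes every stage on real inputs or on a freshly generated
#' synthetic study, writes all outputs under `out_dir`, and records a
#' manifest with subject and record counts at every filtering stage
#' (parsed, engine-filtered, windowed, profiled), so attrition
#' reconciles exactly.
#'
#' @param config A [pipeline_config()] list or path to a YAML file.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the fitted `models`, `profiles`,
#'   `descriptives`, `graph` and the `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   seed = config$seed, simulate = isTRUE(config$simulate),
                   window_days = config$window_days)

  if (isTRUE(config$simulate)) {
    study <- simulate_study(generator_config(seed = config$seed))
    input_dir <- file.path(out_dir, "simulated_inputs")
    paths <- write_study(study, input_dir)
    config$logs <- paths[["logs"]]
    config$clinical <- paths[["clinical"]]
    config$norms <- paths[["norms"]]
    config$corpus <- paths[["corpus"]]
    jsonlite::write_json(
      study$logs$truth$subjects,
      file.path(input_dir, "truth_subjects.json"), digits = NA)
  }
  manifest$inputs <- config[c("logs", "clinical", "norms", "corpus")]

  records <- read_search_log(config$logs)
  clinical <- read_clinical_table(config$clinical)
  norms <- read_norms(config$norms)
  corpus <- read_word_corpus(config$corpus)
  manifest$n_parsed <- nrow(records)
  manifest$n_malformed_skipped <- attr(records, "n_skipped")
  manifest$subjects_parsed <- length(unique(records$subject_id))

  records <- filter_engine(records, config$engines)
  manifest$n_engine_filtered <- nrow(records)
  manifest$subjects_engine_filtered <- length(unique(records$subject_id))

  records <- window_to_evaluation(records, clinical, config$window_days)
  manifest$n_windowed <- nrow(records)
  manifest$subjects_windowed <- length(unique(records$subject_id))
  manifest$excluded_no_window_search <- attr(records, "excluded_subjects")

  cleaned <- clean_searches(records, corpus)
  tab <- term_frequency_table(cleaned)
  profiles <- subject_profiles(cleaned, tab,
                               unique_terms_mode = config$unique_terms_mode)
  manifest$subjects_profiled <- nrow(profiles)
  desc <- cohort_descriptives(profiles, cleaned, tab)

  comp <- composite_scores(clinical, norms, mode = config$composite_mode)
  d <- merge(profiles, comp, by = "subject_id")
  d <- merge(d, clinical[c("subject_id", "age", "sex", "education")],
             by = "subject_id")
  d$female <- as.integer(d$sex == "female")
  models <- lexical_models(
    d, covariates = c("age", "female", "education"))

  graph <- cooccurrence_graph(cleaned, exclude = config$exclude_terms)

  # outputs
  utils::write.csv(cleaned$tokens, file.path(out_dir, "cleaned_tokens.csv"),
                   row.names = FALSE)
  utils::write.csv(profiles, file.path(out_dir, "subject_profiles.csv"),
                   row.names = FALSE)
  utils::write.csv(comp, file.path(out_dir, "composite_scores.csv"),
                   row.names = FALSE)
  sink(file.path(out_dir, "descriptives.txt")); print(desc); sink()
  tab3 <- model_table(models)
  utils::write.csv(cbind(term = rownames(tab3), tab3),
                   file.path(out_dir, "model_table.csv"), row.names = FALSE)
  jsonlite::write_json(
    lapply(models, function(f) list(
      metric = f$metric,
      coefficients = as.data.frame(f$coefficients),
      p_one_sided = f$p_one_sided, r_squared = f$r_squared, n = f$n,
      vif = as.list(f$vif))),
    file.path(out_dir, "models.json"), digits = NA, auto_unbox = TRUE)
  export_graph(graph, file.path(out_dir, "cooccurrence"))

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(list(models = models, profiles = profiles, descriptives = desc,
                 composites = comp, graph = graph, cleaned = cleaned,
                 manifest = manifest))
}
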