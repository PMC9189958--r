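#' Experiment configuration
#'
#' Bundles a simulation config (or an existing cohort directory), a network
#' config, and evaluation settings into one serializable driver
#' configuration. Re-running from the serialized copy reproduces all
#' outputs.
#'
#' @param sim a `seqrisk_sim_config`, or NULL when `cohort_dir` is given.
#' @param model a `seqrisk_model_config`.
#' @param cohort_dir optional directory with an existing cohort (persons.csv
#'   / events.csv).
#' @param sexes strata to analyse.
#' @param seed global seed for splits.
#' @param compare_cox run the 5x2 comparison against the Cox comparator.
#' @param ablation also train the reduced-predictor-set network.
#' @param local_hr_K replicates for local hazard ratios (0 skips the stage).
#' @param hr_codes codes to perturb in the local-HR table.
#' @param min_persons vocabulary rarity threshold.
#' @param out_dir output directory.
#' @return A `seqrisk_experiment` list.
#' @export
experiment_config <- function(sim = NULL, model = model_config(),
                              cohort_dir = NULL, sexes = "F", seed = 1L,
                              compare_cox = TRUE, ablation = FALSE,
                              local_hr_K = 0L, hr_codes = character(0),
                              min_persons = 1L, out_dir = "seqrisk_out") {
  if (is.null(sim) && is.null(cohort_dir))
    stop("provide either a simulation config or a cohort directory")
  structure(list(sim = sim, model = model, cohort_dir = cohort_dir,
                 sexes = sexes, seed = as.integer(seed),
                 compare_cox = isTRUE(compare_cox),
                 ablation = isTRUE(ablation),
                 local_hr_K = as.integer(local_hr_K), hr_codes = hr_codes,
                 min_persons = as.integer(min_persons), out_dir = out_dir),
            class = "seqrisk_experiment")
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, sprintf(...)))
}

#' Run the end-to-end experiment pipeline
#'
#' Simulation (or ingestion of an existing cohort), then per sex stratum:
#' Cox comparator fit and hazard-ratio table, ensemble training, 5x2
#' cross-validated comparison with combined F tests, decile
#' calibration/discrimination tables, optionally the reduced-predictor
#' ablation and perturbation-based local hazard ratios. Every artefact is
#' written as plain text under the configured output directory together
#' with the serialized configuration.
#'
#' @param config a `seqrisk_experiment`.
#' @return The output directory, invisibly; artefacts: `config.yaml`,
#'   `cohort/`, and per stratum `cox_<sex>.json`, `metrics_<sex>.csv`,
#'   `ftest_<sex>.csv`, `deciles_<sex>.csv`, `hr_<sex>.csv`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_experiment_yaml(config, file.path(config$out_dir, "config.yaml"))
  if (!is.null(config$cohort_dir)) {
    stage_log("ingest", "reading cohort from %s", config$cohort_dir)
    cohort <- read_cohort(config$cohort_dir)
  } else {
    stage_log("simulate", "n = %d, seed = %d", config$sim$n_persons,
              config$sim$seed)
    cohort <- simulate_cohort(config$sim)$cohort
    write_cohort(cohort, file.path(config$out_dir, "cohort"))
  }
  for (sex in config$sexes) {
    stratum <- cohort_stratum(cohort, sex)
    stage_log("stratum", "sex %s: %d persons, %d events", sex,
              nrow(stratum$persons), sum(stratum$persons$cvd_event))
    cox_full <- fit_cox(stratum, "full")
    write_cox(cox_full, file.path(config$out_dir,
                                  sprintf("cox_%s.json", sex)))
    deep_spec <- list(type = "deep", config = config$model,
                      min_persons = config$min_persons)
    if (config$compare_cox) {
      stage_log("compare", "5x2 cross-validation, deep vs Cox")
      cv <- run_5x2_cv(stratum, deep_spec, list(type = "cox"),
                       seed = config$seed)
      utils::write.csv(cv$metrics,
                       file.path(config$out_dir,
                                 sprintf("metrics_%s.csv", sex)),
                       row.names = FALSE)
      ft <- do.call(rbind, lapply(names(cv$ftests), function(m)
        data.frame(metric = m, F = cv$ftests[[m]]$F, p = cv$ftests[[m]]$p)))
      utils::write.csv(ft, file.path(config$out_dir,
                                     sprintf("ftest_%s.csv", sex)),
                       row.names = FALSE)
    } else stage_log("compare", "skipped (compare_cox = FALSE)")
    stage_log("train", "final ensemble on the full stratum")
    ens <- train_ensemble(stratum, config$model,
                          min_persons = config$min_persons)
    f <- predict_log_risk(ens, stratum)
    ref <- reference_person(ens$centering, sex)
    f_ref <- as.numeric(predict_log_risk(
      ens, new_cohort(ref, empty_events(), stratum$lookback_months)))
    bl <- breslow_baseline(f, stratum$persons$follow_up_days,
                           stratum$persons$cvd_event, f_ref = f_ref)
    risk <- five_year_risk(f, bl)
    dec <- decile_table(risk, stratum$persons$follow_up_days,
                        stratum$persons$cvd_event)
    utils::write.csv(dec, file.path(config$out_dir,
                                    sprintf("deciles_%s.csv", sex)),
                     row.names = FALSE)
    if (config$ablation) {
      stage_log("ablation", "reduced predictor set")
      cfg_red <- config$model
      cfg_red$predictor_set <- "reduced"
      if (config$local_hr_K >= 2L) {
        hr_red <- local_hr(ensemble_replicates(stratum, cfg_red,
                                               K = config$local_hr_K,
                                               min_persons = config$min_persons),
                           standard_perturbations(config$hr_codes), sex = sex)
        utils::write.csv(hr_red,
                         file.path(config$out_dir,
                                   sprintf("hr_reduced_%s.csv", sex)),
                         row.names = FALSE)
      }
    }
    if (config$local_hr_K >= 2L) {
      stage_log("local-hr", "K = %d replicates", config$local_hr_K)
      reps <- ensemble_replicates(stratum, config$model,
                                  K = config$local_hr_K,
                                  min_persons = config$min_persons)
      hr <- local_hr(reps, standard_perturbations(config$hr_codes), sex = sex)
      utils::write.csv(hr, file.path(config$out_dir,
                                     sprintf("hr_%s.csv", sex)),
                       row.names = FALSE)
    }
  }
  stage_log("done", "outputs in %s", config$out_dir)
  invisible(config$out_dir)
}

#' Serialize / restore an experiment configuration as YAML
#'
#' @param config a `seqrisk_experiment`.
#' @param path file path.
#' @return `path` (write) or the restored `seqrisk_experiment` (read).
#' @export
write_experiment_yaml <- function(config, path) {
  obj <- unclass(config)
  if (!is.null(obj$sim)) {
    obj$sim <- unclass(obj$sim)
    obj$sim$covariate_effects <- as.list(obj$sim$covariate_effects)
    obj$sim$code_effects <- as.list(obj$sim$code_effects)
    obj$sim$ethnicity_probs <- as.list(obj$sim$ethnicity_probs)
    obj$sim$flag_prevalence <- as.list(obj$sim$flag_prevalence)
  }
  obj$model <- unclass(obj$model)
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_experiment_yaml
#' @export
read_experiment_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  model <- do.call(model_config, obj$model)
  sim <- NULL
  if (!is.null(obj$sim)) {
    s <- obj$sim
    s$lookback_months <- NULL
    s$covariate_effects <- unlist(s$covariate_effects)
    if (is.null(s$covariate_effects)) s$covariate_effects <- numeric(0)
    s$code_effects <- unlist(s$code_effects)
    if (is.null(s$code_effects)) s$code_effects <- numeric(0)
    s$ethnicity_probs <- unlist(s$ethnicity_probs)
    s$flag_prevalence <- unlist(s$flag_prevalence)
    sim <- do.call(sim_config, s)
  }
  experiment_config(sim = sim, model = model, cohort_dir = obj$cohort_dir,
                    sexes = obj$sexes, seed = obj$seed,
                    compare_cox = obj$compare_cox, ablation = obj$ablation,
                    local_hr_K = obj$local_hr_K,
                    hr_codes = if (is.null(obj$hr_codes)) character(0)
                               else obj$hr_codes,
                    min_persons = obj$min_persons, out_dir = obj$out_dir)
}
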