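#' Pipeline configuration
#'
#' A single document describing an end-to-end run: protocol, cohort sizes and
#' simulation profiles, screening thresholds, model specification, and the
#' master seed that funnels all randomness. Defaults reproduce the reference
#' analysis constants (family alpha 0.05 over 89 tests, sex cut 0.01, age cut
#' 0.05).
#'
#' @param n_control,n_case training-cohort group sizes.
#' @param n_validation_control,n_validation_case validation-cohort sizes.
#' @param sampling_rate,total_duration protocol overrides (down-scale the
#'   rate for quick runs; timing structure is unchanged).
#' @param control_disconjugacy_sd,case_disconjugacy_sd simulated effect.
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @param p_sex_cut,p_age_cut covariate exclusion thresholds.
#' @param r_cut deduplication correlation threshold.
#' @param methods classifier methods to fit.
#' @param n_repeats cross-validation repeats.
#' @param seed master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_control = 34, n_case = 34,
                            n_validation_control = 50,
                            n_validation_case = 7,
                            sampling_rate = 500, total_duration = 220,
                            control_disconjugacy_sd = 0,
                            case_disconjugacy_sd = 1.5,
                            alpha = 0.05,
                            p_sex_cut = 0.01, p_age_cut = 0.05,
                            r_cut = 0.9,
                            methods = c("best_subset", "lasso",
                                        "random_forest"),
                            n_repeats = 50, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, p_sex_cut > 0, p_sex_cut < 1,
            p_age_cut > 0, p_age_cut < 1, r_cut > 0, r_cut < 1)
  structure(
    list(n_control = n_control, n_case = n_case,
         n_validation_control = n_validation_control,
         n_validation_case = n_validation_case,
         sampling_rate = sampling_rate, total_duration = total_duration,
         control_disconjugacy_sd = control_disconjugacy_sd,
         case_disconjugacy_sd = case_disconjugacy_sd,
         alpha = alpha, p_sex_cut = p_sex_cut, p_age_cut = p_age_cut,
         r_cut = r_cut, methods = methods, n_repeats = n_repeats,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a JSON file
#' @param path JSON file with any subset of [pipeline_config()] fields.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, obj)
}

config_protocol <- function(config) {
  stimulus_protocol(sampling_rate = config$sampling_rate,
                    total_duration = config$total_duration)
}

config_profiles <- function(config) {
  list(
    control = sim_subject_params(
      "control", disconjugacy_sd = config$control_disconjugacy_sd),
    case = sim_subject_params(
      "case", disconjugacy_sd = config$case_disconjugacy_sd)
  )
}

#' Run the full pipeline and write its artifact directory
#'
#' simulate -> preprocess -> metrics -> screen -> fit -> validate. Writes the
#' cohort CSVs, recording CSVs, metric TSVs, screening TSV, model JSONs,
#' evaluation TSVs, ROC CSVs, and a run manifest (config, config hash, seed,
#' package version, stage counts). Rerunning with the same configuration
#' reproduces the same artifacts.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory, created if needed.
#' @param write_recordings also write per-subject recording CSVs (off by
#'   default: they dominate disk usage).
#' @param quiet suppress stage logging.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir, write_recordings = FALSE,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_ <- function(...) if (!quiet) message(sprintf(...))
  protocol <- config_protocol(config)
  prof <- config_profiles(config)

  # --- simulate ---------------------------------------------------------
  log_("[simulate] training cohort: %d controls + %d cases",
       config$n_control, config$n_case)
  train <- simulate_cohort(config$n_control, config$n_case,
                           prof$control, prof$case, protocol,
                           master_seed = config$seed)
  val <- simulate_cohort(config$n_validation_control,
                         config$n_validation_case,
                         prof$control, prof$case, protocol,
                         master_seed = config$seed + 1L)
  val$cohort$subject_id <- paste0("V", val$cohort$subject_id)
  for (i in seq_along(val$recordings)) {
    val$recordings[[i]]$subject_id <- val$cohort$subject_id[i]
  }
  train$cohort <- label_cohort(train$cohort)
  val$cohort <- label_cohort(val$cohort)
  write_cohort(train$cohort, file.path(out_dir, "cohort_train.csv"))
  write_cohort(val$cohort, file.path(out_dir, "cohort_validation.csv"))
  if (write_recordings) {
    rec_dir <- file.path(out_dir, "recordings")
    dir.create(rec_dir, showWarnings = FALSE)
    for (r in c(train$recordings, val$recordings)) {
      write_recording(r, file.path(rec_dir, paste0(r$subject_id, ".csv")))
    }
  }

  # --- metrics ----------------------------------------------------------
  log_("[metrics] computing %d metrics for %d recordings", 89L,
       length(train$recordings) + length(val$recordings))
  train_metrics <- compute_metric_table(train$recordings, train$cohort)
  val_metrics <- compute_metric_table(val$recordings, val$cohort)
  write_metric_table(train_metrics, file.path(out_dir, "metrics_train.tsv"))
  write_metric_table(val_metrics,
                     file.path(out_dir, "metrics_validation.tsv"))

  # --- screen -----------------------------------------------------------
  thr <- bonferroni_threshold(config$alpha, 89L)
  log_("[screen] Bonferroni threshold %.6g (alpha %.3g / 89 tests)",
       thr, config$alpha)
  labels <- ifelse(train$cohort$group == "case", "case", "control")
  screening <- screen_metrics(
    train_metrics, labels,
    control_table = train_metrics[labels == "control", , drop = FALSE],
    control_demographics = train$cohort[labels == "control", ],
    alpha = config$alpha, p_sex_cut = config$p_sex_cut,
    p_age_cut = config$p_age_cut, r_cut = config$r_cut)
  retained <- attr(screening, "retained")
  log_("[screen] %d/89 metrics pass Bonferroni; %d excluded by covariates; %d candidates retained after dedup",
       sum(screening$pass_bonferroni),
       sum(screening$excluded_by_covariate), length(retained))
  utils::write.table(screening, file.path(out_dir, "screening.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE, na = "")

  if (!length(retained)) {
    log_("[screen] no candidate metrics retained; stopping after screening")
    manifest_path <- write_manifest(config, out_dir, list(retained = 0))
    return(invisible(list(train = train, validation = val,
                          metrics = train_metrics, screening = screening)))
  }

  # --- fit + cross-validate + validate ---------------------------------
  results <- list()
  for (method in config$methods) {
    log_("[fit] %s on %d candidate metric(s)", method, length(retained))
    model <- fit_by_method(method, train_metrics, labels, retained,
                           seed = config$seed)
    write_model(model, file.path(out_dir, paste0("model_", method, ".json")))
    cv <- repeated_cv(train_metrics, labels, method, retained,
                      n_repeats = config$n_repeats, seed = config$seed)
    log_("[cv] %s: mean AUC %.3f, mean misclassification %.1f%%",
         method, cv$mean_auc, cv$mean_misclassification)
    report <- validate_external(model, val_metrics, val$cohort)
    write_report(report,
                 file.path(out_dir, paste0("validation_", method, ".tsv")))
    if (!is.null(report$roc_points)) {
      write_roc_points(report,
                       file.path(out_dir, paste0("roc_", method, ".csv")))
    }
    results[[method]] <- list(model = model, cv = cv, report = report)
  }

  write_manifest(config, out_dir, list(
    retained = length(retained),
    pass_bonferroni = sum(screening$pass_bonferroni)))
  invisible(list(train = train, validation = val, metrics = train_metrics,
                 validation_metrics = val_metrics, screening = screening,
                 models = results))
}

write_manifest <- function(config, out_dir, counts) {
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = NA)
  manifest <- list(
    config = unclass(config),
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("oculobox")),
    counts = counts
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  path
}
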