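#' Validate a pipeline configuration
#'
#' @param cfg configuration list (see [run_pipeline()]).
#' @return the validated config with defaults filled in.
#' @export
validate_run_config <- function(cfg) {
  if (!is.list(cfg)) fail_field("config", "must be a list / JSON object")
  if (is.null(cfg$seed) || !is.numeric(cfg$seed))
    fail_field("seed", "an integer seed is required")
  if (is.null(cfg$experiment)) cfg$experiment <- 1L
  if (!cfg$experiment %in% 1:3) fail_field("experiment", "must be 1, 2 or 3")
  known <- c("simulate", "preprocess", "caf", "stats", "fit", "optimality")
  if (is.null(cfg$stages)) cfg$stages <- "simulate"
  bad <- setdiff(cfg$stages, known)
  if (length(bad))
    fail_field("stages", paste("unknown stage:", paste(bad, collapse = ", ")))
  if (is.null(cfg$cohort)) cfg$cohort <- list()
  if (is.null(cfg$cohort$n_subjects_per_group)) cfg$cohort$n_subjects_per_group <- 2L
  if (is.null(cfg$cohort$model)) cfg$cohort$model <- "dmc_shift"
  if (!cfg$cohort$model %in% c("ddm", "dmc", "ddm_shift", "dmc_shift"))
    fail_field("cohort.model", "unknown model")
  if (is.null(cfg$fit)) cfg$fit <- list()
  if (is.null(cfg$fit$model)) cfg$fit$model <- cfg$cohort$model
  if (is.null(cfg$fit$profile)) cfg$fit$profile <- "ci"
  if (is.null(cfg$optimality)) cfg$optimality <- list()
  if (is.null(cfg$optimality$n_trials)) cfg$optimality$n_trials <- 2000L
  cfg
}

#' Run the simulate -> preprocess -> analyse pipeline
#'
#' Executes the requested stages in dependency order (later stages imply
#' `simulate`), writing each stage's outputs as plain-text tables / JSON
#' into `out_dir` and finishing with a run manifest (config hash, seeds,
#' package version, file inventory with checksums, timestamp). A single root
#' seed spawns named substreams per stage, so runs are reproducible byte for
#' byte on the data files.
#'
#' @param config a configuration list or a path to a JSON file with fields
#'   `seed`, `experiment`, `stages`, and optional `cohort`
#'   (`n_subjects_per_group`, `model`), `fit` (`model`, `profile`),
#'   `optimality` (`n_trials`).
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly; also written to `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  cfg <- validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(name) files <<- c(files, name)
  path <- function(name) file.path(out_dir, name)
  write_json_file <- function(x, name) {
    jsonlite::write_json(x, path(name), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    emit(name)
  }

  econf <- experiment_config(cfg$experiment)
  spec <- cohort_spec(cfg$cohort$n_subjects_per_group,
                      model = cfg$cohort$model,
                      seed = derive_seed(cfg$seed, "simulate"))
  cohort <- generate_cohort(spec, econf)
  write_trials(cohort$trials, path("trials.tsv")); emit("trials.tsv")
  write.table(cohort$true_params, path("true_params.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  emit("true_params.tsv")

  acc <- rt <- NULL
  if (any(c("preprocess", "caf", "stats", "fit") %in% cfg$stages)) {
    kept <- exclude_subjects(cohort$trials)
    acc <- filter_trials(kept$trials, "accuracy")
    rt <- filter_trials(kept$trials, "rt")
    write_trials(acc$trials, path("trials_accuracy.tsv")); emit("trials_accuracy.tsv")
    write_trials(rt$trials, path("trials_rt.tsv")); emit("trials_rt.tsv")
    write_json_file(list(subjects = kept$report$subjects_excluded,
                         accuracy_stream = acc$report,
                         rt_stream = rt$report), "exclusion_report.json")
    eff <- congruency_effects(acc$trials, rt$trials)
    write.table(eff$subjects, path("congruency_effects.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    emit("congruency_effects.tsv")
  }
  if ("caf" %in% cfg$stages) {
    caf <- conditional_accuracy(acc$trials)
    write.table(as.data.frame(caf), path("caf.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    emit("caf.tsv")
  }
  fits_tab <- NULL
  if ("fit" %in% cfg$stages) {
    fits <- fit_subjects(rt_stream_for_fit(acc$trials), cfg$fit$model,
                         control = fit_control(cfg$fit$profile),
                         seed = derive_seed(cfg$seed, "fit"))
    fits_tab <- fit_table(fits, groups = cohort$true_params)
    write.table(fits_tab, path("fit_params.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    emit("fit_params.tsv")
  }
  if ("stats" %in% cfg$stages) {
    # fitted parameters when available, otherwise the generating truth
    tab <- if (!is.null(fits_tab)) fits_tab else
      cbind(cohort$true_params)
    param <- if (startsWith(cfg$cohort$model, "ddm")) "v" else "shift_delta"
    sc <- shift_difference_scores(tab, if (endsWith(cfg$cohort$model, "_shift"))
      "shift_delta" else param)
    a <- sc$score[sc$group == "reward_congruent"]
    b <- sc$score[sc$group == "reward_incongruent"]
    res <- independent_t(a, b)
    write_json_file(list(parameter = "difference_score",
                         source = if (is.null(fits_tab)) "true_params" else "fitted",
                         t = res$t, df = res$df, p = res$p, d = res$d,
                         d_ci = as.numeric(res$d_ci),
                         welch_used = res$welch_used), "stats.json")
  }
  if ("optimality" %in% cfg$stages) {
    base <- ddm_shift_params(a = 0.12, v_congruent = 0.35,
                             v_incongruent = 0.25, t0_mean = 0.35,
                             t0_sd = 0.04, shift_time_mean = 0.3,
                             shift_time_sd = 0.05)
    grid <- sweep_grid(base, econf, n_trials = cfg$optimality$n_trials,
                       seed = derive_seed(cfg$seed, "optimality"))
    for (nm in names(grid$mean_discounted_reward)) {
      fn <- sprintf("optimality_%s.tsv", nm)
      write.table(grid$mean_discounted_reward[[nm]], path(fn), sep = "\t",
                  quote = FALSE, col.names = NA)
      emit(fn)
    }
    write_json_file(list(shift_values = grid$shift_values,
                         drift_values = grid$drift_values,
                         n_trials_per_cell = grid$n_trials_per_cell,
                         iti_ms = grid$iti_ms,
                         base_params_source = "package defaults"),
                    "optimality_meta.json")
  }

  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, cfg_file, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    config = cfg,
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("shiftddm")),
    files = lapply(stats::setNames(files, files), function(f)
      unname(tools::md5sum(file.path(out_dir, f)))),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# accuracy-stream rows are what the KS fit consumes (errors retained,
# nulls/post-event trials removed)
rt_stream_for_fit <- function(acc_trials) {
  acc_trials[!is.na(acc_trials$rt_ms) & !is.na(acc_trials$accuracy), ,
             drop = FALSE]
}
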