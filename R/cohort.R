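#' Specification of a synthetic cohort
#'
#' Describes how a cohort of simulated participants is drawn: how many
#' subjects per reward group, which generative model produces behaviour, and
#' the between-subject population (mean and SD per parameter) from which each
#' subject's true parameter vector is sampled. The population may be a single
#' `list(mean = , sd = )` shared by both groups, or a named list with one
#' such population per group (to build cohorts with true group differences).
#'
#' @param n_subjects_per_group number of subjects in each reward group.
#' @param model `"ddm"`, `"dmc"`, `"ddm_shift"` or `"dmc_shift"`; the
#'   no-shift variants force both shift deltas to 0.
#' @param param_population `list(mean = named numeric, sd = named numeric)`
#'   over the model's parameter names, or
#'   `list(reward_congruent = ..., reward_incongruent = ...)`. Defaults to
#'   [default_population()].
#' @param seed integer root seed; every subject draws from a derived
#'   substream, so cohorts are reproducible byte for byte.
#' @return a list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_subjects_per_group, model = "dmc_shift",
                        param_population = NULL, seed = 1L) {
  if (!model %in% c("ddm", "dmc", "ddm_shift", "dmc_shift"))
    fail_field("model", "must be one of ddm, dmc, ddm_shift, dmc_shift")
  if (!is.numeric(n_subjects_per_group) || n_subjects_per_group < 1)
    fail_field("n_subjects_per_group", "must be >= 1")
  if (is.null(param_population)) param_population <- default_population(model)
  spec <- list(n_subjects_per_group = as.integer(n_subjects_per_group),
               model = model, param_population = param_population,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  spec
}

#' Default between-subject parameter populations
#'
#' Typical values from the evidence-accumulation literature: DDM on the
#' classic `sigma = 0.1` scale (seconds), DMC on the `sigma = 4` scale
#' (milliseconds). Boundary-shift means are positive and larger for
#' congruent than incongruent trials, the pattern the fitted models show;
#' shift times sit a few hundred ms into accumulation.
#'
#' @param model model name as in [cohort_spec()].
#' @return `list(mean = , sd = )` of named numeric vectors.
#' @export
default_population <- function(model) {
  if (startsWith(model, "ddm")) {
    # chosen to emulate observed task-switching behaviour: ~95% / ~90%
    # accuracy and ~550 / ~630 ms mean RT on congruent / incongruent trials
    mean <- c(a = 0.11, z_rel = 0.5, v_congruent = 0.28, v_incongruent = 0.20,
              t0_mean = 0.35, t0_sd = 0.04,
              shift_delta_congruent = 0.03, shift_delta_incongruent = 0.01,
              shift_time_mean = 0.30, shift_time_sd = 0.05)
    sd <- c(a = 0.02, z_rel = 0, v_congruent = 0.06, v_incongruent = 0.06,
            t0_mean = 0.04, t0_sd = 0.01,
            shift_delta_congruent = 0.025, shift_delta_incongruent = 0.025,
            shift_time_mean = 0.05, shift_time_sd = 0.01)
  } else {
    mean <- c(b = 75, mu_c = 0.5, zeta = 20, t_peak = 40,
              t0_mean = 320, t0_sd = 30,
              shift_delta_congruent = 10, shift_delta_incongruent = 5,
              shift_time_mean = 300, shift_time_sd = 50)
    sd <- c(b = 10, mu_c = 0.08, zeta = 5, t_peak = 8,
            t0_mean = 30, t0_sd = 5,
            shift_delta_congruent = 15, shift_delta_incongruent = 15,
            shift_time_mean = 50, shift_time_sd = 10)
  }
  if (model %in% c("ddm", "dmc")) {
    shift_fields <- c("shift_delta_congruent", "shift_delta_incongruent",
                      "shift_time_mean", "shift_time_sd")
    mean[shift_fields] <- 0
    sd[shift_fields] <- 0
  }
  list(mean = mean, sd = sd)
}

# clamp a drawn parameter vector into the model's validity region
clamp_population_draw <- function(model, v) {
  if (startsWith(model, "ddm")) {
    v["a"] <- max(v["a"], 0.05)
    v["z_rel"] <- min(max(v["z_rel"], 0.2), 0.8)
    v["v_congruent"] <- max(v["v_congruent"], 0)
    v["v_incongruent"] <- max(v["v_incongruent"], 0)
    lim <- -0.9 * v[["a"]]
  } else {
    v["b"] <- max(v["b"], 20)
    v["mu_c"] <- max(v["mu_c"], 0.05)
    v["zeta"] <- max(v["zeta"], 0)
    v["t_peak"] <- max(v["t_peak"], 5)
    lim <- -0.9 * v[["b"]]
  }
  for (f in c("t0_mean", "t0_sd", "shift_time_mean", "shift_time_sd"))
    v[f] <- max(v[f], 0)
  for (f in c("shift_delta_congruent", "shift_delta_incongruent"))
    v[f] <- max(v[f], lim)
  v
}

params_from_vector <- function(model, v) {
  if (startsWith(model, "ddm")) {
    ddm_shift_params(a = v[["a"]], z_rel = v[["z_rel"]],
                     v_congruent = v[["v_congruent"]],
                     v_incongruent = v[["v_incongruent"]],
                     t0_mean = v[["t0_mean"]], t0_sd = v[["t0_sd"]],
                     shift_delta_congruent = v[["shift_delta_congruent"]],
                     shift_delta_incongruent = v[["shift_delta_incongruent"]],
                     shift_time_mean = v[["shift_time_mean"]],
                     shift_time_sd = v[["shift_time_sd"]])
  } else {
    dmc_shift_params(b = v[["b"]], mu_c = v[["mu_c"]], zeta = v[["zeta"]],
                     t_peak = v[["t_peak"]],
                     t0_mean = v[["t0_mean"]], t0_sd = v[["t0_sd"]],
                     shift_delta_congruent = v[["shift_delta_congruent"]],
                     shift_delta_incongruent = v[["shift_delta_incongruent"]],
                     shift_time_mean = v[["shift_time_mean"]],
                     shift_time_sd = v[["shift_time_sd"]])
  }
}

#' Generate a full synthetic cohort with behaviour
#'
#' Draws per-subject true parameters from the population, builds each
#' subject's trial sequence with [build_design()] (plus the repetition half
#' for Experiment 2), simulates every trial with the generative diffusion
#' model, and delivers rewards according to the schedule. Simulated first
#' passages slower than the deadline become null responses (missing `rt_ms`
#' and `accuracy`); rewards are only delivered on correct trials.
#'
#' @param spec a [cohort_spec()].
#' @param config an [experiment_config()].
#' @return a list of class `"sddm_cohort"` with elements `trials` (one
#'   data.frame over all subjects, DDM times converted to ms), `true_params`
#'   (one row per subject) and the `spec`/`config` used.
#' @examples
#' spec <- cohort_spec(2, model = "dmc_shift", seed = 7)
#' coh <- generate_cohort(spec, experiment_config(1))
#' head(coh$trials)
#' @export
generate_cohort <- function(spec, config) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_config(config)
  groups <- c("reward_congruent", "reward_incongruent")
  pop_for <- function(group) {
    pp <- spec$param_population
    if (!is.null(pp$mean)) pp else pp[[group]]
  }
  time_scale <- if (startsWith(spec$model, "ddm")) 1000 else 1  # -> ms

  all_trials <- list()
  true_rows <- list()
  idx <- 0L
  for (group in groups) {
    pop <- pop_for(group)
    if (is.null(pop$mean) || is.null(pop$sd))
      fail_field("param_population", "needs 'mean' and 'sd' entries")
    for (s in seq_len(spec$n_subjects_per_group)) {
      idx <- idx + 1L
      sid <- sprintf("s%03d", idx)
      sseed <- derive_seed(spec$seed, paste0("subject_", sid))
      v <- with_seed(sseed, {
        draw <- rnorm(length(pop$mean), pop$mean, pop$sd)
        names(draw) <- names(pop$mean)
        clamp_population_draw(spec$model, draw)
      })
      pars <- params_from_vector(spec$model, v)

      des <- build_design(config, group,
                          seed = derive_seed(sseed, "design"),
                          subject_id = sid)
      des <- simulate_onto_design(des, pars, config,
                                  seed = derive_seed(sseed, "behaviour"),
                                  time_scale = time_scale)
      if (config$experiment == 2) {
        rep_half <- build_repetition_half(des, config,
                                          seed = derive_seed(sseed, "rep_half"))
        rep_half <- simulate_onto_design(rep_half, pars, config,
                                         seed = derive_seed(sseed, "behaviour2"),
                                         time_scale = time_scale)
        des$previously_high_rewarded <- NA
        des <- rbind(des, rep_half)
      }
      all_trials[[idx]] <- des
      true_rows[[idx]] <- data.frame(subject_id = sid, group = group,
                                     t(v), stringsAsFactors = FALSE)
    }
  }
  out <- list(trials = do.call(rbind, all_trials),
              true_params = do.call(rbind, true_rows),
              spec = spec, config = config)
  rownames(out$trials) <- NULL
  class(out) <- "sddm_cohort"
  out
}

# simulate rt/accuracy for each row of a design table and deliver rewards
simulate_onto_design <- function(des, pars, config, seed, time_scale) {
  deadline <- config$response_deadline_ms / time_scale
  with_seed(seed, {
    for (cond in c("congruent", "incongruent")) {
      rows <- which(des$congruency == cond)
      if (!length(rows)) next
      sim <- simulate_condition(pars, cond, n = length(rows),
                                deadline = deadline)
      des$rt_ms[rows] <- sim$rt * time_scale
      des$accuracy[rows] <- sim$accuracy
    }
    des$rt_ms[is.na(des$accuracy)] <- NA_real_
    des$reward <- ifelse(is.na(des$accuracy) | des$accuracy == 0, 0,
                         ifelse(des$scheduled_high_reward,
                                config$high_reward, config$low_reward))
    des
  })
}

#' @export
print.sddm_cohort <- function(x, ...) {
  cat(sprintf("<synthetic cohort: %d subjects/group, model %s, %d trials>\n",
              x$spec$n_subjects_per_group, x$spec$model, nrow(x$trials)))
  invisible(x)
}
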