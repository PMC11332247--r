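#' Discounted reward rate of a trial
#'
#' Earned reward divided by the time it took to earn it: reward / (RT +
#' inter-trial interval). Error and null trials earn 0 and contribute 0 to
#' mean rates.
#'
#' @param reward reward magnitude(s) (>= 0).
#' @param rt reaction time(s), seconds (> 0).
#' @param iti inter-trial interval, seconds (>= 0).
#' @return reward rate(s), units per second.
#' @examples
#' discounted_reward(5, rt = 0.5, iti = 0.5)  # 5 per second
#' @export
discounted_reward <- function(reward, rt, iti) {
  if (any(rt <= 0)) fail_field("rt", "must be > 0")
  if (any(iti < 0)) fail_field("iti", "must be >= 0")
  reward / (rt + iti)
}

#' Reward-rate sweep over boundary-shift x drift-rate combinations
#'
#' For every combination of a boundary-shift and a drift-rate value (the
#' default grids give 16 x 16 = 256 agents), and for each congruency
#' condition and reward group, simulates `n_trials` DDM-with-shift trials
#' with the cell's shift and drift substituted for that condition (all other
#' parameters held at `base_params`), delivers high/low rewards by the
#' group's schedule on correct, in-time trials, and records the mean
#' discounted reward rate (errors and null responses count as 0).
#'
#' @param base_params a [ddm_shift_params()] object of average estimates.
#' @param config an [experiment_config()] providing the reward schedule,
#'   deadline and ITI.
#' @param shift_values boundary-shift grid (evidence units).
#' @param drift_values drift-rate grid (evidence units / s).
#' @param n_trials simulated trials per cell (50000 in the full analysis;
#'   use ~2000 for a CI profile).
#' @param seed integer seed; each cell draws from a derived substream, so
#'   the grid is reproducible and cells are independent of grid order.
#' @param dt integration step (s).
#' @return an object of class `"sddm_optgrid"`: the grids, one
#'   `shift x drift` matrix of mean discounted reward per
#'   `congruency.group` combination, and provenance fields.
#' @export
sweep_grid <- function(base_params, config,
                       shift_values = seq(-0.05, 0.10, length.out = 16L),
                       drift_values = seq(0, 0.50, length.out = 16L),
                       n_trials = 2000L, seed = 1L, dt = 0.001) {
  stopifnot(inherits(base_params, "ddm_shift_params"))
  validate_config(config)
  if (!length(shift_values) || !length(drift_values))
    stop("grids must be non-empty", call. = FALSE)
  if (n_trials < 1) fail_field("n_trials", "must be >= 1")

  deadline_s <- config$response_deadline_ms / 1000
  iti_s <- config$iti_ms / 1000
  combos <- expand.grid(congruency = c("congruent", "incongruent"),
                        group = c("reward_congruent", "reward_incongruent"),
                        stringsAsFactors = FALSE)
  rewards <- list()
  for (r in seq_len(nrow(combos))) {
    cond <- combos$congruency[r]; grp <- combos$group[r]
    p_high <- high_reward_prob(config, grp, cond)
    m <- matrix(NA_real_, length(shift_values), length(drift_values),
                dimnames = list(shift = signif(shift_values, 4),
                                drift = signif(drift_values, 4)))
    for (i in seq_along(shift_values)) {
      for (j in seq_along(drift_values)) {
        p <- base_params
        if (cond == "congruent") {
          p$v_congruent <- drift_values[j]
          p$shift_delta_congruent <- shift_values[i]
        } else {
          p$v_incongruent <- drift_values[j]
          p$shift_delta_incongruent <- shift_values[i]
        }
        validate_params(p)
        cell_seed <- derive_seed(seed, sprintf("%s.%s.%d.%d", cond, grp, i, j))
        m[i, j] <- with_seed(cell_seed, {
          sim <- simulate_condition(p, cond, n = n_trials, dt = dt,
                                    deadline = deadline_s)
          correct <- !sim$censored & sim$accuracy == 1
          rew <- numeric(n_trials)
          if (any(correct)) {
            high <- rbinom(sum(correct), 1L, p_high) == 1L
            rew[correct] <- ifelse(high, config$high_reward, config$low_reward)
            rew[correct] <- discounted_reward(rew[correct],
                                              sim$rt[correct], iti_s)
          }
          if (all(sim$censored)) warning("all trials censored in a grid cell")
          mean(rew)
        })
      }
    }
    rewards[[paste(cond, grp, sep = ".")]] <- m
  }
  structure(list(shift_values = shift_values, drift_values = drift_values,
                 mean_discounted_reward = rewards,
                 n_trials_per_cell = n_trials, base_params = base_params,
                 iti_ms = config$iti_ms, seed = seed),
            class = "sddm_optgrid")
}

#' @export
print.sddm_optgrid <- function(x, ...) {
  cat(sprintf("<optimality grid: %d shift x %d drift = %d agents, %d trials/cell>\n",
              length(x$shift_values), length(x$drift_values),
              length(x$shift_values) * length(x$drift_values),
              x$n_trials_per_cell))
  invisible(x)
}
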