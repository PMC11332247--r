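# Shared fixtures, built in code at load time. Kept deliberately small;
# heavier simulations live inside the tests that need them.

# a hand-written single-subject trial table with known exclusion structure
toy_subject_trials <- function(sid = "t01", group = "reward_congruent") {
  n <- 12L
  data.frame(
    subject_id = sid, group = group, block = 1L, trial = seq_len(n),
    stimulus_id = sprintf("%s_stim%02d", sid, seq_len(n)),
    task = rep(c("size", "animacy"), length.out = n),
    congruency = rep(c("congruent", "incongruent"), each = n / 2),
    transition = c(NA, rep(c("repeat", "switch"), length.out = n - 1L)),
    scheduled_high_reward = FALSE,
    #          1    2    3    4     5    6    7    8    9    10  11   12
    rt_ms = c(400, 500, 600, 700, 3000, 450, 199, 520, 560, 480, NA, 610),
    accuracy = c(1, 1, 1, 1, 1, 1, 1, 0, 1, 1, NA, 1),
    reward = c(1, 1, 1, 1, 1, 1, 1, 0, 1, 1, 0, 1),
    stringsAsFactors = FALSE
  )
}

# fast DDM parameter set used across simulation tests
fast_ddm <- function(...) {
  args <- list(a = 0.11, v_congruent = 0.28, v_incongruent = 0.20,
               t0_mean = 0.35, t0_sd = 0.04)
  args[names(list(...))] <- list(...)
  do.call(ddm_shift_params, args)
}

fast_dmc <- function(...) {
  args <- list(b = 75, mu_c = 0.5, zeta = 20, t_peak = 40,
               t0_mean = 320, t0_sd = 30)
  args[names(list(...))] <- list(...)
  do.call(dmc_shift_params, args)
}

signed_sample <- function(sim) {
  s <- ifelse(sim$accuracy == 1, sim$rt, -sim$rt)
  s[!is.na(s)]
}
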