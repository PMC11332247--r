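make_two_task_subject <- function(sid, acc_size, acc_animacy,
                                  group = "reward_congruent") {
  n <- 100L
  data.frame(
    subject_id = sid, group = group, block = 1L, trial = seq_len(n),
    stimulus_id = sprintf("%s_%03d", sid, seq_len(n)),
    task = rep(c("size", "animacy"), each = n / 2),
    congruency = rep(c("congruent", "incongruent"), length.out = n),
    transition = NA_character_, scheduled_high_reward = FALSE,
    rt_ms = 600,
    accuracy = c(rbinom_det(n / 2, acc_size), rbinom_det(n / 2, acc_animacy)),
    reward = 0, stringsAsFactors = FALSE
  )
}
# deterministic accuracy vector with an exact proportion
rbinom_det <- function(n, p) c(rep(1L, round(n * p)), rep(0L, n - round(n * p)))

test_that("subjects at or below the accuracy floor in either task are
           excluded, strictly-above retained", {
  tr <- rbind(make_two_task_subject("s1", 0.60, 0.96),
              make_two_task_subject("s2", 0.62, 0.62),
              make_two_task_subject("s3", 0.96, 0.96))
  res <- exclude_subjects(tr)
  expect_setequal(unique(res$trials$subject_id), c("s2", "s3"))
  expect_equal(res$report$subjects_excluded$subject_id, "s1")
  expect_equal(res$report$subjects_excluded$reason, "low_accuracy")
  expect_error(exclude_subjects(tr[0, ]), "empty")
  expect_error(exclude_subjects(tr, accuracy_floor = 1.2), "accuracy_floor")
})

test_that("long null/premature runs flag inattention", {
  tr <- make_two_task_subject("s9", 0.9, 0.9)
  tr$rt_ms[11:22] <- NA
  tr$accuracy[11:22] <- NA
  res <- exclude_subjects(tr, inattention_run = 10L)
  expect_equal(res$report$subjects_excluded$reason, "inattentive")
})

test_that("trial filters remove the documented reasons in order", {
  tr <- toy_subject_trials()
  acc <- filter_trials(tr, "accuracy")
  # trial 11 missing, trial 12 follows the null, trial 9 follows the error
  expect_equal(acc$report$trials_removed$missing, 1L)
  expect_equal(acc$report$trials_removed$post_null, 1L)
  expect_equal(acc$report$trials_removed$post_error, 1L)
  expect_equal(nrow(acc$trials), nrow(tr) - 3L)
  # the error trial itself survives the accuracy stream
  expect_true(8L %in% acc$trials$trial)

  rt <- filter_trials(tr, "rt")
  expect_equal(rt$report$trials_removed$error, 1L)     # trial 8
  expect_equal(rt$report$trials_removed$fast_rt, 1L)   # trial 7: 199 ms
  # survivors before fences: 400 500 600 700 3000 450 520 480 610
  # type-7 quartiles: Q1 = 480, Q3 = 610, upper fence 610 + 1.5*130 = 805
  expect_equal(rt$report$trials_removed$iqr_high, 1L)  # the 3000 ms trial
  expect_equal(rt$report$trials_removed$iqr_low, 0L)
  expect_false(5L %in% rt$trials$trial)
  counts <- unlist(rt$report$trials_removed)
  expect_equal(sum(counts), nrow(tr) - nrow(rt$trials))
  expect_error(filter_trials(tr, "banana"), "arg")
})

test_that("Tukey fences match an independent quartile computation", {
  rts <- c(400, 500, 600, 700, 3000)
  tr <- toy_subject_trials()[1:5, ]
  tr$rt_ms <- rts; tr$accuracy <- 1L
  out <- filter_trials(tr, "rt")
  # oracle: hand-interpolated type-7 quartiles of the 5 values are 500/700,
  # upper fence 700 + 1.5*200 = 1000, so exactly the 3000 ms trial falls
  expect_equal(sort(out$trials$rt_ms), c(400, 500, 600, 700))
})

test_that("filtering is idempotent and permutation invariant", {
  coh <- generate_cohort(cohort_spec(2, model = "dmc_shift", seed = 3),
                         experiment_config(1))
  once <- filter_trials(coh$trials, "rt")
  twice <- filter_trials(once$trials, "rt")
  # only re-computed IQR fences may remove anything further
  extra <- unlist(twice$report$trials_removed)
  expect_equal(sum(extra[setdiff(names(extra), c("iqr_high", "iqr_low"))]), 0L)

  shuffled <- coh$trials[sample.int(nrow(coh$trials)), ]
  re <- filter_trials(shuffled, "rt")
  expect_equal(re$report$trials_removed, once$report$trials_removed)
  expect_equal(sort(re$trials$rt_ms), sort(once$trials$rt_ms))
})

test_that("congruency effects recover generated condition differences", {
  # analytic-free oracle: a large one-off simulation of the same generator
  pop <- default_population("dmc_shift")
  pop$sd[] <- 0
  par <- params_from_oracle <- dmc_shift_params(
    b = pop$mean["b"], mu_c = pop$mean["mu_c"], zeta = pop$mean["zeta"],
    t_peak = pop$mean["t_peak"], t0_mean = pop$mean["t0_mean"],
    t0_sd = pop$mean["t0_sd"],
    shift_delta_congruent = pop$mean["shift_delta_congruent"],
    shift_delta_incongruent = pop$mean["shift_delta_incongruent"],
    shift_time_mean = pop$mean["shift_time_mean"],
    shift_time_sd = pop$mean["shift_time_sd"])
  big_c <- simulate_condition(par, "congruent", 50000, seed = 61)
  big_i <- simulate_condition(par, "incongruent", 50000, seed = 62)
  true_acc_eff <- mean(big_c$accuracy, na.rm = TRUE) -
    mean(big_i$accuracy, na.rm = TRUE)

  coh <- generate_cohort(cohort_spec(8, model = "dmc_shift",
                                     param_population = pop, seed = 63),
                         experiment_config(1))
  eff <- congruency_effects(filter_trials(coh$trials, "accuracy")$trials,
                            filter_trials(coh$trials, "rt")$trials)
  est <- mean(eff$subjects$acc_effect, na.rm = TRUE)
  # binomial error on ~16 x 160 trials per condition plus oracle error
  expect_lt(abs(est - true_acc_eff), 0.02)
  # zero-difference degenerate case
  one <- coh$trials[coh$trials$subject_id == "s001" & !is.na(coh$trials$accuracy), ]
  one$accuracy <- 1L
  e1 <- congruency_effects(one)
  expect_equal(e1$subjects$acc_effect, 0)
})
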