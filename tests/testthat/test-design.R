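test_that("Experiment 1 design is balanced with unique stimuli", {
  cfg <- experiment_config(1)
  des <- build_design(cfg, "reward_incongruent", seed = 101)
  expect_equal(nrow(des), 320L)
  expect_equal(unname(table(des$congruency)["congruent"]), 160L)
  expect_equal(unname(table(des$congruency)["incongruent"]), 160L)
  expect_false(anyDuplicated(des$stimulus_id) > 0)
  # per-block balance of congruency and of tasks
  for (b in 1:4) {
    blk <- des[des$block == b, ]
    expect_equal(sum(blk$congruency == "congruent"), 40L)
    expect_equal(sum(blk$task == "size"), 40L)
  }
  # transitions: defined except on first block trials, both kinds occur
  expect_true(all(is.na(des$transition[des$trial == 1])))
  expect_true(all(c("repeat", "switch") %in% des$transition))
})

test_that("degenerate configs are rejected", {
  cfg <- experiment_config(1)
  cfg$trials_per_block <- 0L
  expect_error(build_design(cfg, "reward_congruent", seed = 1), "trials_per_block")
  cfg$trials_per_block <- 79L
  expect_error(build_design(cfg, "reward_congruent", seed = 1), "even")
  expect_error(experiment_config(4), "experiment")
  expect_error(build_design(experiment_config(1), "some_group", seed = 1),
               "group")
})

test_that("congruency and task are unassociated in the design", {
  des <- build_design(experiment_config(1), "reward_congruent", seed = 7)
  tab <- table(des$congruency, des$task)
  expect_gt(suppressWarnings(stats::chisq.test(tab)$p.value), 0.99)
})

test_that("reward schedule hits the configured probabilities", {
  cfg <- experiment_config(1)
  # 50 regenerations x 160 incongruent trials = 8000 draws at p = 0.9
  hits <- vapply(1:50, function(s) {
    d <- build_design(cfg, "reward_incongruent", seed = 1000 + s)
    c(sum(d$scheduled_high_reward[d$congruency == "incongruent"]),
      sum(d$scheduled_high_reward[d$congruency == "congruent"]))
  }, numeric(2))
  p_inc <- sum(hits[1, ]) / (50 * 160)
  p_con <- sum(hits[2, ]) / (50 * 160)
  expect_lt(abs(p_inc - 0.90), 3 * sqrt(0.9 * 0.1 / 8000))
  expect_lt(abs(p_con - 0.10), 3 * sqrt(0.9 * 0.1 / 8000))
})

test_that("designs are deterministic given the seed", {
  cfg <- experiment_config(3)
  expect_identical(build_design(cfg, "reward_congruent", seed = 5),
                   build_design(cfg, "reward_congruent", seed = 5))
  expect_false(identical(build_design(cfg, "reward_congruent", seed = 5),
                         build_design(cfg, "reward_congruent", seed = 6)))
})

make_first_half <- function(n_high_inc, seed = 3) {
  cfg <- experiment_config(2)
  fh <- build_design(cfg, "reward_incongruent", seed = seed)
  fh$accuracy <- 1L
  fh$rt_ms <- 600
  fh$reward <- cfg$low_reward
  inc <- which(fh$congruency == "incongruent")
  fh$reward[inc[seq_len(n_high_inc)]] <- cfg$high_reward
  list(cfg = cfg, fh = fh)
}

test_that("repetition half re-rewards exactly one third of previous winners", {
  w <- make_first_half(60)   # 60 %% 3 == 0: no remainder draw involved
  h2 <- build_repetition_half(w$fh, w$cfg, seed = 11)
  expect_setequal(h2$stimulus_id, w$fh$stimulus_id)
  expect_equal(nrow(h2), nrow(w$fh))
  prev_high_inc <- w$fh$stimulus_id[w$fh$reward == w$cfg$high_reward]
  rescheduled <- h2$stimulus_id[h2$scheduled_high_reward &
                                  h2$stimulus_id %in% prev_high_inc]
  expect_equal(length(rescheduled), 20L)
  # tag matches first-half outcome
  expect_setequal(h2$stimulus_id[h2$previously_high_rewarded], prev_high_inc)
  # overall scheduled rate stays at the condition target (50% of 160)
  expect_equal(sum(h2$scheduled_high_reward[h2$congruency == "incongruent"]), 80L)
  expect_equal(sum(h2$scheduled_high_reward[h2$congruency == "congruent"]), 0L)
})

test_that("repetition half handles zero previous winners and bad input", {
  w <- make_first_half(0)
  h2 <- build_repetition_half(w$fh, w$cfg, seed = 2)
  expect_equal(sum(h2$previously_high_rewarded), 0L)
  w$fh$reward <- NA_real_
  expect_error(build_repetition_half(w$fh, w$cfg, seed = 2), "reward")
  expect_error(build_repetition_half(w$fh, experiment_config(1), seed = 2),
               "Experiment 2")
})
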