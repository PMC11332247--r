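#' Configuration of a congruency-contingent-reward task-switching experiment
#'
#' Encodes the design constants of the three experiments: blocked
#' task-switching with unique word stimuli, two tasks (size / animacy) on
#' shared response keys, a 3000 ms response deadline, and probabilistic high
#' vs low reward on correct trials whose probability depends on the trial's
#' congruency and the participant's reward group. Experiments 1 and 3 run
#' 4 blocks of 80 unique stimuli with a 90/10 high-reward schedule;
#' Experiment 2 runs 8 blocks (the last 4 repeat the stimuli of the first 4)
#' with a 50/0 schedule and points instead of cents. Experiment 3 presents
#' the task cue before the target.
#'
#' @param experiment 1, 2 or 3.
#' @param iti_ms inter-trial interval (ms) used for reward-rate discounting;
#'   not printed in the study description, default 1500 (1000 ms fixation
#'   plus a nominal 500 ms feedback screen).
#' @return a list of class `"experiment_config"`.
#' @examples
#' experiment_config(1)
#' @export
experiment_config <- function(experiment = 1, iti_ms = 1500) {
  if (!experiment %in% 1:3) fail_field("experiment", "must be 1, 2 or 3")
  if (!is.numeric(iti_ms) || iti_ms < 0) fail_field("iti_ms", "must be >= 0")
  cfg <- list(
    experiment = as.integer(experiment),
    n_blocks = if (experiment == 2) 8L else 4L,
    trials_per_block = 80L,
    high_reward_prob_rewarded = if (experiment == 2) 0.50 else 0.90,
    high_reward_prob_other    = if (experiment == 2) 0.00 else 0.10,
    response_deadline_ms = 3000,
    cue_precedes_target = experiment == 3,
    high_reward = if (experiment == 2) 10 else 5,
    low_reward = 1,
    iti_ms = iti_ms
  )
  class(cfg) <- "experiment_config"
  validate_config(cfg)
  cfg
}

#' @keywords internal
validate_config <- function(cfg) {
  for (f in c("high_reward_prob_rewarded", "high_reward_prob_other")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) fail_field(f, "must be in [0, 1]")
  }
  if (cfg$high_reward_prob_rewarded <= cfg$high_reward_prob_other)
    fail_field("high_reward_prob_rewarded",
               "rewarded-condition probability must exceed the other condition's")
  if (cfg$trials_per_block < 1) fail_field("trials_per_block", "must be >= 1")
  if (cfg$trials_per_block %% 2 != 0)
    fail_field("trials_per_block", "must be even to balance congruency")
  if (cfg$n_blocks < 1) fail_field("n_blocks", "must be >= 1")
  invisible(cfg)
}

# congruency condition carrying the high high-reward probability for a group
rewarded_condition <- function(group) {
  switch(group,
         reward_congruent = "congruent",
         reward_incongruent = "incongruent",
         fail_field("group", "must be 'reward_congruent' or 'reward_incongruent'"))
}

high_reward_prob <- function(config, group, congruency) {
  ifelse(congruency == rewarded_condition(group),
         config$high_reward_prob_rewarded, config$high_reward_prob_other)
}

trial_columns <- c("subject_id", "group", "block", "trial", "stimulus_id",
                   "task", "congruency", "transition", "scheduled_high_reward",
                   "rt_ms", "accuracy", "reward")

#' Build the trial sequence of one subject's unique-stimulus phase
#'
#' Generates the first experimental half (all blocks for Experiments 1 and 3,
#' blocks 1--4 for Experiment 2): per block, congruency and task are crossed
#' and balanced to the nearest achievable integer, trial order is a uniform
#' shuffle, every trial gets a unique stimulus token, and the high-reward
#' flag is drawn Bernoulli with the group- and congruency-appropriate
#' probability. Behaviour columns (`rt_ms`, `accuracy`, `reward`) are left
#' missing; see [generate_cohort()].
#'
#' @param config an [experiment_config()].
#' @param group `"reward_congruent"` or `"reward_incongruent"`.
#' @param seed integer seed (design is deterministic given the seed).
#' @param subject_id identifier written into the table.
#' @return a data.frame of trial records in presentation order; `transition`
#'   is `NA` on the first trial of each block.
#' @examples
#' d <- build_design(experiment_config(1), "reward_incongruent", seed = 1)
#' table(d$congruency)
#' @export
build_design <- function(config, group, seed, subject_id = "s001") {
  validate_config(config)
  rewarded_condition(group)  # validates group
  n_blocks <- if (config$experiment == 2) config$n_blocks %/% 2L else config$n_blocks
  tp <- config$trials_per_block

  with_seed(seed, {
    blocks <- lapply(seq_len(n_blocks), function(b) {
      # factorial congruency x task cells, as balanced as tp allows
      cells <- expand.grid(congruency = c("congruent", "incongruent"),
                           task = c("size", "animacy"),
                           stringsAsFactors = FALSE)
      reps <- rep(tp %/% 4L, 4L)
      extra <- tp - sum(reps)
      if (extra > 0) {
        # tp even => extra is 0 or 2; add one trial per congruency so the
        # congruency split stays exact (tasks then differ by at most 2)
        idx <- c(which(cells$congruency == "congruent")[1L],
                 which(cells$congruency == "incongruent")[1L])[seq_len(extra)]
        reps[idx] <- reps[idx] + 1L
      }
      blk <- cells[rep(seq_len(4L), reps), , drop = FALSE]
      blk <- blk[sample.int(nrow(blk)), , drop = FALSE]
      blk$block <- b
      blk$trial <- seq_len(nrow(blk))
      blk
    })
    des <- do.call(rbind, blocks)
    rownames(des) <- NULL
    des$subject_id <- subject_id
    des$group <- group
    des$stimulus_id <- sprintf("%s_stim%04d", subject_id, seq_len(nrow(des)))
    prev <- c(NA, des$task[-nrow(des)])
    des$transition <- ifelse(des$trial == 1L, NA,
                             ifelse(des$task == prev, "repeat", "switch"))
    des$scheduled_high_reward <-
      rbinom(nrow(des), 1L, high_reward_prob(config, group, des$congruency)) == 1L
    des$rt_ms <- NA_real_
    des$accuracy <- NA_integer_
    des$reward <- NA_real_
    des[, trial_columns]
  })
}

#' Build Experiment 2's stimulus-repetition half
#'
#' Repeats every stimulus of a completed first half exactly once across four
#' further blocks, with the task re-drawn (so a stimulus may recur under the
#' same or the other task). The second-half reward schedule targets the same
#' per-condition high-reward probability, under the constraint that only one
#' third (rounded down; the remainder resolved by a seeded draw) of the
#' stimuli that earned the high reward in the first half are scheduled for
#' the high reward again; the rest of the quota is drawn from stimuli not
#' previously highly rewarded. Every trial carries a
#' `previously_high_rewarded` tag.
#'
#' @param first_half a completed first-half trial table (behaviour and
#'   rewards filled in) for a single subject.
#' @param config the Experiment 2 [experiment_config()].
#' @param seed integer seed.
#' @return a data.frame of second-half trial records (blocks continue the
#'   first half's numbering) with the extra `previously_high_rewarded`
#'   column.
#' @export
build_repetition_half <- function(first_half, config, seed) {
  validate_config(config)
  if (config$experiment != 2)
    fail_field("config", "repetition halves exist only in Experiment 2")
  need <- c("stimulus_id", "congruency", "accuracy", "reward", "group")
  if (!all(need %in% names(first_half)))
    stop("first_half is missing required columns", call. = FALSE)
  if (all(is.na(first_half$reward)))
    stop("first_half has no reward outcomes; simulate behaviour first",
         call. = FALSE)
  if (anyDuplicated(first_half$stimulus_id))
    stop("first_half stimulus_ids must be unique", call. = FALSE)

  group <- first_half$group[1L]
  stim <- data.frame(
    stimulus_id = first_half$stimulus_id,
    congruency = first_half$congruency,
    prev_high = !is.na(first_half$reward) &
      first_half$reward == config$high_reward,
    stringsAsFactors = FALSE
  )

  with_seed(seed, {
    sched <- rep(FALSE, nrow(stim))
    for (cond in c("congruent", "incongruent")) {
      in_cond <- which(stim$congruency == cond)
      p <- high_reward_prob(config, group, cond)
      target <- round(p * length(in_cond))
      prev <- in_cond[stim$prev_high[in_cond]]
      k <- length(prev) %/% 3L
      r <- length(prev) %% 3L
      if (r > 0 && stats::runif(1) < r / 3) k <- k + 1L  # seeded remainder top-up
      k <- min(k, target)
      from_prev <- if (k > 0) sample(prev, k) else integer(0)
      pool <- setdiff(in_cond, prev)
      n_new <- min(target - k, length(pool))
      from_new <- if (n_new > 0) sample(pool, n_new) else integer(0)
      sched[c(from_prev, from_new)] <- TRUE
    }

    n_blocks2 <- config$n_blocks %/% 2L
    tp <- config$trials_per_block
    ord <- sample.int(nrow(stim))
    half2 <- stim[ord, , drop = FALSE]
    half2$scheduled_high_reward <- sched[ord]
    half2$task <- sample(c("size", "animacy"), nrow(half2), replace = TRUE)
    half2$block <- max(first_half$block) + rep(seq_len(n_blocks2), each = tp)
    half2$trial <- rep(seq_len(tp), n_blocks2)
    prev_task <- c(NA, half2$task[-nrow(half2)])
    half2$transition <- ifelse(half2$trial == 1L, NA,
                               ifelse(half2$task == prev_task, "repeat", "switch"))
    half2$subject_id <- first_half$subject_id[1L]
    half2$group <- group
    half2$rt_ms <- NA_real_
    half2$accuracy <- NA_integer_
    half2$reward <- NA_real_
    out <- half2[, c(trial_columns, "prev_high")]
    names(out)[names(out) == "prev_high"] <- "previously_high_rewarded"
    rownames(out) <- NULL
    out
  })
}
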