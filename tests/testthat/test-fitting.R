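test_that("ks_distance matches hand values and the stats::ks.test oracle", {
  expect_equal(ks_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_distance(c(1, 2, 3), c(10, 11, 12)), 1)
  expect_equal(ks_distance(c(1, 2, 3, 4), c(2, 3, 4, 5)), 0.25)
  expect_error(ks_distance(numeric(0), 1:3), "non-empty")
  set.seed(123)
  for (k in 1:20) {
    a <- round(rnorm(sample(5:60, 1)), sample(0:2, 1))  # rounding forces ties
    b <- round(rnorm(sample(5:60, 1), sd = runif(1, 0.5, 2)), 1)
    oracle <- unname(suppressWarnings(stats::ks.test(a, b)$statistic))
    expect_equal(ks_distance(a, b), oracle, tolerance = 1e-12)
  }
})

test_that("the objective is trial-order invariant, deterministic, and finite
           at the bound edges", {
  sim_c <- simulate_condition(fast_ddm(), "congruent", 150, seed = 1)
  sim_i <- simulate_condition(fast_ddm(), "incongruent", 150, seed = 2)
  data <- list(congruent = signed_sample(sim_c),
               incongruent = signed_sample(sim_i))
  par <- c(0.11, 0.5, 0.28, 0.20, 0.35, 0.04, 0.03, 0.01, 0.3, 0.05)
  o1 <- ks_objective(par, data, "ddm_shift", n_sim = 400, obj_seed = 9,
                     dt = 0.004, deadline = 3)
  o2 <- ks_objective(par, lapply(data, rev), "ddm_shift", n_sim = 400,
                     obj_seed = 9, dt = 0.004, deadline = 3)
  expect_identical(o1, o2)
  expect_true(o1 >= 0 && o1 <= 1)
  # edges of the box stay finite
  b <- default_bounds("ddm_shift")
  expect_true(is.finite(ks_objective(b$lower, data, "ddm_shift", n_sim = 200,
                                     obj_seed = 3, dt = 0.004, deadline = 3)))
  expect_true(is.finite(ks_objective(b$upper, data, "ddm_shift", n_sim = 200,
                                     obj_seed = 3, dt = 0.004, deadline = 3)))
  # crossed boundaries are penalised without simulation
  bad <- par; bad[7] <- -0.2
  expect_gt(ks_objective(bad, data, "ddm_shift", n_sim = 200, obj_seed = 3), 1)
})

test_that("the generating parameters beat random perturbations of themselves", {
  par <- c(a = 0.11, z_rel = 0.5, v_congruent = 0.28, v_incongruent = 0.20,
           t0_mean = 0.35, t0_sd = 0.04)
  p <- fit_vec_to_params_oracle <- ddm_shift_params(
    a = par[["a"]], v_congruent = par[["v_congruent"]],
    v_incongruent = par[["v_incongruent"]], t0_mean = par[["t0_mean"]],
    t0_sd = par[["t0_sd"]])
  data <- list(
    congruent = signed_sample(simulate_condition(p, "congruent", 4000, seed = 5)),
    incongruent = signed_sample(simulate_condition(p, "incongruent", 4000, seed = 6)))
  at_truth <- ks_objective(par, data, "ddm", n_sim = 2000, obj_seed = 11,
                           dt = 0.002, deadline = 3)
  b <- default_bounds("ddm")
  set.seed(31)
  worse <- replicate(20, {
    pert <- pmin(pmax(par * runif(6, 0.6, 1.5), b$lower), b$upper)
    ks_objective(pert, data, "ddm", n_sim = 2000, obj_seed = 11,
                 dt = 0.002, deadline = 3)
  })
  expect_true(all(at_truth < worse))
})

test_that("doubling n_sim moves the objective less than Monte-Carlo
           tolerance", {
  p <- fast_ddm()
  data <- list(
    congruent = signed_sample(simulate_condition(p, "congruent", 2000, seed = 7)),
    incongruent = signed_sample(simulate_condition(p, "incongruent", 2000, seed = 8)))
  par <- c(0.11, 0.5, 0.28, 0.20, 0.35, 0.04)
  o1 <- ks_objective(par, data, "ddm", n_sim = 2000, obj_seed = 13,
                     dt = 0.002, deadline = 3)
  o2 <- ks_objective(par, data, "ddm", n_sim = 4000, obj_seed = 13,
                     dt = 0.002, deadline = 3)
  expect_lt(abs(o1 - o2), 0.04)
})

test_that("fits are deterministic and carry sane diagnostics", {
  coh <- generate_cohort(cohort_spec(1, model = "ddm", seed = 21),
                         experiment_config(1))
  tr <- coh$trials[!is.na(coh$trials$rt_ms), ]
  quick <- fit_control("ci", pop_size = 8L, generations = 4L, n_sim = 300L,
                       polish_maxit = 30L)
  f1 <- fit_subject(tr, "ddm", control = quick, seed = 3)
  f2 <- fit_subject(tr, "ddm", control = quick, seed = 3)
  expect_identical(f1[setdiff(names(f1), "evaluations")],
                   f2[setdiff(names(f2), "evaluations")])
  expect_identical(f1$evaluations, f2$evaluations)
  expect_true(all(f1$params >= default_bounds("ddm")$lower - 1e-12))
  expect_true(all(f1$params <= default_bounds("ddm")$upper + 1e-12))
  expect_true(f1$ks_value >= 0 && f1$ks_value <= 1)
  expect_equal(unname(f1$n_trials_per_condition),
               unname(table(tr$congruency)[c("congruent", "incongruent")]),
               ignore_attr = TRUE)
  expect_error(fit_subject(tr[tr$congruency == "congruent", ], "ddm"),
               "incongruent")
})

test_that("goodness of fit is high for self-fits and collapses under
           parameter shuffling", {
  coh <- generate_cohort(cohort_spec(3, model = "ddm", seed = 55),
                         experiment_config(1))
  tr <- coh$trials
  # fits constructed directly from the generating truth (no optimisation)
  self_fit <- function(row) {
    v <- unlist(row[param_names("ddm")])
    structure(list(subject_id = row$subject_id, model = "ddm",
                   params = v, ks_value = 0,
                   n_trials_per_condition = c(congruent = 160L,
                                              incongruent = 160L),
                   evaluations = 0L, converged = TRUE, seed = 1L,
                   profile = "self"), class = "sddm_fit")
  }
  fits <- lapply(seq_len(nrow(coh$true_params)),
                 function(i) self_fit(coh$true_params[i, ]))
  gof <- goodness_of_fit(fits, tr, n_sim = 4000, seed = 5)
  expect_gt(gof$r_quantile_rt, 0.95)
  expect_gt(gof$r_accuracy, -1.01)  # accuracy r is unstable at 6 points but defined
  expect_true(abs(gof$r_accuracy) <= 1)

  # negative control: permute parameter vectors across subjects
  perm <- fits[c(2, 3, 1)]
  for (i in seq_along(perm)) perm[[i]]$subject_id <- fits[[i]]$subject_id
  gof_perm <- goodness_of_fit(perm, tr, n_sim = 4000, seed = 5)
  expect_lt(gof_perm$r_quantile_rt, gof$r_quantile_rt)
})
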