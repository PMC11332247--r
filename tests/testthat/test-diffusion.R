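test_that("automatic drift has its stationary point at the peak and
           integrates to the amplitude", {
  expect_equal(automatic_drift(40, zeta = 20, t_peak = 40, alpha = 2), 0)
  expect_equal(automatic_drift(300, zeta = 0, t_peak = 40, alpha = 2), 0)
  # quadrature oracle: expected activation at the peak equals zeta
  for (zeta in c(20, -15)) {
    for (alpha in c(2, 3)) {
      area <- stats::integrate(automatic_drift, lower = 1e-9, upper = 40,
                               zeta = zeta, t_peak = 40, alpha = alpha)$value
      expect_equal(area, zeta, tolerance = 1e-4)
    }
  }
  expect_error(automatic_drift(10, 20, t_peak = -1), "t_peak")
  expect_error(automatic_drift(10, 20, t_peak = 40, alpha = 1), "alpha")
  expect_error(automatic_drift(0, 20, t_peak = 40), "t > 0")
})

test_that("boundary_at implements a step change", {
  expect_equal(boundary_at(c(0.1, 0.29, 0.3, 0.5), 75, 11.42, 0.3),
               c(75, 75, 86.42, 86.42))
  expect_equal(boundary_at(c(0.1, 10), 75, 11.42, Inf), c(75, 75))
  expect_equal(boundary_at(c(0.1, 10), 75, 0, 0.2), c(75, 75))
  expect_error(boundary_at(1, 75, -80, 0.1), "cross")
})

test_that("parameter validation rejects invalid vectors", {
  expect_error(ddm_shift_params(a = -1, v_congruent = 0.3,
                                v_incongruent = 0.2, t0_mean = 0.3), "a")
  expect_error(ddm_shift_params(a = 0.1, z_rel = 1.2, v_congruent = 0.3,
                                v_incongruent = 0.2, t0_mean = 0.3), "z_rel")
  expect_error(ddm_shift_params(a = 0.1, v_congruent = 0.3,
                                v_incongruent = 0.2, t0_mean = 0.3,
                                shift_delta_congruent = -0.2), "cross")
  expect_error(dmc_shift_params(b = 75, mu_c = 0.5, zeta = 20, t_peak = 40,
                                alpha = 1, t0_mean = 300), "alpha")
  expect_error(simulate_condition(fast_ddm(), "congruent", n = 0), "n")
  expect_error(simulate_condition(fast_ddm(), "congruent", n = 10, dt = -1),
               "dt")
})

test_that("simulation is deterministic given the seed", {
  a <- simulate_condition(fast_dmc(), "incongruent", n = 200, seed = 42)
  b <- simulate_condition(fast_dmc(), "incongruent", n = 200, seed = 42)
  expect_identical(a, b)
  expect_identical(simulate_trial(fast_ddm(), "congruent", seed = 9),
                   simulate_condition(fast_ddm(), "congruent", 1L, seed = 9))
})

test_that("extreme drift drives accuracy to the ceiling, tiny deadlines censor", {
  s <- simulate_condition(fast_ddm(v_congruent = 5), "congruent",
                          n = 2000, seed = 3)
  expect_gt(mean(s$accuracy, na.rm = TRUE), 0.999)
  s2 <- simulate_condition(fast_ddm(), "congruent", n = 50, deadline = 0.05,
                           seed = 4)
  expect_true(all(s2$censored))
  expect_true(all(is.na(s2$rt)))
})

test_that("accuracy and mean RT are nondecreasing in the boundary", {
  accs <- rts <- numeric(3)
  for (i in seq_along(c(0.07, 0.11, 0.16))) {
    a <- c(0.07, 0.11, 0.16)[i]
    s <- simulate_condition(fast_ddm(a = a), "incongruent", n = 20000,
                            seed = 500 + i)
    accs[i] <- mean(s$accuracy, na.rm = TRUE)
    rts[i] <- mean(s$rt[s$accuracy == 1], na.rm = TRUE)
  }
  expect_true(all(diff(accs) > 0))
  expect_true(all(diff(rts) > 0))
})

test_that("an immediate boundary rise trades speed for accuracy", {
  base <- fast_ddm()
  up <- fast_ddm(shift_delta_congruent = 0.08, shift_time_mean = 0)
  s0 <- simulate_condition(base, "congruent", n = 30000, seed = 21)
  s1 <- simulate_condition(up, "congruent", n = 30000, seed = 21)
  expect_gte(mean(s1$accuracy, na.rm = TRUE), mean(s0$accuracy, na.rm = TRUE))
  expect_gte(mean(s1$rt, na.rm = TRUE), mean(s0$rt, na.rm = TRUE))
})

test_that("shift models with zero delta reproduce the base model exactly
           under matched seeds", {
  base <- fast_ddm()
  shifted <- fast_ddm(shift_delta_congruent = 0, shift_delta_incongruent = 0,
                      shift_time_mean = 0, shift_time_sd = 0)
  expect_identical(simulate_condition(base, "congruent", 500, seed = 77),
                   simulate_condition(shifted, "congruent", 500, seed = 77))
  # and distributionally under different seeds
  s1 <- simulate_condition(fast_dmc(), "incongruent", 8000, seed = 1)
  s2 <- simulate_condition(fast_dmc(shift_delta_incongruent = 0,
                                    shift_time_mean = 500,
                                    shift_time_sd = 20),
                           "incongruent", 8000, seed = 2)
  ks <- suppressWarnings(stats::ks.test(signed_sample(s1), signed_sample(s2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("a DMC with zero automatic activation matches the equivalent DDM", {
  dmc <- fast_dmc(zeta = 0.0001)  # zeta itself must stay positive-definite free
  dmc$zeta <- 0
  ddm_ms <- ddm_shift_params(a = 150, z_rel = 0.5, v_congruent = 0.5,
                             v_incongruent = 0.5, t0_mean = 320, t0_sd = 30,
                             sigma = 4)
  s_dmc <- simulate_condition(dmc, "incongruent", 8000, seed = 5)
  s_ddm <- simulate_condition(ddm_ms, "incongruent", 8000, dt = 1,
                              deadline = 3000, seed = 6)
  ks <- suppressWarnings(stats::ks.test(signed_sample(s_dmc),
                                        signed_sample(s_ddm)))
  expect_gt(ks$p.value, 0.01)
})

test_that("halving dt changes summaries by less than Monte-Carlo error", {
  m <- sapply(c(0.002, 0.001), function(dtv) {
    s <- simulate_condition(fast_ddm(), "incongruent", n = 40000, dt = dtv,
                            seed = 11)
    c(acc = mean(s$accuracy, na.rm = TRUE),
      rt = mean(s$rt[s$accuracy == 1], na.rm = TRUE))
  })
  expect_lt(abs(m["acc", 1] - m["acc", 2]), 0.008)
  expect_lt(abs(m["rt", 1] - m["rt", 2]), 0.008)
})
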