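#' Automatic-activation drift of the diffusion model of conflict
#'
#' The DMC's automatic process has expected activation
#' \deqn{E[X_a](t) = \zeta (t/t_{peak})^{\alpha-1}
#'       \exp\{-(\alpha-1)(t - t_{peak})/t_{peak}\},}
#' a rescaled gamma density that peaks at exactly \eqn{\zeta} when
#' \eqn{t = t_{peak}}. Its time derivative is the drift contribution that is
#' added to the controlled drift:
#' \deqn{\mu_a(t) = E[X_a](t)\,(\alpha-1)(1/t - 1/t_{peak}).}
#' The sign of `zeta` flips the direction of the pulse (positive for
#' congruent, negative for incongruent trials).
#'
#' @param t time since accumulation onset (> 0); vectorised.
#' @param zeta peak amplitude (evidence units); sign sets direction.
#' @param t_peak peak latency (> 0, same time unit as `t`).
#' @param alpha shape parameter (> 1).
#' @return drift contribution(s), evidence units per time unit.
#' @examples
#' automatic_drift(40, zeta = 20, t_peak = 40, alpha = 2)  # 0 at the peak
#' @export
automatic_drift <- function(t, zeta, t_peak, alpha = 2) {
  if (!is.numeric(t_peak) || length(t_peak) != 1L || t_peak <= 0)
    fail_field("t_peak", "must be > 0")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 1)
    fail_field("alpha", "must be > 1")
  if (any(t <= 0)) stop("automatic_drift is defined for t > 0", call. = FALSE)
  am1 <- alpha - 1
  zeta * (t / t_peak)^am1 * exp(-am1 * (t - t_peak) / t_peak) *
    am1 * (1 / t - 1 / t_peak)
}

#' Boundary value at time t under a step shift
#'
#' Returns the (half-)boundary in force at time `t`: `base` before the shift
#' time and `base + shift_delta` from the shift time on. In the DDM the
#' separation changes symmetrically about the start point; in the DMC the
#' bounds step from `+-b` to `+-(b + shift_delta)`. Both reduce to this
#' scalar step function.
#'
#' @param t time(s) since accumulation onset; vectorised.
#' @param base baseline boundary (> 0).
#' @param shift_delta step change; `base + shift_delta` must be > 0.
#' @param shift_time onset of the shift (same unit as `t`); `Inf` or any
#'   value beyond the deadline disables the shift.
#' @return numeric boundary value(s).
#' @examples
#' boundary_at(c(0.1, 0.5), base = 75, shift_delta = 11.42, shift_time = 0.3)
#' @export
boundary_at <- function(t, base, shift_delta = 0, shift_time = Inf) {
  if (!is.numeric(base) || length(base) != 1L || base <= 0)
    fail_field("base", "must be > 0")
  if (base + shift_delta <= 0)
    fail_field("shift_delta", "boundaries would cross: base + shift_delta must be > 0")
  ifelse(t >= shift_time, base + shift_delta, base)
}

# default integration step and response deadline in each model's time unit
model_defaults <- function(params) {
  if (params$model == "ddm") list(dt = 0.001, deadline = 3.0)
  else list(dt = 1, deadline = 3000)
}

#' Simulate a batch of trials from a (shifted) DDM or DMC
#'
#' First-passage simulation by the Euler--Maruyama scheme
#' \eqn{X_{t+dt} = X_t + \mu(t) dt + \sigma \sqrt{dt}\, N(0,1)}. Per trial, a
#' non-decision time and a boundary-shift time are drawn from truncated
#' normals; trials that have not crossed a bound by the deadline are returned
#' censored (`rt` and `response` missing), emulating "TOO SLOW" null
#' responses. The upper bound is the correct response.
#'
#' Time units follow the parameter object: seconds for the DDM
#' (`dt = 0.001`, `deadline = 3`), milliseconds for the DMC (`dt = 1`,
#' `deadline = 3000`).
#'
#' @param params a [ddm_shift_params()] or [dmc_shift_params()] object.
#' @param congruency `"congruent"` or `"incongruent"`; selects the drift
#'   rate (DDM) or the sign of `zeta` (DMC) and the congruency's
#'   `shift_delta`.
#' @param n number of trials (>= 1).
#' @param dt integration step; defaults to the model convention.
#' @param deadline response deadline in the model's time unit.
#' @param seed optional integer; when given, the simulation runs on its own
#'   seeded stream and the caller's RNG is untouched.
#' @return a data.frame with columns `rt` (model time units, `NA` if
#'   censored), `response` (`"upper"`/`"lower"`, `NA` if censored),
#'   `accuracy` (1 for upper/correct) and `censored`.
#' @examples
#' p <- ddm_shift_params(a = 0.12, v_congruent = 0.35, v_incongruent = 0.25,
#'                       t0_mean = 0.35)
#' sim <- simulate_condition(p, "incongruent", n = 100, seed = 1)
#' mean(sim$accuracy, na.rm = TRUE)
#' @export
simulate_condition <- function(params, congruency = c("congruent", "incongruent"),
                               n, dt = NULL, deadline = NULL, seed = NULL) {
  validate_params(params)
  congruency <- match.arg(congruency)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    fail_field("n", "must be a positive integer")
  defs <- model_defaults(params)
  if (is.null(dt)) dt <- defs$dt
  if (is.null(deadline)) deadline <- defs$deadline
  if (dt <= 0) fail_field("dt", "must be > 0")
  if (deadline <= 0) fail_field("deadline", "must be > 0")

  shift_delta <- if (congruency == "congruent") params$shift_delta_congruent
                 else params$shift_delta_incongruent
  if (params$model == "ddm") {
    out <- with_seed(seed, .sim_diffusion_cpp(
      as.integer(n), 0L, params$a, params$z_rel,
      if (congruency == "congruent") params$v_congruent else params$v_incongruent,
      0, 1, 2,
      params$t0_mean, params$t0_sd,
      shift_delta, params$shift_time_mean, params$shift_time_sd,
      params$sigma, dt, deadline))
  } else {
    out <- with_seed(seed, .sim_diffusion_cpp(
      as.integer(n), 1L, params$b, 0.5,
      params$mu_c,
      if (congruency == "congruent") params$zeta else -params$zeta,
      params$t_peak, params$alpha,
      params$t0_mean, params$t0_sd,
      shift_delta, params$shift_time_mean, params$shift_time_sd,
      params$sigma, dt, deadline))
  }
  data.frame(
    rt = out$rt,
    response = c("lower", NA, "upper")[out$response + 2L],
    accuracy = as.integer(out$response == 1L),
    censored = out$censored,
    stringsAsFactors = FALSE
  )
}

#' Simulate a single trial
#'
#' Convenience wrapper around [simulate_condition()] with `n = 1`.
#'
#' @inheritParams simulate_condition
#' @return a one-row data.frame (see [simulate_condition()]).
#' @export
simulate_trial <- function(params, congruency, dt = NULL, deadline = NULL,
                           seed = NULL) {
  simulate_condition(params, congruency, n = 1L, dt = dt,
                     deadline = deadline, seed = seed)
}
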