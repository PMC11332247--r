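#' Parameters of the drift diffusion model with within-trial boundary shifts
#'
#' The standard DDM accumulates evidence between a lower bound at 0 and an
#' upper (correct) bound at `a`, starting from `z_rel * a`. Separate drift
#' rates are used for congruent and incongruent trials. At a noisy shift time
#' (normal, truncated at 0, measured from accumulation onset, i.e. after the
#' non-decision time) the boundary separation steps from `a` to
#' `a + shift_delta`, applied symmetrically about the start point. Time is in
#' seconds and the diffusion coefficient defaults to the classic
#' `sigma = 0.1` scaling.
#'
#' @param a boundary separation (> 0), evidence units.
#' @param z_rel relative start point in (0, 1); 0.5 is unbiased.
#' @param v_congruent,v_incongruent drift rates (evidence units / s) toward
#'   the correct bound.
#' @param t0_mean,t0_sd mean and SD (s) of the trial-varying non-decision
#'   time (normal truncated at 0).
#' @param shift_delta_congruent,shift_delta_incongruent change in boundary
#'   separation (may be negative) applied at the shift time on trials of
#'   each congruency.
#' @param shift_time_mean,shift_time_sd shift-onset distribution (s from
#'   accumulation start; normal truncated at 0).
#' @param sigma diffusion coefficient (fixed scaling constant).
#' @return an object of class `c("ddm_shift_params", "diffusion_params")`.
#' @examples
#' p <- ddm_shift_params(a = 0.12, v_congruent = 0.35, v_incongruent = 0.25,
#'                       t0_mean = 0.35, t0_sd = 0.04)
#' @export
ddm_shift_params <- function(a, z_rel = 0.5, v_congruent, v_incongruent,
                             t0_mean, t0_sd = 0,
                             shift_delta_congruent = 0,
                             shift_delta_incongruent = 0,
                             shift_time_mean = 0, shift_time_sd = 0,
                             sigma = 0.1) {
  p <- list(model = "ddm", a = a, z_rel = z_rel,
            v_congruent = v_congruent, v_incongruent = v_incongruent,
            t0_mean = t0_mean, t0_sd = t0_sd,
            shift_delta_congruent = shift_delta_congruent,
            shift_delta_incongruent = shift_delta_incongruent,
            shift_time_mean = shift_time_mean, shift_time_sd = shift_time_sd,
            sigma = sigma)
  class(p) <- c("ddm_shift_params", "diffusion_params")
  validate_params(p)
  p
}

#' Parameters of the diffusion model of conflict (DMC) with boundary shifts
#'
#' The DMC superimposes a transient, gamma-shaped automatic activation on a
#' constant controlled drift `mu_c`. Accumulation starts at 0 between bounds
#' at `-b` and `+b` (upper = correct). The automatic activation has peak
#' amplitude `zeta` (its sign is set by congruency: positive on congruent,
#' negative on incongruent trials), peak latency `t_peak` and shape `alpha`.
#' At the noisy shift time both bounds step to `+-(b + shift_delta)`.
#' Following the DMC literature, time is in milliseconds and `sigma = 4`.
#'
#' @param b bound (> 0), evidence units; bounds sit at `-b` and `+b`.
#' @param mu_c controlled drift rate (evidence units / ms).
#' @param zeta peak amplitude of the automatic activation (> 0); negated
#'   internally on incongruent trials.
#' @param t_peak peak latency (ms, > 0).
#' @param alpha shape parameter (> 1); commonly fixed at 2.
#' @param t0_mean,t0_sd non-decision time mean and SD (ms).
#' @param shift_delta_congruent,shift_delta_incongruent bound change
#'   (evidence units, may be negative) per congruency.
#' @param shift_time_mean,shift_time_sd shift-onset distribution (ms).
#' @param sigma diffusion coefficient.
#' @return an object of class `c("dmc_shift_params", "diffusion_params")`.
#' @examples
#' p <- dmc_shift_params(b = 75, mu_c = 0.5, zeta = 20, t_peak = 40,
#'                       t0_mean = 320, t0_sd = 30)
#' @export
dmc_shift_params <- function(b, mu_c, zeta, t_peak, alpha = 2,
                             t0_mean, t0_sd = 0,
                             shift_delta_congruent = 0,
                             shift_delta_incongruent = 0,
                             shift_time_mean = 0, shift_time_sd = 0,
                             sigma = 4) {
  p <- list(model = "dmc", b = b, mu_c = mu_c, zeta = zeta,
            t_peak = t_peak, alpha = alpha,
            t0_mean = t0_mean, t0_sd = t0_sd,
            shift_delta_congruent = shift_delta_congruent,
            shift_delta_incongruent = shift_delta_incongruent,
            shift_time_mean = shift_time_mean, shift_time_sd = shift_time_sd,
            sigma = sigma)
  class(p) <- c("dmc_shift_params", "diffusion_params")
  validate_params(p)
  p
}

#' @keywords internal
validate_params <- function(p) {
  num1 <- function(field) {
    v <- p[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      fail_field(field, "must be a single finite number")
    v
  }
  if (p$model == "ddm") {
    if (num1("a") <= 0) fail_field("a", "boundary separation must be > 0")
    z <- num1("z_rel")
    if (z <= 0 || z >= 1) fail_field("z_rel", "must lie in (0, 1)")
    num1("v_congruent"); num1("v_incongruent")
    base <- p$a
  } else {
    if (num1("b") <= 0) fail_field("b", "bound must be > 0")
    num1("mu_c")
    num1("zeta")
    if (num1("t_peak") <= 0) fail_field("t_peak", "peak latency must be > 0")
    if (num1("alpha") <= 1) fail_field("alpha", "shape must be > 1")
    base <- p$b
  }
  if (num1("t0_mean") < 0) fail_field("t0_mean", "must be >= 0")
  if (num1("t0_sd") < 0) fail_field("t0_sd", "must be >= 0")
  if (num1("shift_time_mean") < 0) fail_field("shift_time_mean", "must be >= 0")
  if (num1("shift_time_sd") < 0) fail_field("shift_time_sd", "must be >= 0")
  if (num1("sigma") <= 0) fail_field("sigma", "must be > 0")
  for (f in c("shift_delta_congruent", "shift_delta_incongruent")) {
    if (base + num1(f) <= 0)
      fail_field(f, "boundaries would cross: base + shift_delta must be > 0")
  }
  invisible(p)
}

#' @export
print.diffusion_params <- function(x, ...) {
  cat(sprintf("<%s parameters%s>\n",
              toupper(x$model),
              if (x$shift_delta_congruent != 0 || x$shift_delta_incongruent != 0)
                " with boundary shift" else ""))
  flds <- setdiff(names(x), "model")
  for (f in flds) cat(sprintf("  %-24s %g\n", f, x[[f]]))
  invisible(x)
}
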