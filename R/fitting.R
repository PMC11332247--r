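#' Two-sample Kolmogorov--Smirnov distance
#'
#' The maximum absolute vertical distance between the empirical CDFs of two
#' samples. Used on signed RTs (error RTs negated) so that a single CDF
#' jointly encodes accuracy and the shapes of both the correct and the error
#' RT distribution.
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @return the KS statistic in `[0, 1]`.
#' @examples
#' ks_distance(c(1, 2, 3, 4), c(2, 3, 4, 5))  # 0.25
#' @export
ks_distance <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b))
    stop("ks_distance needs two non-empty samples", call. = FALSE)
  w <- c(sample_a, sample_b)
  step <- c(rep(1 / length(sample_a), length(sample_a)),
            rep(-1 / length(sample_b), length(sample_b)))
  ord <- order(w)
  ws <- w[ord]
  cum <- cumsum(step[ord])
  at_value_end <- c(ws[-1L] != ws[-length(ws)], TRUE)  # evaluate after ties
  max(abs(cum[at_value_end]))
}

# signed-RT encoding: correct trials positive, errors negative
signed_rt <- function(rt, accuracy) ifelse(accuracy == 1, rt, -rt)

#' Parameter vector layout of each fit model
#' @param model `"ddm"`, `"ddm_shift"`, `"dmc"` or `"dmc_shift"`.
#' @return character vector of parameter names, in the stable order used by
#'   bounds, optimizer and reports.
#' @export
param_names <- function(model) {
  base <- if (startsWith(model, "ddm"))
    c("a", "z_rel", "v_congruent", "v_incongruent", "t0_mean", "t0_sd")
  else
    c("b", "mu_c", "zeta", "t_peak", "t0_mean", "t0_sd")
  if (endsWith(model, "_shift"))
    base <- c(base, "shift_delta_congruent", "shift_delta_incongruent",
              "shift_time_mean", "shift_time_sd")
  base
}

#' Default parameter bounds for KS fitting
#'
#' The study's own bounds live in unavailable supplementary material; these
#' defaults come from the DMC/DDM literature and from the scale of the
#' reported effects (DDM shift deltas span the optimality grid's
#' -0.05..0.1). All are overridable in [fit_subject()].
#'
#' @inheritParams param_names
#' @return `list(lower = , upper = )` named numeric vectors.
#' @export
default_bounds <- function(model) {
  if (startsWith(model, "ddm")) {
    lower <- c(a = 0.05, z_rel = 0.3, v_congruent = 0, v_incongruent = 0,
               t0_mean = 0.1, t0_sd = 0)
    upper <- c(a = 0.3, z_rel = 0.7, v_congruent = 0.5, v_incongruent = 0.5,
               t0_mean = 0.6, t0_sd = 0.1)
    if (endsWith(model, "_shift")) {
      lower <- c(lower, shift_delta_congruent = -0.05,
                 shift_delta_incongruent = -0.05,
                 shift_time_mean = 0, shift_time_sd = 0)
      upper <- c(upper, shift_delta_congruent = 0.1,
                 shift_delta_incongruent = 0.1,
                 shift_time_mean = 1, shift_time_sd = 0.1)
    }
  } else {
    lower <- c(b = 20, mu_c = 0.1, zeta = 5, t_peak = 15,
               t0_mean = 100, t0_sd = 0)
    upper <- c(b = 150, mu_c = 1.0, zeta = 50, t_peak = 300,
               t0_mean = 600, t0_sd = 100)
    if (endsWith(model, "_shift")) {
      lower <- c(lower, shift_delta_congruent = -30,
                 shift_delta_incongruent = -30,
                 shift_time_mean = 0, shift_time_sd = 0)
      upper <- c(upper, shift_delta_congruent = 60,
                 shift_delta_incongruent = 60,
                 shift_time_mean = 1000, shift_time_sd = 100)
    }
  }
  list(lower = lower, upper = upper)
}

# fitted vector (possibly without shift fields) -> full params object
fit_vec_to_params <- function(model, v) {
  v <- stats::setNames(as.numeric(v), param_names(model))
  full_names <- c(param_names(paste0(sub("_shift$", "", model), "_shift")))
  full <- stats::setNames(numeric(length(full_names)), full_names)
  full[names(v)] <- v
  params_from_vector(model, full)
}

#' Optimisation profiles for KS fitting
#'
#' `"full"` mirrors the defaults the method description implies (population
#' 10 x dimension, 200 generations, 10000 simulated trials per condition per
#' evaluation, 1 ms steps); `"ci"` is a reduced profile (24 x 40, two
#' averaged CRN replicates of 1500 trials, 2 ms steps, 200 Nelder-Mead
#' polish steps) that keeps recovery studies within a desktop-CPU budget at
#' some cost in estimate precision.
#'
#' @param profile `"ci"` or `"full"`.
#' @param ... overrides for `pop_size`, `generations`, `n_sim`, `dt`.
#' @return a list of control settings.
#' @export
fit_control <- function(profile = c("ci", "full"), ...) {
  profile <- match.arg(profile)
  ctl <- if (profile == "ci")
    list(pop_size = 24L, generations = 40L, n_sim = 1500L, n_seeds = 2L,
         dt = NULL, dt_scale = 2, polish_maxit = 200L)
  else
    list(pop_size = NULL, generations = 200L, n_sim = 10000L, n_seeds = 2L,
         dt = NULL, dt_scale = 1, polish_maxit = 400L)
  ctl$profile <- profile
  over <- list(...)
  ctl[names(over)] <- over
  ctl
}

#' KS objective for a candidate parameter vector
#'
#' Simulates `n_sim` trials per congruency condition under common random
#' numbers (the RNG is re-seeded with `obj_seed` at each evaluation and the
#' caller's stream is preserved) and returns the trial-count-weighted mean
#' of the per-condition KS distances between observed and simulated
#' signed-RT samples. Sparse conditions (< 10 observed trials) trigger a
#' warning at data preparation and simply carry their small trial-count
#' weight. Parameter vectors whose boundaries would cross get a penalty
#' value above 1 without simulation.
#'
#' @param par numeric vector in [param_names()] order.
#' @param data_by_condition list with `congruent` and `incongruent`
#'   signed-RT vectors in model time units.
#' @param model model name.
#' @param n_sim simulated trials per condition (>= 1).
#' @param obj_seed integer seed(s) for the common random numbers; with
#'   several seeds the criterion is averaged over the replicates, which
#'   keeps the optimizer from exploiting one simulation draw.
#' @param dt,deadline integration step and deadline in model units.
#' @return the aggregate criterion (a number in `[0, 1]`, or `> 1` for
#'   infeasible vectors).
#' @export
ks_objective <- function(par, data_by_condition, model, n_sim, obj_seed,
                         dt = NULL, deadline = NULL) {
  nm <- param_names(model)
  base <- par[1L]
  if (endsWith(model, "_shift")) {
    viol <- -(base + min(par[nm %in% c("shift_delta_congruent",
                                       "shift_delta_incongruent")]))
    if (viol >= 0) return(1 + viol)
  }
  params <- fit_vec_to_params(model, par)
  w <- vapply(data_by_condition, length, integer(1))
  one_rep <- function(seed1) with_seed(seed1, {
    vapply(c("congruent", "incongruent"), function(cond) {
      sim <- simulate_condition(params, cond, n = n_sim, dt = dt,
                                deadline = deadline)
      s <- signed_rt(sim$rt, sim$accuracy)
      s <- s[!is.na(s)]
      if (!length(s)) return(1)
      ks_distance(data_by_condition[[cond]], s)
    }, numeric(1))
  })
  ks <- rowMeans(vapply(obj_seed, one_rep, numeric(2)))
  sum(w * ks) / sum(w)
}

#' Fit one subject by KS minimisation with differential evolution
#'
#' Estimates the chosen model's parameters for a single subject by bounded
#' differential evolution on [ks_objective()]. Deterministic given `seed`
#' (one derived stream drives the optimizer, another the common random
#' numbers of the objective). Supplying `init` injects starting vectors into
#' the initial population -- used to warm-start a shift model from its
#' no-shift fit, which guarantees the nested-model KS ordering.
#'
#' @param trials trial table rows for one subject (columns `congruency`,
#'   `rt_ms`, `accuracy`); trials without a recorded response are dropped,
#'   error trials are retained for the signed-RT encoding.
#' @param model `"ddm"`, `"ddm_shift"`, `"dmc"` or `"dmc_shift"`.
#' @param bounds `list(lower=, upper=)`, default [default_bounds()].
#' @param control see [fit_control()].
#' @param seed integer seed.
#' @param init optional numeric vector(s) in [param_names()] order.
#' @return an object of class `"sddm_fit"`: estimated `params`, `ks_value`,
#'   trial counts, optimizer diagnostics and the seed.
#' @export
fit_subject <- function(trials, model, bounds = default_bounds(model),
                        control = fit_control("ci"), seed = 1L, init = NULL) {
  ok <- !is.na(trials$rt_ms) & !is.na(trials$accuracy)
  tr <- trials[ok, , drop = FALSE]
  unit <- if (startsWith(model, "ddm")) 1000 else 1   # ms -> model units
  data_by_condition <- lapply(c(congruent = "congruent",
                                incongruent = "incongruent"), function(cond) {
    rows <- tr[tr$congruency == cond, ]
    if (nrow(rows) == 0L)
      stop(sprintf("no %s trials for this subject", cond), call. = FALSE)
    if (nrow(rows) < 10L)
      warning(sprintf("only %d %s trials; condition carries little weight",
                      nrow(rows), cond))
    signed_rt(rows$rt_ms / unit, rows$accuracy)
  })

  defs <- model_defaults(list(model = sub("_shift$", "", model)))
  dt <- if (is.null(control$dt)) defs$dt * control$dt_scale else control$dt
  deadline <- defs$deadline
  lower <- bounds$lower[param_names(model)]
  upper <- bounds$upper[param_names(model)]
  if (anyNA(lower) || anyNA(upper))
    fail_field("bounds", "must cover every model parameter")
  d <- length(lower)
  pop_size <- if (is.null(control$pop_size)) 10L * d else control$pop_size
  n_seeds <- if (is.null(control$n_seeds)) 1L else control$n_seeds
  obj_seed <- vapply(seq_len(n_seeds),
                     function(k) derive_seed(seed, paste0("objective", k)),
                     integer(1))

  if (startsWith(model, "ddm")) {
    # anchor the population with EZ moment estimates (plus user vectors)
    ez <- ddm_init_vectors(model, data_by_condition, lower, upper)
    if (!is.null(ez)) init <- rbind(init, ez)
  }
  fn <- function(v) ks_objective(v, data_by_condition, model,
                                 n_sim = control$n_sim, obj_seed = obj_seed,
                                 dt = dt, deadline = deadline)
  res <- with_seed(derive_seed(seed, "optimizer"),
                   de_optim(fn, lower, upper, pop_size = pop_size,
                            generations = control$generations, init = init))
  if (isTRUE(control$polish_maxit > 0)) {
    # the CRN objective is deterministic, so a derivative-free local polish
    # is well posed; accepted only if it improves on the DE optimum
    pen <- function(v) if (any(v < lower | v > upper)) 2 else fn(v)
    pol <- stats::optim(res$par, pen, method = "Nelder-Mead",
                        control = list(maxit = control$polish_maxit))
    res$evaluations <- res$evaluations + pol$counts[[1L]]
    if (pol$value <= res$value) {
      res$par <- pol$par
      res$value <- pol$value
    }
  }
  structure(list(
    subject_id = if ("subject_id" %in% names(tr)) tr$subject_id[1L] else NA,
    model = model,
    params = stats::setNames(res$par, param_names(model)),
    ks_value = res$value,
    n_trials_per_condition = vapply(data_by_condition, length, integer(1)),
    evaluations = res$evaluations,
    converged = res$improved,
    seed = seed,
    profile = control$profile
  ), class = "sddm_fit")
}

#' @export
print.sddm_fit <- function(x, ...) {
  cat(sprintf("<%s fit, subject %s: KS = %.4f (%s profile, %d evaluations)>\n",
              x$model, x$subject_id, x$ks_value, x$profile, x$evaluations))
  print(round(x$params, 4))
  invisible(x)
}

#' Fit every subject in a trial table
#'
#' @inheritParams fit_subject
#' @param trials multi-subject trial table.
#' @param seed root seed; each subject gets a derived substream.
#' @return list of `"sddm_fit"` objects, named by subject.
#' @export
fit_subjects <- function(trials, model, bounds = default_bounds(model),
                         control = fit_control("ci"), seed = 1L) {
  sids <- unique(trials$subject_id)
  fits <- lapply(sids, function(sid)
    fit_subject(trials[trials$subject_id == sid, , drop = FALSE], model,
                bounds = bounds, control = control,
                seed = derive_seed(seed, paste0("fit_", sid))))
  names(fits) <- sids
  fits
}

#' Tabulate per-subject fitted parameters
#' @param fits list of `"sddm_fit"` objects.
#' @param groups optional data.frame mapping `subject_id` to `group`.
#' @return data.frame with one row per subject.
#' @export
fit_table <- function(fits, groups = NULL) {
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(subject_id = f$subject_id, model = f$model,
               ks_value = f$ks_value, t(f$params),
               stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  if (!is.null(groups))
    tab$group <- groups$group[match(tab$subject_id, groups$subject_id)]
  tab
}

#' EZ-diffusion moment estimates used to seed the optimizer
#'
#' Closed-form method-of-moments estimates of boundary, drift and
#' non-decision time from accuracy, mean and variance of correct RTs
#' (classic EZ equations, `sigma = 0.1` scale, seconds). Used to anchor the
#' differential-evolution population in the right basin; never reported as
#' estimates themselves.
#'
#' @param accuracy proportion correct (edge-corrected internally).
#' @param mrt,vrt mean and variance of correct RTs in seconds.
#' @param n trial count, for the edge correction.
#' @return `c(a, v, t0)`.
#' @keywords internal
ez_diffusion <- function(accuracy, mrt, vrt, n) {
  s <- 0.1
  pc <- min(max(accuracy, 0.5 + 1 / (2 * n)), 1 - 1 / (2 * n))
  L <- stats::qlogis(pc)
  x <- L * (L * pc^2 - L * pc + pc - 0.5) / max(vrt, 1e-6)
  v <- sign(pc - 0.5) * s * x^(1 / 4)
  a <- s^2 * L / v
  mdt <- (a / (2 * v)) * (1 - exp(-v * a / s^2)) / (1 + exp(-v * a / s^2))
  c(a = a, v = v, t0 = max(mrt - mdt, 0.05))
}

# data-driven initial vectors for the DE population (DDM scale)
ddm_init_vectors <- function(model, data_by_condition, lower, upper) {
  ez_cond <- lapply(data_by_condition, function(s) {
    correct <- s[s > 0]
    if (length(correct) < 5L) return(NULL)
    ez_diffusion(length(correct) / length(s), mean(correct),
                 stats::var(correct), length(s))
  })
  if (any(vapply(ez_cond, is.null, logical(1)))) return(NULL)
  a0 <- mean(c(ez_cond$congruent["a"], ez_cond$incongruent["a"]))
  base <- c(a0, 0.5, ez_cond$congruent["v"], ez_cond$incongruent["v"],
            mean(c(ez_cond$congruent["t0"], ez_cond$incongruent["t0"])), 0.03)
  if (endsWith(model, "_shift"))
    base <- c(base, 0, 0, 0.3, 0.05)
  init <- rbind(base,
                base * c(1.15, 1, 1.1, 1.1, 0.95, rep(1, length(base) - 5L)),
                base * c(0.85, 1, 0.9, 0.9, 1.00, rep(1, length(base) - 5L)))
  init <- pmin(pmax(init, rep(lower, each = nrow(init))),
               rep(upper, each = nrow(init)))
  unname(init)
}

# equal-count quantile-bin means of a sample (sorted, split into n groups)
quantile_bin_means <- function(x, n = 5L) {
  x <- sort(x)
  bin <- ceiling(seq_along(x) / length(x) * n)
  as.numeric(tapply(x, bin, mean))
}

#' Goodness of fit: predicted vs observed quantile means and accuracy
#'
#' Simulates each subject at its fitted parameters and correlates, pooled
#' over subjects x conditions (x quintiles for RT), the predicted with the
#' observed quintile means of correct RTs and the predicted with the
#' observed accuracy.
#'
#' @param fits list of `"sddm_fit"` objects.
#' @param trials the trial table the fits were estimated on.
#' @param n_sim simulated trials per condition per subject.
#' @param seed integer seed.
#' @return `list(r_quantile_rt = , r_accuracy = , table = pooled data)`.
#' @export
goodness_of_fit <- function(fits, trials, n_sim = 2000L, seed = 1L) {
  rows <- list()
  for (f in fits) {
    unit <- if (startsWith(f$model, "ddm")) 1000 else 1
    params <- fit_vec_to_params(f$model, f$params)
    tr <- trials[trials$subject_id == f$subject_id &
                   !is.na(trials$rt_ms) & !is.na(trials$accuracy), ]
    for (cond in c("congruent", "incongruent")) {
      obs <- tr[tr$congruency == cond, ]
      if (nrow(obs) < 5L) next
      sim <- simulate_condition(params, cond, n = n_sim,
                                seed = derive_seed(seed,
                                  paste0(f$subject_id, cond)))
      sim <- sim[!sim$censored, ]
      obs_q <- quantile_bin_means(obs$rt_ms[obs$accuracy == 1])
      sim_q <- quantile_bin_means(sim$rt[sim$accuracy == 1] * unit)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = f$subject_id, congruency = cond,
        quintile = seq_along(obs_q),
        obs_rt = obs_q, pred_rt = sim_q,
        obs_acc = mean(obs$accuracy), pred_acc = mean(sim$accuracy),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  acc <- unique(tab[, c("subject_id", "congruency", "obs_acc", "pred_acc")])
  list(r_quantile_rt = cor(tab$obs_rt, tab$pred_rt),
       r_accuracy = cor(acc$obs_acc, acc$pred_acc),
       table = tab)
}
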