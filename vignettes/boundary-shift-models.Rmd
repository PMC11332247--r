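---
title: "Evidence-accumulation models with within-trial boundary shifts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence-accumulation models with within-trial boundary shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shiftddm)
```

## The scientific problem

In task-switching paradigms with shared response keys, a stimulus is
*congruent* when both tasks map it to the same key and *incongruent* when
they conflict. Selectively rewarding correct responses on one congruency
level more than on the other asks whether people can *learn* a control
strategy through reinforcement rather than deploy it strategically. The
behavioural signature is a modulation of the congruency effect; the
mechanistic question — what changed inside the decision process — calls for
evidence-accumulation modelling.

`shiftddm` implements the full computational pipeline for this question:

1. a **design generator** for congruency-contingent reward schedules
   (4 blocks x 80 unique stimuli; high-reward probability 90/10 per
   congruency in Experiments 1 and 3, 50/0 in Experiment 2, whose second
   half repeats every stimulus once; 3000 ms response deadline),
2. **diffusion simulators** — the standard two-boundary drift diffusion
   model (DDM) and the diffusion model of conflict (DMC) — each optionally
   extended with a *within-trial boundary shift*,
3. **preprocessing** with the study's exclusion rules,
4. **KS-minimisation fitting** by differential evolution,
5. **conditional accuracy functions**, **group comparisons** (Welch/pooled
   t, Cohen's d), and a **reward-rate optimality sweep**.

## Models

### Standard DDM

Evidence $X_t$ accumulates between a lower bound at $0$ and an upper
(correct) bound at $a$ from a start point $z_{rel} \cdot a$:
$dX = v\,dt + \sigma\,dW$, with separate drift rates $v_c, v_i$ for
congruent and incongruent trials, trial-varying non-decision time
$t_0 \sim \mathcal N(\mu_{t_0}, \sigma_{t_0})$ truncated at zero, and the
classic scaling $\sigma = 0.1$ (time in seconds).

### DMC

The DMC superimposes a transient automatic activation on the controlled
drift $\mu_c$. Its expected time course is the rescaled gamma kernel
$E[X_a](t) = \zeta\,(t/t_{peak})^{\alpha-1}
 e^{-(\alpha-1)(t-t_{peak})/t_{peak}}$, which peaks at exactly $\zeta$ when
$t = t_{peak}$; the drift contribution is its derivative (see
`automatic_drift()`). $\zeta$ is positive on congruent and negative on
incongruent trials, producing the fast errors that the standard DDM cannot:
early on, incongruent evidence is pulled toward the wrong bound. Following
the DMC literature the accumulator runs in milliseconds with $\sigma = 4$,
bounds at $\pm b$, start at 0, and $\alpha$ fixed at 2 by default
(estimable via the bounds configuration).

### Within-trial boundary shift

Both models can step their boundary at a noisy shift time measured from
accumulation onset (independent of, but after, the non-decision time):
separation $a \to a + \delta$ (symmetrically about the start point) in the
DDM, bounds $\pm b \to \pm(b+\delta)$ in the DMC, with
congruency-specific $\delta_c, \delta_i$ (positive or negative) and shift
time $\sim \mathcal N(\mu_s, \sigma_s)$ truncated at zero. This models
post-conflict-detection caution adjustments: raising the boundary late in
the trial buys accuracy on the trials that are still running — typically
the conflict-laden slow ones — at a time cost.

Simulation is Euler–Maruyama,
$X_{t+dt} = X_t + \mu(t)\,dt + \sigma\sqrt{dt}\,\mathcal N(0,1)$, first
passage censored at the deadline ("TOO SLOW" null responses). The default
step is 1 ms; halving it moves accuracy and mean RT by less than
Monte-Carlo error at $10^5$ trials (a test asserts this at 2 ms vs 1 ms),
which is why the reduced fitting profile may use 2 ms.

```{r}
p <- dmc_shift_params(b = 75, mu_c = 0.5, zeta = 20, t_peak = 40,
                      t0_mean = 320, t0_sd = 30,
                      shift_delta_congruent = 10,
                      shift_delta_incongruent = 5,
                      shift_time_mean = 300, shift_time_sd = 50)
sim <- simulate_condition(p, "incongruent", n = 2000, seed = 1)
mean(sim$accuracy, na.rm = TRUE)
```

## Fitting by KS minimisation

Parameters are estimated per subject by minimising the two-sample
Kolmogorov–Smirnov statistic between the observed and a simulated RT
distribution, aggregated across congruency conditions by trial-count
weights. Two choices deserve comment:

- **Signed-RT encoding.** The criterion description speaks of RT CDFs only,
  but accuracy must constrain the fit for the model to explain error
  patterns. We therefore negate error RTs so one joint CDF encodes
  accuracy (the mass below zero) and both RT distributions. This is the
  default; the objective function is exposed so a correct-only variant can
  be composed if wanted.
- **Common random numbers.** Each objective evaluation re-seeds its own
  stream, making the objective a deterministic function of (parameters,
  seed). This removes optimizer chatter and makes fits bit-reproducible; it
  also makes a derivative-free local polish (Nelder–Mead, accepted only on
  improvement) well posed after the global differential-evolution search.
  Because an optimizer will happily exploit the noise of a *single* frozen
  simulation draw (we observed fits whose CRN objective beat the truth
  while their unbiased objective did not), the criterion is averaged over
  two independent CRN replicates by default (`fit_control(n_seeds = )`).
- **EZ anchoring.** The DE population for DDM-family fits is seeded with
  closed-form EZ-diffusion moment estimates of boundary, drifts and
  non-decision time (plus ±15% variants). This anchors the search in the
  right basin: without it, subjects near the accuracy ceiling sometimes
  converge to a high-boundary/high-drift basin that the KS criterion at
  320 trials genuinely cannot reject. The anchor is a starting point only,
  never a reported estimate.

The study's own parameter bounds live in supplementary material that is not
available here; `default_bounds()` documents literature-based defaults
(DDM boundary 0.05–0.3, drifts 0–0.5 /s, non-decision 0.1–0.6 s; DMC bound
20–150, controlled drift 0.1–1 /ms, amplitude 5–50, peak latency
15–300 ms), with shift deltas spanning the optimality grid (−0.05 to 0.1
for the DDM). These are package defaults, not values from the source study.

Nested model comparisons (shift vs no-shift) are run by *warm-starting* the
shift model's initial population with the no-shift optimum (zero deltas,
zero shift-time parameters). Because the base simulator consumes exactly
the same random numbers as the shift simulator at zero shift, the
warm-start vector reproduces the base objective value exactly under a
common seed, so the fitted KS of the shift model can never exceed its
reduction's — the qualitative ordering reported for these model families
holds by construction rather than only on average.

Two optimisation profiles exist: `fit_control("full")` (population
10 x dimension, 200 generations, 10,000 simulated trials per evaluation,
1 ms steps) and `fit_control("ci")` (24 x 40, two averaged replicates of
1,500 trials, 2 ms steps, 200 polish steps), which the test suite uses to
keep a 20-subject recovery study around ten minutes on one CPU. The recovery tests' thresholds (rank
correlation above 0.7 for boundary and drift rates; correct shift-delta
sign in a majority of subjects) are repository acceptance levels for the
reduced profile, not claims from the source study.

## What the synthetic cohorts emulate — and what they do not

`generate_cohort()` draws each subject's true parameters from a
between-subject population (`default_population()`), builds a balanced
design, and simulates behaviour from the chosen generative model. Default
populations were fixed once, before any tests were written against them:

- DDM: boundary 0.11 ± 0.02, drifts 0.28/0.20 ± 0.06 /s, non-decision
  0.35 ± 0.04 s — chosen so cohorts show ~95%/~90% accuracy and
  ~550/630 ms mean RT on congruent/incongruent trials, the accuracy and RT
  range typical of these task-switching experiments. (Near-ceiling
  accuracy, besides being unrealistic, leaves the boundary-drift product
  unidentified by a KS criterion.)
- DMC: bound 75, controlled drift 0.5 /ms, amplitude 20, peak latency
  40 ms, σ = 4 — standard DMC literature values; shift deltas average
  10/5 evidence units with 15 between subjects, consistent in scale with
  the reported group difference-score summaries (means ~11/6, SDs ~29).

The generator emulates the designs' balance, uniqueness and reward
schedules. It does **not** emulate: sequential effects beyond the
task-transition structure (no post-conflict adaptation across trials),
learning within the session (parameters are constant over blocks),
stimulus-level variability, or contaminant responses. A green recovery test
therefore establishes that the estimator works *when the model is true at
stationary parameters*, not that the model is true of human data.

## Numerical and design choices

- **Quartile convention** for Tukey fences and CAF edges: linear
  interpolation (R type 7), fixed and documented for bit-reproducibility.
- **IQR fences** are computed once per subject on the RT-stream survivors
  (correct, non-post-event, ≥200 ms trials) and not iterated.
- **Inattention rule**: the source description names "long sequences of
  premature or null responses" without a number; we use ≥10 consecutive
  null/<200 ms responses, configurable.
- **Accuracy floor**: "at or below 60% per task" is implemented as ≤ 0.60.
- **One-third re-reward rule** (Experiment 2's second half): floor(n/3)
  plus a seeded Bernoulli top-up with probability (n mod 3)/3, so the
  expectation equals exactly one third.
- **CAF pooling**: quintile edges pool both congruencies within group so
  the two curves share bins; `pool = "group_congruency"` switches.
- **Welch rule**: a median-centred Levene test at α = 0.05 decides between
  pooled and Welch t by default; both can be forced. Cohen's d always uses
  the pooled SD (matching the convention of reporting d alongside either t
  flavour), with a noncentral-t 95% CI.
- **ITI for reward-rate discounting**: never printed in the source; default
  1500 ms (1000 ms fixation + a nominal 500 ms feedback screen),
  configurable via `experiment_config(iti_ms = )`. The qualitative
  optimality results (interior optimum over boundary shift; monotone gain
  over drift) are asserted at this default.
- **Shift-time noise SD** is a free parameter with a narrow bound
  (0–0.1 s DDM / 0–100 ms DMC), since the source does not say whether it
  was estimated.
- **Omitted classic extensions**: start-point and drift-rate variability
  are not modelled (never mentioned by the modelling description).

## Worked example

```{r}
# group comparison from printed summary statistics
summary_from_stats(11.42, 29.35, 209, 6.11, 27.89, 206)
```

## Limitations

KS fitting with 10 free parameters at 320 trials per subject is noisy;
shift-time parameters in particular are weakly identified because only the
slow tail of trials is still accumulating when the shift arrives. The
reduced profile recovers rank order well but individual shift deltas only
by sign tendency. The pipeline makes no attempt at hierarchical shrinkage
or model-selection criteria beyond raw KS comparison, mirroring the scope
of the analysis it reimplements.
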