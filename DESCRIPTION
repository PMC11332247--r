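Package: shiftddm
Title: Drift Diffusion and Conflict Diffusion Models with Within-Trial
    Boundary Shifts
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation, fitting and analysis of evidence-accumulation
    models of conflict tasks in which the decision boundary may step up or
    down within a trial at a noisy shift time. Provides a trial-sequence
    generator for congruency-contingent reward schedules in task-switching
    designs, the standard drift diffusion model (DDM) and the diffusion
    model of conflict (DMC) with and without boundary shifts, per-subject
    parameter estimation by Kolmogorov-Smirnov minimisation with
    differential evolution, conditional accuracy functions, group
    comparisons (Welch or pooled t, Cohen's d), and reward-rate optimality
    sweeps over boundary-shift by drift-rate grids.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
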