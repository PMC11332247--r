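#' Bounded differential evolution (rand/1/bin)
#'
#' Minimal, seeded DE for box-constrained minimisation of noisy simulation
#' objectives. Candidates outside the box are reflected back inside. The
#' initial population is Latin-hypercube-free uniform sampling, optionally
#' with user-supplied starting vectors injected (used to warm-start nested
#' models from their reduced fits).
#'
#' @param fn objective, called with a single numeric vector.
#' @param lower,upper bound vectors (equal length).
#' @param pop_size population size (>= 4).
#' @param generations number of generations.
#' @param F mutation weight.
#' @param CR crossover probability.
#' @param init optional matrix (rows = vectors) or single vector inserted
#'   into the initial population.
#' @return `list(par, value, evaluations, improved)`; `improved` is FALSE
#'   when no candidate beat the best initial member.
#' @keywords internal
de_optim <- function(fn, lower, upper, pop_size = 40L, generations = 100L,
                     F = 0.8, CR = 0.9, init = NULL) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper >= lower), pop_size >= 4L)
  pop <- matrix(stats::runif(pop_size * d, rep(lower, each = pop_size),
                             rep(upper, each = pop_size)),
                nrow = pop_size)
  if (!is.null(init)) {
    init <- rbind(init)
    k <- min(nrow(init), pop_size)
    pop[seq_len(k), ] <- pmin(pmax(init[seq_len(k), , drop = FALSE],
                                   rep(lower, each = k)),
                              rep(upper, each = k))
  }
  cost <- apply(pop, 1L, fn)
  evals <- pop_size
  init_best <- min(cost)

  reflect <- function(x) {
    for (j in seq_len(d)) {
      if (x[j] < lower[j]) x[j] <- min(upper[j], 2 * lower[j] - x[j])
      if (x[j] > upper[j]) x[j] <- max(lower[j], 2 * upper[j] - x[j])
    }
    x
  }
  for (g in seq_len(generations)) {
    for (i in seq_len(pop_size)) {
      idx <- sample.int(pop_size, 3L)
      while (any(idx == i)) idx <- sample.int(pop_size, 3L)
      mutant <- reflect(pop[idx[1L], ] + F * (pop[idx[2L], ] - pop[idx[3L], ]))
      cross <- stats::runif(d) < CR
      cross[sample.int(d, 1L)] <- TRUE
      trial <- ifelse(cross, mutant, pop[i, ])
      tc <- fn(trial)
      evals <- evals + 1L
      if (tc <= cost[i]) { pop[i, ] <- trial; cost[i] <- tc }
    }
  }
  best <- which.min(cost)
  list(par = pop[best, ], value = cost[best], evaluations = evals,
       improved = cost[best] < init_best)
}
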