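#' Evaluate code under a temporary RNG seed
#'
#' Saves the global RNG state, seeds it with `seed`, evaluates `code` and
#' restores the previous state. With `seed = NULL` the code runs on the
#' current stream. Used throughout so that explicit-seed entry points never
#' perturb the caller's RNG.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a named substream seed from a root seed
#'
#' Deterministic 31-bit hash of (root, name). Each pipeline stage and each
#' simulated subject draws from its own named substream, so adding a stage
#' never perturbs another stage's random numbers.
#'
#' @param root integer root seed.
#' @param name character stream label.
#' @return an integer in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(root, name) {
  stopifnot(length(name) == 1L, nchar(name) > 0L)
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 1000003
  as.integer((abs(as.numeric(root)) %% 2147483647 * 7919 + h * 104729) %% 2147483645 + 1)
}

# internal: stop() with the offending argument named, for config validation
fail_field <- function(field, msg) {
  stop(sprintf("invalid field '%s': %s", field, msg), call. = FALSE)
}
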