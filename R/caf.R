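#' Conditional accuracy function (accuracy per RT quantile bin)
#'
#' Bin edges are RT quantiles (linear interpolation) computed across
#' subjects, pooled within group over both congruency levels so that the
#' congruent and incongruent curves of a group share bins; accuracy is then
#' aggregated per bin x congruency x group. Errors must be retained in the
#' input (accuracy-stream filtering); null responses carry no RT and are
#' ignored.
#'
#' @param trials accuracy-stream filtered trial table with `rt_ms`,
#'   `accuracy`, `congruency`, `group`.
#' @param n_bins number of quantile bins (5 = quintiles).
#' @param pool `"group"` (default: edges pooled over congruencies within
#'   group) or `"group_congruency"` (separate edges per congruency).
#' @return a data.frame (class `"caf_table"`) with `group`, `congruency`,
#'   `quintile`, `accuracy`, `n_trials`, and bin edges in the
#'   `"edges"` attribute.
#' @export
conditional_accuracy <- function(trials, n_bins = 5L,
                                 pool = c("group", "group_congruency")) {
  pool <- match.arg(pool)
  tr <- trials[!is.na(trials$rt_ms) & !is.na(trials$accuracy), , drop = FALSE]
  out <- list(); edges <- list()
  for (g in sort(unique(tr$group))) {
    gt <- tr[tr$group == g, ]
    if (nrow(gt) < n_bins)
      stop(sprintf("group '%s' has fewer trials than bins", g), call. = FALSE)
    for (cond in sort(unique(gt$congruency))) {
      basis <- if (pool == "group") gt else gt[gt$congruency == cond, ]
      if (nrow(basis) < n_bins)
        stop("fewer trials than bins", call. = FALSE)
      e <- quantile(basis$rt_ms, probs = seq(0, 1, length.out = n_bins + 1L),
                    type = 7, names = FALSE)
      e[1L] <- -Inf; e[length(e)] <- Inf   # outermost bins absorb ties/extremes
      ct <- gt[gt$congruency == cond, ]
      bin <- cut(ct$rt_ms, breaks = e, labels = FALSE, include.lowest = TRUE)
      for (b in seq_len(n_bins)) {
        sel <- bin == b
        out[[length(out) + 1L]] <- data.frame(
          group = g, congruency = cond, quintile = b,
          accuracy = if (any(sel)) mean(ct$accuracy[sel]) else NA_real_,
          n_trials = sum(sel), stringsAsFactors = FALSE)
      }
      edges[[paste(g, cond, sep = ".")]] <-
        quantile(basis$rt_ms, probs = seq(0, 1, length.out = n_bins + 1L),
                 type = 7, names = FALSE)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "edges") <- edges
  class(res) <- c("caf_table", class(res))
  res
}
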