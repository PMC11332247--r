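#' Per-subject congruent-minus-incongruent difference scores
#'
#' For boundary shifts: `shift_delta_congruent - shift_delta_incongruent`;
#' for drift rates: `v_congruent - v_incongruent` (DDM) or the analogous
#' columns present in the table. The congruent-minus-incongruent direction
#' is the package convention; negate `score` for the reverse.
#'
#' @param params_table per-subject parameter table (see [fit_table()]) with
#'   a `group` column.
#' @param parameter `"shift_delta"` or `"v"` (column prefix).
#' @return data.frame `subject_id`, `group`, `score`; subjects missing
#'   either column are dropped and listed in the `"dropped"` attribute.
#' @export
shift_difference_scores <- function(params_table,
                                    parameter = c("shift_delta", "v")) {
  parameter <- match.arg(parameter)
  cc <- paste0(parameter, "_congruent")
  ci <- paste0(parameter, "_incongruent")
  if (!all(c(cc, ci) %in% names(params_table)))
    stop(sprintf("columns %s / %s not found", cc, ci), call. = FALSE)
  score <- params_table[[cc]] - params_table[[ci]]
  ok <- !is.na(score)
  structure(
    data.frame(subject_id = params_table$subject_id[ok],
               group = params_table$group[ok],
               score = score[ok], stringsAsFactors = FALSE),
    dropped = params_table$subject_id[!ok])
}

# Brown-Forsythe (median-centred Levene) test for equal variances
levene_test <- function(a, b, center = stats::median) {
  z <- c(abs(a - center(a)), abs(b - center(b)))
  g <- factor(rep(1:2, c(length(a), length(b))))
  n <- length(z); k <- 2L
  zbar <- mean(z); zg <- tapply(z, g, mean)
  num <- (n - k) * sum(table(g) * (zg - zbar)^2)
  den <- (k - 1) * sum((z - zg[g])^2)
  f <- num / den
  list(statistic = f, df = c(k - 1L, n - k),
       p = pf(f, k - 1L, n - k, lower.tail = FALSE))
}

# 95% CI for Cohen's d via the noncentral-t distribution
cohen_d_ci <- function(t, df, n_a, n_b, conf = 0.95) {
  alpha <- (1 - conf) / 2
  mult <- sqrt(1 / n_a + 1 / n_b)
  ncp_limit <- function(target) {
    f <- function(ncp) suppressWarnings(pt(t, df, ncp)) - target
    lohi <- t + c(-1, 1) * (abs(t) + 20)
    tryCatch(uniroot(f, lohi, tol = 1e-8)$root * mult,
             error = function(e) NA_real_)
  }
  c(lower = ncp_limit(1 - alpha), upper = ncp_limit(alpha))
}

make_test_result <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                             variance_rule, welch) {
  diff <- mean_a - mean_b
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
  if (welch) {
    se <- sqrt(sd_a^2 / n_a + sd_b^2 / n_b)
    df <- se^4 / ((sd_a^2 / n_a)^2 / (n_a - 1) + (sd_b^2 / n_b)^2 / (n_b - 1))
  } else {
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  }
  if (se == 0) {
    t <- if (diff == 0) NA_real_ else sign(diff) * Inf
  } else t <- diff / se
  p <- if (is.na(t)) NA_real_ else 2 * pt(-abs(t), df)
  # d uses the pooled SD even when the t is Welch-corrected
  d <- if (sp2 == 0) { if (diff == 0) 0 else sign(diff) * Inf } else diff / sqrt(sp2)
  t_pooled <- if (sp2 == 0) NA_real_ else diff / sqrt(sp2 * (1 / n_a + 1 / n_b))
  d_ci <- if (is.na(t_pooled) || !is.finite(t_pooled)) c(NA_real_, NA_real_)
          else cohen_d_ci(t_pooled, n_a + n_b - 2, n_a, n_b)
  structure(list(t = t, df = df, p = p, d = d, d_ci = d_ci,
                 welch_used = welch, variance_rule = variance_rule,
                 groups = data.frame(group = c("a", "b"),
                                     mean = c(mean_a, mean_b),
                                     sd = c(sd_a, sd_b), n = c(n_a, n_b))),
            class = "sddm_ttest")
}

#' Independent two-sample t-test with effect size
#'
#' Pooled-variance t (df = n_a + n_b - 2) when variances are deemed equal,
#' Welch t with Welch--Satterthwaite df otherwise. The default rule runs a
#' median-centred Levene test at alpha = 0.05; `"pooled"` and `"welch"`
#' force either mode. Cohen's d always uses the pooled SD, with a 95%
#' noncentral-t confidence interval.
#'
#' @param scores_a,scores_b numeric vectors (each n >= 2).
#' @param variance_rule `"levene"`, `"pooled"` or `"welch"`.
#' @return an object of class `"sddm_ttest"`: `t`, `df`, `p`, `d`, `d_ci`,
#'   `welch_used`, and per-group summaries.
#' @export
independent_t <- function(scores_a, scores_b,
                          variance_rule = c("levene", "pooled", "welch")) {
  variance_rule <- match.arg(variance_rule)
  if (length(scores_a) < 2L || length(scores_b) < 2L)
    stop("each group needs at least 2 observations", call. = FALSE)
  welch <- switch(variance_rule,
                  pooled = FALSE, welch = TRUE,
                  levene = levene_test(scores_a, scores_b)$p < 0.05)
  make_test_result(mean(scores_a), sd(scores_a), length(scores_a),
                   mean(scores_b), sd(scores_b), length(scores_b),
                   variance_rule, welch)
}

#' t-test and Cohen's d from printed summary statistics
#'
#' Identical formulas to [independent_t()] but starting from sufficient
#' statistics, for reproducing worked examples from published group
#' summaries (mean, SD, n per group). Levene's test needs raw data, so the
#' rule must be `"pooled"` (default) or `"welch"`.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group summaries.
#' @param variance_rule `"pooled"` or `"welch"`.
#' @return an `"sddm_ttest"` object.
#' @examples
#' # boundary-shift difference scores of the two reward groups:
#' summary_from_stats(11.42, 29.35, 209, 6.11, 27.89, 206)
#' @export
summary_from_stats <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                               variance_rule = c("pooled", "welch")) {
  variance_rule <- match.arg(variance_rule)
  if (n_a < 2 || n_b < 2) stop("each n must be >= 2", call. = FALSE)
  if (sd_a < 0 || sd_b < 0) stop("SDs must be >= 0", call. = FALSE)
  make_test_result(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                   variance_rule, welch = variance_rule == "welch")
}

#' @export
print.sddm_ttest <- function(x, ...) {
  cat(sprintf("t(%s) = %.2f, p = %.3g, Cohen's d = %.2f, 95%% CI [%.2f, %.2f]%s\n",
              format(round(x$df, 2)), x$t, x$p, x$d,
              x$d_ci[1], x$d_ci[2],
              if (x$welch_used) " (Welch)" else ""))
  invisible(x)
}
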