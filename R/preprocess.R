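#' Subject-level exclusions
#'
#' Removes whole subjects that (a) perform at or below the accuracy floor in
#' either task (chance performance), or (b) show signs of inattention,
#' operationalised as a run of at least `inattention_run` consecutive null or
#' premature (< 200 ms) responses. Accuracy per task is computed over trials
#' with a recorded response.
#'
#' @param trials trial-table data.frame.
#' @param accuracy_floor exclusion threshold, in (0, 1); subjects with
#'   accuracy `<=` the floor in either task are dropped.
#' @param inattention_run minimum run length of null/premature responses
#'   that flags a subject as inattentive.
#' @return `list(trials = retained table, report = exclusion report)`; the
#'   report's `subjects_excluded` has one row per dropped subject with a
#'   reason code (`low_accuracy` or `inattentive`).
#' @export
exclude_subjects <- function(trials, accuracy_floor = 0.60,
                             inattention_run = 10L) {
  if (!is.data.frame(trials) || nrow(trials) == 0L)
    stop("empty trial table", call. = FALSE)
  if (!is.numeric(accuracy_floor) || accuracy_floor <= 0 || accuracy_floor >= 1)
    fail_field("accuracy_floor", "must lie in (0, 1)")
  if (all(is.na(trials$accuracy)))
    stop("no subject has defined accuracy", call. = FALSE)

  excluded <- data.frame(subject_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  for (sid in unique(trials$subject_id)) {
    rows <- trials[trials$subject_id == sid, ]
    acc_by_task <- tapply(rows$accuracy, rows$task,
                          function(a) mean(a, na.rm = TRUE))
    if (any(!is.na(acc_by_task) & acc_by_task <= accuracy_floor)) {
      excluded <- rbind(excluded,
                        data.frame(subject_id = sid, reason = "low_accuracy"))
      next
    }
    bad <- is.na(rows$rt_ms) | rows$rt_ms < 200
    runs <- rle(bad)
    if (any(runs$values & runs$lengths >= inattention_run))
      excluded <- rbind(excluded,
                        data.frame(subject_id = sid, reason = "inattentive"))
  }
  keep <- !(trials$subject_id %in% excluded$subject_id)
  list(trials = trials[keep, , drop = FALSE],
       report = list(subjects_excluded = excluded,
                     n_trials_removed = sum(!keep)))
}

#' Trial-level exclusions for the accuracy or RT analysis stream
#'
#' Applies, in order: removal of missing (null) responses and of trials
#' immediately following a null response or an error (both streams); then,
#' for the RT stream only, removal of error trials, of responses faster than
#' `fast_floor_ms`, and of within-subject Tukey-fence outliers (RTs more
#' than 1.5 IQR above the 75th or below the 25th percentile, quartiles by
#' linear interpolation, computed once per subject on the trials surviving
#' the previous steps and not iterated).
#'
#' @param trials trial table after [exclude_subjects()].
#' @param stream `"accuracy"` or `"rt"`.
#' @param fast_floor_ms premature-response floor in ms (RT stream).
#' @param iqr_mult fence multiplier.
#' @return `list(trials = , report = )`; the report counts removed trials by
#'   reason, summing to the difference in row counts.
#' @export
filter_trials <- function(trials, stream = c("accuracy", "rt"),
                          fast_floor_ms = 200, iqr_mult = 1.5) {
  stream <- match.arg(stream)
  if (nrow(trials) == 0L) stop("empty trial table", call. = FALSE)
  # restore presentation order within subject before looking at lagged events
  ord <- order(trials$subject_id, trials$block, trials$trial)
  tr <- trials[ord, , drop = FALSE]

  is_null <- is.na(tr$accuracy)
  prev_same_subj <- c(FALSE, tr$subject_id[-1L] == tr$subject_id[-nrow(tr)])
  prev_null <- prev_same_subj & c(FALSE, is_null[-nrow(tr)])
  prev_error <- prev_same_subj &
    c(FALSE, (!is.na(tr$accuracy) & tr$accuracy == 0)[-nrow(tr)])

  reason <- rep(NA_character_, nrow(tr))
  reason[prev_error] <- "post_error"
  reason[prev_null] <- "post_null"
  reason[is_null] <- "missing"

  if (stream == "rt") {
    err <- is.na(reason) & tr$accuracy == 0
    reason[err] <- "error"
    fast <- is.na(reason) & tr$rt_ms < fast_floor_ms
    reason[fast] <- "fast_rt"
    surv <- is.na(reason)
    for (sid in unique(tr$subject_id)) {
      i <- which(surv & tr$subject_id == sid)
      if (length(i) < 4L) next
      q <- quantile(tr$rt_ms[i], c(0.25, 0.75), type = 7, names = FALSE)
      iqr <- q[2L] - q[1L]
      reason[i[tr$rt_ms[i] > q[2L] + iqr_mult * iqr]] <- "iqr_high"
      reason[i[tr$rt_ms[i] < q[1L] - iqr_mult * iqr]] <- "iqr_low"
    }
  }

  keep <- is.na(reason)
  reasons <- if (stream == "accuracy") c("missing", "post_null", "post_error")
             else c("missing", "post_null", "post_error", "error",
                    "fast_rt", "iqr_high", "iqr_low")
  counts <- vapply(reasons, function(r) sum(reason == r, na.rm = TRUE),
                   integer(1))
  list(trials = tr[keep, , drop = FALSE],
       report = list(stream = stream, trials_removed = as.list(counts),
                     n_in = nrow(tr), n_out = sum(keep)))
}

#' Per-subject congruency effects and group summaries
#'
#' The accuracy congruency effect is accuracy(congruent) minus
#' accuracy(incongruent) on the accuracy-stream table; the RT effect is mean
#' RT(incongruent) minus mean RT(congruent) on the RT-stream table (correct
#' trials only by construction of that stream). Subjects lacking trials in a
#' condition get a missing effect and are listed in the `dropped` attribute.
#'
#' @param acc_trials accuracy-stream filtered trial table.
#' @param rt_trials RT-stream filtered trial table; defaults to
#'   `acc_trials`.
#' @return `list(subjects = per-subject data.frame, groups = group summary
#'   with mean, median and quartiles per effect)`.
#' @export
congruency_effects <- function(acc_trials, rt_trials = acc_trials) {
  eff_one <- function(sid) {
    a <- acc_trials[acc_trials$subject_id == sid, ]
    r <- rt_trials[rt_trials$subject_id == sid, ]
    cond_mean <- function(df, col, cond) {
      v <- df[[col]][df$congruency == cond]
      if (!length(v)) NA_real_ else mean(v, na.rm = TRUE)
    }
    data.frame(
      subject_id = sid,
      group = a$group[1L],
      acc_effect = cond_mean(a, "accuracy", "congruent") -
        cond_mean(a, "accuracy", "incongruent"),
      rt_effect = cond_mean(r, "rt_ms", "incongruent") -
        cond_mean(r, "rt_ms", "congruent"),
      stringsAsFactors = FALSE
    )
  }
  subj <- do.call(rbind, lapply(unique(acc_trials$subject_id), eff_one))
  dropped <- subj$subject_id[is.na(subj$acc_effect) & is.na(subj$rt_effect)]

  summarise <- function(v) {
    v <- v[!is.na(v)]
    c(mean = mean(v), median = median(v),
      q1 = quantile(v, 0.25, type = 7, names = FALSE),
      q3 = quantile(v, 0.75, type = 7, names = FALSE), n = length(v))
  }
  groups <- do.call(rbind, lapply(split(subj, subj$group), function(g)
    data.frame(group = g$group[1L],
               effect = c("acc_effect", "rt_effect"),
               rbind(summarise(g$acc_effect), summarise(g$rt_effect)),
               stringsAsFactors = FALSE)))
  rownames(groups) <- NULL
  structure(list(subjects = subj, groups = groups), dropped = dropped)
}
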