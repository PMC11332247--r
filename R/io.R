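#' Write a trial table to tab-separated text
#'
#' Fixed, documented column order: subject_id, group, block, trial,
#' stimulus_id, task, congruency, transition, scheduled_high_reward, rt_ms,
#' accuracy, reward (plus previously_high_rewarded when present). Missing
#' values are written as empty fields; the logical reward flag as 0/1.
#'
#' @param trials trial-table data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  cols <- intersect(c(trial_columns, "previously_high_rewarded"), names(trials))
  if (!all(trial_columns %in% cols))
    stop("trial table is missing required columns", call. = FALSE)
  out <- trials[, cols]
  for (f in c("scheduled_high_reward", "previously_high_rewarded"))
    if (f %in% cols) out[[f]] <- as.integer(out[[f]])
  write.table(out, path, sep = "\t", quote = FALSE, na = "",
              row.names = FALSE)
  invisible(path)
}

#' Read a trial table written by [write_trials()]
#'
#' @param path input file path.
#' @return a trial-table data.frame with the package's column types.
#' @export
read_trials <- function(path) {
  tr <- read.delim(path, sep = "\t", na.strings = "",
                   stringsAsFactors = FALSE)
  if (!all(trial_columns %in% names(tr)))
    stop("file does not contain a shiftddm trial table", call. = FALSE)
  for (f in c("scheduled_high_reward", "previously_high_rewarded"))
    if (f %in% names(tr)) tr[[f]] <- tr[[f]] == 1L
  tr$accuracy <- as.integer(tr$accuracy)
  tr$rt_ms <- as.numeric(tr$rt_ms)
  tr$reward <- as.numeric(tr$reward)
  tr
}
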