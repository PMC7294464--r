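#' Continuous multichannel recording
#'
#' Carrier for unsegmented EEG: a channels-by-samples matrix in microvolts,
#' a sampling rate, and stimulus events as (sample index, code) pairs.
#'
#' @param montage a [montage].
#' @param data numeric matrix, channels x samples, in uV. Row count must
#'   equal the montage's channel count.
#' @param srate sampling rate in Hz.
#' @param events data.frame with columns `sample` (1-based sample index) and
#'   `code` (character marker), or NULL for none.
#' @return An object of class `"continuous_recording"`.
#' @export
continuous_recording <- function(montage, data, srate, events = NULL) {
  stopifnot(inherits(montage, "montage"))
  data <- as.matrix(data)
  if (nrow(data) != montage$n_channels)
    stop(sprintf("data has %d rows but montage has %d channels",
                 nrow(data), montage$n_channels))
  if (!is.numeric(srate) || length(srate) != 1L || srate <= 0)
    stop("srate must be a positive scalar (Hz)")
  if (is.null(events))
    events <- data.frame(sample = integer(), code = character())
  events <- as.data.frame(events)
  if (!all(c("sample", "code") %in% names(events)))
    stop("events needs columns 'sample' and 'code'")
  if (nrow(events) && (any(events$sample < 1L) ||
                       any(events$sample > ncol(data))))
    stop("event sample indices out of data bounds")
  rownames(data) <- montage$channel_names
  structure(list(montage = montage, data = data, srate = srate,
                 events = events),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %d ch x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$srate,
              ncol(x$data) / x$srate, nrow(x$events)))
  invisible(x)
}

#' Epoched EEG for one subject
#'
#' Single-trial epochs as a trials x channels x samples array in microvolts,
#' with one condition label per trial and a uniform time axis in ms relative
#' to stimulus onset. The epoch window is half-open on the right: at 500 Hz a
#' -200..800 ms epoch holds exactly 500 samples, -200, -198, ..., 798 ms.
#'
#' @param montage a [montage].
#' @param subject_id subject identifier string.
#' @param data numeric array trials x channels x samples (uV); 0 trials
#'   allowed.
#' @param time_ms numeric vector of sample times in ms, strictly increasing
#'   and uniform at 1000/srate.
#' @param condition character vector, one label per trial.
#' @param srate sampling rate in Hz.
#' @return An object of class `"epoch_set"`.
#' @export
epoch_set <- function(montage, subject_id, data, time_ms, condition, srate) {
  stopifnot(inherits(montage, "montage"))
  if (length(dim(data)) != 3L)
    stop("data must be a trials x channels x samples array")
  if (dim(data)[2L] != montage$n_channels)
    stop("channel dimension does not match montage")
  if (dim(data)[3L] != length(time_ms))
    stop("sample dimension does not match time axis")
  if (dim(data)[1L] != length(condition))
    stop("one condition label required per trial")
  if (!is.numeric(srate) || srate <= 0) stop("srate must be positive")
  step <- 1000 / srate
  if (length(time_ms) > 1L) {
    d <- diff(time_ms)
    if (any(d <= 0) || any(abs(d - step) > 1e-6))
      stop(sprintf("time axis must be uniform at %g ms steps", step))
  }
  if (length(data) && !all(is.finite(data)))
    stop("epoch data contains non-finite values")
  structure(list(montage = montage,
                 subject_id = as.character(subject_id)[1L],
                 data = data, time_ms = as.numeric(time_ms),
                 condition = as.character(condition), srate = srate),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  tab <- table(x$condition)
  cat(sprintf("<epoch_set> subject %s: %d trials x %d ch x %d samples, %g..%g ms @ %g Hz\n",
              x$subject_id, dim(x$data)[1L], dim(x$data)[2L], dim(x$data)[3L],
              if (length(x$time_ms)) min(x$time_ms) else NA,
              if (length(x$time_ms)) max(x$time_ms) else NA, x$srate))
  if (length(tab))
    cat("  trials/condition: ",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Subset an epoch_set by trial
#' @param x an [epoch_set]
#' @param trials integer or logical index over trials
#' @return an [epoch_set] with the selected trials
#' @export
subset_trials <- function(x, trials) {
  stopifnot(inherits(x, "epoch_set"))
  epoch_set(x$montage, x$subject_id,
            x$data[trials, , , drop = FALSE], x$time_ms,
            x$condition[trials], x$srate)
}

#' Per-condition ERP averages
#'
#' Trial averages per condition: a named list of channels x samples matrices
#' sharing one time axis, with the number of trials entering each average.
#'
#' @param montage a [montage].
#' @param erps named list of channels x samples matrices (uV), one per
#'   condition.
#' @param n_trials_used named integer vector, trials averaged per condition
#'   (each >= 1).
#' @param time_ms shared time axis in ms.
#' @return An object of class `"erp_set"`.
#' @export
erp_set <- function(montage, erps, n_trials_used, time_ms) {
  stopifnot(inherits(montage, "montage"), is.list(erps))
  if (is.null(names(erps)) || anyDuplicated(names(erps)))
    stop("erps must be a uniquely named list of condition matrices")
  for (nm in names(erps)) {
    m <- erps[[nm]]
    if (!is.matrix(m) || nrow(m) != montage$n_channels ||
        ncol(m) != length(time_ms))
      stop(sprintf("ERP matrix for condition '%s' must be %d x %d",
                   nm, montage$n_channels, length(time_ms)))
  }
  n_trials_used <- n_trials_used[names(erps)]
  if (any(is.na(n_trials_used)) || any(n_trials_used < 1L))
    stop("n_trials_used must be >= 1 for every condition present")
  structure(list(montage = montage, erps = erps,
                 n_trials_used = n_trials_used,
                 time_ms = as.numeric(time_ms)),
            class = "erp_set")
}

#' @export
print.erp_set <- function(x, ...) {
  cat(sprintf("<erp_set> %d conditions x %d ch x %d samples (%g..%g ms)\n",
              length(x$erps), x$montage$n_channels, length(x$time_ms),
              min(x$time_ms), max(x$time_ms)))
  cat("  ", paste(sprintf("%s(n=%d)", names(x$erps), x$n_trials_used),
                  collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Enumerations of the behavioral design ------------------------------------

.lex_levels <- c("w", "n")
.task_levels <- c("global", "local")
.underline_levels <- c("full", "first", "last")
.rt_deadline_ms <- 3000

#' Behavioral trial table
#'
#' Validates a data.frame of lexical-decision trials for the 2 (global
#' lexicality) x 2 (local lexicality) x 2 (task) within-subject design.
#' Columns: `subject`, `global_lex` and `local_lex` in \{w, n\}, `task` in
#' \{global, local\}, `underline_pos` in \{full, first, last\}, `rt_ms`
#' (0 < rt <= 3000, the response deadline; NA allowed for timeouts), and
#' `correct` in \{0, 1\}.
#'
#' @param df a data.frame with the columns above.
#' @return The validated data.frame with class `c("trial_table",
#'   "data.frame")`.
#' @export
trial_table <- function(df) {
  df <- as.data.frame(df)
  needed <- c("subject", "global_lex", "local_lex", "task",
              "underline_pos", "rt_ms", "correct")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop("trial table is missing column(s): ", paste(miss, collapse = ", "))
  bad_row <- function(ok, what) {
    if (!all(ok))
      stop(sprintf("invalid %s in row(s) %s", what,
                   paste(utils::head(which(!ok), 10L), collapse = ", ")))
  }
  df$subject <- as.character(df$subject)
  bad_row(df$global_lex %in% .lex_levels, "global_lex (must be w/n)")
  bad_row(df$local_lex %in% .lex_levels, "local_lex (must be w/n)")
  bad_row(df$task %in% .task_levels, "task (must be global/local)")
  bad_row(df$underline_pos %in% .underline_levels,
          "underline_pos (must be full/first/last)")
  rt <- df$rt_ms
  bad_row(is.na(rt) | rt > 0, "rt_ms (must be positive)")
  if (any(!is.na(rt) & rt > .rt_deadline_ms))
    stop(sprintf(
      "rt_ms exceeds the %d ms response deadline in row(s) %s",
      .rt_deadline_ms,
      paste(utils::head(which(!is.na(rt) & rt > .rt_deadline_ms), 10L),
            collapse = ", ")))
  bad_row(is.na(df$correct) | df$correct %in% c(0, 1), "correct (must be 0/1)")
  class(df) <- c("trial_table", "data.frame")
  df
}

#' Condition label from lexicality factors
#'
#' Builds the usual four-letter condition code, e.g. `"GwLn"` for a
#' global-level word whose two-character constituents are nonwords.
#'
#' @param global_lex,local_lex vectors over \{"w","n"\}
#' @return character vector of labels like "GwLw"
#' @export
condition_label <- function(global_lex, local_lex) {
  paste0("G", global_lex, "L", local_lex)
}
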