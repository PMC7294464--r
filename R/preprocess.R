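# Preprocessing: zero-phase FIR bandpass, epoching with prestimulus baseline
# correction, amplitude-threshold artifact rejection, average reference,
# per-condition ERP averaging and the RMS (quadratic mean across channels)
# waveform.

#' Preprocessing configuration
#'
#' @param low,high bandpass edges in Hz (defaults 0.1 and 30).
#' @param epoch_ms epoch window in ms relative to stimulus onset, half-open
#'   on the right (default -200..800: exactly 500 samples at 500 Hz).
#' @param baseline_ms baseline window in ms, must lie within the epoch
#'   (default -200..0, the prestimulus period).
#' @param threshold_uv artifact rejection threshold in uV (default 50; a
#'   trial is dropped if any in-scope sample exceeds +-threshold).
#' @param reject_channels channel names the threshold applies to, or NULL
#'   for all channels. The rejection rule names the whole epoch, so the
#'   default scope is every channel; restrict to the EOG pair to mimic
#'   blink-only screening.
#' @return An object of class `"preproc_config"`.
#' @export
preproc_config <- function(low = 0.1, high = 30,
                           epoch_ms = c(-200, 800),
                           baseline_ms = c(-200, 0),
                           threshold_uv = 50,
                           reject_channels = NULL) {
  if (!(low < high)) stop("low cutoff must be below high cutoff")
  if (baseline_ms[1L] < epoch_ms[1L] || baseline_ms[2L] > epoch_ms[2L])
    stop("baseline window must lie within the epoch window")
  if (threshold_uv <= 0) stop("rejection threshold must be positive")
  structure(list(low = low, high = high, epoch_ms = epoch_ms,
                 baseline_ms = baseline_ms, threshold_uv = threshold_uv,
                 reject_channels = reject_channels),
            class = "preproc_config")
}

# Hamming-windowed sinc bandpass, built as a cascade of a high-pass and a
# low-pass so each edge gets its own transition bandwidth (common practice:
# 0.25 x cutoff, floored at 2 Hz, but capped so the high-pass transition
# fits between DC and the cutoff — a 0.1 Hz edge needs a ~0.2 Hz transition
# and hence a long kernel, or DC would leak through). Tap counts follow the
# Hamming approximation 3.3 / (df/fs), rounded up to odd for type-I linear
# phase, which centred convolution compensates exactly.
.design_bandpass <- function(low, high, srate) {
  nyq <- srate / 2
  if (high >= nyq) stop("high cutoff must be below the Nyquist frequency")
  if (low <= 0) stop("low cutoff must be positive")
  taps_for <- function(df) {
    n <- ceiling(3.3 * srate / df)
    if (n %% 2L == 0L) n <- n + 1L
    n
  }
  df_low <- min(max(0.25 * low, 2), 2 * low)
  df_high <- min(max(0.25 * high, 2), high / 4)
  hp <- signal::fir1(taps_for(df_low) - 1L, low / nyq, type = "high",
                     window = signal::hamming(taps_for(df_low)))
  lp <- signal::fir1(taps_for(df_high) - 1L, high / nyq, type = "low",
                     window = signal::hamming(taps_for(df_high)))
  # cascade: convolve the two symmetric kernels (still symmetric, odd)
  stats::convolve(hp, rev(lp), type = "open")
}

# zero-phase FIR application: reflect-pad by the group delay, FFT-convolve,
# take the centred segment. b must be odd-length symmetric.
.filtfilt_fir <- function(x, b) {
  n <- length(x)
  L <- (length(b) - 1L) %/% 2L
  if (n <= length(b)) stop("signal shorter than the filter")
  xp <- c(2 * x[1L] - x[(L + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - L)])
  full <- stats::convolve(xp, rev(b), type = "open")
  full[(2L * L + 1L):(2L * L + n)]
}

#' Zero-phase FIR bandpass filter
#'
#' Filters every channel of a continuous recording with a Hamming-windowed
#' sinc FIR bandpass (defaults 0.1-30 Hz) applied with zero phase: the
#' linear-phase filter's group delay is compensated exactly by centred
#' convolution, with reflection padding at the edges.
#'
#' @param x a [continuous_recording].
#' @param cfg a [preproc_config].
#' @return The filtered [continuous_recording].
#' @export
bandpass_fir <- function(x, cfg = preproc_config()) {
  stopifnot(inherits(x, "continuous_recording"))
  b <- .design_bandpass(cfg$low, cfg$high, x$srate)
  out <- t(apply(x$data, 1L, .filtfilt_fir, b = b))
  continuous_recording(x$montage, out, x$srate, x$events)
}

#' Frequency response of the configured bandpass
#'
#' Gain magnitude of the designed filter at given frequencies; useful for
#' verifying passband flatness and stop-band attenuation.
#' @param cfg a [preproc_config]
#' @param srate sampling rate in Hz
#' @param freqs frequencies (Hz) at which to evaluate
#' @return numeric vector of linear gain magnitudes
#' @export
bandpass_response <- function(cfg, srate, freqs) {
  b <- .design_bandpass(cfg$low, cfg$high, srate)
  k <- seq_along(b) - 1L
  vapply(freqs, function(f) {
    Mod(sum(b * exp(-1i * 2 * pi * f * k / srate)))
  }, 0)
}

#' Cut epochs around events and baseline-correct
#'
#' Extracts half-open `[epoch_ms[1], epoch_ms[2])` windows around each
#' event and subtracts, per trial and channel, the mean over the baseline
#' window (prestimulus period). Events too close to the recording edges for
#' a full window are skipped with a message.
#'
#' @param x a [continuous_recording].
#' @param cfg a [preproc_config].
#' @param events optional data.frame (sample, code) overriding `x$events`.
#' @param subject_id label for the resulting [epoch_set].
#' @return An [epoch_set]; condition labels are the event codes.
#' @export
epoch_and_baseline <- function(x, cfg = preproc_config(), events = NULL,
                               subject_id = "sub-01") {
  stopifnot(inherits(x, "continuous_recording"))
  if (is.null(events)) events <- x$events
  if (!nrow(events)) stop("no events to epoch around")
  step <- 1000 / x$srate
  n_pre <- round(-cfg$epoch_ms[1L] / step)
  n_total <- round((cfg$epoch_ms[2L] - cfg$epoch_ms[1L]) / step)
  time_ms <- (seq_len(n_total) - 1L - n_pre) * step
  n_samples <- ncol(x$data)
  first <- events$sample - n_pre
  last <- first + n_total - 1L
  ok <- first >= 1L & last <= n_samples
  if (any(!ok))
    message(sprintf("skipping %d event(s) too close to the recording edge",
                    sum(!ok)))
  if (!any(ok)) stop("no event leaves room for a full epoch window")
  keep <- which(ok)
  dat <- array(0, dim = c(length(keep), nrow(x$data), n_total))
  for (i in seq_along(keep))
    dat[i, , ] <- x$data[, first[keep[i]]:last[keep[i]]]
  e <- epoch_set(x$montage, subject_id, dat, time_ms,
                 events$code[keep], x$srate)
  baseline_correct(e, cfg$baseline_ms)
}

#' Subtract the prestimulus baseline
#'
#' Per trial and channel, subtracts the mean over the half-open baseline
#' window, so that window's mean is exactly zero afterwards.
#' @param e an [epoch_set]
#' @param baseline_ms window `c(from, to)` in ms, half-open on the right
#' @return the corrected [epoch_set]
#' @export
baseline_correct <- function(e, baseline_ms = c(-200, 0)) {
  stopifnot(inherits(e, "epoch_set"))
  sel <- e$time_ms >= baseline_ms[1L] & e$time_ms < baseline_ms[2L]
  if (!any(sel)) stop("baseline window contains no samples")
  bl <- apply(e$data[, , sel, drop = FALSE], c(1L, 2L), mean)
  e$data <- e$data - as.vector(bl)  # recycles over the samples dimension
  e
}

#' Reject trials exceeding the amplitude threshold
#'
#' Drops every trial in which any in-scope channel sample exceeds the
#' threshold in absolute value (default +-50 uV over the whole epoch), and
#' reports a per-trial log with the first offending channel and sample and
#' the fraction dropped.
#'
#' @param e a baseline-corrected [epoch_set].
#' @param cfg a [preproc_config]; `reject_channels` restricts the scope.
#' @return list with `epochs` (kept trials) and `log`, a data.frame with
#'   columns `trial`, `keep`, `channel`, `time_ms` plus attribute
#'   `fraction_dropped`.
#' @export
reject_artifacts <- function(e, cfg = preproc_config()) {
  stopifnot(inherits(e, "epoch_set"))
  ch_idx <- if (is.null(cfg$reject_channels)) seq_len(dim(e$data)[2L])
            else {
              idx <- match(cfg$reject_channels, e$montage$channel_names)
              if (anyNA(idx)) stop("unknown rejection channel(s)")
              idx
            }
  n_trials <- dim(e$data)[1L]
  keep <- logical(n_trials)
  channel <- rep(NA_character_, n_trials)
  t_off <- rep(NA_real_, n_trials)
  for (tr in seq_len(n_trials)) {
    sub <- abs(e$data[tr, ch_idx, , drop = FALSE])
    bad <- which(sub > cfg$threshold_uv, arr.ind = TRUE)
    if (nrow(bad)) {
      channel[tr] <- e$montage$channel_names[ch_idx[bad[1L, 2L]]]
      t_off[tr] <- e$time_ms[bad[1L, 3L]]
    } else keep[tr] <- TRUE
  }
  log <- data.frame(trial = seq_len(n_trials), keep = keep,
                    channel = channel, time_ms = t_off)
  attr(log, "fraction_dropped") <- mean(!keep)
  if (!any(keep))
    warning("all trials rejected at the +-", cfg$threshold_uv,
            " uV threshold")
  list(epochs = subset_trials(e, keep), log = log)
}

#' Re-reference to the average reference
#'
#' Subtracts, at every trial and sample, the instantaneous mean across
#' channels, so the channel mean is zero everywhere. Idempotent.
#'
#' @param e an [epoch_set] with at least two channels.
#' @return The re-referenced [epoch_set].
#' @export
rereference_average <- function(e) {
  stopifnot(inherits(e, "epoch_set"))
  if (dim(e$data)[2L] < 2L)
    stop("average reference needs at least two channels")
  m <- apply(e$data, c(1L, 3L), mean)         # trials x samples
  sweep_arr <- aperm(array(m, dim = c(dim(e$data)[1L], dim(e$data)[3L],
                                      dim(e$data)[2L])), c(1L, 3L, 2L))
  e$data <- e$data - sweep_arr
  e
}

#' Average epochs into per-condition ERPs
#'
#' @param e an [epoch_set].
#' @return An [erp_set] with one channels x samples mean per condition;
#'   conditions without trials are omitted.
#' @export
average_erp <- function(e) {
  stopifnot(inherits(e, "epoch_set"))
  conds <- unique(e$condition)
  if (!length(conds)) stop("epoch set has no trials to average")
  erps <- lapply(conds, function(cn) {
    sel <- e$condition == cn
    apply(e$data[sel, , , drop = FALSE], c(2L, 3L), mean)
  })
  names(erps) <- conds
  n_used <- stats::setNames(vapply(conds, function(cn)
    sum(e$condition == cn), 0L), conds)
  erp_set(e$montage, erps, n_used, e$time_ms)
}

#' RMS waveform across channels
#'
#' The root-mean-square over channels at every time point — a reference-free
#' index of overall response strength: `rms(t) = sqrt(mean_c erp(c,t)^2)`.
#'
#' @param erp an [erp_set].
#' @return matrix, conditions x time, of nonnegative RMS values.
#' @export
erp_rms <- function(erp) {
  stopifnot(inherits(erp, "erp_set"))
  out <- t(vapply(erp$erps, function(m) sqrt(colMeans(m^2)),
                  numeric(length(erp$time_ms))))
  rownames(out) <- names(erp$erps)
  out
}

#' Grand average across subjects
#'
#' Averages per-subject ERPs condition-wise (unweighted across subjects;
#' every subject contributes one mean map regardless of trial counts).
#'
#' @param erp_list list of [erp_set], one per subject, sharing a time axis.
#' @param conditions conditions to average; default those present for every
#'   subject.
#' @return An [erp_set]; `n_trials_used` holds the number of subjects.
#' @export
grand_average <- function(erp_list, conditions = NULL) {
  stopifnot(length(erp_list) >= 1L)
  if (is.null(conditions))
    conditions <- Reduce(intersect, lapply(erp_list, function(e)
      names(e$erps)))
  if (!length(conditions)) stop("no condition shared by all subjects")
  tm <- erp_list[[1L]]$time_ms
  for (e in erp_list)
    if (!isTRUE(all.equal(e$time_ms, tm)))
      stop("subjects do not share a time axis")
  erps <- lapply(conditions, function(cn) {
    Reduce(`+`, lapply(erp_list, function(e) e$erps[[cn]])) /
      length(erp_list)
  })
  names(erps) <- conditions
  n_used <- stats::setNames(rep(length(erp_list), length(conditions)),
                            conditions)
  erp_set(erp_list[[1L]]$montage, erps, n_used, tm)
}

#' Pool conditions into a pseudo-condition, per subject
#'
#' For each subject's [erp_set], averages the member conditions' ERPs into
#' one new condition (used e.g. to form a "three lexical conditions"
#' average, or global/local lexicality pools).
#'
#' @param erp_list list of [erp_set] per subject.
#' @param members condition names to pool.
#' @param name name of the pooled pseudo-condition.
#' @return list of [erp_set] with the pooled condition appended.
#' @export
pool_conditions <- function(erp_list, members, name) {
  lapply(erp_list, function(e) {
    if (!all(members %in% names(e$erps)))
      stop("subject ", e$subject_id %||% "?",
           " is missing a pooled condition")
    pooled <- Reduce(`+`, e$erps[members]) / length(members)
    erps <- c(e$erps, stats::setNames(list(pooled), name))
    n_used <- c(e$n_trials_used,
                stats::setNames(max(1L, min(e$n_trials_used[members])),
                                name))
    erp_set(e$montage, erps, n_used, e$time_ms)
  })
}
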