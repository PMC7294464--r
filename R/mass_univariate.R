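# Electrode-wise amplitude statistics: paired t tests on 20-ms window means
# with Benjamini-Hochberg FDR across the electrode family of each window
# (deliberately no correction across time — liberal by design, to protect
# onset detection from Type II error), pointwise tests at representative
# channels, and onset extraction.

#' Benjamini-Hochberg FDR over one family of p values
#'
#' Step-up FDR control: with ordered p_(1) <= ... <= p_(m), reject all
#' hypotheses up to the largest i with p_(i) <= (i/m) level. Returns the
#' adjusted q values (monotone in p rank) and the rejection mask; the mask
#' equals `q <= level`.
#'
#' @param p_values numeric vector of p values in [0, 1].
#' @param level FDR level (default 0.05).
#' @return list with `q` (adjusted values) and `significant` (logical
#'   mask).
#' @export
fdr_bh <- function(p_values, level = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  q <- stats::p.adjust(p_values, method = "BH")
  list(q = q, significant = !is.na(q) & q <= level)
}

#' Per-window, per-condition electrode means
#'
#' Averages each subject's per-condition ERP within consecutive half-open
#' windows (default 20 ms) tiling the analysis range.
#'
#' @param erp_list list of per-subject [erp_set]s.
#' @param conditions condition names to tabulate; default all shared.
#' @param window_ms window length in ms.
#' @param range_ms analysis range `c(from, to)`; must be tiled by the
#'   window.
#' @return An object of class `"window_means"`: 4-d array `means`
#'   (subject x condition x channel x window), `windows`, `channels`.
#' @export
window_means <- function(erp_list, conditions = NULL, window_ms = 20,
                         range_ms = c(0, 600)) {
  stopifnot(length(erp_list) >= 1L)
  if (is.null(conditions))
    conditions <- Reduce(intersect, lapply(erp_list, function(e)
      names(e$erps)))
  windows <- .tile_windows(range_ms, window_ms)
  n_ch <- erp_list[[1L]]$montage$n_channels
  means <- array(
    0, dim = c(length(erp_list), length(conditions), n_ch, nrow(windows)),
    dimnames = list(NULL, conditions,
                    erp_list[[1L]]$montage$channel_names, NULL))
  for (ci in seq_along(conditions))
    means[, ci, , ] <- .window_mean_array(erp_list, conditions[ci], windows)
  structure(list(means = means, windows = windows,
                 channels = erp_list[[1L]]$montage$channel_names),
            class = "window_means")
}

#' Paired t map over windows and electrodes
#'
#' For every electrode and window, a paired t test across subjects between
#' the two conditions (two-sided p on n-1 degrees of freedom), followed by
#' FDR correction within each window's electrode family — never across
#' windows.
#'
#' @param wm a [window_means()] result.
#' @param cond_a,cond_b condition names present in `wm`.
#' @param level FDR level per window family (default 0.05).
#' @return An object of class `"window_test_result"`: matrices (channels x
#'   windows) `diff_uv`, `t`, `p`, `q`, `significant`; `windows`,
#'   `channels`, `df`, `level`, `degenerate` (cells with zero-variance
#'   nonzero differences).
#' @export
paired_t_map <- function(wm, cond_a, cond_b, level = 0.05) {
  stopifnot(inherits(wm, "window_means"))
  for (cn in c(cond_a, cond_b))
    if (!cn %in% dimnames(wm$means)[[2L]])
      stop("condition '", cn, "' not present in window means")
  n <- dim(wm$means)[1L]
  if (n < 2L) stop("paired t needs at least 2 subjects")
  D <- wm$means[, cond_a, , , drop = FALSE] -
       wm$means[, cond_b, , , drop = FALSE]
  D <- array(D, dim = dim(wm$means)[c(1L, 3L, 4L)])
  mean_d <- apply(D, c(2L, 3L), mean)
  sd_d <- apply(D, c(2L, 3L), stats::sd)
  tstat <- matrix(0, nrow(mean_d), ncol(mean_d))
  pval <- matrix(1, nrow(mean_d), ncol(mean_d))
  degenerate <- sd_d == 0 & mean_d != 0
  ok <- sd_d > 0
  tstat[ok] <- mean_d[ok] / (sd_d[ok] / sqrt(n))
  pval[ok] <- 2 * stats::pt(-abs(tstat[ok]), df = n - 1L)
  tstat[degenerate] <- sign(mean_d[degenerate]) * Inf
  pval[degenerate] <- 0
  # zero-variance all-zero differences keep t = 0, p = 1
  q <- matrix(NA_real_, nrow(pval), ncol(pval))
  sig <- matrix(FALSE, nrow(pval), ncol(pval))
  for (w in seq_len(ncol(pval))) {
    fam <- fdr_bh(pval[, w], level)
    q[, w] <- fam$q
    sig[, w] <- fam$significant
  }
  dimnames(tstat) <- dimnames(pval) <- dimnames(q) <- dimnames(sig) <-
    dimnames(mean_d) <- list(wm$channels, NULL)
  structure(list(diff_uv = mean_d, t = tstat, p = pval, q = q,
                 significant = sig, windows = wm$windows,
                 channels = wm$channels, df = n - 1L, level = level,
                 conditions = c(cond_a, cond_b),
                 degenerate = degenerate),
            class = "window_test_result")
}

#' @export
print.window_test_result <- function(x, ...) {
  cat(sprintf("<window_test_result> %s vs %s: %d electrodes x %d windows, df = %d, FDR level %g per window\n",
              x$conditions[1L], x$conditions[2L], nrow(x$t), ncol(x$t),
              x$df, x$level))
  on <- detect_onset(x)
  if (is.na(on$onset_ms)) cat("  no significant electrode in any window\n")
  else cat(sprintf("  earliest effect: window starting %g ms (%s)\n",
                   on$onset_ms, paste(on$electrodes, collapse = ", ")))
  invisible(x)
}

#' Tidy table of a window test
#' @param res a [window_test_result]
#' @return data.frame: window_start, window_end, electrode, diff, t, p, q,
#'   sig
#' @export
window_test_table <- function(res) {
  stopifnot(inherits(res, "window_test_result"))
  n_w <- nrow(res$windows)
  data.frame(
    window_start = rep(res$windows$start_ms, each = length(res$channels)),
    window_end = rep(res$windows$end_ms, each = length(res$channels)),
    electrode = rep(res$channels, n_w),
    diff = as.vector(res$diff_uv), t = as.vector(res$t),
    p = as.vector(res$p), q = as.vector(res$q),
    sig = as.vector(res$significant))
}

#' Pointwise paired t at representative channels
#'
#' Paired t across subjects at every sample of the named channels, with
#' uncorrected two-sided p; maximal runs of consecutive samples with
#' p < `level` are reported as shaded intervals (the waveform-figure
#' convention).
#'
#' @param erp_list list of per-subject [erp_set]s.
#' @param cond_a,cond_b condition names.
#' @param channels channel names (default the parietal pair P3, P4).
#' @param level uncorrected threshold for shading (default 0.05).
#' @param min_duration_ms drop shaded runs shorter than this (default 0:
#'   every suprathreshold sample is shaded, the waveform-figure convention;
#'   pointwise tests are uncorrected, so isolated one-sample runs are
#'   expected at the false-positive rate even under the null).
#' @return list with `series` (data.frame: channel, time_ms, diff_uv, t,
#'   p) and `intervals` (data.frame: channel, start_ms, end_ms).
#' @export
channel_waveform_test <- function(erp_list, cond_a, cond_b,
                                  channels = c("P3", "P4"), level = 0.05,
                                  min_duration_ms = 0) {
  n <- length(erp_list)
  if (n < 2L) stop("paired test undefined with fewer than 2 subjects")
  mont <- erp_list[[1L]]$montage
  idx <- match(channels, mont$channel_names)
  if (anyNA(idx)) stop("unknown channel(s): ",
                       paste(channels[is.na(idx)], collapse = ", "))
  tm <- erp_list[[1L]]$time_ms
  series <- list(); intervals <- list()
  step <- if (length(tm) > 1L) tm[2L] - tm[1L] else 0
  for (j in seq_along(channels)) {
    D <- t(vapply(erp_list, function(e) {
      e$erps[[cond_a]][idx[j], ] - e$erps[[cond_b]][idx[j], ]
    }, numeric(length(tm))))
    mean_d <- colMeans(D)
    sd_d <- apply(D, 2L, stats::sd)
    tstat <- ifelse(sd_d > 0, mean_d / (sd_d / sqrt(n)), 0)
    pval <- ifelse(sd_d > 0, 2 * stats::pt(-abs(tstat), df = n - 1L), 1)
    series[[j]] <- data.frame(channel = channels[j], time_ms = tm,
                              diff_uv = mean_d, t = tstat, p = pval)
    r <- .runs(pval < level)
    if (nrow(r)) {
      dur <- tm[r$last] + step - tm[r$first]
      r <- r[dur >= min_duration_ms, , drop = FALSE]
    }
    if (nrow(r))
      intervals[[j]] <- data.frame(channel = channels[j],
                                   start_ms = tm[r$first],
                                   end_ms = tm[r$last] + step)
  }
  list(series = do.call(rbind, series),
       intervals = if (length(intervals)) do.call(rbind, intervals)
                   else data.frame(channel = character(),
                                   start_ms = numeric(),
                                   end_ms = numeric()))
}

#' Earliest window with a significant electrode
#'
#' Scans windows in ascending time for the first with at least one
#' FDR-significant electrode — the onset-reading rule for amplitude
#' effects.
#'
#' @param res a [window_test_result].
#' @return list with `onset_ms` (start of the earliest significant window,
#'   NA if none) and `electrodes` (significant channels in that window).
#' @export
detect_onset <- function(res) {
  stopifnot(inherits(res, "window_test_result"))
  any_sig <- colSums(res$significant) > 0
  if (!any(any_sig))
    return(list(onset_ms = NA_real_, electrodes = character()))
  w <- which(any_sig)[1L]
  list(onset_ms = res$windows$start_ms[w],
       electrodes = res$channels[res$significant[, w]])
}
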