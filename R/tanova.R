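# TANOVA: windowed cosine distance between two conditions' group-mean
# topographies, a subject-level label-swap permutation null, and
# cluster-based correction over time (maximal suprathreshold runs, cluster
# mass = summed distance, max-mass null).
#
# The observed statistic is computed on grand means. A label swap within
# subject i replaces (A_i, B_i) by (B_i, A_i); writing D_i = A_i - B_i and
# M = (mean A + mean B)/2, every permutation's pair of grand means is
# M +- (mean_i s_i D_i)/2 with signs s_i. All shuffle statistics are
# therefore computed from sign-weighted means of the subject difference
# maps, which makes thousands of shuffles cheap.

#' Cosine distance between two topographies
#'
#' `d = 1 - (u . v) / (|u| |v|)`, in [0, 2]: 0 for identical patterns, 1
#' for orthogonal ones, 2 for exactly opposite maps. Scale-invariant (the
#' normalization removes response magnitude) and symmetric.
#'
#' @param u,v numeric vectors of equal length >= 2, not all-zero.
#' @return the cosine distance, a scalar in [0, 2].
#' @examples
#' cosine_distance(c(1, 2, 3), c(2, 4, 6))   # 0: same pattern, scaled
#' cosine_distance(c(1, 0), c(0, 1))         # 1: orthogonal
#' cosine_distance(c(1, -2), c(-1, 2))       # 2: opposite
#' @export
cosine_distance <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  if (length(u) < 2L) stop("topography vectors need at least 2 channels")
  ssu <- sum(u * u); ssv <- sum(v * v)
  if (ssu == 0 || ssv == 0)
    stop("cosine distance is undefined for an all-zero topography")
  # normalizing by sqrt(ssu * ssv) (not norm * norm) makes d(u, u) exactly 0
  # and d(u, -u) exactly 2 in floating point
  d <- 1 - sum(u * v) / sqrt(ssu * ssv)
  min(max(d, 0), 2)  # clamp floating-point spill inside the range
}

#' TANOVA configuration
#'
#' @param window_ms analysis window length in ms (default 10); must tile
#'   the analysis range.
#' @param n_shuffles permutation count (default 1000).
#' @param precluster_p threshold forming temporal clusters (default 0.1).
#' @param alpha corrected cluster-level threshold (default 0.05).
#' @param seed integer seed for the shuffle sequence.
#' @return An object of class `"tanova_config"`.
#' @export
tanova_config <- function(window_ms = 10, n_shuffles = 1000,
                          precluster_p = 0.1, alpha = 0.05, seed = 1L) {
  if (n_shuffles < 1L) stop("n_shuffles must be >= 1")
  if (precluster_p <= 0 || precluster_p >= 1)
    stop("precluster_p must be in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (window_ms <= 0) stop("window_ms must be positive")
  structure(list(window_ms = window_ms, n_shuffles = as.integer(n_shuffles),
                 precluster_p = precluster_p, alpha = alpha,
                 seed = as.integer(seed)),
            class = "tanova_config")
}

.tile_windows <- function(range_ms, window_ms) {
  span <- range_ms[2L] - range_ms[1L]
  if (span <= 0) stop("empty analysis range")
  if (abs(span / window_ms - round(span / window_ms)) > 1e-9)
    stop(sprintf("window of %g ms does not tile the %g..%g ms range",
                 window_ms, range_ms[1L], range_ms[2L]))
  starts <- seq(range_ms[1L], range_ms[2L] - window_ms, by = window_ms)
  data.frame(start_ms = starts, end_ms = starts + window_ms)
}

# subjects x channels x windows array of half-open window means for one
# condition
.window_mean_array <- function(erp_list, cond, windows) {
  tm <- erp_list[[1L]]$time_ms
  n_ch <- erp_list[[1L]]$montage$n_channels
  sel <- lapply(seq_len(nrow(windows)), function(w) {
    s <- which(tm >= windows$start_ms[w] & tm < windows$end_ms[w])
    if (!length(s)) stop("analysis window contains no samples")
    s
  })
  out <- array(0, dim = c(length(erp_list), n_ch, nrow(windows)))
  for (i in seq_along(erp_list)) {
    m <- erp_list[[i]]$erps[[cond]]
    if (is.null(m))
      stop("subject ", i, " is missing condition '", cond, "'")
    for (w in seq_len(nrow(windows)))
      out[i, , w] <- rowMeans(m[, sel[[w]], drop = FALSE])
  }
  out
}

# Engine shared by tanova_window / tanova_series: observed distances plus
# the full matrix of shuffle distances (n_shuffles x n_windows), computed
# from one common sign sequence across windows so cluster correction can
# reuse the permutations.
.tanova_engine <- function(erp_list, cond_a, cond_b, windows, cfg) {
  n_subj <- length(erp_list)
  if (n_subj < 2L) stop("TANOVA needs at least 2 subjects")
  A <- .window_mean_array(erp_list, cond_a, windows)
  B <- .window_mean_array(erp_list, cond_b, windows)
  n_ch <- dim(A)[2L]; n_w <- dim(A)[3L]
  Abar <- apply(A, c(2L, 3L), mean)
  Bbar <- apply(B, c(2L, 3L), mean)
  M <- (Abar + Bbar) / 2

  d_from_delta <- function(delta) {
    # delta: channels x windows matrix of (signed mean difference) maps
    mm <- colSums(M^2)
    dd <- colSums(delta^2)
    md <- colSums(M * delta)
    num <- mm - dd / 4
    den <- sqrt(pmax(mm + md + dd / 4, 0) * pmax(mm - md + dd / 4, 0))
    d <- ifelse(den < 1e-24, 0, 1 - num / den)
    pmin(pmax(d, 0), 2)
  }
  d_obs <- d_from_delta(Abar - Bbar)

  # flatten subject difference maps for the sign-weighted means
  Dflat <- matrix(aperm(A - B, c(1L, 2L, 3L)), nrow = n_subj)  # subj x (ch*w)
  signs <- with_seed(cfg$seed,
    matrix(sample(c(-1, 1), cfg$n_shuffles * n_subj, replace = TRUE),
           cfg$n_shuffles, n_subj))
  Delta_flat <- (signs %*% Dflat) / n_subj  # shuffles x (ch*w)
  d_null <- matrix(0, cfg$n_shuffles, n_w)
  for (k in seq_len(cfg$n_shuffles))
    d_null[k, ] <- d_from_delta(matrix(Delta_flat[k, ], n_ch, n_w))

  # add-one p: rank of the observed distance within {observed, shuffles}.
  # Shuffles that reproduce the observed labelling give d* = d_obs up to
  # float rounding; the tolerance keeps those ties counted as ties.
  p <- vapply(seq_len(n_w), function(w)
    (sum(d_null[, w] >= d_obs[w] - 1e-9) + 1) / (cfg$n_shuffles + 1), 0)
  list(d_obs = d_obs, p = p, d_null = d_null, n_subjects = n_subj)
}

#' TANOVA in a single window
#'
#' Cosine distance between the two conditions' grand-mean topographies
#' (averaged over subjects and over the window's samples), with a
#' permutation p from within-subject condition-label swaps: each shuffle
#' flips each subject's pair with a fair coin and recomputes the distance;
#' `p = (#\{d* >= d_obs\} + 1) / (m + 1)`.
#'
#' @param erp_list list of per-subject [erp_set]s, each holding both
#'   conditions.
#' @param cond_a,cond_b condition names.
#' @param window `c(start, end)` ms, half-open.
#' @param cfg a [tanova_config].
#' @return list with `d_obs`, `p`, `n_subjects`.
#' @export
tanova_window <- function(erp_list, cond_a, cond_b, window,
                          cfg = tanova_config()) {
  windows <- data.frame(start_ms = window[1L], end_ms = window[2L])
  eng <- .tanova_engine(erp_list, cond_a, cond_b, windows, cfg)
  list(d_obs = eng$d_obs[1L], p = eng$p[1L], n_subjects = eng$n_subjects)
}

#' Windowed TANOVA series
#'
#' Tiles the analysis range with consecutive windows (default 10 ms) and
#' computes the observed distance and permutation p in each, using one
#' common shuffle sequence across windows so that [cluster_correct()] can
#' reuse the permutations.
#'
#' @param erp_list list of per-subject [erp_set]s.
#' @param cond_a,cond_b condition names.
#' @param range_ms analysis range `c(from, to)` ms, tiled by the window.
#' @param cfg a [tanova_config].
#' @return An object of class `"tanova_result"`: `windows` (data.frame
#'   start_ms, end_ms, d_obs, p), `clusters` (empty until corrected),
#'   `d_null` (shuffles x windows), `cfg`, `conditions`.
#' @export
tanova_series <- function(erp_list, cond_a, cond_b, range_ms = c(0, 600),
                          cfg = tanova_config()) {
  windows <- .tile_windows(range_ms, cfg$window_ms)
  eng <- .tanova_engine(erp_list, cond_a, cond_b, windows, cfg)
  windows$d_obs <- eng$d_obs
  windows$p <- eng$p
  structure(list(windows = windows,
                 clusters = NULL,
                 d_null = eng$d_null,
                 cfg = cfg,
                 conditions = c(cond_a, cond_b),
                 n_subjects = eng$n_subjects),
            class = "tanova_result")
}

# maximal runs of TRUE; returns data.frame(first, last) of indices
.runs <- function(flag) {
  if (!any(flag)) return(data.frame(first = integer(), last = integer()))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(first = starts[r$values], last = ends[r$values])
}

#' Cluster-based temporal correction of a TANOVA series
#'
#' Forms temporal clusters as maximal runs of contiguous windows with
#' uncorrected p below the precluster threshold; each cluster's mass is the
#' sum of observed distances over its windows. The null distribution is the
#' maximal cluster mass per shuffle, where each shuffle's window-wise p is
#' its statistic's rank within the pooled ensemble (observed + all
#' shuffles) and clusters are formed by the same rule. Corrected
#' `p = (#\{max-mass* >= mass\} + 1) / (m + 1)`; a cluster is significant
#' when corrected p <= alpha.
#'
#' @param series a [tanova_series()] result carrying its shuffle
#'   statistics.
#' @param cfg optional [tanova_config] overriding thresholds (the stored
#'   shuffles are reused).
#' @return The series with `clusters` filled in: data.frame with
#'   `start_ms`, `end_ms`, `mass`, `p`, `significant`, plus attribute
#'   `"null_max_mass"` summarizing the null.
#' @export
cluster_correct <- function(series, cfg = NULL) {
  stopifnot(inherits(series, "tanova_result"))
  if (is.null(series$d_null))
    stop("series lacks stored shuffle statistics; recompute with tanova_series()")
  if (is.null(cfg)) cfg <- series$cfg
  m <- nrow(series$d_null)
  n_w <- nrow(series$windows)

  # per-window p for every ensemble member (row 1 = observed), with the
  # same float-tie tolerance as the engine; p_ens[1, ] reproduces the
  # series' add-one p values
  ens <- rbind(series$windows$d_obs, series$d_null)
  p_ens <- apply(ens, 2L, function(x) {
    srt <- sort(x)
    (length(x) - findInterval(x - 1e-9, srt, left.open = TRUE)) / length(x)
  })

  mass_of <- function(p_row, d_row) {
    runs <- .runs(p_row < cfg$precluster_p)
    if (!nrow(runs)) return(list(runs = runs, mass = numeric()))
    mass <- vapply(seq_len(nrow(runs)), function(i)
      sum(d_row[runs$first[i]:runs$last[i]]), 0)
    list(runs = runs, mass = mass)
  }
  obs <- mass_of(p_ens[1L, ], series$windows$d_obs)
  null_max <- vapply(seq_len(m), function(k) {
    ck <- mass_of(p_ens[k + 1L, ], series$d_null[k, ])
    if (length(ck$mass)) max(ck$mass) else 0
  }, 0)

  if (nrow(obs$runs)) {
    clusters <- data.frame(
      start_ms = series$windows$start_ms[obs$runs$first],
      end_ms = series$windows$end_ms[obs$runs$last],
      mass = obs$mass,
      p = vapply(obs$mass, function(ms)
        (sum(null_max >= ms) + 1) / (m + 1), 0))
    clusters$significant <- clusters$p <= cfg$alpha
  } else {
    clusters <- data.frame(start_ms = numeric(), end_ms = numeric(),
                           mass = numeric(), p = numeric(),
                           significant = logical())
  }
  attr(clusters, "null_max_mass") <- stats::quantile(
    null_max, c(0.5, 0.95, 0.99), names = TRUE)
  series$clusters <- clusters
  series$cfg <- cfg
  series
}

#' Pooled-condition TANOVA comparison
#'
#' Averages the pooled conditions into one pseudo-condition per subject and
#' runs the windowed TANOVA plus cluster correction against the single
#' condition (e.g. one condition vs the average of the three lexical
#' conditions).
#'
#' @param erp_list list of per-subject [erp_set]s.
#' @param single_cond the stand-alone condition.
#' @param pooled_conds conditions averaged into the pseudo-condition; must
#'   not contain `single_cond`.
#' @param range_ms analysis range.
#' @param cfg a [tanova_config].
#' @return A corrected [tanova_series()] result.
#' @export
pooled_comparison <- function(erp_list, single_cond, pooled_conds,
                              range_ms = c(0, 600), cfg = tanova_config()) {
  if (single_cond %in% pooled_conds)
    stop("single_cond must not appear in the pooled set")
  pooled_name <- paste0("pool(", paste(pooled_conds, collapse = "+"), ")")
  pooled <- pool_conditions(erp_list, pooled_conds, pooled_name)
  series <- tanova_series(pooled, single_cond, pooled_name, range_ms, cfg)
  cluster_correct(series)
}

#' Earliest significant TANOVA latency
#' @param series a corrected [tanova_series()] result
#' @return start (ms) of the earliest significant cluster, or NA
#' @export
tanova_onset <- function(series) {
  stopifnot(inherits(series, "tanova_result"))
  cl <- series$clusters
  if (is.null(cl) || !nrow(cl) || !any(cl$significant)) return(NA_real_)
  min(cl$start_ms[cl$significant])
}

#' @export
print.tanova_result <- function(x, ...) {
  w <- x$windows
  cat(sprintf("<tanova_result> %s vs %s: %d windows of %g ms (%g..%g ms), %d subjects, %d shuffles\n",
              x$conditions[1L], x$conditions[2L], nrow(w), x$cfg$window_ms,
              min(w$start_ms), max(w$end_ms), x$n_subjects,
              nrow(x$d_null)))
  cat(sprintf("  min uncorrected p = %.4g at %g ms\n",
              min(w$p), w$start_ms[which.min(w$p)]))
  if (!is.null(x$clusters)) {
    if (nrow(x$clusters)) {
      cat(sprintf("  %d temporal cluster(s); %d significant at alpha = %g\n",
                  nrow(x$clusters), sum(x$clusters$significant),
                  x$cfg$alpha))
      for (i in seq_len(nrow(x$clusters)))
        cat(sprintf("    %g-%g ms: mass %.3f, corrected p = %.4g%s\n",
                    x$clusters$start_ms[i], x$clusters$end_ms[i],
                    x$clusters$mass[i], x$clusters$p[i],
                    if (x$clusters$significant[i]) " *" else ""))
    } else cat("  no window below the precluster threshold\n")
  }
  invisible(x)
}

#' Export a TANOVA result as a tidy table
#' @param series a [tanova_result]
#' @return data.frame: window_start, window_end, d_obs, p, cluster_id,
#'   cluster_p, significant
#' @export
tanova_table <- function(series) {
  stopifnot(inherits(series, "tanova_result"))
  w <- series$windows
  out <- data.frame(window_start = w$start_ms, window_end = w$end_ms,
                    d_obs = w$d_obs, p = w$p,
                    cluster_id = NA_integer_, cluster_p = NA_real_,
                    significant = FALSE)
  cl <- series$clusters
  if (!is.null(cl) && nrow(cl)) {
    for (i in seq_len(nrow(cl))) {
      sel <- w$start_ms >= cl$start_ms[i] & w$end_ms <= cl$end_ms[i]
      out$cluster_id[sel] <- i
      out$cluster_p[sel] <- cl$p[i]
      out$significant[sel] <- cl$significant[i]
    }
  }
  out
}
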