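# Temporal K-means clustering of grand-average topographies. Each
# (condition, time point) is one sample; features are the raw amplitudes of
# all channels. K is selected by the baseline-split rule: grow K until the
# prestimulus samples no longer share a single label, then step back one.

#' Build the topography sample matrix
#'
#' Stacks, for every condition and time point in range, the grand-average
#' topography (one row per sample, one column per channel), with metadata
#' recording each row's condition and time.
#'
#' @param grand_erps an [erp_set] of grand averages.
#' @param time_range `c(from, to)` in ms, half-open on the right; default
#'   the full epoch.
#' @return An object of class `"topo_samples"`: list with `x` (samples x
#'   channels matrix) and `meta` (data.frame: condition, time_ms).
#' @export
build_samples <- function(grand_erps, time_range = NULL) {
  stopifnot(inherits(grand_erps, "erp_set"))
  tm <- grand_erps$time_ms
  if (is.null(time_range)) {
    sel <- rep(TRUE, length(tm))
  } else {
    sel <- tm >= time_range[1L] & tm < time_range[2L]
  }
  if (!any(sel)) stop("empty time range")
  conds <- names(grand_erps$erps)
  x <- do.call(rbind, lapply(conds, function(cn)
    t(grand_erps$erps[[cn]][, sel, drop = FALSE])))
  meta <- data.frame(
    condition = rep(conds, each = sum(sel)),
    time_ms = rep(tm[sel], length(conds)))
  colnames(x) <- grand_erps$montage$channel_names
  structure(list(x = x, meta = meta), class = "topo_samples")
}

#' @export
print.topo_samples <- function(x, ...) {
  cat(sprintf("<topo_samples> %d samples (%d conditions x %d time points) x %d channels\n",
              nrow(x$x), length(unique(x$meta$condition)),
              nrow(x$x) / length(unique(x$meta$condition)), ncol(x$x)))
  invisible(x)
}

# squared Euclidean distances samples x centroids
.sqdist <- function(x, centers) {
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  outer(xx, cc, "+") - 2 * tcrossprod(x, centers)
}

# k-means++ seeding: first centre uniform, then each next centre drawn with
# probability proportional to squared distance to the nearest chosen centre
.kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  if (k > 1L) {
    d2 <- .sqdist(x, centers[1L, , drop = FALSE])[, 1L]
    for (j in 2:k) {
      d2 <- pmax(d2, 0)
      idx <- if (sum(d2) <= 0) sample.int(n, 1L)
             else sample.int(n, 1L, prob = d2)
      centers[j, ] <- x[idx, ]
      d2 <- pmin(d2, .sqdist(x, centers[j, , drop = FALSE])[, 1L])
    }
  }
  centers
}

.lloyd <- function(x, centers, max_iter = 300L) {
  k <- nrow(centers)
  labels <- max.col(-.sqdist(x, centers), ties.method = "first")
  inertia_prev <- Inf
  for (it in seq_len(max_iter)) {
    for (j in seq_len(k)) {
      members <- labels == j
      if (!any(members)) {
        # empty cluster: re-seed from the sample farthest from its centroid
        d2 <- .sqdist(x, centers)
        nearest <- d2[cbind(seq_len(nrow(x)), labels)]
        centers[j, ] <- x[which.max(nearest), ]
      } else {
        centers[j, ] <- colMeans(x[members, , drop = FALSE])
      }
    }
    d2 <- .sqdist(x, centers)
    new_labels <- max.col(-d2, ties.method = "first")
    inertia <- sum(d2[cbind(seq_len(nrow(x)), new_labels)])
    if (inertia > inertia_prev + 1e-8 * max(1, inertia_prev))
      stop("internal error: inertia increased during Lloyd iteration")
    inertia_prev <- inertia
    if (all(new_labels == labels)) {
      labels <- new_labels
      break
    }
    labels <- new_labels
  }
  list(labels = labels, centers = centers, inertia = inertia_prev)
}

#' Fit K-means to topography samples
#'
#' Lloyd's algorithm with k-means++ seeding, best of `restarts` random
#' initializations (lowest within-cluster sum of squares), deterministic
#' under `seed`. An emptied cluster is re-seeded from the sample farthest
#' from its current centroid.
#'
#' @param m a [build_samples()] result.
#' @param k number of clusters, `1 <= k <=` number of samples.
#' @param seed integer seed.
#' @param restarts number of k-means++ restarts (default 50).
#' @param max_iter Lloyd iteration cap per restart.
#' @return An object of class `"cluster_solution"`: `k`, `labels` (1..k per
#'   sample), `centers` (k x channels), `inertia`, `meta`, `seed`,
#'   `restarts`; `baseline_cluster` and `rank` are filled by
#'   [rank_clusters()].
#' @export
kmeans_fit <- function(m, k, seed = 1L, restarts = 50L, max_iter = 300L) {
  stopifnot(inherits(m, "topo_samples"))
  n <- nrow(m$x)
  if (k < 1L || k > n)
    stop(sprintf("k must be between 1 and the number of samples (%d)", n))
  if (k == 1L) {
    centers <- matrix(colMeans(m$x), 1L)
    d2 <- .sqdist(m$x, centers)
    sol <- list(labels = rep(1L, n), centers = centers,
                inertia = sum(d2))
  } else {
    sol <- with_seed(seed, {
      best <- NULL
      for (r in seq_len(restarts)) {
        fit <- .lloyd(m$x, .kmeanspp_init(m$x, k), max_iter)
        if (is.null(best) || fit$inertia < best$inertia) best <- fit
      }
      best
    })
  }
  structure(list(k = k, labels = sol$labels, centers = sol$centers,
                 inertia = sol$inertia, meta = m$meta, seed = seed,
                 restarts = restarts, baseline_cluster = NA_integer_,
                 rank = rep(NA_integer_, k)),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> k = %d, inertia = %.4g, %d samples\n",
              x$k, x$inertia, length(x$labels)))
  if (!is.na(x$baseline_cluster))
    cat(sprintf("  baseline cluster: %d; ranks: %s\n", x$baseline_cluster,
                paste(x$rank, collapse = " ")))
  invisible(x)
}

#' Baseline sample mask
#'
#' Marks the prestimulus samples (time < 0 ms) of every condition — the
#' reference period for the stopping rule and the cluster ranking.
#' @param m a [build_samples()] result
#' @return logical vector over samples
#' @export
baseline_mask <- function(m) {
  stopifnot(inherits(m, "topo_samples"))
  m$meta$time_ms < 0
}

#' Select K by the baseline-split rule
#'
#' Fits K-means at K = 2, 3, ... and stops at the first K whose solution
#' assigns the baseline samples more than one label (the baseline period is
#' assumed to hold one consistent resting pattern, so splitting it signals
#' overfitting). Returns the fit at the last K that kept the baseline
#' whole (`rule = "break_minus_one"`, the default) or at the breaking K
#' itself (`rule = "break"`).
#'
#' @param m a [build_samples()] result.
#' @param mask logical baseline mask; default [baseline_mask()] (all
#'   prestimulus samples, pooled across conditions).
#' @param seed integer seed (shared across the K search).
#' @param k_max search cap (default 12); reaching it without a split
#'   returns the fit at `k_max` with a warning.
#' @param restarts restarts per fit.
#' @param rule which K to return once the baseline splits.
#' @param tolerance fraction of baseline samples allowed outside the modal
#'   label before calling it a split; 0 (the default) makes "single
#'   cluster" strict.
#' @return list with `k_star` and `solution` (ranked via
#'   [rank_clusters()]).
#' @export
select_k <- function(m, mask = baseline_mask(m), seed = 1L, k_max = 12L,
                     restarts = 50L, rule = c("break_minus_one", "break"),
                     tolerance = 0) {
  stopifnot(inherits(m, "topo_samples"))
  rule <- match.arg(rule)
  if (!any(mask)) stop("baseline mask is empty")
  split_frac <- function(sol) {
    bl <- sol$labels[mask]
    1 - max(tabulate(bl, sol$k)) / length(bl)
  }
  prev <- NULL
  for (k in 2:k_max) {
    sol <- kmeans_fit(m, k, seed = seed, restarts = restarts)
    if (split_frac(sol) > tolerance) {
      if (rule == "break") {
        return(list(k_star = k, solution = rank_clusters(sol, mask)))
      }
      if (k == 2L) {
        warning("baseline splits already at K = 2; returning the ",
                "degenerate single-cluster solution")
        one <- kmeans_fit(m, 1L, seed = seed, restarts = 1L)
        return(list(k_star = 1L, solution = rank_clusters(one, mask)))
      }
      return(list(k_star = k - 1L, solution = rank_clusters(prev, mask)))
    }
    prev <- sol
  }
  warning("baseline never split; K search capped at k_max = ", k_max)
  list(k_star = k_max, solution = rank_clusters(prev, mask))
}

#' Rank clusters by distance to the baseline cluster
#'
#' Identifies the baseline cluster as the modal label of the baseline
#' samples and ranks all clusters by ascending Euclidean distance of their
#' centroids to the baseline centroid (baseline cluster gets rank 1; ties
#' broken by lower cluster id).
#'
#' @param sol a [kmeans_fit()] solution.
#' @param mask logical baseline mask over the solution's samples.
#' @return The solution with `baseline_cluster` and `rank` filled in.
#' @export
rank_clusters <- function(sol, mask) {
  stopifnot(inherits(sol, "cluster_solution"))
  if (length(mask) != length(sol$labels))
    stop("mask length does not match sample count")
  bl_labels <- sol$labels[mask]
  if (!length(bl_labels)) stop("baseline mask is empty")
  counts <- tabulate(bl_labels, sol$k)
  base_id <- which.max(counts)  # ties: lowest id, as documented
  d <- sqrt(rowSums((sol$centers -
                       matrix(sol$centers[base_id, ], sol$k,
                              ncol(sol$centers), byrow = TRUE))^2))
  ord <- order(d, seq_len(sol$k))  # tie-break by cluster id
  rank <- integer(sol$k)
  rank[ord] <- seq_len(sol$k)
  sol$baseline_cluster <- base_id
  sol$rank <- rank
  sol
}

#' Tabulate a cluster solution
#'
#' @param sol a ranked [cluster_solution]
#' @return data.frame: condition, time_ms, label, rank
#' @export
cluster_table <- function(sol) {
  stopifnot(inherits(sol, "cluster_solution"))
  data.frame(condition = sol$meta$condition,
             time_ms = sol$meta$time_ms,
             label = sol$labels,
             rank = if (all(is.na(sol$rank))) NA_integer_
                    else sol$rank[sol$labels])
}
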