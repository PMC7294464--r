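# topography sample matrix, K-means, baseline-split K selection, ranking

make_samples <- function(x, condition, time_ms) {
  # wrap a raw matrix as topo_samples via an erp_set round is overkill;
  # construct directly with the same structure build_samples emits
  structure(list(x = x, meta = data.frame(condition = condition,
                                          time_ms = time_ms)),
            class = "topo_samples")
}

test_that("sample matrix stacks conditions x time points with metadata", {
  el <- simulated_erp_list(seed = 2, n_subjects = 2, n_trials = 4)
  g <- grand_average(el)
  s <- build_samples(g)
  expect_equal(nrow(s$x), 5L * 500L)  # 5 conditions x 500 time points
  expect_equal(ncol(s$x), 32L)
  expect_equal(sum(baseline_mask(s)), 5L * 100L)

  s2 <- build_samples(g, c(0, 6))
  expect_equal(nrow(s2$x), 5L * 3L)
  expect_equal(unique(s2$meta$time_ms), c(0, 2, 4))
  expect_error(build_samples(g, c(900, 1000)), "empty time range")
})

test_that("k-means separates distant clouds, matches the assignment oracle,
           and is deterministic", {
  set.seed(10)
  cloud <- function(center, n) sweep(matrix(stats::rnorm(n * 3, sd = 0.1),
                                            n, 3), 2, center, "+")
  x <- rbind(cloud(c(0, 0, 0), 15), cloud(c(10, 0, 0), 15))
  s <- make_samples(x, rep(c("a", "b"), each = 15), seq_len(30))
  fit <- kmeans_fit(s, 2, seed = 3, restarts = 10)
  expect_equal(length(unique(fit$labels[1:15])), 1L)
  expect_equal(length(unique(fit$labels[16:30])), 1L)
  expect_false(fit$labels[1] == fit$labels[16])

  # inertia equals the brute-force best-assignment oracle at the fitted
  # centroids, and equals the sum of squared distances to assigned centers
  d2 <- as.matrix(stats::dist(rbind(x, fit$centers)))^2
  cross <- d2[seq_len(30), 31:32]
  expect_equal(fit$inertia, sum(apply(cross, 1, min)), tolerance = 1e-8)

  # stats::kmeans is an independent cross-check on separable data
  km <- stats::kmeans(x, 2, nstart = 10)
  expect_equal(fit$inertia, km$tot.withinss, tolerance = 1e-6)

  expect_identical(kmeans_fit(s, 3, seed = 9)$labels,
                   kmeans_fit(s, 3, seed = 9)$labels)
  # K = n: every sample its own cluster, zero inertia
  fit_n <- kmeans_fit(s, 30, seed = 1, restarts = 3)
  expect_equal(fit_n$inertia, 0, tolerance = 1e-12)
  expect_equal(sort(unique(fit_n$labels)), 1:30)
  expect_error(kmeans_fit(s, 31), "between 1 and")
})

test_that("inertia of the best restart never exceeds single restarts", {
  set.seed(2)
  x <- matrix(stats::rnorm(60 * 4), 60, 4)
  s <- make_samples(x, rep("a", 60), seq_len(60))
  best <- kmeans_fit(s, 4, seed = 5, restarts = 20)$inertia
  singles <- vapply(1:5, function(sd)
    kmeans_fit(s, 4, seed = sd, restarts = 1)$inertia, 0)
  expect_true(all(best <= singles + 1e-8))
})

test_that("baseline-split rule recovers the planted number of patterns", {
  # planted structure: a large noisy baseline cloud at the origin and two
  # well-separated pattern clouds; the correct K is 3 and the baseline,
  # being the most dispersed cluster, is the first to split at K = 4
  n_ch <- 16
  hits <- 0L
  for (sd_i in 1:20) {
    xs <- with_seed(400 + sd_i, {
      u1 <- stats::rnorm(n_ch); u1 <- u1 / sqrt(sum(u1^2))
      u2 <- stats::rnorm(n_ch); u2 <- u2 / sqrt(sum(u2^2))
      rbind(
        matrix(stats::rnorm(200 * n_ch, sd = 0.5), 200, n_ch),
        matrix(5 * u1, 60, n_ch, byrow = TRUE) +
          matrix(stats::rnorm(60 * n_ch, sd = 0.2), 60, n_ch),
        matrix(5 * u2, 60, n_ch, byrow = TRUE) +
          matrix(stats::rnorm(60 * n_ch, sd = 0.2), 60, n_ch))
    })
    tm <- c(seq(-200, -2, length.out = 200), seq(0, 598, length.out = 120))
    s <- make_samples(xs, rep("c1", 320), tm)
    sel <- select_k(s, seed = 500 + sd_i, restarts = 15)
    if (sel$k_star == 3L) hits <- hits + 1L
  }
  expect_gte(hits, 18L)  # allow rare seeding flukes
})

test_that("degenerate inputs cap the K search or collapse to one cluster", {
  x <- matrix(1, 40, 3)
  s <- make_samples(x, rep("a", 40), c(seq(-20, -1), seq(1, 20)))
  expect_warning(sel <- select_k(s, k_max = 5, restarts = 2, seed = 1),
                 "capped")
  expect_equal(sel$k_star, 5L)

  # baseline made of two distant clouds splits at K = 2 already
  y <- rbind(matrix(0, 10, 2), matrix(10, 10, 2), matrix(c(0, 10), 10, 2,
                                                         byrow = TRUE))
  s2 <- make_samples(y, rep("a", 30), c(seq(-10, -1), seq(-10, -1),
                                        seq(1, 10)))
  expect_warning(sel2 <- select_k(s2, seed = 2, restarts = 5),
                 "splits already")
  expect_equal(sel2$k_star, 1L)
  expect_equal(sel2$solution$k, 1L)
})

test_that("cluster ranking orders centroids by distance to the baseline
           cluster with documented tie-breaks", {
  # hand-planted solution: baseline centroid at origin, others at 1 and 2
  x <- rbind(matrix(0, 10, 2),
             matrix(c(1, 0), 5, 2, byrow = TRUE),
             matrix(c(2, 0), 5, 2, byrow = TRUE))
  s <- make_samples(x, rep("a", 20), c(seq(-10, -1), seq(1, 10)))
  fit <- kmeans_fit(s, 3, seed = 4, restarts = 10)
  ranked <- rank_clusters(fit, baseline_mask(s))
  base <- ranked$baseline_cluster
  expect_equal(ranked$rank[base], 1L)
  d <- sqrt(rowSums((ranked$centers -
                       matrix(ranked$centers[base, ], 3, 2,
                              byrow = TRUE))^2))
  expect_equal(ranked$rank, rank(d, ties.method = "first"))

  # equidistant non-baseline centroids: lower cluster id wins
  sol <- structure(list(k = 3L, labels = c(rep(1L, 4), 2L, 3L),
                        centers = rbind(c(0, 0), c(0, 1), c(1, 0)),
                        inertia = 0,
                        meta = data.frame(condition = "a",
                                          time_ms = c(-4:-1, 1, 2)),
                        seed = 1L, restarts = 1L,
                        baseline_cluster = NA_integer_,
                        rank = rep(NA_integer_, 3)),
                   class = "cluster_solution")
  r2 <- rank_clusters(sol, c(rep(TRUE, 4), FALSE, FALSE))
  expect_equal(r2$baseline_cluster, 1L)
  expect_equal(r2$rank, c(1L, 2L, 3L))
})

test_that("solutions are invariant under sample permutation up to label
           renaming", {
  set.seed(6)
  x <- rbind(matrix(stats::rnorm(20 * 2), 20, 2),
             matrix(stats::rnorm(20 * 2, mean = 8), 20, 2))
  s <- make_samples(x, rep("a", 40), seq_len(40))
  perm <- with_seed(7, sample.int(40))
  sp <- make_samples(x[perm, ], rep("a", 40), seq_len(40)[perm])
  f1 <- kmeans_fit(s, 2, seed = 8, restarts = 10)
  f2 <- kmeans_fit(sp, 2, seed = 9, restarts = 10)
  expect_equal(f1$inertia, f2$inertia, tolerance = 1e-9)
  # partitions agree after undoing the permutation
  agree <- table(f1$labels[perm], f2$labels)
  expect_equal(sum(agree > 0), 2L)
})
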