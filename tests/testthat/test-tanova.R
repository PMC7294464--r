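# cosine distance, permutation p, series, cluster correction, pooling

test_that("cosine distance hits its printed endpoints and properties", {
  v <- c(2, -1, 3, 0.5)
  expect_equal(cosine_distance(v, v), 0)
  expect_equal(cosine_distance(v, -v), 2)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_distance(v, 3 * v), 0)          # scale invariance
  expect_error(cosine_distance(v, rep(0, 4)), "all-zero")
  expect_error(cosine_distance(c(1, 2), c(1, 2, 3)), "equal length")

  # properties over random vectors: symmetry, range, scale invariance
  with_seed(13, for (i in 1:50) {
    u <- stats::rnorm(8); w <- stats::rnorm(8)
    d <- cosine_distance(u, w)
    expect_gte(d, 0); expect_lte(d, 2)
    expect_equal(d, cosine_distance(w, u))
    expect_equal(d, cosine_distance(2.5 * u, 0.3 * w), tolerance = 1e-12)
  })
})

test_that("identical conditions give d = 0 and p = 1 in a window and in a
           series", {
  el <- make_erp_list(5, c("A", "B"), gen = function(s, cn, m, tm) {
    with_seed(100 + s, matrix(stats::rnorm(m$n_channels * length(tm)),
                              m$n_channels, length(tm)))
  })
  w <- tanova_window(el, "A", "B", c(0, 100),
                     tanova_config(window_ms = 100, n_shuffles = 99,
                                   seed = 2))
  expect_equal(w$d_obs, 0)
  expect_equal(w$p, 1)

  s <- tanova_series(el, "A", "B", c(0, 100),
                     tanova_config(n_shuffles = 49, seed = 3))
  expect_equal(nrow(s$windows), 10L)  # 100 ms / 10 ms tiling
  expect_true(all(s$windows$p == 1))
  corr <- cluster_correct(s)
  expect_equal(nrow(corr$clusters), 0L)
})

test_that("Monte-Carlo p agrees with the exhaustive sign-flip oracle at
           n = 6 subjects", {
  el <- make_erp_list(6, c("A", "B"), gen = noise_gen(), seed = 21)
  tm <- el[[1L]]$time_ms
  win <- tm >= 0 & tm < 100
  A <- sapply(el, function(e) rowMeans(e$erps$A[, win]))
  B <- sapply(el, function(e) rowMeans(e$erps$B[, win]))
  D <- A - B
  M <- (rowMeans(A) + rowMeans(B)) / 2
  d_obs <- cosine_distance(rowMeans(A), rowMeans(B))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 6)))
  d_star <- apply(signs, 1, function(s) {
    delta <- (D %*% s) / 6
    cosine_distance(M + delta / 2, M - delta / 2)
  })
  # the identity assignment reproduces d_obs up to float noise; count it as
  # the tie it is, as the permutation convention requires
  p_exhaustive <- mean(d_star >= d_obs - 1e-9)

  w <- tanova_window(el, "A", "B", c(0, 100),
                     tanova_config(window_ms = 100, n_shuffles = 5000,
                                   seed = 31))
  expect_equal(w$d_obs, d_obs, tolerance = 1e-9)
  # within 0.02 of the exhaustive p at m = 5000 (and within 3 SE)
  se <- sqrt(p_exhaustive * (1 - p_exhaustive) / 5000)
  expect_lt(abs(w$p - p_exhaustive), max(0.02, 3 * se))
})

test_that("a strongly planted pattern difference attains the minimum p and
           localizes to its window", {
  u <- with_seed(41, stats::rnorm(8)); u <- u / sqrt(sum(u^2))
  el <- make_erp_list(16, c("A", "B"), time_ms = seq(0, 598, 2),
                      gen = planted_gen(u, 150, 250, amp = 4, sd = 0.3),
                      seed = 42)
  cfg <- tanova_config(n_shuffles = 199, seed = 43)
  w <- tanova_window(el, "A", "B", c(150, 250),
                     tanova_config(window_ms = 100, n_shuffles = 199,
                                   seed = 44))
  expect_equal(w$p, 1 / 200)  # minimum attainable with the add-one rule

  s <- cluster_correct(tanova_series(el, "A", "B", c(0, 600), cfg))
  # the planted 150-250 ms interval is suprathreshold throughout (isolated
  # hot windows elsewhere arise at the precluster rate and stay
  # uncorrected-insignificant)
  planted <- s$windows$start_ms >= 150 & s$windows$start_ms < 250
  expect_true(all(s$windows$p[planted] < cfg$precluster_p))
  sig <- s$clusters[s$clusters$significant, ]
  expect_gte(nrow(sig), 1L)
  expect_true(all(sig$start_ms >= 140 & sig$end_ms <= 260))
  expect_lt(abs(tanova_onset(s) - 150), 10 + 1e-9)  # within one window
})

test_that("uniform null p values and family-wise error control hold under
           exchangeability", {
  # p on the attainable grid is roughly uniform: check mean and tail mass
  ps <- numeric(60)
  for (r in seq_len(60)) {
    el <- make_erp_list(8, c("A", "B"), n_channels = 6,
                        time_ms = seq(0, 18, 2), gen = noise_gen(),
                        seed = 900 + r)
    w <- tanova_window(el, "A", "B", c(0, 20),
                       tanova_config(window_ms = 20, n_shuffles = 99,
                                     seed = 950 + r))
    ps[r] <- w$p
  }
  expect_lt(abs(mean(ps) - 0.5), 0.12)
  expect_lt(abs(mean(ps <= 0.2) - 0.2), 0.15)

  # FWER of the cluster correction on a reduced null ensemble
  any_sig <- logical(60)
  for (r in seq_len(60)) {
    el <- simulate_null_erps(8, montage = tiny_montage(8),
                             time_ms = seq(0, 298, 2), seed = 700 + r)
    s <- cluster_correct(tanova_series(el, "A", "B", c(0, 300),
                                       tanova_config(n_shuffles = 99,
                                                     seed = 750 + r)))
    any_sig[r] <- nrow(s$clusters) > 0 && any(s$clusters$significant)
  }
  # 95% binomial bound around 0.05 at 60 replicates
  expect_lte(mean(any_sig), 0.05 + 1.64 * sqrt(0.05 * 0.95 / 60))
})

test_that("pooled comparison reduces to pairwise for a singleton pool and
           recovers a planted common deviation", {
  u <- with_seed(51, stats::rnorm(8)); u <- u / sqrt(sum(u^2))
  gen <- function(s, cn, m, tm) {
    x <- matrix(stats::rnorm(m$n_channels * length(tm), sd = 0.3),
                m$n_channels, length(tm))
    if (cn %in% c("L1", "L2", "L3")) {
      sel <- tm >= 100 & tm < 200
      x[, sel] <- x[, sel] + 3 * u
    }
    x
  }
  el <- make_erp_list(12, c("N", "L1", "L2", "L3"),
                      time_ms = seq(0, 298, 2), gen = gen, seed = 52)
  cfg <- tanova_config(n_shuffles = 199, seed = 53)

  expect_error(pooled_comparison(el, "N", c("N", "L1"), c(0, 300), cfg),
               "must not appear")

  # singleton pool equals the plain pairwise series
  p1 <- pooled_comparison(el, "N", "L1", c(0, 300), cfg)
  s1 <- cluster_correct(tanova_series(el, "N", "L1", c(0, 300), cfg))
  expect_equal(p1$windows$d_obs, s1$windows$d_obs, tolerance = 1e-12)
  expect_equal(p1$windows$p, s1$windows$p)

  # the common deviation of the three pooled conditions is detected
  p3 <- pooled_comparison(el, "N", c("L1", "L2", "L3"), c(0, 300), cfg)
  expect_true(any(p3$clusters$significant))
  expect_lt(abs(tanova_onset(p3) - 100), 10 + 1e-9)
})

test_that("shuffle statistics are reproducible and cluster correction
           requires them", {
  el <- make_erp_list(6, c("A", "B"), gen = noise_gen(), seed = 61)
  cfg <- tanova_config(n_shuffles = 49, seed = 62)
  s1 <- tanova_series(el, "A", "B", c(0, 100), cfg)
  s2 <- tanova_series(el, "A", "B", c(0, 100), cfg)
  expect_identical(s1$d_null, s2$d_null)
  s1$d_null <- NULL
  expect_error(cluster_correct(s1), "recompute")
  expect_error(tanova_series(el, "A", "B", c(0, 95), cfg),
               "does not tile")
})
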