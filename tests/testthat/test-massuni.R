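# window means, paired t maps, FDR, waveform tests, onset extraction

test_that("window means tile the range and average half-open windows", {
  el <- make_erp_list(3, "A", time_ms = seq(0, 598, 2),
                      gen = function(s, cn, m, tm)
                        matrix(2, m$n_channels, length(tm)))
  wm <- window_means(el, window_ms = 20, range_ms = c(0, 600))
  expect_equal(dim(wm$means), c(3L, 1L, 8L, 30L))  # 600/20 windows
  expect_true(all(wm$means == 2))

  # linear ramp 0..1 over one 20 ms window: sampled mean of 0,2,...,18 ms
  el2 <- make_erp_list(2, "A", time_ms = seq(0, 18, 2),
                       gen = function(s, cn, m, tm)
                         matrix(rep(tm / 20, each = m$n_channels),
                                m$n_channels, length(tm)))
  wm2 <- window_means(el2, window_ms = 20, range_ms = c(0, 20))
  expect_equal(unique(as.vector(wm2$means)), mean(seq(0, 18, 2) / 20))
  expect_equal(unique(as.vector(wm2$means)), 0.45)  # 0.5 - half-sample

  expect_error(window_means(el, window_ms = 20, range_ms = c(0, 590)),
               "does not tile")
})

test_that("paired t matches the closed-form textbook fixture and the
           stats::t.test oracle", {
  # subject window means differing by 1, 2, 3, 4 -> t = mean/(sd/sqrt(4))
  diffs <- c(1, 2, 3, 4)
  el <- make_erp_list(4, c("A", "B"), n_channels = 2,
                      time_ms = seq(0, 18, 2),
                      gen = function(s, cn, m, tm) {
                        base <- matrix(s, m$n_channels, length(tm))
                        if (cn == "A") base + diffs[s] else base
                      })
  wm <- window_means(el, window_ms = 20, range_ms = c(0, 20))
  res <- paired_t_map(wm, "A", "B")
  t_hand <- mean(diffs) / (stats::sd(diffs) / sqrt(4))
  expect_equal(unname(res$t[1, 1]), t_hand, tolerance = 1e-3)
  expect_equal(unname(res$t[1, 1]), 3.873, tolerance = 1e-3)
  tt <- stats::t.test(diffs)
  expect_equal(unname(res$p[1, 1]), tt$p.value, tolerance = 1e-12)
  expect_equal(res$df, 3L)

  # identical conditions: t = 0, p = 1 everywhere
  res0 <- paired_t_map(wm, "A", "A")
  expect_true(all(res0$t == 0) && all(res0$p == 1))
})

test_that("BH step-up matches a brute-force evaluation of its definition", {
  step_up_oracle <- function(p, level) {
    m <- length(p)
    ord <- order(p)
    thresh <- which(p[ord] <= seq_len(m) / m * level)
    sig <- rep(FALSE, m)
    if (length(thresh)) sig[ord[seq_len(max(thresh))]] <- TRUE
    sig
  }
  with_seed(71, for (i in 1:25) {
    p <- stats::runif(32)^sample(c(1, 3), 1)  # mix of flat and skewed
    f <- fdr_bh(p, 0.05)
    expect_identical(f$significant, step_up_oracle(p, 0.05))
    expect_true(all(f$q >= p - 1e-12))
    expect_true(all(diff(f$q[order(p)]) >= -1e-12))  # monotone in p rank
  })

  # printed examples
  p <- c(0.001, seq(0.2, 0.9, length.out = 31))
  f <- fdr_bh(p, 0.05)
  expect_identical(which(f$significant), 1L)
  f2 <- fdr_bh(rep(1, 32))
  expect_true(all(!f2$significant) && all(f2$q == 1))
  f3 <- fdr_bh(rep(0.01, 32))
  expect_true(all(f3$significant))
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("per-window FDR stays at its nominal level under the null", {
  # 300 null families of 32 electrode tests from 10 subjects of pure noise
  fdp <- numeric(300)
  with_seed(81, for (r in seq_len(300)) {
    d <- matrix(stats::rnorm(10 * 32), 10, 32)
    tstat <- colMeans(d) / (apply(d, 2, stats::sd) / sqrt(10))
    p <- 2 * stats::pt(-abs(tstat), df = 9)
    f <- fdr_bh(p, 0.05)
    fdp[r] <- mean(f$significant)  # all discoveries are false here
  })
  expect_lte(mean(fdp > 0), 0.05 + 1.64 * sqrt(0.05 * 0.95 / 300))
})

test_that("planted amplitude shifts drive the smallest p values and the
           detected onset", {
  # paired design: conditions share each subject's noise, so pre-onset
  # differences are truly null and the planted 220 ms onset is the first
  # detectable window (the rule itself applies no correction across time)
  u <- c(rep(1, 5), rep(0, 3))  # shift confined to 5 electrodes
  el <- paired_effect_erp_list(12, u, on = 220, off = 400, amp = 1.5,
                               amp_sd = 0.3, sd = 0.4, seed = 91)
  wm <- window_means(el, window_ms = 20, range_ms = c(0, 600))
  res <- paired_t_map(wm, "A", "B")
  w_in <- which(res$windows$start_ms == 300)
  expect_equal(sort(order(res$p[, w_in])[1:5]), 1:5)

  on <- detect_onset(res)
  expect_false(is.na(on$onset_ms))
  expect_lte(abs(on$onset_ms - 220), 20)  # within one analysis window
  expect_true(all(on$electrodes %in% paste0("ch", 1:5)))

  # no significance anywhere -> onset reported as none
  el0 <- make_erp_list(6, "A", gen = noise_gen(0.5), seed = 92)
  res0 <- paired_t_map(window_means(el0, window_ms = 20,
                                    range_ms = c(0, 100)), "A", "A")
  expect_true(is.na(detect_onset(res0)$onset_ms))
  expect_identical(detect_onset(res0)$electrodes, character())
})

test_that("pointwise channel tests shade planted intervals and refuse
           degenerate input", {
  u <- c(0, 0, 1, 1, 0, 0, 0, 0)  # effect on channels ch3/ch4
  el <- make_erp_list(14, c("A", "B"), time_ms = seq(0, 598, 2),
                      gen = planted_gen(u, 160, 400, amp = 2, sd = 0.4),
                      seed = 95)
  cw <- channel_waveform_test(el, "A", "B", channels = c("ch3", "ch4"),
                              min_duration_ms = 20)
  expect_true(nrow(cw$intervals) >= 1)
  earliest <- min(cw$intervals$start_ms)
  expect_lte(abs(earliest - 160), 10)

  expect_error(channel_waveform_test(el, "A", "B", channels = "nope"),
               "unknown channel")
  expect_error(channel_waveform_test(el[1], "A", "B",
                                     channels = c("ch3", "ch4")),
               "fewer than 2 subjects")

  # identical conditions: nothing shaded
  cw0 <- channel_waveform_test(el, "A", "A", channels = c("ch3", "ch4"),
                               min_duration_ms = 20)
  expect_equal(nrow(cw0$intervals), 0L)
})
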