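# error filtering, RM-ANOVA engine, planned contrasts, position control

make_balanced_table <- function(n_subjects, rt_fun, n_rep = 1,
                                tasks = c("global", "local")) {
  cells <- expand.grid(global_lex = c("w", "n"), local_lex = c("w", "n"),
                       task = tasks, stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      data.frame(subject = sprintf("s%02d", s),
                 global_lex = cells$global_lex[i],
                 local_lex = cells$local_lex[i],
                 task = cells$task[i],
                 underline_pos = if (cells$task[i] == "global") "full"
                                 else rep(c("first", "last"),
                                          length.out = n_rep),
                 rt_ms = rt_fun(s, cells[i, ], seq_len(n_rep)),
                 correct = 1)
    }))
  }))
  trial_table(rows)
}

test_that("error filtering drops incorrect rows and applies the 85% screen", {
  d <- build_design(4, seed = 2)
  d$subject <- "s1"
  d$rt_ms <- 500
  d$correct <- 1
  d$correct[1:2] <- 0
  tt <- trial_table(d[, c("subject", "global_lex", "local_lex", "task",
                          "underline_pos", "rt_ms", "correct")])
  out <- filter_trials(tt)
  expect_equal(nrow(out), nrow(tt) - 2L)
  expect_true(all(out$correct == 1))
  acc <- attr(out, "accuracy")
  expect_equal(acc$accuracy, 14 / 16)
  expect_false(acc$below_85)  # 87.5% passes the screen

  # a subject at 84% gets listed
  d2 <- do.call(rbind, lapply(1:2, function(s) {
    x <- build_design(50, seed = s); x$subject <- paste0("s", s)
    x$rt_ms <- 600; x$correct <- 1
    if (s == 2) x$correct[seq_len(32)] <- 0  # 168/200 = 84%
    x
  }))
  tt2 <- trial_table(d2[, c("subject", "global_lex", "local_lex", "task",
                            "underline_pos", "rt_ms", "correct")])
  acc2 <- attr(filter_trials(tt2), "accuracy")
  expect_equal(acc2$below_85, c(FALSE, TRUE))

  # all-correct table passes through unchanged
  d$correct <- 1
  tt3 <- trial_table(d[, names(tt)])
  expect_equal(nrow(filter_trials(tt3)), nrow(tt3))
})

test_that("flat cell means give F = 0 everywhere and missing cells are
           named", {
  tt <- make_balanced_table(4, function(s, cell, r) 700)
  an <- rm_anova_2x2x2(tt)
  expect_true(all(an$table$F == 0))
  expect_true(all(an$table$p == 1))
  expect_equal(an$table$df1, rep(1L, 7))
  expect_equal(an$table$df2, rep(3L, 7))

  tt2 <- tt[!(tt$subject == "s02" & tt$task == "local" &
                tt$global_lex == "w" & tt$local_lex == "n"), ]
  class(tt2) <- c("trial_table", "data.frame")
  expect_error(rm_anova_2x2x2(tt2), "s02.*global_lex=w.*local_lex=n")
})

test_that("the engine reproduces the independent aov Error-strata oracle to
           1e-9", {
  for (rep_seed in 1:3) {
    tt <- with_seed(300 + rep_seed,
      make_balanced_table(6, function(s, cell, r)
        800 + stats::rnorm(1, sd = 80) + length(r)))
    an <- rm_anova_2x2x2(tt)
    df <- stats::aggregate(rt_ms ~ subject + global_lex + local_lex + task,
                           data = tt, FUN = mean)
    for (v in c("subject", "global_lex", "local_lex", "task"))
      df[[v]] <- factor(df[[v]])
    fit <- stats::aov(
      rt_ms ~ global_lex * local_lex * task +
        Error(subject / (global_lex * local_lex * task)), data = df)
    sm <- summary(fit)
    F_aov <- unlist(lapply(sm[-1], function(st) st[[1]][1, "F value"]))
    p_aov <- unlist(lapply(sm[-1], function(st) st[[1]][1, "Pr(>F)"]))
    expect_equal(unname(an$table$F), unname(F_aov), tolerance = 1e-9)
    expect_equal(unname(an$table$p), unname(p_aov), tolerance = 1e-9)
  }
})

test_that("F equals the squared paired t on marginal means for 2-level
           factors", {
  tt <- with_seed(17, make_balanced_table(8, function(s, cell, r)
    900 + stats::rnorm(1, sd = 60) +
      40 * (cell$task == "local") * (s %% 3)))
  an <- rm_anova_2x2x2(tt)
  # marginal subject means for each factor
  for (fac in c("global_lex", "local_lex", "task")) {
    ag <- stats::aggregate(tt$rt_ms,
                           by = list(subject = tt$subject, f = tt[[fac]]),
                           FUN = mean)
    wide <- split(ag$x, ag$f)
    tstat <- stats::t.test(wide[[1]], wide[[2]], paired = TRUE)$statistic
    Fv <- an$table$F[an$table$effect == fac]
    expect_equal(Fv, unname(tstat)^2, tolerance = 1e-9)
  }
})

test_that("planted effects land on their own factor only", {
  # a pure task effect should not inflate the other effects' F
  hits_other <- 0L
  for (r in 1:30) {
    tt <- with_seed(600 + r, make_balanced_table(10, function(s, cell, r2)
      800 + stats::rnorm(1, sd = 50) + 60 * (cell$task == "local")))
    an <- rm_anova_2x2x2(tt)
    p_task <- an$table$p[an$table$effect == "task"]
    expect_lt(p_task, 0.05)
    others <- an$table$p[an$table$effect != "task"]
    hits_other <- hits_other + sum(others < 0.05)
  }
  # 6 null effects x 30 runs at alpha .05: expect ~9 false positives
  expect_lte(hits_other, 20L)
})

test_that("planned contrasts return closed-form paired t values", {
  # two subjects with planted local-task GnLw-GwLw differences of 50, 60
  tt <- make_balanced_table(2, function(s, cell, r) {
    base <- 700
    if (cell$task == "local" && cell$global_lex == "n" &&
        cell$local_lex == "w") base + c(50, 60)[s] else base
  })
  pc <- planned_contrasts(tt)
  row <- pc[pc$name == "GnLw-GwLw (local task)", ]
  expect_equal(row$mean_diff_ms, 55)
  expect_equal(row$t, 11, tolerance = 1e-9)  # 55 / (7.0711 / sqrt(2))
  expect_equal(row$df, 1L)

  # identical cells: zero difference, t = 0
  flat <- make_balanced_table(3, function(s, cell, r) 700)
  pcf <- planned_contrasts(flat)
  expect_true(all(pcf$mean_diff_ms == 0))
  expect_true(all(pcf$t == 0) && all(pcf$p == 1))

  # generator round-trip: planted 112 ms global-task difference recovered
  tt2 <- simulate_rt(build_design(40, seed = 3), n_subjects = 21, seed = 5)
  pc2 <- planned_contrasts(filter_trials(tt2))
  row2 <- pc2[pc2$name == "GnLw-GnLn (global task)", ]
  se <- 200 * sqrt(2 / 20) / sqrt(21)  # trial sd propagated to the contrast
  expect_lt(abs(row2$mean_diff_ms - 112), 3 * se)
  expect_lt(row2$p, 0.05)
})

test_that("underline-position control reuses the engine and detects planted
           position effects only when present", {
  # null position data: engine runs, position p well away from 0
  tt <- with_seed(21, make_balanced_table(8, function(s, cell, r)
    750 + stats::rnorm(2, sd = 30), n_rep = 2, tasks = "local"))
  an <- underline_position_anova(tt)
  expect_equal(nrow(an$table), 7L)
  expect_true("underline_pos" %in% an$table$effect)

  # planted position effect is detected
  tt2 <- with_seed(22, {
    x <- make_balanced_table(10, function(s, cell, r)
      750 + stats::rnorm(2, sd = 10), n_rep = 2, tasks = "local")
    x$rt_ms <- x$rt_ms + 80 * (x$underline_pos == "last")
    x
  })
  an2 <- underline_position_anova(tt2)
  expect_lt(an2$table$p[an2$table$effect == "underline_pos"], 0.01)

  # a table without local-task rows errors
  tg <- make_balanced_table(3, function(s, cell, r) 700, tasks = "global")
  expect_error(underline_position_anova(tg), "local-task")
})
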