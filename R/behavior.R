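# Reaction-time statistics for the 2 x 2 x 2 within-subject design:
# error-trial filtering with the 85% accuracy screen, a repeated-measures
# ANOVA built from the sums-of-squares definitions (each effect tested
# against its own subject-by-effect interaction), and the planned paired
# contrasts.

#' Remove error trials and screen accuracy
#'
#' Keeps correct responses only. Per-subject accuracy is computed first and
#' subjects below the 85 percent screen are listed (attribute
#' `"accuracy"`); subjects left without any correct trial in one of the
#' 8 design cells are flagged in attribute `"incomplete_subjects"` — the
#' ANOVA refuses such subjects by name.
#'
#' @param t a [trial_table].
#' @return The filtered [trial_table] with attributes `accuracy`
#'   (data.frame: subject, accuracy, below_85) and `incomplete_subjects`.
#' @export
filter_trials <- function(t) {
  stopifnot(inherits(t, "trial_table"))
  acc <- stats::aggregate(correct ~ subject, data = t, FUN = mean)
  names(acc)[2L] <- "accuracy"
  acc$below_85 <- acc$accuracy < 0.85
  out <- t[t$correct == 1, , drop = FALSE]
  cell <- interaction(out$global_lex, out$local_lex, out$task, drop = FALSE)
  tab <- table(out$subject, cell)
  incomplete <- rownames(tab)[apply(tab == 0, 1L, any)]
  class(out) <- c("trial_table", "data.frame")
  attr(out, "accuracy") <- acc
  attr(out, "incomplete_subjects") <- incomplete
  out
}

# subject x cell aggregation into a 4-d array (subject, f1, f2, f3);
# errors name the first missing subject/cell
.cell_array <- function(t, factors, agg = mean) {
  lev <- lapply(factors, function(f) sort(unique(t[[f]])))
  subjects <- sort(unique(t$subject))
  dims <- c(length(subjects), lengths(lev))
  Y <- array(NA_real_, dim = dims,
             dimnames = c(list(subjects), lev))
  for (i in seq_along(subjects)) {
    for (a in seq_along(lev[[1L]])) for (b in seq_along(lev[[2L]]))
      for (cc in seq_along(lev[[3L]])) {
        sel <- t$subject == subjects[i] &
          t[[factors[1L]]] == lev[[1L]][a] &
          t[[factors[2L]]] == lev[[2L]][b] &
          t[[factors[3L]]] == lev[[3L]][cc]
        if (!any(sel))
          stop(sprintf("subject %s has no trials in cell %s=%s, %s=%s, %s=%s",
                       subjects[i], factors[1L], lev[[1L]][a],
                       factors[2L], lev[[2L]][b], factors[3L],
                       lev[[3L]][cc]))
        Y[i, a, b, cc] <- agg(t$rt_ms[sel])
      }
  }
  Y
}

# inclusion-exclusion effect estimates over margins of a balanced array:
# effect(M) = margin mean over M minus the sum of all lower-order effects
# nested in M. margin is a sorted integer subset of dims.
.term_effect <- function(Y, margin, cache) {
  key <- if (length(margin)) paste(margin, collapse = ",") else "grand"
  if (!is.null(cache[[key]])) return(cache[[key]])
  if (!length(margin)) {
    eff <- mean(Y)
  } else {
    eff <- apply(Y, margin, mean)
    if (length(margin) == 1L) eff <- as.array(eff)
    subsets <- list(integer())
    for (d in margin)
      subsets <- c(subsets, lapply(subsets, function(s) c(s, d)))
    subsets <- subsets[lengths(subsets) < length(margin)]
    L <- length(margin)
    for (s in subsets) {
      sub_eff <- .term_effect(Y, s, cache)
      if (!length(s)) {
        eff <- eff - as.numeric(sub_eff)
      } else if (length(s) == 1L) {
        eff <- sweep(eff, match(s, margin), as.numeric(sub_eff), "-")
      } else {
        # broadcast sub_eff (dims = s) across margin's remaining dims
        pos <- match(s, margin)
        src_order <- c(pos, setdiff(seq_len(L), pos))
        expanded <- aperm(array(sub_eff, dim = dim(eff)[src_order]),
                          order(src_order))
        eff <- eff - expanded
      }
    }
  }
  cache[[key]] <- eff
  eff
}

# SS of a term = (number of raw cells averaged into each effect entry) x
# sum of squared effect entries
.term_ss <- function(Y, margin, cache) {
  eff <- .term_effect(Y, margin, cache)
  mult <- prod(dim(Y)[setdiff(seq_along(dim(Y)), margin)])
  mult * sum(eff^2)
}

#' Repeated-measures 2x2x2 ANOVA on reaction times
#'
#' Aggregates RT to subject-by-cell means (or another summary) and tests
#' the three main effects, three two-way interactions and the three-way
#' interaction of the within-subject factors. The engine works from the
#' sums-of-squares definitions: for every effect, SS is the scaled sum of
#' squared inclusion-exclusion effect estimates and the error term is the
#' corresponding subject-by-effect interaction, giving F on (1, n-1)
#' degrees of freedom for 2-level factors.
#'
#' @param t a [trial_table] (error trials already removed; every subject
#'   needs at least one trial in all 8 cells).
#' @param factors the three within-subject factor columns (defaults:
#'   global lexicality, local lexicality, task).
#' @param agg trial aggregation function within subject-cell (default
#'   `mean`; medians are the common alternative).
#' @return An object of class `"rm_anova"`: `table` (data.frame: effect,
#'   df1, df2, ss_effect, ss_error, F, p), `cell_means` (8-cell table),
#'   `n_subjects`.
#' @export
rm_anova_2x2x2 <- function(t, factors = c("global_lex", "local_lex", "task"),
                           agg = mean) {
  stopifnot(inherits(t, "trial_table"))
  if (!all(factors %in% names(t))) stop("unknown factor column(s)")
  Y <- .cell_array(t, factors, agg)
  n <- dim(Y)[1L]
  if (n < 2L) stop("ANOVA needs at least 2 subjects")
  cache <- new.env(parent = emptyenv())
  effects <- unlist(lapply(1:3, function(k)
    utils::combn(2:4, k, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(effects, function(margin) {
    df1 <- prod(dim(Y)[margin] - 1L)
    df2 <- df1 * (n - 1L)
    ss_eff <- .term_ss(Y, margin, cache)
    ss_err <- .term_ss(Y, c(1L, margin), cache)
    # degenerate error strata: no effect and no error means F = 0 (flat
    # data); an effect with zero error is infinitely strong evidence
    Fv <- if (ss_err <= 0) {
      if (ss_eff <= 1e-12 * max(1, sum(Y^2))) 0 else Inf
    } else (ss_eff / df1) / (ss_err / df2)
    data.frame(
      effect = paste(factors[margin - 1L], collapse = ":"),
      df1 = df1, df2 = df2, ss_effect = ss_eff, ss_error = ss_err,
      F = Fv, p = stats::pf(Fv, df1, df2, lower.tail = FALSE))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  cm <- apply(Y, c(2L, 3L, 4L), mean)
  structure(list(table = tab, cell_means = cm, n_subjects = n,
                 factors = factors),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("<rm_anova> %d subjects, within factors: %s\n",
              x$n_subjects, paste(x$factors, collapse = " x ")))
  tab <- x$table
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-35s F(%d,%d) = %7.3f, p = %.4g\n", tab$effect[i],
                tab$df1[i], tab$df2[i], tab$F[i], tab$p[i]))
  invisible(x)
}

#' Default planned contrasts of the design
#'
#' The four planned paired comparisons: in the local task GnLw-GwLw (do
#' global nonwords slow local words?) and GwLn-GnLn (do global words slow
#' local nonwords?); in the global task GwLw-GwLn and GnLw-GnLn.
#' @return data.frame with columns name, task, a_global, a_local,
#'   b_global, b_local
#' @export
default_contrasts <- function() {
  data.frame(
    name = c("GnLw-GwLw (local task)", "GwLn-GnLn (local task)",
             "GwLw-GwLn (global task)", "GnLw-GnLn (global task)"),
    task = c("local", "local", "global", "global"),
    a_global = c("n", "w", "w", "n"), a_local = c("w", "n", "w", "w"),
    b_global = c("w", "n", "w", "n"), b_local = c("w", "n", "n", "n"),
    stringsAsFactors = FALSE)
}

#' Planned paired contrasts on subject cell means
#'
#' For each configured contrast, aggregates RT to subject means of the two
#' cells (within the stated task) and runs a two-sided paired t test.
#'
#' @param t a [trial_table] with error trials removed.
#' @param contrasts data.frame like [default_contrasts()].
#' @param agg aggregation function within subject-cell.
#' @return data.frame of class `"contrast_result"`: name, task,
#'   mean_diff_ms, t, df, p.
#' @export
planned_contrasts <- function(t, contrasts = default_contrasts(),
                              agg = mean) {
  stopifnot(inherits(t, "trial_table"))
  subjects <- sort(unique(t$subject))
  cell_mean <- function(g, l, task) {
    vapply(subjects, function(s) {
      sel <- t$subject == s & t$global_lex == g & t$local_lex == l &
        t$task == task
      if (!any(sel))
        stop(sprintf("subject %s has no trials in cell G%sL%s/%s task",
                     s, g, l, task))
      agg(t$rt_ms[sel])
    }, 0)
  }
  rows <- lapply(seq_len(nrow(contrasts)), function(i) {
    ci <- contrasts[i, ]
    a <- cell_mean(ci$a_global, ci$a_local, ci$task)
    b <- cell_mean(ci$b_global, ci$b_local, ci$task)
    d <- a - b
    if (stats::sd(d) == 0) {
      tt <- list(statistic = c(t = 0), p.value = 1,
                 parameter = c(df = length(d) - 1L))
      if (any(d != 0)) tt$statistic <- c(t = sign(mean(d)) * Inf)
      if (any(d != 0)) tt$p.value <- 0
    } else {
      tt <- stats::t.test(a, b, paired = TRUE)
    }
    data.frame(name = ci$name, task = ci$task, mean_diff_ms = mean(d),
               t = unname(tt$statistic), df = length(d) - 1L,
               p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' Underline-position control ANOVA
#'
#' Restricted to local-task trials (the two-character underlines), replaces
#' the task factor by underline position (first vs last) and reruns the
#' repeated-measures engine — the control analysis for stimulus-position
#' confounds.
#'
#' @param t a [trial_table] with error trials removed.
#' @param agg aggregation function within subject-cell.
#' @return An [rm_anova_2x2x2()] result with factors global_lex,
#'   local_lex, underline_pos.
#' @export
underline_position_anova <- function(t, agg = mean) {
  stopifnot(inherits(t, "trial_table"))
  loc <- t[t$task == "local" & t$underline_pos %in% c("first", "last"), ,
           drop = FALSE]
  if (!nrow(loc)) stop("no local-task trials with first/last underlines")
  class(loc) <- c("trial_table", "data.frame")
  rm_anova_2x2x2(loc, factors = c("global_lex", "local_lex",
                                  "underline_pos"), agg = agg)
}
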