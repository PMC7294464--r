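# Synthetic EEG and reaction-time generator. Emulates the data structure the
# analyses assume — 32 channels at 500 Hz, -200..800 ms epochs, five
# conditions (four string types plus a symbol baseline), blink artifacts
# exceeding the rejection threshold, condition-specific latencies of
# topographic pattern change, and log-normal RTs for the 2x2x2 design — with
# exported ground truth so recovery can be scored exactly.

#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so generators are reproducible without clobbering the
#' session's random stream.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Microstate-style topography template
#'
#' A unit-norm vector over channels representing one quasi-stable scalp
#' pattern. Segments of the synthetic signal are scaled copies of these
#' templates.
#'
#' @param topography numeric vector, one value per channel; normalized to
#'   unit Euclidean norm.
#' @param label template name.
#' @return An object of class `"microstate_template"`.
#' @export
microstate_template <- function(topography, label) {
  topography <- as.numeric(topography)
  nrm <- sqrt(sum(topography^2))
  if (!is.finite(nrm) || nrm == 0) stop("template topography must be nonzero")
  structure(list(topography = topography / nrm, label = as.character(label)),
            class = "microstate_template")
}

#' Draw a random smooth-ish template
#' @param n_channels number of channels
#' @param label template name
#' @return a [microstate_template]
#' @export
random_template <- function(n_channels, label) {
  microstate_template(stats::rnorm(n_channels), label)
}

#' Scenario specification for the EEG generator
#'
#' Bundles everything [simulate_eeg()] needs. Defaults reproduce the study
#' conditions the analyses are designed for: 32 channels at 500 Hz, epochs
#' -200..800 ms, 16 subjects, 80 trials per condition, blinks on the
#' frontopolar channels in 15 percent of trials at 80 uV (above the +-50 uV
#' rejection threshold).
#'
#' @param montage a [montage]; default [actichamp_montage()].
#' @param srate sampling rate in Hz.
#' @param epoch_ms epoch window `c(start, end)` in ms, half-open on the
#'   right.
#' @param templates named list of [microstate_template]s.
#' @param conditions named list; per condition a data.frame with columns
#'   `template`, `onset_ms`, `offset_ms`, `amplitude_uv` (segments may
#'   overlap; they add).
#' @param noise list: `sd_uv` sensor noise standard deviation, `mixing`
#'   spatial mixing factor alpha in (0, 1] (1 = independent channels),
#'   `ar` AR(1) coefficient over time in [0, 1).
#' @param subject_jitter_sd per-subject Gaussian jitter added to each
#'   template (then re-normalized), giving between-subject topography
#'   dispersion.
#' @param blink list: `prob` per-trial blink probability, `amplitude_uv`
#'   peak amplitude (> 50), `channels` affected channel names.
#' @param n_subjects,n_trials counts.
#' @param seed integer seed.
#' @return An object of class `"scenario_spec"`.
#' @export
scenario_spec <- function(montage = actichamp_montage(),
                          srate = 500,
                          epoch_ms = c(-200, 800),
                          templates,
                          conditions,
                          noise = list(sd_uv = 1, mixing = 0.7, ar = 0.3),
                          subject_jitter_sd = 0.05,
                          blink = list(prob = 0.15, amplitude_uv = 80,
                                       channels = montage$eog_channels),
                          n_subjects = 16,
                          n_trials = 80,
                          seed = 1L) {
  stopifnot(inherits(montage, "montage"))
  for (tp in templates) {
    if (!inherits(tp, "microstate_template"))
      stop("templates must be microstate_template objects")
    if (length(tp$topography) != montage$n_channels)
      stop("template dimensionality does not match montage")
    if (abs(sqrt(sum(tp$topography^2)) - 1) > 1e-9)
      stop("template must be unit norm")
  }
  for (cn in names(conditions)) {
    seg <- conditions[[cn]]
    if (nrow(seg)) {
      if (!all(seg$template %in% names(templates)))
        stop("condition '", cn, "' references unknown template")
      if (any(seg$onset_ms < epoch_ms[1L]) || any(seg$offset_ms > epoch_ms[2L]))
        stop("condition '", cn, "' has segments outside the epoch window")
      if (any(seg$offset_ms <= seg$onset_ms))
        stop("segment offsets must exceed onsets")
    }
  }
  if (blink$prob < 0 || blink$prob > 1) stop("blink prob must be in [0,1]")
  if (blink$prob > 0 && blink$amplitude_uv <= 50)
    stop("blink amplitude must exceed the 50 uV rejection threshold")
  if (noise$mixing <= 0 || noise$mixing > 1) stop("mixing must be in (0,1]")
  if (noise$ar < 0 || noise$ar >= 1) stop("ar must be in [0,1)")
  structure(list(montage = montage, srate = srate, epoch_ms = epoch_ms,
                 templates = templates, conditions = conditions,
                 noise = noise, subject_jitter_sd = subject_jitter_sd,
                 blink = blink, n_subjects = n_subjects,
                 n_trials = n_trials, seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Default two-stage chunking scenario
#'
#' A five-condition scenario (GwLw, GwLn, GnLw, GnLn, symbol) whose latent
#' structure mirrors the phenomenology the analyses are meant to resolve:
#' a shared visual pattern from 80 ms in all conditions, a "global
#' lexicality" pattern from `global_onset_ms` in the Gw conditions, a
#' "local lexicality" pattern from `local_onset_ms` in the Lw conditions,
#' and a distinct visual pattern for the symbol baseline. The prestimulus
#' period carries no signal, so baseline topographies are exchangeable
#' noise around the origin.
#'
#' @param seed integer seed used both for template generation and for
#'   [simulate_eeg()].
#' @param global_onset_ms,local_onset_ms onsets (ms) of the two lexicality
#'   patterns; the global pattern leads by default.
#' @param n_subjects,n_trials counts passed through.
#' @param noise_sd_uv sensor noise sd in uV.
#' @param blink_prob per-trial blink probability.
#' @return A [scenario_spec].
#' @export
default_scenario <- function(seed = 1L,
                             global_onset_ms = 160,
                             local_onset_ms = 250,
                             n_subjects = 16,
                             n_trials = 80,
                             noise_sd_uv = 1,
                             blink_prob = 0.15) {
  m <- actichamp_montage()
  tpl <- with_seed(seed + 1000L, list(
    visual = random_template(m$n_channels, "visual"),
    visual_symbol = random_template(m$n_channels, "visual_symbol"),
    global_lex = random_template(m$n_channels, "global_lex"),
    local_lex = random_template(m$n_channels, "local_lex")))
  seg <- function(template, onset, offset, amp)
    data.frame(template = template, onset_ms = onset, offset_ms = offset,
               amplitude_uv = amp)
  vis <- seg("visual", 80, 320, 5)
  glo <- seg("global_lex", global_onset_ms, global_onset_ms + 240, 4)
  loc <- seg("local_lex", local_onset_ms, local_onset_ms + 200, 4)
  conditions <- list(
    GwLw = rbind(vis, glo, loc),
    GwLn = rbind(vis, glo),
    GnLw = rbind(vis, loc),
    GnLn = vis,
    symbol = seg("visual_symbol", 80, 320, 5))
  scenario_spec(montage = m, templates = tpl, conditions = conditions,
                noise = list(sd_uv = noise_sd_uv, mixing = 0.7, ar = 0.3),
                blink = list(prob = blink_prob, amplitude_uv = 80,
                             channels = m$eog_channels),
                n_subjects = n_subjects, n_trials = n_trials, seed = seed)
}

#' Build the behavioral design skeleton
#'
#' Crosses the four stimulus types (GwLw, GwLn, GnLw, GnLn) with the two
#' tasks: within each type, half of the trials are randomly assigned to the
#' global task (full underline) and half to the local task, whose underline
#' position (first or last two characters) is balanced. At the default 80
#' trials per type this yields the design's 320 trials.
#'
#' @param n_per_type trials per stimulus type; must be even so tasks split
#'   evenly.
#' @param seed integer seed for the random task assignment.
#' @return A data.frame skeleton with columns `global_lex`, `local_lex`,
#'   `task`, `underline_pos` (no subject, RT, or accuracy yet).
#' @export
build_design <- function(n_per_type = 80, seed = 1L) {
  if (n_per_type < 1) stop("n_per_type must be >= 1")
  if (n_per_type %% 2L != 0L)
    stop("n_per_type must be even: tasks cannot be split evenly otherwise")
  types <- expand.grid(global_lex = .lex_levels, local_lex = .lex_levels,
                       stringsAsFactors = FALSE)
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(types)), function(i) {
      n <- n_per_type
      task <- rep("local", n)
      task[sample.int(n, n %/% 2L)] <- "global"
      n_loc <- sum(task == "local")
      upos <- rep("full", n)
      loc_pos <- rep(c("first", "last"), length.out = n_loc)
      upos[task == "local"] <- sample(loc_pos)
      data.frame(global_lex = types$global_lex[i],
                 local_lex = types$local_lex[i],
                 task = task, underline_pos = upos,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

# raised-cosine on/off ramps so segment edges are smooth (no FIR ringing)
.segment_envelope <- function(time_ms, onset, offset, ramp_ms = 20) {
  env <- numeric(length(time_ms))
  inside <- time_ms >= onset & time_ms < offset
  env[inside] <- 1
  up <- time_ms >= onset & time_ms < onset + ramp_ms
  env[up] <- 0.5 * (1 - cos(pi * (time_ms[up] - onset) / ramp_ms))
  dn <- time_ms >= offset - ramp_ms & time_ms < offset
  env[dn] <- 0.5 * (1 - cos(pi * (offset - time_ms[dn]) / ramp_ms))
  env
}

# spatially mixed AR(1) noise: white channels x samples noise is mixed by
# M = alpha*I + (1-alpha)*J/n (J all-ones), then filtered over time with an
# AR(1) whose innovations are scaled to keep the marginal sd at sd_uv.
.sim_noise <- function(n_channels, n_samples, sd_uv, mixing, ar) {
  if (sd_uv == 0) return(matrix(0, n_channels, n_samples))
  w <- matrix(stats::rnorm(n_channels * n_samples, sd = sd_uv),
              n_channels, n_samples)
  if (mixing < 1) {
    cm <- colMeans(w)
    w <- mixing * w + (1 - mixing) * matrix(cm, n_channels, n_samples,
                                            byrow = TRUE)
  }
  if (ar > 0) {
    scale <- sqrt(1 - ar^2)
    out <- w
    for (t in 2:n_samples)
      out[, t] <- ar * out[, t - 1L] + scale * w[, t]
    out
  } else w
}

.blink_pulse <- function(time_ms, center_ms, width_ms = 200) {
  inside <- abs(time_ms - center_ms) < width_ms / 2
  p <- numeric(length(time_ms))
  p[inside] <- 0.5 * (1 + cos(2 * pi * (time_ms[inside] - center_ms) / width_ms))
  p
}

#' Simulate epoched EEG for a scenario
#'
#' For each subject and trial the signal is the sum over the condition's
#' segments of `amplitude x (subject-jittered template) x temporal
#' envelope`, plus spatio-temporally correlated noise; blinks are added on
#' the configured frontal channels with the configured probability. The
#' returned ground truth records each condition's template sequence and
#' onsets and each trial's blink flag.
#'
#' @param spec a [scenario_spec].
#' @return A list with elements `epochs` (list of [epoch_set], one per
#'   subject) and `ground_truth`.
#' @export
simulate_eeg <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  m <- spec$montage
  step <- 1000 / spec$srate
  time_ms <- seq(spec$epoch_ms[1L], spec$epoch_ms[2L] - step, by = step)
  n_s <- length(time_ms)
  cond_names <- names(spec$conditions)
  blink_idx <- match(spec$blink$channels, m$channel_names)

  with_seed(spec$seed, {
    # per-subject jittered templates
    subj_templates <- lapply(seq_len(spec$n_subjects), function(s) {
      lapply(spec$templates, function(tp) {
        v <- tp$topography
        if (spec$subject_jitter_sd > 0) {
          v <- v + stats::rnorm(length(v), sd = spec$subject_jitter_sd)
          v <- v / sqrt(sum(v^2))
        }
        v
      })
    })
    epochs <- vector("list", spec$n_subjects)
    blink_flags <- vector("list", spec$n_subjects)
    for (s in seq_len(spec$n_subjects)) {
      n_trials_total <- spec$n_trials * length(cond_names)
      dat <- array(0, dim = c(n_trials_total, m$n_channels, n_s))
      condition <- rep(cond_names, each = spec$n_trials)
      blinks <- logical(n_trials_total)
      # deterministic clean signal per condition for this subject
      clean <- lapply(cond_names, function(cn) {
        seg <- spec$conditions[[cn]]
        sig <- matrix(0, m$n_channels, n_s)
        for (k in seq_len(nrow(seg)))
          sig <- sig + seg$amplitude_uv[k] *
            outer(subj_templates[[s]][[seg$template[k]]],
                  .segment_envelope(time_ms, seg$onset_ms[k],
                                    seg$offset_ms[k]))
        sig
      })
      names(clean) <- cond_names
      for (tr in seq_len(n_trials_total)) {
        x <- clean[[condition[tr]]] +
          .sim_noise(m$n_channels, n_s, spec$noise$sd_uv,
                     spec$noise$mixing, spec$noise$ar)
        if (spec$blink$prob > 0 && stats::runif(1) < spec$blink$prob) {
          blinks[tr] <- TRUE
          # blinks follow the stimulus; keeping them post-onset also keeps
          # their peak clear of the baseline-correction window
          center <- stats::runif(1, max(time_ms[1L] + 100, 50),
                                 time_ms[n_s] - 100)
          x[blink_idx, ] <- x[blink_idx, ] +
            rep(spec$blink$amplitude_uv, length(blink_idx)) %o%
              .blink_pulse(time_ms, center)
        }
        dat[tr, , ] <- x
      }
      epochs[[s]] <- epoch_set(m, sprintf("sub-%02d", s), dat, time_ms,
                               condition, spec$srate)
      blink_flags[[s]] <- blinks
    }
    gt <- list(
      conditions = lapply(spec$conditions, function(seg)
        seg[order(seg$onset_ms), c("template", "onset_ms", "offset_ms"),
            drop = FALSE]),
      blink = blink_flags,
      templates = spec$templates)
    list(epochs = epochs, ground_truth = gt)
  })
}

#' Default RT cell parameters
#'
#' Trial-level log-normal parameters for the 8 design cells (4 conditions x
#' 2 tasks). The paper-motivated structure plants a 55 ms GnLw-GwLw and a
#' 54 ms GwLn-GnLn difference in the local task, a 112 ms GnLw-GnLn
#' difference in the global task, and essentially no GwLw-GwLn difference
#' in the global task, around a ~900 ms base. The trial sd of 200 ms puts
#' planned-contrast t statistics in the mid-single digits at 21 subjects
#' and 40 trials per cell.
#'
#' @param accuracy per-cell response accuracy (recycled).
#' @return data.frame with columns `global_lex`, `local_lex`, `task`,
#'   `mean_ms`, `sd_ms`, `accuracy`.
#' @export
default_rt_cells <- function(accuracy = 0.92) {
  cells <- expand.grid(global_lex = .lex_levels, local_lex = .lex_levels,
                       task = .task_levels, stringsAsFactors = FALSE)
  mean_map <- c(
    # global task: Gn slower; GnLw slowest (local words leak through)
    "w.w.global" = 850, "w.n.global" = 858,
    "n.w.global" = 1012, "n.n.global" = 900,
    # local task: global nonwords slow local words; global words slow
    # local nonwords
    "w.w.local" = 880, "w.n.local" = 954,
    "n.w.local" = 935, "n.n.local" = 900)
  key <- paste(cells$global_lex, cells$local_lex, cells$task, sep = ".")
  cells$mean_ms <- unname(mean_map[key])
  cells$sd_ms <- 200
  cells$accuracy <- rep_len(accuracy, nrow(cells))
  cells
}

.lnorm_params <- function(m, s) {
  sdlog <- sqrt(log(1 + (s / m)^2))
  list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate reaction times over a design skeleton
#'
#' Replicates a [build_design()] skeleton across subjects and draws each
#' trial's RT from a log-normal matched (by moments) to the cell's mean and
#' sd, truncated at the 3000 ms response deadline; correctness is Bernoulli
#' per cell. Optional subject-level heterogeneity: a shared intercept
#' (`subject_sd`) and a subject-by-cell effect (`subject_cell_sd`), both
#' defaulting to zero so that `sd_ms = 0` yields RTs exactly equal to the
#' cell means.
#'
#' @param design data.frame from [build_design()].
#' @param cells data.frame like [default_rt_cells()]: one row per
#'   global_lex x local_lex x task cell with `mean_ms`, `sd_ms`,
#'   `accuracy`.
#' @param n_subjects number of subjects.
#' @param seed integer seed.
#' @param subject_sd sd (ms) of a per-subject additive intercept.
#' @param subject_cell_sd sd (ms) of a per-subject-by-cell additive effect.
#' @return A [trial_table] with ground-truth cell means attached as
#'   attribute `"cells"`.
#' @export
simulate_rt <- function(design, cells = default_rt_cells(), n_subjects = 21,
                        seed = 1L, subject_sd = 0, subject_cell_sd = 0) {
  need <- c("global_lex", "local_lex", "task", "mean_ms", "sd_ms", "accuracy")
  if (!all(need %in% names(cells))) stop("cells lacks required columns")
  key <- function(g, l, t) paste(g, l, t, sep = ".")
  cell_key <- key(cells$global_lex, cells$local_lex, cells$task)
  want <- key(rep(.lex_levels, each = 2), rep(.lex_levels, 2), "global")
  want <- c(want, sub("global", "local", want))
  if (!all(want %in% cell_key)) stop("all 8 design cells must be present")
  if (any(cells$mean_ms >= .rt_deadline_ms))
    stop("cell mean at or above the 3000 ms deadline cannot be simulated")
  with_seed(seed, {
    rows <- vector("list", n_subjects)
    for (s in seq_len(n_subjects)) {
      d <- design
      d$subject <- sprintf("sub-%02d", s)
      dk <- key(d$global_lex, d$local_lex, d$task)
      idx <- match(dk, cell_key)
      mu <- cells$mean_ms[idx]
      if (subject_sd > 0) mu <- mu + stats::rnorm(1, sd = subject_sd)
      if (subject_cell_sd > 0) {
        eff <- stats::rnorm(length(cell_key), sd = subject_cell_sd)
        mu <- mu + eff[idx]
      }
      sd_tr <- cells$sd_ms[idx]
      rt <- numeric(nrow(d))
      zero <- sd_tr == 0
      rt[zero] <- mu[zero]
      if (any(!zero)) {
        pars <- .lnorm_params(mu[!zero], sd_tr[!zero])
        draw <- stats::rlnorm(sum(!zero), pars$meanlog, pars$sdlog)
        # truncate at the deadline by redrawing
        over <- draw > .rt_deadline_ms
        guard <- 0L
        while (any(over) && guard < 100L) {
          draw[over] <- stats::rlnorm(sum(over), pars$meanlog[over],
                                      pars$sdlog[over])
          over <- draw > .rt_deadline_ms
          guard <- guard + 1L
        }
        draw[draw > .rt_deadline_ms] <- .rt_deadline_ms
        rt[!zero] <- draw
      }
      d$rt_ms <- rt
      d$correct <- stats::rbinom(nrow(d), 1L, cells$accuracy[idx])
      rows[[s]] <- d
    }
    out <- do.call(rbind, rows)
    out <- out[, c("subject", "global_lex", "local_lex", "task",
                   "underline_pos", "rt_ms", "correct")]
    tt <- trial_table(out)
    attr(tt, "cells") <- cells
    tt
  })
}

#' Simulate null subject ERPs for calibration studies
#'
#' Draws per-subject, per-condition "ERPs" that are pure spatio-temporally
#' correlated noise from one common distribution — the exchangeable null of
#' the topographic permutation tests. Used for false-positive-rate
#' calibration of the TANOVA cluster correction.
#'
#' @param n_subjects number of subjects.
#' @param montage a [montage].
#' @param time_ms time axis in ms.
#' @param conditions condition names (all generated identically).
#' @param noise list with `sd_uv`, `mixing`, `ar` as in [scenario_spec()].
#' @param seed integer seed.
#' @return list of [erp_set], one per subject.
#' @export
simulate_null_erps <- function(n_subjects, montage = actichamp_montage(),
                               time_ms = seq(0, 598, by = 2),
                               conditions = c("A", "B"),
                               noise = list(sd_uv = 1, mixing = 0.7,
                                            ar = 0.3),
                               seed = 1L) {
  with_seed(seed, {
    lapply(seq_len(n_subjects), function(s) {
      erps <- lapply(conditions, function(cn)
        .sim_noise(montage$n_channels, length(time_ms), noise$sd_uv,
                   noise$mixing, noise$ar))
      names(erps) <- conditions
      n_used <- stats::setNames(rep(1L, length(conditions)), conditions)
      erp_set(montage, erps, n_used, time_ms)
    })
  })
}
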