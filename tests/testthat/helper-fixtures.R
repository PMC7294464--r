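# shared fixture builders; everything is generated in code at test time

tiny_montage <- function(n = 4) montage(paste0("ch", seq_len(n)))

# per-subject erp_set list with arbitrary generator for each condition map
make_erp_list <- function(n_subjects, conditions, n_channels = 8,
                          time_ms = seq(0, 98, by = 2), gen, seed = 1) {
  m <- tiny_montage(n_channels)
  with_seed(seed, lapply(seq_len(n_subjects), function(s) {
    erps <- lapply(conditions, function(cn) gen(s, cn, m, time_ms))
    names(erps) <- conditions
    erp_set(m, erps, stats::setNames(rep(1L, length(conditions)),
                                     conditions), time_ms)
  }))
}

noise_gen <- function(sd = 1) function(s, cn, m, tm)
  matrix(stats::rnorm(m$n_channels * length(tm), sd = sd),
         m$n_channels, length(tm))

# a clean planted-difference scenario: conditions share noise-free baseline,
# cond "A" carries pattern u in [on, off) ms on top of shared background
planted_gen <- function(u, on, off, amp = 3, sd = 0.3) {
  function(s, cn, m, tm) {
    x <- matrix(stats::rnorm(m$n_channels * length(tm), sd = sd),
                m$n_channels, length(tm))
    if (cn == "A") {
      sel <- tm >= on & tm < off
      x[, sel] <- x[, sel] + amp * u
    }
    x
  }
}

# paired-difference fixture: both conditions share each subject's noise, so
# the condition difference is exactly zero outside the planted window and
# amp_s * u inside it (amp_s varies by subject -> honest nonzero-variance t)
paired_effect_erp_list <- function(n_subjects, u, on, off, amp = 2,
                                   amp_sd = 0.3, sd = 0.5,
                                   time_ms = seq(0, 598, 2), seed = 1) {
  n_ch <- length(u)
  m <- tiny_montage(n_ch)
  with_seed(seed, lapply(seq_len(n_subjects), function(s) {
    x <- matrix(stats::rnorm(n_ch * length(time_ms), sd = sd),
                n_ch, length(time_ms))
    a <- x
    sel <- time_ms >= on & time_ms < off
    a[, sel] <- a[, sel] + (amp + stats::rnorm(1, sd = amp_sd)) * u
    erp_set(m, list(A = a, B = x), c(A = 1L, B = 1L), time_ms)
  }))
}

# small preprocessed synthetic study: subject ERPs from the EEG generator
simulated_erp_list <- function(seed = 7, n_subjects = 6, n_trials = 16,
                               noise_sd_uv = 0.8, blink_prob = 0, ...) {
  sc <- default_scenario(seed = seed, n_subjects = n_subjects,
                         n_trials = n_trials, noise_sd_uv = noise_sd_uv,
                         blink_prob = blink_prob, ...)
  sim <- simulate_eeg(sc)
  lapply(sim$epochs, function(e)
    average_erp(rereference_average(baseline_correct(e))))
}
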