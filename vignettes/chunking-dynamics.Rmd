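---
title: "Methods: topographic dynamics, permutation statistics and the synthetic benchmark"
author: "chunkdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topographic dynamics, permutation statistics and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chunkdyn)
```

This vignette is the package's own account of the methods it implements:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic generator does and does not
emulate, and the numerical and design decisions taken where the
methodology left room.

## The analysis problem

The package targets ERP studies of reading in which four-character strings
carry lexical status at two levels — the whole string (*global*) and its
two-character halves (*local*) — yielding conditions `GwLw`, `GwLn`,
`GnLw`, `GnLn` plus a `symbol` visual baseline. The scientific questions
are *when* the scalp topography changes pattern (stages of processing),
*when* two conditions' topographies diverge (onset of a lexicality
effect), and *where and when* amplitudes differ (spatial extent), plus the
behavioral question of how lexical status at each level affects decision
time. Each question gets its own engine; all of them operate on
per-subject, per-condition ERP averages (`erp_set` objects) produced by
the preprocessing chain.

## Preprocessing

The chain is: zero-phase FIR bandpass (continuous data) → epoching
(−200…800 ms, half-open on the right, so exactly 500 samples at 500 Hz) →
baseline correction over −200…0 ms → artifact rejection at ±50 μV →
average reference → per-condition averaging. The order of rejection and
re-referencing is configurable in the sense that each step is an
independent function; the pipeline applies rejection first so that a
blink on a frontopolar channel cannot leak into all channels through the
average reference before it is detected.

*Filter.* A Hamming-windowed sinc FIR, passband 0.1–30 Hz, applied with
zero phase (centred convolution; the kernel is odd-length symmetric so
the group delay is an integer number of samples and is compensated
exactly, with reflection padding at the edges). The two band edges get
separate transition bandwidths, 0.25 × cutoff floored at 2 Hz; for the
0.1 Hz edge this is additionally capped at 2 × cutoff (0.2 Hz), because a
transition wider than the distance to DC cannot be realised — with a
single 2 Hz transition the "high-pass" would pass DC almost unattenuated.
The consequence is an ~8500-tap kernel (~17 s at 500 Hz), which is the
honest cost of a 0.1 Hz cutoff; `bandpass_response()` exposes the
realised gain so tests assert the passband (±5%), the ≥ 20 dB stop-band
attenuation at 45 Hz, and the DC suppression rather than trusting the
design.

*Rejection scope.* The ±50 μV criterion names the whole epoch, so the
default scope is **all** channels; restricting to the EOG pair
(`preproc_config(reject_channels = c("Fp1", "Fp2"))`) mimics blink-only
screening. Manual inspection of "remaining noisy trials" is deliberately
out of scope: it is not reproducible, and the deterministic threshold
rule is the part that can be validated.

*RMS.* The across-channel response-strength index is the quadratic mean
`sqrt(mean(amplitude²))` — occasionally misnamed a "geometric mean" in the
literature; a geometric mean of signed amplitudes is undefined, and the
RMS acronym itself settles what is computed.

## Temporal clustering with the baseline-split rule

Samples are the grand-average topographies of every condition at every
time point, clustered on **raw amplitudes** (no per-sample normalisation
— so both pattern and magnitude structure contribute, matching the
amplitudes-as-features convention). The implementation is Lloyd's
algorithm with k-means++ seeding, 50 restarts by default under a fixed
seed, an inertia-monotonicity assertion each iteration, and empty
clusters re-seeded from the farthest sample. `stats::kmeans` could not be
used directly (no k-means++, errors on empty clusters), but it serves as
an independent cross-check in the test suite.

K selection assumes the prestimulus period holds one consistent resting
pattern: if K-means splits the baseline samples into more than one
cluster, the solution is overfitting, so K grows from 2 and the search
stops at the first K that splits the baseline. Two readings of "stop
when it splits" are possible; the package returns the last K that kept
the baseline whole (`rule = "break_minus_one"`, default) and exposes the
breaking K itself behind `rule = "break"`. "Single cluster" is strict
(100% of baseline samples share a label) by default, with a `tolerance`
argument for a softer criterion. The baseline mask is defined as **all
prestimulus samples pooled across conditions** — on real data,
end-of-epoch samples often join the baseline cluster, but that is an
empirical outcome, not part of the definition.

Two degenerate regimes are handled explicitly and surfaced as warnings:
if the baseline splits already at K = 2 the degenerate single-cluster
solution is returned (K\* = 1), and if it never splits the search stops
at `k_max` (default 12). The second regime is routinely reached on
synthetic grand averages: with independent trial noise, averaging over
16 subjects × 80 trials leaves a baseline cloud orders of magnitude
tighter than real baselines (which keep correlated background activity),
so nothing forces a split. This is a known mismatch between the generator
and real data, not a defect of the rule; the recovery tests therefore
plant a baseline cloud with realistic dispersion.

Clusters are ranked by Euclidean distance of their centroid to the
baseline centroid (baseline = rank 1; ties broken by lower cluster id),
giving the "how far from rest" ordering used to colour cluster maps.

## TANOVA

The dissimilarity is the cosine distance between topography vectors,
`d = 1 − u·v/(‖u‖‖v‖)`, range [0, 2]; it is scale-free per map, so no
additional global-field-power normalisation is applied (a deliberate
choice: normalising twice changes nothing and obscures the statistic).
The observed statistic per window is computed on **grand means** — the
two conditions' maps are averaged over subjects and over the window's
samples (the two averages commute) — matching the group-mean-map
convention of the TANOVA literature.

The null swaps the two condition labels within each subject with a fair
coin (for more than two conditions a within-subject label permutation
would generalise this; only the two-condition case is implemented, with
pooling used to reduce multi-condition questions to pairs). Writing
`D_i = A_i − B_i` and `M` for the average of the two grand means, every
sign assignment's pair of grand means is `M ± (mean_i s_i D_i)/2`, so all
shuffle statistics are sign-weighted means of the subject difference
maps — which is why 1000 shuffles over 60 windows cost well under a
second. p values use the add-one estimator `(b + 1)/(m + 1)`, guaranteeing
`p ≥ 1/(m+1) > 0`; one-sided counting (`d* ≥ d`) is forced by the
statistic's nonnegativity. Shuffles that reproduce the observed labelling
give `d* = d` up to float rounding, so ties are counted with a 1e-9
tolerance — without it the estimator is biased low by the number of
identity draws.

Cluster correction over time: windows with `p <` 0.1 (the precluster
threshold) form maximal contiguous runs; cluster mass is the **sum of
observed distances** over member windows (statistic mass, mirroring the
cluster-permutation convention, rather than a p-value transform); the
null is the per-shuffle maximal mass, with each shuffle's own window
p values computed by ranking it within the pooled ensemble of observed +
shuffle statistics; corrected `p = (#{max* ≥ mass} + 1)/(m + 1)`,
significant at 0.05. One shuffle sequence is shared across windows (same
seed) precisely so this re-ranking is valid.

Defaults — 10 ms windows, 1000 shuffles, precluster 0.1, corrected
α = 0.05 — are the study parameters this pipeline replicates, and they
are also what the calibration study runs at (reduced to 199 shuffles):
over 200 simulated null datasets of 12 subjects the family-wise rate of
any significant cluster stays at the nominal 0.05 within binomial
tolerance (`scripts/acceptance.R` recomputes this from scratch).

## Mass-univariate amplitude tests

Per 20-ms half-open window (non-overlapping, anchored at 0 ms — chosen so
window families are disjoint) and per electrode, a two-sided paired t
across subjects; FDR (Benjamini–Hochberg via `stats::p.adjust`) within
each window's 32-electrode family; **no correction across the time axis**.
That omission is intentional and inherited: the onset of an amplitude
effect is read as the earliest window with any significant electrode, and
correcting across time would trade exactly the Type II errors this
analysis exists to avoid. The cost is symmetric and worth stating
plainly: under the null each window's family still fires at ~5%, so with
many pre-onset windows a spuriously early onset is not rare — the
pipeline example in the README shows one. Onset readings from this rule
should be treated as lower bounds and cross-checked against the
cluster-corrected TANOVA onset, which is protected. Zero-variance cells
are handled explicitly: all-zero differences give t = 0, p = 1; constant
nonzero differences are flagged degenerate (infinite t).

Pointwise waveform tests at representative channels (default P3/P4)
report uncorrected p < 0.05 runs as shaded intervals; a
`min_duration_ms` argument suppresses isolated one-sample runs when a
sustained-effect reading is wanted.

## Behavioral statistics

RT is aggregated to subject × cell means first (medians via `agg`), since
the within-subject ANOVA operates on subject-level summaries. The engine
computes the full sums-of-squares decomposition for the 2×2×2
within-subject design: each effect's SS comes from inclusion–exclusion
effect estimates on the balanced cell-mean array, and each effect is
tested against its own subject-by-effect interaction, giving F(1, n−1)
for 2-level factors — no sphericity correction is needed at 2 levels. The
test suite pins the engine to the independent `aov(… + Error(subject/…))`
decomposition to 1e-9 and to the classical F = t² identity on marginal
means. Planned contrasts are two-sided paired t tests on cell means; the
four defaults are the design's planned comparisons (GnLw−GwLw and
GwLn−GnLn in the local task, GwLw−GwLn and GnLw−GnLn in the global task).
The underline-position control reruns the same engine on local-task
trials with task replaced by underline position.

Error trials are removed before analysis; per-subject accuracy is
reported against the 85% screen, and subjects left with an empty design
cell are flagged by name (the ANOVA refuses them rather than silently
imputing).

## The synthetic benchmark

`simulate_eeg()` builds each trial as a sum of segment contributions
`amplitude × template × envelope` plus noise:

- **Templates** are unit-norm random topographies; each subject sees a
  jittered copy (additive Gaussian, sd 0.05, re-normalised), giving
  realistic between-subject map dispersion for the subject-level
  permutation tests.
- **Envelopes** are rectangular with 20 ms raised-cosine ramps — smooth
  enough that the FIR filter would not ring on segment edges.
- **Noise** is white sensor noise (default sd 1 μV) mixed spatially by
  `M = αI + (1−α)J/n` (α = 0.7) and filtered by an AR(1) over time
  (coefficient 0.3, innovations scaled to keep the marginal sd). This is
  the simplest model with both inter-sensor correlation and temporal
  autocorrelation; the permutation tests assume neither away, which is
  the point.
- **Blinks** hit the frontopolar channels in 15% of trials at 80 μV —
  above the ±50 μV criterion by construction — with post-stimulus
  latencies (which also keeps their peaks clear of the baseline-
  correction window).
- **Default scenario** (`default_scenario()`): a shared visual pattern
  from 80 ms in all five conditions, a global-lexicality pattern from
  160 ms in the `Gw` conditions, a local-lexicality pattern from 250 ms
  in the `Lw` conditions, and a distinct visual pattern for `symbol`;
  16 subjects, 80 trials/condition. The amplitudes (3–5 μV) and noise
  levels are *choices*, documented here as synthetic: no SNR or effect
  sizes were available to estimate them from, so they were fixed once at
  values a practitioner would call realistic for visual ERPs and not
  revisited.

`simulate_rt()` draws trial RTs from a log-normal moment-matched to each
cell's mean and sd, truncated at the 3000 ms response deadline, with
Bernoulli accuracy per cell (default 0.92). The default cell means plant
the design's characteristic differences — 55 and 54 ms in the local task,
112 ms and a near-null contrast in the global task — around a 900 ms
base typical of lexical decision; only the differences and t magnitudes
were reported for the original design, so the base and the 200 ms trial
sd were chosen to put planned-contrast t values in the mid-single digits
at 21 subjects. Subject-level heterogeneity (shared intercept,
subject-by-cell effects) defaults to zero so degenerate contracts hold
exactly (`sd = 0` ⇒ RT = cell mean), and can be switched on for more
realistic mixed-variance data.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: no biophysical forward model
(templates are random vectors, not dipolar fields), no 1/f or alpha-band
background (hence the overly tight synthetic baselines noted above), no
eye movements beyond threshold-exceeding blinks, no trial-order or
fatigue effects, and RT distributions are exactly log-normal. The
benchmark validates the *statistics* — calibration, recovery, invariances
— not the electrophysiology.

## Numerical choices

- Cosine distance normalises by `sqrt(ssu·ssv)` rather than the product
  of norms, which makes `d(u,u)` exactly 0 and `d(u,−u)` exactly 2 in
  floating point; results are clamped to [0, 2].
- Permutation tie handling uses a 1e-9 absolute tolerance on `d`
  (range [0, 2]), both in the window p and in the cluster-correction
  ensemble ranks.
- K-means assignment ties break to the lowest cluster index
  (deterministic); inertia is asserted non-increasing every Lloyd
  iteration.
- Epoch windows, baseline windows, analysis windows and TANOVA/mass-
  univariate windows are all half-open `[from, to)`, anchored so that
  0 ms is the first post-onset sample.
- The pipeline fans one global seed out to per-stage seeds by a counter
  formula kept below 2^31; reports are byte-identical across runs with
  the same seed and parameters (the output path is excluded from the
  report for that reason).

## Problem sizes used by the test and acceptance runs

The suite exercises reduced but honest sizes chosen to keep a full run
in the low minutes on one CPU: the TANOVA calibration uses 200 null
datasets × 12 subjects × 199 shuffles (the full-size windows and
thresholds); exhaustive-vs-Monte-Carlo agreement uses 6 subjects (64
sign assignments) × 5000 shuffles; K recovery uses 20 seeded replicates
of a 320-sample planted configuration; ANOVA oracles use 5–6 subjects.
Simulation-heavy properties (power of planted contrasts, FDR level,
noise-covariance convergence) use replicate counts in the tens to low
hundreds with tolerances set by the corresponding binomial error.

## Known limitations

- TANOVA supports two conditions (directly or via pooling); omnibus
  multi-condition permutation is not implemented.
- The clustering module does not implement polarity-invariant
  (microstate-convention) distances or GFP-peak subsampling; K selection
  is the baseline-split rule only.
- The BrainVision reader covers the multiplexed binary dialect (INT_16,
  IEEE_FLOAT_32) that actiChamp-family amplifiers write; vectorised and
  ASCII dialects are rejected with a clear error rather than guessed.
- Average reference assumes the montage's channels are all scalp EEG;
  no bad-channel interpolation exists, so channels must be cleaned or
  excluded upstream.
- The mass-univariate onset rule is liberal by design (see above); its
  output is a candidate onset, not a confirmatory claim.
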