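---
title: "Modelling night-to-night sleep dynamics with sleepwarp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling night-to-night sleep dynamics with sleepwarp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Healthy sleep cycles between NREM and REM every ~90-100 minutes, and the
spectral content of the EEG traces that architecture: slow waves (delta,
1-4 Hz) dominate deep NREM and decay across the night as homeostatic
pressure dissipates; spindles (sigma, 12-16 Hz) mark N2 and recur with slow
(~4-5 s) and infra-slow (~40-50 s) periodicity, phase-locked to slow-wave
peaks; REM shows low-amplitude mixed-frequency activity. When the same
person is recorded over weeks, two questions arise that single-night
polysomnography cannot answer: how variable is an individual's sleep
architecture from night to night, and are stage transitions predictable
minutes ahead from the spectral dynamics alone?

sleepwarp implements a complete analysis for such longitudinal recordings:

1. **spectral** — multitaper decomposition of each night into five band-power
   series, after artefact masking;
2. **oscillations** — spindle and slow-wave event detection and their phase
   coupling;
3. **warping** — open-ended dynamic time warping (OE-DTW) dissimilarity
   between nights, barycenter-averaged "archetypal nights" (OE-DBA), and
   clustering of subjects by their archetypes;
4. **transition_forecast** — point-process GLM forecasting of NREM-to-REM
   and REM-to-NREM transitions at horizons of -8 to +2 minutes;
5. **synthgen** — a synthetic multi-subject cohort generator that reproduces
   the statistical structure all of the above assumes, so the full pipeline
   is testable without clinical data;
6. **pipeline** — `run_pipeline()` ties the stages together with seeds,
   QC, provenance and plain-text outputs.

## Spectral decomposition

Band powers are computed with a DPSS (Slepian) multitaper estimate: seven
tapers on non-overlapping 12-s windows, time-bandwidth product `nw = 4`
(the standard pairing, since 2 x 4 - 1 = 7 tapers are well concentrated;
both are arguments of `multitaper_bandpower()`). The per-window PSD is
integrated with the trapezoidal rule over PSD bins whose centres fall in
[low, high) for delta (1-4), theta (4-8), alpha (8-12), sigma (12-16) and
beta (16-30 Hz). The tapers are built from the classic symmetric
tridiagonal eigenproblem; for windows longer than 1200 samples they are
computed at reduced length and spline-interpolated, which at these small
time-bandwidth products reproduces the exact tapers to ~1e-4 and keeps
startup fast. Windows with more than half of their samples masked are
flagged invalid; sparser masked stretches are linearly interpolated before
tapering.

Artefact masking (`mask_artifacts()`) scans 1-s windows with three rules:
peak voltage above 350 uV (the device dynamic range), line-length (mean
absolute first difference x sampling rate) above 12000 uV/s, and — as a
deliberate addition — line-length *below* 50 uV/s, which flags flat
disconnection gaps that no "higher-than" rule can catch. The upper
line-length default was calibrated once as roughly twice the 99.9th
percentile observed on clean synthetic N2/N3 signal (~6300 uV/s), leaving
headroom for subjects with larger spindles. Masking never alters sample
values.

## Event detection

`detect_spindles()` follows a mean-relative threshold design: the 11-16 Hz
band-passed signal's envelope is computed over N2/N3, candidates are
runs exceeding 5x its mean, boundaries extend outward to the 3x crossing,
and candidates that overlap one another or fall outside 0.5-2.5 s are
discarded. Two choices deserve comment:

* **Envelope definition.** The default envelope is the *squared* magnitude
  of the analytic signal ("absolute power"). This matters: with spindles
  recurring every ~4.5 s the envelope mean is dominated by the spindles
  themselves, and a 5x-mean threshold on the plain magnitude sits *above*
  the burst peaks — detection would be impossible. The squared envelope is
  skewed enough that the same rule works. The magnitude is available via
  `envelope = "analytic"`.
* **Overlap rule.** Both members of an overlapping candidate pair are
  dropped, including the case where two threshold crossings extend into
  one shared 3x-mean region. `overlap = "merge"` fuses them instead. The
  envelope is smoothed over 0.2 s so a clean burst yields a single
  candidate.

Because both thresholds are multiples of the envelope mean, detection is
invariant to rescaling the whole signal.

`detect_slow_waves()` uses conventional zero-crossing half-wave criteria
(0.5-4 Hz band-pass; negative half-waves of 0.25-1 s; adaptive amplitude
threshold at the 75th percentile of candidates, with a 0.1% tolerance so
exact ties all pass). No consensus detector exists for this step, so
phase-locking values downstream should be read as detector-conditional.
`slow_wave_phase()` defines phase 0 at the depolarising positive peak of
the filtered trace; `phase_locking()` is the modulus of the circular mean
of unit phasors at spindle onsets.

`sigma_envelope_spectrum()` Welch-averages 180-s segments of the decimated
sigma envelope within contiguous N2/N3 runs and keeps frequencies below
1 Hz; with 180-s segments the frequency grid (1/180 Hz) lands exactly on
the 4.5-s and 45-s periodicities the generator plants.

## Open-ended warping and archetypes

Each night enters the warping stage as a 5 x L matrix: band powers cropped
to the sleep period, averaged to 60-s bins (12-s resolution is available,
at 25x the pairwise cost), and z-scored per band within the night.
`build_night_features()` applies two inclusion rules, rejecting nights
with a typed QC condition: fewer than two cycle onsets ("min-cycles",
operationalising the 1.5-cycle rule) or more than 20% invalid bins after
sleep onset ("disconnection").

`oe_dtw()` anchors the alignment at sleep onset, moves through the local
Euclidean cost matrix with steps right/down/diagonal, and terminates once
the *shorter* night is fully consumed, at the minimum accumulated cost
over the longer night's axis — so a four-cycle night can match the first
cycles of a five-cycle night without penalty. For equal lengths the open
end applies to either axis, keeping D symmetric. The dissimilarity D is
the accumulated cost divided by the path length. The dynamic program is a
small C++ core; ties prefer the diagonal step. D = 0 holds *exactly* for
identical inputs because local costs are computed by direct differences.

A subtlety worth recording: D is the total cost of the minimum-total-cost
path divided by *that path's* length. Minimising total-cost/length
directly is a different functional that a plain dynamic program does not
compute; the test suite's brute-force oracle therefore enumerates all
admissible open-ended paths and minimises total cost, matching the DP's
criterion.

`pairwise_dissimilarity()` excludes adjacent (consecutive-calendar) nights
of the same subject, which share slow physiological state.
`compare_within_across()` aggregates to per-subject means (within) and
per-subject-pair means (across) before the Student's t-test, avoiding
pseudo-replication from the ~3000 correlated night pairs.

`oe_dba()` extracts archetypal nights: initialise at the medoid, then
repeat — align every member to the current average, re-estimate each
average bin as the mean of all member vectors mapped onto it. Because the
open-ended, length-normalised objective has no monotonicity guarantee of
classic fixed-end DBA, an update that would worsen the summed
dissimilarity is rejected and iteration stops; the recorded
`objective_trace` is non-increasing by construction. Defaults: at most 10
iterations or relative improvement below 1e-3.

`cluster_archetypes()` applies average-linkage hierarchical clustering to
the archetype dissimilarity matrix with a flat cut at `k` (default 2);
`stage_conditioned_dissimilarity()` buckets each path cell's local cost by
the two aligned stage labels, exposing which stage mismatches drive D.

## Transition forecasting

The conditional intensity of a stage transition is modelled as a Poisson
point process on 1-min bins:

log lambda(t) = b0 + bT * T_stage(t) + sum_fb b_fb * P_fb(t)

where `T_stage` is minutes already spent in the current collapsed stage
(NREM = {N1, N2, N3} vs REM; wake breaks runs and contributes no rows) and
`P_fb` are the five log10 band powers averaged over the minute preceding
t. The trivial reference model keeps only `T_stage`. Fitting is IRLS
(`stats::glm.fit`) on features standardised within the training set;
coefficients are reported on the standardised scale. `lambda_to_prob()`
maps intensity to probability via p = 1 - exp(-lambda); AUC is rank-based,
so this monotone choice does not affect evaluation.

Labels: for horizon h <= 0, minute t is positive iff the run it belongs to
ends in a scored transition at minute t - h. For detection horizons
(h > 0) the labelled minute lies *after* the transition, in the target
stage; the row set then adds the first max(h, 2) minutes of each target
run, so labelled and unlabelled target minutes coexist and the fit cannot
separate on stage membership alone.

`cross_validate()` draws, per fold, a random half of the *nights* for
training and tests on the other half — never splitting within a night —
and records fold AUCs for both models per horizon.
`significance_by_horizon()` implements the strict decision rule: a horizon
is significant only if every fold AUC of the spectral model exceeds every
fold AUC of the trivial model *and* every surrogate AUC. Surrogates
retrain the model on nights whose stage sequence is circularly shifted in
time against the band powers (preserving feature autocorrelation) and
evaluate on unshifted test nights. Fewer than 10 surrogates triggers a
warning. On the synthetic cohort the NREM-to-REM direction comes out
significant at horizons -3 to 0 (plus the +2 detection horizon) and not at
-8 to -4, while REM-to-NREM shows no significant prediction horizon —
detection at +2 is flagged there too, which is expected: two minutes into
NREM the spectra are unambiguous, and detection is not prediction.

## The synthetic cohort generator

No generative model exists for the real data, so the generator uses the
minimal structure that reproduces every qualitative dynamic the analyses
rely on: a semi-Markov stage process with stage-conditioned log-normal
band powers.

* **Architecture.** Each night has 3-5 cycles; cycle lengths are normal
  with mean 98 min and SD 29 min, the first cycle scaled by 92/98 and the
  second by 111/98. A cycle unrolls as N1, N2, N3 (optionally split
  N3-N2-N3, so within-NREM position does not pin down time-to-REM), a
  pre-REM N2 run, then REM targeting ~25% of the cycle (increasing across
  cycles for trait-cluster 1, fixed for cluster 2). Brief awakenings are
  inserted inside N2 with per-night probability 0.5 and geometric
  durations.
* **Band powers** (12-s grid, log10 uV^2): per-stage baselines; delta
  multiplied by (1 - delta_decline_rate)^(cycle-1), the homeostatic
  decline; aligned sigma/delta ramps within descending N2 (directly
  correlated) and anti-aligned dynamics within N3; a sharp pre-REM shift
  (delta falling, theta rising) confined to the final ~5 min; i.i.d.
  Gaussian log-power noise (SD 0.15).
* **The pre-REM sigma surge** rises over `sigma_surge_lead_min` (default
  3 min) to a peak x1.5 (`sigma_surge_gain`) about 2.75 min before REM
  onset, falls through baseline over one minute and stays suppressed over
  the final ~1.75 min. Seen through 1-min feature windows — and averaged
  over the half-minute parity that 30-s scoring epochs impose on
  transition times — this makes the fitted sigma weight flip from positive
  to negative about two minutes before onset, the signature the forecaster
  should recover.
* **Raw EEG** (207 Hz, optional): stage-coloured AR(1)-plus-white
  background, discrete biphasic slow waves in N2/N3, spindle bursts at the
  subject's peak frequency (13.5 Hz, or 12 Hz in trait cluster 2) with
  renewal intervals near 4.5 s, amplitudes modulated at the 45-s infra-slow
  period, and onsets snapped to slow-wave peaks with probability
  `plv_target` (0.2) — so the planted onset-phase distribution has the
  target phase-locking value by construction.
* **Subject traits** that survive per-night z-scoring induce the cohort
  structure: cycle timing, N3 fraction, REM fraction, ramp gains, delta
  decline rate (jittered per subject), plus the two planted clusters
  (slower spindles with sigma power shifted toward the alpha band, and the
  REM-duration trend). Cluster offsets are sized so that the 2-cut of the
  archetype dendrogram recovers membership reliably.
* **Seeds.** Every draw descends from one root seed through a documented
  splitting scheme (a 31-bit rolling hash of seed and stage name), so any
  part of a cohort can be regenerated independently and identically.

What the generator does *not* emulate: realistic EEG waveform morphology
(no coupled oscillators or neural-mass dynamics), scorer disagreement,
inter-night circadian drift, or covariates such as caffeine and exercise.
Passing tests therefore demonstrate that the algorithms recover planted
structure of the stated kind at realistic noise levels — not that they
would perform identically on clinical recordings.

## Numerical choices and degenerate inputs

* Z-scoring raises an error naming the offending band when a band has zero
  variance; it is idempotent; invalid bins are untouched.
* `oe_dtw()` errors on resolution mismatches; empty recordings, missing
  N2/N3 and too-few events produce errors (or a warning plus empty result
  where the contract says so).
* Poisson IRLS runs up to 100 iterations; non-convergence is an error,
  quasi-separation (|coef| > 15) is flagged in `fit_meta`.
* AUC is undefined when a test fold lacks both classes; such cells are NA
  and the significance rule treats NA conservatively (not significant).
* The detection-horizon row set (`max(h, 2)` minutes of the target run)
  exists to prevent complete separation of a single labelled target
  minute; see the forecasting section.

## Problem sizes used by the tests

The suite exercises the pipeline at the scale the analyses are designed
for: a cohort of 8 subjects x 10 nights (band powers only) for the
dissimilarity, archetype, clustering and forecasting checks; a 90-min raw
night (~1000 planted spindles, ~500 slow waves) for the detectors; 200
simulated nights for cycle-statistics calibration; 100 random short
sequence pairs against the exhaustive warping oracle; and 20,000 simulated
rows for GLM parameter recovery. The full suite runs in a few minutes on
one core.

## Known limitations

* Absolute D values depend on resolution and normalisation; only orderings
  (within < across, shuffled > intact) and the zero identity are treated
  as reproducible quantities.
* OE-DBA is a heuristic; the guard guarantees a non-increasing objective,
  not a global optimum, and the archetype length is tied to the medoid's.
* PLV magnitudes are conditional on the slow-wave detector and phase
  convention.
* EDF input is out of scope in this implementation; recordings enter as
  in-memory vectors or plain-text TSV (the hypnogram/band-power schemas
  are stable interchange formats).
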