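# Raw EEG synthesis at 207 Hz: stage-coloured background noise, discrete
# slow waves in N2/N3, spindle bursts at the subject's peak frequency with
# ~4-5 s renewal intervals and infra-slow amplitude modulation, onsets
# snapped to slow-wave peaks with probability plv_target, and a ground-truth
# event list. Plus artefact injection (noise transients and flat gaps).

.stage_sd <- c(W = 10, N1 = 12, N2 = 15, N3 = 20, REM = 10)

# one-cycle biphasic slow wave (trough then peak), duration 1.25 s
sw_waveform <- function(fs, amp, dur = 1.25) {
  t <- seq(0, dur, by = 1 / fs)
  -amp * sin(2 * pi * t / dur)
}

# tapered spindle burst envelope (flat middle, cosine ramps over the outer
# quarters) -- keeps onset/offset detectable near the planted boundaries
tukey_win <- function(n, alpha = 0.5) {
  w <- rep(1, n)
  edge <- floor(alpha * n / 2)
  if (edge > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(edge) / edge))
    w[seq_len(edge)] <- ramp
    w[n + 1 - seq_len(edge)] <- ramp
  }
  w
}

#' Simulate a raw sub-scalp EEG night
#'
#' Builds a 207-Hz signal from stage-coloured background noise, planted slow
#' waves (biphasic, 0.8 Hz scale) in N2/N3, planted spindle bursts at the
#' profile's spindle peak frequency with renewal intervals near
#' `spindle_slow_period_s`, amplitudes modulated at
#' `spindle_infraslow_period_s`, and spindle onsets snapped to slow-wave
#' peaks with probability `plv_target`. Ground-truth event lists are
#' returned alongside the recording.
#'
#' @param hyp A [hypnogram()].
#' @param profile A subject profile from [make_profile()].
#' @param seed Integer seed.
#' @param spindle_amplitude Peak spindle amplitude as a multiple of the
#'   stage background SD (default 6).
#' @param infraslow_mod_depth Depth of the infra-slow amplitude modulation
#'   of spindles (default 0.4; 0 plants every spindle at exactly
#'   `spindle_amplitude` times the background SD).
#' @return A list with elements `recording` ([recording()]), `spindles`
#'   (data frame: onset_s, offset_s, amplitude, freq_hz, phase, snapped,
#'   stage) and `slow_waves` (data frame: trough_s, peak_s, peak_to_peak,
#'   stage).
#' @export
simulate_raw_eeg <- function(hyp, profile, seed = 1, spindle_amplitude = 6,
                             infraslow_mod_depth = 0.4) {
  stopifnot(inherits(hyp, "sw_hypnogram"))
  validate_profile(profile)
  fs <- 207
  n <- round(hyp_duration_s(hyp) * fs)
  stg <- stage_at(hyp, (seq_len(n) - 0.5) / fs)
  with_seed(split_seed(seed, "raweeg"), {
    # background: AR(1)-coloured + broadband white, scaled per stage
    ar <- as.numeric(stats::filter(rnorm(n), 0.95, method = "recursive"))
    ar <- ar * sqrt(1 - 0.95^2)  # unit variance
    x <- .stage_sd[stg] * (0.9 * ar + 0.45 * rnorm(n))
    x[stg == "REM"] <- x[stg == "REM"] +
      4 * sin(2 * pi * 6.5 * (which(stg == "REM") / fs))

    runs <- true_runs(stg %in% c("N2", "N3"))
    sw_list <- list()
    for (k in seq_len(nrow(runs))) {
      t0 <- (runs[k, "start"] - 1) / fs
      t1 <- runs[k, "end"] / fs
      run_stage <- stg[runs[k, "start"]]
      t <- t0 + runif(1, 0, 2)
      while (TRUE) {
        gap <- if (run_stage == "N3") runif(1, 1.5, 3.5) else runif(1, 3, 6)
        t <- t + gap
        if (t + 1.25 > t1) break
        amp <- if (run_stage == "N3") runif(1, 60, 90) else runif(1, 40, 60)
        w <- sw_waveform(fs, amp)
        idx <- round(t * fs) + seq_along(w)
        idx <- idx[idx >= 1 & idx <= n]
        x[idx] <- x[idx] + w[seq_along(idx)]
        sw_list[[length(sw_list) + 1]] <-
          data.frame(trough_s = t + 0.3125, peak_s = t + 0.9375,
                     peak_to_peak = 2 * amp, stage = run_stage)
      }
    }
    slow_waves <- if (length(sw_list)) do.call(rbind, sw_list)
      else data.frame(trough_s = numeric(), peak_s = numeric(),
                      peak_to_peak = numeric(), stage = character())

    sp_list <- list()
    for (k in seq_len(nrow(runs))) {
      t0 <- (runs[k, "start"] - 1) / fs
      t1 <- runs[k, "end"] / fs
      run_stage <- stg[runs[k, "start"]]
      peaks <- slow_waves$peak_s[slow_waves$peak_s > t0 &
                                   slow_waves$peak_s < t1]
      t <- t0 + runif(1, 0, profile$spindle_slow_period_s)
      prev_off <- -Inf
      while (TRUE) {
        gap <- if (run_stage == "N3")
          max(2.5, rnorm(1, 6, 0.8))
        else
          max(2.2, rnorm(1, profile$spindle_slow_period_s, 0.6))
        t <- t + gap
        dur <- runif(1, 0.9, 1.4)
        if (t + dur > t1) break
        onset <- t
        snapped <- FALSE
        phase <- runif(1, -pi, pi)
        if (runif(1) < profile$plv_target && length(peaks)) {
          cand <- peaks[which.min(abs(peaks - onset))]
          if (abs(cand - onset) < 2.5 && cand > prev_off + 0.3 &&
              cand + dur < t1) {
            onset <- cand
            snapped <- TRUE
            phase <- 0
          }
        }
        amp <- spindle_amplitude * .stage_sd[run_stage] *
          (1 + infraslow_mod_depth *
             sin(2 * pi * onset / profile$spindle_infraslow_period_s))
        m <- round(dur * fs)
        tt <- seq_len(m) / fs
        burst <- amp * tukey_win(m) *
          sin(2 * pi * profile$spindle_peak_hz * tt + runif(1, 0, 2 * pi))
        idx <- round(onset * fs) + seq_len(m)
        idx <- idx[idx >= 1 & idx <= n]
        x[idx] <- x[idx] + burst[seq_along(idx)]
        sp_list[[length(sp_list) + 1]] <-
          data.frame(onset_s = onset, offset_s = onset + dur,
                     amplitude = amp, freq_hz = profile$spindle_peak_hz,
                     phase = phase, snapped = snapped, stage = run_stage)
        prev_off <- onset + dur
        t <- onset
      }
    }
    spindles <- if (length(sp_list)) do.call(rbind, sp_list)
      else data.frame(onset_s = numeric(), offset_s = numeric(),
                      amplitude = numeric(), freq_hz = numeric(),
                      phase = numeric(), snapped = logical(),
                      stage = character())
    list(recording = recording(x, fs = fs, start_time = hyp$start_time),
         spindles = spindles, slow_waves = slow_waves)
  })
}

#' Inject artefacts into a recording
#'
#' Inserts high-amplitude broadband transients and flat disconnection gaps
#' at a given hourly rate, recording the ground-truth intervals in the
#' returned object's `artifacts` field.
#'
#' @param rec A [recording()].
#' @param rate Artefact events per hour (transients and gaps alternate).
#' @param seed Integer seed.
#' @return A modified copy of `rec` with an `artifacts` data frame
#'   (`onset_s`, `offset_s`, `type`).
#' @export
inject_artifacts <- function(rec, rate, seed = 1) {
  stopifnot(inherits(rec, "sw_recording"), rate >= 0)
  hours <- length(rec$samples) / rec$fs / 3600
  n_art <- round(rate * hours)
  if (n_art == 0) {
    rec$artifacts <- data.frame(onset_s = numeric(), offset_s = numeric(),
                                type = character())
    return(rec)
  }
  total_s <- length(rec$samples) / rec$fs
  with_seed(split_seed(seed, "artifacts"), {
    types <- rep(c("transient", "gap"), length.out = n_art)
    placed <- data.frame(onset_s = numeric(), offset_s = numeric(),
                         type = character())
    for (i in seq_len(n_art)) {
      dur <- if (types[i] == "transient") runif(1, 0.3, 2) else runif(1, 2, 20)
      for (try in 1:100) {
        on <- runif(1, 0, total_s - dur)
        if (!any(on < placed$offset_s + 1 & on + dur > placed$onset_s - 1))
          break
      }
      idx <- (round(on * rec$fs) + 1):round((on + dur) * rec$fs)
      if (types[i] == "transient") {
        rec$samples[idx] <- runif(1, 450, 600) * runif(length(idx), -1, 1)
      } else {
        rec$samples[idx] <- 0
      }
      placed <- rbind(placed, data.frame(onset_s = on, offset_s = on + dur,
                                         type = types[i]))
    }
    rec$artifacts <- placed[order(placed$onset_s), ]
    rec
  })
}

#' Generate a complete synthetic night
#'
#' Convenience wrapper tying the generator together: hypnogram, band powers,
#' and (optionally) raw EEG with ground-truth events, all derived from one
#' root seed via the package's seed-splitting scheme.
#'
#' @param profile A subject profile from [make_profile()].
#' @param seed Integer root seed for this night.
#' @param raw If `TRUE`, also synthesise the 207-Hz recording (slower).
#' @return An object of class `sw_night`: `hypnogram`, `bandpower`,
#'   `recording` (or `NULL`), `spindles`, `slow_waves`, `subject_id`, `seed`.
#' @export
generate_night <- function(profile, seed = 1, raw = FALSE) {
  validate_profile(profile)
  hyp <- simulate_hypnogram(profile, seed)
  bp <- simulate_bandpower(hyp, profile, seed)
  rec <- NULL; spin <- NULL; sw <- NULL
  if (raw) {
    r <- simulate_raw_eeg(hyp, profile, seed)
    rec <- r$recording; spin <- r$spindles; sw <- r$slow_waves
  }
  structure(list(hypnogram = hyp, bandpower = bp, recording = rec,
                 spindles = spin, slow_waves = sw,
                 subject_id = profile$subject_id, cluster = profile$cluster,
                 seed = seed),
            class = "sw_night")
}

#' @export
print.sw_night <- function(x, ...) {
  cat(sprintf("<sw_night> subject %s, seed %d, %.1f h%s\n", x$subject_id,
              x$seed, hyp_duration_s(x$hypnogram) / 3600,
              if (is.null(x$recording)) "" else " (+raw EEG)"))
  invisible(x)
}
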