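# Discrete sleep oscillations: spindle detection by mean-relative envelope
# thresholds, inter-spindle periodicity, slow-wave detection by zero-crossing
# half-wave criteria, spindle/slow-wave phase locking, and the sigma-delta
# trajectory in feature space.

#' Detect sleep spindles
#'
#' Filters the signal at 11-16 Hz, computes its envelope over N2/N3
#' samples, marks candidates where the (lightly smoothed) envelope exceeds
#' `core_factor` times its N2/N3 mean, extends their boundaries outward to
#' the `edge_factor`-times-mean crossing, then discards candidates that
#' overlap one another or fall outside the 0.5-2.5 s duration window.
#' Thresholds are mean-relative, so detection is invariant to a global
#' rescaling of the signal.
#'
#' @param rec A [recording()].
#' @param hyp The night's [hypnogram()].
#' @param core_factor Candidate threshold as a multiple of the mean
#'   envelope (default 5).
#' @param edge_factor Boundary threshold as a multiple of the mean
#'   envelope (default 3).
#' @param min_dur,max_dur Admissible duration window in seconds.
#' @param envelope `"power"` (squared magnitude of the analytic signal,
#'   the default: with spindles recurring every few seconds the envelope
#'   mean is spindle-dominated, and only the skew of the squared envelope
#'   keeps the 5x-mean threshold below the burst peaks) or `"analytic"`
#'   (the magnitude itself).
#' @param overlap `"discard"` drops both members of an overlapping pair
#'   (the default); `"merge"` fuses them into one event.
#' @return A data frame of class `sw_events`, sorted by onset: `onset_s`,
#'   `offset_s`, `duration_s`, `peak_amplitude`, `mean_freq`.
#' @export
detect_spindles <- function(rec, hyp, core_factor = 5, edge_factor = 3,
                            min_dur = 0.5, max_dur = 2.5,
                            envelope = c("power", "analytic"),
                            overlap = c("discard", "merge")) {
  stopifnot(inherits(rec, "sw_recording"), inherits(hyp, "sw_hypnogram"))
  envelope <- match.arg(envelope)
  overlap <- match.arg(overlap)
  n <- length(rec$samples)
  domain <- stage_sample_mask(hyp, rec$fs, n) & rec$mask
  empty <- data.frame(onset_s = numeric(), offset_s = numeric(),
                      duration_s = numeric(), peak_amplitude = numeric(),
                      mean_freq = numeric())
  class(empty) <- c("sw_events", "data.frame")
  if (!any(domain)) {
    warning("no N2/N3 data; returning empty spindle list")
    return(empty)
  }
  bf <- signal::butter(4, c(11, 16) / (rec$fs / 2), type = "pass")
  filt <- signal::filtfilt(bf, rec$samples)
  env <- Mod(analytic_signal(filt))
  if (envelope == "power") env <- env^2
  # light smoothing avoids splitting one burst into several candidates
  k <- max(1L, round(0.2 * rec$fs))
  env_s <- as.numeric(stats::filter(env, rep(1 / k, k), sides = 2))
  env_s[is.na(env_s)] <- env[is.na(env_s)]
  m <- mean(env_s[domain])
  core <- true_runs(env_s > core_factor * m & domain)
  if (nrow(core) == 0) return(empty)
  below <- env_s < edge_factor * m | !domain
  # extend each core outward to the edge_factor crossing (within the domain)
  ev <- t(apply(core, 1, function(r) {
    on <- r["start"]
    while (on > 1 && !below[on - 1]) on <- on - 1
    off <- r["end"]
    while (off < n && !below[off + 1]) off <- off + 1
    c(on, off)
  }))
  # NOTE: two cores whose extensions meet inside one 3x-mean region yield
  # candidates sharing samples; under the literal overlap rule both are
  # discarded (the "merge" alternative fuses them instead)
  if (overlap == "discard" && nrow(ev) > 1) {
    drop <- rep(FALSE, nrow(ev))
    for (i in 1:(nrow(ev) - 1)) {
      if (ev[i + 1, 1] <= ev[i, 2]) drop[c(i, i + 1)] <- TRUE
    }
    ev <- ev[!drop, , drop = FALSE]
  } else if (overlap == "merge" && nrow(ev) > 1) {
    merged <- ev[1, , drop = FALSE]
    for (i in 2:nrow(ev)) {
      if (ev[i, 1] <= merged[nrow(merged), 2])
        merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], ev[i, 2])
      else merged <- rbind(merged, ev[i, ])
    }
    ev <- merged
  }
  if (nrow(ev) == 0) return(empty)
  dur <- (ev[, 2] - ev[, 1] + 1) / rec$fs
  keep <- dur >= min_dur & dur <= max_dur
  ev <- ev[keep, , drop = FALSE]
  dur <- dur[keep]
  if (nrow(ev) == 0) return(empty)
  out <- data.frame(
    onset_s = (ev[, 1] - 1) / rec$fs,
    offset_s = ev[, 2] / rec$fs,
    duration_s = dur,
    peak_amplitude = vapply(seq_len(nrow(ev)), function(i)
      max(env[ev[i, 1]:ev[i, 2]]), 0),
    mean_freq = vapply(seq_len(nrow(ev)), function(i) {
      x <- filt[ev[i, 1]:ev[i, 2]]
      zc <- sum(diff(sign(x)) != 0)
      zc / 2 / dur[i]
    }, 0))
  out <- out[order(out$onset_s), ]
  rownames(out) <- NULL
  class(out) <- c("sw_events", "data.frame")
  out
}

#' Inter-spindle intervals
#'
#' Differences consecutive spindle onsets, restricted to pairs that fall in
#' the same contiguous N2/N3 run (intervals never span REM or wake blocks),
#' and summarises them as a histogram.
#'
#' @param events An event data frame with an `onset_s` column.
#' @param hyp Optional [hypnogram()]; when supplied, onsets are grouped by
#'   contiguous N2/N3 run before differencing.
#' @param bin_width_s Histogram bin width in seconds (default 0.5).
#' @param max_s Histogram upper limit in seconds (default 30).
#' @return A list: `intervals` (seconds), `breaks`, `counts` and
#'   `modal_interval_s` (centre of the fullest bin).
#' @export
inter_spindle_intervals <- function(events, hyp = NULL, bin_width_s = 0.5,
                                    max_s = 30) {
  if (nrow(events) < 2) stop("need at least 2 events")
  onsets <- sort(events$onset_s)
  if (is.null(hyp)) {
    ints <- diff(onsets)
  } else {
    # group by contiguous N2/N3 runs of the hypnogram
    epm <- hyp$epoch_s
    runs <- true_runs(hyp$labels %in% c("N2", "N3"))
    run_of <- function(t) {
      e <- floor(t / epm) + 1
      hit <- which(runs[, "start"] <= e & runs[, "end"] >= e)
      if (length(hit)) hit[1] else NA_integer_
    }
    rid <- vapply(onsets, run_of, 0L)
    ints <- unlist(lapply(split(onsets, rid), function(o)
      if (length(o) > 1) diff(o) else numeric(0)), use.names = FALSE)
  }
  ints <- ints[ints <= max_s]
  breaks <- seq(0, max_s, by = bin_width_s)
  counts <- as.numeric(table(cut(ints, breaks)))
  modal <- breaks[which.max(counts)] + bin_width_s / 2
  list(intervals = ints, breaks = breaks, counts = counts,
       modal_interval_s = modal)
}

#' Detect slow waves
#'
#' Band-passes the signal at 0.5-4 Hz, splits it into half-waves at zero
#' crossings, and keeps negative half-waves of 0.25-1 s whose trough
#' amplitude reaches the adaptive threshold (75th percentile of candidate
#' amplitudes). Each kept event is paired with the following positive
#' half-wave to give trough and peak times.
#'
#' @param rec A [recording()].
#' @param hyp The night's [hypnogram()]; detection is restricted to N2/N3.
#' @param min_half_s,max_half_s Admissible negative half-wave duration (s).
#' @param amp_quantile Adaptive amplitude threshold quantile (default 0.75).
#' @return A data frame of class `sw_events`: `trough_s`, `peak_s`,
#'   `peak_to_peak`, `duration_s`.
#' @export
detect_slow_waves <- function(rec, hyp, min_half_s = 0.25, max_half_s = 1,
                              amp_quantile = 0.75) {
  stopifnot(inherits(rec, "sw_recording"), inherits(hyp, "sw_hypnogram"))
  n <- length(rec$samples)
  domain <- stage_sample_mask(hyp, rec$fs, n) & rec$mask
  empty <- data.frame(trough_s = numeric(), peak_s = numeric(),
                      peak_to_peak = numeric(), duration_s = numeric())
  class(empty) <- c("sw_events", "data.frame")
  if (!any(domain)) {
    warning("no N2/N3 data; returning empty slow-wave list")
    return(empty)
  }
  bf <- signal::butter(4, c(0.5, 4) / (rec$fs / 2), type = "pass")
  filt <- signal::filtfilt(bf, rec$samples)
  sgn <- sign(filt)
  sgn[sgn == 0] <- 1
  cross <- which(diff(sgn) != 0)
  if (length(cross) < 2) return(empty)
  cand <- list()
  for (i in seq_len(length(cross) - 1)) {
    a <- cross[i] + 1; b <- cross[i + 1]
    if (filt[a] >= 0) next                      # want negative half-waves
    if (!domain[a] || !domain[b]) next
    dur <- (b - a + 1) / rec$fs
    if (dur < min_half_s || dur > max_half_s) next
    tr <- a - 1 + which.min(filt[a:b])
    # following positive half-wave -> peak
    b2 <- if (i + 2 <= length(cross)) cross[i + 2] else min(b + round(rec$fs), n)
    pk <- b + which.max(filt[(b + 1):b2])
    cand[[length(cand) + 1]] <- c(tr, pk, -filt[tr], filt[pk], dur)
  }
  if (length(cand) == 0) return(empty)
  cand <- do.call(rbind, cand)
  thr <- quantile(cand[, 3], amp_quantile, names = FALSE)
  # 0.1% tolerance keeps ties (e.g. a pure oscillation where every trough
  # has the same amplitude up to filter edge ringing)
  keep <- cand[, 3] >= thr * (1 - 1e-3)
  out <- data.frame(trough_s = (cand[keep, 1] - 0.5) / rec$fs,
                    peak_s = (cand[keep, 2] - 0.5) / rec$fs,
                    peak_to_peak = cand[keep, 3] + pmax(cand[keep, 4], 0),
                    duration_s = cand[keep, 5])
  out <- out[order(out$trough_s), ]
  rownames(out) <- NULL
  class(out) <- c("sw_events", "data.frame")
  out
}

#' Instantaneous slow-oscillation phase
#'
#' Phase of the analytic signal of the 0.5-4 Hz filtered trace; phase 0
#' falls at the depolarising positive peak.
#'
#' @param rec A [recording()].
#' @param polarity `1` keeps the recording's polarity; `-1` flips it.
#' @return A function mapping time (seconds from recording start) to phase
#'   in radians.
#' @export
slow_wave_phase <- function(rec, polarity = 1) {
  stopifnot(inherits(rec, "sw_recording"))
  bf <- signal::butter(4, c(0.5, 4) / (rec$fs / 2), type = "pass")
  filt <- polarity * signal::filtfilt(bf, rec$samples)
  ph <- Arg(analytic_signal(filt))
  fs <- rec$fs
  n <- length(ph)
  function(t_s) ph[pmin(pmax(round(t_s * fs), 1), n)]
}

#' Circular phase-locking statistics
#'
#' @param phases Numeric vector of phases in radians.
#' @return An object of class `sw_plv`: `plv` (modulus of the circular mean
#'   of unit phasors), `preferred_phase` (its argument) and `n_events`.
#' @export
phase_locking <- function(phases) {
  stopifnot(is.numeric(phases), length(phases) > 0)
  z <- mean(exp(1i * phases))
  structure(list(plv = Mod(z), preferred_phase = Arg(z),
                 n_events = length(phases)),
            class = "sw_plv")
}

#' @export
print.sw_plv <- function(x, ...) {
  cat(sprintf("<sw_plv> PLV = %.3f at %.2f rad (n = %d)\n",
              x$plv, x$preferred_phase, x$n_events))
  invisible(x)
}

#' Spindle/slow-wave phase locking
#'
#' Samples the slow-oscillation phase at each spindle onset and summarises
#' the concentration of those phases as a phase-locking value.
#'
#' @param spindles Event data frame with `onset_s`.
#' @param slow_phase Function mapping time to phase, e.g. from
#'   [slow_wave_phase()].
#' @param min_events Minimum number of spindles required (default 10).
#' @return An object of class `sw_plv`.
#' @export
spindle_sw_plv <- function(spindles, slow_phase, min_events = 10) {
  if (nrow(spindles) < min_events)
    stop(sprintf("need at least %d spindles, got %d", min_events,
                 nrow(spindles)))
  phase_locking(slow_phase(spindles$onset_s))
}

#' Sigma-delta trajectory
#'
#' Sliding-window means of sigma and delta power (default 5-min window,
#' 1-min step) tracing the night's position in the sigma-delta feature
#' plane.
#'
#' @param series A [band_power_series()].
#' @param window_min Window length in minutes.
#' @param step_min Step in minutes.
#' @return A data frame: `t_center_s`, `sigma_mean`, `delta_mean`.
#' @export
sigma_delta_trajectory <- function(series, window_min = 5, step_min = 1) {
  stopifnot(inherits(series, "sw_bandpower"))
  wb <- round(window_min * 60 / series$bin_s)
  sb <- max(1L, round(step_min * 60 / series$bin_s))
  L <- n_bins(series)
  if (L < wb) stop("series shorter than one window")
  starts <- seq(1, L - wb + 1, by = sb)
  res <- t(vapply(starts, function(s0) {
    idx <- s0:(s0 + wb - 1)
    idx <- idx[series$valid[idx]]
    c(sigma = mean(series$values["sigma", idx]),
      delta = mean(series$values["delta", idx]))
  }, c(sigma = 0, delta = 0)))
  data.frame(t_center_s = (starts - 1 + wb / 2) * series$bin_s,
             sigma_mean = res[, "sigma"], delta_mean = res[, "delta"])
}
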