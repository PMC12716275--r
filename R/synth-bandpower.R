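# Stage-conditioned log-normal band powers on the 12-s grid, with the
# within-night dynamics the downstream analyses rely on: homeostatic delta
# decline across cycles, within-N2 sigma/delta ramps (directly correlated),
# within-N3 sigma decay against a delta plateau (anti-correlated), and a
# transient sigma surge that rises before each REM onset, peaks about
# 2.25 min out, and collapses below baseline over the final minute.

# Pre-REM sigma surge profile in log10 units; tau_min < 0 is time to REM
# onset. The surge rises over lead_min minutes to a peak 2.75 min before
# onset, falls through baseline over one minute, and stays suppressed over
# the final 1.75 min -- so the sigma weight seen through 1-min feature
# windows flips from positive to negative about two minutes before onset.
surge_profile <- function(tau_min, lead_min, gain) {
  g <- log10(gain)
  out <- numeric(length(tau_min))
  rise <- tau_min >= -(lead_min + 2.75) & tau_min < -2.75
  fall <- tau_min >= -2.75 & tau_min < -1.75
  hold <- tau_min >= -1.75 & tau_min < 0
  out[rise] <- g * (tau_min[rise] + lead_min + 2.75) / lead_min
  out[fall] <- g * (1 - 2 * (tau_min[fall] + 2.75))
  out[hold] <- -g
  out
}

#' Simulate a night's five-band power series
#'
#' Generates stage-conditioned log-normal band powers on a 12-s grid from a
#' hypnogram and subject profile: per-stage baselines, delta multiplied by
#' `(1 - delta_decline_rate)^(cycle - 1)`, aligned sigma/delta ramps within
#' descending N2, anti-aligned dynamics within N3, a theta rise with delta
#' fall in pre-REM N2, and the pre-REM sigma surge, plus i.i.d. Gaussian
#' log-power noise.
#'
#' @param hyp A [hypnogram()].
#' @param profile A subject profile from [make_profile()].
#' @param seed Integer seed.
#' @param n_bins Optional expected number of 12-s bins; an error is raised
#'   if it disagrees with the hypnogram duration (+/- 1 bin).
#' @return A [band_power_series()] (linear uV^2 values).
#' @export
simulate_bandpower <- function(hyp, profile, seed = 1, n_bins = NULL) {
  stopifnot(inherits(hyp, "sw_hypnogram"))
  validate_profile(profile)
  if (n_epochs(hyp) == 0) stop("hypnogram is empty")
  bin_s <- 12
  L <- floor(hyp_duration_s(hyp) / bin_s)
  if (!is.null(n_bins) && abs(n_bins - L) > 1)
    stop(sprintf("requested %d bins but hypnogram spans %d", n_bins, L))
  centers <- (seq_len(L) - 0.5) * bin_s
  stg <- stage_at(hyp, centers)
  bl <- profile$band_baselines
  logp <- t(bl[stg, , drop = FALSE])  # 5 x L

  # cycle index per bin (homeostatic decline applies within NREM)
  cyc <- rep(1L, L)
  cycles <- segment_cycles(hyp)
  if (nrow(cycles) > 0) {
    onset_s <- (cycles$start_epoch - 1) * hyp$epoch_s
    cyc <- pmax(1L, findInterval(centers, onset_s))
  }
  nrem <- stg %in% c("N1", "N2", "N3")
  logp["delta", nrem] <- logp["delta", nrem] +
    (cyc[nrem] - 1) * log10(1 - profile$delta_decline_rate)

  # within-run ramps
  g <- profile$ramp_gain
  r <- rle(stg)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (i in seq_along(r$values)) {
    s <- r$values[i]
    if (!s %in% c("N2", "N3")) next
    idx <- starts[i]:ends[i]
    p <- (seq_along(idx) - 0.5) / length(idx)
    if (s == "N3") {
      logp["delta", idx] <- logp["delta", idx] + 0.25 * p
      logp["sigma", idx] <- logp["sigma", idx] + g * (0.35 - 0.7 * p)
    } else {
      # descending N2 (next non-W stage is N3) vs pre-REM N2
      nxt <- if (i < length(r$values)) {
        after <- r$values[(i + 1):length(r$values)]
        after <- after[after != "W"]
        if (length(after)) after[1] else NA
      } else NA
      if (identical(nxt, "N3")) {
        logp["delta", idx] <- logp["delta", idx] + g * 0.7 * (p - 0.5)
        logp["sigma", idx] <- logp["sigma", idx] + g * 0.6 * (p - 0.5)
      } else {
        # pre-REM N2: the spectral shift towards REM (delta falling, theta
        # rising) is sharp, confined to the final ~5 min of the run
        to_end_min <- (length(idx) - seq_along(idx) + 0.5) * bin_s / 60
        prox <- pmax(0, 1 - to_end_min / 5)
        logp["delta", idx] <- logp["delta", idx] + 0.1 - 0.35 * prox
        logp["theta", idx] <- logp["theta", idx] + 0.2 * prox
      }
    }
  }

  # pre-REM sigma surge, applied to NREM bins ahead of each scored REM onset
  rem_runs <- true_runs(stg == "REM")
  for (k in seq_len(nrow(rem_runs))) {
    onset <- (rem_runs[k, "start"] - 1) * bin_s
    tau_min <- (centers - onset) / 60
    sel <- stg %in% c("N2", "N3") &
      tau_min >= -(profile$sigma_surge_lead_min + 2.75) & tau_min < 0
    if (any(sel))
      logp["sigma", sel] <- logp["sigma", sel] +
        surge_profile(tau_min[sel], profile$sigma_surge_lead_min,
                      profile$sigma_surge_gain)
  }

  with_seed(split_seed(seed, "bandpower"), {
    logp <- logp + matrix(rnorm(5 * L, 0, profile$noise_sd), 5, L)
  })
  band_power_series(10^logp, bin_s = bin_s, start_time = hyp$start_time)
}
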