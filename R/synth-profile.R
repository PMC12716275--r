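# Subject profiles for the synthetic cohort generator.
#
# Defaults encode the study conditions the downstream analyses assume:
# NREM-REM cycles of 98 +/- 29 min with a shorter first (x0.94) and longer
# second (x1.13) cycle, about 25% REM, delta power declining across cycles
# (sleep homeostasis), a pre-REM sigma surge, spindles with ~4.5 s and ~45 s
# periodicity phase-locked to slow-wave peaks (target PLV 0.2), and two
# trait clusters (cluster 2: spindle peak ~1.5 Hz slower with sigma power
# leaking into the alpha band, and fixed rather than increasing REM duration
# across cycles).

# stage x band (rows W,N1,N2,N3,REM; cols delta..beta), log10 uV^2
.base_band_baselines <- function() {
  m <- rbind(W   = c(1.00, 0.80, 0.90, 0.30, 0.50),
             N1  = c(1.20, 0.95, 0.70, 0.40, 0.40),
             N2  = c(1.60, 1.00, 0.70, 0.90, 0.30),
             N3  = c(2.20, 1.10, 0.60, 0.70, 0.15),
             REM = c(1.00, 0.90, 0.75, 0.30, 0.50))
  colnames(m) <- band_names()
  m
}

#' Create a synthetic subject profile
#'
#' Draws the subject-level traits that make nights from the same subject
#' resemble each other more than nights from different subjects: cycle
#' timing, stage-conditioned band-power baselines, homeostatic delta decline,
#' spindle properties and the pre-REM sigma surge. Two trait clusters are
#' supported; cluster 2 differs only in its stated trait parameters (slower
#' spindle peak frequency with correspondingly alpha-shifted N2/N3 band
#' baselines, and fixed instead of increasing REM duration across cycles).
#'
#' @param seed Integer seed; profiles are deterministic given `(seed, cluster)`.
#' @param cluster Trait cluster, 1 or 2.
#' @param subject_id Subject identifier (defaults to `"s<seed>"`).
#' @return An object of class `sw_profile` (a named list of trait values).
#' @export
make_profile <- function(seed = 1, cluster = 1, subject_id = NULL) {
  if (!cluster %in% c(1, 2))
    stop("cluster must be 1 or 2")
  if (is.null(subject_id)) subject_id <- paste0("s", seed)
  # subject jitter is drawn identically for both clusters so that cluster 2
  # differs from cluster 1 only in the trait parameters set afterwards
  jit <- with_seed(split_seed(seed, "profile"), list(
    cycle_mean_min = min(120, max(75, rnorm(1, 98, 8))),
    cycle_sd_min = runif(1, 24, 34),
    baseline_jitter = matrix(rnorm(25, 0, 0.04), 5, 5),
    delta_decline_rate = runif(1, 0.10, 0.20),
    n3_frac = runif(1, 0.35, 0.50),
    rem_frac = runif(1, 0.22, 0.28),
    ramp_gain = runif(1, 0.8, 1.2)
  ))
  baselines <- .base_band_baselines() + jit$baseline_jitter
  if (cluster == 2) {
    # slower spindles: sigma-band activity shifted towards the alpha edge,
    # sized so the planted clusters are recoverable from z-scored band
    # dynamics
    baselines["N2", "alpha"] <- baselines["N2", "alpha"] + 0.35
    baselines["N3", "alpha"] <- baselines["N3", "alpha"] + 0.25
    baselines["N2", "sigma"] <- baselines["N2", "sigma"] - 0.15
  }
  structure(list(
    subject_id = subject_id,
    cluster = cluster,
    cycle_mean_min = jit$cycle_mean_min,
    cycle_sd_min = jit$cycle_sd_min,
    first_cycle_scale = 92 / 98,
    second_cycle_scale = 111 / 98,
    n_cycles_range = c(3L, 5L),
    band_baselines = baselines,
    delta_decline_rate = jit$delta_decline_rate,
    n3_frac = jit$n3_frac,
    rem_frac = jit$rem_frac,
    ramp_gain = jit$ramp_gain,
    rem_trend = if (cluster == 1) "increasing" else "fixed",
    sigma_surge_lead_min = 3,
    sigma_surge_gain = 1.5,
    spindle_peak_hz = if (cluster == 1) 13.5 else 12.0,
    spindle_slow_period_s = 4.5,
    spindle_infraslow_period_s = 45,
    plv_target = 0.2,
    noise_sd = 0.15,
    waso_prob = 0.5
  ), class = "sw_profile")
}

#' @export
print.sw_profile <- function(x, ...) {
  cat(sprintf(paste0("<sw_profile> %s (cluster %d): cycles %.0f+/-%.0f min,",
                     " REM %.0f%%, spindle peak %.1f Hz, REM trend %s\n"),
              x$subject_id, x$cluster, x$cycle_mean_min, x$cycle_sd_min,
              100 * x$rem_frac, x$spindle_peak_hz, x$rem_trend))
  invisible(x)
}

validate_profile <- function(profile) {
  stopifnot(inherits(profile, "sw_profile"))
  if (profile$cycle_mean_min <= 0) stop("cycle_mean_min must be positive")
  if (any(profile$n_cycles_range < 1) || any(profile$n_cycles_range > 8))
    stop("n_cycles_range must lie within [1, 8]")
  if (profile$plv_target < 0 || profile$plv_target > 1)
    stop("plv_target must lie in [0, 1]")
  if (profile$first_cycle_scale >= profile$second_cycle_scale)
    stop("first_cycle_scale must be below second_cycle_scale")
  invisible(profile)
}
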