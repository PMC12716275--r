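# Semi-Markov hypnogram simulation: each NREM-REM cycle unrolls as
# N1 -> N2 -> N3 -> N2 -> REM with durations drawn from the subject profile,
# plus occasional brief awakenings inserted inside N2.

#' Simulate a night's hypnogram
#'
#' Draws a semi-Markov stage sequence with 3-5 NREM-REM cycles (range from
#' the profile). Cycle lengths are normal with the profile mean/SD, the
#' first cycle scaled shorter and the second longer; REM occupies roughly a
#' quarter of each cycle (increasing across cycles for "increasing"-trend
#' profiles); N3 occupancy declines across cycles. Brief awakenings are
#' inserted inside N2 with per-night probability `profile$waso_prob` and
#' geometric durations.
#'
#' @param profile A subject profile from [make_profile()].
#' @param seed Integer seed; output is deterministic given `(profile, seed)`.
#' @return An [hypnogram()] object (30-s epochs).
#' @export
simulate_hypnogram <- function(profile, seed = 1) {
  validate_profile(profile)
  with_seed(split_seed(seed, "hypnogram"), {
    rng <- profile$n_cycles_range
    n_cycles <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1)
    n_cycles <- max(1L, n_cycles)
    rem_factor <- function(k) {
      if (profile$rem_trend == "increasing")
        c(0.7, 0.9, 1.1, 1.3)[min(k, 4)]
      else 1
    }
    labels <- character(0)
    for (k in seq_len(n_cycles)) {
      scale_k <- if (k == 1) profile$first_cycle_scale
                 else if (k == 2) profile$second_cycle_scale else 1
      len_k <- max(40, rnorm(1, profile$cycle_mean_min * scale_k,
                             profile$cycle_sd_min))
      rem_k <- min(0.4 * len_k,
                   max(5, len_k * profile$rem_frac * rem_factor(k)))
      nrem_k <- len_k - rem_k
      n1_k <- if (k == 1) 4 else 1.5
      n3_k <- max(2, (nrem_k - n1_k) * profile$n3_frac *
                       max(0.15, 1 - 0.25 * (k - 1)))
      rest <- max(4, nrem_k - n1_k - n3_k)
      n2a_k <- 0.58 * rest
      n2b_k <- rest - n2a_k
      ep <- function(minutes) max(1L, round(minutes * 2))
      # N3 <-> N2 alternation: deep sleep often splits into blocks with an
      # intervening N2 return, so within-NREM position alone does not pin
      # down the time to REM
      nrem_part <- if (n3_k >= 14 && runif(1) < 0.6) {
        n3_a <- runif(1, 0.4, 0.7) * n3_k
        ret <- runif(1, 2, 8)
        n2a_adj <- max(2, n2a_k - ret / 2)
        n2b_adj <- max(2, n2b_k - ret / 2)
        c(rep("N2", ep(n2a_adj)), rep("N3", ep(n3_a)), rep("N2", ep(ret)),
          rep("N3", ep(n3_k - n3_a)), rep("N2", ep(n2b_adj)))
      } else {
        c(rep("N2", ep(n2a_k)), rep("N3", ep(n3_k)), rep("N2", ep(n2b_k)))
      }
      labels <- c(labels, rep("N1", ep(n1_k)), nrem_part,
                  rep("REM", ep(rem_k)))
    }
    # brief awakenings, inserted strictly inside N2 runs so the REM-period
    # count and cycle structure are preserved
    if (runif(1) < profile$waso_prob) {
      for (i in seq_len(sample(1:3, 1))) {
        runs <- true_runs(labels == "N2")
        runs <- runs[runs[, "end"] - runs[, "start"] >= 4, , drop = FALSE]
        if (nrow(runs) == 0) break
        r <- runs[sample(nrow(runs), 1), ]
        at <- sample((r["start"] + 2):(r["end"] - 2), 1)
        w_len <- rgeom(1, 1 / 4) + 1L
        labels <- append(labels, rep("W", w_len), after = at)
      }
    }
    hypnogram(labels)
  })
}
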