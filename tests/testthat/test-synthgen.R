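# Synthetic cohort generator: subject profiles, hypnograms, band powers,
# raw EEG and artefact injection.

test_that("profiles are deterministic and cluster traits are isolated", {
  p1 <- make_profile(1, 1)
  expect_identical(p1, make_profile(1, 1))
  expect_equal(p1$spindle_peak_hz, 13.5)
  expect_error(make_profile(1, 3), "cluster must be 1 or 2")

  p2 <- make_profile(1, 2)
  expect_lte(p2$spindle_peak_hz, p1$spindle_peak_hz - 1)
  expect_identical(p2$rem_trend, "fixed")
  expect_identical(p1$rem_trend, "increasing")
  # cluster 2 differs only in its stated trait parameters
  expect_equal(p2$cycle_mean_min, p1$cycle_mean_min)
  expect_equal(p2$delta_decline_rate, p1$delta_decline_rate)
  expect_equal(p2$noise_sd, p1$noise_sd)
  expect_equal(p2$band_baselines["REM", ], p1$band_baselines["REM", ])
  expect_gt(p2$band_baselines["N2", "alpha"], p1$band_baselines["N2", "alpha"])
})

test_that("hypnograms have the requested cycle count and are reproducible", {
  p <- make_profile(1, 1)
  p$n_cycles_range <- c(4L, 4L)
  h <- simulate_hypnogram(p, 11)
  expect_equal(sum(rle(h$labels)$values == "REM"), 4)
  expect_identical(simulate_hypnogram(p, 11)$labels, h$labels)
})

test_that("simulated cycle lengths match the profile over many nights", {
  p <- make_profile(1, 1)
  first <- second <- all_len <- rem_pct <- c()
  for (s in 1:200) {
    h <- simulate_hypnogram(p, s)
    cy <- segment_cycles(h)
    all_len <- c(all_len, cy$duration_min)
    if (nrow(cy) >= 2) {
      first <- c(first, cy$duration_min[1])
      second <- c(second, cy$duration_min[2])
    }
    rem_pct <- c(rem_pct, static_stats(h)$stage_pct[["REM"]])
  }
  expect_lt(abs(mean(all_len) - p$cycle_mean_min), 5)
  expect_lt(mean(first), mean(second))  # shorter first, longer second cycle
  expect_true(all(rem_pct >= 18 & rem_pct <= 32))
})

test_that("band powers carry the planted within-night dynamics", {
  p <- make_profile(1, 1)
  rn2 <- rn3 <- dd <- rise <- c()
  for (s in 1:3) {
    h <- simulate_hypnogram(p, s)
    bp <- simulate_bandpower(h, p, s)
    centers <- (seq_len(ncol(bp$values)) - 0.5) * bp$bin_s
    stg <- stage_at_epochs(h, centers)
    lv <- log10(bp$values)
    rn2 <- c(rn2, cor(lv["sigma", stg == "N2"], lv["delta", stg == "N2"]))
    rn3 <- c(rn3, cor(lv["sigma", stg == "N3"], lv["delta", stg == "N3"]))
    cy <- segment_cycles(h)
    ci <- pmax(1, findInterval(centers, (cy$start_epoch - 1) * h$epoch_s))
    dd <- c(dd, mean(lv["delta", stg == "N3" & ci == 1]) -
                mean(lv["delta", stg == "N3" & ci == 3]))
    # sigma climbs over the minutes leading into the pre-REM peak
    rr <- which(diff(c(FALSE, stg == "REM")) == 1)
    for (k in rr) {
      tau <- (centers - (k - 1) * bp$bin_s) / 60
      nrem <- stg %in% c("N2", "N3")
      a <- lv["sigma", nrem & tau > -5 & tau <= -3]
      b <- lv["sigma", nrem & tau > -7 & tau <= -5]
      if (length(a) > 3 && length(b) > 3) rise <- c(rise, mean(a) - mean(b))
    }
  }
  expect_true(all(rn2 > 0))  # sigma/delta correlated in N2
  expect_true(all(rn3 < 0))  # anti-correlated in N3
  expect_true(all(dd > 0))   # homeostatic delta decline across cycles
  expect_gt(mean(rise), 0)   # pre-REM sigma surge
})

test_that("band-power grid length tracks the hypnogram duration", {
  p <- make_profile(1, 1)
  h <- simulate_hypnogram(p, 4)
  bp <- simulate_bandpower(h, p, 4)
  expect_lte(abs(ncol(bp$values) - length(h$labels) * h$epoch_s / 12), 1)
  expect_error(simulate_bandpower(h, p, 4, n_bins = ncol(bp$values) + 50),
               "hypnogram spans")
})

test_that("raw EEG plants events inside N2/N3 with the right periodicity", {
  r <- sw_raw_night()
  hyp <- sw_raw_hyp()
  stages <- stage_at_epochs(hyp, r$spindles$onset_s)
  expect_true(all(stages %in% c("N2", "N3")))
  expect_true(all(stage_at_epochs(hyp, r$spindles$offset_s) %in%
                    c("N2", "N3")))
  isi <- inter_spindle_intervals(r$spindles, hyp)
  expect_gte(isi$modal_interval_s, 3)
  expect_lte(isi$modal_interval_s, 6)
  # planted onset phases concentrate to the requested PLV
  pl <- phase_locking(r$spindles$phase)
  expect_lt(abs(pl$plv - make_profile(1, 1)$plv_target), 0.05)
  # determinism
  r2 <- simulate_raw_eeg(sw_raw_hyp(), make_profile(1, 1), seed = 7)
  expect_identical(r2$recording$samples, sw_raw_night()$recording$samples)
})

test_that("artefact injection is controlled by the hourly rate", {
  rec <- recording(rnorm(8 * 3600 * 32, 0, 10), fs = 32)
  r0 <- inject_artifacts(rec, rate = 0, seed = 1)
  expect_identical(r0$samples, rec$samples)
  expect_equal(nrow(r0$artifacts), 0)

  r6 <- inject_artifacts(rec, rate = 6, seed = 1)
  expect_equal(nrow(r6$artifacts), 48)  # 6/h over 8 h
  tr <- r6$artifacts[r6$artifacts$type == "transient", ]
  peak <- vapply(seq_len(nrow(tr)), function(i) {
    idx <- round(tr$onset_s[i] * 32):round(tr$offset_s[i] * 32)
    max(abs(r6$samples[idx]))
  }, 0)
  expect_true(all(peak > 5 * sd(rec$samples)))
  gap <- r6$artifacts[r6$artifacts$type == "gap", ]
  idx <- round(gap$onset_s[1] * 32 + 2):round(gap$offset_s[1] * 32 - 2)
  expect_true(all(r6$samples[idx] == 0))
})
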