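# Spindle detection, inter-spindle periodicity, slow waves, phase locking
# and the sigma-delta trajectory.

test_that("planted spindles are recovered with high recall and precision", {
  r <- sw_raw_night(depth = 0)   # every spindle at exactly 6x background
  sp <- detect_spindles(r$recording, sw_raw_hyp())
  expect_gt(nrow(r$spindles), 200)
  expect_gte(event_recall(r$spindles$onset_s, sp$onset_s), 0.9)
  expect_gte(event_recall(sp$onset_s, r$spindles$onset_s), 0.9)  # precision
  expect_true(all(sp$duration_s >= 0.5 & sp$duration_s <= 2.5))
  expect_true(all(diff(sp$onset_s) > 0))
  expect_true(all(head(sp$offset_s, -1) <= tail(sp$onset_s, -1)))  # disjoint
  expect_true(all(sp$mean_freq > 11 & sp$mean_freq < 16))
})

test_that("detection is invariant to a global signal rescaling", {
  r <- sw_raw_night(depth = 0)
  sp1 <- detect_spindles(r$recording, sw_raw_hyp())
  scaled <- r$recording
  scaled$samples <- scaled$samples * 7.3
  sp2 <- detect_spindles(scaled, sw_raw_hyp())
  expect_equal(sp1$onset_s, sp2$onset_s)
  expect_equal(sp1$duration_s, sp2$duration_s)
})

test_that("duration and overlap rules are enforced", {
  fs <- 207
  hyp <- hypnogram(rep("N2", 120))
  n <- 60 * 60 * fs
  t <- seq_len(n) / fs
  # amplitude path: 30 clean spindles, one 0.25-s burst, and one pair of
  # bursts bridged above the 3x-mean (but below the 5x-mean) level so that
  # their extended boundaries overlap
  knots_t <- c(0, 30)
  knots_a <- c(1, 1)
  for (k in 1:30) {
    at <- 30 + k * 60
    knots_t <- c(knots_t, at, at + 0.15, at + 0.95, at + 1.1)
    knots_a <- c(knots_a, 1, 8, 8, 1)
  }
  knots_t <- c(knots_t, 45, 45.05, 45.2, 45.25)      # too-short burst
  knots_a <- c(knots_a, 1, 8, 8, 1)
  knots_t <- c(knots_t, 100, 100.15, 100.55, 100.7,  # bridged pair
               101.3, 101.45, 101.85, 102.0, 3600)
  knots_a <- c(knots_a, 1, 8, 8, 2.4, 2.4, 8, 8, 1, 1)
  o <- order(knots_t)
  A <- approx(knots_t[o], knots_a[o], xout = t, rule = 2)$y
  rec <- recording(A * sin(2 * pi * 13 * t), fs)

  sp <- detect_spindles(rec, hyp)
  expect_false(any(abs(sp$onset_s - 45) < 0.5))            # duration rule
  expect_equal(sum(sp$onset_s > 99 & sp$onset_s < 104), 0) # both discarded
  expect_equal(nrow(sp), 30)
  # the merge alternative fuses the pair into one long event instead
  spm <- detect_spindles(rec, hyp, overlap = "merge")
  expect_equal(sum(spm$onset_s > 99 & spm$onset_s < 104), 1)
})

test_that("spindle detection warns and returns empty without N2/N3", {
  rec <- recording(rnorm(207 * 120), 207)
  hyp <- hypnogram(rep(c("W", "REM"), each = 2))
  expect_warning(sp <- detect_spindles(rec, hyp), "no N2/N3")
  expect_equal(nrow(sp), 0)
})

test_that("inter-spindle intervals stay within contiguous N2/N3 runs", {
  ev <- data.frame(onset_s = c(0, 4.5, 9.0))
  isi <- inter_spindle_intervals(ev)
  expect_equal(isi$intervals, c(4.5, 4.5))

  # events separated by a REM block are never differenced across it
  hyp <- hypnogram(c(rep("N2", 20), rep("REM", 20), rep("N2", 20)))
  ev2 <- data.frame(onset_s = c(100, 104.5, 1300, 1306))
  isi2 <- inter_spindle_intervals(ev2, hyp)
  expect_equal(sort(isi2$intervals), c(4.5, 6))
  expect_false(any(isi2$intervals > 30))

  expect_error(inter_spindle_intervals(data.frame(onset_s = 1)),
               "at least 2")
})

test_that("slow-wave detection finds every cycle of a pure oscillation", {
  fs <- 207
  hyp <- hypnogram(rep("N3", 4))  # 2 min
  t <- seq_len(120 * fs) / fs
  sw <- detect_slow_waves(recording(80 * sin(2 * pi * t), fs), hyp)
  expect_gt(nrow(sw), 110)  # one event per 1-Hz cycle, minus edges
  expect_true(all(abs(sw$peak_s - sw$trough_s - 0.5) < 0.1))

  flat <- detect_slow_waves(recording(rep(0, 120 * fs), fs), hyp)
  expect_equal(nrow(flat), 0)
})

test_that("planted slow waves are recovered", {
  r <- sw_raw_night()
  sw <- detect_slow_waves(r$recording, sw_raw_hyp())
  expect_gte(event_recall(r$slow_waves$trough_s, sw$trough_s, tol = 0.25),
             0.8)
})

test_that("phase locking is calibrated on known phase distributions", {
  pl <- phase_locking(rep(pi / 3, 25))
  expect_equal(pl$plv, 1)
  expect_equal(pl$preferred_phase, pi / 3)

  pl0 <- phase_locking(seq(0, 2 * pi, length.out = 9)[-9])
  expect_lt(pl0$plv, 1e-12)

  set.seed(1)
  plu <- phase_locking(runif(10000, -pi, pi))
  expect_lt(plu$plv, 0.03)

  # rotation invariance
  set.seed(2)
  ph <- runif(200, -pi, pi / 2)
  a <- phase_locking(ph)
  b <- phase_locking(ph + 0.7)
  expect_equal(a$plv, b$plv)
  expect_equal((b$preferred_phase - a$preferred_phase) %% (2 * pi), 0.7,
               tolerance = 1e-9)
})

test_that("spindle/slow-wave PLV needs a minimum event count", {
  expect_error(
    spindle_sw_plv(data.frame(onset_s = 1:5), function(t) rep(0, length(t))),
    "at least 10")
  res <- spindle_sw_plv(data.frame(onset_s = 1:12),
                        function(t) rep(pi / 4, length(t)))
  expect_equal(res$plv, 1)
  expect_equal(res$n_events, 12)
})

test_that("slow-wave phase is zero at the depolarising peak", {
  fs <- 207
  t <- seq_len(60 * fs) / fs
  rec <- recording(50 * sin(2 * pi * 1 * t), fs)
  ph <- slow_wave_phase(rec)
  peaks <- which(diff(sign(diff(50 * sin(2 * pi * t)))) < 0) / fs
  expect_lt(max(abs(ph(peaks[5:50]))), 0.15)
})

test_that("sigma-delta trajectory summarises sliding-window dynamics", {
  const <- band_power_series(matrix(rep(c(1, 2, 3, 4, 5), 60), 5))
  tr <- sigma_delta_trajectory(const)
  expect_true(all(tr$sigma_mean == 4) && all(tr$delta_mean == 1))

  one <- sigma_delta_trajectory(const, window_min = 12)
  expect_equal(nrow(one), 1)
  expect_equal(one$sigma_mean, 4)

  expect_error(sigma_delta_trajectory(const, window_min = 20),
               "shorter than")

  # planted N2 -> N3 dynamics: delta climbs while sigma rises then falls
  p <- make_profile(1, 1)
  hyp <- hypnogram(c(rep("N2", 60), rep("N3", 60)))
  bp <- simulate_bandpower(hyp, p, seed = 2)
  lbp <- bp
  lbp$values <- log10(lbp$values)
  tr2 <- sigma_delta_trajectory(lbp)
  n <- nrow(tr2)
  expect_gt(mean(tr2$delta_mean[(n - 10):n]),
            mean(tr2$delta_mean[1:10]))
  mid <- which.max(tr2$sigma_mean)
  expect_gt(mid, 5)
  expect_lt(mid, n - 5)
})
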