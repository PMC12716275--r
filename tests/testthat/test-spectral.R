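# Artefact masking, multitaper band powers, z-scoring, envelope spectra.

test_that("mask_artifacts flags threshold violations and nothing else", {
  fs <- 207
  x <- 100 * sin(2 * pi * 5 * (1:(60 * fs)) / fs)
  clean <- mask_artifacts(recording(x, fs = fs))
  expect_true(all(clean$mask))
  expect_identical(clean$samples, x)  # pure masking, values untouched

  x2 <- x
  x2[30 * fs + 5] <- 500  # one spike above the 350 uV range
  spiked <- mask_artifacts(recording(x2, fs = fs))
  expect_false(all(spiked$mask[(30 * fs + 1):(31 * fs)]))
  expect_true(all(spiked$mask[1:(29 * fs)]))
  expect_identical(spiked$samples, x2)

  expect_error(mask_artifacts(recording(numeric(0))), "empty")
})

test_that("injected artefacts are recovered with high sensitivity", {
  r <- sw_raw_night()
  ra <- inject_artifacts(r$recording, rate = 6, seed = 3)
  masked <- mask_artifacts(ra)
  fs <- ra$fs
  gt <- rep(FALSE, length(ra$samples))
  for (i in seq_len(nrow(ra$artifacts))) {
    idx <- max(1, round(ra$artifacts$onset_s[i] * fs)):
      round(ra$artifacts$offset_s[i] * fs)
    gt[idx] <- TRUE
  }
  sensitivity <- sum(!masked$mask & gt) / sum(gt)
  expect_gte(sensitivity, 0.9)
})

test_that("multitaper band powers are calibrated", {
  fs <- 207
  n <- round(12 * fs) * 10
  # zero signal -> zero power
  expect_equal(max(multitaper_bandpower(recording(rep(0, n), fs))$values), 0)
  # a unit 6 Hz sinusoid concentrates in theta with ~A^2/2 power
  bp <- multitaper_bandpower(recording(sin(2 * pi * 6 * (1:n) / fs), fs))
  frac <- bp$values["theta", ] / colSums(bp$values)
  expect_true(all(frac >= 0.9))
  expect_lt(abs(mean(bp$values["theta", ]) - 0.5), 0.05)
  # taper count incompatible with the time-bandwidth product
  expect_error(multitaper_bandpower(recording(rnorm(n), fs), n_tapers = 9),
               "2\\*nw-1")
})

test_that("white-noise band power is proportional to bandwidth", {
  set.seed(1)
  fs <- 207
  bp <- multitaper_bandpower(recording(rnorm(round(12 * fs) * 100, 0, 10),
                                       fs))
  per_hz <- rowMeans(bp$values) / (band_edges()[, "high"] -
                                     band_edges()[, "low"])
  expect_lt((max(per_hz) - min(per_hz)) / mean(per_hz), 0.1)
  # Parseval-style bound: banded power cannot exceed the signal variance
  expect_true(all(colSums(bp$values) <= 10^2 * 1.1))
})

test_that("multitaper estimate matches the analytic AR(1) spectrum", {
  set.seed(2)
  fs <- 207
  phi <- 0.6
  x <- as.numeric(stats::filter(rnorm(round(12 * fs) * 200), phi,
                                method = "recursive"))
  bp <- multitaper_bandpower(recording(x, fs))
  aspec <- function(f) (1 / fs) / (1 + phi^2 - 2 * phi * cos(2 * pi * f / fs))
  for (b in rownames(bp$values)) {
    be <- band_edges()[b, ]
    expect_val <- 2 * mean(aspec(seq(be[1], be[2], by = 1e-3))) *
      (be[2] - be[1])
    expect_lt(abs(mean(bp$values[b, ]) / expect_val - 1), 0.1)
  }
})

test_that("masked bins are flagged invalid beyond the 50% rule", {
  fs <- 207
  n <- round(12 * fs) * 4
  rec <- recording(rnorm(n), fs = fs)
  rec$mask[1:round(12 * fs * 0.8)] <- FALSE       # bin 1: 80% masked
  rec$mask[round(12 * fs) + 1:(2 * fs)] <- FALSE  # bin 2: ~17% masked
  bp <- multitaper_bandpower(rec)
  expect_false(bp$valid[1])
  expect_true(all(bp$valid[2:4]))
  expect_true(all(is.na(bp$values[, 1])))
})

test_that("z-scoring standardises, is idempotent, and rejects flat bands", {
  set.seed(3)
  bp <- band_power_series(matrix(10^rnorm(5 * 50), 5, 50))
  z <- zscore_bands(bp)
  expect_true(all(abs(rowMeans(z$values)) < 1e-9))
  expect_true(all(abs(apply(z$values, 1, sd) - 1) < 1e-9))
  expect_equal(zscore_bands(z)$values, z$values)

  flat <- band_power_series(rbind(matrix(10^rnorm(4 * 50), 4, 50),
                                  rep(2, 50)))
  expect_error(zscore_bands(flat), "beta")
})

test_that("sigma-envelope spectrum locates slow and infra-slow periodicity", {
  fs <- 207
  # pure 0.2 Hz amplitude modulation of a sigma-band carrier
  t <- (1:(10 * 60 * fs)) / fs
  x <- 20 * (1 + 0.8 * sin(2 * pi * 0.2 * t)) * sin(2 * pi * 13 * t)
  es <- sigma_envelope_spectrum(recording(x, fs), rep(TRUE, length(x)))
  expect_equal(envelope_peak(es, c(0.1, 1)), 0.2, tolerance = 0.02)

  # generated night: peaks reflect the planted 4.5 s and 45 s periods
  r <- sw_raw_night()
  mask <- stage_at_epochs(sw_raw_hyp(),
                          (seq_along(r$recording$samples) - 0.5) / fs) %in%
    c("N2", "N3")
  es2 <- sigma_envelope_spectrum(r$recording, mask)
  expect_gt(envelope_peak(es2, c(0.1, 1)), 0.18)
  expect_lt(envelope_peak(es2, c(0.1, 1)), 0.28)
  expect_gt(envelope_peak(es2, c(0.01, 0.05)), 0.018)
  expect_lt(envelope_peak(es2, c(0.01, 0.05)), 0.027)

  short <- recording(rnorm(60 * fs), fs)
  expect_error(sigma_envelope_spectrum(short, rep(TRUE, 60 * fs)),
               "5 minutes")
})
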