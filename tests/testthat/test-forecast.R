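# Design construction, point-process GLM fitting, cross-validation and
# surrogate significance for stage-transition forecasting.

toy_night <- function(nrem_min = 10, rem_min = 5) {
  list(list(
    bandpower = band_power_series(
      matrix(10, 5, (nrem_min + rem_min) * 5)),
    hypnogram = hypnogram(c(rep("N2", nrem_min * 2), rep("REM", rem_min * 2)))
  ))
}

test_that("labels sit exactly at the requested horizon", {
  d2 <- build_design(toy_night(), "nrem_rem", -2)
  expect_equal(d2$rows$t[d2$labels == 1], 8)
  expect_equal(d2$rows$T_stage, 1:10)

  d0 <- build_design(toy_night(), "nrem_rem", 0)
  expect_equal(d0$rows$t[d0$labels == 1], 10)

  dp <- build_design(toy_night(), "nrem_rem", 2)
  expect_equal(dp$rows$t[dp$labels == 1], 12)
  expect_true(all(dp$rows$stage[dp$labels == 1] == "REM"))

  expect_error(build_design(toy_night(), "nrem_rem", -9), "\\[-8, 2\\]")
  expect_error(build_design(toy_night(), "nrem_rem", 3), "\\[-8, 2\\]")
})

test_that("wake bouts break runs: no NREM->REM label across wake", {
  ng <- list(list(
    bandpower = band_power_series(matrix(10, 5, 100)),
    hypnogram = hypnogram(c(rep("N2", 20), rep("W", 4), rep("REM", 10)))))
  d <- build_design(ng, "nrem_rem", 0)
  expect_equal(sum(d$labels), 0)
})

test_that("the GLM recovers known coefficients within 3 SE", {
  set.seed(9)
  n <- 12000
  rows <- data.frame(T_stage = rep(1:80, length.out = n),
                     delta = rnorm(n), theta = rnorm(n), alpha = rnorm(n),
                     sigma = rnorm(n), beta = rnorm(n))
  beta_true <- c(-4.5, 0.8, -0.4, 0.25, 0, 0.6, -0.3)
  X <- cbind(1, scale(as.matrix(rows)))
  y <- rpois(n, exp(X %*% beta_true))
  fit <- fit_ppglm(rows, y)
  expect_true(all(abs(coef(fit) - beta_true) / fit$se < 3))
  expect_true(fit$fit_meta$converged)

  # labels independent of features: band coefficients indistinguishable
  # from zero
  y0 <- rpois(n, 0.02)
  fit0 <- fit_ppglm(rows, y0)
  z <- abs(coef(fit0)[band_names()] / fit0$se[band_names()])
  expect_true(all(z < 3))

  expect_error(fit_ppglm(rows, rep(0, n)), "positive label")
})

test_that("the trivial model is nested and tracks time-in-stage", {
  set.seed(10)
  n <- 8000
  rows <- data.frame(T_stage = rep(1:40, length.out = n),
                     delta = rnorm(n), theta = rnorm(n), alpha = rnorm(n),
                     sigma = rnorm(n), beta = rnorm(n))
  y <- rpois(n, exp(-4 + 0.06 * rows$T_stage))
  full <- fit_ppglm(rows, y)
  triv <- fit_trivial(rows, y)
  expect_gte(triv$deviance, full$deviance)  # nesting
  bT_unstd <- coef(triv)[["T_stage"]] / triv$scale[["T_stage"]]
  expect_lt(abs(bT_unstd - 0.06), 3 * triv$se[["T_stage"]] /
              triv$scale[["T_stage"]])
  # lambda is monotone in T_stage when its coefficient is positive
  grid <- rows[1:40, ]
  grid$T_stage <- 1:40
  expect_true(all(diff(predict(triv, grid)) > 0))
  expect_true(all(predict(triv, grid) > 0))
  expect_true(all(lambda_to_prob(predict(triv, grid)) >= 0 &
                    lambda_to_prob(predict(triv, grid)) <= 1))
})

test_that("a random-score predictor scores AUC ~ 0.5", {
  set.seed(11)
  y <- rep(c(0, 1), c(1800, 200))
  auc <- sleepwarp:::auc_score(y, runif(2000))
  expect_lt(abs(auc - 0.5), 0.05)
})

test_that("cross-validation splits at night level and fills AUC matrices", {
  nights <- sw_cohort()[seq(1, 40, by = 2)]  # 20 nights
  fc <- cross_validate(nights, "nrem_rem", horizons = c(-3, -2, 0),
                       n_folds = 4, seed = 2)
  expect_equal(dim(fc$auc_full), c(4, 3))
  for (tr in fc$fold_train) {
    expect_equal(length(tr), 10)
    expect_equal(anyDuplicated(tr), 0)
    expect_true(all(tr %in% 1:20))
  }
  ok <- !is.na(fc$auc_full)
  expect_true(any(ok))
  expect_true(all(fc$auc_full[ok] >= 0 & fc$auc_full[ok] <= 1))
  expect_true(all(fc$auc_trivial[!is.na(fc$auc_trivial)] <= 1))
  expect_error(cross_validate(nights[1:3], "nrem_rem"), "at least 4")
})

test_that("significance requires full AUCs to clear both references", {
  nights <- sw_cohort()[seq(1, 40, by = 2)]
  fc <- cross_validate(nights, "nrem_rem", horizons = c(-2, -8),
                       n_folds = 4, seed = 2)
  expect_warning(sig <- significance_by_horizon(fc, surrogates = 5,
                                                seed = 2),
                 "fewer than 10")
  d <- sig$detail
  recomputed <- !is.na(d$min_full) & !is.na(d$max_trivial) &
    !is.na(d$max_surrogate) & d$min_full > d$max_trivial &
    d$min_full > d$max_surrogate
  expect_equal(d$significant, recomputed)
  expect_equal(dim(sig$surrogate_auc), c(5, 2))
})

test_that("coefficient tables cover every horizon and feature", {
  nights <- sw_cohort()[seq(1, 40, by = 2)]
  fc <- cross_validate(nights, "nrem_rem", horizons = c(-3, -1),
                       n_folds = 3, seed = 5)
  tab <- coefficients_by_horizon(fc)
  expect_equal(nrow(tab), 2 * 6)  # horizons x (T_stage + 5 bands)
  expect_true(all(c("horizon", "feature", "estimate", "sd") %in% names(tab)))
  expect_true(all(is.finite(tab$estimate)))
})
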