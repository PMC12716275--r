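# Point-process GLM for stage-transition intensity: a Poisson GLM with log
# link on 1-min bins, log lambda = b0 + bT * T_stage + sum_fb b_fb * P_fb,
# fitted by iteratively reweighted least squares. The trivial reference
# model keeps only the time-in-stage term. Features are standardised on
# the training data (moments stored for prediction).

.full_features <- function() c("T_stage", band_names())

fit_pp <- function(rows, labels, features, direction = NA, horizon = NA,
                   type = "full") {
  stopifnot(length(labels) == nrow(rows))
  if (sum(labels) < 1) stop("need at least one positive label")
  X <- as.matrix(rows[, features, drop = FALSE])
  if (anyNA(X)) stop("non-finite features in design")
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  if (any(scale == 0))
    stop("design not full rank: zero variance in ",
         paste(features[scale == 0], collapse = ", "))
  Xs <- cbind("(Intercept)" = 1, sweep(sweep(X, 2, center), 2, scale, "/"))
  fit <- stats::glm.fit(Xs, labels, family = poisson(),
                        control = list(maxit = 100))
  if (!fit$converged)
    stop(sprintf("IRLS did not converge in %d iterations (deviance %.3f)",
                 fit$iter, fit$deviance))
  # standard errors from the Fisher information at the optimum
  w <- fit$weights
  XtWX <- crossprod(Xs * sqrt(w))
  se <- tryCatch(sqrt(diag(solve(XtWX))),
                 error = function(e) rep(NA_real_, ncol(Xs)))
  names(se) <- colnames(Xs)
  structure(list(
    coefficients = fit$coefficients, se = se,
    deviance = fit$deviance, null_deviance = fit$null.deviance,
    n = nrow(Xs), n_events = sum(labels), iter = fit$iter,
    features = features, center = center, scale = scale,
    direction = direction, horizon = horizon, type = type,
    fit_meta = list(converged = fit$converged,
                    separation = max(abs(fit$coefficients)) > 15)
  ), class = "sw_ppglm")
}

#' Fit the spectral point-process GLM
#'
#' Poisson GLM with log link for the per-minute transition intensity, with
#' time-in-stage and the five (log10) band powers as predictors. Features
#' are standardised internally; coefficients are reported on the
#' standardised scale.
#'
#' @param rows Design rows from [build_design()].
#' @param labels 0/1 transition labels from [build_design()].
#' @param direction,horizon Optional metadata stored with the fit.
#' @return An object of class `sw_ppglm`.
#' @export
fit_ppglm <- function(rows, labels, direction = NA, horizon = NA) {
  fit_pp(rows, labels, .full_features(), direction, horizon, "full")
}

#' Fit the trivial reference model
#'
#' The nested reference: intercept plus time-in-stage only, encoding the
#' null hypothesis that spectral composition carries no predictive
#' information beyond elapsed time.
#'
#' @inheritParams fit_ppglm
#' @return An object of class `sw_ppglm`.
#' @export
fit_trivial <- function(rows, labels, direction = NA, horizon = NA) {
  fit_pp(rows, labels, "T_stage", direction, horizon, "trivial")
}

#' @export
coef.sw_ppglm <- function(object, ...) object$coefficients

#' @export
print.sw_ppglm <- function(x, ...) {
  cat(sprintf(
    "<sw_ppglm> %s model, %d rows, %d events, deviance %.1f (iter %d)\n",
    x$type, x$n, x$n_events, x$deviance, x$iter))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.sw_ppglm <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- data.frame(estimate = object$coefficients, se = object$se,
                    z = z, p = 2 * stats::pnorm(-abs(z)))
  cat(sprintf("Point-process GLM (%s), %d rows, %d transition events\n",
              object$type, object$n, object$n_events))
  print(round(tab, 4))
  invisible(tab)
}

#' Predict per-minute transition intensity
#'
#' @param object An `sw_ppglm`.
#' @param rows New design rows (same columns as used in fitting).
#' @param ... Unused.
#' @return Numeric vector of conditional intensities `lambda` (events/min).
#' @export
predict.sw_ppglm <- function(object, rows, ...) {
  X <- as.matrix(rows[, object$features, drop = FALSE])
  Xs <- cbind(1, sweep(sweep(X, 2, object$center), 2, object$scale, "/"))
  as.numeric(exp(Xs %*% object$coefficients))
}

#' Transition probability from intensity
#'
#' Maps a conditional Poisson intensity to the probability of at least one
#' transition within the bin: `p = 1 - exp(-lambda * delta)`.
#'
#' @param lambda Intensity (events/min).
#' @param delta_min Bin width in minutes (default 1).
#' @return Probabilities in `[0, 1]`.
#' @export
lambda_to_prob <- function(lambda, delta_min = 1) {
  1 - exp(-lambda * delta_min)
}
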