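# Cross-validated forecasting performance: repeated random half/half
# night-level splits, AUC of the predicted intensity against test labels
# per horizon, for both the spectral and the trivial model, plus
# surrogate-based significance (circularly time-shifted stage labels) and
# coefficient summaries by horizon.

auc_score <- function(labels, scores) {
  if (length(unique(labels)) < 2) return(NA_real_)
  as.numeric(pROC::auc(response = labels, predictor = scores,
                       levels = c(0, 1), direction = "<", quiet = TRUE))
}

#' Cross-validate transition forecasting
#'
#' For each fold, a random half of the nights trains the spectral and
#' trivial models and the other half tests them (night-level splits only,
#' never within-night). Per horizon the AUC of the predicted intensity
#' against the held-out transition labels is recorded for both models.
#'
#' @param nights List of nights (elements with `$bandpower`, `$hypnogram`).
#' @param direction `"nrem_rem"` or `"rem_nrem"`.
#' @param horizons Integer vector of horizons in minutes (default -8..2).
#' @param n_folds Number of random half/half splits (default 10).
#' @param seed Integer seed for the fold draws.
#' @return An object of class `sw_forecast`: `auc_full` and `auc_trivial`
#'   (folds x horizons matrices), `coefs` (coefficient x horizon x fold
#'   array, standardised, full model), `horizons`, `direction`,
#'   `fold_train` (list of training-night indices).
#' @export
cross_validate <- function(nights, direction = c("nrem_rem", "rem_nrem"),
                           horizons = -8:2, n_folds = 10, seed = 1) {
  direction <- match.arg(direction)
  n <- length(nights)
  if (n < 4) stop("need at least 4 nights for night-level cross-validation")
  tables <- lapply(seq_along(nights), function(i)
    night_minute_table(nights[[i]]$bandpower, nights[[i]]$hypnogram,
                       night_id = paste0("night", i)))
  nms <- paste0("h", horizons)
  auc_full <- matrix(NA_real_, n_folds, length(horizons),
                     dimnames = list(NULL, nms))
  auc_triv <- auc_full
  coef_names <- c("(Intercept)", .full_features())
  coefs <- array(NA_real_, c(length(coef_names), length(horizons), n_folds),
                 dimnames = list(coef_names, nms, NULL))
  folds <- with_seed(split_seed(seed, paste0("cv_", direction)), {
    lapply(seq_len(n_folds), function(f) sort(sample(n, floor(n / 2))))
  })
  for (f in seq_len(n_folds)) {
    tr <- folds[[f]]
    te <- setdiff(seq_len(n), tr)
    for (hi in seq_along(horizons)) {
      h <- horizons[hi]
      dtr <- build_design(NULL, direction, h, tables = tables[tr])
      dte <- build_design(NULL, direction, h, tables = tables[te])
      if (sum(dtr$labels) < 2 || length(unique(dte$labels)) < 2) next
      full <- tryCatch(fit_ppglm(dtr$rows, dtr$labels, direction, h),
                       error = function(e) NULL)
      triv <- tryCatch(fit_trivial(dtr$rows, dtr$labels, direction, h),
                       error = function(e) NULL)
      if (!is.null(full)) {
        auc_full[f, hi] <- auc_score(dte$labels, predict(full, dte$rows))
        coefs[, hi, f] <- full$coefficients
      }
      if (!is.null(triv))
        auc_triv[f, hi] <- auc_score(dte$labels, predict(triv, dte$rows))
    }
  }
  structure(list(auc_full = auc_full, auc_trivial = auc_triv,
                 coefs = coefs, horizons = horizons, direction = direction,
                 fold_train = folds, tables = tables, seed = seed),
            class = "sw_forecast")
}

#' @export
print.sw_forecast <- function(x, ...) {
  cat(sprintf("<sw_forecast> %s, %d folds x %d horizons\n", x$direction,
              nrow(x$auc_full), length(x$horizons)))
  m <- rbind(full = colMeans(x$auc_full, na.rm = TRUE),
             trivial = colMeans(x$auc_trivial, na.rm = TRUE))
  print(round(m, 3))
  invisible(x)
}

#' Surrogate-based significance by horizon
#'
#' Declares a horizon significant only under the strict rule that every
#' fold AUC of the spectral model exceeds every fold AUC of the trivial
#' model AND every surrogate AUC. Surrogate models are trained on nights
#' whose stage sequence is circularly shifted in time relative to the band
#' powers (preserving feature autocorrelation) and evaluated on unshifted
#' test nights.
#'
#' @param result An `sw_forecast` from [cross_validate()].
#' @param surrogates Number of surrogate re-trainings (default 20; fewer
#'   than 10 triggers a warning).
#' @param seed Integer seed for shifts and the surrogate split.
#' @return An object of class `sw_significance`: `significant_horizons`
#'   (integer vector), per-horizon `detail`, and the surrogate AUC matrix.
#' @export
significance_by_horizon <- function(result, surrogates = 20, seed = 1) {
  stopifnot(inherits(result, "sw_forecast"))
  if (nrow(result$auc_full) < 2) stop("need at least 2 folds")
  if (surrogates < 10)
    warning("fewer than 10 surrogates gives a weak significance floor")
  tables <- result$tables
  n <- length(tables)
  horizons <- result$horizons
  surr_auc <- matrix(NA_real_, surrogates, length(horizons),
                     dimnames = list(NULL, colnames(result$auc_full)))
  with_seed(split_seed(seed, paste0("surr_", result$direction)), {
    for (s in seq_len(surrogates)) {
      tr <- sort(sample(n, floor(n / 2)))
      te <- setdiff(seq_len(n), tr)
      shifted <- lapply(tables[tr], function(tb) {
        k <- sample(5:(nrow(tb) - 5), 1)
        stage_shifted <- tb$stage[c((k + 1):nrow(tb), 1:k)]
        r <- rle(stage_shifted)
        tb$stage <- stage_shifted
        tb$run_id <- rep(seq_along(r$lengths), r$lengths)
        tb$T_stage <- unlist(lapply(r$lengths, seq_len), use.names = FALSE)
        tb
      })
      for (hi in seq_along(horizons)) {
        h <- horizons[hi]
        dtr <- build_design(NULL, result$direction, h, tables = shifted)
        dte <- build_design(NULL, result$direction, h, tables = tables[te])
        if (sum(dtr$labels) < 2 || length(unique(dte$labels)) < 2) next
        fit <- tryCatch(fit_ppglm(dtr$rows, dtr$labels),
                        error = function(e) NULL)
        if (!is.null(fit))
          surr_auc[s, hi] <- auc_score(dte$labels, predict(fit, dte$rows))
      }
    }
  })
  detail <- data.frame(
    horizon = horizons,
    min_full = apply(result$auc_full, 2, function(v)
      if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)),
    max_trivial = apply(result$auc_trivial, 2, function(v)
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)),
    max_surrogate = apply(surr_auc, 2, function(v)
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)))
  detail$significant <- !is.na(detail$min_full) &
    !is.na(detail$max_trivial) & !is.na(detail$max_surrogate) &
    detail$min_full > detail$max_trivial &
    detail$min_full > detail$max_surrogate
  structure(list(significant_horizons = horizons[detail$significant],
                 detail = detail, surrogate_auc = surr_auc),
            class = "sw_significance")
}

#' @export
print.sw_significance <- function(x, ...) {
  cat("<sw_significance> significant horizons:",
      if (length(x$significant_horizons))
        paste(x$significant_horizons, collapse = ", ") else "none", "\n")
  print(round(x$detail[, -1], 3))
  invisible(x)
}

#' Model coefficients by horizon
#'
#' Mean and SD over folds of the standardised spectral-model coefficients,
#' tabulated per horizon (the per-band weights of Fig.-style coefficient
#' plots).
#'
#' @param result An `sw_forecast` from [cross_validate()].
#' @return A data frame: `horizon`, `feature`, `estimate`, `sd`.
#' @export
coefficients_by_horizon <- function(result) {
  stopifnot(inherits(result, "sw_forecast"))
  feats <- c("T_stage", band_names())
  out <- expand.grid(horizon = result$horizons, feature = feats,
                     stringsAsFactors = FALSE)
  out$estimate <- NA_real_
  out$sd <- NA_real_
  for (i in seq_len(nrow(out))) {
    hi <- match(out$horizon[i], result$horizons)
    v <- result$coefs[out$feature[i], hi, ]
    out$estimate[i] <- mean(v, na.rm = TRUE)
    out$sd[i] <- sd(v, na.rm = TRUE)
  }
  out
}
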