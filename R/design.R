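# Design construction for transition forecasting: 1-min rows carrying the
# time already spent in the current (collapsed NREM/REM) stage and the five
# log10 band powers averaged over the preceding minute, with labels marking
# minutes a fixed horizon away from a scored stage transition. Negative
# horizons are prediction (the transition lies ahead); horizons in (0, +2]
# are detection (the transition already occurred). Wake bouts break stage
# runs and contribute no rows.

collapse_stage <- function(labels) {
  ifelse(labels %in% c("N1", "N2", "N3"), "NREM",
         ifelse(labels == "REM", "REM", "W"))
}

# one night's minute-resolution table shared by all horizons
night_minute_table <- function(bp, hyp, night_id = "night") {
  stopifnot(inherits(bp, "sw_bandpower"), inherits(hyp, "sw_hypnogram"))
  bins_per_min <- 60 / bp$bin_s
  epochs_per_min <- 60 / hyp$epoch_s
  n_min <- floor(hyp_duration_s(hyp) / 60)
  # stage of a minute = stage of its last epoch
  stage <- collapse_stage(hyp$labels[pmin(seq_len(n_min) * epochs_per_min,
                                          n_epochs(hyp))])
  r <- rle(stage)
  run_id <- rep(seq_along(r$lengths), r$lengths)
  t_stage <- unlist(lapply(r$lengths, seq_len), use.names = FALSE)
  feats <- matrix(NA_real_, n_min, 5,
                  dimnames = list(NULL, band_names()))
  valid <- logical(n_min)
  for (m in seq_len(n_min)) {
    # a row is stamped at instant t = m minutes; its features average the
    # preceding 1-min window (t-1, t], i.e. the bins of minute m
    idx <- (m - 1) * bins_per_min + seq_len(bins_per_min)
    idx <- idx[idx <= n_bins(bp)]
    if (length(idx) && all(bp$valid[idx])) {
      feats[m, ] <- log10(rowMeans(bp$values[, idx, drop = FALSE]))
      valid[m] <- TRUE
    }
  }
  data.frame(night_id = night_id, t = seq_len(n_min), stage = stage,
             run_id = run_id, T_stage = t_stage, feats,
             valid = valid, stringsAsFactors = FALSE)
}

#' Build a forecasting design matrix
#'
#' Assembles 1-min design rows and transition labels for one direction and
#' horizon across a set of nights. Rows are minutes spent in the source
#' stage (collapsed NREM or REM); for positive (detection) horizons the
#' first `horizon_min` minutes of each target run are added, since the
#' labelled minute then lies after the transition. `label = 1` marks the
#' minute exactly `horizon_min` away from a scored source-to-target
#' transition (direct transitions only; wake bouts break runs).
#'
#' @param nights List of nights; each element needs `$bandpower` and
#'   `$hypnogram` (e.g. [generate_night()] output), or pass precomputed
#'   minute tables via `tables`.
#' @param direction `"nrem_rem"` (NREM to REM) or `"rem_nrem"`.
#' @param horizon_min Integer horizon in minutes, in `[-8, 2]`.
#' @param tables Optional precomputed list from internal minute tables
#'   (used by [cross_validate()] to avoid recomputation).
#' @return A list: `rows` (data frame of predictors `T_stage`,
#'   `delta`..`beta` plus bookkeeping columns) and `labels` (0/1 vector).
#' @export
build_design <- function(nights, direction = c("nrem_rem", "rem_nrem"),
                         horizon_min, tables = NULL) {
  direction <- match.arg(direction)
  if (horizon_min < -8 || horizon_min > 2)
    stop("horizon_min must lie in [-8, 2]")
  if (is.null(tables))
    tables <- lapply(seq_along(nights), function(i)
      night_minute_table(nights[[i]]$bandpower, nights[[i]]$hypnogram,
                         night_id = paste0("night", i)))
  src <- if (direction == "nrem_rem") "NREM" else "REM"
  tgt <- if (direction == "nrem_rem") "REM" else "NREM"
  h <- as.integer(horizon_min)
  out <- lapply(tables, function(tb) {
    runs <- tb[!duplicated(tb$run_id), c("run_id", "stage")]
    run_last <- tapply(tb$t, tb$run_id, max)
    run_first <- tapply(tb$t, tb$run_id, min)
    # transitions: source run directly followed by target run
    trans_T <- integer(0)
    for (i in seq_len(nrow(runs) - 1)) {
      if (runs$stage[i] == src && runs$stage[i + 1] == tgt)
        trans_T <- c(trans_T, run_last[[as.character(runs$run_id[i])]])
    }
    keep <- tb$stage == src & tb$valid
    if (h > 0 && length(trans_T)) {
      # detection horizons: include the first max(h, 2) minutes of each
      # target run so labelled and unlabelled target minutes coexist and
      # the fit cannot separate on stage membership alone
      span <- max(h, 2)
      det <- tb$stage == tgt & tb$valid &
        tb$t %in% unlist(lapply(trans_T, function(T0) (T0 + 1):(T0 + span)))
      keep <- keep | det
    }
    rows <- tb[keep, , drop = FALSE]
    lab <- as.integer(rows$t %in% (trans_T + h) &
                        (if (h <= 0) rows$stage == src else rows$stage == tgt))
    # a labelled minute must belong to the run that transitions
    if (h <= 0 && any(lab == 1)) {
      for (ii in which(lab == 1)) {
        T0 <- rows$t[ii] - h
        run_end_here <- run_last[[as.character(rows$run_id[ii])]]
        if (run_end_here != T0) lab[ii] <- 0L
      }
    }
    list(rows = rows, labels = lab)
  })
  rows <- do.call(rbind, lapply(out, `[[`, "rows"))
  labels <- unlist(lapply(out, `[[`, "labels"), use.names = FALSE)
  rownames(rows) <- NULL
  list(rows = rows, labels = labels, direction = direction,
       horizon_min = h)
}
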