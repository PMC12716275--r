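# Night feature matrices for warping: cropped to the sleep period,
# down-averaged to the DTW resolution, z-scored per band, with typed
# quality-control rejection of nights that fail the inclusion criteria.

#' Build a night's warping features
#'
#' Crops the band-power series to the sleep period (sleep onset to final
#' awakening), down-averages the 12-s bins to `resolution_s`, z-scores each
#' band over the night, and attaches per-bin stage labels. Nights shorter
#' than 1.5 NREM-REM cycles (operationalised as fewer than two cycle
#' onsets) are rejected with QC reason `"min-cycles"`; nights with more
#' than `max_invalid_frac` invalid bins after sleep onset with reason
#' `"disconnection"`. Remaining isolated invalid bins are linearly
#' interpolated. Rejections are signalled as classed conditions that
#' [is_qc_error()] recognises.
#'
#' @param series A [band_power_series()] (linear power).
#' @param hyp The matching [hypnogram()].
#' @param resolution_s Target bin length in seconds (default 60; must be a
#'   multiple of the series bin length).
#' @param night_id,subject_id Identifiers carried into downstream tables.
#' @param night_index Calendar night index within subject (used for the
#'   adjacent-night exclusion in [pairwise_dissimilarity()]).
#' @param min_cycles Minimum number of cycle onsets (default 2).
#' @param max_invalid_frac Maximum tolerated fraction of invalid bins.
#' @return An object of class `sw_night_features`: `matrix` (5 x L,
#'   z-scored), `bin_s`, `stages` (length L), `night_id`, `subject_id`,
#'   `night_index`, `sleep_onset_bin`.
#' @export
build_night_features <- function(series, hyp, resolution_s = 60,
                                 night_id = "night", subject_id = "subject",
                                 night_index = 1L, min_cycles = 2,
                                 max_invalid_frac = 0.2) {
  stopifnot(inherits(series, "sw_bandpower"), inherits(hyp, "sw_hypnogram"))
  if (resolution_s %% series$bin_s != 0)
    stop("resolution_s must be a multiple of the series bin length")
  sleep <- which(hyp$labels != "W")
  if (length(sleep) == 0) qc_error("no-sleep", "night contains no sleep")
  cyc <- segment_cycles(hyp)
  if (nrow(cyc) < min_cycles)
    qc_error("min-cycles",
             sprintf("night has %d cycle onset(s); need %d (1.5-cycle rule)",
                     nrow(cyc), min_cycles))
  on_s <- (min(sleep) - 1) * hyp$epoch_s
  off_s <- max(sleep) * hyp$epoch_s
  b0 <- floor(on_s / series$bin_s) + 1
  b1 <- min(n_bins(series), floor(off_s / series$bin_s))
  vals <- series$values[, b0:b1, drop = FALSE]
  valid <- series$valid[b0:b1]
  if (mean(!valid) > max_invalid_frac)
    qc_error("disconnection",
             sprintf("%.0f%% of bins after sleep onset are invalid",
                     100 * mean(!valid)))
  fac <- resolution_s / series$bin_s
  L <- floor(ncol(vals) / fac)
  if (L < 10) qc_error("too-short", "fewer than 10 feature bins")
  grp <- rep(seq_len(L), each = fac)
  idx <- seq_len(L * fac)
  mat <- matrix(NA_real_, 5, L, dimnames = list(band_names(), NULL))
  for (b in 1:5) {
    v <- vals[b, idx]
    v[!valid[idx]] <- NA
    mat[b, ] <- tapply(v, grp, mean, na.rm = TRUE)
    if (anyNA(mat[b, ])) {  # interpolate bins that were fully invalid
      ok <- which(!is.na(mat[b, ]))
      mat[b, ] <- approx(ok, mat[b, ok], xout = seq_len(L), rule = 2)$y
    }
    s <- sd(mat[b, ])
    if (s == 0) stop("zero variance in band ", band_names()[b])
    mat[b, ] <- (mat[b, ] - mean(mat[b, ])) / s
  }
  centers <- on_s + (seq_len(L) - 0.5) * resolution_s
  structure(list(matrix = mat, bin_s = resolution_s,
                 stages = stage_at(hyp, centers),
                 night_id = night_id, subject_id = subject_id,
                 night_index = as.integer(night_index),
                 sleep_onset_bin = 1L),
            class = "sw_night_features")
}

#' @export
print.sw_night_features <- function(x, ...) {
  cat(sprintf("<sw_night_features> %s/%s: 5 x %d bins of %gs\n",
              x$subject_id, x$night_id, ncol(x$matrix), x$bin_s))
  invisible(x)
}
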