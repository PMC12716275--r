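# Pre-processing and time-frequency decomposition: artefact masking by
# voltage / line-length rules, DPSS multitaper band powers on 12-s bins,
# per-band z-scoring, and the periodicity spectrum of the sigma envelope.

#' Mask artefacts in a recording
#'
#' Flags 1-s windows whose peak voltage or line-length (mean absolute first
#' difference times the sampling rate) exceeds the given thresholds, or
#' whose line-length falls below a flatline floor (disconnection). Sample
#' values are never altered; only the usability mask changes.
#'
#' @param rec A [recording()].
#' @param voltage_thresh Peak-voltage threshold in uV (default 350, the
#'   device dynamic range).
#' @param linelength_thresh Upper line-length threshold in uV/s (default
#'   12000, the 99.9th percentile observed on clean synthetic N2/N3 signal).
#' @param flat_thresh Lower line-length floor in uV/s below which a window
#'   is treated as a disconnection (default 50; set to 0 to disable).
#' @param window_s Analysis window in seconds (default 1).
#' @return The recording with its mask updated.
#' @export
mask_artifacts <- function(rec, voltage_thresh = 350,
                           linelength_thresh = 12000, flat_thresh = 50,
                           window_s = 1) {
  stopifnot(inherits(rec, "sw_recording"))
  if (length(rec$samples) == 0) stop("recording is empty")
  if (voltage_thresh <= 0 || linelength_thresh <= 0)
    stop("thresholds must be positive")
  w <- round(window_s * rec$fs)
  n_w <- floor(length(rec$samples) / w)
  if (n_w == 0) return(rec)
  seg <- matrix(rec$samples[seq_len(n_w * w)], nrow = w)
  vmax <- apply(abs(seg), 2, max)
  ll <- colMeans(abs(diff(seg))) * rec$fs
  bad <- vmax > voltage_thresh | ll > linelength_thresh | ll < flat_thresh
  bad_samples <- rep(bad, each = w)
  rec$mask[seq_len(n_w * w)] <- rec$mask[seq_len(n_w * w)] & !bad_samples
  rec
}

# Discrete prolate spheroidal (Slepian) tapers via the standard symmetric
# tridiagonal eigenproblem. For long windows the tapers are computed at a
# reduced length and spline-interpolated, which is accurate for the small
# time-bandwidth products used here.
dpss_tapers <- function(n, nw = 4, k = 7) {
  key <- sprintf("dpss_%d_%g_%d", n, nw, k)
  if (!is.null(.sw_cache[[key]])) return(.sw_cache[[key]])
  n_eff <- if (n > 1200) 1201L else n
  w <- nw / n_eff
  t <- 0:(n_eff - 1)
  diag_v <- ((n_eff - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  off_v <- t[-1] * (n_eff - t[-1]) / 2
  m <- diag(diag_v)
  m[cbind(1:(n_eff - 1), 2:n_eff)] <- off_v
  m[cbind(2:n_eff, 1:(n_eff - 1))] <- off_v
  ev <- eigen(m, symmetric = TRUE)
  tap <- ev$vectors[, seq_len(k), drop = FALSE]
  if (n_eff < n) {
    x0 <- seq(0, 1, length.out = n_eff)
    x1 <- seq(0, 1, length.out = n)
    tap <- apply(tap, 2, function(v) stats::spline(x0, v, xout = x1)$y)
  }
  # normalise to unit energy; fix sign so each taper starts upward
  tap <- apply(tap, 2, function(v) {
    v <- v / sqrt(sum(v^2))
    if (sum(v) < 0 || (abs(sum(v)) < 1e-8 && v[2] < 0)) v <- -v
    v
  })
  .sw_cache[[key]] <- tap
  tap
}

#' Multitaper five-band power series
#'
#' Computes a DPSS multitaper power spectral density in consecutive
#' non-overlapping bins (default 12 s, seven tapers) and integrates it over
#' the five canonical bands (trapezoidal rule over PSD bins whose centres
#' fall in `[low, high)`). Bins with more than half of their samples masked
#' are flagged invalid; sparser masked samples are linearly interpolated
#' before tapering.
#'
#' @param rec A [recording()].
#' @param bin_s Bin length in seconds (default 12).
#' @param n_tapers Number of DPSS tapers (default 7).
#' @param nw Time-bandwidth product (default 4, pairing 7 tapers with
#'   `2 * nw - 1`).
#' @return A [band_power_series()].
#' @export
multitaper_bandpower <- function(rec, bin_s = 12, n_tapers = 7, nw = 4) {
  stopifnot(inherits(rec, "sw_recording"))
  if (rec$fs <= 60)
    stop("sampling rate too low to resolve the 16-30 Hz beta band")
  if (n_tapers > 2 * nw - 1)
    stop(sprintf(paste0("n_tapers = %d incompatible with time-bandwidth ",
                        "product nw = %g: at most 2*nw-1 = %d tapers are ",
                        "well concentrated"), n_tapers, nw, 2 * nw - 1))
  nseg <- round(bin_s * rec$fs)
  n_b <- floor(length(rec$samples) / nseg)
  if (n_b < 1) stop("recording shorter than one bin")
  tap <- dpss_tapers(nseg, nw, n_tapers)
  freqs <- (0:(nseg - 1)) * rec$fs / nseg
  half <- freqs > 0 & freqs < rec$fs / 2
  f_pos <- freqs[half]
  be <- band_edges()
  sel <- lapply(seq_len(nrow(be)), function(b)
    which(f_pos >= be[b, 1] & f_pos < be[b, 2]))

  vals <- matrix(NA_real_, 5, n_b, dimnames = list(band_names(), NULL))
  valid <- rep(TRUE, n_b)
  chunk <- 256L
  for (c0 in seq(1, n_b, by = chunk)) {
    cols <- c0:min(c0 + chunk - 1L, n_b)
    seg <- matrix(rec$samples[(cols[1] - 1) * nseg +
                                seq_len(nseg * length(cols))], nrow = nseg)
    mseg <- matrix(rec$mask[(cols[1] - 1) * nseg +
                              seq_len(nseg * length(cols))], nrow = nseg)
    frac_bad <- 1 - colMeans(mseg)
    valid[cols] <- frac_bad <= 0.5
    for (j in seq_along(cols)) {
      if (!valid[cols[j]]) next
      if (frac_bad[j] > 0) {
        good <- which(mseg[, j])
        seg[, j] <- approx(good, seg[good, j], xout = seq_len(nseg),
                           rule = 2)$y
      }
      seg[, j] <- seg[, j] - mean(seg[, j])
    }
    ok <- which(valid[cols])
    if (length(ok) == 0) next
    psd <- 0
    for (k in seq_len(n_tapers)) {
      F <- stats::mvfft(seg[, ok, drop = FALSE] * tap[, k])
      psd <- psd + (2 / rec$fs) * Mod(F[half, , drop = FALSE])^2
    }
    psd <- psd / n_tapers
    for (b in 1:5) {
      s <- sel[[b]]
      vals[b, cols[ok]] <- apply(psd[s, , drop = FALSE], 2,
                                 function(y) trapz(f_pos[s], y))
    }
  }
  band_power_series(vals, bin_s = bin_s, valid = valid,
                    start_time = rec$start_time)
}

#' Z-score band powers
#'
#' Standardises each band to mean 0 / SD 1 over valid bins. With
#' `scope = "night"` a single series is standardised within itself; with
#' `scope = "subject"` a list of series is standardised with pooled
#' per-band moments.
#'
#' @param series A [band_power_series()], or a list of them when
#'   `scope = "subject"`.
#' @param scope Normalisation scope.
#' @return The standardised series (or list of series).
#' @export
zscore_bands <- function(series, scope = c("night", "subject")) {
  scope <- match.arg(scope)
  if (scope == "subject") {
    stopifnot(is.list(series), all(vapply(series, inherits, TRUE,
                                          "sw_bandpower")))
    pooled <- do.call(cbind, lapply(series, function(s)
      s$values[, s$valid, drop = FALSE]))
    if (ncol(pooled) < 2) stop("need at least 2 valid bins")
    m <- rowMeans(pooled)
    s <- apply(pooled, 1, sd)
    if (any(s == 0))
      stop("zero variance in band(s): ",
           paste(band_names()[s == 0], collapse = ", "))
    return(lapply(series, function(x) {
      x$values[, x$valid] <- (x$values[, x$valid] - m) / s
      x
    }))
  }
  stopifnot(inherits(series, "sw_bandpower"))
  v <- series$valid
  if (sum(v) < 2) stop("need at least 2 valid bins")
  m <- rowMeans(series$values[, v, drop = FALSE])
  s <- apply(series$values[, v, drop = FALSE], 1, sd)
  if (any(s == 0))
    stop("zero variance in band(s): ",
         paste(band_names()[s == 0], collapse = ", "))
  series$values[, v] <- (series$values[, v] - m) / s
  series
}

#' Periodicity spectrum of the sigma-band envelope
#'
#' Band-passes the recording at 11-16 Hz, computes the envelope (magnitude
#' of the analytic signal, or squared magnitude with
#' `envelope = "power"`), decimates it, and returns a Welch spectrum of the
#' envelope below 1 Hz computed over contiguous N2/N3 runs. Peaks in the
#' 0.1-1 Hz and 0.01-0.05 Hz ranges reflect the slow (~4-5 s) and
#' infra-slow (~40-50 s) periodicity of spindle activity.
#'
#' @param rec A [recording()].
#' @param n2n3_mask Per-sample logical, `TRUE` where the night is scored
#'   N2 or N3 (see [stage_sample_mask()]... construct from a hypnogram).
#' @param seg_s Welch segment length in seconds (default 180).
#' @param envelope Envelope definition.
#' @return An object of class `sw_envspec` with `freqs` (Hz) and `power`.
#' @export
sigma_envelope_spectrum <- function(rec, n2n3_mask, seg_s = 180,
                                    envelope = c("analytic", "power")) {
  stopifnot(inherits(rec, "sw_recording"))
  envelope <- match.arg(envelope)
  if (length(n2n3_mask) != length(rec$samples))
    stop("n2n3_mask length must equal samples length")
  if (sum(n2n3_mask) < 5 * 60 * rec$fs)
    stop("need at least 5 minutes of N2/N3 signal")
  bf <- signal::butter(4, c(11, 16) / (rec$fs / 2), type = "pass")
  filt <- signal::filtfilt(bf, rec$samples)
  env <- Mod(analytic_signal(filt))
  if (envelope == "power") env <- env^2
  # decimate by block averaging to ~9 Hz; a block is N2/N3 if fully inside
  dec <- 23L
  n_blk <- floor(length(env) / dec)
  fs_e <- rec$fs / dec
  env_d <- colMeans(matrix(env[seq_len(n_blk * dec)], nrow = dec))
  mask_d <- colMeans(matrix(n2n3_mask[seq_len(n_blk * dec)],
                            nrow = dec)) == 1
  seg_n <- round(seg_s * fs_e)
  runs <- true_runs(mask_d)
  runs <- runs[runs[, "end"] - runs[, "start"] + 1 >= seg_n, , drop = FALSE]
  if (nrow(runs) == 0)
    stop(sprintf("no contiguous N2/N3 run of at least %gs", seg_s))
  win <- 0.5 * (1 - cos(2 * pi * seq_len(seg_n) / (seg_n + 1)))
  acc <- 0; n_seg <- 0
  for (k in seq_len(nrow(runs))) {
    idx <- runs[k, "start"]:runs[k, "end"]
    step <- floor(seg_n / 2)
    for (s0 in seq(1, length(idx) - seg_n + 1, by = step)) {
      x <- env_d[idx[s0:(s0 + seg_n - 1)]]
      x <- stats::resid(lm(x ~ seq_along(x)))  # detrend
      X <- fft(x * win)
      acc <- acc + Mod(X)^2 / (fs_e * sum(win^2))
      n_seg <- n_seg + 1
    }
  }
  psd <- 2 * acc / n_seg
  freqs <- (0:(seg_n - 1)) * fs_e / seg_n
  keep <- freqs > 0 & freqs < 1
  structure(list(freqs = freqs[keep], power = psd[keep],
                 band_source = "sigma", n_segments = n_seg),
            class = "sw_envspec")
}

#' @export
print.sw_envspec <- function(x, ...) {
  cat(sprintf("<sw_envspec> %d frequencies < 1 Hz from %d segment(s)\n",
              length(x$freqs), x$n_segments))
  cat(sprintf("  slow peak %.3f Hz (%.1f s), infra-slow peak %.4f Hz (%.0f s)\n",
              envelope_peak(x, c(0.1, 1)), 1 / envelope_peak(x, c(0.1, 1)),
              envelope_peak(x, c(0.01, 0.05)),
              1 / envelope_peak(x, c(0.01, 0.05))))
  invisible(x)
}

#' Locate the peak of an envelope spectrum in a frequency range
#'
#' @param spec An `sw_envspec` from [sigma_envelope_spectrum()].
#' @param f_range Two-element numeric range in Hz.
#' @return Frequency (Hz) of the maximum power inside the range.
#' @export
envelope_peak <- function(spec, f_range) {
  stopifnot(inherits(spec, "sw_envspec"), length(f_range) == 2)
  sel <- spec$freqs >= f_range[1] & spec$freqs <= f_range[2]
  if (!any(sel)) stop("no frequencies in requested range")
  spec$freqs[sel][which.max(spec$power[sel])]
}
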