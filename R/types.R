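# Core containers. Light-weight S3 lists: a recording (raw samples + usable
# mask), a hypnogram (30-s stage labels) and a band-power series (5 x L
# matrix on a 12-s grid).

#' Construct a recording
#'
#' A single-channel EEG recording for one night: raw samples in microvolts,
#' sampling rate, and a per-sample usability mask (`TRUE` = usable).
#'
#' @param samples Numeric vector of EEG samples (uV).
#' @param fs Sampling rate in Hz (nominal 207 for sub-scalp devices).
#' @param channels Character vector of channel labels.
#' @param mask Logical vector, same length as `samples`; `TRUE` marks usable
#'   samples. Defaults to all usable.
#' @param start_time Clock time of the first sample, seconds from midnight.
#' @return An object of class `sw_recording`.
#' @export
recording <- function(samples, fs = 207, channels = "sqEEG",
                      mask = NULL, start_time = 0) {
  stopifnot(is.numeric(samples), fs > 0)
  if (is.null(mask)) mask <- rep(TRUE, length(samples))
  if (length(mask) != length(samples))
    stop("mask length must equal samples length")
  structure(list(samples = as.numeric(samples), fs = fs,
                 channels = channels, mask = as.logical(mask),
                 start_time = start_time),
            class = "sw_recording")
}

#' @export
print.sw_recording <- function(x, ...) {
  cat(sprintf("<sw_recording> %.1f min at %g Hz, %.1f%% usable\n",
              length(x$samples) / x$fs / 60, x$fs, 100 * mean(x$mask)))
  invisible(x)
}

#' Construct a hypnogram
#'
#' Per-epoch sleep stage labels (default 30-s epochs) aligned to the
#' recording clock. Stages follow the conventional five-level scheme
#' W / N1 / N2 / N3 / REM.
#'
#' @param labels Character vector of stage labels.
#' @param epoch_s Epoch duration in seconds (default 30).
#' @param start_time Clock time of the first epoch, seconds from midnight.
#' @return An object of class `sw_hypnogram`.
#' @export
hypnogram <- function(labels, epoch_s = 30, start_time = 0) {
  labels <- as.character(labels)
  if (length(labels) == 0) stop("hypnogram labels must be non-empty")
  if (epoch_s <= 0) stop("epoch_s must be positive")
  bad <- setdiff(unique(labels), stage_levels())
  if (length(bad))
    stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  structure(list(labels = labels, epoch_s = epoch_s, start_time = start_time),
            class = "sw_hypnogram")
}

#' @export
print.sw_hypnogram <- function(x, ...) {
  tab <- table(factor(x$labels, levels = stage_levels()))
  cat(sprintf("<sw_hypnogram> %d epochs of %gs (%.1f h)\n",
              length(x$labels), x$epoch_s,
              length(x$labels) * x$epoch_s / 3600))
  cat("  ", paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

n_epochs <- function(hyp) length(hyp$labels)
hyp_duration_s <- function(hyp) length(hyp$labels) * hyp$epoch_s

# stage label at arbitrary times (seconds from hypnogram start)
stage_at <- function(hyp, t_s) {
  idx <- pmin(pmax(floor(t_s / hyp$epoch_s) + 1, 1L), n_epochs(hyp))
  hyp$labels[idx]
}

# per-sample logical: sample lies in one of `stages`
stage_sample_mask <- function(hyp, fs, n, stages = c("N2", "N3")) {
  t_s <- (seq_len(n) - 0.5) / fs
  stage_at(hyp, t_s) %in% stages
}

#' Construct a band-power series
#'
#' A 5 x L matrix of band powers (rows delta, theta, alpha, sigma, beta; uV^2)
#' on a regular grid (default 12-s bins), with a per-bin validity flag.
#'
#' @param values 5 x L numeric matrix, rows in canonical band order.
#' @param bin_s Bin duration in seconds (default 12).
#' @param valid Logical vector of length L; invalid bins carry no usable
#'   power estimate (artefact or disconnection).
#' @param start_time Clock time of the first bin, seconds from midnight.
#' @return An object of class `sw_bandpower`.
#' @export
band_power_series <- function(values, bin_s = 12, valid = NULL,
                              start_time = 0) {
  values <- as.matrix(values)
  if (nrow(values) != 5)
    stop("band-power matrix must have 5 rows (delta..beta)")
  dimnames(values) <- list(band_names(), NULL)
  if (is.null(valid)) valid <- rep(TRUE, ncol(values))
  if (length(valid) != ncol(values))
    stop("valid flag length must equal number of bins")
  if (any(values[, valid] < 0, na.rm = TRUE))
    stop("band powers must be non-negative where valid")
  structure(list(values = values, bin_s = bin_s, valid = as.logical(valid),
                 band_edges = band_edges(), start_time = start_time),
            class = "sw_bandpower")
}

#' @export
print.sw_bandpower <- function(x, ...) {
  cat(sprintf("<sw_bandpower> 5 x %d bins of %gs (%.1f h), %.1f%% valid\n",
              ncol(x$values), x$bin_s, ncol(x$values) * x$bin_s / 3600,
              100 * mean(x$valid)))
  invisible(x)
}

n_bins <- function(bp) ncol(bp$values)
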