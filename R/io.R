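# Plain-text interchange: hypnograms and band powers as TSV, events as
# BED-like TSV, dissimilarity matrices as TSV, models and ground truth as
# JSON, dendrograms as Newick (see clustering.R).

#' Write a hypnogram to TSV
#'
#' Columns: `epoch_index`, `clock_time` (seconds from midnight at epoch
#' start) and `stage`.
#'
#' @param hyp A [hypnogram()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_hypnogram_tsv <- function(hyp, path) {
  stopifnot(inherits(hyp, "sw_hypnogram"))
  df <- data.frame(epoch_index = seq_len(n_epochs(hyp)),
                   clock_time = hyp$start_time +
                     (seq_len(n_epochs(hyp)) - 1) * hyp$epoch_s,
                   stage = hyp$labels)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a hypnogram from TSV
#'
#' @param path File written by [write_hypnogram_tsv()].
#' @return A [hypnogram()].
#' @export
read_hypnogram_tsv <- function(path) {
  df <- read.delim(path)
  epoch_s <- if (nrow(df) > 1) df$clock_time[2] - df$clock_time[1] else 30
  hypnogram(df$stage, epoch_s = epoch_s, start_time = df$clock_time[1])
}

#' Write a band-power series to TSV
#'
#' Columns: `time_s` (bin start), `delta`, `theta`, `alpha`, `sigma`,
#' `beta`. Invalid bins are written as `NA`.
#'
#' @param bp A [band_power_series()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_bandpower_tsv <- function(bp, path) {
  stopifnot(inherits(bp, "sw_bandpower"))
  v <- bp$values
  v[, !bp$valid] <- NA
  df <- data.frame(time_s = bp$start_time + (seq_len(n_bins(bp)) - 1) *
                     bp$bin_s, t(v))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a band-power series from TSV
#'
#' @param path File written by [write_bandpower_tsv()].
#' @return A [band_power_series()].
#' @export
read_bandpower_tsv <- function(path) {
  df <- read.delim(path)
  vals <- t(as.matrix(df[, band_names()]))
  valid <- !apply(is.na(vals), 2, any)
  vals[, !valid] <- 0
  bin_s <- if (nrow(df) > 1) df$time_s[2] - df$time_s[1] else 12
  band_power_series(vals, bin_s = bin_s, valid = valid,
                    start_time = df$time_s[1])
}

#' Write detected events to BED-like TSV
#'
#' Columns: `night_id`, `onset_s`, `offset_s`, `type`, `amplitude`.
#'
#' @param events Event data frame (spindles or slow waves).
#' @param path Output file.
#' @param night_id Identifier for the night.
#' @param type Event type string (e.g. `"spindle"`).
#' @return The path, invisibly.
#' @export
write_events_tsv <- function(events, path, night_id = "night",
                             type = "spindle") {
  onset <- if ("onset_s" %in% names(events)) events$onset_s
           else events$trough_s
  offset <- if ("offset_s" %in% names(events)) events$offset_s
            else events$peak_s
  amp <- if ("peak_amplitude" %in% names(events)) events$peak_amplitude
         else events$peak_to_peak
  df <- data.frame(night_id = night_id, onset_s = onset, offset_s = offset,
                   type = type, amplitude = amp)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a dissimilarity matrix to TSV
#'
#' @param dis An `sw_dissimilarity` (or plain matrix).
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_dissimilarity_tsv <- function(dis, path) {
  m <- if (inherits(dis, "sw_dissimilarity")) dis$matrix else dis
  write.table(data.frame(night_id = rownames(m), m, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
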