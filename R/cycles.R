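# NREM-REM cycle segmentation and classical per-night summary statistics.

#' Segment a hypnogram into NREM-REM cycles
#'
#' A cycle is a maximal NREM run of at least `min_nrem_min` minutes
#' (ignoring wake interruptions shorter than `max_interrupt_min`) together
#' with the REM run that follows it; the terminal cycle may lack REM.
#' Cycle boundaries are placed at NREM onsets.
#'
#' @param hyp A [hypnogram()].
#' @param min_nrem_min Minimum NREM duration starting a cycle (minutes).
#' @param max_interrupt_min Wake interruptions shorter than this are
#'   absorbed into the surrounding sleep (minutes).
#' @return A data frame with one row per cycle: `cycle`, `start_epoch`,
#'   `end_epoch`, `duration_min`, `nrem_min`, `rem_min`. Zero rows if the
#'   night contains no sleep.
#' @export
segment_cycles <- function(hyp, min_nrem_min = 15, max_interrupt_min = 5) {
  stopifnot(inherits(hyp, "sw_hypnogram"))
  epm <- 60 / hyp$epoch_s  # epochs per minute
  coll <- ifelse(hyp$labels %in% c("N1", "N2", "N3"), "NREM",
                 ifelse(hyp$labels == "REM", "REM", "W"))
  sleep_idx <- which(coll != "W")
  if (length(sleep_idx) == 0)
    return(data.frame(cycle = integer(), start_epoch = integer(),
                      end_epoch = integer(), duration_min = numeric(),
                      nrem_min = numeric(), rem_min = numeric()))
  # absorb brief wake interruptions inside the sleep period
  r <- rle(coll)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  for (i in seq_along(r$values)) {
    if (r$values[i] == "W" && i > 1 && i < length(r$values) &&
        r$lengths[i] < max_interrupt_min * epm)
      coll[starts[i]:ends[i]] <- r$values[i - 1]
  }
  r <- rle(coll)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  # cycle onsets: long-enough NREM runs at sleep start or following REM/wake
  onsets <- integer(0)
  prev_sleep <- NA_character_
  for (i in seq_along(r$values)) {
    v <- r$values[i]
    if (v == "NREM" && r$lengths[i] >= min_nrem_min * epm &&
        (is.na(prev_sleep) || prev_sleep != "NREM"))
      onsets <- c(onsets, starts[i])
    if (v != "W") prev_sleep <- v
  }
  if (length(onsets) == 0)
    return(data.frame(cycle = integer(), start_epoch = integer(),
                      end_epoch = integer(), duration_min = numeric(),
                      nrem_min = numeric(), rem_min = numeric()))
  last_sleep <- max(sleep_idx)
  bounds <- c(onsets, last_sleep + 1L)
  out <- lapply(seq_along(onsets), function(k) {
    span <- bounds[k]:(bounds[k + 1] - 1L)
    data.frame(cycle = k, start_epoch = bounds[k],
               end_epoch = bounds[k + 1] - 1L,
               duration_min = length(span) / epm,
               nrem_min = sum(coll[span] == "NREM") / epm,
               rem_min = sum(coll[span] == "REM") / epm)
  })
  do.call(rbind, out)
}

#' Classical per-night sleep statistics
#'
#' Totals are computed over the sleep period, i.e. from sleep onset (first
#' non-wake epoch) to the final awakening (last non-wake epoch). WASO is
#' wake time inside that interval.
#'
#' @param hyp A [hypnogram()].
#' @return An object of class `sw_stats`: total sleep time, WASO, stage
#'   percentages over the sleep period (summing to 100), cycle count and
#'   per-cycle durations.
#' @export
static_stats <- function(hyp) {
  stopifnot(inherits(hyp, "sw_hypnogram"))
  epm <- 60 / hyp$epoch_s
  sleep_idx <- which(hyp$labels != "W")
  if (length(sleep_idx) == 0) {
    return(structure(list(tst_min = 0, waso_min = 0,
                          stage_pct = setNames(rep(NA_real_, 5),
                                               stage_levels()),
                          n_cycles = 0L, cycle_min = numeric()),
                     class = "sw_stats"))
  }
  period <- min(sleep_idx):max(sleep_idx)
  lab <- hyp$labels[period]
  pct <- 100 * table(factor(lab, levels = stage_levels())) / length(lab)
  cyc <- segment_cycles(hyp)
  structure(list(
    tst_min = sum(lab != "W") / epm,
    waso_min = sum(lab == "W") / epm,
    stage_pct = setNames(as.numeric(pct), stage_levels()),
    n_cycles = nrow(cyc),
    cycle_min = cyc$duration_min
  ), class = "sw_stats")
}

#' @export
print.sw_stats <- function(x, ...) {
  cat(sprintf("<sw_stats> TST %.0f min, WASO %.0f min, %d cycle(s)\n",
              x$tst_min, x$waso_min, x$n_cycles))
  cat("  stage %:", paste(sprintf("%s %.1f", names(x$stage_pct),
                                  x$stage_pct), collapse = ", "), "\n")
  invisible(x)
}
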