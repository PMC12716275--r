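# Internal helpers shared across modules.

#' Frequency band definitions
#'
#' The five canonical EEG bands used throughout the package, in fixed row
#' order: delta (1-4 Hz), theta (4-8 Hz), alpha (8-12 Hz), sigma (12-16 Hz)
#' and beta (16-30 Hz).
#'
#' @return A 5 x 2 numeric matrix of band edges in Hz, with rownames
#'   `delta`, `theta`, `alpha`, `sigma`, `beta`.
#' @export
band_edges <- function() {
  m <- rbind(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 12),
             sigma = c(12, 16), beta = c(16, 30))
  colnames(m) <- c("low", "high")
  m
}

band_names <- function() rownames(band_edges())

stage_levels <- function() c("W", "N1", "N2", "N3", "REM")

# Deterministic seed splitting: every stochastic operation derives a child
# seed from (root seed, key) through a modular polynomial rolling hash
# (base 131, modulus 2^31 - 1), so independent stages draw from
# independent, reproducible streams and seeds stay valid 32-bit integers.
string_hash <- function(s) {
  h <- 7
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

split_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  string_hash(paste0(format(seed, scientific = FALSE), "/", key))
}

with_seed <- function(seed, code) withr::with_seed(seed, code)

# trapezoidal integral of y over x (both numeric vectors, x increasing)
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# analytic signal via FFT (Marple); returns complex vector
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# runs of TRUE in a logical vector -> matrix with columns start, end (indices)
true_runs <- function(x) {
  r <- rle(as.logical(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & !is.na(r$values)
  cbind(start = starts[keep], end = ends[keep])
}

# rolling hash of a deparsed R object, as hex string (config provenance)
object_hash <- function(x) {
  sprintf("%08x", string_hash(paste(deparse(x), collapse = "\n")))
}

# typed quality-control failure used by build_night_features
qc_error <- function(reason, message) {
  stop(structure(class = c("sw_qc_error", "error", "condition"),
                 list(message = message, call = sys.call(-1), reason = reason)))
}

#' Test whether a condition is a night quality-control rejection
#'
#' @param x An object, typically caught with `tryCatch()`.
#' @return `TRUE` for conditions signalled when a night fails inclusion
#'   criteria in [build_night_features()].
#' @export
is_qc_error <- function(x) inherits(x, "sw_qc_error")

qc_reason <- function(x) if (is_qc_error(x)) x$reason else NA_character_
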