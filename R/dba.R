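# Archetypal nights by open-ended DTW barycenter averaging (DBA): the
# heuristic alternately aligns every member night to the current average
# and re-estimates each average bin as the mean of all feature vectors
# mapped onto it. A monotone guard keeps the recorded objective trace
# non-increasing: an update that would worsen the summed dissimilarity is
# rejected and iteration stops at the previous average.

#' DTW barycenter average of a set of nights
#'
#' Iteratively estimates the "archetypal night" minimising the summed
#' open-ended DTW dissimilarity to all member nights. Initialised at the
#' medoid (the member with the lowest summed dissimilarity to the others),
#' then refined with classic DBA updates under open-ended alignment.
#'
#' @param nights List of [build_night_features()] objects (or matrices).
#' @param init `"medoid"`, or a 5 x L matrix to start from.
#' @param max_iter Maximum DBA iterations (default 10).
#' @param tol Relative objective change below which iteration stops.
#' @param metric Local distance passed to [oe_dtw()].
#' @return An object of class `sw_archetype`: `matrix` (5 x L barycenter),
#'   `member_ids`, `subject_id`, `bin_s`, `objective_trace`
#'   (non-increasing).
#' @export
oe_dba <- function(nights, init = "medoid", max_iter = 10, tol = 1e-3,
                   metric = "euclidean") {
  if (length(nights) == 0) stop("need at least one night")
  mats <- lapply(nights, feature_matrix)
  ids <- vapply(seq_along(nights), function(i) {
    x <- nights[[i]]
    if (inherits(x, "sw_night_features")) x$night_id else paste0("m", i)
  }, "")
  subj <- unique(vapply(nights, function(x)
    if (inherits(x, "sw_night_features")) x$subject_id else "", ""))
  bin_s <- if (inherits(nights[[1]], "sw_night_features"))
    nights[[1]]$bin_s else NA_real_

  objective <- function(avg) {
    sum(vapply(mats, function(m)
      oe_dtw(avg, m, metric = metric)$dissimilarity, 0))
  }
  if (length(nights) == 1) {
    return(structure(list(matrix = mats[[1]], member_ids = ids,
                          subject_id = subj, bin_s = bin_s,
                          objective_trace = 0),
                     class = "sw_archetype"))
  }
  if (is.matrix(init)) {
    avg <- init
  } else {
    n <- length(mats)
    Dm <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      Dm[i, j] <- Dm[j, i] <-
        oe_dtw(mats[[i]], mats[[j]], metric = metric)$dissimilarity
    avg <- mats[[which.min(rowSums(Dm))]]
  }
  trace <- objective(avg)
  for (it in seq_len(max_iter)) {
    L <- ncol(avg)
    sums <- matrix(0, nrow(avg), L)
    counts <- numeric(L)
    for (m in mats) {
      wr <- oe_dtw(avg, m, metric = metric)
      for (r in seq_len(nrow(wr$path))) {
        i <- wr$path[r, "a"]; j <- wr$path[r, "b"]
        sums[, i] <- sums[, i] + m[, j]
        counts[i] <- counts[i] + 1
      }
    }
    cand <- sweep(sums, 2, pmax(counts, 1), "/")
    obj_new <- objective(cand)
    if (obj_new > tail(trace, 1)) break  # reject worsening update
    avg <- cand
    improvement <- (tail(trace, 1) - obj_new) / max(tail(trace, 1), 1e-12)
    trace <- c(trace, obj_new)
    if (improvement < tol) break
  }
  structure(list(matrix = avg, member_ids = ids, subject_id = subj,
                 bin_s = bin_s, objective_trace = trace),
            class = "sw_archetype")
}

#' @export
print.sw_archetype <- function(x, ...) {
  cat(sprintf(
    "<sw_archetype> %s: 5 x %d bins from %d night(s), objective %.3f\n",
    paste(x$subject_id, collapse = "+"), ncol(x$matrix),
    length(x$member_ids), tail(x$objective_trace, 1)))
  invisible(x)
}

#' Shared archetype across subjects
#'
#' [oe_dba()] applied to nights pooled across the subjects of a cluster,
#' yielding the cluster's shared archetypal sleep pattern.
#'
#' @inheritParams oe_dba
#' @return An `sw_archetype` whose `subject_id` lists every contributing
#'   subject.
#' @export
shared_archetype <- function(nights, init = "medoid", max_iter = 10,
                             tol = 1e-3, metric = "euclidean") {
  oe_dba(nights, init = init, max_iter = max_iter, tol = tol,
         metric = metric)
}
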