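# Open-ended dynamic time warping between nights. The alignment is anchored
# at sleep onset, uses steps {(1,0),(0,1),(1,1)} through the local-cost
# matrix, and exits once every bin of the shorter night has been aligned
# (open end), so nights with different numbers of sleep cycles remain
# comparable. The dissimilarity D is the accumulated cost along the optimal
# path divided by the path length.

feature_matrix <- function(x) {
  if (inherits(x, "sw_night_features")) x$matrix
  else if (is.matrix(x)) x
  else stop("expected a night-features object or a numeric matrix")
}

# local cost matrix between feature matrices (columns = time bins);
# computed by direct differences so identical bins cost exactly zero
local_cost <- function(a, b, metric = "euclidean") {
  if (metric == "euclidean") {
    d2 <- 0
    for (k in seq_len(nrow(a))) d2 <- d2 + outer(a[k, ], b[k, ], "-")^2
    sqrt(d2)
  } else if (metric == "cosine") {
    na <- sqrt(colSums(a^2)); nb <- sqrt(colSums(b^2))
    1 - crossprod(a, b) / outer(pmax(na, 1e-12), pmax(nb, 1e-12))
  } else stop("unknown metric: ", metric)
}

#' Open-ended DTW between two nights
#'
#' Aligns two five-band feature matrices with open-ended dynamic time
#' warping: the path starts at the common sleep onset and terminates when
#' the shorter night's last bin has been consumed, at the minimum
#' accumulated cost over the longer night's time axis (for equal lengths
#' the open end applies to either axis, keeping D symmetric). The local
#' cost is the Euclidean distance between z-scored 5-vectors.
#'
#' @param a,b [build_night_features()] objects or plain 5 x L matrices with
#'   identical band order and resolution.
#' @param metric `"euclidean"` (default) or `"cosine"` local distance.
#' @return An object of class `sw_warp`: `path` (two-column index matrix
#'   into `a` and `b`), `dissimilarity` (length-normalised cost `D`),
#'   `total_cost`, `matched_len` (bins of the longer night consumed).
#' @export
oe_dtw <- function(a, b, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  if (inherits(a, "sw_night_features") && inherits(b, "sw_night_features") &&
      a$bin_s != b$bin_s)
    stop("nights have different resolutions: ", a$bin_s, " vs ", b$bin_s)
  ma <- feature_matrix(a); mb <- feature_matrix(b)
  if (nrow(ma) != nrow(mb)) stop("feature matrices differ in band count")
  La <- ncol(ma); Lb <- ncol(mb)
  swap <- La > Lb
  cost <- if (swap) local_cost(mb, ma, metric) else local_cost(ma, mb, metric)
  res <- oe_dtw_core(cost, open_both = (La == Lb))
  path <- res$path
  if (swap) path <- path[, c(2, 1), drop = FALSE]
  colnames(path) <- c("a", "b")
  structure(list(path = path,
                 dissimilarity = res$total / nrow(path),
                 total_cost = res$total,
                 matched_len = if (swap) res$end_row else res$end_col),
            class = "sw_warp")
}

#' @export
print.sw_warp <- function(x, ...) {
  cat(sprintf("<sw_warp> D = %.3f over %d path cells (matched %d bins)\n",
              x$dissimilarity, nrow(x$path), x$matched_len))
  invisible(x)
}

#' Pairwise night dissimilarity matrix
#'
#' Computes the open-ended DTW dissimilarity for every unordered pair of
#' nights, excluding adjacent (consecutive-calendar) nights of the same
#' subject, which share slow physiological state and would bias the
#' within-subject average.
#'
#' @param nights A list of [build_night_features()] objects.
#' @param exclude_adjacent Exclude same-subject pairs whose `night_index`
#'   differs by 1 (default `TRUE`).
#' @param metric Local distance passed to [oe_dtw()].
#' @return An object of class `sw_dissimilarity`: `matrix` (symmetric,
#'   `NA` where excluded, zero diagonal) and `table` (one row per computed
#'   pair: ids, subjects, `within`, `D`).
#' @export
pairwise_dissimilarity <- function(nights, exclude_adjacent = TRUE,
                                   metric = "euclidean") {
  n <- length(nights)
  if (n < 2) stop("need at least 2 nights")
  ids <- vapply(nights, function(x) x$night_id, "")
  subj <- vapply(nights, function(x) x$subject_id, "")
  nidx <- vapply(nights, function(x) x$night_index, 0L)
  D <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(D) <- 0
  rows <- list()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      adjacent <- subj[i] == subj[j] && abs(nidx[i] - nidx[j]) == 1
      if (exclude_adjacent && adjacent) next
      d <- oe_dtw(nights[[i]], nights[[j]], metric = metric)$dissimilarity
      D[i, j] <- D[j, i] <- d
      rows[[length(rows) + 1]] <- data.frame(
        night_a = ids[i], night_b = ids[j],
        subject_a = subj[i], subject_b = subj[j],
        within = subj[i] == subj[j], D = d)
    }
  }
  structure(list(matrix = D, table = do.call(rbind, rows)),
            class = "sw_dissimilarity")
}

#' @export
print.sw_dissimilarity <- function(x, ...) {
  tab <- x$table
  cat(sprintf("<sw_dissimilarity> %d nights, %d computed pairs\n",
              nrow(x$matrix), nrow(tab)))
  if (any(tab$within) && any(!tab$within))
    cat(sprintf("  mean D within %.2f, across %.2f\n",
                mean(tab$D[tab$within]), mean(tab$D[!tab$within])))
  invisible(x)
}

#' Compare within- and across-subject dissimilarity
#'
#' Two-sample Student's t-test of within- versus across-subject night
#' dissimilarity. To avoid pseudo-replication the unit of analysis is the
#' per-subject mean (within group) and the per-subject-pair mean (across
#' group), not the raw night pairs.
#'
#' @param dis An `sw_dissimilarity` or its `table`.
#' @return An object of class `sw_ttest`: group means and SDs, `t`,
#'   `p_value`, and the aggregated group values.
#' @export
compare_within_across <- function(dis) {
  tab <- if (inherits(dis, "sw_dissimilarity")) dis$table else dis
  w <- tab[tab$within, ]
  a <- tab[!tab$within, ]
  if (nrow(w) == 0 || nrow(a) == 0)
    stop("both within- and across-subject pairs are required")
  within_vals <- tapply(w$D, w$subject_a, mean)
  key <- paste(pmin(a$subject_a, a$subject_b), pmax(a$subject_a, a$subject_b))
  across_vals <- tapply(a$D, key, mean)
  if (length(within_vals) < 2 || length(across_vals) < 2)
    stop("need at least 2 units per group for a t-test")
  tt <- t.test(within_vals, across_vals, var.equal = TRUE)
  structure(list(
    within_mean = mean(within_vals), within_sd = sd(within_vals),
    across_mean = mean(across_vals), across_sd = sd(across_vals),
    t = unname(tt$statistic), p_value = tt$p.value,
    within_values = within_vals, across_values = across_vals),
    class = "sw_ttest")
}

#' @export
print.sw_ttest <- function(x, ...) {
  cat(sprintf("<sw_ttest> within D = %.2f +/- %.2f, across D = %.2f +/- %.2f\n",
              x$within_mean, x$within_sd, x$across_mean, x$across_sd))
  cat(sprintf("  t = %.2f, p = %.3g\n", x$t, x$p_value))
  invisible(x)
}
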