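# Stage-conditioned dissimilarity: local warping costs bucketed by the
# visually scored stages of the two aligned bins, revealing which stage
# mismatches drive night-to-night dissimilarity (e.g. REM aligned to N3).

#' Stage-conditioned dissimilarity matrix
#'
#' Warps every admissible pair of nights and accumulates the local cost of
#' each path cell into a (stage_a, stage_b) bucket, using the per-bin stage
#' labels carried by the feature objects. Bucket means are symmetrised.
#'
#' @param nights List of [build_night_features()] objects.
#' @param exclude_adjacent As in [pairwise_dissimilarity()].
#' @param metric Local distance passed to [oe_dtw()].
#' @return A list: `matrix` (5 x 5 symmetric mean local cost, stages
#'   W/N1/N2/N3/REM), `counts` (path cells per unordered stage pair;
#'   their sum equals the total path length over all pairs).
#' @export
stage_conditioned_dissimilarity <- function(nights, exclude_adjacent = TRUE,
                                            metric = "euclidean") {
  n <- length(nights)
  if (n < 2) stop("need at least 2 nights")
  lv <- stage_levels()
  sums <- matrix(0, 5, 5, dimnames = list(lv, lv))
  counts <- matrix(0, 5, 5, dimnames = list(lv, lv))
  subj <- vapply(nights, function(x) x$subject_id, "")
  nidx <- vapply(nights, function(x) x$night_index, 0L)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (exclude_adjacent && subj[i] == subj[j] &&
          abs(nidx[i] - nidx[j]) == 1) next
      a <- nights[[i]]; b <- nights[[j]]
      wr <- oe_dtw(a, b, metric = metric)
      pa <- wr$path[, "a"]; pb <- wr$path[, "b"]
      cost <- sqrt(colSums((a$matrix[, pa, drop = FALSE] -
                              b$matrix[, pb, drop = FALSE])^2))
      sa <- factor(a$stages[pa], levels = lv)
      sb <- factor(b$stages[pb], levels = lv)
      t_sum <- tapply(cost, list(sa, sb), sum, default = 0)
      t_cnt <- table(sa, sb)
      sums <- sums + t_sum
      counts <- counts + t_cnt
    }
  }
  sym_sums <- sums + t(sums)
  sym_counts_mat <- counts + t(counts)
  m <- sym_sums / pmax(sym_counts_mat, 1)
  m[sym_counts_mat == 0] <- NA
  list(matrix = m, counts = counts)
}
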