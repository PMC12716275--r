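# Shared fixtures, memoised so expensive objects are built once per run.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

# cohort under the study conditions: 8 subjects (2 in trait cluster 2),
# 10 nights each, band powers only
sw_cohort <- function(root_seed = 1, n_subj = 8, n_nights = 10,
                      cluster2 = c(7, 8)) {
  key <- sprintf("cohort_%d_%d_%d", root_seed, n_subj, n_nights)
  memo(key, {
    nights <- list()
    for (s in seq_len(n_subj)) {
      prof <- make_profile(
        seed = sleepwarp:::split_seed(root_seed, paste0("subject", s)),
        cluster = if (s %in% cluster2) 2 else 1,
        subject_id = sprintf("s%02d", s))
      for (k in seq_len(n_nights)) {
        ng <- generate_night(prof, seed = sleepwarp:::split_seed(
          root_seed, sprintf("s%d_n%d", s, k)))
        ng$night_id <- sprintf("s%02d_n%02d", s, k)
        ng$night_index <- k
        nights[[length(nights) + 1]] <- ng
      }
    }
    nights
  })
}

sw_cohort_features <- function(root_seed = 1) {
  memo(sprintf("features_%d", root_seed), {
    feats <- list()
    for (ng in sw_cohort(root_seed)) {
      f <- tryCatch(
        build_night_features(ng$bandpower, ng$hypnogram,
                             night_id = ng$night_id,
                             subject_id = ng$subject_id,
                             night_index = ng$night_index),
        sw_qc_error = function(e) NULL)
      if (!is.null(f)) feats[[length(feats) + 1]] <- f
    }
    feats
  })
}

sw_pairwise <- function(root_seed = 1) {
  memo(sprintf("pairwise_%d", root_seed),
       pairwise_dissimilarity(sw_cohort_features(root_seed)))
}

sw_archetypes <- function(root_seed = 1) {
  memo(sprintf("arch_%d", root_seed), {
    feats <- sw_cohort_features(root_seed)
    subj <- unique(vapply(feats, function(f) f$subject_id, ""))
    lapply(subj, function(sid)
      oe_dba(feats[vapply(feats, function(f) f$subject_id == sid, TRUE)]))
  })
}

# a 90-min night with raw EEG and ground-truth events; `depth` controls the
# infra-slow spindle amplitude modulation (0 = constant planted amplitude)
sw_raw_hyp <- function() {
  hypnogram(c(rep("N2", 80), rep("N3", 30), rep("N2", 40), rep("REM", 20)))
}

sw_raw_night <- function(depth = 0.4) {
  memo(sprintf("raw_%g", depth),
       simulate_raw_eeg(sw_raw_hyp(), make_profile(1, 1), seed = 7,
                        infraslow_mod_depth = depth))
}

stage_at_epochs <- function(hyp, t_s) sleepwarp:::stage_at(hyp, t_s)

# event matching at a fixed onset tolerance
event_recall <- function(truth_onsets, det_onsets, tol = 0.25) {
  if (length(truth_onsets) == 0) return(NA_real_)
  mean(vapply(truth_onsets, function(o)
    any(abs(det_onsets - o) <= tol), TRUE))
}

# independent oracle: exhaustive enumeration of every admissible open-ended
# warping path (steps right/down/diagonal from the top-left corner, exiting
# once the shorter sequence is consumed), minimising TOTAL accumulated cost
brute_oe_dtw <- function(a, b) {
  swap <- ncol(a) > ncol(b)
  if (swap) { tmp <- a; a <- b; b <- tmp }
  n <- ncol(a); m <- ncol(b)
  cost <- matrix(0, n, m)
  for (i in 1:n) for (j in 1:m)
    cost[i, j] <- sqrt(sum((a[, i] - b[, j])^2))
  open_both <- n == m
  best <- list(total = Inf, len = NA)
  rec <- function(i, j, tot, len) {
    tot <- tot + cost[i, j]; len <- len + 1
    if (i == n || (open_both && j == m)) {
      if (tot < best$total) best <<- list(total = tot, len = len)
      return(invisible())
    }
    if (i < n && j < m) rec(i + 1, j + 1, tot, len)
    if (i < n) rec(i + 1, j, tot, len)
    if (j < m) rec(i, j + 1, tot, len)
  }
  rec(1, 1, 0, 0)
  best
}
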