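# Open-ended DTW, night features with QC, pairwise dissimilarity,
# barycenter averaging, stage-conditioned costs and archetype clustering.

test_that("self-alignment is exactly zero along the diagonal", {
  f <- sw_cohort_features()[[1]]
  w <- oe_dtw(f, f)
  expect_identical(w$dissimilarity, 0)
  expect_true(all(w$path[, 1] == w$path[, 2]))
  expect_equal(w$matched_len, ncol(f$matrix))
})

test_that("a truncated copy matches open-endedly at zero cost", {
  f <- sw_cohort_features()[[1]]
  cut <- f
  cut$matrix <- f$matrix[, seq_len(floor(0.6 * ncol(f$matrix)))]
  expect_identical(oe_dtw(f, cut)$dissimilarity, 0)
  expect_identical(oe_dtw(cut, f)$dissimilarity, 0)
})

test_that("the dynamic program matches exhaustive path enumeration", {
  set.seed(42)
  for (r in 1:25) {
    La <- sample(3:7, 1)
    Lb <- sample(3:7, 1)
    a <- matrix(rnorm(5 * La), 5)
    b <- matrix(rnorm(5 * Lb), 5)
    w <- oe_dtw(a, b)
    o <- brute_oe_dtw(a, b)
    expect_equal(w$total_cost, o$total, tolerance = 1e-10)
    expect_equal(w$dissimilarity, o$total / o$len, tolerance = 1e-10)
  }
})

test_that("D is invariant to permuting band rows of both nights", {
  set.seed(7)
  a <- matrix(rnorm(5 * 30), 5)
  b <- matrix(rnorm(5 * 40), 5)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(oe_dtw(a, b)$dissimilarity,
               oe_dtw(a[perm, ], b[perm, ])$dissimilarity)
})

test_that("resolution mismatches are rejected", {
  f <- sw_cohort_features()[[1]]
  g <- sw_cohort_features()[[2]]
  g$bin_s <- 12
  expect_error(oe_dtw(f, g), "different resolutions")
})

test_that("night features pass QC or fail with a typed reason", {
  p <- make_profile(1, 1)
  hyp <- simulate_hypnogram(p, 3)
  bp <- simulate_bandpower(hyp, p, 3)
  f <- build_night_features(bp, hyp, night_id = "n", subject_id = "s")
  dur_min <- sum(hyp$labels != "W") / 2
  expect_lte(abs(ncol(f$matrix) - dur_min), 2)
  expect_true(all(abs(rowMeans(f$matrix)) < 1e-9))
  expect_equal(f$sleep_onset_bin, 1L)

  one_cycle <- hypnogram(rep("N2", 180))
  e <- tryCatch(build_night_features(simulate_bandpower(one_cycle, p, 1),
                                     one_cycle),
                sw_qc_error = function(e) e)
  expect_true(is_qc_error(e))
  expect_equal(e$reason, "min-cycles")

  bp2 <- bp
  bp2$valid[seq_len(floor(0.25 * length(bp2$valid)))] <- FALSE
  e2 <- tryCatch(build_night_features(bp2, hyp), sw_qc_error = function(e) e)
  expect_true(is_qc_error(e2))
  expect_equal(e2$reason, "disconnection")
})

test_that("pairwise dissimilarity excludes adjacent same-subject nights", {
  all_feats <- sw_cohort_features()
  other <- which(vapply(all_feats, function(f)
    f$subject_id != all_feats[[1]]$subject_id, TRUE))[1]
  feats <- list(all_feats[[1]], all_feats[[2]], all_feats[[other]])
  # nights 1 and 2 belong to the same subject on consecutive calendar nights
  expect_equal(feats[[1]]$subject_id, feats[[2]]$subject_id)
  expect_equal(abs(feats[[1]]$night_index - feats[[2]]$night_index), 1)
  dis <- pairwise_dissimilarity(feats)
  expect_true(is.na(dis$matrix[1, 2]))
  expect_equal(nrow(dis$table), 2)
  expect_identical(dis$matrix, t(dis$matrix))
  expect_true(all(diag(dis$matrix) == 0))
})

test_that("temporal shuffling of one night increases D", {
  feats <- sw_cohort_features()
  f1 <- feats[[1]]
  f2 <- feats[[3]]
  shuf <- f2
  set.seed(1)
  shuf$matrix <- f2$matrix[, sample(ncol(f2$matrix))]
  expect_gt(oe_dtw(f1, shuf)$dissimilarity, oe_dtw(f1, f2)$dissimilarity)
})

test_that("within/across comparison aggregates and tests correctly", {
  mk <- function(sa, sb, d) data.frame(night_a = "x", night_b = "y",
                                       subject_a = sa, subject_b = sb,
                                       within = sa == sb, D = d)
  # identical group values -> t = 0, p = 1
  tab <- rbind(mk("a", "a", 1), mk("b", "b", 2), mk("c", "c", 3),
               mk("a", "b", 1), mk("a", "c", 2), mk("b", "c", 3))
  cmp <- compare_within_across(tab)
  expect_equal(cmp$t, 0)
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$within_mean, cmp$across_mean)
  expect_true(is.finite(cmp$within_sd) && is.finite(cmp$across_sd))

  # a 2-SD planted separation at 8 subjects is detected
  set.seed(4)
  subs <- paste0("s", 1:8)
  rows <- list()
  for (s in subs) rows[[length(rows) + 1]] <- mk(s, s, rnorm(1, 2, 0.5))
  for (i in 1:7) for (j in (i + 1):8)
    rows[[length(rows) + 1]] <- mk(subs[i], subs[j], rnorm(1, 3, 0.5))
  cmp2 <- compare_within_across(do.call(rbind, rows))
  expect_lt(cmp2$p_value, 0.05)
  expect_lt(cmp2$within_mean, cmp2$across_mean)

  expect_error(compare_within_across(rbind(mk("a", "a", 1), mk("a", "b", 2))),
               "at least 2")
})

test_that("DBA handles degenerate inputs and improves on the plain mean", {
  f <- sw_cohort_features()[[1]]
  single <- oe_dba(list(f))
  expect_identical(single$matrix, f$matrix)
  expect_identical(single$objective_trace, 0)

  same <- oe_dba(list(f, f, f))
  expect_equal(same$matrix, f$matrix)
  expect_lt(tail(same$objective_trace, 1), 1e-9)

  # time-jittered copies of one template
  set.seed(5)
  template <- matrix(0, 5, 100)
  for (b in 1:5)
    template[b, ] <- sin(2 * pi * (1:100) / 50 + b) +
      0.3 * sin(2 * pi * (1:100) / 17 + 2 * b)
  copies <- lapply(1:20, function(i) {
    idx <- pmin(pmax(1:100 + sample(-8:8, 1), 1), 100)
    template[, idx] + matrix(rnorm(500, 0, 0.1), 5)
  })
  dba <- oe_dba(copies, max_iter = 15)
  expect_true(all(diff(dba$objective_trace) <= 1e-9))
  am <- Reduce(`+`, copies) / length(copies)
  obj_am <- sum(vapply(copies, function(m) oe_dtw(am, m)$dissimilarity, 0))
  expect_lte(tail(dba$objective_trace, 1), obj_am)
})

test_that("stage-conditioned costs vanish on identical nights and conserve", {
  f <- sw_cohort_features()[[1]]
  g <- f
  g$night_index <- f$night_index + 5L  # not adjacent
  sc <- stage_conditioned_dissimilarity(list(f, g))
  present <- unique(f$stages)
  for (s in present) expect_lt(sc$matrix[s, s], 1e-12)
  expect_equal(sum(sc$counts), nrow(oe_dtw(f, g)$path))
})

test_that("archetype clustering merges duplicates first, heights monotone", {
  arch <- sw_archetypes()
  a <- arch[[1]]
  dup <- a
  dup$subject_id <- "dup"
  cl <- cluster_archetypes(list(arch[[2]], a, dup), k = 2)
  expect_equal(cl$hclust$height[1], 0)
  expect_true(all(diff(cl$hclust$height) >= 0))
  expect_equal(cl$clusters[[a$subject_id]], cl$clusters[["dup"]])
})
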