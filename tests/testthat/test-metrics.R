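test_that("confusion counts match the per-pixel tally", {
  set.seed(51)
  truth <- matrix(rbinom(256, 1, 0.4), 16, 16)
  # perfect prediction: no false calls
  cc <- confusion_counts(truth, truth, 0.5)
  expect_identical(cc$FP + cc$FN, 0L)
  # all-ones prediction: TP = k, FP = n - k
  cc <- confusion_counts(matrix(1, 16, 16), truth, 0.5)
  expect_equal(cc$TP, sum(truth)); expect_equal(cc$FP, 256 - sum(truth))
  expect_identical(cc$TN + cc$FN, 0L)
  # random case vs a nested-loop tally
  pred <- matrix(runif(256), 16, 16)
  cc <- confusion_counts(pred, truth, 0.3)
  tp <- tn <- fp <- fn <- 0L
  for (i in 1:16) for (j in 1:16) {
    p <- pred[i, j] >= 0.3; y <- truth[i, j] == 1
    if (p && y) tp <- tp + 1L else if (!p && !y) tn <- tn + 1L
    else if (p) fp <- fp + 1L else fn <- fn + 1L
  }
  expect_identical(c(cc$TP, cc$TN, cc$FP, cc$FN), c(tp, tn, fp, fn))
  expect_error(confusion_counts(pred, truth[1:8, ]), "match")
})

test_that("accuracy, IOU and Dice match hand arithmetic and conventions", {
  cc <- list(TP = 8, TN = 2, FP = 1, FN = 1)
  expect_equal(accuracy(cc), 10 / 12, tolerance = 1e-12)       # 0.8333
  expect_equal(iou(cc), 0.8, tolerance = 1e-12)
  expect_equal(dice(cc), 16 / 18, tolerance = 1e-12)           # 0.8889
  perfect <- list(TP = 5, TN = 5, FP = 0, FN = 0)
  expect_identical(c(accuracy(perfect), iou(perfect), dice(perfect)), c(1, 1, 1))
  # empty-union convention: both empty -> 1; one side empty -> 0
  both_empty <- list(TP = 0, TN = 10, FP = 0, FN = 0)
  expect_identical(c(iou(both_empty), dice(both_empty)), c(1, 1))
  one_empty <- list(TP = 0, TN = 5, FP = 3, FN = 0)
  expect_identical(c(iou(one_empty), dice(one_empty)), c(0, 0))
})

test_that("Dice is the harmonic transform of IOU on random confusion tables", {
  set.seed(52)
  for (i in 1:1000) {
    cc <- list(TP = sample(0:50, 1), TN = sample(0:50, 1),
               FP = sample(0:50, 1), FN = sample(0:50, 1))
    expect_equal(dice(cc), 2 * iou(cc) / (1 + iou(cc)), tolerance = 1e-12)
  }
})

test_that("metrics are invariant to joint spatial permutation", {
  set.seed(53)
  truth <- matrix(rbinom(64, 1, 0.5), 8, 8)
  pred <- matrix(runif(64), 8, 8)
  perm <- sample(64)
  a <- confusion_counts(pred, truth, 0.5)
  b <- confusion_counts(matrix(pred[perm], 8, 8), matrix(truth[perm], 8, 8), 0.5)
  expect_identical(unclass(a), unclass(b))
})

test_that("Rand score matches pair enumeration, including the split/merge example", {
  # T = two 2-pixel segments, S = one 4-pixel segment:
  # same-in-both 2, same-in-S 6, same-in-T 2 -> harmonic mean of (1/3, 1) = 0.5
  T <- matrix(c(1, 1, 2, 2), 1, 4)
  S <- matrix(1, 1, 4)
  expect_equal(foreground_restricted_rand_score(S, T), 0.5, tolerance = 1e-12)
  expect_equal(oracle_rand_score(S, T), 0.5, tolerance = 1e-12)
  # identity: both conditional probabilities are 1
  set.seed(54)
  T <- matrix(sample.int(4, 36, replace = TRUE), 6, 6)
  expect_identical(foreground_restricted_rand_score(T, T), 1)
  # random 12x12 labelings vs the O(n^2) oracle
  for (i in 1:4) {
    pair <- random_seg_pair(12, 12, k_s = 4, k_t = 3)
    expect_equal(foreground_restricted_rand_score(pair$S, pair$T),
                 oracle_rand_score(pair$S, pair$T), tolerance = 1e-12)
  }
})

test_that("information score matches the direct-entropy oracle", {
  set.seed(55)
  # S = T with >= 2 segments: I = H(S) = H(T) -> 1
  T <- matrix(sample.int(3, 49, replace = TRUE), 7, 7)
  expect_equal(information_theoretic_score(T, T), 1, tolerance = 1e-12)
  for (i in 1:4) {
    pair <- random_seg_pair(12, 12, k_s = 5, k_t = 4)
    expect_equal(information_theoretic_score(pair$S, pair$T),
                 oracle_info_score(pair$S, pair$T), tolerance = 1e-10)
  }
  # statistically independent labelings on a large image score near 0
  S <- matrix(sample.int(2, 120^2, replace = TRUE), 120, 120)
  T <- matrix(sample.int(2, 120^2, replace = TRUE), 120, 120)
  expect_lt(information_theoretic_score(S, T), 0.05)
})

test_that("scores are invariant to segment relabeling", {
  set.seed(56)
  pair <- random_seg_pair(10, 10, k_s = 4, k_t = 3)
  relab <- c(40, 10, 30, 20)[pair$S]
  dim(relab) <- dim(pair$S)
  expect_equal(foreground_restricted_rand_score(relab, pair$T),
               foreground_restricted_rand_score(pair$S, pair$T), tolerance = 1e-12)
  expect_equal(information_theoretic_score(relab, pair$T),
               information_theoretic_score(pair$S, pair$T), tolerance = 1e-12)
  expect_error(foreground_restricted_rand_score(pair$S, pair$T * 0), "foreground")
})

test_that("connected-component labeling is 4-connective", {
  m <- matrix(0, 4, 4)
  m[1, 1] <- 1; m[2, 2] <- 1   # diagonal contact must not join
  lab <- label_components(m)
  expect_identical(length(setdiff(unique(as.vector(lab)), 0L)), 2L)
  m2 <- matrix(0, 4, 4); m2[1, 1:2] <- 1
  expect_identical(length(setdiff(unique(as.vector(label_components(m2))), 0L)), 1L)
})

test_that("threshold sweep recovers a perfect boundary map and is monotone", {
  data <- tiny_em_data(n = 1, hw = 32, seed = 6)[[1]]
  truth_seg <- label_components(data$mask)
  boundary <- 1 - (data$mask > 0)   # exact boundary probabilities
  mx <- maximal_score_over_thresholds(boundary, truth_seg)
  expect_equal(mx$v_rand, 1, tolerance = 1e-12)
  expect_equal(mx$v_info, 1, tolerance = 1e-12)
  # constant 0.5 map: the sweep sees all-boundary or one big component
  flat <- matrix(0.5, 32, 32)
  two_case <- vapply(c(0.3, 0.7), function(th) {
    S <- label_components(flat < th)
    foreground_restricted_rand_score(S, truth_seg)
  }, numeric(1))
  mx_flat <- maximal_score_over_thresholds(flat, truth_seg, c(0.3, 0.7))
  expect_equal(mx_flat$v_rand, max(two_case), tolerance = 1e-12)
  # maxima never decrease when thresholds are added
  set.seed(57)
  noisy <- pmin(pmax(boundary + matrix(rnorm(1024, 0, 0.3), 32, 32), 0.01), 0.99)
  small <- maximal_score_over_thresholds(noisy, truth_seg, c(0.4, 0.6))
  big <- maximal_score_over_thresholds(noisy, truth_seg, c(0.2, 0.4, 0.6, 0.8))
  expect_gte(big$v_rand, small$v_rand)
  expect_gte(big$v_info, small$v_info)
  expect_error(maximal_score_over_thresholds(flat, truth_seg, numeric(0)), "non-empty")
})
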