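test_that("perfect agreement gives kappa 1 and accuracy 100%", {
  s <- sample(0:4, 50, replace = TRUE)
  r <- confusionAndScores(s, s)
  expect_equal(r$kappa, 1)
  expect_equal(r$accuracy, 1)
  expect_equal(r$macroF1, 1)
})

test_that("the worked confusion matrix gives kappa 0.40 and accuracy 70%", {
  ## confusion [[40,10],[20,30]]: 40 a/a, 10 a-pred/b-ref, 20 b-pred/a-ref
  pred <- rep(c("a", "a", "b", "b"), c(40, 10, 20, 30))
  ref <- rep(c("a", "b", "a", "b"), c(40, 10, 20, 30))
  r <- confusionAndScores(pred, ref)
  expect_equal(r$accuracy, 0.70)
  expect_equal(r$kappa, 0.40)
  expect_equal(r$kappa, bruteKappa(pred, ref))
})

test_that("a constant rater yields kappa 0 unless agreement is perfect", {
  expect_equal(cohenKappa(rep(1, 20), rep(1, 20)), 1)
  expect_equal(cohenKappa(rep(1, 20), rep(c(1, 2), 10)), 0)
})

test_that("kappa and scores match brute-force oracles on random instances", {
  set.seed(50)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    K <- sample(2:5, 1)
    pred <- sample(0:(K - 1), n, replace = TRUE)
    ref <- sample(0:(K - 1), n, replace = TRUE)
    r <- suppressWarnings(confusionAndScores(pred, ref))
    expect_equal(r$kappa, bruteKappa(pred, ref), tolerance = 1e-12)
    expect_equal(r$accuracy, bruteAccuracy(pred, ref), tolerance = 1e-12)
    expect_equal(r$macroF1, bruteMacroF1(pred, ref), tolerance = 1e-12)
  }
})

test_that("REJECT pairs are excluded symmetrically", {
  pred <- c(1, 2, NA, 3, 1)
  ref <- c(1, NA, 2, 3, 1)
  r <- confusionAndScores(pred, ref)
  expect_equal(r$nEpochs, 3)
  expect_equal(r$accuracy, 1)
  expect_error(confusionAndScores(c(NA, NA), c(1, 2)), "no overlapping")
})

test_that("kappa is invariant under simultaneous relabeling", {
  set.seed(51)
  a <- sample(0:3, 80, replace = TRUE)
  b <- sample(0:3, 80, replace = TRUE)
  perm <- c(3, 0, 2, 1)
  expect_equal(cohenKappa(a, b), cohenKappa(perm[a + 1], perm[b + 1]))
})

test_that("bootstrap CIs are percentile-based, deterministic, and shrink with n", {
  accMetric <- function(p, r) mean(p == r)
  s <- sample(0:2, 40, replace = TRUE)
  ci0 <- bootstrapCI(accMetric, s, s, n = 200, seed = 1)
  expect_equal(ci0$lo, 1)
  expect_equal(ci0$hi, 1)
  expect_equal(ci0$point, 1)
  set.seed(52)
  ref <- sample(0:1, 400, replace = TRUE)
  pred <- ifelse(runif(400) < 0.8, ref, 1 - ref)
  a <- bootstrapCI(accMetric, pred, ref, n = 500, seed = 7)
  b <- bootstrapCI(accMetric, pred, ref, n = 500, seed = 7)
  expect_identical(a, b)
  expect_true(a$lo <= a$point && a$point <= a$hi)
  ## width ~ 1/sqrt(n): quadrupling epochs about halves the width
  ratios <- vapply(1:20, function(seed) {
    set.seed(seed)
    refS <- sample(0:1, 100, replace = TRUE)
    predS <- ifelse(runif(100) < 0.8, refS, 1 - refS)
    refL <- sample(0:1, 400, replace = TRUE)
    predL <- ifelse(runif(400) < 0.8, refL, 1 - refL)
    ws <- bootstrapCI(accMetric, predS, refS, n = 300, seed = seed)
    wl <- bootstrapCI(accMetric, predL, refL, n = 300, seed = seed)
    (ws$hi - ws$lo) / (wl$hi - wl$lo)
  }, 0)
  expect_gt(mean(ratios), 1.5)
  expect_lt(mean(ratios), 2.7)
})

test_that("per-subject accuracies aggregate to the cohort accuracy", {
  set.seed(53)
  subj <- rep(sprintf("s%d", 1:5), times = c(10, 20, 15, 5, 30))
  ref <- sample(0:2, length(subj), replace = TRUE)
  pred <- ifelse(runif(length(subj)) < 0.7, ref, (ref + 1) %% 3)
  rep1 <- perSubjectReport(pred, subj, list(truth = ref))
  expect_equal(sum(rep1$perSubject$accuracy * rep1$perSubject$nEpochs) /
                 sum(rep1$perSubject$nEpochs),
               mean(pred == ref))
  ## perfect predictor: every subject 100%
  rep2 <- perSubjectReport(ref, subj, list(truth = ref))
  expect_true(all(rep2$perSubject$accuracy == 1))
})

test_that("per-channel accuracies are consistent when the background is global", {
  ## two well-separated classes; every channel sees the same global state
  co <- simulateCohort(nSubjects = 5, hoursPerSubject = 1.5,
                       scoreSet = c(0L, 5L), seed = 9)
  chans <- S4Vectors::metadata(co$featureTables[[1]])$channelLabels
  chanFeats <- lapply(setNames(chans, chans), function(ch)
    do.call(rbind, lapply(co$featureTables, channelFeatureMatrix,
                          channel = ch)))
  ## single-channel restrictions leave the pairwise synchrony features
  ## constant (all imputed), which zscoreFit warns about
  rep <- suppressWarnings(
    perSubjectReport(co$truth5, co$subjects, list(truth = co$truth5),
                     channelFeatures = chanFeats,
                     labelsForChannels = co$truth5))
  expect_equal(nrow(rep$perChannel), length(chans))
  expect_true(all(rep$perChannel$accuracy > 0.9))
  expect_lte(diff(range(rep$perChannel$accuracy)), 0.05)
})

test_that("predictions on missing-feature rows are imputed and flagged", {
  set.seed(56)
  X <- rbind(matrix(rnorm(40, -3), 20, 2), matrix(rnorm(40, 3), 20, 2))
  m <- trainSVM(makeTS(X, rep(0:1, each = 20)))
  Xna <- rbind(X[1, ], c(NA, 2.5))
  ps <- predictProba(m, Xna)
  expect_equal(attr(ps, "imputed"), c(FALSE, TRUE))
  expect_true(all(is.finite(probMatrix(ps))))
})

test_that("composite agreement substitutes and flags non-inferiority", {
  set.seed(54)
  truth <- sample(0:4, 4000, replace = TRUE)
  noisy <- function(s, p) ifelse(runif(length(s)) < p, s,
                                 sample(0:4, length(s), replace = TRUE))
  e1 <- noisy(truth, 0.8)
  e2 <- noisy(truth, 0.8)
  ## clf identical to E1
  ca <- compositeAgreement(e1, e2, e1)
  expect_equal(unname(ca$kappa["E1_clf"]), 1)
  expect_equal(unname(ca$kappa["E2_clf"]), unname(ca$kappa["E1_E2"]))
  ## three independent random series: all pairwise kappa near 0
  r1 <- sample(0:4, 10000, replace = TRUE)
  r2 <- sample(0:4, 10000, replace = TRUE)
  r3 <- sample(0:4, 10000, replace = TRUE)
  ci <- compositeAgreement(r1, r2, r3)
  expect_true(all(abs(ci$kappa) < 0.05))
  ## a denoised copy of the latent truth beats noisy raters
  clf <- noisy(truth, 0.97)
  cb <- compositeAgreement(e1, e2, clf)
  expect_true(cb$nonInferior)
})

test_that("merging scores cannot reduce accuracy when confusions stay in-group", {
  ## all confusions inside {0,1,2}: merged accuracy is 1
  ref <- rep(0:6, each = 10)
  pred <- ref
  low <- ref %in% 0:2
  set.seed(55)
  pred[low] <- sample(0:2, sum(low), replace = TRUE)
  accBefore <- mean(pred == ref)
  map <- c(0, 0, 0, 1, 2, 3, 4)
  accAfter <- mean(map[pred + 1] == map[ref + 1])
  expect_lt(accBefore, 1)
  expect_equal(accAfter, 1)
})
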