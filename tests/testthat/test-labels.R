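test_that("7-to-5 merger maps scores exactly and preserves REJECT", {
  expect_equal(scores(merge7to5(ScoreSeries(0:6))), c(0, 0, 0, 1, 2, 3, 4))
  expect_equal(scores(merge7to5(ScoreSeries(c(5, 5, 3)))), c(3, 3, 1))
  allRej <- ScoreSeries(rep(NA_integer_, 4))
  expect_true(all(is.na(scores(merge7to5(allRej)))))
  expect_equal(scheme(merge7to5(ScoreSeries(0:6))), "5-score")
  expect_error(merge7to5(merge7to5(ScoreSeries(0:6))), "already")
})

test_that("median smoothing removes isolated spikes and honours REJECT", {
  expect_equal(scores(smoothScores(ScoreSeries(rep(2L, 9)), 5)), rep(2L, 9))
  expect_equal(scores(smoothScores(ScoreSeries(c(1, 1, 1, 4, 1, 1, 1)), 5)),
               rep(1L, 7))
  s <- smoothScores(ScoreSeries(c(1, 1, NA, 1, 1)), 3)
  expect_true(is.na(scores(s)[3]))
  expect_equal(scores(s)[-3], rep(1L, 4))
  expect_error(smoothScores(ScoreSeries(1:5), 4), "odd")
  expect_error(smoothScores(ScoreSeries(1:5), 15), "3..13")
})

test_that("smoothing matches the brute-force running median on random series", {
  set.seed(20)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    s <- sample(c(0:6, NA), n, replace = TRUE)
    w <- sample(c(3, 5, 7), 1)
    expect_identical(scores(smoothScores(ScoreSeries(s), w)),
                     as.integer(bruteRunningMedian(s, w)))
  }
})

test_that("smoothing never introduces a score absent from the window", {
  set.seed(21)
  for (i in 1:50) {
    s <- sample(0:6, 20, replace = TRUE)
    sm <- scores(smoothScores(ScoreSeries(s), 5))
    for (j in seq_along(s)) {
      win <- s[max(1, j - 2):min(20, j + 2)]
      expect_true(sm[j] %in% win)
    }
  }
})

test_that("CONS keeps agreements once; ALL doubles consensus epochs", {
  X <- matrix(seq_len(2 * 3), 2, 3)
  e1 <- ScoreSeries(c(2L, 3L), raterId = "E1")
  e2 <- ScoreSeries(c(2L, 4L), raterId = "E2")
  cons <- buildTrainingSet(e1, e2, X, mode = "CONS")
  expect_equal(nrow(trainingFeatures(cons)), 1)
  expect_equal(trainingLabels(cons), 2L)
  all <- buildTrainingSet(e1, e2, X, mode = "ALL")
  expect_equal(nrow(trainingFeatures(all)), 4)
  expect_equal(sort(trainingLabels(all)), c(2L, 2L, 3L, 4L))
  ## full agreement on n epochs: ALL has 2n rows, CONS has n
  n <- 7
  Xn <- matrix(rnorm(n * 2), n, 2)
  a <- ScoreSeries(rep(1L, n)); b <- ScoreSeries(rep(1L, n))
  expect_equal(nrow(trainingFeatures(buildTrainingSet(a, b, Xn, "ALL"))), 2 * n)
  expect_equal(nrow(trainingFeatures(buildTrainingSet(a, b, Xn, "CONS"))), n)
  ## REJECT handling: excluded from CONS, per-rater in ALL
  e1r <- ScoreSeries(c(2L, NA)); e2r <- ScoreSeries(c(2L, 4L))
  expect_equal(nrow(trainingFeatures(buildTrainingSet(e1r, e2r, X, "CONS"))), 1)
  expect_equal(nrow(trainingFeatures(buildTrainingSet(e1r, e2r, X, "ALL"))), 3)
  expect_error(buildTrainingSet(e1, ScoreSeries(c(1L, 2L, 3L)), X),
               "misaligned")
})

test_that("hierarchy groupings partition the scores and round-trip", {
  g <- groupHierarchy(ScoreSeries(c(0L, 3L, 6L)), "severity")
  expect_equal(g$level1, c(1L, 2L, 3L))
  expect_equal(names(g$groups), c("normal", "moderate", "severe"))
  expect_equal(groupHierarchy(ScoreSeries(rep(2L, 5)), "severity")$level1,
               rep(1L, 5))
  for (strategy in c("severity", "continuity")) {
    s <- ScoreSeries(0:6)
    g <- groupHierarchy(s, strategy)
    expect_equal(ungroupHierarchy(g$level1, g$level2, g$groups), 0:6)
    s5 <- ScoreSeries(0:4, scheme = "5-score")
    g5 <- groupHierarchy(s5, strategy)
    expect_equal(ungroupHierarchy(g5$level1, g5$level2, g5$groups), 0:4)
  }
  expect_error(groupHierarchy(ScoreSeries(0:6), "nonsense"))
  expect_error(groupHierarchy(ScoreSeries(0:6), "severity",
                              groups = list(a = 0:2, b = 4:6)),
               "partition")
})

test_that("SMOTE balances to the majority count with convex synthetic rows", {
  set.seed(22)
  X <- rbind(matrix(rnorm(200, 0), 100, 2), matrix(rnorm(40, 5), 20, 2))
  ts <- makeTS(X, rep(c(0, 1), c(100, 20)))
  bal <- smoteBalance(ts, k = 10, seed = 1)
  expect_equal(as.integer(table(trainingLabels(bal))), c(100L, 100L))
  ## already balanced: unchanged
  tsb <- makeTS(X[1:40, ], rep(0:1, each = 20))
  expect_identical(trainingFeatures(smoteBalance(tsb, seed = 1)),
                   trainingFeatures(tsb))
  ## minority of exactly 2 rows: every synthetic point on the unique segment
  X2 <- rbind(matrix(rnorm(60), 30, 2), c(0, 0), c(1, 2))
  ts2 <- makeTS(X2, rep(c(0, 1), c(30, 2)))
  bal2 <- smoteBalance(ts2, k = 10, seed = 2)
  syn <- trainingFeatures(bal2)[bal2@provenance$rater == "SMOTE", , drop = FALSE]
  expect_equal(nrow(syn), 28)
  lambda <- syn[, 1] / 1
  expect_equal(syn[, 2], 2 * lambda, tolerance = 1e-12)
  expect_true(all(lambda >= 0 & lambda <= 1))
  ## singleton class errors with its name
  ts1 <- makeTS(X2[29:31, ], c(0L, 0L, 7L))
  expect_error(smoteBalance(ts1), "7")
})

test_that("the merger does not lower agreement when confusion sits in {0,1,2}", {
  set.seed(31)
  truth <- rep(0:6, each = 60)
  confuse <- function(s) {
    low <- s %in% 0:2 & runif(length(s)) < 0.4
    s[low] <- vapply(s[low], function(v) sample(setdiff(0:2, v), 1), 0L)
    s
  }
  e1 <- ScoreSeries(confuse(truth), raterId = "E1")
  e2 <- ScoreSeries(confuse(truth), raterId = "E2")
  k7 <- cohenKappa(scores(e1), scores(e2))
  k5 <- cohenKappa(scores(merge7to5(e1)), scores(merge7to5(e2)))
  expect_gte(k5, k7)
  expect_gt(k5, 0.95)  # all disagreement lived inside the merged group
})
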