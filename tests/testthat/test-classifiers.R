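test_that("z-scoring uses training-fold population statistics", {
  norm <- zscoreFit(matrix(c(1, 2, 3), 3, 1))
  z <- zscoreApply(norm, matrix(c(1, 2, 3), 3, 1))
  expect_equal(as.numeric(z), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  ## test value equal to the train mean maps to 0
  expect_equal(as.numeric(zscoreApply(norm, matrix(2, 1, 1))), 0)
  ## constant column: centered only, warning
  expect_warning(n2 <- zscoreFit(matrix(5, 4, 1)), "constant")
  expect_equal(as.numeric(zscoreApply(n2, matrix(5, 2, 1))), c(0, 0))
  expect_error(zscoreFit(matrix(numeric(0), 0, 2)), "empty")
  ## missing values imputed by the training median
  nm <- zscoreFit(matrix(c(1, NA, 3, 4), 4, 1))
  expect_equal(nm$impute, 3, ignore_attr = TRUE)
})

test_that("the SVM ensemble instantiates K(K-1)/2 calibrated binary learners", {
  set.seed(40)
  K <- 5
  X <- do.call(rbind, lapply(1:K, function(k) matrix(rnorm(60, 4 * k), 30, 2)))
  ts <- makeTS(X, rep(seq_len(K) - 1, each = 30),
               subject = rep(sprintf("s%d", 1:6), 25))
  m <- trainSVM(ts)
  expect_s4_class(m, "SVMModel")
  expect_equal(length(m@learners), K * (K - 1) / 2)
  ps <- predictProba(m, X)
  expect_true(max(abs(rowSums(probMatrix(ps)) - 1)) < 1e-9)
  expect_gt(mean(m@classSet[max.col(probMatrix(ps))] == trainingLabels(ts)),
            0.95)
})

test_that("a separable two-class problem is fit perfectly", {
  X <- rbind(matrix(rnorm(40, -3), 20, 2), matrix(rnorm(40, 3), 20, 2))
  ts <- makeTS(X, rep(0:1, each = 20))
  m <- trainSVM(ts)
  p <- probMatrix(predictProba(m, X))
  expect_equal(mean(m@classSet[max.col(p)] == trainingLabels(ts)), 1)
  expect_error(trainSVM(makeTS(X, rep(1L, 40))), "2 classes")
  expect_error(predictProba(m, X[, 1, drop = FALSE]), "feature-count")
})

test_that("Bayesian optimization tunes the cost inside its bounds", {
  set.seed(41)
  X <- rbind(matrix(rnorm(60, -1.5), 30, 2), matrix(rnorm(60, 1.5), 30, 2))
  ts <- makeTS(X, rep(0:1, each = 30), subject = rep(sprintf("s%d", 1:6), 10))
  m <- trainSVM(ts, neoTrainingConfig(tune = TRUE, tuneEvals = 8, seed = 2))
  expect_gte(m@cost, 1e-3)
  expect_lte(m@cost, 1e3)
  ## 1-D GP optimizer finds the max of a smooth function
  opt <- neobg:::bayesOpt1d(function(x) -(x - 1)^2, -3, 3, nEvals = 15,
                            seed = 1)
  expect_lt(abs(opt$x - 1), 0.35)
})

test_that("the learning-rate schedule reduces by 75% every 6,000 iterations", {
  expect_equal(mfnnLearningRate(1), 0.1)
  expect_equal(mfnnLearningRate(6000), 0.1)
  expect_equal(mfnnLearningRate(6001), 0.025)
  expect_equal(mfnnLearningRate(12001), 0.00625)
})

test_that("the MFNN learns XOR and exposes softmax posteriors", {
  X <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)
  y <- c(0L, 1L, 1L, 0L)
  ts <- makeTS(X, y)
  m <- suppressWarnings(
    trainMFNN(ts, neoTrainingConfig(hiddenSizes = c(4, 2), seed = 0,
                                    maxIters = 30000)))
  p <- probMatrix(predictProba(m, X))
  expect_equal(mean(m@classSet[max.col(p)] == y), 1)
  expect_true(all(abs(rowSums(p) - 1) < 1e-12))
})

test_that("an RNN with zero recurrent weights reproduces its source MFNN", {
  set.seed(42)
  X <- matrix(rnorm(60 * 3), 60, 3)
  y <- rep(0:2, each = 20)
  ts <- makeTS(X, y, subject = rep(c("a", "b"), each = 30))
  mf <- suppressWarnings(trainMFNN(ts, neoTrainingConfig(
    hiddenSizes = c(8, 5), maxIters = 300, seed = 1)))
  rn <- trainRNN(ts, mf, zeroRecurrent = TRUE)
  pa <- probMatrix(predictProba(mf, X))
  pb <- probMatrix(predictProba(rn, X, subjects = ts@provenance$subject))
  expect_equal(pa, pb, tolerance = 1e-12)
})

test_that("the RNN resets its state at subject boundaries", {
  set.seed(43)
  X <- matrix(rnorm(40 * 3), 40, 3)
  y <- rep(0:1, 20)
  subj <- rep(c("a", "b"), each = 20)
  ts <- makeTS(X, y, subject = subj)
  mf <- suppressWarnings(trainMFNN(ts, neoTrainingConfig(
    hiddenSizes = c(6, 4), maxIters = 300, seed = 2)))
  rn <- trainRNN(ts, mf, neoTrainingConfig(rnnEpochs = 1, seed = 2))
  pa <- probMatrix(predictProba(rn, X, subjects = subj))
  ## permute subject order: per-subject predictions unchanged
  perm <- c(21:40, 1:20)
  pb <- probMatrix(predictProba(rn, X[perm, ], subjects = subj[perm]))
  expect_equal(pb[21:40, ], pa[1:20, ], tolerance = 1e-12)
  expect_equal(pb[1:20, ], pa[21:40, ], tolerance = 1e-12)
  ## unordered training rows are rejected
  tsBad <- makeTS(X[c(2, 1, 3:40), ], y[c(2, 1, 3:40)], subject = subj)
  tsBad@provenance$epoch <- c(2L, 1L, 3:20, 1:20)
  expect_error(trainRNN(tsBad, mf), "ordered")
})

test_that("temporal structure lets the RNN match or beat the MFNN on average", {
  runSeed <- function(seed) {
    set.seed(seed)
    nSub <- 6; nEp <- 40
    subj <- rep(sprintf("s%d", 1:nSub), each = nEp)
    y <- integer(0)
    for (s in 1:nSub) {
      cl <- sample(0:2, 1)
      v <- integer(nEp)
      for (t in 1:nEp) {
        if (runif(1) < 0.07) cl <- sample(0:2, 1)
        v[t] <- cl
      }
      y <- c(y, v)
    }
    X <- matrix(rnorm(length(y) * 3, sd = 2), ncol = 3) + y
    tr <- subj %in% sprintf("s%d", 1:4)
    ts <- makeTS(X[tr, ], y[tr], subject = subj[tr])
    mf <- suppressWarnings(trainMFNN(ts, neoTrainingConfig(
      hiddenSizes = c(8, 5), maxIters = 1500, seed = seed)))
    rn <- trainRNN(ts, mf, neoTrainingConfig(rnnLr = 2e-3, rnnEpochs = 4,
                                             seed = seed))
    pm <- max.col(probMatrix(predictProba(mf, X[!tr, ])))
    pr <- max.col(probMatrix(predictProba(rn, X[!tr, ],
                                          subjects = subj[!tr])))
    c(mfnn = mean(mf@classSet[pm] == y[!tr]),
      rnn = mean(rn@classSet[pr] == y[!tr]))
  }
  res <- t(vapply(1:20, runSeed, c(mfnn = 0, rnn = 0)))
  expect_gte(mean(res[, "rnn"]), mean(res[, "mfnn"]))
})

test_that("LOSO builds one fold per subject with no leakage and deterministic output", {
  set.seed(44)
  nSub <- 27
  subj <- rep(sprintf("s%02d", 1:nSub), each = 4)
  y <- rep(rep(0:1, each = 2), nSub)
  X <- matrix(rnorm(length(y) * 2, sd = 0.5), ncol = 2) + 3 * y
  res <- losoCrossValidate(X, subj, y, design = "svm", smote = FALSE)
  expect_equal(length(res$folds), nSub)
  for (f in res$folds) expect_false(f$subject %in% f$trainSubjects)
  res2 <- losoCrossValidate(X, subj, y, design = "svm", smote = FALSE)
  expect_identical(res$predicted, res2$predicted)
  expect_gt(mean(res$predicted == y), 0.95)
  expect_error(losoCrossValidate(X[1:4, ], subj[1:4], y[1:4]),
               "at least 2 subjects")
})

test_that("hierarchical posteriors obey the law of total probability", {
  set.seed(45)
  labs <- c(0L, 1L, 3L)  # one score from each severity group (5-score)
  y <- rep(labs, each = 30)
  X <- matrix(rnorm(90 * 2, sd = 0.7), ncol = 2) + 2 * as.numeric(y)
  ts <- makeTS(X, y, subject = rep(sprintf("s%d", 1:6), 15))
  hm <- trainHierarchical(ts, design = "svm", strategy = "severity",
                          scheme = "5-score")
  p <- probMatrix(predictProba(hm, X))
  expect_equal(rowSums(p), rep(1, 90), tolerance = 1e-9)
  expect_gt(mean(hm@classSet[max.col(p)] == y), 0.9)
})

test_that("relabeling classes permutes the posterior columns", {
  set.seed(46)
  X <- rbind(matrix(rnorm(60, -3), 30, 2), matrix(rnorm(60, 0), 30, 2),
             matrix(rnorm(60, 3), 30, 2))
  y <- rep(c(0L, 1L, 2L), each = 30)
  ts1 <- makeTS(X, y)
  ts2 <- makeTS(X, c(2L, 0L, 1L)[y + 1])  # 0->2, 1->0, 2->1
  m1 <- trainSVM(ts1, neoTrainingConfig(seed = 3))
  m2 <- trainSVM(ts2, neoTrainingConfig(seed = 3))
  p1 <- probMatrix(predictProba(m1, X))
  p2 <- probMatrix(predictProba(m2, X))
  expect_equal(p2[, c("0", "1", "2")], p1[, c("1", "2", "0")],
               tolerance = 1e-6, ignore_attr = TRUE)
})
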