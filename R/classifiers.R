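## Classifier designs: pairwise linear SVM with calibrated coupled
## posteriors, a two-hidden-layer tanh feed-forward network (MFNN), and a
## recurrent network (RNN) with a one-epoch-delay feedback from the second
## hidden layer trained by real-time recurrent learning. All designs
## normalize features to z-scores with statistics from the training fold
## only, impute missing values by training-fold medians, and emit class
## posterior probabilities.

#' Training configuration
#'
#' Defaults follow the reference training recipe: initial learning rate
#' 0.1, reduced by 75% every 6,000 iterations (repeating schedule),
#' momentum 0.8, at most 120,000 full-batch iterations or stop when the
#' training RMSE falls below 1e-3, with 10% of training rows held out as
#' an inner validation set for overfitting control. Hidden sizes default
#' to (30, 15).
#'
#' @param ... overrides for any field.
#' @return a list of configuration values.
#' @export
neoTrainingConfig <- function(...) {
  cfg <- list(
    lrInitial = 0.1, lrDecayEvery = 6000L, lrDecayFactor = 0.75,
    momentum = 0.8, maxIters = 120000L, rmseStop = 1e-3,
    validationFraction = 0.10, valPatience = 25L, valCheckEvery = 200L,
    hiddenSizes = c(30L, 15L),
    cost = 1, tune = FALSE, tuneEvals = 30L, tuneFolds = 5L,
    rnnLr = 1e-3, rnnEpochs = 3L,
    seed = 1L)
  utils::modifyList(cfg, list(...))
}

#' Learning rate at a given training iteration
#'
#' The staged schedule: the initial rate is reduced by `lrDecayFactor`
#' (75%) after every `lrDecayEvery` (6,000) iterations, repeating. So the
#' rate is 0.1 for iterations 1..6,000, 0.025 from iteration 6,001, and
#' so on.
#'
#' @param iter iteration number (1-based).
#' @param config a [neoTrainingConfig()].
#' @return the learning rate.
#' @export
#' @examples
#' mfnnLearningRate(6001)  # 0.025
mfnnLearningRate <- function(iter, config = neoTrainingConfig()) {
  config$lrInitial *
    (1 - config$lrDecayFactor)^(floor((iter - 1) / config$lrDecayEvery))
}

#' Z-score normalization fitted on training data
#'
#' Centers and scales by the training-fold per-feature mean and
#' population SD (division by sqrt(n)); zero-variance features are
#' centered only (with a warning). Missing values are imputed by the
#' training-fold feature medians before scaling.
#'
#' @param train rows x features training matrix.
#' @return list(center, scale, impute) usable with [zscoreApply()].
#' @export
zscoreFit <- function(train) {
  if (nrow(train) < 1) stop("empty training matrix")
  impute <- apply(train, 2, function(v) {
    m <- median(v, na.rm = TRUE)
    if (is.finite(m)) m else 0
  })
  filled <- zscoreImpute(train, impute)
  center <- colMeans(filled)
  n <- nrow(filled)
  scale <- sqrt(colMeans(sweep(filled, 2, center)^2))
  if (any(scale == 0)) {
    warning("constant feature(s) detected; centering only")
    scale[scale == 0] <- 1
  }
  list(center = center, scale = scale, impute = impute)
}

zscoreImpute <- function(x, impute) {
  for (j in seq_len(ncol(x))) {
    bad <- !is.finite(x[, j])
    if (any(bad)) x[bad, j] <- impute[j]
  }
  x
}

#' @rdname zscoreFit
#' @param norm the fitted list from `zscoreFit`.
#' @param x matrix to normalize (training or test).
#' @export
zscoreApply <- function(norm, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(norm$center))
    stop(sprintf("feature-count mismatch: %d columns vs %d fitted features",
                 ncol(x), length(norm$center)))
  x <- zscoreImpute(x, norm$impute)
  sweep(sweep(x, 2, norm$center), 2, norm$scale, "/")
}

## ---- 1-D Bayesian optimization (GP + expected improvement) ------------------

## Maximizes f over [lower, upper]; used for the SVM box-constraint on the
## log10 scale. Squared-exponential GP, EI acquisition on a grid.
bayesOpt1d <- function(f, lower, upper, nEvals = 30, nInit = 5, seed = 1) {
  set.seed(seed)
  nInit <- min(nInit, nEvals)
  xs <- runif(nInit, lower, upper)
  ys <- vapply(xs, f, 0)
  l <- (upper - lower) / 4
  grid <- seq(lower, upper, length.out = 128)
  kfun <- function(a, b) exp(-outer(a, b, "-")^2 / (2 * l^2))
  while (length(xs) < nEvals) {
    K <- kfun(xs, xs) + diag(1e-4, length(xs))
    ky <- solve(K, ys - mean(ys))
    ks <- kfun(grid, xs)
    mu <- mean(ys) + ks %*% ky
    v <- pmax(1 - rowSums((ks %*% solve(K)) * ks), 1e-10)
    s <- sqrt(v)
    best <- max(ys)
    z <- (mu - best) / s
    ei <- (mu - best) * stats::pnorm(z) + s * stats::dnorm(z)
    xNew <- grid[which.max(ei)]
    if (min(abs(xNew - xs)) < 1e-6) xNew <- runif(1, lower, upper)
    xs <- c(xs, xNew)
    ys <- c(ys, f(xNew))
  }
  list(x = xs[which.max(ys)], y = max(ys), xs = xs, ys = ys)
}

## ---- pairwise linear SVM ensemble -------------------------------------------

## One calibrated binary learner. Platt-style sigmoid calibration with
## regularized targets (finite even under perfect separation).
fitBinarySVM <- function(X, y01, cost) {
  fit <- e1071::svm(X, factor(y01), kernel = "linear", cost = cost,
                    scale = FALSE)
  dv <- attr(predict(fit, X, decision.values = TRUE), "decision.values")[, 1]
  nPos <- sum(y01 == 1); nNeg <- sum(y01 == 0)
  t <- ifelse(y01 == 1, (nPos + 1) / (nPos + 2), 1 / (nNeg + 2))
  cal <- suppressWarnings(glm(t ~ dv, family = stats::quasibinomial()))
  cc <- coef(cal)
  cc[!is.finite(cc)] <- 0  # degenerate calibration (constant decision values)
  list(svm = fit, cal = cc)
}

predictBinarySVM <- function(learner, X) {
  dv <- attr(predict(learner$svm, X, decision.values = TRUE),
             "decision.values")[, 1]
  stats::plogis(learner$cal[1] + learner$cal[2] * dv)
}

#' Train the pairwise linear SVM classifier
#'
#' Error-correcting output-code ensemble of K(K-1)/2 binary linear SVMs
#' with one-vs-one coding. Each binary learner's decision values are
#' calibrated to pair-conditional probabilities by a Platt-style sigmoid
#' fitted on training data; multiclass posteriors are obtained by
#' pairwise coupling (normalized average of the pairwise probabilities).
#' The box constraint can be tuned by Bayesian optimization of the
#' internal subject-grouped 5-fold cross-validated accuracy over a
#' log-uniform range 1e-3..1e3.
#'
#' @param ts a [TrainingSet-class] with raw (unnormalized) features.
#' @param config a [neoTrainingConfig()]; set `tune = TRUE` to enable
#'   Bayesian optimization of the cost (`tuneEvals` evaluations).
#' @param approach recorded classification approach label.
#' @return an [SVMModel-class].
#' @export
trainSVM <- function(ts, config = neoTrainingConfig(), approach = "flat") {
  stopifnot(is(ts, "TrainingSet"))
  classSet <- sort(unique(trainingLabels(ts)))
  if (length(classSet) < 2) stop("at least 2 classes are required")
  norm <- zscoreFit(trainingFeatures(ts))
  X <- zscoreApply(norm, trainingFeatures(ts))
  y <- trainingLabels(ts)
  cost <- config$cost
  if (isTRUE(config$tune)) {
    groups <- ts@provenance$subject
    obj <- function(logc) {
      svmInnerCV(X, y, groups, 10^logc, folds = config$tuneFolds,
                 seed = config$seed)
    }
    opt <- bayesOpt1d(obj, -3, 3, nEvals = config$tuneEvals,
                      seed = config$seed)
    cost <- 10^opt$x
  }
  pairs <- t(utils::combn(classSet, 2))
  learners <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    sel <- y %in% pairs[i, ]
    learners[[i]] <- fitBinarySVM(X[sel, , drop = FALSE],
                                  as.integer(y[sel] == pairs[i, 1]), cost)
  }
  new("SVMModel", learners = learners, pairs = pairs, cost = cost,
      classSet = as.integer(classSet), norm = norm, approach = approach,
      featureNames = colnames(trainingFeatures(ts)) %||%
        paste0("f", seq_len(ncol(trainingFeatures(ts)))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Accuracy of the one-vs-one linear SVM ensemble under grouped k-fold CV
## (the tuning and wrapper objective). Uses e1071's multiclass one-vs-one
## voting directly: the same K(K-1)/2 binary linear learners, evaluated
## in compiled code.
svmInnerCV <- function(X, y, groups, cost, folds = 5, seed = 1) {
  set.seed(seed)
  ug <- unique(groups)
  if (length(ug) >= folds) {
    gf <- sample(rep(seq_len(folds), length.out = length(ug)))
    foldOf <- gf[match(groups, ug)]
  } else {
    foldOf <- sample(rep(seq_len(folds), length.out = length(y)))
  }
  correct <- 0; total <- 0
  for (fo in seq_len(folds)) {
    tr <- foldOf != fo
    if (length(unique(y[tr])) < 2 || !any(!tr)) next
    fit <- e1071::svm(X[tr, , drop = FALSE], factor(y[tr]),
                      kernel = "linear", cost = cost, scale = FALSE)
    pred <- as.character(predict(fit, X[!tr, , drop = FALSE]))
    correct <- correct + sum(pred == as.character(y[!tr]))
    total <- total + sum(!tr)
  }
  if (total == 0) 0 else correct / total
}

#' @describeIn trainSVM posterior probabilities by pairwise coupling.
#' @export
setMethod("predictProba", "SVMModel", function(model, newdata, ...) {
  newdata <- as.matrix(newdata)
  imputed <- apply(!is.finite(newdata), 1, any)
  X <- zscoreApply(model@norm, newdata)
  K <- length(model@classSet)
  probs <- matrix(0, nrow(X), K)
  for (i in seq_along(model@learners)) {
    r <- predictBinarySVM(model@learners[[i]], X)
    a <- match(model@pairs[i, 1], model@classSet)
    b <- match(model@pairs[i, 2], model@classSet)
    probs[, a] <- probs[, a] + r
    probs[, b] <- probs[, b] + (1 - r)
  }
  probs <- probs / (K * (K - 1) / 2)
  colnames(probs) <- model@classSet
  ps <- probSeries(probs, classValues = model@classSet)
  attr(ps, "imputed") <- imputed
  ps
})

## ---- multilayer feed-forward network ----------------------------------------

mfnnForward <- function(W, X) {
  H1 <- tanh(sweep(X %*% t(W$W1), 2, W$b1, "+"))
  H2 <- tanh(sweep(H1 %*% t(W$W2), 2, W$b2, "+"))
  O <- tanh(sweep(H2 %*% t(W$W3), 2, W$b3, "+"))
  list(H1 = H1, H2 = H2, O = O)
}

softmaxRows <- function(O) {
  e <- exp(O - apply(O, 1, max))
  e / rowSums(e)
}

#' Train the multilayer feed-forward network
#'
#' Two tanh hidden layers and a tanh output layer; class probabilities
#' come from the softmax of the output activations. Training is
#' full-batch gradient descent on the squared error against +/-1 targets
#' with momentum and the staged learning-rate schedule
#' ([mfnnLearningRate()]). Stops at `maxIters`, when the training RMSE
#' drops below `rmseStop`, or when the inner-validation loss (10% of
#' rows, used when n >= 10) stops improving.
#'
#' @param ts a [TrainingSet-class] with raw features.
#' @param config a [neoTrainingConfig()].
#' @param approach recorded classification approach label.
#' @return an [MFNNModel-class].
#' @export
trainMFNN <- function(ts, config = neoTrainingConfig(), approach = "flat") {
  stopifnot(is(ts, "TrainingSet"))
  classSet <- sort(unique(trainingLabels(ts)))
  if (length(classSet) < 2) stop("at least 2 classes are required")
  set.seed(config$seed)
  norm <- zscoreFit(trainingFeatures(ts))
  X <- zscoreApply(norm, trainingFeatures(ts))
  y <- trainingLabels(ts)
  K <- length(classSet)
  Tmat <- matrix(-1, nrow(X), K)
  Tmat[cbind(seq_len(nrow(X)), match(y, classSet))] <- 1
  h <- config$hiddenSizes
  p <- ncol(X)
  init <- function(nr, nc) matrix(rnorm(nr * nc, sd = sqrt(1 / nc)), nr, nc)
  W <- list(W1 = init(h[1], p), b1 = numeric(h[1]),
            W2 = init(h[2], h[1]), b2 = numeric(h[2]),
            W3 = init(K, h[2]), b3 = numeric(K))
  V <- lapply(W, function(w) w * 0)
  n <- nrow(X)
  useVal <- n >= 10 && config$validationFraction > 0
  valIdx <- if (useVal)
    sample(n, max(1, round(n * config$validationFraction))) else integer(0)
  trIdx <- setdiff(seq_len(n), valIdx)
  Xt <- X[trIdx, , drop = FALSE]; Tt <- Tmat[trIdx, , drop = FALSE]
  Xv <- X[valIdx, , drop = FALSE]; Tv <- Tmat[valIdx, , drop = FALSE]
  bestVal <- Inf; bestW <- W; badChecks <- 0L
  history <- list(rmse = NA_real_, iters = 0L, stopped = "maxIters")
  nt <- nrow(Xt)
  for (iter in seq_len(config$maxIters)) {
    lr <- mfnnLearningRate(iter, config)
    fw <- mfnnForward(W, Xt)
    err <- fw$O - Tt
    dO <- 2 * err * (1 - fw$O^2) / nt
    dH2 <- (dO %*% W$W3) * (1 - fw$H2^2)
    dH1 <- (dH2 %*% W$W2) * (1 - fw$H1^2)
    G <- list(W1 = t(dH1) %*% Xt, b1 = colSums(dH1),
              W2 = t(dH2) %*% fw$H1, b2 = colSums(dH2),
              W3 = t(dO) %*% fw$H2, b3 = colSums(dO))
    for (k in names(W)) {
      V[[k]] <- config$momentum * V[[k]] - lr * G[[k]]
      W[[k]] <- W[[k]] + V[[k]]
    }
    rmse <- sqrt(mean(err^2))
    if (rmse < config$rmseStop) {
      history$stopped <- "rmse"
      history$iters <- iter
      break
    }
    if (useVal && iter %% config$valCheckEvery == 0) {
      vo <- mfnnForward(W, Xv)$O
      vloss <- mean((vo - Tv)^2)
      if (vloss < bestVal - 1e-8) {
        bestVal <- vloss; bestW <- W; badChecks <- 0L
      } else {
        badChecks <- badChecks + 1L
        if (badChecks >= config$valPatience) {
          W <- bestW
          history$stopped <- "validation"
          history$iters <- iter
          break
        }
      }
    }
    if (iter == config$maxIters) history$iters <- iter
    if (!is.finite(rmse))
      stop(sprintf("training diverged (non-finite loss at iteration %d)", iter))
  }
  history$rmse <- sqrt(mean((mfnnForward(W, Xt)$O - Tt)^2))
  new("MFNNModel", weights = W, config = config, history = history,
      classSet = as.integer(classSet), norm = norm, approach = approach,
      featureNames = colnames(trainingFeatures(ts)) %||%
        paste0("f", seq_len(p)))
}

#' @describeIn trainMFNN softmax posteriors of the output activations.
#' @export
setMethod("predictProba", "MFNNModel", function(model, newdata, ...) {
  newdata <- as.matrix(newdata)
  imputed <- apply(!is.finite(newdata), 1, any)
  X <- zscoreApply(model@norm, newdata)
  probs <- softmaxRows(mfnnForward(model@weights, X)$O)
  colnames(probs) <- model@classSet
  ps <- probSeries(probs, classValues = model@classSet)
  attr(ps, "imputed") <- imputed
  ps
})

## ---- recurrent network (RTRL) ------------------------------------------------

rnnForwardSeq <- function(W, X, reset) {
  n <- nrow(X)
  h2 <- numeric(nrow(W$Wr))
  O <- matrix(0, n, nrow(W$W3))
  for (t in seq_len(n)) {
    if (reset[t]) h2 <- numeric(nrow(W$Wr))
    h1 <- tanh(W$W1 %*% X[t, ] + W$b1)
    z2 <- W$W2 %*% h1 + W$b2 + W$Wr %*% h2
    h2 <- tanh(z2)
    O[t, ] <- tanh(W$W3 %*% h2 + W$b3)
  }
  O
}

#' Train the recurrent network by real-time recurrent learning
#'
#' The second hidden layer of a trained MFNN is connected to a
#' feed-backward layer with a one-epoch time delay. Forward-path weights
#' are initialized from the trained MFNN; recurrent weights start as small
#' random values. RTRL tracks the exact sensitivities of the recurrent
#' layer's state to its parameters (recurrent matrix, second-layer weights
#' and bias) across time; the input and output layers are fine-tuned with
#' instantaneous gradients. Learning rates are very small and set per
#' class, scaled inversely to the class frequency in the training data.
#' The hidden state is reset at subject boundaries.
#'
#' @param ts a [TrainingSet-class] whose rows are ordered by subject and
#'   time (epochs in temporal order within each subject).
#' @param mfnn the pretrained [MFNNModel-class].
#' @param config a [neoTrainingConfig()]; `rnnLr` is the base rate and
#'   `rnnEpochs` the number of passes.
#' @param zeroRecurrent start the recurrent weights at exactly zero and
#'   skip training (the model then reproduces the MFNN).
#' @return an [RNNModel-class].
#' @export
trainRNN <- function(ts, mfnn, config = neoTrainingConfig(),
                     zeroRecurrent = FALSE) {
  stopifnot(is(ts, "TrainingSet"), is(mfnn, "MFNNModel"))
  prov <- ts@provenance
  ord <- order(match(prov$subject, unique(prov$subject)), prov$epoch)
  if (!identical(ord, seq_len(nrow(prov))))
    stop("training rows must be ordered by subject and time")
  classSet <- mfnn@classSet
  X <- zscoreApply(mfnn@norm, trainingFeatures(ts))
  y <- trainingLabels(ts)
  K <- length(classSet)
  h2n <- nrow(mfnn@weights$W2)
  set.seed(config$seed)
  W <- mfnn@weights
  W$Wr <- if (zeroRecurrent) matrix(0, h2n, h2n) else
    matrix(rnorm(h2n * h2n, sd = 0.01), h2n, h2n)
  reset <- c(TRUE, prov$subject[-1] != prov$subject[-nrow(prov)])
  if (!zeroRecurrent) {
    counts <- table(factor(y, levels = classSet))
    lrClass <- config$rnnLr * length(y) / (K * pmax(as.numeric(counts), 1))
    names(lrClass) <- classSet
    h1n <- nrow(W$W1)
    nTheta <- h2n * h2n + h2n * h1n + h2n
    o2 <- h2n * h2n; o3 <- o2 + h2n * h1n
    for (pass in seq_len(config$rnnEpochs)) {
      h2 <- numeric(h2n)
      S <- matrix(0, h2n, nTheta)
      for (t in seq_len(nrow(X))) {
        if (reset[t]) { h2 <- numeric(h2n); S[] <- 0 }
        x <- X[t, ]
        h1 <- as.numeric(tanh(W$W1 %*% x + W$b1))
        h2prev <- h2
        z2 <- as.numeric(W$W2 %*% h1 + W$b2 + W$Wr %*% h2prev)
        h2 <- tanh(z2)
        o <- as.numeric(tanh(W$W3 %*% h2 + W$b3))
        Dir <- matrix(0, h2n, nTheta)
        for (j in seq_len(h2n))
          Dir[cbind(seq_len(h2n), (j - 1) * h2n + seq_len(h2n))] <- h2prev[j]
        for (j in seq_len(h1n))
          Dir[cbind(seq_len(h2n), o2 + (j - 1) * h2n + seq_len(h2n))] <- h1[j]
        Dir[cbind(seq_len(h2n), o3 + seq_len(h2n))] <- 1
        S <- (1 - h2^2) * (W$Wr %*% S + Dir)
        target <- rep(-1, K); target[match(y[t], classSet)] <- 1
        dO <- 2 * (o - target) * (1 - o^2)
        gh2 <- as.numeric(t(W$W3) %*% dO)
        gTheta <- as.numeric(gh2 %*% S)
        lr <- lrClass[as.character(y[t])]
        W$Wr <- W$Wr - lr * matrix(gTheta[seq_len(o2)], h2n, h2n)
        W$W2 <- W$W2 - lr * matrix(gTheta[(o2 + 1):o3], h2n, h1n)
        W$b2 <- W$b2 - lr * gTheta[(o3 + 1):nTheta]
        ## instantaneous fine-tuning of input and output layers
        W$W3 <- W$W3 - lr * outer(dO, h2)
        W$b3 <- W$b3 - lr * dO
        gz2 <- gh2 * (1 - h2^2)
        gh1 <- as.numeric(t(W$W2) %*% gz2) * (1 - h1^2)
        W$W1 <- W$W1 - lr * outer(gh1, x)
        W$b1 <- W$b1 - lr * gh1
      }
    }
  }
  new("RNNModel", weights = W, config = config,
      classSet = classSet, norm = mfnn@norm, approach = mfnn@approach,
      featureNames = mfnn@featureNames)
}

#' @describeIn trainRNN sequential posteriors; supply `subjects` to reset
#'   the hidden state at subject boundaries.
#' @param subjects optional subject id per row of `newdata`.
#' @export
setMethod("predictProba", "RNNModel", function(model, newdata,
                                               subjects = NULL, ...) {
  newdata <- as.matrix(newdata)
  imputed <- apply(!is.finite(newdata), 1, any)
  X <- zscoreApply(model@norm, newdata)
  reset <- if (is.null(subjects)) c(TRUE, rep(FALSE, nrow(X) - 1)) else
    c(TRUE, subjects[-1] != subjects[-length(subjects)])
  O <- rnnForwardSeq(model@weights, X, reset)
  probs <- softmaxRows(O)
  colnames(probs) <- model@classSet
  ps <- probSeries(probs, classValues = model@classSet)
  attr(ps, "imputed") <- imputed
  ps
})

## ---- hierarchical composition ------------------------------------------------

trainDesign <- function(ts, design, config, approach) {
  switch(design,
         svm = trainSVM(ts, config, approach),
         mfnn = trainMFNN(ts, config, approach),
         stop(sprintf("unknown design '%s'", design)))
}

subsetTrainingSet <- function(ts, sel, labels = NULL) {
  new("TrainingSet",
      features = trainingFeatures(ts)[sel, , drop = FALSE],
      labels = as.integer(if (is.null(labels)) trainingLabels(ts)[sel]
                          else labels),
      weights = ts@weights[sel],
      provenance = ts@provenance[sel, , drop = FALSE],
      mode = ts@mode)
}

#' Train a hierarchical (two-level) classifier
#'
#' Level 1 classifies the score group (continuity- or severity-based);
#' level 2 classifies the score within each multi-score group. Posteriors
#' compose by the product rule, P(score) = P(group) x P(score | group),
#' so they still sum to 1.
#'
#' @param ts a [TrainingSet-class].
#' @param design "svm" or "mfnn" (recurrent designs need an unbroken
#'   epoch sequence and are flat-only).
#' @param strategy "continuity" or "severity".
#' @param scheme "7-score" or "5-score".
#' @param config a [neoTrainingConfig()].
#' @return a [HierarchicalModel-class].
#' @export
trainHierarchical <- function(ts, design = "svm",
                              strategy = c("severity", "continuity"),
                              scheme = "5-score",
                              config = neoTrainingConfig()) {
  strategy <- match.arg(strategy)
  groups <- hierarchyGroups(strategy, scheme)
  y <- trainingLabels(ts)
  g <- rep(NA_integer_, length(y))
  for (i in seq_along(groups)) g[y %in% groups[[i]]] <- i
  level1 <- trainDesign(subsetTrainingSet(ts, !is.na(g), g[!is.na(g)]),
                        design, config, strategy)
  level2 <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    sel <- !is.na(g) & g == i
    present <- sort(unique(y[sel]))
    if (length(present) >= 2)
      level2[[i]] <- trainDesign(subsetTrainingSet(ts, sel), design, config,
                                 strategy)
  }
  new("HierarchicalModel", level1 = level1, level2 = level2, groups = groups,
      classSet = as.integer(sort(unique(y))), norm = level1@norm,
      approach = strategy, featureNames = level1@featureNames)
}

#' @describeIn trainHierarchical composed posteriors over the full score
#'   set.
#' @export
setMethod("predictProba", "HierarchicalModel", function(model, newdata, ...) {
  pg <- probMatrix(predictProba(model@level1, newdata))
  out <- matrix(0, nrow(pg), length(model@classSet))
  colnames(out) <- model@classSet
  for (i in seq_along(model@groups)) {
    gi <- match(i, model@level1@classSet)
    pGroup <- if (!is.na(gi)) pg[, gi] else rep(0, nrow(pg))
    scoresIn <- sort(model@groups[[i]])
    scoresIn <- scoresIn[scoresIn %in% model@classSet]
    if (!length(scoresIn)) next
    if (!is.null(model@level2[[i]])) {
      pw <- probMatrix(predictProba(model@level2[[i]], newdata))
      for (s in scoresIn) {
        si <- match(s, model@level2[[i]]@classSet)
        if (!is.na(si))
          out[, as.character(s)] <- out[, as.character(s)] + pGroup * pw[, si]
      }
    } else if (length(scoresIn) == 1) {
      out[, as.character(scoresIn)] <- out[, as.character(scoresIn)] + pGroup
    }
  }
  out <- out / pmax(rowSums(out), .Machine$double.eps)
  ps <- probSeries(out, classValues = model@classSet)
  attr(ps, "imputed") <- apply(!is.finite(as.matrix(newdata)), 1, any)
  ps
})

## ---- leave-one-subject-out cross-validation ----------------------------------

## Stack training rows for a fold from one or two raters' labels.
stackTraining <- function(features, subjects, epochs, l1, l2, mode) {
  if (is.null(l2)) {
    keep <- !is.na(l1)
    return(new("TrainingSet",
               features = features[keep, , drop = FALSE],
               labels = as.integer(l1[keep]), weights = rep(1, sum(keep)),
               provenance = data.frame(subject = subjects[keep],
                                       epoch = epochs[keep], rater = "truth",
                                       stringsAsFactors = FALSE),
               mode = "SINGLE"))
  }
  if (mode == "CONS") {
    keep <- !is.na(l1) & !is.na(l2) & l1 == l2
    new("TrainingSet",
        features = features[keep, , drop = FALSE],
        labels = as.integer(l1[keep]), weights = rep(1, sum(keep)),
        provenance = data.frame(subject = subjects[keep],
                                epoch = epochs[keep], rater = "CONS",
                                stringsAsFactors = FALSE),
        mode = "CONS")
  } else {
    k1 <- !is.na(l1); k2 <- !is.na(l2)
    new("TrainingSet",
        features = rbind(features[k1, , drop = FALSE],
                         features[k2, , drop = FALSE]),
        labels = as.integer(c(l1[k1], l2[k2])),
        weights = rep(1, sum(k1) + sum(k2)),
        provenance = data.frame(
          subject = c(subjects[k1], subjects[k2]),
          epoch = c(epochs[k1], epochs[k2]),
          rater = c(rep("E1", sum(k1)), rep("E2", sum(k2))),
          stringsAsFactors = FALSE),
        mode = "ALL")
  }
}

#' Leave-one-subject-out cross-validation
#'
#' One fold per subject: the model is trained on all other subjects' data
#' (consensus or all-rater rows per `mode`), with feature imputation,
#' z-score normalization, optional SMOTE balancing and hyperparameter
#' tuning all performed inside the training fold only, then applied to
#' the held-out subject. Predictions are concatenated per subject in
#' epoch order.
#'
#' @param features epochs x features matrix over all subjects (NA =
#'   missing).
#' @param subjects subject id per row.
#' @param e1 integer labels per row from rater 1 (NA = REJECT).
#' @param e2 optional labels from rater 2; when supplied, `mode` selects
#'   CONS/ALL merging.
#' @param design "svm", "mfnn" or "rnn".
#' @param approach "flat", "continuity" or "severity".
#' @param mode "ALL" or "CONS".
#' @param scheme "5-score" or "7-score" (used for hierarchy groupings).
#' @param smote logical; balance classes by [smoteBalance()] inside the
#'   fold.
#' @param smoteK SMOTE neighbourhood size.
#' @param config a [neoTrainingConfig()].
#' @return list with `predicted` (integer per epoch), `probs`
#'   ([ProbSeries-class] over all epochs), `classSet`, and `folds` (per
#'   subject: indices and the trained model's class set).
#' @export
losoCrossValidate <- function(features, subjects, e1, e2 = NULL,
                              design = "svm", approach = "flat",
                              mode = "ALL", scheme = "5-score",
                              smote = TRUE, smoteK = 10,
                              config = neoTrainingConfig()) {
  features <- as.matrix(features)
  subjects <- as.character(subjects)
  us <- unique(subjects)
  if (length(us) < 2) stop("LOSO needs at least 2 subjects")
  epochs <- stats::ave(seq_along(subjects), subjects, FUN = seq_along)
  n <- nrow(features)
  classSet <- sort(unique(c(e1[!is.na(e1)], if (!is.null(e2)) e2[!is.na(e2)])))
  probs <- matrix(NA_real_, n, length(classSet))
  colnames(probs) <- classSet
  predicted <- rep(NA_integer_, n)
  folds <- list()
  for (fi in seq_along(us)) {
    s <- us[fi]
    te <- subjects == s
    tr <- !te
    ts <- stackTraining(features[tr, , drop = FALSE], subjects[tr],
                        epochs[tr], e1[tr], if (!is.null(e2)) e2[tr],
                        mode)
    if (nrow(trainingFeatures(ts)) == 0 ||
        length(unique(trainingLabels(ts))) < 2) {
      warning(sprintf("fold '%s' skipped: insufficient training labels", s))
      next
    }
    foldSeed <- config$seed * 1000L + fi
    foldConfig <- utils::modifyList(config, list(seed = foldSeed))
    if (smote) ts <- smoteBalance(ts, k = smoteK, seed = foldSeed)
    model <- if (approach == "flat") {
      if (design == "rnn") {
        mf <- trainMFNN(ts, foldConfig)
        trainRNN(ts, mf, foldConfig)
      } else trainDesign(ts, design, foldConfig, "flat")
    } else {
      trainHierarchical(ts, design, approach, scheme, foldConfig)
    }
    ps <- if (design == "rnn" && approach == "flat")
      predictProba(model, features[te, , drop = FALSE],
                   subjects = subjects[te])
    else predictProba(model, features[te, , drop = FALSE])
    pm <- probMatrix(ps)
    cols <- match(model@classSet, classSet)
    full <- matrix(0, sum(te), length(classSet))
    full[, cols] <- pm
    probs[te, ] <- full
    predicted[te] <- classSet[max.col(full, ties.method = "first")]
    folds[[s]] <- list(subject = s, testIdx = which(te),
                       trainSubjects = setdiff(us, s),
                       classSet = model@classSet)
  }
  done <- !is.na(predicted)
  list(predicted = predicted,
       probs = probSeries(probs[done, , drop = FALSE],
                          classValues = classSet),
       probMatrix = probs, classSet = classSet, folds = folds,
       subjects = subjects)
}
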