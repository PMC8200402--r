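## Genetic-algorithm wrapper feature selection over the 98-feature
## registry. Chromosomes are feature bitmasks; fitness is the inner
## subject-grouped cross-validated accuracy of the wrapped classifier on
## the masked features. Fitness evaluations are memoized, elitism keeps
## the best chromosome, and the search stops at the generation limit or
## the evaluation budget.

#' GA configuration
#'
#' Reference settings: population of 100 subsets, two-point crossover at
#' rate 0.6, per-gene bit-flip mutation at rate 0.1, 50 generations, at
#' most 5,000 fitness evaluations. Parent selection is
#' fitness-proportional (roulette); tournament selection (size 3) is
#' available via `selection = "tournament"`. One elite slot carries the
#' best chromosome found so far. Chromosomes are initialized
#' Bernoulli(0.3) per gene so initial subsets vary in size.
#'
#' @param ... overrides.
#' @return configuration list.
#' @export
gaConfig <- function(...) {
  cfg <- list(populationSize = 100L, crossoverRate = 0.6, mutationRate = 0.1,
              generations = 50L, maxEvaluations = 5000L, initProb = 0.3,
              selection = "roulette", tournamentK = 3L,
              innerFolds = 5L, seed = 1L)
  cfg <- utils::modifyList(cfg, list(...))
  if (cfg$populationSize %% 2 != 0) stop("population size must be even")
  stopifnot(cfg$crossoverRate >= 0, cfg$crossoverRate <= 1,
            cfg$mutationRate >= 0, cfg$mutationRate <= 1,
            cfg$selection %in% c("tournament", "roulette"))
  cfg
}

## Inner grouped-CV accuracy of a linear SVM on the masked features; the
## wrapper objective.
wrapperFitness <- function(mask, X, y, groups, folds, cost = 1, seed = 1) {
  if (!any(mask)) return(0)
  svmInnerCV(X[, mask, drop = FALSE], y, groups, cost, folds = folds,
             seed = seed)
}

twoPointCrossover <- function(a, b) {
  p <- length(a)
  pts <- sort(sample.int(p, 2))
  mid <- (pts[1] + 1):pts[2]
  if (pts[1] + 1 > pts[2]) return(list(a, b))
  a2 <- a; b2 <- b
  a2[mid] <- b[mid]; b2[mid] <- a[mid]
  list(a2, b2)
}

#' Genetic-algorithm wrapper feature selection
#'
#' Searches feature-subset bitmasks maximizing the inner subject-grouped
#' cross-validated accuracy of a linear SVM wrapper. All-zero chromosomes
#' are repaired to a random single feature. Identical chromosomes are
#' never re-evaluated (memoized fitness).
#'
#' @param features epochs x features matrix (missing values allowed; they
#'   are imputed inside the wrapper's training folds).
#' @param labels integer labels per row (NA rows dropped).
#' @param subjects subject id per row (grouped inner CV).
#' @param config a [gaConfig()].
#' @return list with `best` (logical mask), `bestFitness`,
#'   `selectionCounts` (per-feature count in the final population, 0..
#'   population size), `evaluations` (number of distinct fitness
#'   evaluations), `history` (best fitness per generation).
#' @export
gaSelect <- function(features, labels, subjects, config = gaConfig()) {
  keep <- !is.na(labels)
  X <- as.matrix(features)[keep, , drop = FALSE]
  y <- labels[keep]
  groups <- as.character(subjects)[keep]
  if (length(unique(y)) < 2) stop("at least 2 classes are required")
  ## impute by global medians for the wrapper objective (fold-internal
  ## normalization happens inside the inner CV's SVM fits)
  norm <- zscoreFit(X)
  X <- zscoreApply(norm, X)
  p <- ncol(X)
  set.seed(config$seed)
  popN <- config$populationSize
  pop <- matrix(runif(popN * p) < config$initProb, popN, p)
  repair <- function(m) {
    if (!any(m)) m[sample.int(p, 1)] <- TRUE
    m
  }
  pop <- t(apply(pop, 1, repair))
  cache <- new.env(hash = TRUE)
  evals <- 0L
  evalMask <- function(m) {
    key <- paste(which(m), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    if (evals >= config$maxEvaluations) return(NA_real_)
    evals <<- evals + 1L
    f <- wrapperFitness(m, X, y, groups, config$innerFolds,
                        seed = config$seed)
    cache[[key]] <- f
    f
  }
  fitness <- apply(pop, 1, evalMask)
  fitness[is.na(fitness)] <- 0
  bestMask <- pop[which.max(fitness), ]
  bestFitness <- max(fitness)
  history <- numeric(0)
  for (gen in seq_len(config$generations)) {
    if (evals >= config$maxEvaluations) break
    history <- c(history, bestFitness)
    pick <- if (config$selection == "roulette") {
      w <- fitness - min(fitness) + 1e-9
      function() sample.int(popN, 1, prob = w)
    } else {
      function() {
        cand <- sample.int(popN, config$tournamentK)
        cand[which.max(fitness[cand])]
      }
    }
    newPop <- matrix(FALSE, popN, p)
    newPop[1, ] <- bestMask  # elitism: best chromosome found so far
    i <- 2L
    while (i <= popN) {
      kids <- if (runif(1) < config$crossoverRate)
        twoPointCrossover(pop[pick(), ], pop[pick(), ])
      else list(pop[pick(), ], pop[pick(), ])
      for (kid in kids) {
        if (i > popN) break
        flip <- runif(p) < config$mutationRate  # per-gene bit flips
        kid[flip] <- !kid[flip]
        newPop[i, ] <- repair(kid)
        i <- i + 1L
      }
    }
    pop <- newPop
    fitness <- apply(pop, 1, evalMask)
    fitness[is.na(fitness)] <- 0
    if (max(fitness) > bestFitness) {
      bestFitness <- max(fitness)
      bestMask <- pop[which.max(fitness), ]
    }
  }
  counts <- colSums(pop)
  names(counts) <- colnames(features)
  list(best = setNames(bestMask, colnames(features)),
       bestFitness = bestFitness,
       selectionCounts = counts, evaluations = evals,
       history = c(history, bestFitness))
}

#' Artifact-threshold sweep of the GA selection
#'
#' Re-runs channel/epoch rejection of the stored per-channel features at
#' each artifact threshold (via [aggregateFeatures()]), runs the GA at
#' each threshold, and reports per-threshold subsets plus the features
#' robust across thresholds (selected in over half of the final
#' population at every threshold).
#'
#' @param featureTables list of per-subject feature tables from
#'   [computeFeatureTable()].
#' @param labels list (per subject) or vector of integer labels.
#' @param thresholds channel-rejection thresholds to sweep.
#' @param config a [gaConfig()].
#' @return list with per-threshold GA results, the cross-threshold
#'   selection-frequency matrix, and `robust` (feature ids selected in
#'   over 50% of the final population at every threshold).
#' @export
thresholdSweep <- function(featureTables, labels,
                           thresholds = c(0, 0.10, 0.25, 0.50),
                           config = gaConfig()) {
  if (!is.list(featureTables)) featureTables <- list(featureTables)
  labVec <- if (is.list(labels)) unlist(labels) else labels
  perThr <- list()
  freq <- NULL
  for (th in thresholds) {
    agg <- lapply(featureTables, aggregateFeatures, chanThresh = th)
    X <- do.call(rbind, lapply(agg, featureValues))
    subj <- unlist(lapply(agg, function(a)
      as.character(SummarizedExperiment::colData(a)$subject)))
    res <- gaSelect(X, labVec, subj, config)
    perThr[[as.character(th)]] <- res
    freq <- rbind(freq, res$selectionCounts / config$populationSize)
  }
  rownames(freq) <- as.character(thresholds)
  robust <- colnames(freq)[apply(freq > 0.5, 2, all)]
  list(perThreshold = perThr, selectionFrequency = freq, robust = robust,
       thresholds = thresholds)
}

#' Accuracy as features are added by selection rank
#'
#' Trains the classifier on the top-1, top-2, ..., top-p features by the
#' given ranking and reports LOSO accuracy at each size.
#'
#' @param ranking feature indices or names, best first.
#' @param features epochs x features matrix.
#' @param subjects subject id per row.
#' @param labels integer labels per row.
#' @param sizes subset sizes to evaluate (default 1..p).
#' @param config a [neoTrainingConfig()] for the wrapped SVM.
#' @return data.frame with size and accuracy.
#' @export
accuracyVsCountCurve <- function(ranking, features, subjects, labels,
                                 sizes = NULL,
                                 config = neoTrainingConfig()) {
  features <- as.matrix(features)
  if (is.character(ranking)) ranking <- match(ranking, colnames(features))
  if (is.null(sizes)) sizes <- seq_along(ranking)
  acc <- vapply(sizes, function(k) {
    sel <- ranking[seq_len(k)]
    res <- losoCrossValidate(features[, sel, drop = FALSE], subjects,
                             labels, design = "svm", smote = FALSE,
                             config = config)
    ok <- !is.na(res$predicted) & !is.na(labels)
    mean(res$predicted[ok] == labels[ok])
  }, 0)
  data.frame(size = sizes, accuracy = acc)
}
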