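## Performance measures: confusion matrices, Cohen's kappa, macro and
## weighted accuracy/F1, bootstrap confidence intervals, per-subject and
## per-channel reports, and the composite human/classifier agreement
## table. REJECT (NA) epochs are excluded pairwise from every measure.

#' Cohen's kappa between two aligned categorical series
#'
#' kappa = (po - pe) / (1 - pe), with chance agreement pe from the
#' marginals. Degenerate convention: when pe = 1 (both raters constant),
#' kappa is 1 if the observed agreement is perfect and 0 otherwise.
#'
#' @param a,b aligned vectors; NA pairs excluded.
#' @return kappa between -1 and 1.
#' @export
cohenKappa <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (!length(a)) stop("no overlapping gradable epochs")
  lev <- sort(unique(c(a, b)))
  tab <- table(factor(a, lev), factor(b, lev))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < 1e-12) return(if (po >= 1 - 1e-12) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Confusion matrix and agreement scores
#'
#' Computes the K x K confusion matrix (reference in columns), overall
#' accuracy, Cohen's kappa, and macro (unweighted class mean) and
#' weighted (reference-support weighted) averages of per-class accuracy
#' (recall) and F1. Classes with no predictions and no references
#' contribute 0 to the macro averages, with a warning.
#'
#' @param pred predicted labels (or a [ScoreSeries-class]).
#' @param ref reference labels (or a [ScoreSeries-class]).
#' @return object of class `agreementResult`: list with confusion, kappa,
#'   accuracy, macroAcc, weightedAcc, macroF1, weightedF1, nEpochs.
#' @export
confusionAndScores <- function(pred, ref) {
  if (is(pred, "ScoreSeries")) pred <- scores(pred)
  if (is(ref, "ScoreSeries")) ref <- scores(ref)
  if (length(pred) != length(ref)) stop("series lengths differ")
  ok <- !is.na(pred) & !is.na(ref)
  if (!any(ok)) stop("no overlapping gradable epochs")
  pred <- pred[ok]; ref <- ref[ok]
  lev <- sort(unique(c(pred, ref)))
  tab <- table(factor(pred, lev), factor(ref, lev))
  n <- sum(tab)
  support <- colSums(tab)
  recall <- precision <- f1 <- numeric(length(lev))
  for (i in seq_along(lev)) {
    tp <- tab[i, i]
    recall[i] <- if (support[i] > 0) tp / support[i] else NA
    predN <- sum(tab[i, ])
    precision[i] <- if (predN > 0) tp / predN else NA
    f1[i] <- if (!is.na(recall[i]) && !is.na(precision[i]) &&
                 (recall[i] + precision[i]) > 0)
      2 * precision[i] * recall[i] / (precision[i] + recall[i]) else NA
  }
  undefined <- is.na(f1)
  if (any(undefined & support == 0))
    warning("class(es) with no support; contributing 0 to macro averages")
  f1z <- ifelse(is.na(f1), 0, f1)
  recz <- ifelse(is.na(recall), 0, recall)
  structure(list(
    confusion = tab,
    kappa = cohenKappa(pred, ref),
    accuracy = sum(diag(tab)) / n,
    macroAcc = mean(recz),
    weightedAcc = sum(recz * support) / n,
    macroF1 = mean(f1z),
    weightedF1 = sum(f1z * support) / n,
    perClass = data.frame(class = lev, support = as.numeric(support),
                          recall = recall, precision = precision, f1 = f1),
    nEpochs = n), class = "agreementResult")
}

#' @export
print.agreementResult <- function(x, ...) {
  cat(sprintf("Agreement over %d epochs: accuracy %.3f, kappa %.3f\n",
              x$nEpochs, x$accuracy, x$kappa))
  cat(sprintf("  macro acc %.3f / F1 %.3f; weighted acc %.3f / F1 %.3f\n",
              x$macroAcc, x$macroF1, x$weightedAcc, x$weightedF1))
  invisible(x)
}

#' Bootstrap confidence interval for an agreement metric
#'
#' Resamples epochs (prediction/reference pairs) with replacement and
#' reports the percentile 95% interval.
#'
#' @param metric function(pred, ref) -> scalar, e.g.
#'   `function(p, r) mean(p == r)` or [cohenKappa()].
#' @param pred,ref aligned label vectors (NA pairs excluded first).
#' @param n number of resamples (default 1,000).
#' @param seed integer seed.
#' @param level confidence level.
#' @return list with point, lo, hi, n, seed.
#' @export
bootstrapCI <- function(metric, pred, ref, n = 1000, seed = 1,
                        level = 0.95) {
  ok <- !is.na(pred) & !is.na(ref)
  pred <- pred[ok]; ref <- ref[ok]
  if (length(pred) < 10) stop("need at least 10 gradable epochs")
  set.seed(seed)
  point <- metric(pred, ref)
  stat <- vapply(seq_len(n), function(i) {
    idx <- sample.int(length(pred), replace = TRUE)
    metric(pred[idx], ref[idx])
  }, 0)
  a <- (1 - level) / 2
  q <- quantile(stat, c(a, 1 - a), names = FALSE, na.rm = TRUE)
  list(point = point, lo = q[1], hi = q[2], n = n, seed = seed)
}

#' Per-subject and per-channel performance report
#'
#' Per-subject accuracy of LOSO predictions against one or more reference
#' series, plus (optionally) per-channel accuracy obtained by re-running
#' the LOSO classification on channel-restricted feature tables.
#'
#' @param predicted integer predictions per epoch.
#' @param subjects subject id per epoch.
#' @param references named list of reference label vectors (e.g.,
#'   list(CONS = ..., E1 = ..., E2 = ...)).
#' @param channelFeatures optional named list (channel -> epochs x
#'   features matrix) of channel-restricted features.
#' @param labelsForChannels labels used to re-run LOSO per channel
#'   (defaults to the first reference).
#' @param config a [neoTrainingConfig()] for the per-channel re-runs.
#' @return list with `perSubject` (data.frame) and `perChannel`
#'   (data.frame or NULL).
#' @export
perSubjectReport <- function(predicted, subjects, references,
                             channelFeatures = NULL,
                             labelsForChannels = NULL,
                             config = neoTrainingConfig()) {
  if (!is.list(references)) references <- list(reference = references)
  us <- unique(subjects)
  rows <- list()
  for (s in us) {
    sel <- subjects == s
    for (rn in names(references)) {
      r <- references[[rn]][sel]
      p <- predicted[sel]
      ok <- !is.na(r) & !is.na(p)
      if (!any(ok)) {
        warning(sprintf("subject '%s' has no gradable epochs vs %s", s, rn))
        next
      }
      rows[[length(rows) + 1]] <- data.frame(
        subject = s, reference = rn, nEpochs = sum(ok),
        accuracy = mean(p[ok] == r[ok]), stringsAsFactors = FALSE)
    }
  }
  perSubject <- do.call(rbind, rows)
  perChannel <- NULL
  if (!is.null(channelFeatures)) {
    if (is.null(labelsForChannels)) labelsForChannels <- references[[1]]
    accs <- vapply(names(channelFeatures), function(ch) {
      res <- losoCrossValidate(channelFeatures[[ch]], subjects,
                               labelsForChannels, design = "svm",
                               smote = FALSE, config = config)
      ok <- !is.na(res$predicted) & !is.na(labelsForChannels)
      mean(res$predicted[ok] == labelsForChannels[ok])
    }, 0)
    perChannel <- data.frame(channel = names(channelFeatures),
                             accuracy = accs, stringsAsFactors = FALSE)
  }
  list(perSubject = perSubject, perChannel = perChannel)
}

#' Composite agreement between two raters and a classifier
#'
#' Pairwise Cohen's kappa for (E1, E2), (E1, clf) and (E2, clf), plus a
#' non-inferiority flag: the classifier is non-inferior to a human rater
#' when its worse agreement with either rater is at least the inter-rater
#' agreement.
#'
#' @param e1,e2 rater label vectors (or [ScoreSeries-class]).
#' @param clf classifier label vector.
#' @return list with `kappa` (named numeric) and `nonInferior` (logical).
#' @export
compositeAgreement <- function(e1, e2, clf) {
  if (is(e1, "ScoreSeries")) e1 <- scores(e1)
  if (is(e2, "ScoreSeries")) e2 <- scores(e2)
  if (is(clf, "ScoreSeries")) clf <- scores(clf)
  k <- c(E1_E2 = cohenKappa(e1, e2),
         E1_clf = cohenKappa(e1, clf),
         E2_clf = cohenKappa(e2, clf))
  list(kappa = k, nonInferior = min(k["E1_clf"], k["E2_clf"]) >= k["E1_E2"])
}
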