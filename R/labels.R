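## Expert score handling: 7-to-5 score merger, running-median smoothing,
## consensus/all training-set construction, hierarchical grouping, and
## SMOTE class balancing. REJECT epochs (NA) carry no background
## information: they are excluded from smoothing windows, never
## overwritten, and dropped from training sets.

#' Merge the 7-score scheme to the 5-score scheme
#'
#' Scores 0, 1 and 2 (normal/near-normal vigilance states with the same
#' clinical interpretation) merge into one score; the remaining scores are
#' renumbered: \{0,1,2\} -> 0, 3 -> 1, 4 -> 2, 5 -> 3, 6 -> 4. REJECT is
#' preserved.
#'
#' @param series a 7-score [ScoreSeries-class].
#' @return a 5-score [ScoreSeries-class].
#' @export
#' @examples
#' scores(merge7to5(ScoreSeries(0:6)))  # 0 0 0 1 2 3 4
merge7to5 <- function(series) {
  stopifnot(is(series, "ScoreSeries"))
  if (scheme(series) != "7-score")
    stop("series is already on the 5-score scheme")
  map <- c(0L, 0L, 0L, 1L, 2L, 3L, 4L)
  s <- scores(series)
  out <- ifelse(is.na(s), NA_integer_, map[s + 1L])
  ScoreSeries(out, scheme = "5-score", subjectId = subjectId(series),
              raterId = series@raterId)
}

## Running median over non-REJECT neighbours. Shrunken windows at the
## edges; even counts take the lower middle value so the output stays a
## valid ordinal score.
runningMedianScores <- function(s, window) {
  n <- length(s)
  half <- (window - 1L) %/% 2L
  out <- s
  for (i in seq_len(n)) {
    if (is.na(s[i])) next
    lo <- max(1L, i - half); hi <- min(n, i + half)
    w <- s[lo:hi]
    w <- sort(w[!is.na(w)])
    out[i] <- w[ceiling(length(w) / 2)]
  }
  out
}

#' Median smoothing of a score series
#'
#' Centered running median over the non-REJECT scores in the window;
#' edges use the available shrunken window; REJECT positions stay REJECT.
#' With an even number of gradable neighbours the lower middle value is
#' taken, so smoothing never invents a score absent from the window.
#' The default window of 5 epochs (25 min) is the annotation-smoothing
#' setting; classifier outputs are smoothed with window 7.
#'
#' @param series a [ScoreSeries-class].
#' @param window odd integer window length in epochs (3-13).
#' @return the smoothed [ScoreSeries-class].
#' @export
smoothScores <- function(series, window = 5) {
  stopifnot(is(series, "ScoreSeries"))
  if (window %% 2 == 0) stop("'window' must be odd")
  if (window < 3 || window > 13) stop("'window' must be in 3..13")
  out <- runningMedianScores(scores(series), as.integer(window))
  ScoreSeries(out, scheme = scheme(series), subjectId = subjectId(series),
              raterId = series@raterId)
}

#' Build a training set from two raters' annotations
#'
#' CONS keeps only epochs where the raters agree (one row each); ALL emits
#' one row per rater per epoch, so consensus epochs appear twice (double
#' weight) and disagreement epochs contribute both scores. Epochs marked
#' REJECT by either rater are excluded from CONS; in ALL they are excluded
#' per rater.
#'
#' @param e1,e2 aligned [ScoreSeries-class] from the two raters.
#' @param features epochs x features numeric matrix aligned with the
#'   series.
#' @param mode "CONS" or "ALL".
#' @return A [TrainingSet-class].
#' @export
buildTrainingSet <- function(e1, e2, features, mode = c("ALL", "CONS")) {
  mode <- match.arg(mode)
  stopifnot(is(e1, "ScoreSeries"), is(e2, "ScoreSeries"))
  s1 <- scores(e1); s2 <- scores(e2)
  if (length(s1) != length(s2) || length(s1) != nrow(features))
    stop("annotation series and feature rows are misaligned")
  rows <- list()
  if (mode == "CONS") {
    keep <- !is.na(s1) & !is.na(s2) & s1 == s2
    rows <- data.frame(epoch = which(keep), label = s1[keep],
                       rater = "CONS", stringsAsFactors = FALSE)
  } else {
    k1 <- !is.na(s1); k2 <- !is.na(s2)
    rows <- rbind(
      data.frame(epoch = which(k1), label = s1[k1], rater = e1@raterId,
                 stringsAsFactors = FALSE),
      data.frame(epoch = which(k2), label = s2[k2], rater = e2@raterId,
                 stringsAsFactors = FALSE))
  }
  new("TrainingSet",
      features = features[rows$epoch, , drop = FALSE],
      labels = as.integer(rows$label),
      weights = rep(1, nrow(rows)),
      provenance = data.frame(subject = subjectId(e1), epoch = rows$epoch,
                              rater = rows$rater, stringsAsFactors = FALSE),
      mode = mode)
}

#' Default hierarchical score groupings
#'
#' Level-1 groupings of the background scores for the two hierarchical
#' classification strategies. Severity groups by clinical inference
#' (normal \{0,1,2\}, moderate \{3,4\}, severe \{5,6\}); continuity
#' separates the continuity-defined scores \{0,1,2,3,5\} from the
#' amplitude-defined ones \{4,6\}. On the 5-score scheme the merged score
#' 0 stands for the original \{0,1,2\}.
#'
#' @param strategy "severity" or "continuity".
#' @param scheme "7-score" or "5-score".
#' @return named list mapping group name to score vector.
#' @export
hierarchyGroups <- function(strategy = c("severity", "continuity"),
                            scheme = c("7-score", "5-score")) {
  strategy <- match.arg(strategy)
  scheme <- match.arg(scheme)
  if (strategy == "severity") {
    if (scheme == "7-score")
      list(normal = 0:2, moderate = 3:4, severe = 5:6)
    else
      list(normal = 0L, moderate = 1:2, severe = 3:4)
  } else {
    if (scheme == "7-score")
      list(continuity = c(0L, 1L, 2L, 3L, 5L), amplitude = c(4L, 6L))
    else
      list(continuity = c(0L, 1L, 3L), amplitude = c(2L, 4L))
  }
}

#' Group a score series for hierarchical classification
#'
#' Maps each score to its level-1 group and its within-group sublabel.
#' Reassembling (group, sublabel) reproduces the original score exactly.
#'
#' @param series a [ScoreSeries-class].
#' @param strategy "severity" or "continuity".
#' @param groups optional custom grouping (named list of score vectors
#'   partitioning the scheme's scores).
#' @return list with `level1` (integer group index per epoch, NA for
#'   REJECT), `level2` (position of the score within its group), `groups`
#'   (the mapping used).
#' @export
groupHierarchy <- function(series, strategy = c("severity", "continuity"),
                           groups = NULL) {
  stopifnot(is(series, "ScoreSeries"))
  strategy <- match.arg(strategy)
  if (is.null(groups)) groups <- hierarchyGroups(strategy, scheme(series))
  all <- sort(unlist(groups))
  hi <- if (scheme(series) == "7-score") 6L else 4L
  if (!identical(as.integer(all), 0:hi))
    stop("'groups' must partition the scores of the scheme")
  s <- scores(series)
  level1 <- rep(NA_integer_, length(s))
  level2 <- rep(NA_integer_, length(s))
  for (g in seq_along(groups)) {
    inG <- !is.na(s) & s %in% groups[[g]]
    level1[inG] <- g
    level2[inG] <- match(s[inG], sort(groups[[g]]))
  }
  list(level1 = level1, level2 = level2, groups = groups)
}

#' @rdname groupHierarchy
#' @param level1,level2 outputs of `groupHierarchy`.
#' @export
ungroupHierarchy <- function(level1, level2, groups) {
  out <- rep(NA_integer_, length(level1))
  for (g in seq_along(groups)) {
    inG <- !is.na(level1) & level1 == g
    out[inG] <- sort(groups[[g]])[level2[inG]]
  }
  out
}

#' SMOTE class balancing
#'
#' Synthetic minority oversampling: minority classes are oversampled to
#' the majority count; each synthetic row is a uniform convex combination
#' of a minority row and one of its k nearest minority neighbours
#' (Euclidean distance in feature space). k is capped at class size - 1.
#'
#' @param ts a [TrainingSet-class]; every class must have >= 2 members.
#' @param k number of nearest neighbours (default 10).
#' @param seed integer seed.
#' @return the balanced [TrainingSet-class] (synthetic rows are flagged
#'   with rater "SMOTE" in the provenance).
#' @export
smoteBalance <- function(ts, k = 10, seed = 1) {
  stopifnot(is(ts, "TrainingSet"))
  set.seed(seed)
  labs <- trainingLabels(ts)
  counts <- table(labs)
  if (any(counts < 2)) {
    bad <- names(counts)[counts < 2]
    stop(sprintf("class %s has fewer than 2 members; cannot oversample",
                 paste(bad, collapse = ", ")))
  }
  target <- max(counts)
  X <- trainingFeatures(ts)
  newX <- list(); newL <- integer(0); newEp <- integer(0); newSub <- character(0)
  for (cl in names(counts)) {
    need <- target - counts[[cl]]
    if (need == 0) next
    idx <- which(labs == as.integer(cl))
    Xc <- X[idx, , drop = FALSE]
    kc <- min(k, nrow(Xc) - 1)
    D <- as.matrix(stats::dist(Xc))
    diag(D) <- Inf
    ord <- apply(D, 1, function(d) order(d)[seq_len(kc)])
    nn <- if (kc == 1) matrix(ord, ncol = 1) else t(ord)
    pick <- sample(nrow(Xc), need, replace = TRUE)
    syn <- matrix(0, need, ncol(X))
    for (i in seq_len(need)) {
      a <- pick[i]
      b <- nn[a, sample.int(kc, 1)]
      lam <- runif(1)
      syn[i, ] <- Xc[a, ] + lam * (Xc[b, ] - Xc[a, ])
    }
    newX[[length(newX) + 1]] <- syn
    newL <- c(newL, rep(as.integer(cl), need))
    newEp <- c(newEp, rep(NA_integer_, need))
    newSub <- c(newSub, rep(ts@provenance$subject[idx[1]], need))
  }
  if (!length(newX)) return(ts)
  synX <- do.call(rbind, newX)
  colnames(synX) <- colnames(X)
  new("TrainingSet",
      features = rbind(X, synX),
      labels = c(labs, newL),
      weights = c(ts@weights, rep(1, length(newL))),
      provenance = rbind(ts@provenance,
                         data.frame(subject = newSub, epoch = newEp,
                                    rater = "SMOTE", stringsAsFactors = FALSE)),
      mode = ts@mode)
}
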