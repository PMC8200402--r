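## End-to-end synthetic cohort: simulate labeled recordings for several
## subjects, preprocess, extract features, and simulate two expert
## raters. This is the test bench standing in for clinical data.

#' Simulate a labeled multi-subject cohort through the full pipeline
#'
#' Each subject receives a trajectory of background states: blocks of
#' `blockMinutes` drawn as a random walk over `scoreSet` (gradual
#' evolution between neighbouring severity states). Recordings are
#' simulated at the native rate, preprocessed to 64 Hz epochs, and the
#' full feature table is computed. Two synthetic raters annotate each
#' subject as noisy copies of the truth.
#'
#' @param nSubjects number of subjects.
#' @param hoursPerSubject recording duration per subject (multiple of the
#'   block structure; 3 h by default).
#' @param nChannels channels per recording (default 4: the reduced F3,
#'   F4, P3, P4 monitoring montage).
#' @param fsNative native sampling rate.
#' @param scoreSet 7-score classes visited by the trajectories (default:
#'   one representative of each merged 5-score class).
#' @param blockMinutes allowed block lengths in minutes (multiples of 5).
#' @param raterAgreement per-epoch probability that a rater copies the
#'   truth.
#' @param artifactRate artifact events per hour.
#' @param chanThresh,epochThresh rejection thresholds.
#' @param seed master seed; per-subject seeds derive from it.
#' @return list with stacked `features` (epochs x 98), `subjects`,
#'   integer 7-score vectors `truth`, `e1`, `e2`, their merged 5-score
#'   versions `truth5`, `e1s5`, `e2s5` (raters merged then smoothed with
#'   window 5), per-subject `featureTables`, and `series` (per-subject
#'   ScoreSeries lists).
#' @export
simulateCohort <- function(nSubjects = 10, hoursPerSubject = 3,
                           nChannels = 4, fsNative = 200,
                           scoreSet = c(0L, 3L, 4L, 5L, 6L),
                           blockMinutes = c(35, 40, 45, 50, 55, 60),
                           raterAgreement = 0.9, artifactRate = 0,
                           chanThresh = 0.25, epochThresh = 0.5,
                           seed = 1) {
  stopifnot(all(blockMinutes %% 5 == 0))
  featureTables <- list(); series <- list()
  feats <- list(); subjVec <- character(0)
  truth <- e1v <- e2v <- integer(0)
  truth5v <- e1s5v <- e2s5v <- integer(0)
  for (s in seq_len(nSubjects)) {
    sSeed <- seed * 100L + s
    set.seed(sSeed)
    totalMin <- hoursPerSubject * 60
    traj <- list()
    cur <- sample(scoreSet, 1)
    used <- 0
    while (used < totalMin) {
      len <- min(sample(blockMinutes, 1), totalMin - used)
      ## never leave a remainder shorter than the minimum block: absorb it
      ## so every true state lasts at least min(blockMinutes)
      if (totalMin - used - len < min(blockMinutes)) len <- totalMin - used
      len <- max(5, 5 * floor(len / 5))
      traj[[length(traj) + 1]] <- c(cur, len)
      used <- used + len
      pos <- match(cur, scoreSet)
      step <- sample(c(-1, 1), 1)
      pos <- min(max(pos + step, 1), length(scoreSet))
      cur <- scoreSet[pos]
    }
    cfg <- simConfig(traj, nChannels = nChannels, fsNative = fsNative,
                     artifactRate = artifactRate, seed = sSeed,
                     subjectId = sprintf("subj%02d", s))
    sim <- simulateRecording(cfg)
    es <- preprocessRecording(sim$recording, chanThresh, epochThresh)
    ft <- computeFeatureTable(es)
    tr <- sim$truth
    e1 <- simulateRaters(tr, pAgree = raterAgreement, raterId = "E1",
                         seed = sSeed + 1L)
    e2 <- simulateRaters(tr, pAgree = raterAgreement, raterId = "E2",
                         seed = sSeed + 2L)
    e1s5 <- smoothScores(merge7to5(e1), 5)
    e2s5 <- smoothScores(merge7to5(e2), 5)
    featureTables[[s]] <- ft
    series[[s]] <- list(truth = tr, e1 = e1, e2 = e2,
                        e1s5 = e1s5, e2s5 = e2s5)
    X <- featureValues(ft)
    feats[[s]] <- X
    subjVec <- c(subjVec, rep(subjectId(tr), nrow(X)))
    truth <- c(truth, scores(tr))
    e1v <- c(e1v, scores(e1)); e2v <- c(e2v, scores(e2))
    truth5v <- c(truth5v, scores(merge7to5(tr)))
    e1s5v <- c(e1s5v, scores(e1s5)); e2s5v <- c(e2s5v, scores(e2s5))
  }
  list(features = do.call(rbind, feats), subjects = subjVec,
       truth = truth, e1 = e1v, e2 = e2v,
       truth5 = truth5v, e1s5 = e1s5v, e2s5 = e2s5v,
       featureTables = featureTables, series = series)
}

#' Smooth a stacked prediction vector per subject
#'
#' Applies [smoothScores()] within each subject's epoch sequence of a
#' stacked prediction vector (classifier-output smoothing, default
#' window 7).
#'
#' @param predicted integer labels per epoch.
#' @param subjects subject id per epoch.
#' @param window odd smoothing window.
#' @param scheme score scheme of the labels.
#' @return smoothed integer vector.
#' @export
smoothPredictions <- function(predicted, subjects, window = 7,
                              scheme = "5-score") {
  out <- predicted
  for (s in unique(subjects)) {
    sel <- subjects == s
    ss <- ScoreSeries(predicted[sel], scheme = scheme, subjectId = s,
                      raterId = "clf")
    out[sel] <- scores(smoothScores(ss, window))
  }
  out
}
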