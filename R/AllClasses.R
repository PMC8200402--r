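#' @import methods
#' @importFrom stats median quantile sd rnorm runif rgamma rpois rbinom fft
#'   approx predict glm binomial coef aggregate setNames
#' @importFrom utils head tail write.table read.table
#' @useDynLib neobg, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

## Central data objects. Scores are stored as integers on the clinical
## ordinal scale; REJECT (ungradable epoch) is represented by NA.

#' EEGRecording: continuous multi-channel EEG
#'
#' Container for a continuous multi-channel scalp EEG recording in
#' microvolts. Channels are rows of `data`; electrode labels follow the
#' international 10-20 placement for referential montages, or
#' "A-B" compound labels for bipolar derivations.
#'
#' @slot data numeric matrix, channels x samples, in microvolts.
#' @slot channelLabels character vector of electrode labels.
#' @slot fs sampling rate in Hz.
#' @slot montage "referential" or "bipolar".
#' @slot subjectId subject identifier.
#' @exportClass EEGRecording
setClass("EEGRecording",
  representation(
    data = "matrix",
    channelLabels = "character",
    fs = "numeric",
    montage = "character",
    subjectId = "character"
  ),
  prototype(montage = "referential", subjectId = "subject")
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (nrow(object@data) != length(object@channelLabels))
    msg <- c(msg, "number of rows of 'data' must equal length of 'channelLabels'")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "'fs' must be a single positive number")
  if (!object@montage %in% c("referential", "bipolar"))
    msg <- c(msg, "'montage' must be 'referential' or 'bipolar'")
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param channelLabels character vector, one label per row of `data`.
#' @param fs sampling rate in Hz.
#' @param montage "referential" (default) or "bipolar".
#' @param subjectId subject identifier string.
#' @return An [EEGRecording-class] object.
#' @export
EEGRecording <- function(data, channelLabels, fs, montage = "referential",
                         subjectId = "subject") {
  new("EEGRecording", data = data, channelLabels = as.character(channelLabels),
      fs = fs, montage = montage, subjectId = as.character(subjectId))
}

#' EpochSet: artifact-masked 5-minute epochs at 64 Hz
#'
#' Result of the preprocessing chain. Epoch data are stored as a
#' channel x sample x epoch array at 64 Hz; each epoch holds exactly
#' 19,200 samples (300 s). The artifact mask marks samples flagged by the
#' amplitude/flat-signal scan; `maskedFraction` is its per-epoch,
#' per-channel mean, from which channel and epoch rejection flags are
#' derived (a channel is rejected in an epoch when at least the channel
#' threshold of its samples is masked; the epoch is rejected when at least
#' the epoch threshold of channels is rejected).
#'
#' @slot epochs numeric array, channel x 19200 x epoch (microvolts, 64 Hz).
#' @slot artifactMask logical array, same shape as `epochs`.
#' @slot maskedFraction numeric matrix, epoch x channel.
#' @slot channelRejected logical matrix, epoch x channel.
#' @slot epochRejected logical vector, one per epoch.
#' @slot channelLabels character vector.
#' @slot fs sampling rate (always 64).
#' @slot subjectId subject identifier.
#' @exportClass EpochSet
setClass("EpochSet",
  representation(
    epochs = "array",
    artifactMask = "array",
    maskedFraction = "matrix",
    channelRejected = "matrix",
    epochRejected = "logical",
    channelLabels = "character",
    fs = "numeric",
    subjectId = "character"
  )
)

setValidity("EpochSet", function(object) {
  d <- dim(object@epochs)
  msg <- character()
  if (length(d) != 3L)
    msg <- c(msg, "'epochs' must be a 3-d array (channel x sample x epoch)")
  else {
    if (d[2] != 19200L)
      msg <- c(msg, "each epoch must hold exactly 19,200 samples per channel")
    if (!identical(dim(object@artifactMask), d))
      msg <- c(msg, "'artifactMask' must have the same shape as 'epochs'")
    if (!identical(dim(object@maskedFraction), c(d[3], d[1])))
      msg <- c(msg, "'maskedFraction' must be epoch x channel")
    if (!identical(dim(object@channelRejected), c(d[3], d[1])))
      msg <- c(msg, "'channelRejected' must be epoch x channel")
    if (length(object@epochRejected) != d[3])
      msg <- c(msg, "'epochRejected' must have one flag per epoch")
    if (length(object@channelLabels) != d[1])
      msg <- c(msg, "'channelLabels' must have one label per channel")
  }
  if (length(msg)) msg else TRUE
})

#' ScoreSeries: per-epoch ordinal background scores
#'
#' One background score per non-overlapping 5-minute epoch on either the
#' 7-score clinical scale (0-6) or the merged 5-score scale (0-4). REJECT
#' (ungradable) epochs are stored as NA and are excluded from all metric
#' computations.
#'
#' @slot scores integer vector; NA encodes REJECT.
#' @slot scheme "7-score" or "5-score".
#' @slot subjectId subject identifier.
#' @slot raterId rater/classifier identifier.
#' @exportClass ScoreSeries
setClass("ScoreSeries",
  representation(
    scores = "integer",
    scheme = "character",
    subjectId = "character",
    raterId = "character"
  ),
  prototype(scheme = "7-score", subjectId = "subject", raterId = "rater")
)

setValidity("ScoreSeries", function(object) {
  msg <- character()
  if (!object@scheme %in% c("7-score", "5-score"))
    msg <- c(msg, "'scheme' must be '7-score' or '5-score'")
  hi <- if (object@scheme == "7-score") 6L else 4L
  s <- object@scores[!is.na(object@scores)]
  if (length(s) && (any(s < 0L) || any(s > hi)))
    msg <- c(msg, sprintf("scores must lie in 0..%d (NA = REJECT)", hi))
  if (length(msg)) msg else TRUE
})

#' Construct a ScoreSeries
#'
#' @param scores integer-like vector of per-epoch scores; NA = REJECT.
#' @param scheme "7-score" (default) or "5-score".
#' @param subjectId,raterId identifiers.
#' @return A [ScoreSeries-class] object.
#' @export
ScoreSeries <- function(scores, scheme = "7-score", subjectId = "subject",
                        raterId = "rater") {
  new("ScoreSeries", scores = as.integer(scores), scheme = scheme,
      subjectId = as.character(subjectId), raterId = as.character(raterId))
}

#' BackgroundClassParams: generative parameters of one background class
#'
#' Parameters realizing one clinical background score. Discontinuous
#' classes (1, 2, 3, 5) alternate bursts and interburst intervals (IBI):
#' the IBI voltage and duration define the class (trace alternant: IBI
#' voltage >= 25 uV, split at 6 s IBI duration; trace discontinu: IBI
#' voltage < 25 uV; burst suppression: IBI voltage < 5 uV). Amplitude
#' classes are defined by the continuous envelope range: depressed
#' 5-15 uV, very low voltage < 5 uV. Validity enforces these inequalities.
#'
#' @slot score integer 0-6.
#' @slot burstAmp peak-to-peak burst amplitude, uV.
#' @slot ibiAmp peak-to-peak interburst voltage, uV.
#' @slot ibiDur mean interburst duration, s.
#' @slot burstDur mean burst duration, s.
#' @slot contRange length-2 amplitude envelope (low, high) for
#'   non-bursting classes, uV peak-to-peak.
#' @slot spectralExponent 1/f slope of the carrier noise.
#' @exportClass BackgroundClassParams
setClass("BackgroundClassParams",
  representation(
    score = "integer",
    burstAmp = "numeric",
    ibiAmp = "numeric",
    ibiDur = "numeric",
    burstDur = "numeric",
    contRange = "numeric",
    spectralExponent = "numeric"
  )
)

setValidity("BackgroundClassParams", function(object) {
  msg <- character()
  s <- object@score
  if (length(s) != 1L || is.na(s) || s < 0L || s > 6L)
    msg <- c(msg, "'score' must be a single integer in 0..6")
  else {
    if (s == 1L && !(object@ibiAmp >= 25 && object@ibiDur <= 6))
      msg <- c(msg, "score 1 requires IBI voltage >= 25 uV and IBI duration <= 6 s")
    if (s == 2L && !(object@ibiAmp >= 25 && object@ibiDur > 6))
      msg <- c(msg, "score 2 requires IBI voltage >= 25 uV and IBI duration > 6 s")
    if (s == 3L && !(object@ibiAmp < 25))
      msg <- c(msg, "score 3 requires IBI voltage < 25 uV")
    if (s == 5L && !(object@ibiAmp < 5))
      msg <- c(msg, "score 5 requires IBI voltage < 5 uV")
    if (s == 4L && !(object@contRange[1] >= 5 && object@contRange[2] <= 15))
      msg <- c(msg, "score 4 requires the amplitude envelope within [5, 15] uV")
    if (s == 6L && !(object@contRange[2] < 5))
      msg <- c(msg, "score 6 requires the envelope < 5 uV")
    if (s %in% c(1L, 2L, 3L, 5L) && (object@ibiDur <= 0 || object@burstDur <= 0))
      msg <- c(msg, "burst/IBI durations must be positive")
    if (length(object@contRange) != 2L || any(object@contRange < 0) ||
        object@contRange[1] > object@contRange[2])
      msg <- c(msg, "'contRange' must be nonnegative (low, high)")
  }
  if (length(msg)) msg else TRUE
})

#' ProbSeries: per-epoch class posterior probabilities
#'
#' @slot probs numeric matrix, epochs x classes; each row sums to 1.
#' @slot classValues numeric score value of each class column (the
#'   position of the class on the ordinal background scale).
#' @slot time epoch start times in hours.
#' @exportClass ProbSeries
setClass("ProbSeries",
  representation(
    probs = "matrix",
    classValues = "numeric",
    time = "numeric"
  )
)

setValidity("ProbSeries", function(object) {
  msg <- character()
  p <- object@probs
  if (ncol(p) != length(object@classValues))
    msg <- c(msg, "'classValues' must match the number of probability columns")
  if (nrow(p) != length(object@time))
    msg <- c(msg, "'time' must have one entry per epoch")
  ok <- is.finite(p)
  if (!all(ok))
    msg <- c(msg, "probabilities must be finite")
  else {
    if (any(p < -1e-9) || any(p > 1 + 1e-9))
      msg <- c(msg, "probabilities must lie in [0, 1]")
    if (nrow(p) && any(abs(rowSums(p) - 1) > 1e-6))
      msg <- c(msg, "each probability row must sum to 1 (tolerance 1e-6)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ProbSeries
#'
#' @param probs epochs x classes probability matrix (rows sum to 1).
#' @param classValues numeric value of each class on the score scale;
#'   defaults to the column names or 0..K-1.
#' @param time epoch start times in hours (defaults to 5-min spacing).
#' @return A [ProbSeries-class] object.
#' @export
probSeries <- function(probs, classValues = NULL, time = NULL) {
  probs <- as.matrix(probs)
  if (is.null(classValues)) {
    classValues <- if (!is.null(colnames(probs)))
      suppressWarnings(as.numeric(colnames(probs))) else seq_len(ncol(probs)) - 1
    if (anyNA(classValues)) classValues <- seq_len(ncol(probs)) - 1
  }
  if (is.null(time)) time <- (seq_len(nrow(probs)) - 1) * 5 / 60
  new("ProbSeries", probs = probs, classValues = as.numeric(classValues),
      time = as.numeric(time))
}

#' BTrend: unidimensional background trend with uncertainty band
#'
#' @slot bt smoothed probability-weighted score per epoch.
#' @slot btRaw unsmoothed weighted average.
#' @slot uncertainty per-epoch nonnegative half-width (probability-weighted
#'   SD of the class values).
#' @slot time epoch start times in hours.
#' @slot window smoothing window in epochs.
#' @exportClass BTrend
setClass("BTrend",
  representation(
    bt = "numeric",
    btRaw = "numeric",
    uncertainty = "numeric",
    time = "numeric",
    window = "integer"
  )
)

#' TrainingSet: rows for classifier training
#'
#' @slot features numeric matrix, rows x features.
#' @slot labels integer class labels.
#' @slot weights numeric row weights.
#' @slot provenance data.frame with subject, epoch, rater per row.
#' @slot mode "CONS", "ALL" or "SINGLE".
#' @exportClass TrainingSet
setClass("TrainingSet",
  representation(
    features = "matrix",
    labels = "integer",
    weights = "numeric",
    provenance = "data.frame",
    mode = "character"
  )
)

setValidity("TrainingSet", function(object) {
  n <- nrow(object@features)
  msg <- character()
  if (length(object@labels) != n) msg <- c(msg, "one label per feature row required")
  if (length(object@weights) != n) msg <- c(msg, "one weight per feature row required")
  if (nrow(object@provenance) != n) msg <- c(msg, "one provenance row per feature row required")
  if (length(msg)) msg else TRUE
})

## Trained classifier models -------------------------------------------------

#' Virtual parent of trained background classifiers
#' @slot classSet integer labels the model distinguishes.
#' @slot norm list(center, scale, impute) fitted on the training fold only.
#' @slot approach "flat", "continuity" or "severity".
#' @slot featureNames feature ids used at fit time.
#' @exportClass NeoModel
setClass("NeoModel",
  representation("VIRTUAL",
    classSet = "integer",
    norm = "list",
    approach = "character",
    featureNames = "character"
  )
)

#' @rdname NeoModel-class
#' @slot learners list of pairwise binary SVMs with calibration.
#' @slot pairs integer matrix of class pairs, one row per binary learner.
#' @slot cost tuned box-constraint value.
#' @exportClass SVMModel
setClass("SVMModel", contains = "NeoModel",
  representation(learners = "list", pairs = "matrix", cost = "numeric"))

#' @rdname NeoModel-class
#' @slot weights list of layer weights and biases (W1,b1,W2,b2,W3,b3).
#' @slot config training configuration used.
#' @slot history list of training diagnostics.
#' @exportClass MFNNModel
setClass("MFNNModel", contains = "NeoModel",
  representation(weights = "list", config = "list", history = "list"))

#' @rdname NeoModel-class
#' @slot weights forward weights plus recurrent matrix Wr.
#' @slot config training configuration used.
#' @exportClass RNNModel
setClass("RNNModel", contains = "NeoModel",
  representation(weights = "list", config = "list"))

#' Hierarchical model: level-1 grouper plus per-group level-2 models
#' @slot level1 trained level-1 model over group indices.
#' @slot level2 list of level-2 models, one per multi-class group.
#' @slot groups named list mapping group name -> score vector.
#' @exportClass HierarchicalModel
setClass("HierarchicalModel", contains = "NeoModel",
  representation(level1 = "NeoModel", level2 = "list", groups = "list"))

## show methods ---------------------------------------------------------------

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording '%s': %d channels x %d samples @ %g Hz (%s), %.1f min\n",
              object@subjectId, nrow(object@data), ncol(object@data),
              object@fs, object@montage, ncol(object@data) / object@fs / 60))
  cat("  channels:", paste(object@channelLabels, collapse = " "), "\n")
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@epochs)
  cat(sprintf("EpochSet '%s': %d epochs x %d channels x %d samples @ %g Hz\n",
              object@subjectId, d[3], d[1], d[2], object@fs))
  cat(sprintf("  rejected: %d/%d channel-epochs, %d/%d epochs\n",
              sum(object@channelRejected), length(object@channelRejected),
              sum(object@epochRejected), d[3]))
})

setMethod("show", "ScoreSeries", function(object) {
  cat(sprintf("ScoreSeries '%s' (%s, rater %s): %d epochs, %d REJECT\n",
              object@subjectId, object@scheme, object@raterId,
              length(object@scores), sum(is.na(object@scores))))
})

setMethod("show", "BackgroundClassParams", function(object) {
  cat(sprintf("BackgroundClassParams score %d\n", object@score))
})

setMethod("show", "ProbSeries", function(object) {
  cat(sprintf("ProbSeries: %d epochs x %d classes (values %s)\n",
              nrow(object@probs), ncol(object@probs),
              paste(object@classValues, collapse = ", ")))
})

setMethod("show", "BTrend", function(object) {
  cat(sprintf("BTrend: %d epochs, smoothing window %d\n",
              length(object@bt), object@window))
})

setMethod("show", "TrainingSet", function(object) {
  cat(sprintf("TrainingSet (%s): %d rows x %d features, classes {%s}\n",
              object@mode, nrow(object@features), ncol(object@features),
              paste(sort(unique(object@labels)), collapse = ",")))
})

setMethod("show", "SVMModel", function(object) {
  cat(sprintf("SVMModel (%s): %d classes, %d pairwise linear learners, cost %.4g\n",
              object@approach, length(object@classSet),
              length(object@learners), object@cost))
})

setMethod("show", "MFNNModel", function(object) {
  cat(sprintf("MFNNModel (%s): %d classes, hidden (%d, %d)\n",
              object@approach, length(object@classSet),
              nrow(object@weights$W1), nrow(object@weights$W2)))
})

setMethod("show", "RNNModel", function(object) {
  cat(sprintf("RNNModel (%s): %d classes, recurrent layer %d units\n",
              object@approach, length(object@classSet), nrow(object@weights$Wr)))
})

## Accessors ------------------------------------------------------------------

#' Accessors for neobg data classes
#'
#' Small generic accessors so code never reaches into slots directly.
#'
#' @param x an object of the relevant class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setMethod("channelLabels", "EEGRecording", function(x) x@channelLabels)
#' @rdname accessors
#' @export
setMethod("channelLabels", "EpochSet", function(x) x@channelLabels)

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@fs)
#' @rdname accessors
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@fs)

#' @rdname accessors
#' @export
setGeneric("eegData", function(x) standardGeneric("eegData"))
#' @rdname accessors
#' @export
setMethod("eegData", "EEGRecording", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setMethod("subjectId", "EEGRecording", function(x) x@subjectId)
#' @rdname accessors
#' @export
setMethod("subjectId", "EpochSet", function(x) x@subjectId)
#' @rdname accessors
#' @export
setMethod("subjectId", "ScoreSeries", function(x) x@subjectId)

#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
#' @rdname accessors
#' @export
setMethod("scores", "ScoreSeries", function(x) x@scores)

#' @rdname accessors
#' @export
setGeneric("scheme", function(x) standardGeneric("scheme"))
#' @rdname accessors
#' @export
setMethod("scheme", "ScoreSeries", function(x) x@scheme)

#' @rdname accessors
#' @export
setGeneric("epochArray", function(x) standardGeneric("epochArray"))
#' @rdname accessors
#' @export
setMethod("epochArray", "EpochSet", function(x) x@epochs)

#' @rdname accessors
#' @export
setGeneric("artifactMask", function(x) standardGeneric("artifactMask"))
#' @rdname accessors
#' @export
setMethod("artifactMask", "EpochSet", function(x) x@artifactMask)

#' @rdname accessors
#' @export
setGeneric("maskedFraction", function(x) standardGeneric("maskedFraction"))
#' @rdname accessors
#' @export
setMethod("maskedFraction", "EpochSet", function(x) x@maskedFraction)

#' @rdname accessors
#' @export
setGeneric("channelRejected", function(x) standardGeneric("channelRejected"))
#' @rdname accessors
#' @export
setMethod("channelRejected", "EpochSet", function(x) x@channelRejected)

#' @rdname accessors
#' @export
setGeneric("epochRejected", function(x) standardGeneric("epochRejected"))
#' @rdname accessors
#' @export
setMethod("epochRejected", "EpochSet", function(x) x@epochRejected)

#' @rdname accessors
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))
#' @rdname accessors
#' @export
setMethod("nEpochs", "EpochSet", function(x) dim(x@epochs)[3])
#' @rdname accessors
#' @export
setMethod("nEpochs", "ScoreSeries", function(x) length(x@scores))
#' @rdname accessors
#' @export
setMethod("nEpochs", "ProbSeries", function(x) nrow(x@probs))

#' @rdname accessors
#' @export
setGeneric("probMatrix", function(x) standardGeneric("probMatrix"))
#' @rdname accessors
#' @export
setMethod("probMatrix", "ProbSeries", function(x) x@probs)

#' @rdname accessors
#' @export
setGeneric("classValues", function(x) standardGeneric("classValues"))
#' @rdname accessors
#' @export
setMethod("classValues", "ProbSeries", function(x) x@classValues)

#' @rdname accessors
#' @export
setGeneric("trendValues", function(x) standardGeneric("trendValues"))
#' @rdname accessors
#' @export
setMethod("trendValues", "BTrend", function(x) x@bt)

#' @rdname accessors
#' @export
setGeneric("trendUncertainty", function(x) standardGeneric("trendUncertainty"))
#' @rdname accessors
#' @export
setMethod("trendUncertainty", "BTrend", function(x) x@uncertainty)

#' @rdname accessors
#' @export
setGeneric("trainingFeatures", function(x) standardGeneric("trainingFeatures"))
#' @rdname accessors
#' @export
setMethod("trainingFeatures", "TrainingSet", function(x) x@features)

#' @rdname accessors
#' @export
setGeneric("trainingLabels", function(x) standardGeneric("trainingLabels"))
#' @rdname accessors
#' @export
setMethod("trainingLabels", "TrainingSet", function(x) x@labels)

#' Posterior class probabilities from a trained model
#'
#' @param model a trained [NeoModel-class].
#' @param newdata numeric matrix of feature rows, ordered in time when the
#'   model is recurrent.
#' @param ... method-specific arguments.
#' @return A [ProbSeries-class] with one row per input row.
#' @export
setGeneric("predictProba", function(model, newdata, ...) standardGeneric("predictProba"))
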