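## Preprocessing chain, applied in fixed order: artifact scan on the
## native-rate signal -> zero-phase Chebyshev II band-pass 0.5-35 Hz ->
## resample to 64 Hz -> segment into non-overlapping 5-min epochs ->
## channel/epoch rejection. The artifact mask is computed before
## filtering (filtering would blur true amplitudes) and carried to 64 Hz
## by nearest-sample mapping.

EPOCH_SECONDS <- 300
TARGET_FS <- 64
EPOCH_SAMPLES <- EPOCH_SECONDS * TARGET_FS  # 19,200

#' Per-sample artifact detection
#'
#' Flags samples whose absolute amplitude exceeds 500 uV (strict
#' inequality: "exceeding" the threshold) and samples lying in a
#' constant-valued run of at least `flatMinS` seconds (flat signal, e.g.,
#' a detached electrode). NaN samples are flagged with a warning.
#'
#' @param x single-channel signal in uV.
#' @param fs sampling rate in Hz (needed for the flat-run length).
#' @param ampThreshold amplitude bound in uV (default 500).
#' @param flatMinS minimum flat-run duration in seconds (default 1).
#' @return logical mask, TRUE where artifactual.
#' @export
#' @examples
#' detectArtifactSamples(c(0, 501, -600, 499), fs = 4)
detectArtifactSamples <- function(x, fs, ampThreshold = 500, flatMinS = 1) {
  mask <- abs(x) > ampThreshold
  if (anyNA(x) || any(is.nan(x))) {
    warning("NaN/NA samples detected; masking them as artifacts")
    mask[is.na(x)] <- TRUE
  }
  n <- length(x)
  minRun <- max(2L, ceiling(flatMinS * fs))
  if (n >= minRun) {
    d <- diff(x)
    newRun <- c(TRUE, d != 0 | is.na(d))
    grp <- cumsum(newRun)
    runLen <- tabulate(grp)
    mask[runLen[grp] >= minRun] <- TRUE
  }
  mask
}

## Chebyshev II design: stopband edges 0.25 and 40 Hz at 40 dB
## attenuation place the -3 dB passband close to the nominal 0.5-35 Hz.
## Tests assert the realized magnitude response, not the nominal edges.
designBandpass <- function(fs, stopLo = 0.25, stopHi = 40, atten = 40,
                           order = 5) {
  if (fs < 100) stop("sampling rate too low for the 35 Hz passband edge")
  signal::cheby2(order, atten, c(stopLo, stopHi) / (fs / 2), type = "pass")
}

#' Zero-phase band-pass filter (0.5-35 Hz, 5th-order Chebyshev type II)
#'
#' Applied forward-backward so the effective attenuation doubles and the
#' phase response is zero; output length equals input length.
#'
#' @param x signal vector or channels x samples matrix.
#' @param fs sampling rate in Hz (>= 100).
#' @return filtered signal, same shape as `x`.
#' @export
bandpassFilter <- function(x, fs) {
  flt <- designBandpass(fs)
  if (is.matrix(x)) {
    t(apply(x, 1, function(ch) signal::filtfilt(flt, ch)))
  } else {
    signal::filtfilt(flt, x)
  }
}

#' Resample to 64 Hz with anti-aliasing
#'
#' Zero-phase Butterworth low-pass (6th order, 28 Hz cutoff) as the
#' anti-aliasing filter, followed by cubic-spline evaluation on the exact
#' 64 Hz grid. Output length is round(n * 64 / fs).
#'
#' @param x signal vector or channels x samples matrix.
#' @param fsNative native sampling rate; rates outside {200, 250, 256}
#'   are accepted with a warning.
#' @return signal at 64 Hz.
#' @export
resampleTo64 <- function(x, fsNative) {
  if (!fsNative %in% c(200, 250, 256))
    warning("native rate outside {200, 250, 256} Hz")
  aa <- signal::butter(6, 28 / (fsNative / 2))
  resample1 <- function(v) {
    nOut <- round(length(v) * TARGET_FS / fsNative)
    lp <- signal::filtfilt(aa, v)
    tOut <- (seq_len(nOut) - 1) / TARGET_FS
    stats::spline(x = (seq_along(v) - 1) / fsNative, y = lp, xout = tOut,
                  method = "fmm")$y
  }
  if (is.matrix(x)) t(apply(x, 1, resample1)) else resample1(x)
}

## Nearest-sample mapping of a native-rate logical mask onto the 64 Hz
## grid.
carryMask <- function(mask, fsNative, nOut) {
  idx <- pmin(length(mask), pmax(1L, round((seq_len(nOut) - 0.5) *
                                             fsNative / TARGET_FS + 0.5)))
  mask[idx]
}

#' Segment a 64 Hz recording into 5-minute epochs
#'
#' Produces floor(duration / 300 s) non-overlapping epochs of exactly
#' 19,200 samples per channel; any trailing remainder is dropped. A
#' recording shorter than one epoch yields an empty set with a warning.
#'
#' @param data channels x samples matrix at 64 Hz.
#' @param mask logical artifact mask, same shape.
#' @param channelLabels,subjectId metadata carried into the result.
#' @return An [EpochSet-class] with rejection flags not yet computed
#'   (all FALSE); see [rejectChannelsAndEpochs()].
#' @export
segmentEpochs <- function(data, mask = NULL, channelLabels = NULL,
                          subjectId = "subject") {
  if (!is.matrix(data)) data <- matrix(data, 1)
  nCh <- nrow(data)
  if (is.null(mask)) mask <- matrix(FALSE, nCh, ncol(data))
  if (is.null(channelLabels)) channelLabels <- paste0("ch", seq_len(nCh))
  nEp <- floor(ncol(data) / EPOCH_SAMPLES)
  if (nEp == 0) warning("recording shorter than one 5-minute epoch")
  epochs <- array(0, dim = c(nCh, EPOCH_SAMPLES, nEp))
  amask <- array(FALSE, dim = c(nCh, EPOCH_SAMPLES, nEp))
  for (e in seq_len(nEp)) {
    idx <- ((e - 1) * EPOCH_SAMPLES + 1):(e * EPOCH_SAMPLES)
    epochs[, , e] <- data[, idx, drop = FALSE]
    amask[, , e] <- mask[, idx, drop = FALSE]
  }
  mf <- matrix(0, nEp, nCh)
  if (nEp > 0) mf <- t(apply(amask, 3, function(m) rowMeans(matrix(m, nCh))))
  if (nEp == 1) mf <- matrix(mf, 1, nCh)
  new("EpochSet", epochs = epochs, artifactMask = amask,
      maskedFraction = matrix(mf, nEp, nCh),
      channelRejected = matrix(FALSE, nEp, nCh),
      epochRejected = rep(FALSE, nEp),
      channelLabels = channelLabels, fs = TARGET_FS,
      subjectId = as.character(subjectId))
}

#' Apply channel and epoch rejection rules
#'
#' A channel is rejected within an epoch when at least `chanThresh` of its
#' samples are masked as artifacts; an epoch is rejected when at least
#' `epochThresh` of its channels are rejected ("at least" = >=, so 4 of 8
#' channels rejects the epoch at the default 50%). Thresholds are
#' configurable for the artifact-threshold sweep of the feature
#' evaluation; `chanThresh = 0` rejects any channel with at least one
#' masked sample.
#'
#' @param epochSet an [EpochSet-class].
#' @param chanThresh channel rejection threshold (fraction, default 0.25).
#' @param epochThresh epoch rejection threshold (fraction, default 0.5).
#' @return the [EpochSet-class] with updated rejection flags.
#' @export
rejectChannelsAndEpochs <- function(epochSet, chanThresh = 0.25,
                                    epochThresh = 0.5) {
  stopifnot(is(epochSet, "EpochSet"))
  mf <- maskedFraction(epochSet)
  if (chanThresh == 0) {
    rej <- mf > 0
  } else {
    rej <- mf >= chanThresh
  }
  epochSet@channelRejected <- rej
  epochSet@epochRejected <- rowMeans(rej) >= epochThresh
  epochSet
}

#' Derive bipolar channels from a referential recording
#'
#' Each bipolar channel is the sample-wise difference of its two
#' referential electrodes; artifact masks (when supplied) are OR-combined.
#' Default pairs are the aEEG-style derivations F3-P3, F4-P4 and P3-P4.
#'
#' @param recording an [EEGRecording-class] (referential montage).
#' @param pairs list of c(anode, cathode) label pairs.
#' @param mask optional channels x samples logical mask aligned with the
#'   recording; returned OR-combined per pair as an attribute "mask".
#' @return A bipolar [EEGRecording-class].
#' @export
deriveBipolar <- function(recording,
                          pairs = list(c("F3", "P3"), c("F4", "P4"),
                                       c("P3", "P4")),
                          mask = NULL) {
  stopifnot(is(recording, "EEGRecording"))
  labs <- channelLabels(recording)
  data <- eegData(recording)
  out <- matrix(0, length(pairs), ncol(data))
  outMask <- if (!is.null(mask)) matrix(FALSE, length(pairs), ncol(data))
  newLabs <- character(length(pairs))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    miss <- setdiff(p, labs)
    if (length(miss))
      stop(sprintf("electrode(s) %s not present in the recording",
                   paste(miss, collapse = ", ")))
    a <- match(p[1], labs); b <- match(p[2], labs)
    out[i, ] <- data[a, ] - data[b, ]
    if (!is.null(mask)) outMask[i, ] <- mask[a, ] | mask[b, ]
    newLabs[i] <- paste0(p[1], "-", p[2])
  }
  rec <- EEGRecording(out, newLabs, samplingRate(recording),
                      montage = "bipolar", subjectId = subjectId(recording))
  if (!is.null(mask)) attr(rec, "mask") <- outMask
  rec
}

#' Full preprocessing chain: recording to artifact-masked 64 Hz epochs
#'
#' Runs, in order: per-sample artifact scan on the native signal,
#' zero-phase Chebyshev II band-pass (0.5-35 Hz), resampling to 64 Hz,
#' segmentation into 5-minute epochs of 19,200 samples, and channel/epoch
#' rejection.
#'
#' @param recording an [EEGRecording-class].
#' @param chanThresh,epochThresh rejection thresholds, see
#'   [rejectChannelsAndEpochs()].
#' @return An [EpochSet-class].
#' @export
preprocessRecording <- function(recording, chanThresh = 0.25,
                                epochThresh = 0.5) {
  stopifnot(is(recording, "EEGRecording"))
  data <- eegData(recording)
  fs <- samplingRate(recording)
  mask <- t(apply(data, 1, detectArtifactSamples, fs = fs))
  filt <- bandpassFilter(data, fs)
  res <- resampleTo64(filt, fs)
  nOut <- ncol(res)
  mask64 <- t(apply(mask, 1, carryMask, fsNative = fs, nOut = nOut))
  es <- segmentEpochs(res, mask64, channelLabels(recording),
                      subjectId(recording))
  rejectChannelsAndEpochs(es, chanThresh, epochThresh)
}
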