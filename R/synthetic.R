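## Synthetic neonatal EEG with known background class labels.
##
## The generator realizes the clinical scoring definitions directly:
## discontinuous classes alternate bursts and interburst intervals (IBI)
## whose peak-to-peak voltages and durations satisfy the class
## inequalities; amplitude classes keep a continuous envelope inside the
## stated range. All channels share one burst gate (the background is a
## global brain state) and carry independent 1/f-like carrier noise.

#' Generative parameters for a background class
#'
#' Returns a [BackgroundClassParams-class] for a clinical score, with
#' defaults that satisfy the class definition: trace alternant (scores 1,
#' 2) has IBI voltage >= 25 uV with mean IBI duration <= 6 s resp. > 6 s;
#' trace discontinu (3) has IBI voltage < 25 uV; burst suppression (5) has
#' IBI voltage < 5 uV; depressed (4) keeps the envelope within 5-15 uV and
#' very low voltage (6) below 5 uV. The continuous class (0) has no
#' quantitative clinical definition; the default 25-50 uV envelope is a
#' configurable convention.
#'
#' @param score integer 0-6.
#' @param ... override any slot (burstAmp, ibiAmp, ibiDur, burstDur,
#'   contRange, spectralExponent).
#' @return A [BackgroundClassParams-class] object.
#' @export
#' @examples
#' backgroundClassParams(5)  # burst suppression: IBI voltage < 5 uV
backgroundClassParams <- function(score, ...) {
  score <- as.integer(score)
  defaults <- switch(as.character(score),
    "0" = list(burstAmp = 0,   ibiAmp = 0,  ibiDur = 1,  burstDur = 1,
               contRange = c(25, 50)),
    "1" = list(burstAmp = 100, ibiAmp = 30, ibiDur = 4,  burstDur = 6,
               contRange = c(0, 0)),
    "2" = list(burstAmp = 100, ibiAmp = 30, ibiDur = 9,  burstDur = 6,
               contRange = c(0, 0)),
    "3" = list(burstAmp = 60,  ibiAmp = 10, ibiDur = 8,  burstDur = 5,
               contRange = c(0, 0)),
    "4" = list(burstAmp = 0,   ibiAmp = 0,  ibiDur = 1,  burstDur = 1,
               contRange = c(5, 15)),
    "5" = list(burstAmp = 50,  ibiAmp = 2,  ibiDur = 10, burstDur = 2,
               contRange = c(0, 0)),
    "6" = list(burstAmp = 0,   ibiAmp = 0,  ibiDur = 1,  burstDur = 1,
               contRange = c(0.5, 4)),
    stop("'score' must be in 0..6")
  )
  args <- utils::modifyList(c(defaults, list(spectralExponent = 1.2)), list(...))
  new("BackgroundClassParams", score = score,
      burstAmp = args$burstAmp, ibiAmp = args$ibiAmp, ibiDur = args$ibiDur,
      burstDur = args$burstDur, contRange = as.numeric(args$contRange),
      spectralExponent = args$spectralExponent)
}

#' @export
#' @rdname backgroundClassParams
isDiscontinuous <- function(score) as.integer(score) %in% c(1L, 2L, 3L, 5L)

## Band-limited 1/f^alpha noise, scaled so max |x| = 1 (an all-zero
## vector when the band is empty). FFT synthesis with random phases.
colorednoise <- function(n, fs, alpha = 1.2, band = c(0.5, 30)) {
  nfft <- n
  f <- seq(0, fs / 2, length.out = floor(nfft / 2) + 1)
  mag <- numeric(length(f))
  inband <- f >= band[1] & f <= band[2]
  mag[inband] <- 1 / (f[inband]^(alpha / 2))
  ph <- runif(length(f), 0, 2 * pi)
  spec <- mag * exp(1i * ph)
  full <- c(spec, Conj(rev(spec[2:(nfft - length(spec) + 1)])))
  x <- Re(fft(full, inverse = TRUE))
  m <- max(abs(x))
  if (m > 0) x / m else x
}

## Amplitude-stabilized 1/f^alpha carrier: the colored noise is divided
## by its own smoothed analytic-signal envelope so that its local
## peak-to-peak amplitude is ~2 everywhere (swings ~ +/-1), then hard
## clipped at +/-1.2. Multiplying by env/2 thus realizes a local
## peak-to-peak close to the requested envelope and never above 1.2x it,
## which keeps the strict class amplitude bounds (e.g., < 5 uV for very
## low voltage) intact.
stabilizedCarrier <- function(n, fs, alpha, clip = 1.2) {
  carrier <- colorednoise(n, fs, alpha = alpha)
  if (all(carrier == 0)) return(carrier)
  h <- hilbertEnvelope(carrier)
  lp <- signal::butter(2, min(0.5, fs / 4) / (fs / 2))
  hs <- signal::filtfilt(lp, h)
  hs <- pmax(hs, 0.3 * stats::median(h))
  pmin(pmax(carrier / hs, -clip), clip)
}

## Raised-cosine edge ramp applied to a rectangular gate.
smoothGate <- function(gate, fs, edge = 0.25) {
  ne <- max(1L, round(edge * fs))
  w <- 0.5 * (1 - cos(pi * seq_len(ne) / ne))
  k <- c(w, rev(w))
  k <- k / sum(k)
  out <- stats::filter(c(rep(gate[1], length(k)), gate, rep(gate[length(gate)], length(k))),
                       k, sides = 2)
  out <- as.numeric(out)[(length(k) + 1):(length(k) + length(gate))]
  pmin(pmax(out, 0), 1)
}

## Alternating burst/IBI gate with gamma-distributed segment durations
## (shape 6 keeps the spread around the configured means modest).
burstGate <- function(n, fs, burstDur, ibiDur, shape = 6) {
  gate <- numeric(n)
  pos <- 1L
  inBurst <- runif(1) < burstDur / (burstDur + ibiDur)
  while (pos <= n) {
    m <- if (inBurst) burstDur else ibiDur
    len <- max(1L, round(rgamma(1, shape = shape, scale = m / shape) * fs))
    end <- min(n, pos + len - 1L)
    gate[pos:end] <- as.numeric(inBurst)
    pos <- end + 1L
    inBurst <- !inBurst
  }
  gate
}

#' Simulate one multichannel epoch of a single background class
#'
#' Channels share the burst gate / amplitude envelope (global background
#' state) but carry independent carrier noise. For discontinuous classes
#' the peak-to-peak amplitude alternates between `burstAmp` and `ibiAmp`;
#' for amplitude classes a slow random envelope spans `contRange`. Each
#' channel is normalized so its maximum absolute value equals half the
#' local envelope, hence measured peak-to-peak voltages never exceed the
#' configured class bounds.
#'
#' @param params a [BackgroundClassParams-class].
#' @param nChannels number of channels.
#' @param fs sampling rate, Hz.
#' @param durationS epoch duration in seconds.
#' @param seed integer seed; the same seed reproduces the signal exactly.
#' @return list with `signal` (nChannels x fs*durationS matrix, uV) and
#'   `envelope` (the shared peak-to-peak target envelope, uV).
#' @export
simulateEpoch <- function(params, nChannels, fs, durationS, seed = NULL) {
  stopifnot(is(params, "BackgroundClassParams"))
  validObject(params)
  if (durationS <= 0) stop("'durationS' must be positive")
  if (fs <= 0) stop("'fs' must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- round(fs * durationS)
  if (isDiscontinuous(params@score)) {
    gate <- smoothGate(burstGate(n, fs, params@burstDur, params@ibiDur), fs)
    env <- params@ibiAmp + (params@burstAmp - params@ibiAmp) * gate
  } else {
    lo <- params@contRange[1]; hi <- params@contRange[2]
    if (hi == 0) {
      env <- rep(0, n)
    } else {
      slow <- colorednoise(n, fs, alpha = 2, band = c(1 / durationS, 0.05))
      if (diff(range(slow)) > 0) {
        slow <- (slow - min(slow)) / diff(range(slow))
      } else slow <- rep(0.5, n)
      env <- lo + (hi - lo) * slow
    }
  }
  sig <- matrix(0, nChannels, n)
  for (ch in seq_len(nChannels)) {
    carrier <- stabilizedCarrier(n, fs, params@spectralExponent)
    sig[ch, ] <- carrier * env / 2
  }
  list(signal = sig, envelope = env)
}

#' Simulation configuration for a labeled recording
#'
#' @param trajectory list of `c(score, durationMin)` pairs (or a 2-column
#'   matrix); durations must be positive multiples of 5 minutes.
#' @param nChannels number of channels; labels are taken from the standard
#'   10-20 set.
#' @param fsNative native sampling rate (200, 250 or 256 Hz).
#' @param artifactRate artifact events per hour for [injectArtifacts()].
#' @param seed integer seed; fully determines the output.
#' @param subjectId subject identifier.
#' @param channelLabels optional explicit labels.
#' @param classParams optional named list of [BackgroundClassParams-class]
#'   overriding the defaults of [backgroundClassParams()].
#' @return A `SimConfig` list (validated).
#' @export
simConfig <- function(trajectory, nChannels = 8, fsNative = 250,
                      artifactRate = 0, seed = 1, subjectId = "sim",
                      channelLabels = NULL, classParams = list()) {
  traj <- do.call(rbind, lapply(trajectory, function(x) as.numeric(x[1:2])))
  if (any(traj[, 2] <= 0) || any(traj[, 2] %% 5 != 0))
    stop("trajectory durations must be positive multiples of 5 minutes")
  if (!fsNative %in% c(200, 250, 256))
    warning("native rate outside {200, 250, 256} Hz")
  std <- c("F3", "F4", "P3", "P4", "C3", "C4", "O1", "O2", "T3", "T4",
           "Fp1", "Fp2", "F7", "F8", "T5", "T6")
  if (is.null(channelLabels)) channelLabels <- std[seq_len(nChannels)]
  structure(list(trajectory = traj, nChannels = nChannels,
                 fsNative = fsNative, artifactRate = artifactRate,
                 seed = as.integer(seed), subjectId = subjectId,
                 channelLabels = channelLabels, classParams = classParams),
            class = "SimConfig")
}

#' Simulate a continuous labeled recording
#'
#' Concatenates per-class segments along the configured trajectory with
#' 20-second raised-cosine crossfades at transitions. The ground-truth
#' label of each 5-minute epoch is the class occupying the majority of
#' that epoch (transitions fall on epoch boundaries here, so the label is
#' simply the segment's class).
#'
#' @param config a `SimConfig` from [simConfig()].
#' @return list with `recording` ([EEGRecording-class]) and `truth`
#'   ([ScoreSeries-class], 7-score scheme).
#' @export
simulateRecording <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  fs <- config$fsNative
  nCh <- config$nChannels
  nSeg <- nrow(config$trajectory)
  xfade <- round(20 * fs)  # 20 s crossfade (< 30 s)
  segs <- vector("list", nSeg)
  labels <- integer(0)
  for (i in seq_len(nSeg)) {
    score <- as.integer(config$trajectory[i, 1])
    durS <- config$trajectory[i, 2] * 60
    key <- as.character(score)
    params <- if (!is.null(config$classParams[[key]]))
      config$classParams[[key]] else backgroundClassParams(score)
    ## segments before the last carry a crossfade tail so that the
    ## overlap-add below preserves the total duration exactly
    extraS <- if (i < nSeg) xfade / fs else 0
    segs[[i]] <- simulateEpoch(params, nCh, fs, durS + extraS)$signal
    labels <- c(labels, rep(score, config$trajectory[i, 2] / 5))
  }
  data <- segs[[1]]
  if (nSeg > 1) {
    for (i in 2:nSeg) {
      nOv <- min(xfade, ncol(segs[[i]]))
      w <- matrix(0.5 * (1 - cos(pi * seq_len(nOv) / (nOv + 1))),
                  nCh, nOv, byrow = TRUE)
      tailIdx <- (ncol(data) - nOv + 1):ncol(data)
      blended <- data[, tailIdx, drop = FALSE] * (1 - w) +
        segs[[i]][, seq_len(nOv), drop = FALSE] * w
      data <- cbind(data[, seq_len(ncol(data) - nOv), drop = FALSE], blended,
                    segs[[i]][, -seq_len(nOv), drop = FALSE])
    }
  }
  rec <- EEGRecording(data, config$channelLabels, fs,
                      subjectId = config$subjectId)
  truth <- ScoreSeries(labels, scheme = "7-score",
                       subjectId = config$subjectId, raterId = "truth")
  if (config$artifactRate > 0) {
    art <- injectArtifacts(rec, rate = config$artifactRate,
                           seed = config$seed + 1L)
    rec <- art$recording
    attr(rec, "artifactLog") <- art$log
  }
  list(recording = rec, truth = truth)
}

#' Inject NICU-style artifacts into a recording
#'
#' Two artifact kinds mirror the automated artifact scan they are meant to
#' trigger: `high_amplitude` events exceed +/-500 uV; `flat` events are
#' constant-valued runs of at least 1 s (electrode detachment).
#'
#' @param recording an [EEGRecording-class].
#' @param rate expected events per hour (Poisson).
#' @param kinds subset of c("high_amplitude", "flat").
#' @param seed integer seed.
#' @return list with modified `recording` and a `log` data.frame
#'   (channel, onset_s, duration_s, kind).
#' @export
injectArtifacts <- function(recording, rate,
                            kinds = c("high_amplitude", "flat"), seed = NULL) {
  stopifnot(is(recording, "EEGRecording"), rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  data <- eegData(recording)
  fs <- samplingRate(recording)
  hours <- ncol(data) / fs / 3600
  nEvents <- if (rate > 0) rpois(1, rate * hours) else 0L
  log <- data.frame(channel = character(0), onset_s = numeric(0),
                    duration_s = numeric(0), kind = character(0),
                    stringsAsFactors = FALSE)
  if (nEvents > 0) {
    for (i in seq_len(nEvents)) {
      kind <- sample(kinds, 1)
      ch <- sample(nrow(data), 1)
      dur <- if (kind == "flat") runif(1, 1.5, 5) else runif(1, 0.5, 3)
      onset <- runif(1, 0, max(0.001, ncol(data) / fs - dur))
      idx <- round(onset * fs):min(ncol(data), round((onset + dur) * fs))
      idx <- idx[idx >= 1]
      if (kind == "flat") {
        data[ch, idx] <- data[ch, idx[1]]
      } else {
        amp <- runif(1, 600, 1500) * sample(c(-1, 1), 1)
        bump <- sin(pi * seq_along(idx) / length(idx))
        data[ch, idx] <- data[ch, idx] + amp * bump
      }
      log <- rbind(log, data.frame(channel = channelLabels(recording)[ch],
                                   onset_s = onset, duration_s = dur,
                                   kind = kind, stringsAsFactors = FALSE))
    }
  }
  out <- EEGRecording(data, channelLabels(recording), fs,
                      montage = recording@montage,
                      subjectId = subjectId(recording))
  list(recording = out, log = log)
}

#' Simulate expert raters as noisy copies of the truth
#'
#' Each epoch keeps the true score with probability `pAgree`; otherwise it
#' is replaced by a neighbouring score (or by a uniform draw within
#' `confuseWithin` when the true score belongs to that set, emulating
#' raters who mix up clinically equivalent low scores).
#'
#' @param truth a [ScoreSeries-class].
#' @param pAgree per-epoch probability of copying the truth.
#' @param pReject per-epoch probability of marking REJECT.
#' @param confuseWithin optional integer set; disagreements on scores in
#'   this set stay inside the set.
#' @param raterId identifier for the new series.
#' @param seed integer seed.
#' @return A [ScoreSeries-class].
#' @export
simulateRaters <- function(truth, pAgree = 0.9, pReject = 0,
                           confuseWithin = NULL, raterId = "E1", seed = 1) {
  stopifnot(is(truth, "ScoreSeries"))
  set.seed(seed)
  hi <- if (scheme(truth) == "7-score") 6L else 4L
  s <- scores(truth)
  out <- s
  for (i in seq_along(s)) {
    if (is.na(s[i])) next
    if (runif(1) < pReject) { out[i] <- NA_integer_; next }
    if (runif(1) >= pAgree) {
      if (!is.null(confuseWithin) && s[i] %in% confuseWithin) {
        alt <- setdiff(confuseWithin, s[i])
      } else {
        alt <- intersect(c(s[i] - 1L, s[i] + 1L), 0:hi)
      }
      out[i] <- if (length(alt)) alt[sample.int(length(alt), 1)] else s[i]
    }
  }
  ScoreSeries(out, scheme = scheme(truth), subjectId = subjectId(truth),
              raterId = raterId)
}
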