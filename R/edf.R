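## Minimal European Data Format (EDF) I/O: 16-bit integer samples with
## per-channel physical scaling, 1-second data records. Covers plain EDF
## as produced by NICU monitors for continuous recordings; no EDF+
## annotations. Header dates are fixed so identical data yield identical
## files.

padField <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16-bit integers over a symmetric per-channel
#' physical range (physical dimension uV), one data record per second.
#' Any trailing part-second of data is dropped, as EDF records are whole
#' seconds.
#'
#' @param recording an [EEGRecording-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEDF <- function(recording, path) {
  stopifnot(is(recording, "EEGRecording"))
  data <- eegData(recording)
  fs <- samplingRate(recording)
  if (fs != round(fs)) stop("EDF export requires an integer sampling rate")
  ns <- nrow(data)
  nRec <- floor(ncol(data) / fs)
  if (nRec < 1) stop("recording shorter than one 1-s EDF record")
  data <- data[, seq_len(nRec * fs), drop = FALSE]
  physMax <- pmax(apply(abs(data), 1, max), 1)
  physMax <- ceiling(physMax)
  dig <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    padField("0", 8),
    padField(subjectId(recording), 80),
    padField("neobg synthetic", 80),
    padField("01.01.00", 8), padField("00.00.00", 8),
    padField(256 + ns * 256, 8),
    padField("", 44),
    padField(nRec, 8),
    padField(1, 8),
    padField(ns, 4)
  )
  writeChar(paste(hdr, collapse = ""), con, eos = NULL)
  writeChar(paste(vapply(channelLabels(recording), padField, "", width = 16),
                  collapse = ""), con, eos = NULL)
  writeChar(paste(rep(padField("AgAgCl electrode", 80), ns), collapse = ""),
            con, eos = NULL)
  writeChar(paste(rep(padField("uV", 8), ns), collapse = ""), con, eos = NULL)
  writeChar(paste(vapply(-physMax, padField, "", width = 8), collapse = ""),
            con, eos = NULL)
  writeChar(paste(vapply(physMax, padField, "", width = 8), collapse = ""),
            con, eos = NULL)
  writeChar(paste(rep(padField(-dig, 8), ns), collapse = ""), con, eos = NULL)
  writeChar(paste(rep(padField(dig, 8), ns), collapse = ""), con, eos = NULL)
  writeChar(paste(rep(padField("", 80), ns), collapse = ""), con, eos = NULL)
  writeChar(paste(rep(padField(fs, 8), ns), collapse = ""), con, eos = NULL)
  writeChar(paste(rep(padField("", 32), ns), collapse = ""), con, eos = NULL)
  scale <- physMax / dig
  for (r in seq_len(nRec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      v <- as.integer(pmin(pmax(round(data[ch, idx] / scale[ch]), -dig), dig))
      writeBin(v, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written by [writeEDF()] (plain EDF, integer rates)
#'
#' @param path EDF file path.
#' @return An [EEGRecording-class].
#' @export
readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)
  patient <- trimws(rd(80))
  rd(80); rd(8); rd(8); rd(8); rd(44)
  nRec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  rd(80 * ns); rd(8 * ns)
  physMin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  physMax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  digMin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  digMax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(80 * ns)
  nsamp <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(32 * ns)
  fs <- nsamp / recDur
  if (length(unique(fs)) != 1)
    stop("channels with differing sampling rates are not supported")
  data <- matrix(0, ns, nRec * nsamp[1])
  for (r in seq_len(nRec)) {
    for (ch in seq_len(ns)) {
      v <- readBin(con, "integer", n = nsamp[ch], size = 2, endian = "little")
      g <- (physMax[ch] - physMin[ch]) / (digMax[ch] - digMin[ch])
      data[ch, ((r - 1) * nsamp[ch] + 1):(r * nsamp[ch])] <-
        physMin[ch] + g * (v - digMin[ch])
    }
  }
  EEGRecording(data, labels, fs[1], subjectId = patient)
}

#' Read/write per-epoch annotation files
#'
#' Delimited text with columns subject, epoch_index (1-based), rater,
#' score. REJECT epochs are written as the literal string "REJECT".
#'
#' @param series a [ScoreSeries-class] or list of them.
#' @param path file path.
#' @return `writeAnnotations`: `path` invisibly. `readAnnotations`: a list
#'   of [ScoreSeries-class], one per (subject, rater).
#' @export
writeAnnotations <- function(series, path) {
  if (is(series, "ScoreSeries")) series <- list(series)
  rows <- do.call(rbind, lapply(series, function(s) {
    sc <- scores(s)
    data.frame(subject = subjectId(s), epoch_index = seq_along(sc),
               rater = s@raterId,
               score = ifelse(is.na(sc), "REJECT", as.character(sc)),
               scheme = scheme(s), stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAnnotations
#' @export
readAnnotations <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = "character")
  out <- list()
  for (key in unique(paste(tab$subject, tab$rater, sep = "\r"))) {
    sub <- tab[paste(tab$subject, tab$rater, sep = "\r") == key, ]
    sub <- sub[order(as.integer(sub$epoch_index)), ]
    sc <- suppressWarnings(as.integer(sub$score))
    out[[length(out) + 1]] <- ScoreSeries(
      sc, scheme = sub$scheme[1], subjectId = sub$subject[1],
      raterId = sub$rater[1])
  }
  out
}
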