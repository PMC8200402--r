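## Independent brute-force oracles. Each reimplements the defined
## quantity from first principles (plain loops), never calling the
## package's own computation path.

bruteKappa <- function(a, b) {
  lev <- sort(unique(c(a, b)))
  n <- length(a)
  po <- sum(a == b) / n
  pe <- 0
  for (l in lev) pe <- pe + (sum(a == l) / n) * (sum(b == l) / n)
  if (abs(1 - pe) < 1e-12) return(if (po >= 1 - 1e-12) 1 else 0)
  (po - pe) / (1 - pe)
}

bruteAccuracy <- function(a, b) sum(a == b) / length(a)

bruteMacroF1 <- function(pred, ref) {
  lev <- sort(unique(c(pred, ref)))
  f1 <- numeric(length(lev))
  for (i in seq_along(lev)) {
    l <- lev[i]
    tp <- sum(pred == l & ref == l)
    fp <- sum(pred == l & ref != l)
    fn <- sum(pred != l & ref == l)
    f1[i] <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  }
  mean(f1)
}

## centered running median over non-NA neighbours, shrunken at edges,
## lower-middle tie rule
bruteRunningMedian <- function(s, window) {
  n <- length(s)
  half <- (window - 1) %/% 2
  out <- s
  for (i in seq_len(n)) {
    if (is.na(s[i])) next
    w <- s[max(1, i - half):min(n, i + half)]
    w <- sort(w[!is.na(w)])
    out[i] <- w[ceiling(length(w) / 2)]
  }
  out
}

## Welch periodogram band power recomputed with explicit loops
bruteBandPower <- function(x, band, fs, winS = 8, overlap = 0.5) {
  N <- min(round(winS * fs), length(x))
  step <- max(1, round(N * (1 - overlap)))
  w <- numeric(N)
  for (i in seq_len(N)) w[i] <- 0.5 * (1 - cos(2 * pi * i / (N + 1)))
  U <- sum(w * w)
  nf <- floor(N / 2) + 1
  psd <- numeric(nf)
  starts <- seq(1, length(x) - N + 1, by = step)
  for (s in starts) {
    seg <- x[s:(s + N - 1)] * w
    X <- fft(seg)
    for (k in seq_len(nf)) psd[k] <- psd[k] + Mod(X[k])^2 / (U * fs)
  }
  psd <- psd / length(starts)
  last <- nf - if (N %% 2 == 0) 1 else 0
  for (k in 2:last) psd[k] <- 2 * psd[k]
  f <- seq(0, fs / 2, length.out = nf)
  df <- f[2] - f[1]
  total <- 0
  for (k in seq_len(nf)) if (f[k] >= band[1] && f[k] < band[2])
    total <- total + psd[k] * df
  total
}

## naive sample entropy (double loop, Chebyshev distance, no self-match)
bruteSampEn <- function(x, m, r) {
  n <- length(x)
  A <- 0; B <- 0
  for (i in 1:(n - m - 1)) {
    for (j in (i + 1):(n - m)) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        B <- B + 1
        if (max(dm, abs(x[i + m] - x[j + m])) <= r) A <- A + 1
      }
    }
  }
  if (B == 0 || A == 0) return(NA_real_)
  -log(A / B)
}

## rule-based background class oracle from the measured 1-s p2p profile
## (thresholds straight from the clinical class definitions)
oracleP2P <- function(x, fs) {
  nb <- floor(length(x) / fs)
  vapply(seq_len(nb), function(i) {
    seg <- x[((i - 1) * fs + 1):(i * fs)]
    max(seg) - min(seg)
  }, 0)
}

ruleClassify <- function(sig, fs = 64) {
  prof <- colMeans(do.call(rbind, lapply(seq_len(nrow(sig)), function(ch)
    oracleP2P(sig[ch, ], fs))))
  p95 <- quantile(prof, 0.95, names = FALSE)
  p5 <- quantile(prof, 0.05, names = FALSE)
  if (p95 < 5) return(6L)
  if (p95 <= 20) return(4L)
  if (p95 / max(p5, 0.5) < 3) return(0L)
  th <- (p95 + p5) / 2
  ibi <- prof < th
  r <- rle(ibi)
  ibiDur <- mean(r$lengths[r$values])
  ibiV <- median(prof[ibi])
  if (ibiV >= 25) return(if (ibiDur <= 6) 1L else 2L)
  if (ibiV < 5) return(5L)
  3L
}

## planted feature-selection dataset: 5 informative + pure-noise features.
## Informative feature j is the marker of class j (mean shift = snr, unit
## noise) against a baseline class 0, so each of the five is individually
## necessary for full accuracy.
plantedDataset <- function(seed, n = 120, pNoise = 93, snr = 3) {
  set.seed(seed)
  y <- rep(0:5, length.out = n)
  subj <- rep(sprintf("s%d", 1:10), length.out = n)
  Xi <- sapply(1:5, function(j) snr * (y == j) + rnorm(n))
  Xn <- matrix(rnorm(n * pNoise), n, pNoise)
  X <- cbind(Xi, Xn)
  colnames(X) <- c(paste0("inf", 1:5), paste0("noise", seq_len(pNoise)))
  list(X = X, y = as.integer(y), subj = subj)
}

## tiny TrainingSet constructor for classifier tests
makeTS <- function(X, y, subject = "s") {
  n <- nrow(X)
  subj <- if (length(subject) == 1) rep(subject, n) else subject
  new("TrainingSet", features = X, labels = as.integer(y),
      weights = rep(1, n),
      provenance = data.frame(subject = subj,
                              epoch = stats::ave(seq_len(n), subj,
                                                 FUN = seq_along),
                              rater = "t", stringsAsFactors = FALSE),
      mode = "SINGLE")
}
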