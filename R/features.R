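## Quantitative EEG feature bank: 98 features per derivation and epoch,
## spanning amplitude, spectral, complexity, discontinuity, modulation
## and (inter-channel) synchrony categories. Features are computed per
## channel on each 5-minute epoch and summarised across non-rejected
## channels by the median. Synchrony features are pairwise (homologous
## electrode pairs) and summarised by the median over pairs.

## ---- shared signal primitives ----------------------------------------------

## Analytic-signal magnitude (FFT Hilbert transform).
hilbertEnvelope <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

## Envelope smoothed by a 1 Hz low-pass (amplitude modulation profile).
amEnvelope <- function(x, fs, cutoff = 1) {
  e <- hilbertEnvelope(x)
  if (sd(e) == 0) return(e)
  bw <- signal::butter(4, cutoff / (fs / 2))
  pmax(signal::filtfilt(bw, e), 0)
}

#' Welch periodogram
#'
#' Averaged modified periodogram: Hann-tapered segments (default 8 s) with
#' 50% overlap, one-sided density scaled so that the integral over
#' frequency equals the signal variance (power in uV^2).
#'
#' @param x signal vector (uV).
#' @param fs sampling rate in Hz.
#' @param winS segment length in seconds.
#' @param overlap fractional overlap between segments.
#' @return list with `f` (Hz) and `psd` (uV^2/Hz).
#' @export
welchPSD <- function(x, fs, winS = 8, overlap = 0.5) {
  N <- round(winS * fs)
  N <- min(N, length(x))
  step <- max(1L, round(N * (1 - overlap)))
  starts <- seq(1L, length(x) - N + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(N) / (N + 1)))
  U <- sum(w^2)
  acc <- numeric(floor(N / 2) + 1)
  for (s in starts) {
    seg <- x[s:(s + N - 1)] * w
    X <- fft(seg)
    P <- Mod(X[seq_along(acc)])^2 / (U * fs)
    acc <- acc + P
  }
  psd <- acc / length(starts)
  psd[2:(length(psd) - if (N %% 2 == 0) 1 else 0)] <-
    2 * psd[2:(length(psd) - if (N %% 2 == 0) 1 else 0)]
  list(f = seq(0, fs / 2, length.out = length(psd)), psd = psd)
}

#' Band power from the Welch periodogram
#'
#' Mean spectral power in the half-open band `[lo, hi)`, in uV^2
#' (PSD integrated over the band).
#'
#' @param x signal vector at 64 Hz (other rates allowed via `fs`).
#' @param band numeric length-2, band edges in Hz.
#' @param fs sampling rate.
#' @param psd optional precomputed [welchPSD()] result.
#' @return band power in uV^2.
#' @export
#' @examples
#' x <- 10 * sin(2 * pi * 10 * seq(0, 300, by = 1/64))
#' bandPower(x, c(9, 11))  # ~ A^2/2 = 50
bandPower <- function(x, band = c(9, 11), fs = 64, psd = NULL) {
  if (is.null(psd)) psd <- welchPSD(x, fs)
  df <- psd$f[2] - psd$f[1]
  sel <- psd$f >= band[1] & psd$f < band[2]
  sum(psd$psd[sel]) * df
}

#' Amplitude modulation statistics
#'
#' Mean and standard deviation of the amplitude modulation profile (the
#' magnitude of the analytic signal, low-pass smoothed at 1 Hz), in uV.
#'
#' @param x signal vector.
#' @param fs sampling rate in Hz.
#' @return named numeric c(mean, sd).
#' @export
amplitudeModulationStats <- function(x, fs = 64) {
  if (all(x == 0)) return(c(mean = 0, sd = 0))
  e <- amEnvelope(x, fs)
  c(mean = mean(e), sd = sd(e))
}

#' Activation synchrony index between two channels
#'
#' Quantifies co-occurrence of high-amplitude activations: each channel's
#' amplitude-modulation envelope is binarized at its own 75th percentile
#' and the index is the phi (Pearson) correlation of the two binary
#' activation trains. Symmetric; 1 for identical channels; approximately
#' 0 for independent activation timing. Degenerate inputs (constant
#' envelope, e.g., an all-zero channel) return 0.
#'
#' @param a,b same-length signal vectors.
#' @param fs sampling rate in Hz.
#' @return synchrony score between -1 and 1.
#' @export
activationSynchronyIndex <- function(a, b, fs = 64) {
  stopifnot(length(a) == length(b))
  act <- function(x) {
    e <- amEnvelope(x, fs)
    th <- quantile(e, 0.75, names = FALSE)
    v <- as.numeric(e > th)
    if (sd(v) == 0) NULL else v
  }
  va <- act(a); vb <- act(b)
  if (is.null(va) || is.null(vb)) return(0)
  stats::cor(va, vb)
}

#' Multiscale entropy curve and its average slope
#'
#' Sample entropy (m = 2, r = 0.15 * SD of the original signal, fixed
#' across scales) computed on coarse-grained versions of the signal at
#' scales 1..`maxScale` (non-overlapping window means), then the
#' least-squares slope of entropy against scale. White noise loses
#' entropy quickly with scale (negative slope); 1/f-like signals hold
#' their entropy (slope nearer 0).
#'
#' @param x signal vector.
#' @param maxScale largest coarse-graining factor.
#' @param m template length.
#' @param rFactor tolerance as a fraction of SD.
#' @return list with `scales`, `entropy` and `slope`. Constant signals
#'   yield NA slope (entropy undefined).
#' @export
multiscaleEntropy <- function(x, maxScale = 20, m = 2, rFactor = 0.15) {
  if (length(x) < maxScale * 20)
    stop("signal too short for the requested number of scales")
  s0 <- sd(x)
  if (s0 == 0) return(list(scales = seq_len(maxScale),
                           entropy = rep(NA_real_, maxScale), slope = NA_real_))
  r <- rFactor * s0
  ent <- vapply(seq_len(maxScale), function(sc) {
    nb <- floor(length(x) / sc)
    cg <- if (sc == 1) x else colMeans(matrix(x[seq_len(nb * sc)], sc))
    .sampen_cpp(cg, m, r)
  }, 0)
  ok <- is.finite(ent)
  slope <- if (sum(ok) >= 2) {
    sc <- seq_len(maxScale)[ok]
    stats::cov(sc, ent[ok]) / stats::var(sc)
  } else NA_real_
  list(scales = seq_len(maxScale), entropy = ent, slope = slope)
}

#' @rdname multiscaleEntropy
#' @export
multiscaleEntropySlope <- function(x, maxScale = 20, m = 2, rFactor = 0.15) {
  multiscaleEntropy(x, maxScale, m, rFactor)$slope
}

#' Sample entropy
#'
#' @param x signal vector.
#' @param m template length (default 2).
#' @param r tolerance in signal units; default 0.15 * SD(x).
#' @return sample entropy (NA for constant or too-short signals).
#' @export
sampleEntropy <- function(x, m = 2, r = 0.15 * sd(x)) {
  if (!is.finite(r) || r <= 0) return(NA_real_)
  .sampen_cpp(as.numeric(x), as.integer(m), r)
}

## Per-sample peak-to-peak profile: range over a sliding ~1.5 s window,
## computed on a 0.5 s block grid for speed.
p2pProfile <- function(x, fs) {
  bs <- max(1L, round(fs / 2))
  nb <- floor(length(x) / bs)
  m <- matrix(x[seq_len(nb * bs)], bs)
  bmax <- apply(m, 2, max); bmin <- apply(m, 2, min)
  rmax <- pmax(bmax, c(bmax[1], bmax[-nb]), c(bmax[-1], bmax[nb]))
  rmin <- pmin(bmin, c(bmin[1], bmin[-nb]), c(bmin[-1], bmin[nb]))
  rng <- rmax - rmin
  prof <- rep(rng, each = bs)
  c(prof, rep(rng[nb], length(x) - length(prof)))
}

## Burst/IBI segmentation of the p2p profile at threshold thr (uV) with a
## 1 s minimum segment duration (shorter segments merge into their
## neighbour).
segmentBursts <- function(prof, fs, thr) {
  isBurst <- prof >= thr
  r <- rle(isBurst)
  minLen <- fs
  # absorb runs shorter than 1 s into the previous state
  if (length(r$lengths) > 1) {
    keep <- r$lengths >= minLen
    vals <- r$values
    for (i in seq_along(vals)) if (!keep[i] && i > 1) vals[i] <- vals[i - 1]
    isBurst <- inverse.rle(list(lengths = r$lengths, values = vals))
    r <- rle(isBurst)
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts, end = ends, burst = r$values,
             dur = r$lengths / fs)
}

discontinuityFeatures <- function(x, fs, prof = NULL) {
  if (is.null(prof)) prof <- p2pProfile(x, fs)
  out <- c()
  for (cfg in list(list(tag = "bs", thr = 5), list(tag = "ta", thr = 25))) {
    seg <- segmentBursts(prof, fs, cfg$thr)
    bd <- seg$dur[seg$burst]
    id <- seg$dur[!seg$burst]
    ibiSamples <- unlist(mapply(function(s, e) s:e, seg$start[!seg$burst],
                                seg$end[!seg$burst], SIMPLIFY = FALSE))
    bSamples <- unlist(mapply(function(s, e) s:e, seg$start[seg$burst],
                              seg$end[seg$burst], SIMPLIFY = FALSE))
    v <- c(
      length(bd) / (length(x) / fs / 60),
      if (length(bd)) mean(bd) else 0,
      if (length(bd) > 1) sd(bd) else 0,
      if (length(bd)) max(bd) else 0,
      if (length(id)) mean(id) else 0,
      if (length(id) > 1) sd(id) else 0,
      if (length(id)) max(id) else 0,
      if (length(ibiSamples)) median(prof[ibiSamples]) else 0,
      if (length(ibiSamples)) quantile(prof[ibiSamples], 0.95, names = FALSE) else 0,
      if (length(bSamples)) quantile(prof[bSamples], 0.95, names = FALSE) else 0,
      length(ibiSamples) / length(x)
    )
    names(v) <- paste0("disc_", cfg$tag, "_",
                       c("bursts_per_min", "burst_dur_mean", "burst_dur_sd",
                         "burst_dur_max", "ibi_dur_mean", "ibi_dur_sd",
                         "ibi_dur_max", "ibi_volt_median", "ibi_volt_p95",
                         "burst_amp_p95", "ibi_fraction"))
    out <- c(out, v)
  }
  supp <- vapply(c(5, 10, 15, 25), function(th) mean(prof < th), 0)
  names(supp) <- paste0("disc_suppression_ratio_", c(5, 10, 15, 25))
  c(out, supp)
}

## Permutation entropy, order 3, lag 1, normalized to [0, 1].
permEntropy <- function(x) {
  n <- length(x) - 2
  if (n < 10) return(NA_real_)
  a <- x[1:n]; b <- x[2:(n + 1)]; c3 <- x[3:(n + 2)]
  pat <- 1L + (a < b) + 2L * (b < c3) + 4L * (a < c3)
  tab <- tabulate(pat, 8)
  p <- tab[tab > 0] / n
  -sum(p * log(p)) / log(6)
}

## ---- the registry -----------------------------------------------------------

AMP_IDS <- c("amp_sd", "amp_mad", "amp_mean_abs", "amp_skew", "amp_kurt",
             "amp_p2p", "amp_crest",
             paste0("reeg_", c("p5", "p25", "p50", "p75", "p95", "mean",
                               "sd", "bandwidth", "asymmetry")),
             "line_length", "nonlinear_energy", "zero_crossings",
             paste0("hjorth_", c("activity", "mobility", "complexity")))

SPEC_BANDS <- list(c(0.5, 3), c(3, 8), c(8, 15), c(15, 30), c(9, 11))
SPEC_BAND_IDS <- c("0.5_3", "3_8", "8_15", "15_30", "9_11")
SPEC_IDS <- c(paste0("spec_power_", SPEC_BAND_IDS),
              paste0("spec_relpower_", SPEC_BAND_IDS),
              "spec_power_total", "spec_sef50", "spec_sef80", "spec_sef90",
              "spec_sef95", "spec_entropy", "spec_peak_freq",
              "spec_mean_freq", "spec_slope", "spec_ratio_delta_theta",
              "spec_ratio_theta_alpha")

CPLX_IDS <- c("cplx_sampen", "cplx_sampen_scale5", "cplx_sampen_scale10",
              "cplx_apen", "cplx_mse_slope", "cplx_mse_mean",
              "cplx_perm_entropy", "cplx_lz", "cplx_higuchi_fd",
              "cplx_katz_fd", "cplx_ar_residual_sd")

DISC_IDS <- c(paste0("disc_bs_", c("bursts_per_min", "burst_dur_mean",
                                   "burst_dur_sd", "burst_dur_max",
                                   "ibi_dur_mean", "ibi_dur_sd",
                                   "ibi_dur_max", "ibi_volt_median",
                                   "ibi_volt_p95", "burst_amp_p95",
                                   "ibi_fraction")),
              paste0("disc_ta_", c("bursts_per_min", "burst_dur_mean",
                                   "burst_dur_sd", "burst_dur_max",
                                   "ibi_dur_mean", "ibi_dur_sd",
                                   "ibi_dur_max", "ibi_volt_median",
                                   "ibi_volt_p95", "burst_amp_p95",
                                   "ibi_fraction")),
              paste0("disc_suppression_ratio_", c(5, 10, 15, 25)))

MOD_IDS <- c("mod_am_mean", "mod_am_sd", "mod_am_cv", "mod_env_skew",
             "mod_env_kurt", "mod_env_p5", "mod_env_p50", "mod_env_p95",
             "mod_env_iqr", "mod_depth", "mod_am_peak_freq")

SYNC_IDS <- c("sync_asi", "sync_env_corr", "sync_sig_corr",
              "sync_coh_delta", "sync_coh_theta", "sync_coh_alpha",
              "sync_xcorr_max")

#' The 98-feature registry
#'
#' Registry of all quantitative EEG features computed per channel (or per
#' homologous channel pair for the synchrony category) on 64 Hz 5-minute
#' epochs. Feature ids are stable across runs. The dimensionless flag
#' marks gain-invariant features (entropies, relative powers, synchrony,
#' shape statistics); all others scale with signal amplitude.
#'
#' @return data.frame with columns feature_id, category, dimensionless,
#'   parameterization; exactly 98 rows.
#' @export
featureRegistry <- function() {
  reg <- rbind(
    data.frame(feature_id = AMP_IDS, category = "amplitude",
               stringsAsFactors = FALSE),
    data.frame(feature_id = SPEC_IDS, category = "spectral",
               stringsAsFactors = FALSE),
    data.frame(feature_id = CPLX_IDS, category = "complexity",
               stringsAsFactors = FALSE),
    data.frame(feature_id = DISC_IDS, category = "discontinuity",
               stringsAsFactors = FALSE),
    data.frame(feature_id = MOD_IDS, category = "modulation",
               stringsAsFactors = FALSE),
    data.frame(feature_id = SYNC_IDS, category = "synchrony",
               stringsAsFactors = FALSE)
  )
  dimless <- c("amp_skew", "amp_kurt", "amp_crest", "reeg_asymmetry",
               "hjorth_mobility", "hjorth_complexity",
               paste0("spec_relpower_", SPEC_BAND_IDS), "spec_sef50",
               "spec_sef80", "spec_sef90", "spec_sef95", "spec_entropy",
               "spec_peak_freq", "spec_mean_freq", "spec_slope",
               "spec_ratio_delta_theta", "spec_ratio_theta_alpha",
               setdiff(CPLX_IDS, "cplx_ar_residual_sd"),
               grep("dur|fraction|bursts_per_min|suppression",
                    DISC_IDS, value = TRUE),
               "mod_am_cv", "mod_env_skew", "mod_env_kurt", "mod_depth",
               "mod_am_peak_freq", SYNC_IDS)
  reg$dimensionless <- reg$feature_id %in% dimless
  param <- c(
    rep("full epoch, 64 Hz", 7),
    rep("range-EEG: peak-to-peak per 2 s non-overlapping window", 9),
    rep("full epoch", 6),
    rep("Welch 8 s Hann 50% overlap", length(SPEC_IDS)),
    rep("central 1024 samples; m=2, r=0.15 SD; scales 1..20 (MSE)", 6),
    "order 3, lag 1", "median-binarized, central 1024 samples",
    "kmax = 8", "Katz", "AR(5) Yule-Walker residual SD",
    rep("p2p profile (1.5 s window); thresholds 5 uV (bs) / 25 uV (ta); 1 s min segment",
        22),
    rep("profile below threshold", 4),
    rep("analytic envelope low-passed at 1 Hz", length(MOD_IDS)),
    "envelope binarized at 75th percentile, phi coefficient",
    "Pearson r of envelopes", "Pearson r of signals",
    "mean magnitude-squared coherence 0.5-3 Hz", "3-8 Hz", "8-15 Hz",
    "max |cross-correlation| within +/-0.5 s"
  )
  reg$parameterization <- param
  stopifnot(nrow(reg) == 98L, !anyDuplicated(reg$feature_id))
  reg
}

## ---- per-channel computation -------------------------------------------------

## All non-synchrony features for one channel of one epoch.
channelFeatures <- function(x, fs = 64) {
  out <- setNames(rep(NA_real_, 98 - length(SYNC_IDS)),
                  c(AMP_IDS, SPEC_IDS, CPLX_IDS, DISC_IDS, MOD_IDS))
  n <- length(x)
  durS <- n / fs
  ## amplitude
  s0 <- sd(x)
  out["amp_sd"] <- s0
  out["amp_mad"] <- stats::mad(x)
  out["amp_mean_abs"] <- mean(abs(x))
  out["amp_skew"] <- if (s0 > 0) e1071::skewness(x) else 0
  out["amp_kurt"] <- if (s0 > 0) e1071::kurtosis(x) else 0
  out["amp_p2p"] <- diff(range(x))
  rms <- sqrt(mean(x^2))
  out["amp_crest"] <- if (rms > 0) max(abs(x)) / rms else 0
  w <- round(2 * fs)
  nw <- floor(n / w)
  reeg <- apply(matrix(x[seq_len(nw * w)], w), 2, function(v) diff(range(v)))
  q <- quantile(reeg, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
  out[paste0("reeg_", c("p5", "p25", "p50", "p75", "p95"))] <- q
  out["reeg_mean"] <- mean(reeg)
  out["reeg_sd"] <- sd(reeg)
  out["reeg_bandwidth"] <- q[5] - q[1]
  out["reeg_asymmetry"] <- if (q[5] > q[1])
    (q[5] + q[1] - 2 * q[3]) / (q[5] - q[1]) else 0
  dx <- diff(x)
  out["line_length"] <- mean(abs(dx))
  if (n > 2) {
    teager <- x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n]
    out["nonlinear_energy"] <- mean(teager)
  }
  out["zero_crossings"] <- sum(x[-n] * x[-1] < 0) / durS
  vx <- stats::var(x); vd <- stats::var(dx); vdd <- stats::var(diff(dx))
  out["hjorth_activity"] <- vx
  mob <- if (vx > 0) sqrt(vd / vx) else 0
  out["hjorth_mobility"] <- mob
  out["hjorth_complexity"] <- if (vd > 0 && mob > 0) sqrt(vdd / vd) / mob else 0
  ## spectral
  psd <- welchPSD(x, fs)
  df <- psd$f[2] - psd$f[1]
  tot <- bandPower(x, c(0.5, 30), fs, psd = psd)
  bp <- vapply(SPEC_BANDS, function(b) bandPower(x, b, fs, psd = psd), 0)
  out[paste0("spec_power_", SPEC_BAND_IDS)] <- bp
  out[paste0("spec_relpower_", SPEC_BAND_IDS)] <-
    if (tot > 0) bp / tot else rep(0, 5)
  out["spec_power_total"] <- tot
  sel <- psd$f >= 0.5 & psd$f < 30
  pf <- psd$f[sel]; pp <- psd$psd[sel]
  if (tot > 0 && sum(pp) > 0) {
    cum <- cumsum(pp) / sum(pp)
    out["spec_sef50"] <- pf[which(cum >= 0.5)[1]]
    out["spec_sef80"] <- pf[which(cum >= 0.8)[1]]
    out["spec_sef90"] <- pf[which(cum >= 0.9)[1]]
    out["spec_sef95"] <- pf[which(cum >= 0.95)[1]]
    pn <- pp / sum(pp)
    out["spec_entropy"] <- -sum(pn[pn > 0] * log(pn[pn > 0])) / log(length(pn))
    out["spec_peak_freq"] <- pf[which.max(pp)]
    out["spec_mean_freq"] <- sum(pf * pp) / sum(pp)
    fitSel <- pf >= 1 & pf <= 30 & pp > 0
    if (sum(fitSel) > 3) {
      lx <- log(pf[fitSel]); ly <- log(pp[fitSel])
      out["spec_slope"] <- stats::cov(lx, ly) / stats::var(lx)
    }
    out["spec_ratio_delta_theta"] <- if (bp[2] > 0) bp[1] / bp[2] else NA_real_
    out["spec_ratio_theta_alpha"] <- if (bp[3] > 0) bp[2] / bp[3] else NA_real_
  }
  ## complexity (entropies on a central 1024-sample window for tractability)
  mid <- max(1L, floor((n - 1024) / 2))
  xe <- x[mid:min(n, mid + 1023)]
  if (sd(xe) > 0) {
    mse <- multiscaleEntropy(xe, maxScale = min(20, floor(length(xe) / 20)))
    out["cplx_sampen"] <- mse$entropy[1]
    out["cplx_sampen_scale5"] <- mse$entropy[5]
    out["cplx_sampen_scale10"] <- mse$entropy[10]
    out["cplx_mse_slope"] <- mse$slope
    out["cplx_mse_mean"] <- mean(mse$entropy, na.rm = TRUE)
    xa <- xe[seq_len(min(512, length(xe)))]
    out["cplx_apen"] <- .apen_cpp(xa, 2L, 0.15 * sd(xa))
    out["cplx_perm_entropy"] <- permEntropy(xe)
    out["cplx_lz"] <- .lz_cpp(as.integer(xe > median(xe)))
    out["cplx_higuchi_fd"] <- .higuchi_cpp(x, 8L)
    L <- sum(abs(dx))
    d <- max(abs(x - x[1]))
    if (L > 0 && d > 0) {
      a <- L / (n - 1)
      out["cplx_katz_fd"] <- log10(L / a) / (log10(d / a) + log10(L / a))
    }
    arfit <- tryCatch(stats::ar(x, order.max = 5, aic = FALSE,
                                method = "yule-walker"),
                      error = function(e) NULL)
    if (!is.null(arfit)) out["cplx_ar_residual_sd"] <- sqrt(arfit$var.pred)
  }
  ## discontinuity
  prof <- p2pProfile(x, fs)
  out[names(discontinuityFeatures(x, fs, prof))] <-
    discontinuityFeatures(x, fs, prof)
  ## modulation
  e <- amEnvelope(x, fs)
  me <- mean(e); se <- sd(e)
  out["mod_am_mean"] <- me
  out["mod_am_sd"] <- se
  out["mod_am_cv"] <- if (me > 0) se / me else 0
  out["mod_env_skew"] <- if (se > 0) e1071::skewness(e) else 0
  out["mod_env_kurt"] <- if (se > 0) e1071::kurtosis(e) else 0
  eq <- quantile(e, c(0.05, 0.5, 0.95), names = FALSE)
  out[c("mod_env_p5", "mod_env_p50", "mod_env_p95")] <- eq
  out["mod_env_iqr"] <- diff(quantile(e, c(0.25, 0.75), names = FALSE))
  out["mod_depth"] <- if (eq[3] + eq[1] > 0)
    (eq[3] - eq[1]) / (eq[3] + eq[1]) else 0
  if (se > 0) {
    ep <- welchPSD(e - me, fs, winS = min(60, durS))
    msel <- ep$f >= 0.01 & ep$f <= 1
    if (any(msel)) out["mod_am_peak_freq"] <- ep$f[msel][which.max(ep$psd[msel])]
  } else out["mod_am_peak_freq"] <- 0
  out
}

## Synchrony features for one channel pair.
pairFeatures <- function(a, b, fs = 64) {
  out <- setNames(rep(NA_real_, length(SYNC_IDS)), SYNC_IDS)
  out["sync_asi"] <- activationSynchronyIndex(a, b, fs)
  ea <- amEnvelope(a, fs); eb <- amEnvelope(b, fs)
  out["sync_env_corr"] <- if (sd(ea) > 0 && sd(eb) > 0) stats::cor(ea, eb) else 0
  out["sync_sig_corr"] <- if (sd(a) > 0 && sd(b) > 0) stats::cor(a, b) else 0
  pa <- welchPSD(a, fs); pb <- welchPSD(b, fs)
  cross <- welchCross(a, b, fs)
  coh <- Mod(cross$pxy)^2 / pmax(pa$psd * pb$psd, .Machine$double.eps)
  for (i in seq_len(3)) {
    bnd <- SPEC_BANDS[[i]]
    sel <- pa$f >= bnd[1] & pa$f < bnd[2]
    out[c("sync_coh_delta", "sync_coh_theta", "sync_coh_alpha")[i]] <-
      mean(coh[sel])
  }
  if (sd(a) > 0 && sd(b) > 0) {
    za <- (a - mean(a)) / sd(a); zb <- (b - mean(b)) / sd(b)
    maxLag <- round(fs / 2)
    cc <- stats::ccf(za, zb, lag.max = maxLag, plot = FALSE)
    out["sync_xcorr_max"] <- max(abs(cc$acf))
  } else out["sync_xcorr_max"] <- 0
  out
}

## Welch cross-spectrum with the same segmentation as welchPSD.
welchCross <- function(x, y, fs, winS = 8, overlap = 0.5) {
  N <- round(winS * fs)
  N <- min(N, length(x))
  step <- max(1L, round(N * (1 - overlap)))
  starts <- seq(1L, length(x) - N + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(N) / (N + 1)))
  U <- sum(w^2)
  nf <- floor(N / 2) + 1
  acc <- complex(nf)
  for (s in starts) {
    X <- fft(x[s:(s + N - 1)] * w)[seq_len(nf)]
    Y <- fft(y[s:(s + N - 1)] * w)[seq_len(nf)]
    acc <- acc + X * Conj(Y) / (U * fs)
  }
  pxy <- acc / length(starts)
  pxy[2:(nf - if (N %% 2 == 0) 1 else 0)] <-
    2 * pxy[2:(nf - if (N %% 2 == 0) 1 else 0)]
  list(f = seq(0, fs / 2, length.out = nf), pxy = pxy)
}

## Homologous left/right electrode pairs from 10-20 labels (odd digit ->
## +1 gives the contralateral partner). Falls back to all channel pairs
## when fewer than one homologous pair exists.
homologousPairs <- function(labels) {
  partner <- vapply(labels, function(l) {
    chars <- strsplit(l, "")[[1]]
    digs <- grepl("[0-9]", chars)
    num <- suppressWarnings(as.integer(paste(chars[digs], collapse = "")))
    if (is.na(num) || num %% 2 == 0) return(NA_character_)
    sub("[0-9]+", num + 1L, l)
  }, "")
  pairs <- list()
  for (i in seq_along(labels)) {
    j <- match(partner[i], labels)
    if (!is.na(j)) pairs[[length(pairs) + 1]] <- c(i, j)
  }
  if (!length(pairs) && length(labels) >= 2) {
    cmb <- utils::combn(seq_along(labels), 2)
    pairs <- lapply(seq_len(min(ncol(cmb), 8)), function(k) cmb[, k])
  }
  pairs
}

#' Compute the feature table for an epoch set
#'
#' Computes all registry features per channel (synchrony features per
#' homologous channel pair) on every epoch, then aggregates across
#' non-rejected channels by the median. Rejected epochs yield missing
#' rows. The per-channel and per-pair values, together with the masked
#' fractions, are retained in the metadata so that the aggregation can be
#' redone at other artifact-rejection thresholds without recomputation
#' (see [aggregateFeatures()]).
#'
#' @param epochSet a preprocessed [EpochSet-class].
#' @param registry the feature registry (defaults to [featureRegistry()]).
#' @return A [SummarizedExperiment::SummarizedExperiment] with assays
#'   `features` (feature x epoch) and `missing`, registry as rowData and
#'   subject/epoch/rejection info as colData.
#' @export
computeFeatureTable <- function(epochSet, registry = featureRegistry()) {
  stopifnot(is(epochSet, "EpochSet"))
  ep <- epochArray(epochSet)
  nCh <- dim(ep)[1]; nE <- dim(ep)[3]
  fs <- samplingRate(epochSet)
  chIds <- setdiff(registry$feature_id, SYNC_IDS)
  perChannel <- array(NA_real_, dim = c(nE, nCh, length(chIds)),
                      dimnames = list(NULL, channelLabels(epochSet), chIds))
  pairs <- homologousPairs(channelLabels(epochSet))
  perPair <- array(NA_real_, dim = c(nE, length(pairs), length(SYNC_IDS)),
                   dimnames = list(NULL, NULL, SYNC_IDS))
  for (e in seq_len(nE)) {
    for (ch in seq_len(nCh)) {
      perChannel[e, ch, ] <- channelFeatures(ep[ch, , e], fs)
    }
    for (k in seq_along(pairs)) {
      p <- pairs[[k]]
      perPair[e, k, ] <- pairFeatures(ep[p[1], , e], ep[p[2], , e], fs)
    }
  }
  ft <- buildFeatureTable(perChannel, perPair, pairs, epochSet, registry)
  ft
}

## Aggregate per-channel/per-pair values under the EpochSet's current
## rejection flags into a SummarizedExperiment.
buildFeatureTable <- function(perChannel, perPair, pairs, epochSet, registry) {
  agg <- aggregateMatrix(perChannel, perPair, pairs,
                         channelRejected(epochSet), epochRejected(epochSet),
                         registry)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(agg$values), missing = t(agg$missing)),
    rowData = S4Vectors::DataFrame(registry),
    colData = S4Vectors::DataFrame(
      subject = rep(subjectId(epochSet), nrow(agg$values)),
      epoch = seq_len(nrow(agg$values)),
      epochRejected = epochRejected(epochSet))
  )
  S4Vectors::metadata(se) <- list(
    perChannel = perChannel, perPair = perPair, pairs = pairs,
    maskedFraction = maskedFraction(epochSet),
    channelLabels = channelLabels(epochSet))
  se
}

aggregateMatrix <- function(perChannel, perPair, pairs, chanRej, epochRej,
                            registry) {
  nE <- dim(perChannel)[1]
  ids <- registry$feature_id
  values <- matrix(NA_real_, nE, length(ids), dimnames = list(NULL, ids))
  missing <- matrix(TRUE, nE, length(ids), dimnames = list(NULL, ids))
  chIds <- dimnames(perChannel)[[3]]
  for (e in seq_len(nE)) {
    if (epochRej[e]) next
    keep <- !chanRej[e, ]
    if (any(keep)) {
      sub <- perChannel[e, keep, , drop = FALSE]
      med <- apply(sub, 3, function(v) median(v, na.rm = TRUE))
      values[e, chIds] <- med
      missing[e, chIds] <- !is.finite(med)
    }
    if (length(pairs)) {
      pairKeep <- vapply(pairs, function(p) all(!chanRej[e, p]), TRUE)
      if (any(pairKeep)) {
        sub <- perPair[e, pairKeep, , drop = FALSE]
        med <- apply(sub, 3, function(v) median(v, na.rm = TRUE))
        values[e, SYNC_IDS] <- med
        missing[e, SYNC_IDS] <- !is.finite(med)
      }
    }
  }
  values[!is.finite(values)] <- NA_real_
  list(values = values, missing = missing)
}

#' Re-aggregate a feature table at different rejection thresholds
#'
#' Recomputes channel/epoch rejection from the stored masked fractions at
#' the given thresholds and re-aggregates the stored per-channel feature
#' values, without recomputing any feature.
#'
#' @param ft a feature table from [computeFeatureTable()].
#' @param chanThresh,epochThresh rejection thresholds (fractions).
#' @return a new feature table (same metadata, new aggregation).
#' @export
aggregateFeatures <- function(ft, chanThresh = 0.25, epochThresh = 0.5) {
  md <- S4Vectors::metadata(ft)
  mf <- md$maskedFraction
  chanRej <- if (chanThresh == 0) mf > 0 else mf >= chanThresh
  epochRej <- rowMeans(chanRej) >= epochThresh
  registry <- as.data.frame(SummarizedExperiment::rowData(ft))
  agg <- aggregateMatrix(md$perChannel, md$perPair, md$pairs, chanRej,
                         epochRej, registry)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(agg$values), missing = t(agg$missing)),
    rowData = SummarizedExperiment::rowData(ft),
    colData = S4Vectors::DataFrame(
      subject = SummarizedExperiment::colData(ft)$subject,
      epoch = seq_len(nrow(agg$values)),
      epochRejected = epochRej)
  )
  S4Vectors::metadata(se) <- md
  se
}

#' Extract the epochs x features value matrix from a feature table
#'
#' @param ft a feature table ([computeFeatureTable()]).
#' @return numeric matrix, epochs x features (NA = missing).
#' @export
featureValues <- function(ft) t(SummarizedExperiment::assay(ft, "features"))

#' Channel-restricted feature matrix
#'
#' Per-channel feature values for a single channel, in registry order.
#' Synchrony features are pairwise and therefore NA in a single-channel
#' restriction (classifiers impute them from training-fold medians).
#'
#' @param ft a feature table ([computeFeatureTable()]).
#' @param channel channel label or index.
#' @return numeric matrix, epochs x 98 features.
#' @export
channelFeatureMatrix <- function(ft, channel) {
  md <- S4Vectors::metadata(ft)
  if (is.character(channel)) channel <- match(channel, md$channelLabels)
  if (is.na(channel)) stop("unknown channel")
  reg <- as.data.frame(SummarizedExperiment::rowData(ft))
  out <- matrix(NA_real_, dim(md$perChannel)[1], nrow(reg),
                dimnames = list(NULL, reg$feature_id))
  chIds <- dimnames(md$perChannel)[[3]]
  out[, chIds] <- md$perChannel[, channel, ]
  out
}

#' @rdname featureValues
#' @export
featureMissing <- function(ft) t(SummarizedExperiment::assay(ft, "missing"))
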