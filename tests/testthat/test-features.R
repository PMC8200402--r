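test_that("the registry holds exactly 98 stable ids including the named top-5", {
  reg <- featureRegistry()
  expect_equal(nrow(reg), 98)
  expect_false(anyDuplicated(reg$feature_id) > 0)
  expect_true(all(c("mod_am_sd", "mod_am_mean", "sync_asi",
                    "cplx_mse_slope", "spec_power_9_11") %in% reg$feature_id))
  expect_setequal(unique(reg$category),
                  c("amplitude", "spectral", "complexity", "discontinuity",
                    "modulation", "synchrony"))
  expect_identical(reg$feature_id, featureRegistry()$feature_id)
})

test_that("every feature is computable on a 5-min epoch of every class", {
  for (sc in 0:6) {
    sig <- simulateEpoch(backgroundClassParams(sc), 2, 64, 300,
                         seed = 40 + sc)$signal
    v <- neobg:::channelFeatures(sig[1, ], 64)
    expect_true(all(is.finite(v)), label = sprintf("score %d finite", sc))
    pv <- neobg:::pairFeatures(sig[1, ], sig[2, ], 64)
    expect_true(all(is.finite(pv)), label = sprintf("score %d pair", sc))
  }
})

test_that("band power of a 10 uV 10 Hz sine is ~50 uV^2 in the 9-11 Hz band", {
  x <- 10 * sin(2 * pi * 10 * seq(0, 300, by = 1 / 64))
  p911 <- bandPower(x, c(9, 11))
  expect_lt(abs(p911 / 50 - 1), 0.05)
  total <- bandPower(x, c(0.5, 30))
  expect_lt(abs(total / 50 - 1), 0.05)
  ## 5 Hz sine leaves the 9-11 Hz band empty
  x5 <- 10 * sin(2 * pi * 5 * seq(0, 300, by = 1 / 64))
  expect_lt(bandPower(x5, c(9, 11)) / bandPower(x5, c(0.5, 30)), 0.01)
})

test_that("white-noise band power matches the brute-force periodogram sum", {
  set.seed(8)
  for (i in 1:3) {
    x <- rnorm(2048, sd = 5)
    mine <- bandPower(x, c(3, 8), fs = 64)
    brute <- bruteBandPower(x, c(3, 8), fs = 64)
    expect_lt(abs(mine / brute - 1), 0.01)
  }
})

test_that("amplitude modulation statistics behave analytically", {
  fs <- 64
  t <- seq(0, 300 - 1 / fs, by = 1 / fs)
  ## unmodulated carrier: mean ~ A, sd ~ 0
  s <- amplitudeModulationStats(8 * sin(2 * pi * 10 * t), fs)
  expect_lt(abs(s["mean"] / 8 - 1), 0.05)
  expect_lt(s["sd"] / 8, 0.05)
  ## two-level envelope with equal dwell: sd/mean ~ 1
  gate <- rep(rep(c(1, 0), each = 10 * fs), length.out = length(t))
  s2 <- amplitudeModulationStats(8 * gate * sin(2 * pi * 10 * t), fs)
  expect_lt(abs(s2["sd"] / s2["mean"] - 1), 0.10)
  ## zero signal
  expect_equal(unname(amplitudeModulationStats(numeric(640), fs)), c(0, 0))
})

test_that("activation synchrony is maximal for identical channels and drops for shuffled gates", {
  fs <- 64
  set.seed(9)
  n <- 20 * fs
  gate <- neobg:::smoothGate(neobg:::burstGate(n, fs, 2, 3), fs)
  mk <- function(g) (2 + 48 * g) * rnorm(n)
  a <- mk(gate)
  expect_equal(activationSynchronyIndex(a, a, fs), 1)
  b <- mk(gate)  # shared gate, independent carrier
  asiShared <- activationSynchronyIndex(a, b, fs)
  ## permutation oracle: circularly shift the second channel's gate
  perm <- vapply(1:300, function(i) {
    sh <- sample(n - 1, 1)
    activationSynchronyIndex(a, c(b[(sh + 1):n], b[1:sh]), fs)
  }, 0)
  expect_gt(asiShared, quantile(perm, 0.95))
  expect_lt(abs(mean(perm)), 0.2)
  ## symmetric and degenerate-safe
  expect_equal(activationSynchronyIndex(a, b, fs),
               activationSynchronyIndex(b, a, fs))
  expect_equal(activationSynchronyIndex(numeric(n), numeric(n), fs), 0)
})

test_that("multiscale entropy slope separates white from 1/f noise", {
  slopes <- sapply(1:20, function(seed) {
    set.seed(seed)
    white <- rnorm(2000)
    pink <- neobg:::colorednoise(2000, 64, alpha = 2, band = c(0.5, 30))
    c(white = multiscaleEntropySlope(white, maxScale = 10),
      pink = multiscaleEntropySlope(pink, maxScale = 10))
  })
  expect_true(all(slopes["white", ] < 0))
  expect_true(all(slopes["pink", ] > slopes["white", ]))
  ## determinism
  set.seed(3); x <- rnorm(1500)
  expect_identical(multiscaleEntropySlope(x), multiscaleEntropySlope(x))
  ## constant signal undefined
  expect_true(is.na(multiscaleEntropySlope(rep(1, 1500))))
})

test_that("sample entropy matches the brute-force oracle and pracma", {
  set.seed(10)
  for (i in 1:5) {
    x <- rnorm(150)
    r <- 0.2 * sd(x)
    expect_equal(sampleEntropy(x, 2, r), bruteSampEn(x, 2, r),
                 tolerance = 1e-12)
  }
  skip_if_not_installed("pracma")
  x <- rnorm(400)
  expect_equal(sampleEntropy(x, 2, 0.2 * sd(x)),
               pracma::sample_entropy(x, edim = 2, r = 0.2 * sd(x)),
               tolerance = 1e-8)
})

test_that("channel-median aggregation matches direct medians and handles rejection", {
  reg <- featureRegistry()
  nF <- 98 - sum(reg$category == "synchrony")
  perChannel <- array(NA_real_, c(2, 3, nF),
                      dimnames = list(NULL, NULL,
                                      setdiff(reg$feature_id,
                                              reg$feature_id[reg$category == "synchrony"])))
  perChannel[1, , ] <- matrix(rep(c(1, 2, 9), nF), 3)
  perChannel[2, , ] <- matrix(rep(c(1, 2, 9), nF), 3)
  chanRej <- matrix(FALSE, 2, 3)
  chanRej[2, 3] <- TRUE  # drop the '9' channel in epoch 2
  agg <- neobg:::aggregateMatrix(perChannel, array(0, c(2, 0, 7)), list(),
                                 chanRej, c(FALSE, FALSE), reg)
  expect_equal(unname(agg$values[1, "amp_sd"]), 2)     # median {1,2,9}
  expect_equal(unname(agg$values[2, "amp_sd"]), 1.5)   # median {1,2}
  ## rejected epoch -> all missing
  agg2 <- neobg:::aggregateMatrix(perChannel, array(0, c(2, 0, 7)), list(),
                                  chanRej, c(TRUE, FALSE), reg)
  expect_true(all(agg2$missing[1, ]))
})

test_that("identical channels aggregate to the single-channel value", {
  x <- simulateEpoch(backgroundClassParams(3), 1, 64, 300, seed = 11)$signal
  es <- segmentEpochs(rbind(x[1, ], x[1, ], x[1, ]), channelLabels = c("F3", "F4", "P3"))
  es <- rejectChannelsAndEpochs(es)
  ft <- computeFeatureTable(es)
  single <- neobg:::channelFeatures(x[1, ], 64)
  vals <- featureValues(ft)[1, names(single)]
  expect_equal(unname(vals), unname(single))
})

test_that("gain covariance: dimensionless features are invariant, amplitude features scale", {
  x <- simulateEpoch(backgroundClassParams(1), 1, 64, 300, seed = 12)$signal[1, ]
  reg <- featureRegistry()
  f1 <- neobg:::channelFeatures(x, 64)
  for (g in c(0.5, 2)) {
    fg <- neobg:::channelFeatures(g * x, 64)
    dimless <- intersect(reg$feature_id[reg$dimensionless], names(f1))
    ## discontinuity stats move with thresholds when the signal is rescaled;
    ## check the scale-free shape/entropy/spectral-ratio features
    dimless <- dimless[!grepl("^disc_", dimless)]
    expect_equal(fg[dimless], f1[dimless], tolerance = 0.05)
    linear <- c("amp_sd", "amp_mad", "amp_p2p", "reeg_p50", "reeg_mean",
                "line_length", "mod_am_mean", "mod_am_sd")
    expect_equal(unname(fg[linear]), unname(g * f1[linear]),
                 tolerance = 1e-6)
  }
})

test_that("mean envelope amplitude orders the amplitude classes 0 > 4 > 6", {
  for (seed in 1:20) {
    m <- vapply(c(0, 4, 6), function(sc) {
      sig <- simulateEpoch(backgroundClassParams(sc), 1, 64, 60,
                           seed = seed)$signal
      amplitudeModulationStats(sig[1, ], 64)["mean"]
    }, 0)
    expect_true(m[1] > m[2] && m[2] > m[3])
  }
})

test_that("re-aggregation at other thresholds changes rejection, not features", {
  x <- simulateEpoch(backgroundClassParams(0), 2, 64, 300, seed = 13)$signal
  es <- segmentEpochs(x, channelLabels = c("F3", "F4"))
  es@maskedFraction <- matrix(c(0.15, 0), 1, 2)
  es <- rejectChannelsAndEpochs(es)
  ft <- computeFeatureTable(es)
  ft10 <- aggregateFeatures(ft, chanThresh = 0.10, epochThresh = 0.75)
  md <- S4Vectors::metadata(ft10)
  expect_identical(md$perChannel, S4Vectors::metadata(ft)$perChannel)
  ## at 10% the first channel is rejected, so the aggregate equals channel 2
  expect_equal(unname(featureValues(ft10)[1, "amp_sd"]),
               unname(md$perChannel[1, 2, "amp_sd"]))
})
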