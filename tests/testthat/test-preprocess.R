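test_that("amplitude artifacts are flagged strictly above 500 uV", {
  x <- c(0, 501, -600, 499)
  expect_equal(detectArtifactSamples(x, fs = 4), c(FALSE, TRUE, TRUE, FALSE))
})

test_that("flat runs of at least 1 s are fully masked", {
  expect_true(all(detectArtifactSamples(rep(0, 640), fs = 64)))
  ## sub-second flat run is not flagged
  x <- rnorm(640)
  x[100:130] <- 5  # 31 samples < 64
  expect_false(any(detectArtifactSamples(x, fs = 64)[100:130]))
  ## exactly 1 s flagged
  x[200:263] <- 7
  expect_true(all(detectArtifactSamples(x, fs = 64)[200:263]))
})

test_that("a clean physiological-range signal is not masked and NaN warns", {
  x <- 100 * sin(2 * pi * 3 * seq(0, 10, by = 1 / 256))
  expect_false(any(detectArtifactSamples(x, fs = 256)))
  x[5] <- NaN
  expect_warning(m <- detectArtifactSamples(x, fs = 256), "NaN")
  expect_true(m[5])
})

test_that("band-pass keeps 10 Hz and attenuates 50 Hz by the stopband design", {
  fs <- 256
  t <- seq(0, 20, by = 1 / fs)
  pass <- bandpassFilter(sin(2 * pi * 10 * t), fs)
  mid <- seq(round(length(t) * 0.2), round(length(t) * 0.8))
  rmsIn <- sqrt(mean(sin(2 * pi * 10 * t[mid])^2))
  expect_lt(abs(sqrt(mean(pass[mid]^2)) / rmsIn - 1), 0.05)
  stopSig <- bandpassFilter(sin(2 * pi * 50 * t), fs)
  atten <- 20 * log10(sqrt(mean(stopSig[mid]^2)) / sqrt(0.5))
  expect_lt(atten, -40)
  expect_equal(bandpassFilter(numeric(1000), fs), numeric(1000))
  expect_equal(length(pass), length(t))
})

test_that("resampling reaches exactly 19,200 samples per 5 minutes", {
  for (fs in c(200, 250, 256)) {
    x <- rnorm(300 * fs)
    expect_equal(length(resampleTo64(x, fs)), 19200)
  }
  expect_warning(resampleTo64(rnorm(1000), 100), "native rate")
})

test_that("a 5 Hz sine survives resampling with amplitude within 2%", {
  for (fs in c(200, 250, 256)) {
    t <- seq(0, 60 - 1 / fs, by = 1 / fs)
    y <- resampleTo64(sin(2 * pi * 5 * t), fs)
    mid <- seq(round(length(y) * 0.1), round(length(y) * 0.9))
    amp <- sqrt(2 * mean(y[mid]^2))
    expect_lt(abs(amp - 1), 0.02)
  }
})

test_that("segmentation drops the trailing remainder", {
  d64 <- matrix(rnorm(2 * 1100 * 64), 2)
  es <- segmentEpochs(d64)
  expect_equal(nEpochs(es), 3)
  expect_equal(dim(epochArray(es))[2], 19200)
  expect_equal(nEpochs(segmentEpochs(matrix(rnorm(300 * 64), 1))), 1)
  expect_warning(es0 <- segmentEpochs(matrix(rnorm(299 * 64), 1)),
                 "shorter than one")
  expect_equal(nEpochs(es0), 0)
})

test_that("channel and epoch rejection use at-least thresholds", {
  es <- segmentEpochs(matrix(rnorm(8 * 19200), 8))
  ## channel with exactly 25% masked is rejected
  mf <- matrix(0, 1, 8)
  mf[1, 1:4] <- 0.25
  es@maskedFraction <- mf
  es <- rejectChannelsAndEpochs(es)
  expect_true(all(channelRejected(es)[1, 1:4]))
  expect_false(any(channelRejected(es)[1, 5:8]))
  ## 4 of 8 channels rejected = 50% -> epoch rejected ("at least")
  expect_true(epochRejected(es)[1])
  ## clean epoch: nothing rejected
  es@maskedFraction <- matrix(0, 1, 8)
  es <- rejectChannelsAndEpochs(es)
  expect_false(any(channelRejected(es)))
  expect_false(any(epochRejected(es)))
})

test_that("rejection counts are monotone over the threshold sweep", {
  set.seed(5)
  es <- segmentEpochs(matrix(rnorm(4 * 19200 * 2), 4))
  es@maskedFraction <- matrix(runif(8, 0, 0.6), 2, 4)
  counts <- vapply(c(0, 0.10, 0.25, 0.50), function(th)
    sum(channelRejected(rejectChannelsAndEpochs(es, chanThresh = th))), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("bipolar derivation is the channel difference with OR-ed masks", {
  set.seed(6)
  d <- matrix(rnorm(4 * 1000), 4)
  rec <- EEGRecording(d, c("F3", "F4", "P3", "P4"), 256)
  bip <- deriveBipolar(rec)
  expect_equal(channelLabels(bip), c("F3-P3", "F4-P4", "P3-P4"))
  expect_equal(eegData(bip)[1, ], d[1, ] - d[3, ])
  expect_equal(eegData(bip)[3, ], d[3, ] - d[4, ])
  ## identical electrodes cancel; zero reference passes through
  rec2 <- EEGRecording(rbind(d[1, ], d[1, ], 0), c("F3", "P3", "P4"), 256)
  bip2 <- deriveBipolar(rec2, pairs = list(c("F3", "P3"), c("P3", "P4")))
  expect_true(all(eegData(bip2)[1, ] == 0))
  expect_equal(eegData(bip2)[2, ], d[1, ])
  expect_error(deriveBipolar(rec, pairs = list(c("F3", "O1"))), "O1")
  mask <- matrix(FALSE, 4, 1000); mask[1, 1:10] <- TRUE
  bip3 <- deriveBipolar(rec, mask = mask)
  expect_true(all(attr(bip3, "mask")[1, 1:10]))
})

test_that("filtering and resampling are linear in the signal gain", {
  set.seed(7)
  x <- rnorm(250 * 40, sd = 20)
  f1 <- resampleTo64(bandpassFilter(x, 250), 250)
  f3 <- resampleTo64(bandpassFilter(3 * x, 250), 250)
  ## the 10th-order recursion at a 0.25 Hz edge is ill-conditioned, so
  ## floating-point linearity holds to ~1e-4 relative, not 1e-15
  expect_equal(f3, 3 * f1, tolerance = 1e-3)
})

test_that("the full chain yields 19,200-sample epochs regardless of rejection", {
  rec <- EEGRecording(matrix(rnorm(2 * 650 * 200, sd = 15), 2),
                      c("F3", "F4"), 200)
  es <- preprocessRecording(rec)
  expect_equal(nEpochs(es), 2)  # floor(650/300)
  expect_equal(dim(epochArray(es))[2], 19200)
  expect_equal(samplingRate(es), 64)
})
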