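test_that("self-coherence is one and the estimator matches the DFT oracle", {
  fs <- 1024
  set.seed(41)
  x <- rnorm(10 * fs)
  pr <- mscProfile(x, x, fs)
  expect_true(all(abs(coherence(pr) - 1) < 1e-9))
  ## 4-block toy: exact agreement with the brute-force direct-DFT oracle
  nfft <- 32
  x4 <- rnorm(4 * nfft); y4 <- 0.5 * x4 + rnorm(4 * nfft)
  pr4 <- mscProfile(x4, y4, fs = 64, nfft = nfft, overlap = 0)
  oracle <- bruteMsc(x4, y4, nfft, step = nfft,
                     window = gammacoh:::hannWindow(nfft))
  expect_equal(coherence(pr4), oracle, tolerance = 1e-10)
  expect_equal(pr4@nBlocks, 4L)
  ## contract errors
  expect_error(mscProfile(x, x[-1], fs), "equal length")
  expect_error(mscProfile(rnorm(2048), rnorm(2048), fs, nfft = 2048),
               "2 blocks")
})

test_that("coherence is symmetric and scale-invariant", {
  fs <- 256
  set.seed(42)
  x <- rnorm(10 * fs); y <- 0.7 * x + rnorm(10 * fs)
  pxy <- mscProfile(x, y, fs, nfft = 512)
  pyx <- mscProfile(y, x, fs, nfft = 512)
  expect_equal(coherence(pxy), coherence(pyx), tolerance = 1e-12)
  pab <- mscProfile(3.2 * x, -0.5 * y, fs, nfft = 512)
  expect_equal(coherence(pab), coherence(pxy), tolerance = 1e-9)
})

test_that("the z' transform follows atanh(sqrt(msc))", {
  expect_equal(zTransform(0), 0)
  ## independently evaluated: 0.5 * ln((1 + sqrt(0.75)) / (1 - sqrt(0.75)))
  expect_equal(zTransform(0.75), 1.3169579, tolerance = 1e-6)
  expect_true(all(diff(zTransform(seq(0, 0.99, 0.01))) > 0))
  expect_warning(zc <- zTransform(1), "clipped")
  expect_gt(zc, 13)
  expect_error(zTransform(1.5), "0, 1")
  ## alternative convention
  expect_equal(zTransform(0.5, method = "atanh"), atanh(0.5))
})

test_that("band summaries respect their band and constant profiles", {
  fs <- 1024
  set.seed(43)
  x <- rnorm(20 * fs)
  pr <- mscProfile(x, x, fs)
  ## constant msc = 1 - eps: band mean equals the constant regardless of band
  suppressWarnings({
    z1 <- bandMeanZ(pr, c(30, 45))
    z2 <- bandMeanZ(pr, c(5, 20))
  })
  expect_equal(z1, z2, tolerance = 1e-6)
  expect_error(bandMeanZ(pr, c(45, 30)), "lo > hi")
  expect_error(bandMsc(pr, c(45, 30)), "lo > hi")
  ## 30-45 Hz inclusive on the 0.5-Hz grid spans 31 points
  expect_equal(sum(pr@freqs >= 30 & pr@freqs <= 45), 31)
})

test_that("a synthetic coupled pair matches the closed-form oracle", {
  ses <- generateRecording(cleanCouplingConfig(0.75, 300, seed = 44))
  x <- signalMatrix(ses$recording)
  pr <- mscProfile(x[1, ], x[2, ], 1024)
  expected <- ses$groundTruth@expectedBandMsc[["AW"]]
  expect_equal(expected, 0.5625)
  expect_lt(abs(bandMsc(pr) - expected), 0.05)
  expect_lt(abs(zTransform(bandMsc(pr)) - zTransform(expected)), 0.1)
})

test_that("the coherogram tracks a coupling switch and stays near zero when uncoupled", {
  fs <- 1024
  ## coupling 0.8 for 200 s then 0.05 (synthetic injection at t0 = 200)
  sts <- list(AW = syntheticState("AW", 2, 25, couplingFraction = 0.8,
                                  jitter = 0),
              K15 = syntheticState("K15", 2, 25, couplingFraction = 0.05,
                                   jitter = 0))
  ses <- generateRecording(
    syntheticConfig(data.frame(state = c("AW", "K15"),
                               duration = c(200, 200)),
                    states = sts, seed = 45))
  x <- signalMatrix(ses$recording)
  cg <- coherogram(x[1, ], x[2, ], fs, seg = 50, step = 50)
  sel <- cg@freqs >= 30 & cg@freqs <= 45
  bz <- rowMeans(cg@z[, sel])
  pre <- bz[cg@times < 200]; post <- bz[cg@times > 200]
  pooledSd <- sqrt((stats::var(pre) + stats::var(post)) / 2)
  expect_gt(mean(pre) - mean(post), 5 * pooledSd)
  ## uncoupled pair: every band z' under the bias ceiling z(3/L)
  set.seed(46)
  x0 <- rnorm(300 * fs); y0 <- rnorm(300 * fs)
  cg0 <- coherogram(x0, y0, fs, seg = 100, step = 100)
  L <- 99
  expect_true(all(rowMeans(cg0@z[, sel]) < zTransform(3 / L)))
  expect_error(coherogram(x0, y0, fs, seg = 100, step = 0), "positive")
})

test_that("block permutation preserves the shuffled channel's PSD exactly", {
  fs <- 1024
  set.seed(47)
  y <- rnorm(20 * fs)
  nb <- floor(length(y) / 2048)
  perm <- sample(nb)
  ys <- permuteBlocks(y, 2048, perm)
  expect_equal(sort(ys), sort(y))
  p0 <- welchPsd(y[1:(nb * 2048)], fs, overlap = 0)
  p1 <- welchPsd(ys[1:(nb * 2048)], fs, overlap = 0)
  expect_equal(p1@power, p0@power, tolerance = 1e-12)
  ## identity permutation leaves the series untouched
  expect_identical(permuteBlocks(y, 2048, seq_len(nb)), y)
  expect_error(permuteBlocks(y, 2048, seq_len(nb - 1)), "permutation")
})

test_that("the shuffle surrogate separates a coupled pair from its null", {
  ses <- generateRecording(cleanCouplingConfig(0.8, 100, seed = 48))
  x <- signalMatrix(ses$recording)
  sur <- shuffleSurrogate(x[1, ], x[2, ], 1024, nShuffles = 100, seed = 49)
  expect_gt(sur$observed, max(sur$null))
  expect_equal(sur$quantile, 1)
  ## misaligned block duration is a contract error
  expect_error(shuffleSurrogate(x[1, ], x[2, ], 1024, blockDur = 1.5),
               "misaligned")
})
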