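test_that("generateBurst meets its amplitude, endpoint and spectral contract", {
  fs <- 1024
  w <- generateBurst(0.3, 25, 40, fs)
  expect_equal(max(abs(w)), 25)
  expect_equal(length(generateBurst(0.5, 25, 40, fs)), 512)
  expect_equal(w[1], 0)
  expect_equal(w[length(w)], 0)
  ## spectral peak at the carrier
  spec <- Mod(fft(c(w, numeric(4096 - length(w)))))[1:2048]
  fpk <- (which.max(spec) - 1) * fs / 4096
  expect_lt(abs(fpk - 40), 1)
  ## zero amplitude
  expect_true(all(generateBurst(0.3, 0, 40, fs) == 0))
  ## invalid arguments
  expect_error(generateBurst(-0.1, 25, 40, fs), "positive")
  expect_error(generateBurst(0.3, 25, 40, -1), "positive")
  expect_error(generateBurst(0.3, 25, 20, fs), "30")
})

test_that("a source-free configuration generates an all-zero signal", {
  st <- syntheticState("AW", burstRate = 0, burstAmp = 0,
                       couplingFraction = 0.5,
                       backgroundSpec = data.frame(lo = 1, hi = 20,
                                                   power = 0))
  ses <- generateRecording(
    syntheticConfig(data.frame(state = "AW", duration = 20),
                    states = list(AW = st), seed = 1))
  expect_true(all(signalMatrix(ses$recording) == 0))
})

test_that("identical configurations reproduce sessions bit for bit", {
  cfg <- syntheticConfig(c(AW = 30, REM = 30), seed = 9)
  s1 <- generateRecording(cfg)
  s2 <- generateRecording(cfg)
  expect_identical(signalMatrix(s1$recording), signalMatrix(s2$recording))
  expect_identical(s1$groundTruth@bursts, s2$groundTruth@bursts)
  ## different seed differs
  s3 <- generateRecording(syntheticConfig(c(AW = 30, REM = 30), seed = 10))
  expect_false(identical(signalMatrix(s1$recording),
                         signalMatrix(s3$recording)))
})

test_that("annotation epochs are 10 s and consistent with the state sequence", {
  ses <- generateRecording(syntheticConfig(c(AW = 50, NREM = 30), seed = 2))
  ep <- epochs(ses$annotation)
  expect_equal(nrow(ep), 8)
  expect_true(all(ep$duration == 10))
  expect_equal(ep$state, c(rep("AW", 5), rep("NREM", 3)))
  expect_equal(ep$start, seq(0, 70, by = 10))
})

test_that("unknown states in the sequence are rejected", {
  expect_error(
    syntheticConfig(data.frame(state = "XX", duration = 20),
                    states = statePresets()),
    "XX")
})

test_that("shared bursts land at identical onsets on every channel", {
  ses <- generateRecording(cleanCouplingConfig(1, 60, seed = 3))
  b <- ses$groundTruth@bursts
  expect_true(all(b$shared))
  byCh <- split(b$onset, b$channel)
  expect_equal(byCh[[1]], byCh[[2]])
})

test_that("expectedBandMsc matches its closed form at the corner cases", {
  bg0 <- data.frame(lo = 1, hi = 20, power = 0)
  ## fully shared, no independent power -> 1
  stS <- syntheticState("AW", 2, 25, couplingFraction = 1,
                        backgroundSpec = bg0, burstAmpSd = 0)
  expect_equal(expectedBandMsc(stS), 1)
  ## no shared power -> 0
  stN <- syntheticState("AW", 2, 25, couplingFraction = 0,
                        backgroundSpec = bg0, burstAmpSd = 0)
  expect_equal(expectedBandMsc(stN), 0)
  ## S = N -> 1/4: in-band background power set equal to burst power
  p0 <- 2 * 0.35 * (3 / 8) * 0.5 * 25^2
  stH <- syntheticState("AW", 2, 25, couplingFraction = 1,
                        backgroundSpec = data.frame(lo = 30, hi = 45,
                                                    power = p0),
                        burstAmpSd = 0)
  expect_equal(expectedBandMsc(stH), 0.25)
})

test_that("S = N coupling configuration is recovered by the estimator", {
  ## empirical check of the 1/4 closed form on a long record
  p0 <- 2 * 0.35 * (3 / 8) * 0.5 * 25^2
  stH <- syntheticState("AW", 2, 25, couplingFraction = 1,
                        backgroundSpec = data.frame(lo = 30, hi = 45,
                                                    power = p0),
                        burstAmpSd = 0, jitter = 0)
  ses <- generateRecording(
    syntheticConfig(data.frame(state = "AW", duration = 400),
                    states = list(AW = stH), seed = 12))
  x <- signalMatrix(ses$recording)
  est <- bandMsc(mscProfile(x[1, ], x[2, ], 1024))
  expect_lt(abs(est - 0.25), 0.05)
})

test_that("within-state background is stationary across halves", {
  ses <- generateRecording(syntheticConfig(c(QW = 200), seed = 4))
  x <- signalMatrix(ses$recording)[1, ]
  fs <- 1024
  p1 <- welchPsd(x[1:(100 * fs)], fs)
  p2 <- welchPsd(x[(100 * fs + 1):(200 * fs)], fs)
  v1 <- sum(p1@power) * 0.5
  v2 <- sum(p2@power) * 0.5
  expect_lt(abs(v1 - v2) / v1, 0.10)
})

test_that("estimated band coherence increases with coupling fraction", {
  zs <- vapply(c(0, 0.5, 1), function(cp) {
    ses <- generateRecording(cleanCouplingConfig(cp, 100, seed = 31))
    x <- signalMatrix(ses$recording)
    suppressWarnings(bandMeanZ(mscProfile(x[1, ], x[2, ], 1024)))
  }, numeric(1))
  expect_true(all(diff(zs) > 0))
})

test_that("state presets encode the published state contrasts", {
  ps <- statePresets()
  m <- vapply(ps, expectedBandMsc, numeric(1))
  expect_true(m[["AW"]] > m[["QW"]])
  expect_true(m[["QW"]] > m[["NREM"]])
  expect_true(m[["NREM"]] > m[["REM"]])
  expect_true(m[["K5"]] > m[["K10"]])
  expect_true(m[["K10"]] > m[["K15"]])
  expect_lt(abs(m[["REM"]] - m[["K15"]]), 0.01)
  ## parameter validation
  expect_error(syntheticState("AW", 1, 20, couplingFraction = 1.2),
               "couplingFraction")
  expect_error(syntheticState("AW", -1, 20, couplingFraction = 0.5),
               "burstRate")
  expect_error(syntheticState("AW", 1, 20, couplingFraction = 0.5,
                              burstDurRange = c(0.5, 0.2)),
               "burstDurRange")
})
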