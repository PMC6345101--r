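## Shared fixture: a 100-s trace with 50 identical injected bursts.
injectedBurstFixture <- function(noiseSd = 2, seed = 61, nBursts = 50) {
  fs <- 1024
  set.seed(seed)
  sig <- stats::rnorm(100 * fs, sd = noiseSd)
  tpl <- generateBurst(0.3, 25, 40, fs)
  ons <- round(seq(2, 97, length.out = nBursts) * fs)
  for (o in ons) sig[o:(o + length(tpl) - 1)] <-
      sig[o:(o + length(tpl) - 1)] + tpl
  list(fs = fs, sig = sig, tpl = tpl, ons = ons)
}

test_that("burst detection recovers injected bursts and their triggers", {
  fx <- injectedBurstFixture()
  filt <- firBandpass(fx$sig, fs = fx$fs)
  env <- signalEnvelope(filt, fx$fs)
  bs <- detectBursts(env, filt, fx$fs)
  expect_gte(nrow(bs), 48)
  expect_lte(nrow(bs), 52)
  expect_true(all(bs$onset < bs$trigger & bs$trigger < bs$offset))
  expect_true(all(bs$peakAmp > 0))
  ## triggers within 25 ms of the injected envelope peak for 95% of bursts
  pkTimes <- (fx$ons - 1) / fx$fs + 0.15
  err <- vapply(bs$trigger, function(tt) min(abs(tt - pkTimes)), numeric(1))
  expect_gte(mean(err <= 0.025), 0.95)
})

test_that("burst detection handles degenerate input and threshold monotonicity", {
  fs <- 1024
  expect_equal(nrow(detectBursts(numeric(1000), numeric(1000), fs)), 0)
  expect_error(detectBursts(numeric(0), numeric(0), fs), "non-empty")
  fx <- injectedBurstFixture()
  filt <- firBandpass(fx$sig, fs = fx$fs)
  env <- signalEnvelope(filt, fx$fs)
  counts <- vapply(c(1, 2, 3, 5),
                   function(th) nrow(detectBursts(env, filt, fx$fs,
                                                  threshSd = th)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the triggered average recovers the injected template", {
  fx <- injectedBurstFixture(noiseSd = 1)
  filt <- firBandpass(fx$sig, fs = fx$fs)
  env <- signalEnvelope(filt, fx$fs)
  bs <- detectBursts(env, filt, fx$fs)
  expect_gte(nrow(bs), 50 - 2)
  bta <- burstTriggeredAverage(bs, filt, fx$fs, seed = 62)
  ## align the template at its own absolute peak, positive polarity
  hw <- round(0.25 * fx$fs)
  pk <- which.max(abs(fx$tpl))
  tseg <- numeric(2 * hw + 1)
  idx <- (pk - hw):(pk + hw)
  ok <- idx >= 1 & idx <= length(fx$tpl)
  tseg[ok] <- fx$tpl[idx[ok]]
  if (fx$tpl[pk] < 0) tseg <- -tseg
  expect_gt(stats::cor(bta$waveform, tseg), 0.99)
  expect_equal(length(bta$waveform), 2 * hw + 1)
})

test_that("a single-event average is that aligned segment", {
  fs <- 1024
  set.seed(63)
  sig <- stats::rnorm(10 * fs)
  ev <- data.frame(channel = "", onset = 4.9, trigger = 5, offset = 5.2,
                   peakAmp = 1)
  bta <- burstTriggeredAverage(ev, sig, fs, n = 1)
  tc <- round(5 * fs) + 1
  seg <- sig[(tc - 256):(tc + 256)]
  if (sig[tc] < 0) seg <- -seg
  expect_equal(bta$waveform, seg)
  expect_equal(bta$nBursts, 1)
  ## no eligible event (window exceeds recording) is an error
  evBad <- data.frame(channel = "", onset = 0, trigger = 0.01, offset = 0.2,
                      peakAmp = 1)
  expect_error(burstTriggeredAverage(evBad, sig, fs), "no burst")
})

test_that("averaging N segments shrinks background noise like 1/sqrt(N)", {
  fs <- 1024
  tpl <- generateBurst(0.3, 25, 40, fs)
  set.seed(64)
  rmsAt <- function(N) {
    segs <- vapply(seq_len(N), function(i) {
      sig <- stats::rnorm(1024, sd = 3)
      sig[300:(300 + length(tpl) - 1)] <- sig[300:(300 + length(tpl) - 1)] +
        tpl
      sig
    }, numeric(1024))
    avg <- rowMeans(segs)
    ## background RMS measured away from the burst
    sqrt(mean(avg[c(1:250, 700:1024)]^2))
  }
  ratio <- rmsAt(100) / rmsAt(10)
  expect_lt(abs(ratio - sqrt(10 / 100) / sqrt(1)) / sqrt(0.1), 0.45)
})

test_that("alert bursts average larger and longer than REM bursts", {
  ps <- statePresets()
  getAvg <- function(state, seed) {
    ses <- generateRecording(
      syntheticConfig(stats::setNames(100, state), states = ps,
                      seed = seed))
    filt <- firBandpass(signalMatrix(ses$recording)[1, ], fs = 1024)
    env <- signalEnvelope(filt, 1024)
    bs <- detectBursts(env, filt, 1024)
    burstTriggeredAverage(bs, filt, 1024, seed = seed)
  }
  aw <- getAvg("AW", 65)
  rem <- getAvg("REM", 65)
  expect_gt(max(abs(aw$waveform)), max(abs(rem$waveform)))
  ## duration proxy: time the average envelope stays above half its peak
  dur <- function(b) mean(abs(b$waveform) > 0.25 * max(abs(b$waveform)))
  expect_gt(dur(aw), dur(rem))
})

test_that("burst co-occurrence is high for coupled channels only", {
  ses <- generateRecording(cleanCouplingConfig(1, 60, seed = 66))
  x <- signalMatrix(ses$recording)
  detect <- function(v) {
    filt <- firBandpass(v, fs = 1024)
    detectBursts(signalEnvelope(filt, 1024), filt, 1024)
  }
  b1 <- detect(x[1, ]); b2 <- detect(x[2, ])
  expect_gt(burstCooccurrence(b1, b2), 0.8)
  ses0 <- generateRecording(cleanCouplingConfig(0, 60, seed = 66))
  x0 <- signalMatrix(ses0$recording)
  b10 <- detect(x0[1, ]); b20 <- detect(x0[2, ])
  expect_lt(burstCooccurrence(b10, b20), 0.5)
})
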