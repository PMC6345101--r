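test_that("twelve 100-s windows give 1,200 s of analyzed signal", {
  ann <- singleStateAnnotation("REM", 1500)
  win <- selectWindows(ann, "REM", seed = 1)
  expect_equal(nrow(win), 12)
  expect_equal(sum(win$duration), 1200)
  ## non-overlap
  win <- win[order(win$start), ]
  expect_true(all(diff(win$start) >= 100))
})

test_that("a state absent from the annotation is a capacity error", {
  ann <- singleStateAnnotation("AW", 300)
  expect_error(selectWindows(ann, "REM", seed = 1), "capacity")
  ## insufficient contiguous time also errors, naming the state
  expect_error(selectWindows(ann, "AW", n = 12, seed = 1), "AW")
})

test_that("stimulus neighborhoods are excluded from window selection", {
  ann <- singleStateAnnotation(
    "QW", 3000,
    events = data.frame(time = 1000, kind = "sound_on", payload = ""))
  win <- selectWindows(ann, "QW", n = 5, seed = 2)
  ## no window may intersect [700, 1300]
  expect_true(all(win$start + win$duration <= 700 | win$start >= 1300))
  ## with stimulusClear = FALSE the zone is usable again
  win2 <- selectWindows(ann, "QW", n = 12, stimulusClear = FALSE, seed = 2)
  expect_equal(nrow(win2), 12)
})

test_that("artifact intervals are excluded from window selection", {
  ann <- singleStateAnnotation(
    "NREM", 2000,
    events = data.frame(time = c(500, 600),
                        kind = c("artifact_start", "artifact_end"),
                        payload = ""))
  win <- selectWindows(ann, "NREM", n = 8, seed = 3)
  expect_true(all(win$start + win$duration <= 500 | win$start >= 600))
})

test_that("window selection is deterministic given a seed and respects state runs", {
  set.seed(99)
  for (rep in 1:8) {
    ## random annotation: alternating runs of random states/lengths
    states <- sample(c("AW", "QW", "NREM", "REM"), 6, replace = TRUE)
    lens <- sample(15:40, 6) * 10
    ep <- NULL; t0 <- 0
    for (i in seq_along(states)) {
      ep <- rbind(ep, data.frame(start = seq(t0, t0 + lens[i] - 10, 10),
                                 duration = 10, state = states[i]))
      t0 <- t0 + lens[i]
    }
    ann <- stateAnnotation(ep)
    st <- states[1]
    n <- 2
    w1 <- selectWindows(ann, st, n = n, seed = 7)
    w2 <- selectWindows(ann, st, n = n, seed = 7)
    expect_identical(w1, w2)
    expect_true(all(diff(sort(w1$start)) >= 100 | nrow(w1) < 2))
    ## every window lies inside a contiguous run of its state
    for (j in seq_len(nrow(w1))) {
      cov <- ep$state[ep$start >= w1$start[j] &
                        ep$start < w1$start[j] + w1$duration[j]]
      expect_true(all(cov == st))
      expect_equal(length(cov), 10)
    }
  }
})

test_that("the gamma band-pass meets its pass/stop specification", {
  fs <- 1024
  t <- (0:(20 * fs - 1)) / fs
  mid <- (5 * fs):(15 * fs)
  gain <- function(f) {
    y <- firBandpass(sin(2 * pi * f * t), fs = fs)
    max(abs(y[mid]))
  }
  ## within +-1 dB across the passband interior
  for (f in c(32, 37, 43))
    expect_true(gain(f) >= 0.89 && gain(f) <= 1.12)
  ## >= 40 dB down at lo-10 and hi+10
  expect_lt(gain(20), 0.01)
  expect_lt(gain(55), 0.01)
  ## zero in, zero out; length preserved
  z <- firBandpass(numeric(4096), fs = fs)
  expect_equal(length(z), 4096)
  expect_true(all(z == 0))
  ## band outside Nyquist rejected
  expect_error(firBandpass(rnorm(4096), 200, 600, fs = fs), "Nyquist")
  expect_error(firBandpass(rnorm(4096), 45, 30, fs = fs), "lo")
})

test_that("filtered white noise carries under 1% energy outside 25-50 Hz", {
  fs <- 1024
  set.seed(11)
  y <- firBandpass(rnorm(60 * fs), fs = fs)
  p <- welchPsd(y, fs)
  outside <- p@freqs < 25 | p@freqs > 50
  expect_lt(sum(p@power[outside]) / sum(p@power), 0.01)
})

test_that("envelopes recover amplitude and burst support", {
  fs <- 1024
  t <- (0:(10 * fs - 1)) / fs
  x <- 3 * sin(2 * pi * 40 * t)
  env <- signalEnvelope(x, fs, "analytic")
  core <- env[(fs):(9 * fs)]
  expect_true(all(abs(core - 3) < 0.03))
  expect_true(all(signalEnvelope(numeric(1000), fs) == 0))
  ## rectified+smoothed envelope of a constant sinusoid ~ 2A/pi
  envR <- signalEnvelope(x, fs, "rectify_smooth")
  expect_lt(abs(mean(envR[(fs):(9 * fs)]) - 2 * 3 / pi), 0.05)
  ## a 300-ms 25-uV burst: envelope peak within 10% of 25, support local
  sig <- numeric(10 * fs)
  on <- 5 * fs
  tpl <- generateBurst(0.3, 25, 40, fs)
  sig[on:(on + length(tpl) - 1)] <- tpl
  envB <- signalEnvelope(sig, fs, "analytic")
  expect_lt(abs(max(envB) - 25) / 25, 0.10)
  sup <- which(envB > 0.1 * max(envB))
  expect_gte(min(sup), on - 0.05 * fs)
  expect_lte(max(sup), on + length(tpl) + 0.05 * fs)
  expect_error(signalEnvelope(x, fs, "nope"))
})
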