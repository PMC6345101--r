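## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths: direct DFT sums instead of fft(), explicit
## sums of squares instead of the ANOVA machinery.

## Direct DFT of one block: X[k+1] = sum_n x[n+1] exp(-2i pi k n / N).
directDft <- function(x) {
  N <- length(x)
  k <- 0:(N - 1)
  vapply(k, function(kk)
    sum(x * exp(-2i * pi * kk * (0:(N - 1)) / N)), complex(1))
}

## Brute-force Welch-block MSC on consecutive windowed blocks.
bruteMsc <- function(x, y, nfft, step, window) {
  starts <- seq(1, length(x) - nfft + 1, by = step)
  nf <- nfft %/% 2 + 1
  Sxx <- Syy <- numeric(nf)
  Sxy <- complex(nf)
  for (s in starts) {
    X <- directDft(x[s:(s + nfft - 1)] * window)[seq_len(nf)]
    Y <- directDft(y[s:(s + nfft - 1)] * window)[seq_len(nf)]
    Sxx <- Sxx + Mod(X)^2
    Syy <- Syy + Mod(Y)^2
    Sxy <- Sxy + X * Conj(Y)
  }
  nb <- length(starts)
  Mod(Sxy / nb)^2 / ((Sxx / nb) * (Syy / nb))
}

## Brute-force one-sided Welch PSD (density scaling) on the same blocks.
brutePsd <- function(x, fs, nfft, step, window) {
  starts <- seq(1, length(x) - nfft + 1, by = step)
  nf <- nfft %/% 2 + 1
  acc <- numeric(nf)
  for (s in starts)
    acc <- acc + Mod(directDft(x[s:(s + nfft - 1)] * window)[seq_len(nf)])^2
  p <- acc / length(starts) / (fs * sum(window^2))
  scale <- rep(2, nf); scale[1] <- 1
  if (nfft %% 2 == 0) scale[nf] <- 1
  p * scale
}

## Brute-force one-way ANOVA F from explicit sums of squares.
bruteOnewayF <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  k <- length(groups); N <- length(all)
  (ssb / (k - 1)) / (ssw / (N - k))
}

## Brute-force one-way repeated-measures F (condition effect, subject
## blocked) from explicit sums of squares.
bruteRmF <- function(mat) {
  s <- nrow(mat); cc <- ncol(mat)
  gm <- mean(mat)
  ssCond <- s * sum((colMeans(mat) - gm)^2)
  ssSubj <- cc * sum((rowMeans(mat) - gm)^2)
  ssTot <- sum((mat - gm)^2)
  ssErr <- ssTot - ssCond - ssSubj
  (ssCond / (cc - 1)) / (ssErr / ((cc - 1) * (s - 1)))
}

## A no-background, no-scatter, no-jitter two-channel burst config: the
## regime where expectedBandMsc is exact.
cleanCouplingConfig <- function(coupling, durS, seed, rate = 2, amp = 25) {
  st <- syntheticState("AW", burstRate = rate, burstAmp = amp,
                       couplingFraction = coupling,
                       backgroundSpec = data.frame(lo = 1, hi = 20,
                                                   power = 0),
                       burstAmpSd = 0, jitter = 0)
  syntheticConfig(data.frame(state = "AW", duration = durS),
                  states = list(AW = st), seed = seed)
}

## Annotation covering `durS` seconds of one state.
singleStateAnnotation <- function(state, durS, events = NULL) {
  stateAnnotation(data.frame(start = seq(0, durS - 10, by = 10),
                             duration = 10, state = state), events)
}
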