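## Synthetic multichannel EEG with known state-dependent gamma coupling.
##
## Generative model per state:
##   signal = band-limited Gaussian background + slow waves + gamma bursts.
## Bursts are Hann-enveloped 35-40 Hz sinusoids of 200-500 ms and ~20-25 uV
## arriving as Poisson streams. A fraction `couplingFraction` of the burst
## stream comes from a source shared across channels (copied with small
## per-channel envelope jitter and amplitude scatter); the remainder is
## independent per channel. The shared/independent in-band power split
## gives a closed-form expected band coherence (expectedBandMsc), so every
## downstream estimator can be validated against ground truth.

#' Default background band specification
#'
#' Piecewise band-limited Gaussian background components: (lo, hi, power)
#' with total power in microvolts^2 spread uniformly over each band. The
#' declining power with frequency emulates the 1/f-like EEG background.
#'
#' @return data.frame with columns `lo`, `hi`, `power`.
#' @export
defaultBackgroundSpec <- function() {
  data.frame(lo    = c(0.5,  4, 12, 30, 45, 60),
             hi    = c(4,   12, 30, 45, 60, 100),
             power = c(120, 60, 40, 10,  5,   5))
}

#' State parameter presets
#'
#' Generative presets for the seven study conditions. Cross-channel burst
#' coupling is high in alert wakefulness, intermediate in quiet wakefulness
#' and NREM sleep, and near-absent in REM sleep and after 15 mg/kg
#' ketamine; 30-45 Hz power is comparable in QW, REM and ketamine and
#' highest in AW; NREM adds slow waves; ketamine adds delta and beta peaks
#' plus elevated 45-60 Hz content, with coupling decreasing with dose.
#'
#' @return named list of [SyntheticState-class] objects
#'   (AW, QW, NREM, REM, K5, K10, K15).
#' @export
statePresets <- function() {
  bg <- defaultBackgroundSpec()
  list(
    AW   = syntheticState("AW",   burstRate = 2.0, burstAmp = 25,
                          couplingFraction = 0.80, backgroundSpec = bg),
    QW   = syntheticState("QW",   burstRate = 1.2, burstAmp = 20,
                          couplingFraction = 0.50, backgroundSpec = bg),
    NREM = syntheticState("NREM", burstRate = 0.8, burstAmp = 18,
                          couplingFraction = 0.30, backgroundSpec = bg,
                          slowWaveAmp = 150),
    REM  = syntheticState("REM",  burstRate = 1.2, burstAmp = 20,
                          couplingFraction = 0.05, backgroundSpec = bg),
    K5   = syntheticState("K5",   burstRate = 1.2, burstAmp = 20,
                          couplingFraction = 0.40, backgroundSpec = bg,
                          slowWaveAmp = 80, betaPeak = c(22.5, 100),
                          highGammaGain = 2),
    K10  = syntheticState("K10",  burstRate = 1.2, burstAmp = 20,
                          couplingFraction = 0.20, backgroundSpec = bg,
                          slowWaveAmp = 100, betaPeak = c(22.5, 120),
                          highGammaGain = 3),
    K15  = syntheticState("K15",  burstRate = 1.2, burstAmp = 20,
                          couplingFraction = 0.05, backgroundSpec = bg,
                          slowWaveAmp = 120, betaPeak = c(22.5, 150),
                          highGammaGain = 4))
}

#' Generate a single gamma burst waveform
#'
#' An amplitude-modulated sinusoid: Hann envelope (zero at both endpoints)
#' times a carrier in the low-gamma band, rescaled so the peak absolute
#' amplitude equals `amp` exactly.
#'
#' @param dur burst duration, seconds.
#' @param amp peak absolute amplitude, microvolts.
#' @param carrierFreq carrier frequency, Hz (30-45).
#' @param fs sampling rate, Hz.
#' @param phase carrier phase offset, radians.
#' @return numeric vector of `round(dur * fs)` samples.
#' @examples
#' w <- generateBurst(0.3, 25, 40, 1024)
#' max(abs(w))   # 25
#' @export
generateBurst <- function(dur, amp, carrierFreq, fs, phase = 0) {
  if (!is.finite(dur) || dur <= 0) stop("burst duration must be positive")
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive")
  if (carrierFreq < 30 || carrierFreq > 45)
    stop("carrierFreq must lie in [30, 45] Hz")
  n <- round(dur * fs)
  if (n < 3) stop("burst too short for the sampling rate")
  env <- hannWindow(n, periodic = FALSE)
  w <- env * sin(2 * pi * carrierFreq * (0:(n - 1)) / fs + phase)
  m <- max(abs(w))
  if (m > 0 && amp > 0) w * (amp / m) else w * 0
}

## Effective background spec for a state: base bands + slow waves + beta
## peak + high-gamma gain, as (lo, hi, power) rows. Used both by the
## generator and by the closed-form oracle.
effectiveBackgroundSpec <- function(state) {
  bg <- state@backgroundSpec
  if (state@slowWaveAmp > 0)
    bg <- rbind(bg, data.frame(lo = 0.5, hi = 4,
                               power = state@slowWaveAmp^2 / 2))
  if (length(state@betaPeak) == 2)
    bg <- rbind(bg, data.frame(lo = state@betaPeak[1] - 2,
                               hi = state@betaPeak[1] + 2,
                               power = state@betaPeak[2]))
  if (state@highGammaGain != 1 && nrow(bg)) {
    hg <- bg$lo >= 45 & bg$hi <= 60
    bg$power[hg] <- bg$power[hg] * state@highGammaGain
  }
  bg
}

## Background power falling inside [lo, hi] Hz for a state.
backgroundBandPower <- function(state, band = c(30, 45)) {
  bg <- effectiveBackgroundSpec(state)
  if (!nrow(bg)) return(0)
  frac <- mapply(function(l, h) overlapLength(l, h, band[1], band[2]) / (h - l),
                 bg$lo, bg$hi)
  sum(bg$power * frac)
}

## Mean power (uV^2) contributed by the burst stream of one channel:
## rate * E[dur] * mean(hann^2) * 1/2 * amp^2 * (1 + sd^2).
## mean(hann^2) = 3/8 for the Hann envelope.
burstStreamPower <- function(state, scatter = TRUE) {
  meanDur <- mean(state@burstDurRange)
  p0 <- state@burstRate * meanDur * (3 / 8) * 0.5 * state@burstAmp^2
  if (scatter) p0 * (1 + state@burstAmpSd^2) else p0
}

#' Closed-form expected band coherence for a state
#'
#' For the two-channel mixing model with shared in-band power S and
#' independent in-band power N per channel, the magnitude-squared coherence
#' is S^2 / (S + N)^2. Here S = couplingFraction x burst-stream power
#' (cross-channel amplitude scatter averages out of the cross-spectrum) and
#' S + N = total burst power (including scatter) + in-band background. The
#' value is exact when the envelope jitter is zero and an upper-bound
#' approximation otherwise.
#'
#' @param state a [SyntheticState-class].
#' @param band analysis band, Hz.
#' @return expected magnitude-squared coherence in [0, 1].
#' @examples
#' s <- syntheticState("AW", 2, 25, couplingFraction = 1,
#'                     backgroundSpec = data.frame(lo = 1, hi = 20, power = 0))
#' expectedBandMsc(s)   # 1 up to amplitude-scatter loss
#' @export
expectedBandMsc <- function(state, band = c(30, 45)) {
  S <- state@couplingFraction * burstStreamPower(state, scatter = FALSE)
  tot <- burstStreamPower(state, scatter = TRUE) +
    backgroundBandPower(state, band)
  if (tot <= 0) return(0)
  min(1, (S / tot)^2)
}

## Band-limited Gaussian background for one channel segment, synthesized
## directly in the frequency domain (Hermitian-symmetric spectrum with the
## white-noise DFT statistics, scaled per band) so each (lo, hi, power)
## band carries exactly `power` variance in expectation.
shapedBackground <- function(n, fs, bg) {
  if (!nrow(bg) || all(bg$power == 0)) return(numeric(n))
  nHalf <- floor(n / 2)
  fpos <- (1:nHalf) * fs / n            # positive-frequency bins
  Hpos <- numeric(nHalf)
  for (i in seq_len(nrow(bg))) {
    sel <- fpos >= bg$lo[i] & fpos < bg$hi[i]
    m <- 2 * sum(sel)                    # two-sided bin count
    if (m > 0 && bg$power[i] > 0)
      Hpos[sel] <- sqrt(Hpos[sel]^2 + bg$power[i] * n / m)
  }
  X <- complex(n)
  act <- which(Hpos > 0)                 # draw only where the gain is nonzero
  nyq <- if (n %% 2 == 0) nHalf else 0L
  inner <- act[act != nyq]
  if (length(inner)) {
    z <- complex(real = stats::rnorm(length(inner), sd = sqrt(n / 2)),
                 imaginary = stats::rnorm(length(inner), sd = sqrt(n / 2)))
    X[inner + 1] <- Hpos[inner] * z
    X[n - inner + 1] <- Conj(X[inner + 1])
  }
  if (nyq && Hpos[nyq] > 0)
    X[nyq + 1] <- Hpos[nyq] * stats::rnorm(1, sd = sqrt(n))
  Re(stats::fft(X, inverse = TRUE)) / n
}

## Samples of one burst as (idx, values) within a segment of n samples.
## envOnset: envelope start (s, segment-relative); carrierOnset: time the
## carrier phase is referenced to (shared across channels for coupled
## bursts unless jitterCarrier).
burstSamples <- function(n, fs, envOnset, dur, amp, f, phase, carrierOnset) {
  ns <- round(dur * fs)
  i0 <- round(envOnset * fs) + 1
  if (ns < 3 || i0 > n) return(NULL)
  idx <- i0:min(n, i0 + ns - 1)
  env <- hannWindow(ns, periodic = FALSE)[seq_along(idx)]
  tt <- (idx - 1) / fs - carrierOnset
  list(idx = idx, values = amp * env * sin(2 * pi * f * tt + phase))
}

#' Generate a synthetic multichannel EEG session
#'
#' Simulates the configured state sequence: per state segment and channel,
#' shaped background noise plus slow waves, a Poisson stream of shared
#' gamma bursts (rate x couplingFraction, copied to every channel with
#' independent envelope jitter and amplitude scatter) and independent
#' bursts (remaining rate, per channel). Identical configuration (including
#' seed) reproduces the session bit for bit.
#'
#' @param config a [SyntheticConfig-class].
#' @return list with elements `recording` ([EEGRecording-class]),
#'   `annotation` ([StateAnnotation-class], 10-s epochs) and `groundTruth`
#'   ([GroundTruth-class]).
#' @examples
#' cfg <- syntheticConfig(c(AW = 100, REM = 100), seed = 7)
#' ses <- generateRecording(cfg)
#' ses$recording
#' @export
generateRecording <- function(config) {
  validObject(config)
  fs <- config@fs
  nCh <- length(config@channelSites)
  seq_ <- config@stateSequence
  total <- sum(seq_$duration)
  nTot <- round(total * fs)
  sig <- matrix(0, nrow = nCh, ncol = nTot)
  bCh <- list(); bOn <- list(); bDur <- list(); bSh <- list()
  note <- function(ch, on, du, sh) {
    k <- length(bCh) + 1L
    bCh[[k]] <<- ch; bOn[[k]] <<- on; bDur[[k]] <<- du; bSh[[k]] <<- sh
  }

  withSeed(config@seed, {
    segStart <- 0
    for (si in seq_len(nrow(seq_))) {
      stLabel <- seq_$state[si]
      stPar <- config@states[[stLabel]]
      if (is.null(stPar)) stop("unknown state in sequence: ", stLabel)
      dur <- seq_$duration[si]
      n <- round(dur * fs)
      off <- round(segStart * fs)
      bg <- effectiveBackgroundSpec(stPar)

      for (ch in seq_len(nCh))
        sig[ch, off + seq_len(n)] <- shapedBackground(n, fs, bg)

      maxDur <- stPar@burstDurRange[2]
      ## shared burst stream
      nShared <- stats::rpois(1, stPar@burstRate * stPar@couplingFraction * dur)
      if (nShared > 0) {
        ons <- sort(stats::runif(nShared, 0, max(0, dur - maxDur)))
        for (b in seq_len(nShared)) {
          bd <- stats::runif(1, stPar@burstDurRange[1], stPar@burstDurRange[2])
          f <- stats::runif(1, stPar@carrierRange[1], stPar@carrierRange[2])
          ph <- stats::runif(1, 0, 2 * pi)
          for (ch in seq_len(nCh)) {
            a <- stPar@burstAmp *
              max(0, 1 + stats::rnorm(1, 0, stPar@burstAmpSd))
            jit <- if (stPar@jitter > 0)
              stats::runif(1, -stPar@jitter, stPar@jitter) else 0
            carrierOnset <- if (stPar@jitterCarrier)
              ons[b] + jit else ons[b]
            bs <- burstSamples(n, fs, max(0, ons[b] + jit), bd, a, f, ph,
                               carrierOnset)
            if (!is.null(bs))
              sig[ch, off + bs$idx] <- sig[ch, off + bs$idx] + bs$values
            note(config@channelSites[ch], segStart + ons[b], bd, TRUE)
          }
        }
      }
      ## independent burst streams
      indRate <- stPar@burstRate * (1 - stPar@couplingFraction)
      for (ch in seq_len(nCh)) {
        nInd <- stats::rpois(1, indRate * dur)
        if (nInd > 0) {
          ons <- sort(stats::runif(nInd, 0, max(0, dur - maxDur)))
          for (b in seq_len(nInd)) {
            bd <- stats::runif(1, stPar@burstDurRange[1],
                               stPar@burstDurRange[2])
            f <- stats::runif(1, stPar@carrierRange[1],
                              stPar@carrierRange[2])
            ph <- stats::runif(1, 0, 2 * pi)
            a <- stPar@burstAmp *
              max(0, 1 + stats::rnorm(1, 0, stPar@burstAmpSd))
            bs <- burstSamples(n, fs, ons[b], bd, a, f, ph, ons[b])
            if (!is.null(bs))
              sig[ch, off + bs$idx] <- sig[ch, off + bs$idx] + bs$values
            note(config@channelSites[ch], segStart + ons[b], bd, FALSE)
          }
        }
      }
      segStart <- segStart + dur
    }
  })

  rec <- eegRecording(sig, fs, config@channelSites)

  ## 10-s epochs consistent with the state sequence
  epochList <- list()
  segStart <- 0
  for (si in seq_len(nrow(seq_))) {
    d <- seq_$duration[si]
    nEp <- floor(d / 10)
    if (nEp > 0)
      epochList[[si]] <- data.frame(
        start = segStart + 10 * (seq_len(nEp) - 1), duration = 10,
        state = seq_$state[si], stringsAsFactors = FALSE)
    segStart <- segStart + d
  }
  ann <- stateAnnotation(do.call(rbind, epochList))

  bursts <- data.frame(channel = unlist(bCh), onset = unlist(bOn),
                       duration = unlist(bDur), shared = unlist(bSh),
                       stringsAsFactors = FALSE)
  expMsc <- vapply(unique(seq_$state),
                   function(s) expectedBandMsc(config@states[[s]]),
                   numeric(1))
  gt <- new("GroundTruth", bursts = bursts, expectedBandMsc = expMsc)

  list(recording = rec, annotation = ann, groundTruth = gt)
}
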