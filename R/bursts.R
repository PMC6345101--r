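## Gamma burst detection and burst-triggered averaging.

#' Detect gamma bursts from a band-limited signal and its envelope
#'
#' A burst is a maximal run of samples where the envelope exceeds
#' mean + threshSd x SD (statistics over the analyzed signal) lasting at
#' least `minDur` seconds. The trigger is placed at the extremum of the
#' absolute filtered signal within the run -- the peak of the wave with
#' greatest amplitude.
#'
#' @param envelope non-negative envelope, aligned with `filtered`.
#' @param filtered band-pass filtered signal (30-45 Hz).
#' @param fs sampling rate, Hz.
#' @param threshSd threshold in envelope standard deviations above the
#'   mean.
#' @param minDur minimum burst duration, seconds.
#' @return data.frame(channel, onset, trigger, offset, peakAmp), times in
#'   seconds; zero rows when nothing crosses threshold.
#' @export
detectBursts <- function(envelope, filtered, fs, threshSd = 2.0,
                         minDur = 0.1) {
  if (!length(envelope) || length(envelope) != length(filtered))
    stop("envelope and filtered must be aligned, non-empty vectors")
  thr <- mean(envelope) + threshSd * stats::sd(envelope)
  over <- envelope > thr
  empty <- data.frame(channel = character(0), onset = numeric(0),
                      trigger = numeric(0), offset = numeric(0),
                      peakAmp = numeric(0))
  if (!any(over) || !is.finite(thr)) return(empty)
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (r$lengths >= round(minDur * fs))
  if (!any(keep)) return(empty)
  starts <- starts[keep]; ends <- ends[keep]
  rows <- lapply(seq_along(starts), function(i) {
    idx <- starts[i]:ends[i]
    pk <- idx[which.max(abs(filtered[idx]))]
    data.frame(channel = "", onset = (starts[i] - 1) / fs,
               trigger = (pk - 1) / fs, offset = ends[i] / fs,
               peakAmp = abs(filtered[pk]))
  })
  do.call(rbind, rows)
}

#' Burst-triggered average waveform
#'
#' Selects up to `n` detected bursts uniformly at random, extracts
#' +-`halfWindow` seconds of `signal` around each trigger, aligns polarity
#' (the trigger extremum is made positive) and returns the element-wise
#' mean. Averaging reveals the stereotyped burst waveform; incoherent
#' background shrinks as 1/sqrt(n).
#'
#' @param bursts data.frame from [detectBursts()].
#' @param signal the trace to average (e.g. the 30-45 Hz filtered signal,
#'   or a 3-Hz high-passed raw trace).
#' @param fs sampling rate, Hz.
#' @param n number of bursts to draw.
#' @param halfWindow half-width of the averaging window, seconds.
#' @param alignSignal optional trace used to decide trigger polarity;
#'   defaults to `signal`.
#' @param seed optional integer seed for the random draw.
#' @return list with `waveform` (length 2*halfWindow*fs + 1), `times`
#'   (seconds relative to trigger) and `nBursts`.
#' @export
burstTriggeredAverage <- function(bursts, signal, fs, n = 100,
                                  halfWindow = 0.25, alignSignal = NULL,
                                  seed = NULL) {
  if (is.null(alignSignal)) alignSignal <- signal
  hw <- round(halfWindow * fs)
  trig <- round(bursts$trigger * fs) + 1
  ok <- trig - hw >= 1 & trig + hw <= length(signal)
  trig <- trig[ok]
  if (!length(trig)) stop("no burst with a full window inside the recording")
  pick <- if (length(trig) > n)
    withSeed(seed, sample(length(trig), n)) else seq_along(trig)
  segs <- vapply(trig[pick], function(tc) {
    seg <- signal[(tc - hw):(tc + hw)]
    if (alignSignal[tc] < 0) -seg else seg
  }, numeric(2 * hw + 1))
  list(waveform = rowMeans(segs), times = (-hw:hw) / fs,
       nBursts = length(pick))
}

#' Cross-channel burst co-occurrence rate (diagnostic)
#'
#' Fraction of bursts on channel A whose trigger lies within `tol` seconds
#' of some trigger on channel B. A convenience diagnostic only; coupling
#' is quantified by coherence.
#'
#' @param burstsA,burstsB data.frames from [detectBursts()].
#' @param tol matching tolerance, seconds.
#' @return scalar rate in [0, 1] (NA if `burstsA` is empty).
#' @export
burstCooccurrence <- function(burstsA, burstsB, tol = 0.05) {
  if (!nrow(burstsA)) return(NA_real_)
  if (!nrow(burstsB)) return(0)
  mean(vapply(burstsA$trigger, function(t)
    any(abs(burstsB$trigger - t) <= tol), logical(1)))
}
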