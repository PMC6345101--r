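## Window selection and band filtering.

#' Select artifact-free analysis windows for one state
#'
#' Places `n` non-overlapping windows of `dur` seconds inside contiguous
#' runs of the requested state, excluding annotated artifact intervals and
#' (when `stimulusClear`) anything within `stimulusExclusion` seconds of a
#' sound/visual event. Candidate slots tile each eligible interval from its
#' start; `n` of them are drawn uniformly at random, so repeated calls with
#' one seed are reproducible. The default 12 x 100 s per state gives the
#' canonical 1,200 s of analyzed signal.
#'
#' @param ann a [StateAnnotation-class].
#' @param state state label to select.
#' @param n number of windows.
#' @param dur window duration, seconds.
#' @param stimulusExclusion half-width of the exclusion zone around
#'   sound/visual events, seconds.
#' @param stimulusClear exclude stimulus neighborhoods? Set `FALSE` when
#'   windows are deliberately taken during stimulation (e.g. alert
#'   wakefulness).
#' @param seed optional integer seed for the random draw.
#' @return data.frame(start, duration, state), sorted by start.
#' @export
selectWindows <- function(ann, state, n = 12, dur = 100,
                          stimulusExclusion = 300, stimulusClear = TRUE,
                          seed = NULL) {
  ep <- epochs(ann)
  ev <- events(ann)
  sel <- ep$state == state
  if (!any(sel))
    stop("capacity error: state ", state, " absent from annotation (0 s available)")
  ep <- ep[sel, , drop = FALSE]
  ## contiguous same-state runs
  brk <- c(TRUE, abs(ep$start[-1] - (ep$start[-nrow(ep)] +
                                       ep$duration[-nrow(ep)])) > 1e-9)
  runId <- cumsum(brk)
  runs <- do.call(rbind, lapply(split(seq_len(nrow(ep)), runId), function(i) {
    c(ep$start[i[1]], ep$start[i[length(i)]] + ep$duration[i[length(i)]])
  }))

  excl <- matrix(numeric(0), ncol = 2)
  if (nrow(ev)) {
    st <- ev$time[ev$kind == "artifact_start"]
    en <- ev$time[ev$kind == "artifact_end"]
    if (length(st) != length(en))
      stop("unpaired artifact_start/artifact_end events")
    if (length(st)) excl <- rbind(excl, cbind(st, en))
    if (stimulusClear) {
      stim <- ev$time[ev$kind %in% c("sound_on", "sound_off",
                                     "visual_on", "visual_off")]
      if (length(stim))
        excl <- rbind(excl, cbind(stim - stimulusExclusion,
                                  stim + stimulusExclusion))
    }
  }
  elig <- intervalDiff(runs, excl)
  slots <- matrix(numeric(0), ncol = 2)
  if (nrow(elig)) {
    for (i in seq_len(nrow(elig))) {
      k <- floor((elig[i, 2] - elig[i, 1]) / dur + 1e-9)
      if (k >= 1) {
        s0 <- elig[i, 1] + dur * (seq_len(k) - 1)
        slots <- rbind(slots, cbind(s0, s0 + dur))
      }
    }
  }
  avail <- if (nrow(elig)) sum(elig[, 2] - elig[, 1]) else 0
  if (nrow(slots) < n)
    stop("capacity error: state ", state, " has only ", nrow(slots),
         " eligible ", dur, "-s windows (", round(avail),
         " s eligible time); ", n, " requested")
  pick <- withSeed(seed, sort(sample(nrow(slots), n)))
  data.frame(start = slots[pick, 1], duration = dur, state = state,
             stringsAsFactors = FALSE)
}

## Design the zero-phase band-pass used throughout: Hamming windowed-sinc
## FIR applied forward-backward (signal::filtfilt), so the effective
## magnitude response is |H|^2. Cutoffs are widened by `margin` Hz so the
## -12 dB (squared) points sit outside the nominal band and the passband
## stays within +-1 dB.
designBandpass <- function(lo, hi, fs, transition = 4, margin = 1) {
  ord <- ceiling(3.3 * fs / transition)
  if (ord %% 2 == 1) ord <- ord + 1
  signal::fir1(ord, c(lo - margin, hi + margin) / (fs / 2), type = "pass",
               window = signal::hamming(ord + 1))
}

#' Zero-phase FIR band-pass filter
#'
#' Hamming windowed-sinc FIR applied forward and backward
#' ([signal::filtfilt()]), giving zero phase distortion between channels.
#' The default 30-45 Hz band isolates low-gamma activity. Output length
#' equals input length.
#'
#' @param rec an [EEGRecording-class] or a numeric vector.
#' @param lo,hi band edges, Hz (must satisfy lo < hi < fs/2).
#' @param fs sampling rate, required when `rec` is a plain vector.
#' @return filtered object of the same type as `rec`.
#' @export
firBandpass <- function(rec, lo = 30, hi = 45, fs = NULL) {
  if (is(rec, "EEGRecording")) {
    fs <- samplingRate(rec)
    x <- signalMatrix(rec)
  } else {
    if (is.null(fs)) stop("fs required for plain-vector input")
    x <- matrix(rec, nrow = 1)
  }
  if (!(lo < hi)) stop("invalid band: lo must be < hi")
  if (hi >= fs / 2) stop("invalid band: hi must be below Nyquist (fs/2)")
  b <- designBandpass(lo, hi, fs)
  y <- t(apply(x, 1, function(row) signal::filtfilt(b, row)))
  if (is(rec, "EEGRecording")) {
    out <- rec
    out@samples <- y
    out
  } else drop(y)
}

#' Amplitude envelope of a band-limited signal
#'
#' Either full-wave rectification followed by a 50-ms moving average
#' (`"rectify_smooth"`) or the magnitude of the analytic signal
#' (`"analytic"`). Output is non-negative and the same length as the
#' input.
#'
#' @param x numeric vector, already band-limited.
#' @param fs sampling rate, Hz.
#' @param method `"analytic"` (default) or `"rectify_smooth"`.
#' @param smoothDur moving-average length for `"rectify_smooth"`, seconds.
#' @return numeric vector of envelope values.
#' @export
signalEnvelope <- function(x, fs, method = c("analytic", "rectify_smooth"),
                           smoothDur = 0.05) {
  method <- match.arg(method)
  if (method == "analytic") return(Mod(analyticSignal(x)))
  k <- max(1, round(smoothDur * fs))
  as.numeric(stats::filter(abs(x), rep(1 / k, k), sides = 2) |>
               (\(v) { v[is.na(v)] <- 0; v })())
}

#' Flag high-amplitude samples as candidate artifacts
#'
#' Convenience pre-flagger (off by default in the pipeline): marks
#' intervals where |x| exceeds `threshold` microvolts, for conversion into
#' artifact_start/artifact_end events.
#'
#' @param x numeric vector, microvolts.
#' @param fs sampling rate, Hz.
#' @param threshold amplitude threshold, microvolts.
#' @param pad seconds added on both sides of each flagged run.
#' @return data.frame(start, end) in seconds (possibly empty).
#' @export
flagArtifacts <- function(x, fs, threshold = 500, pad = 0.5) {
  over <- abs(x) > threshold
  if (!any(over)) return(data.frame(start = numeric(0), end = numeric(0)))
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(start = pmax(0, (starts[keep] - 1) / fs - pad),
             end = ends[keep] / fs + pad)
}
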