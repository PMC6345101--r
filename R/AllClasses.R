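#' @import methods
NULL

## Recognised cortical site codes (frontal/parietal/occipital montage) and
## hemisphere codes used in channel labels such as "Pf-r".
.knownSites <- c("Pf", "M1", "S1", "Pp", "V1", "other")
.knownHemis <- c("r", "l", "unknown")
.stateLevels <- c("AW", "QW", "NREM", "REM", "K5", "K10", "K15")

#' EEGRecording: a uniform-rate multichannel EEG signal
#'
#' Container for a monopolar multichannel EEG recording: a channels x time
#' matrix of samples in microvolts, the sampling rate, and per-channel
#' metadata (name, cortical site, hemisphere, unit).
#'
#' @slot samples numeric matrix, channels x time, in microvolts.
#' @slot fs sampling rate in Hz.
#' @slot channels data.frame with columns `name`, `site`, `hemisphere`,
#'   `unit`; one row per channel.
#' @slot startTime recording start offset in seconds.
#' @export
setClass("EEGRecording",
  representation(samples = "matrix", fs = "numeric",
                 channels = "data.frame", startTime = "numeric"),
  prototype(startTime = 0))

setValidity("EEGRecording", function(object) {
  msg <- character(0)
  if (length(object@fs) != 1 || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (nrow(object@samples) != nrow(object@channels))
    msg <- c(msg, "one channel-metadata row is required per signal row")
  if (anyNA(object@samples))
    msg <- c(msg, "samples must not contain NA/NaN (mask artifacts upstream)")
  need <- c("name", "site", "hemisphere", "unit")
  if (!all(need %in% names(object@channels)))
    msg <- c(msg, paste("channels needs columns:", paste(need, collapse = ", ")))
  else {
    if (any(!nzchar(object@channels$name)))
      msg <- c(msg, "channel names must be non-empty")
    key <- paste(object@channels$site, object@channels$hemisphere)
    known <- object@channels$site != "other"
    if (anyDuplicated(key[known]))
      msg <- c(msg, "site + hemisphere combination must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param samples channels x time numeric matrix (microvolts).
#' @param fs sampling rate, Hz.
#' @param channels data.frame of channel metadata, or a character vector of
#'   channel labels which are parsed with [parseSiteLabel()].
#' @param startTime start offset in seconds.
#' @return an [EEGRecording-class] object.
#' @examples
#' rec <- eegRecording(matrix(rnorm(2048), 2), fs = 1024,
#'                     channels = c("Pf-r", "Pp-r"))
#' nChannels(rec)
#' @export
eegRecording <- function(samples, fs, channels, startTime = 0) {
  if (is.character(channels)) {
    channels <- do.call(rbind, lapply(channels, function(lbl) {
      p <- parseSiteLabel(lbl)
      data.frame(name = lbl, site = p$site, hemisphere = p$hemisphere,
                 unit = "uV", stringsAsFactors = FALSE)
    }))
  }
  new("EEGRecording", samples = samples, fs = fs, channels = channels,
      startTime = startTime)
}

#' StateAnnotation: scored behavioral-state epochs and events
#'
#' Ordered, non-overlapping 10-s epochs labeling the behavioral or
#' pharmacological state, plus point events (injections, stimuli, artifact
#' bounds).
#'
#' @slot epochs data.frame with columns `start`, `duration`, `state`.
#' @slot events data.frame with columns `time`, `kind`, `payload`.
#' @export
setClass("StateAnnotation",
  representation(epochs = "data.frame", events = "data.frame"))

.eventKinds <- c("injection", "sound_on", "sound_off", "visual_on",
                 "visual_off", "artifact_start", "artifact_end")

setValidity("StateAnnotation", function(object) {
  ep <- object@epochs
  msg <- character(0)
  if (!all(c("start", "duration", "state") %in% names(ep)))
    return("epochs needs columns start, duration, state")
  if (nrow(ep) > 1) {
    if (is.unsorted(ep$start, strictly = TRUE))
      msg <- c(msg, "epochs must be sorted by start")
    if (any(ep$start[-1] - (ep$start[-nrow(ep)] + ep$duration[-nrow(ep)]) < -1e-9))
      msg <- c(msg, "epochs must not overlap")
  }
  if (any(ep$duration <= 0)) msg <- c(msg, "epoch durations must be positive")
  ev <- object@events
  if (!all(c("time", "kind") %in% names(ev)))
    msg <- c(msg, "events needs columns time, kind")
  else if (nrow(ev) && !all(ev$kind %in% .eventKinds))
    msg <- c(msg, paste("unknown event kind; allowed:",
                        paste(.eventKinds, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a StateAnnotation
#'
#' Epochs are checked against the canonical 10-s scoring length; a trailing
#' shorter epoch is tolerated when `tolerance` permits.
#'
#' @param epochs data.frame(start, duration, state) in seconds.
#' @param events optional data.frame(time, kind, payload).
#' @param epochLength required epoch length, seconds (default 10).
#' @param tolerance absolute tolerance on the epoch length; the final epoch
#'   may be shorter than `epochLength` regardless.
#' @return a [StateAnnotation-class] object.
#' @export
stateAnnotation <- function(epochs, events = NULL, epochLength = 10,
                            tolerance = 1e-6) {
  if (is.null(events))
    events <- data.frame(time = numeric(0), kind = character(0),
                         payload = character(0), stringsAsFactors = FALSE)
  if (!"payload" %in% names(events)) events$payload <- ""
  epochs <- epochs[order(epochs$start), , drop = FALSE]
  if (nrow(epochs)) {
    dev <- abs(epochs$duration - epochLength)
    bad <- dev > tolerance
    ## allow only a trailing short epoch
    if (any(bad[-nrow(epochs)]) ||
        (bad[nrow(epochs)] && epochs$duration[nrow(epochs)] > epochLength + tolerance))
      stop("epoch durations must equal ", epochLength,
           " s (trailing epoch may be shorter)")
  }
  new("StateAnnotation", epochs = epochs, events = events)
}

#' SpectralEstimate: a power spectral density
#'
#' @slot freqs frequency grid, Hz (ascending, spacing fs/nfft).
#' @slot power one-sided PSD, microvolts^2/Hz.
#' @slot method "welch" or "multitaper".
#' @slot params list of estimator parameters (nfft, overlap, ...).
#' @export
setClass("SpectralEstimate",
  representation(freqs = "numeric", power = "numeric", method = "character",
                 params = "list"))

setValidity("SpectralEstimate", function(object) {
  msg <- character(0)
  if (length(object@freqs) != length(object@power))
    msg <- c(msg, "freqs and power lengths differ")
  if (any(object@power < 0)) msg <- c(msg, "power must be non-negative")
  if (is.unsorted(object@freqs)) msg <- c(msg, "freqs must ascend")
  if (length(msg)) msg else TRUE
})

#' Spectrogram: a time-frequency power map
#'
#' @slot times segment-center times, seconds.
#' @slot freqs frequencies, Hz.
#' @slot power time x frequency matrix of non-negative power.
#' @slot method "multitaper" or "wavelet".
#' @export
setClass("Spectrogram",
  representation(times = "numeric", freqs = "numeric", power = "matrix",
                 method = "character"))

setValidity("Spectrogram", function(object) {
  msg <- character(0)
  if (nrow(object@power) != length(object@times) ||
      ncol(object@power) != length(object@freqs))
    msg <- c(msg, "power must be times x freqs")
  if (any(object@power < 0)) msg <- c(msg, "power must be non-negative")
  if (length(msg)) msg else TRUE
})

#' CoherenceProfile: per-frequency magnitude-squared coherence
#'
#' The Welch-block magnitude-squared coherence between one channel pair over
#' one analysis window, on a 0.5-Hz grid under the default configuration
#' (fs = 1024 Hz, nfft = 2048).
#'
#' @slot freqs frequency grid, Hz.
#' @slot msc magnitude-squared coherence in [0, 1] per frequency.
#' @slot sxx,syy block-averaged auto-spectra (arbitrary common scale).
#' @slot sxy block-averaged complex cross-spectrum, same scale.
#' @slot pair character(2), the two channel names.
#' @slot nBlocks number of Welch blocks actually averaged.
#' @slot window list describing the analysis window (start, duration, state).
#' @export
setClass("CoherenceProfile",
  representation(freqs = "numeric", msc = "numeric", sxx = "numeric",
                 syy = "numeric", sxy = "complex", pair = "character",
                 nBlocks = "integer", window = "list"))

setValidity("CoherenceProfile", function(object) {
  msg <- character(0)
  if (length(object@freqs) != length(object@msc))
    msg <- c(msg, "freqs and msc lengths differ")
  if (length(object@sxx) &&
      (length(object@sxx) != length(object@freqs) ||
         length(object@syy) != length(object@freqs) ||
         length(object@sxy) != length(object@freqs)))
    msg <- c(msg, "sxx/syy/sxy must match freqs in length")
  if (any(object@msc < -1e-12 | object@msc > 1 + 1e-9))
    msg <- c(msg, "msc must lie in [0, 1]")
  if (length(object@pair) != 2 || object@pair[1] == object@pair[2])
    msg <- c(msg, "pair must name two distinct channels")
  if (length(msg)) msg else TRUE
})

#' ZCoherenceSummary: band-averaged z'-coherence with per-window replicates
#'
#' @slot band numeric(2), band edges in Hz.
#' @slot perWindowZ z' value per analysis window.
#' @slot meanZ mean of `perWindowZ`.
#' @slot seZ standard error of `perWindowZ`.
#' @slot pair character(2) channel names.
#' @slot state behavioral/pharmacological state label.
#' @export
setClass("ZCoherenceSummary",
  representation(band = "numeric", perWindowZ = "numeric", meanZ = "numeric",
                 seZ = "numeric", pair = "character", state = "character"))

setValidity("ZCoherenceSummary", function(object) {
  msg <- character(0)
  if (any(object@perWindowZ < 0)) msg <- c(msg, "z' must be non-negative")
  if (length(object@perWindowZ) &&
      abs(object@meanZ - mean(object@perWindowZ)) > 1e-8)
    msg <- c(msg, "meanZ inconsistent with perWindowZ")
  if (length(msg)) msg else TRUE
})

#' Coherogram: time-resolved band coherence map
#'
#' @slot times segment-center times, seconds.
#' @slot freqs frequencies, Hz.
#' @slot z time x frequency matrix of z'-coherence.
#' @slot pair character(2) channel names.
#' @export
setClass("Coherogram",
  representation(times = "numeric", freqs = "numeric", z = "matrix",
                 pair = "character"))

setValidity("Coherogram", function(object) {
  msg <- character(0)
  if (nrow(object@z) != length(object@times) ||
      ncol(object@z) != length(object@freqs))
    msg <- c(msg, "z must be times x freqs")
  if (any(object@z < 0)) msg <- c(msg, "z' must be non-negative")
  if (length(msg)) msg else TRUE
})

#' StatResult: an ANOVA result with post-hoc matrix
#'
#' @slot test "oneway_anova" or "rm_anova".
#' @slot F the F statistic.
#' @slot df numeric(2), (between, within) degrees of freedom.
#' @slot p the p-value.
#' @slot posthoc symmetric matrix of pairwise adjusted p-values (unit
#'   diagonal) or a 0 x 0 matrix.
#' @slot posthocMethod "tamhane" or "bonferroni".
#' @slot details list of auxiliary quantities (group means, alternative df
#'   conventions, flags).
#' @export
setClass("StatResult",
  representation(test = "character", F = "numeric", df = "numeric",
                 p = "numeric", posthoc = "matrix",
                 posthocMethod = "character", details = "list"))

setValidity("StatResult", function(object) {
  msg <- character(0)
  if (is.finite(object@F) && object@F < 0) msg <- c(msg, "F must be >= 0")
  if (is.finite(object@p) && (object@p < 0 || object@p > 1))
    msg <- c(msg, "p must be in [0, 1]")
  ph <- object@posthoc
  if (length(ph) && (nrow(ph) != ncol(ph) ||
      max(abs(ph - t(ph)), na.rm = TRUE) > 1e-12))
    msg <- c(msg, "posthoc must be symmetric")
  if (length(msg)) msg else TRUE
})

#' SyntheticState: generative parameters for one behavioral state
#'
#' Parameters of the state-conditional generative model: Poisson gamma
#' bursts (rate, peak amplitude, duration range, carrier range), the
#' fraction of burst activity driven by a source shared across channels,
#' band-limited Gaussian background components, NREM/ketamine slow waves,
#' an optional beta spectral peak and a high-gamma (45-60 Hz) gain.
#'
#' @slot label state label, one of AW, QW, NREM, REM, K5, K10, K15.
#' @slot burstRate bursts per second per channel.
#' @slot burstAmp burst peak amplitude, microvolts.
#' @slot burstAmpSd relative per-burst/per-channel amplitude scatter.
#' @slot burstDurRange numeric(2) burst duration range, seconds.
#' @slot couplingFraction fraction of burst power from the shared source,
#'   in [0, 1].
#' @slot carrierRange numeric(2) burst carrier frequency range, Hz.
#' @slot backgroundSpec data.frame(lo, hi, power): band-limited Gaussian
#'   background components, each with total power `power` (microvolts^2)
#'   spread uniformly over [lo, hi] Hz.
#' @slot slowWaveAmp slow-wave (0.5-4 Hz) amplitude, microvolts (0 = none).
#' @slot betaPeak numeric(2) (center Hz, power) or numeric(0) for none.
#' @slot highGammaGain power multiplier applied to 45-60 Hz background.
#' @slot jitter half-width of the uniform per-channel envelope jitter of
#'   shared bursts, seconds.
#' @slot jitterCarrier logical; if TRUE the jitter also shifts the carrier
#'   (time-shifting the whole waveform) instead of the envelope alone.
#' @export
setClass("SyntheticState",
  representation(label = "character", burstRate = "numeric",
                 burstAmp = "numeric", burstAmpSd = "numeric",
                 burstDurRange = "numeric", couplingFraction = "numeric",
                 carrierRange = "numeric", backgroundSpec = "data.frame",
                 slowWaveAmp = "numeric", betaPeak = "numeric",
                 highGammaGain = "numeric", jitter = "numeric",
                 jitterCarrier = "logical"))

setValidity("SyntheticState", function(object) {
  msg <- character(0)
  if (object@couplingFraction < 0 || object@couplingFraction > 1)
    msg <- c(msg, "couplingFraction must lie in [0, 1]")
  d <- object@burstDurRange
  if (length(d) != 2 || d[1] <= 0 || d[2] > 2 || d[1] > d[2])
    msg <- c(msg, "burstDurRange must satisfy 0 < min <= max <= 2 s")
  if (object@burstRate < 0) msg <- c(msg, "burstRate must be >= 0")
  if (object@burstAmp < 0 || object@slowWaveAmp < 0 ||
      (nrow(object@backgroundSpec) && any(object@backgroundSpec$power < 0)))
    msg <- c(msg, "all powers/amplitudes must be >= 0")
  cr <- object@carrierRange
  if (length(cr) != 2 || cr[1] < 30 || cr[2] > 45 || cr[1] > cr[2])
    msg <- c(msg, "carrierRange must lie within [30, 45] Hz")
  if (object@jitter < 0) msg <- c(msg, "jitter must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SyntheticState
#'
#' @param label state label.
#' @param burstRate bursts/s/channel.
#' @param burstAmp peak amplitude, microvolts.
#' @param couplingFraction shared-source fraction in [0, 1].
#' @param burstDurRange duration range, seconds.
#' @param burstAmpSd relative amplitude scatter (sd/mean).
#' @param carrierRange carrier frequency range, Hz, within [30, 45].
#' @param backgroundSpec data.frame(lo, hi, power) background bands.
#' @param slowWaveAmp slow-wave amplitude, microvolts.
#' @param betaPeak numeric(2) (center Hz, power) or numeric(0).
#' @param highGammaGain 45-60 Hz background power multiplier.
#' @param jitter shared-burst envelope jitter half-width, seconds.
#' @param jitterCarrier shift carrier along with the envelope?
#' @return a [SyntheticState-class] object.
#' @export
syntheticState <- function(label, burstRate, burstAmp, couplingFraction,
                           burstDurRange = c(0.2, 0.5), burstAmpSd = 0.15,
                           carrierRange = c(35, 40),
                           backgroundSpec = defaultBackgroundSpec(),
                           slowWaveAmp = 0, betaPeak = numeric(0),
                           highGammaGain = 1, jitter = 0.010,
                           jitterCarrier = FALSE) {
  new("SyntheticState", label = label, burstRate = burstRate,
      burstAmp = burstAmp, burstAmpSd = burstAmpSd,
      burstDurRange = burstDurRange, couplingFraction = couplingFraction,
      carrierRange = carrierRange, backgroundSpec = backgroundSpec,
      slowWaveAmp = slowWaveAmp, betaPeak = betaPeak,
      highGammaGain = highGammaGain, jitter = jitter,
      jitterCarrier = jitterCarrier)
}

#' SyntheticConfig: a full synthetic-session description
#'
#' @slot fs sampling rate, Hz.
#' @slot channelSites character vector of channel labels (e.g. "Pf-r").
#' @slot states named list of [SyntheticState-class] parameter sets.
#' @slot stateSequence data.frame(state, duration): ordered state segments,
#'   durations in seconds (multiples of the 10-s epoch).
#' @slot seed integer seed making the session reproducible.
#' @export
setClass("SyntheticConfig",
  representation(fs = "numeric", channelSites = "character",
                 states = "list", stateSequence = "data.frame",
                 seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  msg <- character(0)
  if (object@fs <= 0) msg <- c(msg, "fs must be positive")
  sq <- object@stateSequence
  if (!all(c("state", "duration") %in% names(sq)))
    return("stateSequence needs columns state, duration")
  if (any(sq$duration <= 0)) msg <- c(msg, "segment durations must be positive")
  miss <- setdiff(unique(sq$state), names(object@states))
  if (length(miss))
    msg <- c(msg, paste("no parameters for state(s):",
                        paste(miss, collapse = ", ")))
  if (length(object@channelSites) < 1)
    msg <- c(msg, "at least one channel is required")
  if (length(msg)) msg else TRUE
})

#' Construct a SyntheticConfig
#'
#' @param stateSequence data.frame(state, duration seconds) or a named
#'   numeric vector of durations.
#' @param states named list of [SyntheticState-class]; defaults to
#'   [statePresets()].
#' @param fs sampling rate, Hz.
#' @param channelSites channel labels.
#' @param seed integer seed.
#' @return a [SyntheticConfig-class] object.
#' @export
syntheticConfig <- function(stateSequence, states = statePresets(),
                            fs = 1024, channelSites = c("Pf-r", "Pp-r"),
                            seed = 1L) {
  if (is.numeric(stateSequence) && !is.null(names(stateSequence)))
    stateSequence <- data.frame(state = names(stateSequence),
                                duration = as.numeric(stateSequence),
                                stringsAsFactors = FALSE)
  new("SyntheticConfig", fs = fs, channelSites = channelSites,
      states = states, stateSequence = stateSequence, seed = as.integer(seed))
}

#' GroundTruth: generator-side truth for a synthetic session
#'
#' @slot bursts data.frame(channel, onset, duration, shared): every burst
#'   placed by the generator; shared bursts appear with identical onsets on
#'   all channels.
#' @slot expectedBandMsc named numeric: closed-form expected 30-45 Hz band
#'   magnitude-squared coherence per state.
#' @export
setClass("GroundTruth",
  representation(bursts = "data.frame", expectedBandMsc = "numeric"))

setValidity("GroundTruth", function(object) {
  v <- object@expectedBandMsc
  if (length(v) && (any(v < 0) || any(v > 1)))
    "expectedBandMsc must lie in [0, 1]" else TRUE
})
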