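#' @include AllClasses.R
NULL

#' Accessors for gammacoh classes
#'
#' `samplingRate`, `nChannels`, `channelInfo`, `signalMatrix`,
#' `recordingDuration`, `epochs`, `events`, `coherence`, `bandZ` extract the
#' obvious components of the package's S4 containers without touching slots.
#'
#' @param object a gammacoh S4 object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("channelInfo", function(object) standardGeneric("channelInfo"))
#' @rdname accessors
#' @export
setGeneric("signalMatrix", function(object) standardGeneric("signalMatrix"))
#' @rdname accessors
#' @export
setGeneric("recordingDuration",
           function(object) standardGeneric("recordingDuration"))
#' @rdname accessors
#' @export
setGeneric("epochs", function(object) standardGeneric("epochs"))
#' @rdname accessors
#' @export
setGeneric("events", function(object) standardGeneric("events"))
#' @rdname accessors
#' @export
setGeneric("coherence", function(object) standardGeneric("coherence"))
#' @rdname accessors
#' @export
setGeneric("frequencies", function(object) standardGeneric("frequencies"))

#' @rdname accessors
setMethod("samplingRate", "EEGRecording", function(object) object@fs)
#' @rdname accessors
setMethod("nChannels", "EEGRecording", function(object) nrow(object@samples))
#' @rdname accessors
setMethod("channelInfo", "EEGRecording", function(object) object@channels)
#' @rdname accessors
setMethod("signalMatrix", "EEGRecording", function(object) object@samples)
#' @rdname accessors
setMethod("recordingDuration", "EEGRecording",
          function(object) ncol(object@samples) / object@fs)
#' @rdname accessors
setMethod("epochs", "StateAnnotation", function(object) object@epochs)
#' @rdname accessors
setMethod("events", "StateAnnotation", function(object) object@events)
#' @rdname accessors
setMethod("coherence", "CoherenceProfile", function(object) object@msc)
#' @rdname accessors
setMethod("frequencies", "CoherenceProfile", function(object) object@freqs)
#' @rdname accessors
setMethod("frequencies", "SpectralEstimate", function(object) object@freqs)

setMethod("show", "EEGRecording", function(object) {
  cat("EEGRecording:", nChannels(object), "channel(s) x",
      ncol(object@samples), "samples @", object@fs, "Hz (",
      sprintf("%.1f", recordingDuration(object)), "s )\n")
  cat("  channels:", paste(object@channels$name, collapse = ", "), "\n")
})

setMethod("show", "StateAnnotation", function(object) {
  ep <- object@epochs
  cat("StateAnnotation:", nrow(ep), "epochs,",
      nrow(object@events), "events\n")
  if (nrow(ep)) {
    tab <- table(ep$state)
    cat("  states:",
        paste(sprintf("%s (%d)", names(tab), as.integer(tab)),
              collapse = ", "), "\n")
  }
})

setMethod("show", "CoherenceProfile", function(object) {
  cat("CoherenceProfile:", paste(object@pair, collapse = " vs "),
      "|", length(object@freqs), "frequencies,",
      object@nBlocks, "Welch blocks\n")
})

setMethod("show", "ZCoherenceSummary", function(object) {
  cat(sprintf("ZCoherenceSummary: %s | %s | band %.1f-%.1f Hz\n",
              paste(object@pair, collapse = " vs "), object@state,
              object@band[1], object@band[2]))
  cat(sprintf("  mean z' = %.3f (SE %.3f, n = %d windows)\n",
              object@meanZ, object@seZ, length(object@perWindowZ)))
})

setMethod("show", "StatResult", function(object) {
  cat(sprintf("StatResult [%s]: F(%g, %g) = %.3f, p = %.4g\n",
              object@test, object@df[1], object@df[2], object@F, object@p))
  if (length(object@posthoc))
    cat("  post-hoc:", object@posthocMethod, "adjusted, ",
        nrow(object@posthoc), "groups\n")
})

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig:", length(object@channelSites), "channel(s) @",
      object@fs, "Hz, seed", object@seed, "\n")
  cat("  sequence:",
      paste(sprintf("%s (%gs)", object@stateSequence$state,
                    object@stateSequence$duration), collapse = " -> "), "\n")
})

setMethod("show", "Spectrogram", function(object) {
  cat(sprintf("Spectrogram [%s]: %d times x %d freqs\n", object@method,
              length(object@times), length(object@freqs)))
})

setMethod("show", "Coherogram", function(object) {
  cat(sprintf("Coherogram: %s | %d times x %d freqs\n",
              paste(object@pair, collapse = " vs "),
              length(object@times), length(object@freqs)))
})

#' Image plots for time-frequency maps
#'
#' @param x a Spectrogram or Coherogram.
#' @param y unused.
#' @param logPower plot log10 power (spectrograms only).
#' @param ... passed to [graphics::image()].
#' @return invisibly, `x`.
#' @export
setMethod("plot", signature(x = "Spectrogram", y = "missing"),
  function(x, y, logPower = TRUE, ...) {
    z <- if (logPower) log10(x@power + 1e-12) else x@power
    graphics::image(x@times, x@freqs, z, xlab = "time (s)",
                    ylab = "frequency (Hz)",
                    col = grDevices::hcl.colors(64, "viridis"), ...)
    invisible(x)
  })

#' @rdname plot-Spectrogram-missing-method
#' @export
setMethod("plot", signature(x = "Coherogram", y = "missing"),
  function(x, y, ...) {
    graphics::image(x@times, x@freqs, x@z, xlab = "time (s)",
                    ylab = "frequency (Hz)",
                    col = grDevices::hcl.colors(64, "viridis"), ...)
    invisible(x)
  })
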