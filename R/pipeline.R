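## End-to-end orchestration: synthesize or load a session, select windows,
## estimate per-window band power and coherence, tabulate and test.

#' Build a run configuration
#'
#' Collects every knob of an end-to-end run. Provide either `synthetic`
#' (a [SyntheticConfig-class]) or `recordingPath` + `annotationPath`.
#'
#' @param synthetic optional [SyntheticConfig-class] to simulate.
#' @param recordingPath optional EDF path.
#' @param annotationPath optional epoch CSV path.
#' @param eventPath optional event CSV path.
#' @param states state labels to analyze.
#' @param pairs list of character(2) channel-name pairs; default all pairs.
#' @param band analysis band, Hz.
#' @param nWindows windows per state.
#' @param windowDur window duration, seconds.
#' @param stimulusExclusion exclusion half-width around stimuli, seconds.
#' @param stimulusClear exclude stimulus neighborhoods during window
#'   selection?
#' @param nfft Welch block size.
#' @param overlap Welch overlap fraction.
#' @param zMethod z'-transform convention, see [zTransform()].
#' @param seed master seed; all stage seeds derive from it.
#' @param outDir optional output directory for CSV tables + manifest.
#' @return a list of class "gammacohRunConfig".
#' @export
runConfig <- function(synthetic = NULL, recordingPath = NULL,
                      annotationPath = NULL, eventPath = NULL,
                      states = c("AW", "QW", "NREM", "REM", "K15"),
                      pairs = NULL, band = c(30, 45), nWindows = 12,
                      windowDur = 100, stimulusExclusion = 300,
                      stimulusClear = TRUE, nfft = 2048, overlap = 0.5,
                      zMethod = "atanh_sqrt", seed = 1, outDir = NULL) {
  cfg <- list(synthetic = synthetic, recordingPath = recordingPath,
              annotationPath = annotationPath, eventPath = eventPath,
              states = states, pairs = pairs, band = band,
              nWindows = nWindows, windowDur = windowDur,
              stimulusExclusion = stimulusExclusion,
              stimulusClear = stimulusClear, nfft = nfft,
              overlap = overlap, zMethod = zMethod, seed = seed,
              outDir = outDir)
  class(cfg) <- "gammacohRunConfig"
  cfg
}

#' Synthetic session covering the requested states
#'
#' Convenience builder: one contiguous segment per state, long enough for
#' `nWindows` windows of `windowDur` seconds plus one spare slot.
#'
#' @param states state labels (must exist in `presets`).
#' @param seed integer seed.
#' @param nWindows,windowDur window plan the session must support.
#' @param presets named list of [SyntheticState-class].
#' @param channelSites channel labels.
#' @param fs sampling rate, Hz.
#' @return a [SyntheticConfig-class].
#' @export
sessionConfig <- function(states, seed = 1L, nWindows = 12,
                          windowDur = 100, presets = statePresets(),
                          channelSites = c("Pf-r", "Pp-r"), fs = 1024) {
  segDur <- ceiling(((nWindows + 1) * windowDur) / 10) * 10
  syntheticConfig(stats::setNames(rep(segDur, length(states)), states),
                  states = presets, fs = fs,
                  channelSites = channelSites, seed = seed)
}

## Resolve (recording, annotation) from a run config.
resolveSession <- function(cfg) {
  if (!is.null(cfg$synthetic)) {
    ses <- generateRecording(cfg$synthetic)
    list(recording = ses$recording, annotation = ses$annotation,
         groundTruth = ses$groundTruth)
  } else if (!is.null(cfg$recordingPath) && !is.null(cfg$annotationPath)) {
    list(recording = readRecording(cfg$recordingPath),
         annotation = readAnnotation(cfg$annotationPath, cfg$eventPath),
         groundTruth = NULL)
  } else stop("config must provide `synthetic` or recording + annotation paths")
}

## "0.123 +- 0.045" formatting for the state-column tables.
fmtMeanSe <- function(m, se) sprintf("%.3f +- %.3f", m, se)

#' Run the full state comparison
#'
#' For every requested state, selects `nWindows` artifact-free windows,
#' then per window computes band power per channel and band z'-coherence
#' per channel pair. Produces the per-channel power table and per-pair
#' coherence table (states as columns, mean +- SE), a one-way ANOVA with
#' Tamhane post-hoc across states per channel/pair, and per-pair
#' [ZCoherenceSummary-class] objects. Fully reproducible from config +
#' seed; when `outDir` is set the tables and a run manifest are written as
#' CSV/JSON.
#'
#' @param cfg a config from [runConfig()].
#' @return list with `powerTable`, `coherenceTable`, `perWindow`,
#'   `powerAnova`, `coherenceAnova`, `summaries`, `windows`, `recording`,
#'   `annotation`, `groundTruth`, `manifest`.
#' @export
runStateComparison <- function(cfg) {
  stopifnot(inherits(cfg, "gammacohRunConfig"))
  ses <- resolveSession(cfg)
  rec <- ses$recording; ann <- ses$annotation
  fs <- samplingRate(rec)
  chNames <- channelInfo(rec)$name
  pairs <- cfg$pairs
  if (is.null(pairs)) {
    cmb <- utils::combn(chNames, 2)
    pairs <- lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
  }
  x <- signalMatrix(rec)

  windows <- list(); perWindow <- list()
  for (si in seq_along(cfg$states)) {
    st <- cfg$states[si]
    win <- selectWindows(ann, st, n = cfg$nWindows, dur = cfg$windowDur,
                         stimulusExclusion = cfg$stimulusExclusion,
                         stimulusClear = cfg$stimulusClear,
                         seed = childSeed(cfg$seed, si))
    windows[[st]] <- win
    for (wi in seq_len(nrow(win))) {
      idx <- (round(win$start[wi] * fs) + 1):
        (round((win$start[wi] + win$duration[wi]) * fs))
      segs <- x[, idx, drop = FALSE]
      for (ch in seq_along(chNames)) {
        bp <- bandPower(welchPsd(segs[ch, ], fs, cfg$nfft, cfg$overlap),
                        cfg$band)
        perWindow[[length(perWindow) + 1L]] <- data.frame(
          state = st, windowStart = win$start[wi], kind = "power",
          unit = chNames[ch], value = bp, stringsAsFactors = FALSE)
      }
      for (pr in pairs) {
        i1 <- match(pr[1], chNames); i2 <- match(pr[2], chNames)
        prof <- mscProfile(segs[i1, ], segs[i2, ], fs, cfg$nfft,
                           cfg$overlap, pair = pr,
                           window = list(start = win$start[wi],
                                         duration = win$duration[wi],
                                         state = st))
        z <- bandMeanZ(prof, cfg$band, zMethod = cfg$zMethod)
        perWindow[[length(perWindow) + 1L]] <- data.frame(
          state = st, windowStart = win$start[wi], kind = "coherence",
          unit = paste(pr, collapse = ":"), value = z,
          stringsAsFactors = FALSE)
      }
    }
  }
  perWindow <- do.call(rbind, perWindow)

  buildTable <- function(kind) {
    dd <- perWindow[perWindow$kind == kind, ]
    units <- unique(dd$unit)
    anovas <- list(); rows <- list()
    for (u in units) {
      du <- dd[dd$unit == u, ]
      groups <- lapply(cfg$states, function(s) du$value[du$state == s])
      names(groups) <- cfg$states
      an <- onewayAnova(groups)
      anovas[[u]] <- an
      cells <- vapply(cfg$states, function(s) {
        v <- groups[[s]]
        fmtMeanSe(mean(v), stats::sd(v) / sqrt(length(v)))
      }, "")
      rows[[u]] <- data.frame(unit = u, t(cells), F = an@F, p = an@p,
                              stringsAsFactors = FALSE, check.names = FALSE)
    }
    tab <- do.call(rbind, rows)
    names(tab)[1 + seq_along(cfg$states)] <- cfg$states
    rownames(tab) <- NULL
    list(table = tab, anova = anovas)
  }
  pw <- buildTable("power")
  co <- buildTable("coherence")

  summaries <- list()
  for (pr in pairs) {
    key <- paste(pr, collapse = ":")
    for (st in cfg$states) {
      zz <- perWindow$value[perWindow$kind == "coherence" &
                              perWindow$unit == key &
                              perWindow$state == st]
      summaries[[paste(key, st, sep = "|")]] <-
        zCoherenceSummary(zz, pr, st, cfg$band)
    }
  }

  manifest <- list(
    package = as.character(utils::packageVersion("gammacoh")),
    seed = cfg$seed, states = cfg$states, band = cfg$band,
    nWindows = cfg$nWindows, windowDur = cfg$windowDur,
    nfft = cfg$nfft, overlap = cfg$overlap, zMethod = cfg$zMethod,
    pairs = vapply(pairs, paste, "", collapse = ":"),
    windows = do.call(rbind, windows))

  if (!is.null(cfg$outDir)) {
    dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(pw$table, file.path(cfg$outDir, "power_table.csv"),
                     row.names = FALSE)
    utils::write.csv(co$table, file.path(cfg$outDir, "coherence_table.csv"),
                     row.names = FALSE)
    utils::write.csv(perWindow, file.path(cfg$outDir, "per_window.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }

  list(powerTable = pw$table, coherenceTable = co$table,
       perWindow = perWindow, powerAnova = pw$anova,
       coherenceAnova = co$anova, summaries = summaries,
       windows = windows, recording = rec, annotation = ann,
       groundTruth = ses$groundTruth, manifest = manifest)
}

#' Run the ketamine dose-response analysis
#'
#' Simulates (or reuses) one session per subject covering alert
#' wakefulness and the ketamine doses, computes each subject's mean band
#' z'-coherence per condition for one channel pair, and summarizes the
#' dose-response with a repeated-measures ANOVA.
#'
#' @param doses condition labels (columns of the dose-response matrix).
#' @param nSubjects number of simulated subjects.
#' @param seed master seed.
#' @param presets state presets used for simulation.
#' @param nWindows,windowDur window plan per condition.
#' @param band analysis band, Hz.
#' @param pair character(2) channel names (default first two channels).
#' @return list with `zMatrix` (subjects x doses), `table` and `anova`
#'   from [doseResponseTable()].
#' @export
runDoseResponse <- function(doses = c("AW", "K5", "K10", "K15"),
                            nSubjects = 5, seed = 1,
                            presets = statePresets(), nWindows = 12,
                            windowDur = 100, band = c(30, 45),
                            pair = NULL) {
  Z <- matrix(NA_real_, nSubjects, length(doses),
              dimnames = list(NULL, doses))
  for (subj in seq_len(nSubjects)) {
    cfg <- runConfig(
      synthetic = sessionConfig(doses, seed = childSeed(seed, 100 + subj),
                                nWindows = nWindows,
                                windowDur = windowDur, presets = presets),
      states = doses, nWindows = nWindows, windowDur = windowDur,
      band = band, seed = childSeed(seed, 200 + subj))
    res <- runStateComparison(cfg)
    if (is.null(pair))
      pair <- res$manifest$pairs[1]
    key <- if (length(pair) == 2) paste(pair, collapse = ":") else pair
    for (d in doses)
      Z[subj, d] <- res$summaries[[paste(key, d, sep = "|")]]@meanZ
  }
  c(list(zMatrix = Z), doseResponseTable(Z))
}
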