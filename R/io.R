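## EDF (European Data Format) I/O for uniform-rate multichannel EEG.
##
## Implements the 16-bit EDF subset used here: one fixed record duration,
## identical sampling rate across selected signals, physical dimension uV.
## Header layout: 256 bytes fixed + 256 bytes per signal, ASCII fields;
## data records are little-endian int16 with per-signal linear scaling
## between (digMin, digMax) and (physMin, physMax).

.padField <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Parse a channel label into cortical site and hemisphere
#'
#' Labels follow the convention "SITE-HEMISPHERE", e.g. "Pf-r" for right
#' prefrontal, with sites Pf, M1, S1, Pp, V1 and hemispheres r/l.
#' Unparseable labels map to site "other" with a warning.
#'
#' @param label channel label.
#' @return list(site, hemisphere).
#' @examples
#' parseSiteLabel("Pp-l")
#' @export
parseSiteLabel <- function(label) {
  m <- regmatches(label, regexec("^(Pf|M1|S1|Pp|V1)[-_ ]?(r|l)?", label))[[1]]
  if (length(m) == 0 || !nzchar(m[2])) {
    warning("unparseable site label: ", label, " (site set to 'other')")
    return(list(site = "other", hemisphere = "unknown"))
  }
  list(site = m[2], hemisphere = if (nzchar(m[3])) m[3] else "unknown")
}

#' Write a recording to an EDF file
#'
#' Samples are scaled to 16-bit integers over a symmetric physical range
#' covering the data, so the round-trip quantization error is at most
#' physical_range / 2^16. The recording is truncated to a whole number of
#' 1-second data records (with a warning if samples are dropped).
#'
#' @param rec an [EEGRecording-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeRecording <- function(rec, path) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- samplingRate(rec)
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate")
  fs <- round(fs)
  x <- signalMatrix(rec)
  nCh <- nrow(x)
  if (ncol(x) == 0) stop("cannot write a zero-length recording")
  nRec <- floor(ncol(x) / fs)
  if (nRec < 1) stop("recording shorter than one 1-s data record")
  if (nRec * fs < ncol(x))
    warning("truncating ", ncol(x) - nRec * fs,
            " trailing samples to whole data records")
  x <- x[, seq_len(nRec * fs), drop = FALSE]

  physMax <- max(1, ceiling(max(abs(x)) * 1.0001))
  physMin <- -physMax
  digMax <- 32767; digMin <- -32768
  scale <- (digMax - digMin) / (physMax - physMin)
  xi <- round((x - physMin) * scale) + digMin
  xi[xi > digMax] <- digMax; xi[xi < digMin] <- digMin

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .padField("0", 8),
    .padField("X X X X", 80),
    .padField("Startdate X X X X", 80),
    .padField("01.01.00", 8), .padField("00.00.00", 8),
    .padField(256 * (nCh + 1), 8),
    .padField("", 44),
    .padField(nRec, 8),
    .padField("1", 8),
    .padField(nCh, 4),
    paste(vapply(channelInfo(rec)$name, .padField, "", width = 16),
          collapse = ""),
    paste(rep(.padField("", 80), nCh), collapse = ""),
    paste(rep(.padField("uV", 8), nCh), collapse = ""),
    paste(rep(.padField(physMin, 8), nCh), collapse = ""),
    paste(rep(.padField(physMax, 8), nCh), collapse = ""),
    paste(rep(.padField(digMin, 8), nCh), collapse = ""),
    paste(rep(.padField(digMax, 8), nCh), collapse = ""),
    paste(rep(.padField("", 80), nCh), collapse = ""),
    paste(rep(.padField(fs, 8), nCh), collapse = ""),
    paste(rep(.padField("", 32), nCh), collapse = ""))
  writeChar(hdr, con, eos = NULL)
  for (r in seq_len(nRec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(nCh))
      writeBin(as.integer(xi[ch, cols]), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a recording from an EDF file
#'
#' Applies the EDF physical scaling (output in microvolts) and populates
#' channel metadata by parsing labels with [parseSiteLabel()]. All selected
#' channels must share one sampling rate.
#'
#' @param path EDF file path.
#' @param channels optional character vector restricting which signal
#'   labels to load.
#' @return an [EEGRecording-class].
#' @export
readRecording <- function(path, channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nc) trimws(readChar(con, nc, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                       # header bytes
  rd(44)
  nRec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fld(16); fld(80)
  units <- fld(8)
  physMin <- as.numeric(fld(8)); physMax <- as.numeric(fld(8))
  digMin <- as.numeric(fld(8)); digMax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))   # samples per record per signal
  fld(32)

  sel <- if (is.null(channels)) seq_len(ns) else match(channels, labels)
  if (anyNA(sel)) stop("channel(s) not found in EDF: ",
                       paste(channels[is.na(sel)], collapse = ", "))
  rates <- spr[sel] / recDur
  if (length(unique(rates)) != 1)
    stop("unsupported-format: selected channels have mixed sampling rates (",
         paste(unique(rates), collapse = ", "), " Hz)")
  fs <- rates[1]

  out <- matrix(0, nrow = length(sel), ncol = nRec * spr[sel[1]])
  for (r in seq_len(nRec)) {
    for (i in seq_len(ns)) {
      vals <- readBin(con, "integer", n = spr[i], size = 2,
                      endian = "little", signed = TRUE)
      k <- match(i, sel)
      if (!is.na(k)) {
        g <- (physMax[i] - physMin[i]) / (digMax[i] - digMin[i])
        out[k, ((r - 1) * spr[i] + 1):(r * spr[i])] <-
          (vals - digMin[i]) * g + physMin[i]
      }
    }
  }
  chinfo <- do.call(rbind, lapply(seq_along(sel), function(k) {
    p <- parseSiteLabel(labels[sel[k]])
    data.frame(name = labels[sel[k]], site = p$site,
               hemisphere = p$hemisphere, unit = units[sel[k]],
               stringsAsFactors = FALSE)
  }))
  new("EEGRecording", samples = out, fs = fs, channels = chinfo,
      startTime = 0)
}

#' Read a state annotation from CSV files
#'
#' The epoch file has columns `start_s,state` (10-s epochs implied) or
#' `start_s,duration_s,state`; the optional event file has columns
#' `time_s,kind` and optionally `payload`.
#'
#' @param epochPath epoch CSV path.
#' @param eventPath optional event CSV path.
#' @param epochLength canonical epoch length, seconds.
#' @param tolerance permitted deviation from `epochLength`.
#' @return a [StateAnnotation-class].
#' @export
readAnnotation <- function(epochPath, eventPath = NULL, epochLength = 10,
                           tolerance = 1e-6) {
  ep <- utils::read.csv(epochPath, stringsAsFactors = FALSE)
  if (!all(c("start_s", "state") %in% names(ep)))
    stop("epoch CSV needs columns start_s, state")
  dur <- if ("duration_s" %in% names(ep)) ep$duration_s else
    rep(epochLength, nrow(ep))
  epochs <- data.frame(start = ep$start_s, duration = dur, state = ep$state,
                       stringsAsFactors = FALSE)
  events <- NULL
  if (!is.null(eventPath)) {
    ev <- utils::read.csv(eventPath, stringsAsFactors = FALSE)
    if (!all(c("time_s", "kind") %in% names(ev)))
      stop("event CSV needs columns time_s, kind")
    events <- data.frame(time = ev$time_s, kind = ev$kind,
                         payload = if ("payload" %in% names(ev))
                           ev$payload else "",
                         stringsAsFactors = FALSE)
  }
  stateAnnotation(epochs, events, epochLength = epochLength,
                  tolerance = tolerance)
}

#' Write a state annotation to CSV files
#'
#' @param ann a [StateAnnotation-class].
#' @param epochPath epoch CSV path.
#' @param eventPath optional event CSV path.
#' @return invisibly, `epochPath`.
#' @export
writeAnnotation <- function(ann, epochPath, eventPath = NULL) {
  ep <- epochs(ann)
  utils::write.csv(data.frame(start_s = ep$start, duration_s = ep$duration,
                              state = ep$state),
                   epochPath, row.names = FALSE)
  if (!is.null(eventPath)) {
    ev <- events(ann)
    utils::write.csv(data.frame(time_s = ev$time, kind = ev$kind,
                                payload = ev$payload),
                     eventPath, row.names = FALSE)
  }
  invisible(epochPath)
}
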