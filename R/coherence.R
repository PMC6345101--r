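## Magnitude-squared coherence, z'-transform, band summaries, coherograms,
## and the channel block-shuffle surrogate.

#' Welch-block magnitude-squared coherence
#'
#' msc(f) = |<X_b(f) Y_b*(f)>_b|^2 / (<|X_b|^2>_b <|Y_b|^2>_b) over the
#' same Hann-windowed overlapping blocks as [welchPsd()]. With the default
#' configuration (fs = 1024 Hz, nfft = 2048, overlap 0.5) a 100-s window
#' yields 99 blocks on a 0.5-Hz grid. Note the estimator has a positive
#' bias of about 1/nBlocks for uncoupled signals.
#'
#' @param x,y equal-length numeric vectors.
#' @param fs sampling rate, Hz.
#' @param nfft block size, samples.
#' @param overlap block overlap fraction.
#' @param pair character(2) channel names for bookkeeping.
#' @param window optional list describing the analysis window.
#' @return a [CoherenceProfile-class].
#' @examples
#' x <- rnorm(20480)
#' p <- mscProfile(x, x, fs = 1024)
#' all(abs(coherence(p) - 1) < 1e-9)
#' @export
mscProfile <- function(x, y, fs, nfft = 2048, overlap = 0.5,
                       pair = c("x", "y"), window = list()) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  bx <- welchBlocks(x, fs, nfft, overlap)
  by <- welchBlocks(y, fs, nfft, overlap)
  if (bx$nBlocks < 2)
    stop("need at least 2 blocks (MSC is identically 1 for a single block)")
  Sxx <- rowMeans(Mod(bx$X)^2)
  Syy <- rowMeans(Mod(by$X)^2)
  Sxy <- rowMeans(bx$X * Conj(by$X))
  den <- Sxx * Syy
  msc <- ifelse(den > 0, Mod(Sxy)^2 / den, 0)
  msc <- pmin(1, pmax(0, msc))
  new("CoherenceProfile", freqs = bx$freqs, msc = msc, sxx = Sxx,
      syy = Syy, sxy = Sxy, pair = pair,
      nBlocks = as.integer(bx$nBlocks), window = window)
}

#' Band magnitude-squared coherence
#'
#' Summary MSC over a band. The default `"pooled"` method aggregates the
#' spectra before forming the ratio,
#' |sum Sxy|^2 / (sum Sxx * sum Syy), which is the quantity the lumped
#' shared/independent power mixing model predicts (S^2/(S+N)^2) even when
#' the shared and independent components have different spectral shapes;
#' frequencies carrying no power contribute nothing. `"mean"` is the plain
#' mean of the per-frequency MSC over the band grid.
#'
#' @param profile a [CoherenceProfile-class].
#' @param band numeric(2) band edges, Hz (inclusive).
#' @param method `"pooled"` (default) or `"mean"`.
#' @return band MSC in [0, 1].
#' @export
bandMsc <- function(profile, band = c(30, 45),
                    method = c("pooled", "mean")) {
  method <- match.arg(method)
  if (band[1] > band[2]) stop("invalid band: lo > hi")
  sel <- profile@freqs >= band[1] & profile@freqs <= band[2]
  if (!any(sel)) stop("band contains no grid frequencies")
  if (method == "pooled" && length(profile@sxx)) {
    den <- sum(profile@sxx[sel]) * sum(profile@syy[sel])
    if (den <= 0) return(0)
    min(1, Mod(sum(profile@sxy[sel]))^2 / den)
  } else mean(profile@msc[sel])
}

#' Variance-stabilizing z'-transform of coherence
#'
#' z' = atanh(sqrt(msc)): strictly increasing, 0 at msc = 0, diverging as
#' msc approaches 1 (inputs are clipped at 1 - 1e-12 with a warning). The
#' alternative convention atanh(msc) is available via `method`.
#'
#' @param msc magnitude-squared coherence value(s) in [0, 1].
#' @param method `"atanh_sqrt"` (default) or `"atanh"`.
#' @return z' value(s), dimensionless and non-negative.
#' @examples
#' zTransform(0.75)  # atanh(sqrt(0.75))
#' @export
zTransform <- function(msc, method = c("atanh_sqrt", "atanh")) {
  method <- match.arg(method)
  if (any(msc < -1e-12 | msc > 1 + 1e-12, na.rm = TRUE))
    stop("msc values must lie in [0, 1]")
  msc <- pmin(pmax(msc, 0), 1)
  if (any(msc >= 1 - 1e-12)) {
    warning("msc at/near 1 clipped to 1 - 1e-12 before z'")
    msc <- pmin(msc, 1 - 1e-12)
  }
  if (method == "atanh_sqrt") atanh(sqrt(msc)) else atanh(msc)
}

#' Band-mean z'-coherence of a profile
#'
#' Mean of z'(msc(f)) over grid frequencies with lo <= f <= hi (inclusive
#' ends; the default 30-45 Hz band spans 31 points on the 0.5-Hz grid).
#'
#' @param profile a [CoherenceProfile-class].
#' @param band numeric(2) band edges, Hz.
#' @param zMethod passed to [zTransform()].
#' @return band-mean z', dimensionless.
#' @export
bandMeanZ <- function(profile, band = c(30, 45), zMethod = "atanh_sqrt") {
  if (band[1] > band[2]) stop("invalid band: lo > hi")
  sel <- profile@freqs >= band[1] & profile@freqs <= band[2]
  if (!any(sel)) stop("band contains no grid frequencies")
  mean(zTransform(profile@msc[sel], method = zMethod))
}

#' Summarize per-window z' values for one pair and state
#'
#' @param perWindowZ numeric vector of band z' values, one per window.
#' @param pair character(2) channel names.
#' @param state state label.
#' @param band numeric(2), Hz.
#' @return a [ZCoherenceSummary-class].
#' @export
zCoherenceSummary <- function(perWindowZ, pair, state, band = c(30, 45)) {
  new("ZCoherenceSummary", band = band, perWindowZ = perWindowZ,
      meanZ = mean(perWindowZ),
      seZ = if (length(perWindowZ) > 1)
        stats::sd(perWindowZ) / sqrt(length(perWindowZ)) else 0,
      pair = pair, state = state)
}

#' Time-resolved coherogram
#'
#' Sliding application of [mscProfile()] + [zTransform()]: one coherence
#' profile per `seg`-second segment advanced by `step` seconds, stamped at
#' the segment center.
#'
#' @param x,y equal-length numeric vectors.
#' @param fs sampling rate, Hz.
#' @param seg segment length, seconds.
#' @param step segment step, seconds.
#' @param nfft Welch block size within each segment.
#' @param overlap Welch overlap.
#' @param pair character(2) channel names.
#' @return a [Coherogram-class].
#' @export
coherogram <- function(x, y, fs, seg = 100, step = 10, nfft = 2048,
                       overlap = 0.5, pair = c("x", "y")) {
  if (step <= 0) stop("step must be positive")
  nSeg <- round(seg * fs)
  if (length(x) < nSeg) stop("signal shorter than one segment")
  starts <- seq(1, length(x) - nSeg + 1, by = round(step * fs))
  zRows <- NULL
  for (s in starts) {
    pr <- mscProfile(x[s:(s + nSeg - 1)], y[s:(s + nSeg - 1)], fs, nfft,
                     overlap, pair = pair)
    zRows <- rbind(zRows, zTransform(pr@msc))
  }
  new("Coherogram", times = (starts - 1) / fs + seg / 2,
      freqs = (0:(nfft %/% 2)) * fs / nfft, z = zRows, pair = pair)
}

#' Reorder a signal's analysis blocks
#'
#' Cuts `x` into consecutive non-overlapping blocks of `blockLen` samples
#' and concatenates them in the order `perm` (trailing samples that do not
#' fill a block are kept in place).
#'
#' @param x numeric vector.
#' @param blockLen block length, samples.
#' @param perm permutation of `seq_len(floor(length(x)/blockLen))`.
#' @return permuted numeric vector, same length as `x`.
#' @export
permuteBlocks <- function(x, blockLen, perm) {
  nb <- floor(length(x) / blockLen)
  if (length(perm) != nb || !setequal(perm, seq_len(nb)))
    stop("perm must be a permutation of the ", nb, " whole blocks")
  head_ <- x[seq_len(nb * blockLen)]
  m <- matrix(head_, nrow = blockLen)
  c(as.numeric(m[, perm]), x[-seq_len(nb * blockLen)])
}

#' Channel block-shuffle surrogate null for band coherence
#'
#' Permutes the order of `y`'s analysis blocks while leaving `x` untouched
#' and recomputes the band z' per permutation, yielding an empirical null
#' for the observed coupling. Blocks are non-overlapping and aligned with
#' the Welch grid, so the block-averaged PSD of the shuffled channel is
#' exactly invariant -- the shuffle destroys cross-channel alignment while
#' preserving each channel's spectrum.
#'
#' @param x,y equal-length numeric vectors.
#' @param fs sampling rate, Hz.
#' @param nShuffles number of random permutations.
#' @param blockDur block duration, seconds; `blockDur * fs` must equal
#'   `nfft` (the Welch alignment requirement).
#' @param nfft Welch block size.
#' @param band band for the summary statistic, Hz.
#' @param seed optional integer seed.
#' @return list with `observed` (band z' of the intact pair, non-overlap
#'   estimator), `null` (numeric vector of length `nShuffles`),
#'   `nullMean`, `nullSd`, `quantile` (fraction of null below observed)
#'   and `nBlocks`.
#' @export
shuffleSurrogate <- function(x, y, fs, nShuffles = 200, blockDur = 2,
                             nfft = 2048, band = c(30, 45), seed = NULL) {
  if (nShuffles < 1) stop("nShuffles must be >= 1")
  blockLen <- round(blockDur * fs)
  if (blockLen != nfft)
    stop("block misaligned: blockDur * fs (", blockLen,
         ") must equal nfft (", nfft, ")")
  if (length(x) != length(y)) stop("x and y must have equal length")
  nb <- floor(length(x) / nfft)
  if (nb < 2) stop("need at least 2 whole blocks")
  n <- nb * nfft
  bx <- welchBlocks(x[seq_len(n)], fs, nfft, overlap = 0)
  by <- welchBlocks(y[seq_len(n)], fs, nfft, overlap = 0)
  Sxx <- rowMeans(Mod(bx$X)^2)
  Syy <- rowMeans(Mod(by$X)^2)
  sel <- bx$freqs >= band[1] & bx$freqs <= band[2]
  bandZ <- function(Ymat) {
    Sxy <- rowMeans(bx$X * Conj(Ymat))
    den <- Sxx * Syy
    msc <- ifelse(den > 0, Mod(Sxy)^2 / den, 0)
    mean(zTransform(pmin(1, pmax(0, msc[sel]))))
  }
  observed <- bandZ(by$X)
  null <- withSeed(seed, vapply(seq_len(nShuffles), function(i)
    bandZ(by$X[, sample(nb)]), numeric(1)))
  list(observed = observed, null = null, nullMean = mean(null),
       nullSd = stats::sd(null), quantile = mean(null < observed),
       nBlocks = nb)
}
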