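## Power spectral estimation: Welch, multitaper (Slepian), Morlet wavelet.

## Windowed block FFTs shared by the Welch PSD and the coherence
## estimator: returns the complex one-sided FFT matrix (freq x block), the
## frequency grid, and the window power for normalization. With the
## defaults (fs = 1024, nfft = 2048, overlap 0.5) a 100-s signal yields 99
## blocks on a 0.5-Hz grid -- the canonical "100 time-blocks" setup.
welchBlocks <- function(x, fs, nfft = 2048, overlap = 0.5,
                        windowFn = hannWindow) {
  n <- length(x)
  if (n < nfft) stop("signal shorter than one block (nfft = ", nfft, ")")
  step <- max(1, round(nfft * (1 - overlap)))
  starts <- seq(1, n - nfft + 1, by = step)
  w <- windowFn(nfft)
  nf <- nfft %/% 2 + 1
  idx <- outer(seq_len(nfft) - 1L, as.integer(starts), `+`)
  X <- stats::mvfft(matrix(x[idx], nrow = nfft) * w)[seq_len(nf), ,
                                                     drop = FALSE]
  list(X = X, freqs = (seq_len(nf) - 1) * fs / nfft, U = sum(w^2),
       nBlocks = length(starts), nfft = nfft, fs = fs)
}

## One-sided PSD (uV^2/Hz) from a welchBlocks result.
psdFromBlocks <- function(bl) {
  p <- rowMeans(Mod(bl$X)^2) / (bl$fs * bl$U)
  nf <- length(p)
  scale <- rep(2, nf); scale[1] <- 1
  if (bl$nfft %% 2 == 0) scale[nf] <- 1
  p * scale
}

#' Welch power spectral density
#'
#' Average of Hann-windowed, overlapping block periodograms with density
#' normalization: the integral of the PSD over frequency equals the signal
#' variance (up to window-correction tolerance). With fs = 1024 Hz and
#' nfft = 2048 the frequency spacing is exactly 0.5 Hz.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param nfft block size, samples.
#' @param overlap block overlap fraction in [0, 1).
#' @return a [SpectralEstimate-class].
#' @examples
#' psd <- welchPsd(rnorm(102400), fs = 1024)
#' diff(frequencies(psd))[1]    # 0.5 Hz
#' @export
welchPsd <- function(x, fs, nfft = 2048, overlap = 0.5) {
  bl <- welchBlocks(x, fs, nfft, overlap)
  new("SpectralEstimate", freqs = bl$freqs, power = psdFromBlocks(bl),
      method = "welch",
      params = list(nfft = nfft, overlap = overlap, nBlocks = bl$nBlocks))
}

#' Band-average power
#'
#' Mean PSD over grid frequencies inside `band` (inclusive ends) times the
#' band width: the power (uV^2) attributed to the band.
#'
#' @param psd a [SpectralEstimate-class].
#' @param band numeric(2), Hz.
#' @return band power, uV^2.
#' @export
bandPower <- function(psd, band = c(30, 45)) {
  if (band[1] > band[2]) stop("invalid band: lo > hi")
  sel <- psd@freqs >= band[1] & psd@freqs <= band[2]
  if (!any(sel)) stop("band contains no grid frequencies")
  mean(psd@power[sel]) * (band[2] - band[1])
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' First `k` DPSS tapers of length `n` at time-bandwidth product `nw`,
#' computed from the symmetric tridiagonal formulation of the spectral
#' concentration problem. For `n` above `maxExact` the tapers are computed
#' at reduced length and spline-interpolated, then re-orthonormalized
#' (the standard low-memory construction).
#'
#' @param n taper length, samples.
#' @param nw time-bandwidth product.
#' @param k number of tapers (k <= 2*nw - 1 recommended).
#' @return n x k matrix; columns are unit-energy tapers.
#' @export
dpssTapers <- function(n, nw = 3, k = 5, maxExact = 512) {
  if (k > 2 * nw - 1)
    warning("k > 2*nw - 1: higher-order tapers are poorly concentrated")
  nEff <- min(n, maxExact)
  W <- nw / nEff
  i <- 0:(nEff - 1)
  diag_ <- ((nEff - 1 - 2 * i) / 2)^2 * cos(2 * pi * W)
  off <- (1:(nEff - 1)) * (nEff - (1:(nEff - 1))) / 2
  A <- matrix(0, nEff, nEff)
  A[cbind(i + 1, i + 1)] <- diag_
  A[cbind(1:(nEff - 1), 2:nEff)] <- off
  A[cbind(2:nEff, 1:(nEff - 1))] <- off
  eg <- eigen(A, symmetric = TRUE)
  V <- eg$vectors[, seq_len(k), drop = FALSE]
  if (nEff < n) {
    V <- apply(V, 2, function(v)
      stats::spline(seq(0, 1, length.out = nEff), v, n = n)$y)
    V <- qr.Q(qr(V))           # restore orthonormality after interpolation
  }
  ## sign convention: symmetric tapers positive mean, antisymmetric
  ## positive initial slope
  for (j in seq_len(k)) {
    s <- sum(V[, j])
    if (abs(s) > 1e-8) { if (s < 0) V[, j] <- -V[, j] }
    else if (V[2, j] - V[1, j] < 0) V[, j] <- -V[, j]
  }
  V / rep(sqrt(colSums(V^2)), each = n)
}

#' Multitaper spectrogram
#'
#' Sliding-window eigenspectrum average over Slepian tapers. Averaging k
#' orthogonal tapers reduces the variance of the spectral estimate by
#' about 1/k relative to a single taper.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param window segment length, seconds.
#' @param step segment step, seconds.
#' @param timeBandwidth time-bandwidth product NW.
#' @param nTapers number of tapers.
#' @return a [Spectrogram-class] (method "multitaper").
#' @export
multitaperSpectrogram <- function(x, fs, window = 2, step = 0.5,
                                  timeBandwidth = 3, nTapers = 5) {
  nWin <- round(window * fs)
  if (nWin > length(x)) stop("window longer than signal")
  nStep <- max(1, round(step * fs))
  tapers <- dpssTapers(nWin, timeBandwidth, nTapers)
  starts <- seq(1, length(x) - nWin + 1, by = nStep)
  nf <- nWin %/% 2 + 1
  P <- matrix(0, nrow = length(starts), ncol = nf)
  scale <- rep(2, nf); scale[1] <- 1
  if (nWin %% 2 == 0) scale[nf] <- 1
  for (s in seq_along(starts)) {
    seg <- x[starts[s]:(starts[s] + nWin - 1)]
    acc <- numeric(nf)
    for (j in seq_len(nTapers))
      acc <- acc + Mod(stats::fft(seg * tapers[, j])[seq_len(nf)])^2
    P[s, ] <- acc / nTapers / fs * scale
  }
  new("Spectrogram", times = (starts - 1 + nWin / 2) / fs,
      freqs = (seq_len(nf) - 1) * fs / nWin, power = P,
      method = "multitaper")
}

#' Morlet wavelet spectrogram
#'
#' Squared magnitude of the continuous wavelet transform with complex
#' Morlet kernels (`nCycles` cycles per frequency), computed by FFT
#' convolution. Favors time localization for visualizing individual gamma
#' bursts.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param freqs frequencies to evaluate, Hz.
#' @param nCycles cycles per kernel.
#' @param step time subsampling of the output, seconds (default one
#'   sample).
#' @return a [Spectrogram-class] (method "wavelet").
#' @export
morletSpectrogram <- function(x, fs, freqs = seq(30, 45, by = 0.5),
                              nCycles = 7, step = NULL) {
  if (!length(freqs)) stop("freqs must be non-empty")
  n <- length(x)
  keep <- if (is.null(step)) seq_len(n) else
    seq(1, n, by = max(1, round(step * fs)))
  P <- matrix(0, nrow = length(keep), ncol = length(freqs))
  nPad <- stats::nextn(2 * n, 2)
  X <- stats::fft(c(x, numeric(nPad - n)))
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    sdT <- nCycles / (2 * pi * f)
    half <- max(3, ceiling(3.5 * sdT * fs))
    tt <- (-half:half) / fs
    kern <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sdT^2))
    kern <- kern / sqrt(sum(Mod(kern)^2))     # unit-energy kernel
    K <- stats::fft(c(kern, complex(real = numeric(nPad - length(kern)))))
    conv <- stats::fft(X * K, inverse = TRUE) / nPad
    ## center the kernel: sample i of x aligns with conv index i + half
    P[, fi] <- Mod(conv[keep + half])^2
  }
  new("Spectrogram", times = (keep - 1) / fs, freqs = freqs, power = P,
      method = "wavelet")
}
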