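## Internal numeric helpers shared across estimators.

#' Hann window
#'
#' @param n window length in samples.
#' @param periodic logical; `TRUE` gives the DFT-periodic variant used for
#'   Welch blocks, `FALSE` the symmetric variant (zero at both endpoints).
#' @return numeric vector of length `n`.
#' @keywords internal
hannWindow <- function(n, periodic = TRUE) {
  if (n < 1) stop("window length must be >= 1")
  if (n == 1) return(1)
  denom <- if (periodic) n else n - 1
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / denom)
}

#' Analytic signal via the frequency domain
#'
#' Returns the complex analytic signal whose modulus is the instantaneous
#' amplitude envelope of `x`. `x` should already be band-limited.
#'
#' @param x numeric vector.
#' @return complex vector, same length as `x`.
#' @keywords internal
analyticSignal <- function(x) {
  n <- length(x)
  if (n == 0L) return(complex(0))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

## Evaluate expr under a temporary RNG seed, restoring the caller's RNG
## state afterwards. seed = NULL leaves the current stream untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

## Derive a reproducible child seed below 2^31 from a base seed and an index.
childSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1000003 + index * 7919) %% 2147483629)
}

## Subtract a set of closed exclusion intervals from [start, end] intervals.
## Both arguments are two-column matrices (start, end); returns the same.
intervalDiff <- function(intervals, exclusions) {
  if (is.null(exclusions) || nrow(exclusions) == 0) return(intervals)
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(intervals))) {
    segs <- intervals[i, , drop = FALSE]
    for (j in seq_len(nrow(exclusions))) {
      lo <- exclusions[j, 1]; hi <- exclusions[j, 2]
      nxt <- matrix(numeric(0), ncol = 2)
      for (k in seq_len(nrow(segs))) {
        a <- segs[k, 1]; b <- segs[k, 2]
        if (hi <= a || lo >= b) {            # no overlap
          nxt <- rbind(nxt, c(a, b))
        } else {
          if (lo > a) nxt <- rbind(nxt, c(a, lo))
          if (hi < b) nxt <- rbind(nxt, c(hi, b))
        }
      }
      segs <- nxt
      if (nrow(segs) == 0) break
    }
    out <- rbind(out, segs)
  }
  out
}

## Overlap length of [a1,a2] with [b1,b2].
overlapLength <- function(a1, a2, b1, b2) max(0, min(a2, b2) - max(a1, b1))
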