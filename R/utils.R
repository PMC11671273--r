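# Internal numerical helpers shared across modules.

#' @importFrom stats fft nextn
NULL

## Linear convolution of a real/complex signal with a kernel via FFT.
## Returns the "full" convolution of length length(x) + length(h) - 1.
convFull <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nf <- stats::nextn(n, 2L)
  y <- stats::fft(stats::fft(c(x, rep(0, nf - length(x)))) *
                  stats::fft(c(h, rep(0, nf - length(h)))), inverse = TRUE) / nf
  y[seq_len(n)]
}

## Reflect-pad a vector by `npad` samples at both ends (edge sample not repeated).
reflectPad <- function(x, npad) {
  n <- length(x)
  npad <- min(npad, n - 1L)
  c(x[(npad + 1L):2L], x, x[(n - 1L):(n - npad)])
}

## Zero-phase FIR filtering: reflect-pad by 3 filter lengths, convolve with the
## kernel forward and backward (net response h * rev(h), exactly zero phase),
## trim the padding.  `h` must be a plain numeric FIR impulse response.
filterZeroPhase <- function(x, h) {
  L <- length(h)
  npad <- min(3L * L, length(x) - 1L)
  xp <- reflectPad(x, npad)
  g <- Re(convFull(h, rev(h)))        # symmetric, length 2L-1, centre at L
  y <- Re(convFull(xp, g))
  y[(npad + L):(npad + L + length(x) - 1L)]
}

## Row-wise zero-phase filtering of a channels x samples matrix.
filterZeroPhaseMat <- function(mat, h) {
  out <- mat
  for (i in seq_len(nrow(mat))) out[i, ] <- filterZeroPhase(mat[i, ], h)
  out
}

## Analytic signal via frequency-domain Hilbert transform.
analyticSignal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  w <- numeric(n)
  if (n %% 2L == 0L) {
    w[1L] <- 1; w[n / 2L + 1L] <- 1; w[2L:(n / 2L)] <- 2
  } else {
    w[1L] <- 1; w[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * w, inverse = TRUE) / n
}

## Unit-sum Gaussian kernel sampled at `step` spacing, truncated at +-halfWidth.
gaussKernel <- function(sd, halfWidth, step) {
  x <- seq(-halfWidth, halfWidth, by = step)
  k <- exp(-x^2 / (2 * sd^2))
  k / sum(k)
}

## Sample indices for the half-open interval [startMs, endMs) at rate fs (Hz),
## sample 1 covering time 0.
halfOpenIdx <- function(startMs, endMs, fs) {
  i0 <- floor(startMs * fs / 1000) + 1L
  i1 <- ceiling(endMs * fs / 1000)
  if (endMs <= startMs) return(integer(0))
  seq.int(i0, i1)
}

## Phase unwrapping (cumulative removal of 2*pi jumps).
unwrapPhase <- function(p) {
  dp <- diff(p)
  jumps <- round(dp / (2 * pi))
  p - c(0, cumsum(jumps)) * 2 * pi + 0 * p  # keep length
}

## 1/f^alpha noise of length n at sampling rate fs, unit standard deviation
## scaled to `sd`; spectrum flattened below `fLow` to keep variance finite.
oneOverFNoise <- function(n, fs, alpha = 1, sd = 1, fLow = 1) {
  nf <- stats::nextn(n, 2L)
  f <- c(0, seq_len(nf / 2), seq.int(nf / 2 - 1L, 1L)) * fs / nf
  amp <- 1 / pmax(f, fLow)^(alpha / 2)
  amp[1L] <- 0
  ph <- stats::runif(nf, 0, 2 * pi)
  spec <- amp * exp(1i * ph)
  ## enforce Hermitian symmetry for a real signal
  spec[(nf / 2 + 2L):nf] <- Conj(spec[(nf / 2):2L])
  spec[nf / 2 + 1L] <- Re(spec[nf / 2 + 1L])
  x <- Re(stats::fft(spec, inverse = TRUE))[seq_len(n)]
  sd * (x - mean(x)) / stats::sd(x)
}

## Ornstein-Uhlenbeck process, stationary sd `sd`, time constant tauMs, step dtMs.
ouProcess <- function(n, sd, tauMs, dtMs) {
  if (sd <= 0) return(numeric(n))
  a <- exp(-dtMs / tauMs)
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - a^2))
  innov[1L] <- stats::rnorm(1, 0, sd)   # start in the stationary distribution
  as.numeric(stats::filter(innov, a, method = "recursive"))
}
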