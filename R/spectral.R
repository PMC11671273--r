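## Morlet wavelet time-frequency analysis, PSD with 1/f correction, and
## data-driven gamma-band determination.

#' Build a Morlet wavelet bank
#'
#' Complex Morlet wavelets \eqn{\Psi(t) = A e^{-t^2/2\sigma_t^2} e^{2\pi i f_0 t}}
#' with \eqn{f_0/\sigma_f = 6}, \eqn{\sigma_t = 1/(\pi\sigma_f)} and
#' \eqn{A = (\sigma_t\sqrt{\pi})^{-1/2}} so the total energy of each wavelet
#' is 1. Center frequencies follow a geometric grid
#' \eqn{f_0[i] = f_{min} 2^{i/v}} (v voices per octave, default 8) truncated
#' at \code{fmax}.
#'
#' @param fmin,fmax frequency range (Hz), default 5-160
#' @param voicesPerOctave grid density (default 8)
#' @param fs sampling rate of the signals to analyze (Hz, default 1,000)
#' @return list of class "WaveletBank": \code{freqs}, \code{sigmaT} (s),
#'   \code{sigmaF} (Hz), \code{wavelets} (list of complex vectors),
#'   \code{fs}, \code{nyquistHz}
#' @export
buildWaveletBank <- function(fmin = 5, fmax = 160, voicesPerOctave = 8,
                             fs = 1000) {
  if (!(fmin > 0 && fmin < fmax)) stop("need 0 < fmin < fmax")
  i <- 0:ceiling(voicesPerOctave * log2(fmax / fmin))
  f0 <- fmin * 2^(i / voicesPerOctave)
  f0 <- f0[f0 <= fmax + 1e-9]
  sigmaF <- f0 / 6
  sigmaT <- 1 / (pi * sigmaF)
  wavelets <- lapply(seq_along(f0), function(k) {
    st <- sigmaT[k]
    half <- ceiling(4 * st * fs)
    t <- (-half:half) / fs
    A <- (st * sqrt(pi))^(-1 / 2)
    A * exp(-t^2 / (2 * st^2)) * exp(2i * pi * f0[k] * t)
  })
  structure(list(freqs = f0, sigmaT = sigmaT, sigmaF = sigmaF,
                 wavelets = wavelets, fs = fs, nyquistHz = fs / 2),
            class = "WaveletBank")
}

#' @export
print.WaveletBank <- function(x, ...) {
  cat(sprintf("WaveletBank: %d Morlet wavelets, %g-%g Hz (f0/sigma_f = 6), fs = %g Hz\n",
              length(x$freqs), min(x$freqs), max(x$freqs), x$fs))
  invisible(x)
}

## Restrict a bank to frequencies within a band (used for gamma-band work).
bankSubset <- function(bank, bandHz) {
  keep <- bank$freqs >= bandHz[1L] - 1e-9 & bank$freqs <= bandHz[2L] + 1e-9
  if (!any(keep)) stop("no wavelet frequencies inside the band")
  structure(list(freqs = bank$freqs[keep], sigmaT = bank$sigmaT[keep],
                 sigmaF = bank$sigmaF[keep], wavelets = bank$wavelets[keep],
                 fs = bank$fs, nyquistHz = bank$nyquistHz),
            class = "WaveletBank")
}

#' Morlet wavelet transform
#'
#' Convolves a 1 kHz signal with every wavelet in the bank. Samples within
#' 3 sigma_t of either signal edge are flagged invalid per frequency and are
#' excluded from downstream PSD/PhC averaging.
#'
#' @param x numeric vector (one channel)
#' @param bank a \code{\link{buildWaveletBank}} result
#' @return list of class "Tfr": \code{coef} (freqs x time, complex),
#'   \code{freqs}, \code{fs}, \code{validFrom}, \code{validTo} (sample
#'   indices per frequency), \code{oneOverFCorrected = FALSE}
#' @export
waveletTransform <- function(x, bank) {
  n <- length(x)
  minLen <- ceiling(6 * min(bank$sigmaT) * bank$fs)
  if (n < minLen) stop("signal too short for every wavelet in the bank")
  nf <- length(bank$freqs)
  coef <- matrix(0i, nf, n)
  validFrom <- integer(nf); validTo <- integer(nf)
  for (k in seq_len(nf)) {
    w <- bank$wavelets[[k]]
    L <- length(w)               # odd, centered
    full <- convFull(x, w)       # length n + L - 1
    half <- (L - 1L) %/% 2L
    coef[k, ] <- full[(half + 1L):(half + n)] / bank$fs
    edge <- ceiling(3 * bank$sigmaT[k] * bank$fs)
    validFrom[k] <- min(edge + 1L, n)
    validTo[k] <- max(n - edge, 1L)
  }
  structure(list(coef = coef, freqs = bank$freqs, fs = bank$fs,
                 validFrom = validFrom, validTo = validTo,
                 oneOverFCorrected = FALSE), class = "Tfr")
}

#' @export
print.Tfr <- function(x, ...) {
  cat(sprintf("Tfr: %d freqs x %d samples at %g Hz (1/f corrected: %s)\n",
              nrow(x$coef), ncol(x$coef), x$fs, x$oneOverFCorrected))
  invisible(x)
}

#' Power spectrum from a wavelet transform
#'
#' PSD(f) = mean over the window of |W|^2 divided by the Nyquist frequency
#' (500 Hz at 1 kHz sampling); with \code{oneOverFCorrect} each value is
#' additionally multiplied by its wavelet center frequency to correct the
#' 1/f bias. Only samples flagged valid (outside the 3 sigma_t edge zones)
#' enter the average.
#'
#' @param tfr a \code{\link{waveletTransform}} result
#' @param windowMs half-open window in ms from trial start, or NULL for the
#'   full valid extent
#' @param oneOverFCorrect logical (default TRUE)
#' @return numeric vector of power values, one per center frequency
#' @export
psdSpectrum <- function(tfr, windowMs = NULL, oneOverFCorrect = TRUE) {
  n <- ncol(tfr$coef)
  idx <- if (is.null(windowMs)) seq_len(n)
         else halfOpenIdx(windowMs[1L], windowMs[2L], tfr$fs)
  if (length(idx) == 0L) stop("empty window")
  p <- vapply(seq_along(tfr$freqs), function(k) {
    use <- idx[idx >= tfr$validFrom[k] & idx <= tfr$validTo[k]]
    if (length(use) == 0L) return(NA_real_)
    mean(Mod(tfr$coef[k, use])^2) / (tfr$fs / 2)
  }, numeric(1))
  if (oneOverFCorrect) p <- p * tfr$freqs
  p
}

#' Determine the gamma band from a mean corrected PSD
#'
#' Finds the gamma peak (maximum of the 1/f-corrected mean PSD within the
#' search range, default 30-120 Hz) and returns the frequencies at which the
#' PSD crosses half the peak value on each side, using linear interpolation
#' between grid frequencies (the FWHM band).
#'
#' @param psd mean 1/f-corrected PSD (one value per frequency)
#' @param freqs wavelet center frequencies (Hz)
#' @param searchHz peak search range (default c(30, 120))
#' @return numeric c(loHz, hiHz)
#' @export
determineGammaBand <- function(psd, freqs, searchHz = c(30, 120)) {
  stopifnot(length(psd) == length(freqs))
  inRange <- which(freqs >= searchHz[1L] & freqs <= searchHz[2L])
  if (length(inRange) < 3L) stop("too few frequencies in the search range")
  sub <- psd[inRange]
  if (diff(range(sub)) < .Machine$double.eps * max(abs(sub), 1))
    stop("no gamma peak above the surrounding baseline")
  pk <- inRange[which.max(sub)]
  if (pk == inRange[1L] || pk == inRange[length(inRange)])
    stop("no gamma peak above the surrounding baseline")
  half <- psd[pk] / 2
  ## walk left
  lo <- freqs[1L]
  j <- pk
  while (j > 1L && psd[j - 1L] >= half) j <- j - 1L
  if (j > 1L) {
    lo <- freqs[j - 1L] + (freqs[j] - freqs[j - 1L]) *
      (half - psd[j - 1L]) / (psd[j] - psd[j - 1L])
  }
  ## walk right
  hi <- freqs[length(freqs)]
  j <- pk
  while (j < length(psd) && psd[j + 1L] >= half) j <- j + 1L
  if (j < length(psd)) {
    hi <- freqs[j] + (freqs[j + 1L] - freqs[j]) *
      (psd[j] - half) / (psd[j] - psd[j + 1L])
  }
  c(lo, hi)
}
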