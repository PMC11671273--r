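## Dominant gamma-frequency estimation from trough-to-trough cycle periods
## of above-median-amplitude gamma episodes.

#' Broad gamma band-pass filter
#'
#' Zero-phase FIR band-pass: passband 35-120 Hz, stop edges 25 and 140 Hz,
#' 20 dB suppression, applied forward and backward; signals must be at
#' 1,000 Hz.
#'
#' @param x numeric vector
#' @param fs sampling rate, must be 1,000 Hz
#' @return filtered vector
#' @export
bandpassGamma <- function(x, fs = 1000) {
  if (abs(fs - 1000) > 1e-9) stop("bandpassGamma expects 1,000 Hz signals")
  h <- firKaiser(c(35, 120), c(25, 140), 20, fs, "bandpass")
  if (length(x) <= length(h)) stop("series shorter than the filter")
  filterZeroPhase(x, h)
}

#' Instantaneous phase and amplitude of a narrowband signal
#'
#' Hilbert transform (analytic signal) yielding instantaneous phase in
#' (-pi, pi] and amplitude envelope; the envelope is smoothed with a
#' Gaussian (sigma = 10 ms, truncated at +-3 sigma, unit sum).
#'
#' @param x narrowband numeric vector
#' @param fs sampling rate (Hz, default 1,000)
#' @param smoothSdMs envelope smoothing SD in ms (default 10)
#' @return list(phase, amplitude)
#' @export
analyticPhaseAmplitude <- function(x, fs = 1000, smoothSdMs = 10) {
  if (length(x) == 0L) stop("empty series")
  a <- analyticSignal(x)
  amp <- Mod(a)
  sdSamp <- smoothSdMs * fs / 1000
  k <- gaussKernel(sdSamp, 3 * sdSamp, 1)
  half <- (length(k) - 1L) / 2L
  ampPad <- reflectPad(amp, half)
  ampSm <- Re(convFull(ampPad, k))[(2L * half + 1L):(2L * half + length(x))]
  list(phase = Arg(a), amplitude = ampSm)
}

#' Detect gamma troughs in above-median-amplitude episodes
#'
#' The median smoothed amplitude over the MC2/3 window is computed per trial.
#' Within maximal runs of at least 40 ms in which the amplitude continuously
#' exceeds that median, trough times are located where the unwrapped
#' instantaneous phase crosses \eqn{\pi + 2\pi k} (linear interpolation
#' between samples). Cycle periods are successive trough differences within
#' the same run; periods outside [1/120, 1/35] s are flagged not accepted.
#'
#' @param phase instantaneous phase (full trial, 1 kHz)
#' @param amplitude smoothed amplitude (full trial, 1 kHz)
#' @param windowMs analysis window c(startMs, endMs), typically MC2/3
#' @param fs sampling rate (Hz, default 1,000)
#' @param minRunMs minimum episode duration (ms, default 40)
#' @return list of class "CycleSeries": \code{troughTimesMs},
#'   \code{periodsS}, \code{accepted}
#' @export
detectGammaTroughs <- function(phase, amplitude, windowMs, fs = 1000,
                               minRunMs = 40) {
  idx <- halfOpenIdx(windowMs[1L], windowMs[2L], fs)
  if (length(idx) == 0L) stop("empty analysis window")
  amp <- amplitude[idx]
  med <- stats::median(amp)
  above <- amp > med
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  troughAll <- numeric(0)
  periods <- numeric(0)
  minRun <- minRunMs * fs / 1000
  for (j in seq_along(r$values)) {
    if (!r$values[j] || r$lengths[j] < minRun) next
    seg <- idx[starts[j]:ends[j]]
    u <- unwrapPhase(phase[seg])
    lev <- floor((u - pi) / (2 * pi))
    tt <- numeric(0)
    for (i in seq_len(length(u) - 1L)) {
      if (lev[i + 1L] > lev[i]) {
        for (m in (lev[i] + 1L):lev[i + 1L]) {
          v <- pi + 2 * pi * m
          frac <- (v - u[i]) / (u[i + 1L] - u[i])
          tt <- c(tt, (seg[i] - 1L + frac) / fs * 1000)
        }
      }
    }
    if (length(tt) >= 2L) periods <- c(periods, diff(tt) / 1000)
    troughAll <- c(troughAll, tt)
  }
  structure(list(troughTimesMs = troughAll, periodsS = periods,
                 accepted = periods >= 1 / 120 - 1e-12 &
                            periods <= 1 / 35 + 1e-12),
            class = "CycleSeries")
}

#' @export
print.CycleSeries <- function(x, ...) {
  cat(sprintf("CycleSeries: %d troughs, %d periods (%d accepted)\n",
              length(x$troughTimesMs), length(x$periodsS), sum(x$accepted)))
  invisible(x)
}

#' Dominant gamma frequency from pooled cycle periods
#'
#' Pools the accepted cycle periods of all supplied \code{CycleSeries}
#' (typically all trials of one session and attention condition) and returns
#' the reciprocal of their median. An even count uses the midpoint of the
#' two central periods.
#'
#' @param cycleSeriesList list of \code{\link{detectGammaTroughs}} results
#' @return list of class "DominantFrequency": \code{freqHz},
#'   \code{medianPeriodS}, \code{nCycles}
#' @export
dominantFrequencyFromPeriods <- function(cycleSeriesList) {
  if (inherits(cycleSeriesList, "CycleSeries"))
    cycleSeriesList <- list(cycleSeriesList)
  periods <- unlist(lapply(cycleSeriesList, function(cs)
    cs$periodsS[cs$accepted]))
  if (length(periods) == 0L) stop("no accepted gamma cycle periods")
  medP <- stats::median(periods)
  structure(list(freqHz = 1 / medP, medianPeriodS = medP,
                 nCycles = length(periods)), class = "DominantFrequency")
}

#' @export
print.DominantFrequency <- function(x, ...) {
  cat(sprintf("DominantFrequency: %.2f Hz (median of %d cycle periods)\n",
              x$freqHz, x$nCycles))
  invisible(x)
}

#' Dominant gamma frequency of a channel across trials
#'
#' Convenience wrapper running band-pass, Hilbert phase/amplitude and trough
#' detection over the MC2/3 window of every trial, then pooling periods.
#'
#' @param csdTrials list of \linkS4class{CsdTrial}
#' @param channel channel index
#' @param condition optional attention label filter
#' @return a "DominantFrequency" list
#' @export
dominantFrequencyOfChannel <- function(csdTrials, channel, condition = NULL) {
  if (!is.null(condition))
    csdTrials <- Filter(function(tr) tr@condition@attention == condition,
                        csdTrials)
  if (length(csdTrials) == 0L) stop("no trials for the requested condition")
  series <- lapply(csdTrials, function(tr) {
    nb <- bandpassGamma(tr@data[channel, ], tr@fs)
    pa <- analyticPhaseAmplitude(nb, tr@fs)
    detectGammaTroughs(pa$phase, pa$amplitude,
                       epochWindow(tr@epochs, "mc23"), tr@fs)
  })
  dominantFrequencyFromPeriods(series)
}
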