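## Gamma-power depth profiles and hotspot selection: one hotspot electrode
## per laminar domain, found as a discrete peak flanked by same-domain
## neighbors with lower power, or - failing that - by the gradient
## "hidden-peak" rule; plus the channel-inclusion rules.

#' Gamma-power depth profile
#'
#' Per channel: mean 1/f-corrected wavelet PSD within the gamma band over the
#' analysis window, averaged across the trials of one condition (or all
#' supplied trials).
#'
#' @param csdTrials list of \linkS4class{CsdTrial} (or other derived trials)
#' @param bank a \code{\link{buildWaveletBank}} result
#' @param bandHz gamma band c(lo, hi) in Hz
#' @param window epoch name or numeric window (ms), default "mc23"
#' @param condition optional attention label filter
#' @return numeric vector, one mean gamma power per channel
#' @export
gammaPowerDepthProfile <- function(csdTrials, bank, bandHz = c(42.5, 130.5),
                                   window = "mc23", condition = NULL) {
  if (!is.null(condition))
    csdTrials <- Filter(function(tr) tr@condition@attention == condition,
                        csdTrials)
  if (length(csdTrials) == 0L) stop("no trials for the requested condition")
  gb <- bankSubset(bank, bandHz)
  nCh <- nrow(csdTrials[[1L]]@data)
  acc <- numeric(nCh)
  for (tr in csdTrials) {
    win <- if (is.character(window)) epochWindow(tr@epochs, window) else window
    for (ch in seq_len(nCh)) {
      tfr <- waveletTransform(tr@data[ch, ], gb)
      acc[ch] <- acc[ch] + mean(psdSpectrum(tfr, win, oneOverFCorrect = TRUE))
    }
  }
  acc / length(csdTrials)
}

#' Find the gamma-power hotspot of one laminar domain
#'
#' Rule 1 (local peak): an interior channel of the domain strictly greater
#' than both same-domain neighbors; ties broken toward larger power, then
#' toward the more superficial channel. Rule 2 (hidden peak): on the first
#' differences g of the profile along the domain, an interior local minimum
#' of g with g > 0 on both sides (rising flank) selects the first electrode
#' of that pair; an interior local maximum of g with g < 0 on both sides
#' (falling flank) selects the second electrode. Otherwise no hotspot.
#'
#' @param profile gamma power per channel (whole probe)
#' @param domainChannels channel indices of the domain, superficial to deep
#' @return list(channel, method, power); channel is NA with method "none"
#'   when no hotspot is found
#' @export
findDomainHotspot <- function(profile, domainChannels) {
  p <- profile[domainChannels]
  m <- length(p)
  if (m < 3L) return(list(channel = NA_integer_, method = "none",
                          power = NA_real_))
  ## rule 1: strict interior local peak
  peaks <- which(vapply(2:(m - 1L), function(i)
    p[i] > p[i - 1L] && p[i] > p[i + 1L], logical(1))) + 1L
  if (length(peaks) > 0L) {
    best <- peaks[order(-p[peaks], peaks)][1L]
    ch <- domainChannels[best]
    return(list(channel = ch, method = "local_peak", power = profile[ch]))
  }
  ## rule 2: gradient extremum on a monotone flank
  g <- diff(p)                         # g[i] = p[i+1] - p[i], length m-1
  if (length(g) >= 3L) {
    for (i in 2:(length(g) - 1L)) {
      if (g[i] < g[i - 1L] && g[i] < g[i + 1L] &&
          g[i - 1L] > 0 && g[i + 1L] > 0) {
        ## local minimum of the gradient on a rising flank -> first electrode
        ch <- domainChannels[i]
        return(list(channel = ch, method = "gradient_rising",
                    power = profile[ch]))
      }
      if (g[i] > g[i - 1L] && g[i] > g[i + 1L] &&
          g[i - 1L] < 0 && g[i + 1L] < 0) {
        ## local maximum of the gradient on a falling flank -> second electrode
        ch <- domainChannels[i + 1L]
        return(list(channel = ch, method = "gradient_falling",
                    power = profile[ch]))
      }
    }
  }
  list(channel = NA_integer_, method = "none", power = NA_real_)
}

#' Detect hotspots in all three laminar domains
#'
#' @param profile gamma power per channel
#' @param assignment a \linkS4class{LaminarAssignment}
#' @return a \linkS4class{HotspotSet}
#' @export
detectHotspots <- function(profile, assignment) {
  rows <- lapply(c("SG", "G", "IG"), function(dm) {
    hs <- findDomainHotspot(profile, domainChannels(assignment, dm))
    data.frame(domain = dm, channel = hs$channel, method = hs$method,
               power = hs$power, stringsAsFactors = FALSE)
  })
  new("HotspotSet", table = do.call(rbind, rows))
}

#' Stimulus-response inclusion check for a hotspot electrode
#'
#' An electrode is included only when its gamma-band CSD power during MCs 2
#' and 3 is at least 2.5 times its gamma power during the baseline period.
#'
#' @param powerMc23 gamma power during MCs 2/3
#' @param powerBaseline gamma power during the baseline
#' @return logical
#' @export
checkHotspotInclusion <- function(powerMc23, powerBaseline) {
  stopifnot(powerMc23 >= 0)
  if (powerBaseline <= 0) stop("baseline power must be positive")
  powerMc23 >= 2.5 * powerBaseline
}

#' Select ESA source channels
#'
#' Keeps the two-thirds of channels (ceiling) with the strongest ESA gamma
#' power; ties broken toward the more superficial channel.
#'
#' @param esaGammaPower ESA gamma power per channel
#' @return sorted integer vector of selected channel indices
#' @export
selectEsaChannels <- function(esaGammaPower) {
  n <- length(esaGammaPower)
  if (n < 3L) stop("need at least 3 channels")
  k <- ceiling(2 * n / 3)
  ord <- order(-esaGammaPower, seq_len(n))
  sort(ord[seq_len(k)])
}
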