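## Bias-corrected phase coherence (phase-locking value) between hotspot CSD
## signals and ESA or CSD signals across depth.

#' Phase-locking value across trials
#'
#' \eqn{PhC(t) = |N^{-1}\sum_k e^{i(\phi_{a,k}(t) - \phi_{b,k}(t))}|} for two
#' sets of single-frequency phase time courses.
#'
#' @param phasesA,phasesB trials x time matrices of phases (radians), equal
#'   dimensions and trial alignment
#' @return numeric vector over time, values in [0, 1]
#' @export
phaseCoherenceTf <- function(phasesA, phasesB) {
  stopifnot(is.matrix(phasesA), all(dim(phasesA) == dim(phasesB)))
  if (nrow(phasesA) < 2L) stop("PhC needs at least 2 trials")
  Mod(colMeans(exp(1i * (phasesA - phasesB))))
}

#' Expected phase-locking value under random phases
#'
#' The mean resultant length of N unit phasors with independent uniform
#' phases: \eqn{EV(N) = \sqrt{\pi}/(2\sqrt{N})}. Subtracted from raw PhC to
#' correct the trial-count-dependent bias.
#'
#' @param N trial count (>= 1)
#' @return expected PLV
#' @export
expectedPlv <- function(N) {
  if (any(N < 1)) stop("N must be at least 1")
  sqrt(pi) / (2 * sqrt(N))
}

#' Spectrolaminar phase-coherence profile
#'
#' Corrected PhC between the CSD signal of a reference (hotspot) channel and
#' target signals at every depth and gamma-band wavelet frequency: per
#' channel and frequency the trial PLV is averaged over the valid part of
#' the analysis window and the expected value EV(N) is subtracted. For
#' \code{kind = "csd_csd"} the reference channel and its two adjacent
#' channels are excluded (NA); for \code{kind = "csd_esa"} the targets are
#' restricted to \code{targetChannels} (the selected ESA channels).
#'
#' @param refTrials list of \linkS4class{CsdTrial} supplying the reference
#' @param targetTrials list of \linkS4class{EsaTrial} or \linkS4class{CsdTrial},
#'   trial-aligned with \code{refTrials}
#' @param refChannel reference channel index
#' @param bank a \code{\link{buildWaveletBank}} result
#' @param bandHz gamma band for the summary (default c(42.5, 130.5))
#' @param window epoch name or numeric window in ms (default "mc23")
#' @param kind "csd_esa" or "csd_csd"
#' @param targetChannels channels to evaluate (default: all for csd_csd
#'   minus exclusions; required subset for csd_esa)
#' @return a \linkS4class{PhcProfile}
#' @export
spectrolaminarPhcProfile <- function(refTrials, targetTrials, refChannel,
                                     bank, bandHz = c(42.5, 130.5),
                                     window = "mc23",
                                     kind = c("csd_esa", "csd_csd"),
                                     targetChannels = NULL) {
  kind <- match.arg(kind)
  N <- length(refTrials)
  if (N < 2L || length(targetTrials) != N)
    stop("need >= 2 trial-aligned reference/target pairs")
  nCh <- nrow(targetTrials[[1L]]@data)
  gb <- bankSubset(bank, bandHz)
  nF <- length(gb$freqs)
  if (is.null(targetChannels)) targetChannels <- seq_len(nCh)
  if (kind == "csd_csd")
    targetChannels <- setdiff(targetChannels,
                              (refChannel - 1L):(refChannel + 1L))
  if (length(targetChannels) == 0L) stop("no eligible target channels")

  nT <- ncol(refTrials[[1L]]@data)
  acc <- array(0i, c(nCh, nF, nT))
  for (k in seq_len(N)) {
    refTfr <- waveletTransform(refTrials[[k]]@data[refChannel, ], gb)
    refPhasor <- exp(1i * Arg(refTfr$coef))
    for (ch in targetChannels) {
      tgt <- waveletTransform(targetTrials[[k]]@data[ch, ], gb)
      acc[ch, , ] <- acc[ch, , ] + refPhasor * exp(-1i * Arg(tgt$coef))
    }
    if (k == 1L) {
      validFrom <- refTfr$validFrom; validTo <- refTfr$validTo
    }
  }
  win <- if (is.character(window))
    epochWindow(refTrials[[1L]]@epochs, window) else window
  idx <- halfOpenIdx(win[1L], win[2L], 1000)
  values <- matrix(NA_real_, nCh, nF)
  for (ch in targetChannels) {
    for (f in seq_len(nF)) {
      use <- idx[idx >= validFrom[f] & idx <= validTo[f]]
      values[ch, f] <- mean(Mod(acc[ch, f, use] / N)) - expectedPlv(N)
    }
  }
  new("PhcProfile", values = values, freqs = gb$freqs,
      gammaSummary = rowMeans(values), bandHz = bandHz,
      nTrials = as.integer(N), kind = kind,
      refChannel = as.integer(refChannel), biasCorrected = TRUE)
}

#' Normalized domain-preference profile
#'
#' Given the gamma-band PhC depth profiles referenced to the SG, G and IG
#' hotspots, returns for each depth the ratio of each value to the sum of
#' the three values at that depth. Depths with a nonpositive sum (or any
#' missing value) are NA.
#'
#' @param profiles list of three numeric vectors (per-channel gamma PhC),
#'   in the order SG, G, IG
#' @return 3 x channels matrix of ratios; columns sum to 1 where defined
#' @export
normalizedDomainPreference <- function(profiles) {
  stopifnot(length(profiles) == 3L)
  m <- do.call(rbind, profiles)
  sums <- colSums(m)
  ratios <- sweep(m, 2L, sums, "/")
  ratios[, !is.finite(sums) | sums <= 0] <- NA_real_
  rownames(ratios) <- c("SG", "G", "IG")
  ratios
}

#' Attention contrast of inter-domain phase coherence
#'
#' For a hotspot in one domain, selects the partner electrode in a second
#' domain with the highest attend-in gamma PhC with the hotspot (ties broken
#' toward the more superficial channel) and returns the gamma-band mean
#' corrected PhC at that electrode pair in the attend-in and attend-nearby
#' conditions.
#'
#' @param csdTrialsIn,csdTrialsNearby lists of \linkS4class{CsdTrial} for the
#'   two conditions
#' @param refChannel hotspot channel (reference domain)
#' @param partnerChannels candidate channels of the other domain
#' @param bank a \code{\link{buildWaveletBank}} result
#' @param bandHz gamma band (default c(42.5, 130.5))
#' @return list(partner, phcAttendIn, phcAttendNearby)
#' @export
attentionPhcContrast <- function(csdTrialsIn, csdTrialsNearby, refChannel,
                                 partnerChannels, bank,
                                 bandHz = c(42.5, 130.5)) {
  if (length(partnerChannels) == 0L) stop("no candidate partner channels")
  profIn <- spectrolaminarPhcProfile(csdTrialsIn, csdTrialsIn, refChannel,
                                     bank, bandHz, kind = "csd_csd",
                                     targetChannels = partnerChannels)
  gIn <- phcGammaSummary(profIn)
  cand <- intersect(partnerChannels,
                    setdiff(partnerChannels,
                            (refChannel - 1L):(refChannel + 1L)))
  best <- cand[order(-gIn[cand], cand)][1L]
  profNb <- spectrolaminarPhcProfile(csdTrialsNearby, csdTrialsNearby,
                                     refChannel, bank, bandHz,
                                     kind = "csd_csd",
                                     targetChannels = best)
  list(partner = best, phcAttendIn = gIn[best],
       phcAttendNearby = phcGammaSummary(profNb)[best])
}

#' Depth-aligned median PhC profile across sessions
#'
#' Aligns per-session gamma-PhC depth profiles by the layer-III/IV border
#' (depth relative to the border) and takes the median across sessions at
#' each relative depth. Depths covered by fewer than two-thirds (ceiling) of
#' the sessions are omitted (NA).
#'
#' @param profiles list of numeric vectors, one per session, named by
#'   border-relative depth in micrometers
#' @return named numeric vector: median profile over the union of depths
#' @export
averageProfilesAcrossSessions <- function(profiles) {
  if (length(profiles) < 2L) stop("need at least 2 sessions")
  depths <- sort(unique(as.numeric(unlist(lapply(profiles, names)))))
  need <- ceiling(2 * length(profiles) / 3)
  out <- vapply(depths, function(d) {
    vals <- unlist(lapply(profiles, function(p) {
      v <- p[as.character(d)]
      if (is.null(v) || is.na(v)) NULL else as.numeric(v)
    }))
    if (length(vals) < need) NA_real_ else stats::median(vals)
  }, numeric(1))
  names(out) <- depths
  out
}
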