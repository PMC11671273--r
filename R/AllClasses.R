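#' @import methods
NULL

## ---------------------------------------------------------------------------
## Core S4 containers.  Conventions used throughout the package:
##   * time is milliseconds from trial start, intervals are half-open [a, b);
##   * channel 1 is the most superficial contact, depth increases downward;
##   * depths are micrometers below the topmost contact;
##   * CSD sign convention: sinks negative, sources positive.
## ---------------------------------------------------------------------------

#' Laminar probe geometry
#'
#' Describes a linear multi-contact probe: number of contacts and the
#' center-to-center spacing. Contact 1 is the most superficial; the depth of
#' contact \eqn{i} is \eqn{(i-1)\times\mathrm{pitch}} micrometers below it.
#'
#' @slot nChannels integer, number of contacts (at least 4; typically 16 or 32)
#' @slot pitchUm contact spacing in micrometers (default 100)
#' @export
setClass("ProbeGeometry",
  representation(nChannels = "integer", pitchUm = "numeric"),
  validity = function(object) {
    if (length(object@nChannels) != 1L || object@nChannels < 4L)
      return("nChannels must be a single integer >= 4")
    if (length(object@pitchUm) != 1L || object@pitchUm <= 0)
      return("pitchUm must be a single positive number")
    TRUE
  })

#' @rdname ProbeGeometry-class
#' @param nChannels number of contacts
#' @param pitchUm contact spacing (micrometers)
#' @return a \code{ProbeGeometry} object
#' @examples
#' probeGeometry(16)
#' @export
probeGeometry <- function(nChannels = 16L, pitchUm = 100) {
  new("ProbeGeometry", nChannels = as.integer(nChannels), pitchUm = pitchUm)
}

#' Trial epoch structure
#'
#' Timing of the task epochs within one trial: a 1,050 ms baseline with only
#' the fixation point, stimulus onset, a 520 ms static period, and successive
#' 1,000 ms morph cycles (MCs). When the lever release falls inside the
#' analysed MC2/3 window, analysis stops 150 ms before it; otherwise at the
#' end of MC3.
#'
#' @slot fsRaw raw sampling rate (Hz)
#' @slot baselineMs numeric length 2, the baseline interval (default [0, 1050))
#' @slot stimOnsetMs stimulus onset (ms)
#' @slot staticEndMs end of the static period (= onset + 520 ms)
#' @slot mcBoundsMs morph-cycle boundaries (length nMC + 1, contiguous 1,000 ms)
#' @slot leverReleaseMs lever release time (ms) or NA
#' @slot analysisEndMs end of the analysed window (ms)
#' @export
setClass("TrialEpochs",
  representation(fsRaw = "numeric", baselineMs = "numeric",
                 stimOnsetMs = "numeric", staticEndMs = "numeric",
                 mcBoundsMs = "numeric", leverReleaseMs = "numeric",
                 analysisEndMs = "numeric"),
  validity = function(object) {
    if (object@fsRaw <= 0) return("fsRaw must be positive")
    if (length(object@baselineMs) != 2L) return("baselineMs must have length 2")
    if (length(object@mcBoundsMs) < 2L) return("need at least one morph cycle")
    if (any(abs(diff(object@mcBoundsMs) - 1000) > 1e-9))
      return("morph cycles must be contiguous and exactly 1,000 ms long")
    if (abs(object@staticEndMs - (object@stimOnsetMs + 520)) > 1e-9)
      return("static period must end 520 ms after stimulus onset")
    TRUE
  })

#' @rdname TrialEpochs-class
#' @param fsRaw raw sampling rate (Hz)
#' @param nMc number of morph cycles (default 3)
#' @param leverReleaseMs lever release time in ms, or NA if absent
#' @param baselineMs baseline duration (ms)
#' @param staticMs static-period duration (ms)
#' @return a \code{TrialEpochs} object; \code{analysisEndMs} is set to
#'   \code{leverReleaseMs - 150} when that lies inside the MC2/3 window, else
#'   to the end of MC3.
#' @export
trialEpochs <- function(fsRaw, nMc = 3L, leverReleaseMs = NA_real_,
                        baselineMs = 1050, staticMs = 520) {
  onset <- baselineMs
  staticEnd <- onset + staticMs
  bounds <- staticEnd + 1000 * (0:nMc)
  mc3End <- if (nMc >= 3L) bounds[4L] else bounds[length(bounds)]
  analysisEnd <- mc3End
  if (is.finite(leverReleaseMs) && leverReleaseMs > bounds[2L] &&
      leverReleaseMs <= mc3End) {
    analysisEnd <- max(leverReleaseMs - 150, bounds[2L])
  }
  new("TrialEpochs", fsRaw = fsRaw, baselineMs = c(0, baselineMs),
      stimOnsetMs = onset, staticEndMs = staticEnd, mcBoundsMs = bounds,
      leverReleaseMs = as.numeric(leverReleaseMs), analysisEndMs = analysisEnd)
}

#' Trial condition labels
#'
#' Attention condition and stimulus/behavioral flags for one trial. Exactly
#' one attention label (\code{attend_in}, \code{attend_nearby},
#' \code{attend_away}) applies per trial.
#'
#' @slot attention one of "attend_in", "attend_nearby", "attend_away"
#' @slot rfStimPresent was a stimulus shown in the recorded receptive fields?
#' @slot nearbyStimPresent was the nearby distractor shown?
#' @slot correct was the trial performed correctly?
#' @export
setClass("Condition",
  representation(attention = "character", rfStimPresent = "logical",
                 nearbyStimPresent = "logical", correct = "logical"),
  validity = function(object) {
    if (length(object@attention) != 1L ||
        !object@attention %in% c("attend_in", "attend_nearby", "attend_away"))
      return("attention must be one of attend_in/attend_nearby/attend_away")
    TRUE
  })

#' @rdname Condition-class
#' @param attention attention label
#' @param rfStimPresent,nearbyStimPresent,correct logical flags
#' @return a \code{Condition} object
#' @export
condition <- function(attention, rfStimPresent = TRUE,
                      nearbyStimPresent = TRUE, correct = TRUE) {
  new("Condition", attention = attention, rfStimPresent = rfStimPresent,
      nearbyStimPresent = nearbyStimPresent, correct = correct)
}

## Shared layout of all trial-signal classes: channels/positions x samples.
setClass("NeuralTrial",
  representation("VIRTUAL", data = "matrix", fs = "numeric",
                 epochs = "TrialEpochs", condition = "Condition"),
  validity = function(object) {
    if (!is.numeric(object@data)) return("data must be numeric")
    if (any(!is.finite(object@data))) return("data contains non-finite samples")
    TRUE
  })

#' Broadband trial
#'
#' One trial of raw multichannel traces (volts, arbitrary gain) at the raw
#' sampling rate, rows ordered superficial to deep.
#' @slot data channels x samples matrix
#' @slot fs sampling rate (Hz)
#' @slot epochs a \linkS4class{TrialEpochs}
#' @slot condition a \linkS4class{Condition}
#' @export
setClass("BroadbandTrial", contains = "NeuralTrial")

#' @rdname BroadbandTrial-class
#' @param data channels x samples matrix
#' @param fs sampling rate (Hz)
#' @param epochs a \code{TrialEpochs}
#' @param condition a \code{Condition}
#' @export
broadbandTrial <- function(data, fs, epochs, condition) {
  new("BroadbandTrial", data = data, fs = fs, epochs = epochs,
      condition = condition)
}

## Derived 1 kHz signals with an explicit depth axis.
setClass("DerivedTrial", contains = "NeuralTrial",
  representation("VIRTUAL", depthsUm = "numeric"),
  validity = function(object) {
    if (abs(object@fs - 1000) > 1e-9) return("derived signals must be at 1,000 Hz")
    if (length(object@depthsUm) != nrow(object@data))
      return("depthsUm must match the number of rows")
    TRUE
  })

#' Derived per-trial signals at 1 kHz
#'
#' \code{LfpTrial}, \code{EsaTrial} and \code{CsdTrial} hold, respectively,
#' the low-passed local field potential, the entire spiking activity envelope,
#' and the current source density (positions coincide with electrode depths),
#' all downsampled to 1,000 Hz.
#' @slot data positions x samples matrix
#' @slot fs sampling rate, fixed at 1,000 Hz
#' @slot depthsUm depth of each row (micrometers)
#' @slot epochs a \linkS4class{TrialEpochs}
#' @slot condition a \linkS4class{Condition}
#' @aliases EsaTrial-class CsdTrial-class
#' @export
setClass("LfpTrial", contains = "DerivedTrial")
#' @rdname LfpTrial-class
#' @export
setClass("EsaTrial", contains = "DerivedTrial")
#' @rdname LfpTrial-class
#' @export
setClass("CsdTrial", contains = "DerivedTrial")

#' @rdname LfpTrial-class
#' @param class one of "LfpTrial", "EsaTrial", "CsdTrial"
#' @param data positions x samples matrix
#' @param depthsUm row depths (micrometers)
#' @param epochs a \code{TrialEpochs}
#' @param condition a \code{Condition}
#' @export
derivedTrial <- function(class, data, depthsUm, epochs, condition) {
  new(class, data = data, fs = 1000, depthsUm = depthsUm, epochs = epochs,
      condition = condition)
}

#' Recording session
#'
#' An ordered collection of trials sharing one probe and sampling rate, plus
#' session-level behavioral performance (fraction of correct responses,
#' disregarding fixation breaks) and provenance metadata.
#'
#' @slot probe a \linkS4class{ProbeGeometry}
#' @slot trials list of \linkS4class{BroadbandTrial}
#' @slot performance fraction correct in [0, 1]
#' @slot metadata free-form list (seed, generator parameters, ...)
#' @export
setClass("Session",
  representation(probe = "ProbeGeometry", trials = "list",
                 performance = "numeric", metadata = "list"),
  validity = function(object) {
    n <- object@probe@nChannels
    for (tr in object@trials) {
      if (!is(tr, "BroadbandTrial")) return("trials must be BroadbandTrial objects")
      if (nrow(tr@data) != n) return("trial channel count does not match probe")
    }
    fss <- vapply(object@trials, function(tr) tr@fs, numeric(1))
    if (length(fss) > 1L && any(abs(diff(fss)) > 1e-9))
      return("all trials must share one sampling rate")
    if (object@performance < 0 || object@performance > 1)
      return("performance must lie in [0, 1]")
    TRUE
  })

#' @rdname Session-class
#' @param probe a \code{ProbeGeometry}
#' @param trials list of \code{BroadbandTrial}
#' @param performance fraction of correct trials
#' @param metadata provenance list
#' @export
session <- function(probe, trials, performance = 1, metadata = list()) {
  new("Session", probe = probe, trials = trials, performance = performance,
      metadata = metadata)
}

#' Laminar domain assignment
#'
#' The layer-III/IV border depth and the laminar domain of each contact:
#' supragranular (SG) strictly above the border, granular (G) from the border
#' down to 500 um below it, infragranular (IG) further below.
#'
#' @slot borderUm border depth (micrometers)
#' @slot domains character vector per channel, values "SG", "G", "IG"
#' @slot depthsUm channel depths
#' @slot method "polarity" or "refined"
#' @export
setClass("LaminarAssignment",
  representation(borderUm = "numeric", domains = "character",
                 depthsUm = "numeric", method = "character"),
  validity = function(object) {
    if (length(object@domains) != length(object@depthsUm))
      return("domains and depthsUm must have equal length")
    if (!all(object@domains %in% c("SG", "G", "IG")))
      return("domains must be SG/G/IG")
    sg <- object@domains == "SG"
    if (any(object@depthsUm[sg] >= object@borderUm))
      return("SG channels must lie strictly above the border")
    g <- object@domains == "G"
    if (any(object@depthsUm[g] < object@borderUm |
            object@depthsUm[g] > object@borderUm + 500))
      return("G channels must lie within [border, border + 500 um]")
    ig <- object@domains == "IG"
    if (any(object@depthsUm[ig] <= object@borderUm + 500))
      return("IG channels must lie below border + 500 um")
    TRUE
  })

#' Gamma-power hotspots
#'
#' One gamma-power hotspot electrode per laminar domain, with the detection
#' method ("local_peak", "gradient_rising", "gradient_falling" or "none") and
#' the gamma power at the selected contact.
#'
#' @slot table data.frame with columns domain, channel, method, power
#' @export
setClass("HotspotSet",
  representation(table = "data.frame"),
  validity = function(object) {
    need <- c("domain", "channel", "method", "power")
    if (!all(need %in% names(object@table)))
      return("table must have columns domain, channel, method, power")
    TRUE
  })

#' Spectrolaminar phase-coherence profile
#'
#' Bias-corrected phase-locking values between a reference hotspot CSD signal
#' and target signals (ESA or CSD) at every depth and wavelet frequency.
#' Channels excluded by the selection rules carry NA.
#'
#' @slot values channels x frequency matrix of corrected PhC
#' @slot freqs wavelet center frequencies (Hz)
#' @slot gammaSummary per-channel mean corrected PhC over the gamma band
#' @slot bandHz the gamma band used for the summary
#' @slot nTrials trial count N entering the PLV
#' @slot kind "csd_esa" or "csd_csd"
#' @slot refChannel reference (hotspot) channel index
#' @slot biasCorrected logical flag
#' @export
setClass("PhcProfile",
  representation(values = "matrix", freqs = "numeric", gammaSummary = "numeric",
                 bandHz = "numeric", nTrials = "integer", kind = "character",
                 refChannel = "integer", biasCorrected = "logical"),
  validity = function(object) {
    if (object@nTrials < 2L) return("PhC needs at least 2 trials")
    if (!object@kind %in% c("csd_esa", "csd_csd"))
      return("kind must be csd_esa or csd_csd")
    if (ncol(object@values) != length(object@freqs))
      return("values columns must match freqs")
    TRUE
  })
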