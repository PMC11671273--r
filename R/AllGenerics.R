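#' Accessors for probe and trial objects
#'
#' \code{depthsUm} returns contact depths in micrometers below the topmost
#' contact; \code{nChannels} the number of contacts; \code{trialData} the
#' channels x samples matrix; \code{samplingRate} the rate in Hz;
#' \code{trialEpochsOf} and \code{trialCondition} the epoch and condition
#' objects; \code{domainOf} the laminar domain label per channel.
#'
#' @param object a package object
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("depthsUm", function(object) standardGeneric("depthsUm"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("trialData", function(object) standardGeneric("trialData"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("trialEpochsOf", function(object) standardGeneric("trialEpochsOf"))
#' @rdname accessors
#' @export
setGeneric("trialCondition", function(object) standardGeneric("trialCondition"))
#' @rdname accessors
#' @export
setGeneric("domainOf", function(object) standardGeneric("domainOf"))
#' @rdname accessors
#' @export
setGeneric("borderDepth", function(object) standardGeneric("borderDepth"))
#' @rdname accessors
#' @export
setGeneric("hotspotChannel", function(object, domain) standardGeneric("hotspotChannel"))

#' @rdname accessors
#' @export
setMethod("depthsUm", "ProbeGeometry", function(object)
  (seq_len(object@nChannels) - 1) * object@pitchUm)
#' @rdname accessors
#' @export
setMethod("depthsUm", "DerivedTrial", function(object) object@depthsUm)
#' @rdname accessors
#' @export
setMethod("depthsUm", "LaminarAssignment", function(object) object@depthsUm)
#' @rdname accessors
#' @export
setMethod("nChannels", "ProbeGeometry", function(object) object@nChannels)
#' @rdname accessors
#' @export
setMethod("nChannels", "NeuralTrial", function(object) nrow(object@data))
#' @rdname accessors
#' @export
setMethod("trialData", "NeuralTrial", function(object) object@data)
#' @rdname accessors
#' @export
setMethod("samplingRate", "NeuralTrial", function(object) object@fs)
#' @rdname accessors
#' @export
setMethod("trialEpochsOf", "NeuralTrial", function(object) object@epochs)
#' @rdname accessors
#' @export
setMethod("trialCondition", "NeuralTrial", function(object) object@condition)
#' @rdname accessors
#' @export
setMethod("domainOf", "LaminarAssignment", function(object) object@domains)
#' @rdname accessors
#' @export
setMethod("borderDepth", "LaminarAssignment", function(object) object@borderUm)

#' @rdname accessors
#' @param domain one of "SG", "G", "IG"
#' @export
setMethod("hotspotChannel", "HotspotSet", function(object, domain) {
  row <- object@table[object@table$domain == domain, , drop = FALSE]
  if (nrow(row) == 0L || is.na(row$channel[1L])) return(NA_integer_)
  as.integer(row$channel[1L])
})

#' @describeIn accessors hotspot summary table (domain, channel, method, power)
#' @export
hotspotTable <- function(object) object@table

#' @describeIn accessors corrected PhC matrix of a profile
#' @export
phcValues <- function(object) object@values

#' @describeIn accessors per-channel gamma-band PhC summary of a profile
#' @export
phcGammaSummary <- function(object) object@gammaSummary

setMethod("show", "ProbeGeometry", function(object) {
  cat(sprintf("ProbeGeometry: %d contacts, %g um pitch (span %g um)\n",
              object@nChannels, object@pitchUm,
              (object@nChannels - 1) * object@pitchUm))
})

setMethod("show", "Session", function(object) {
  att <- vapply(object@trials, function(tr) tr@condition@attention, character(1))
  cat(sprintf("Session: %d trials on a %d-channel probe, performance %.2f\n",
              length(object@trials), object@probe@nChannels,
              object@performance))
  if (length(att)) print(table(att))
})

setMethod("show", "NeuralTrial", function(object) {
  cat(sprintf("%s: %d channels x %d samples at %g Hz (%s)\n",
              class(object), nrow(object@data), ncol(object@data), object@fs,
              object@condition@attention))
})

setMethod("show", "LaminarAssignment", function(object) {
  cat(sprintf("LaminarAssignment (%s): layer-III/IV border at %g um\n",
              object@method, object@borderUm))
  print(table(factor(object@domains, levels = c("SG", "G", "IG"))))
})

setMethod("show", "HotspotSet", function(object) {
  cat("HotspotSet:\n")
  print(object@table, row.names = FALSE)
})

setMethod("show", "PhcProfile", function(object) {
  cat(sprintf(
    "PhcProfile (%s): %d channels x %d freqs, N = %d trials, band %g-%g Hz\n",
    object@kind, nrow(object@values), ncol(object@values), object@nTrials,
    object@bandHz[1L], object@bandHz[2L]))
})
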