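## Spline inverse current source density (iCSD).
##
## Volume-conductor model: current sources are evenly distributed in
## cylindrical discs (radius R) stacked along the column axis in an isotropic
## medium of conductivity sigma; the CSD varies smoothly with depth as a
## natural cubic spline through the electrode positions and is zero beyond
## the end knots.

#' iCSD parameters
#'
#' @param discRadiusUm disc radius R (micrometers, default 500)
#' @param conductivitySm medium conductivity sigma (S/m, default 0.4)
#' @param smoothSdUm SD of the spatial Gaussian smoother (default 200)
#' @param smoothWindowUm finite window of the smoother (default 1,000)
#' @param gridStepUm quadrature step for the forward integrals (default 5)
#' @return a list of class "ICsdParams"
#' @export
icsdParams <- function(discRadiusUm = 500, conductivitySm = 0.4,
                       smoothSdUm = 200, smoothWindowUm = 1000,
                       gridStepUm = 5) {
  stopifnot(discRadiusUm > 0, conductivitySm > 0, smoothSdUm > 0,
            smoothWindowUm >= 2 * smoothSdUm, gridStepUm > 0)
  structure(list(discRadiusUm = discRadiusUm, conductivitySm = conductivitySm,
                 smoothSdUm = smoothSdUm, smoothWindowUm = smoothWindowUm,
                 gridStepUm = gridStepUm), class = "ICsdParams")
}

#' Disc-source potential kernel
#'
#' Potential at vertical distance dz from a disc of homogeneous CSD with unit
#' source density times thickness: \eqn{(1/2\sigma)(\sqrt{dz^2+R^2}-|dz|)}
#' (SI units, m^2/S). Multiplying by a CSD (A/m^3) and a disc thickness (m)
#' yields volts.
#'
#' @param dzUm vertical distance(s) in micrometers
#' @param params an \code{\link{icsdParams}} list
#' @return kernel value(s), m^2/S
#' @export
discPotentialKernel <- function(dzUm, params = icsdParams()) {
  dz <- dzUm * 1e-6
  R <- params$discRadiusUm * 1e-6
  (sqrt(dz^2 + R^2) - abs(dz)) / (2 * params$conductivitySm)
}

## Forward operator mapping CSD values on a fine depth grid (A/m^3) to
## potentials (V) at the electrode depths; includes trapezoid weights.
discForwardOperator <- function(elDepthsUm, zGridUm, params) {
  stepM <- (zGridUm[2L] - zGridUm[1L]) * 1e-6
  w <- rep(1, length(zGridUm)); w[c(1L, length(w))] <- 0.5
  K <- outer(elDepthsUm, zGridUm,
             function(a, b) discPotentialKernel(a - b, params))
  K * rep(w * stepM, each = length(elDepthsUm))
}

#' Build the spline iCSD forward matrix
#'
#' Column k holds the potentials at all electrodes generated by the natural
#' cubic spline CSD basis element that is 1 at knot k (electrode depth k) and
#' 0 at the other knots, zero beyond the end knots, integrated against the
#' disc kernel on a fine quadrature grid.
#'
#' @param probe a \linkS4class{ProbeGeometry}
#' @param params an \code{\link{icsdParams}} list
#' @return list of class "ForwardMatrix" with elements \code{F} (n x n),
#'   \code{probe}, \code{params}
#' @export
buildForwardMatrix <- function(probe, params = icsdParams()) {
  d <- depthsUm(probe)
  n <- length(d)
  if (n < 4L) stop("spline iCSD needs at least 4 electrodes")
  z <- seq(d[1L], d[n], by = params$gridStepUm)
  K <- discForwardOperator(d, z, params)
  B <- vapply(seq_len(n), function(k) {
    e <- numeric(n); e[k] <- 1
    stats::spline(d, e, xout = z, method = "natural")$y
  }, numeric(length(z)))
  Fm <- K %*% B
  structure(list(F = Fm, Finv = solve(Fm), probe = probe, params = params),
            class = "ForwardMatrix")
}

#' @export
print.ForwardMatrix <- function(x, ...) {
  cat(sprintf("spline iCSD ForwardMatrix: %d x %d (R = %g um, sigma = %g S/m)\n",
              nrow(x$F), ncol(x$F), x$params$discRadiusUm,
              x$params$conductivitySm))
  invisible(x)
}

#' Invert LFP to CSD (spline iCSD)
#'
#' Solves F c = phi per time sample for the CSD values at the spline knots
#' (the electrode depths). Output positions coincide with electrode depths;
#' no spatial smoothing is applied (see \code{\link{smoothDepthProfile}}).
#'
#' @param lfp an \linkS4class{LfpTrial}
#' @param fm a \code{\link{buildForwardMatrix}} result
#' @return a \linkS4class{CsdTrial} (A/m^3 for LFP in volts)
#' @export
invertSplineIcsd <- function(lfp, fm) {
  stopifnot(is(lfp, "LfpTrial") || is(lfp, "DerivedTrial"))
  if (nrow(lfp@data) != nrow(fm$F))
    stop("LFP channel count does not match the forward matrix")
  csd <- fm$Finv %*% lfp@data
  derivedTrial("CsdTrial", csd, depthsUm = depthsUm(fm$probe),
               epochs = lfp@epochs, condition = lfp@condition)
}

## Smoothing weight matrix along depth: Gaussian (SD smoothSdUm) truncated to
## +- smoothWindowUm/2, renormalized to unit sum at every position (edges
## included).
depthSmoothingMatrix <- function(depths, params) {
  half <- params$smoothWindowUm / 2
  W <- outer(depths, depths, function(a, b) {
    w <- exp(-(a - b)^2 / (2 * params$smoothSdUm^2))
    w[abs(a - b) > half + 1e-9] <- 0
    w
  })
  W / rowSums(W)
}

#' Spatially smooth a CSD depth profile
#'
#' Convolves the CSD along depth with a Gaussian (SD 200 um, finite window
#' 1,000 um by default) for each point in time; the kernel is renormalized to
#' unit sum, including at the edges, so constant profiles are unchanged.
#'
#' @param csd a \linkS4class{CsdTrial} (or any derived trial)
#' @param params an \code{\link{icsdParams}} list
#' @return smoothed trial of the same class
#' @export
smoothDepthProfile <- function(csd, params = icsdParams()) {
  if (nrow(csd@data) < 2L) stop("need at least 2 positions to smooth")
  W <- depthSmoothingMatrix(csd@depthsUm, params)
  out <- csd
  out@data <- W %*% csd@data
  out
}

#' Evoked-onset CSD map
#'
#' Averages the LFP over the first 250 ms after stimulus onset across all
#' correct trials with a stimulus in the receptive field (all attention
#' conditions), inverts the average with the spline iCSD and smooths it
#' along depth. This map is the input for layer identification.
#'
#' @param lfpTrials list of \linkS4class{LfpTrial}
#' @param fm a \code{\link{buildForwardMatrix}} result
#' @param params an \code{\link{icsdParams}} list
#' @return list of class "EvokedCsdMap": \code{csd} (channels x time),
#'   \code{depthsUm}, \code{timesMs} (ms after stimulus onset)
#' @export
evokedOnsetCsd <- function(lfpTrials, fm, params = icsdParams()) {
  keep <- vapply(lfpTrials, function(tr)
    tr@condition@rfStimPresent && tr@condition@correct, logical(1))
  if (!any(keep)) stop("no eligible trials (correct, stimulus in RF)")
  lfpTrials <- lfpTrials[keep]
  acc <- NULL
  for (tr in lfpTrials) {
    seg <- sliceEpoch(tr, "onset250")
    acc <- if (is.null(acc)) seg else acc + seg
  }
  avg <- acc / length(lfpTrials)
  csd <- fm$Finv %*% avg
  W <- depthSmoothingMatrix(depthsUm(fm$probe), params)
  structure(list(csd = W %*% csd, depthsUm = depthsUm(fm$probe),
                 timesMs = (seq_len(ncol(avg)) - 1) / 1),
            class = "EvokedCsdMap")
}
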