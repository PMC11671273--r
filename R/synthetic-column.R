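## Synthetic cortical column: three depth-localized gamma oscillators with
## attention-dependent power/frequency gains, an evoked onset source/sink
## pattern at the layer-III/IV border, spiking phase-locked to the local
## oscillator, within-domain correlated low-frequency baseline activity and
## 1/f background noise. The true CSD lives on a fine depth grid; electrode
## potentials follow from the same disc volume-conductor kernel that the
## iCSD inversion assumes, so every pipeline stage has a recoverable target.

#' Oscillator specification
#'
#' One laminar gamma oscillator: a balanced (zero net current)
#' difference-of-Gaussians depth profile centered on \code{centerDepthUm},
#' oscillating at \code{baseFreqHz} plus a slow Ornstein-Uhlenbeck frequency
#' drift, with condition-dependent amplitude gains and frequency shifts.
#'
#' @param domain "SG", "G_upper" or "IG"
#' @param centerDepthUm center depth (micrometers)
#' @param spatialSdUm SD of the central lobe (micrometers)
#' @param baseFreqHz oscillation frequency (35-120 Hz)
#' @param freqJitterSdHz SD of the slow frequency drift (Hz, default 2)
#' @param baseAmplitude CSD amplitude at the profile peak (A/m^3)
#' @param ampGain named amplitude factors per condition (attend_away = 1);
#'   the measured gamma-power modulation is gain^2 - 1
#' @param freqShiftHz named additive frequency shifts per condition (Hz)
#' @return list of class "OscillatorSpec"
#' @export
oscillatorSpec <- function(domain, centerDepthUm, spatialSdUm, baseFreqHz,
                           freqJitterSdHz = 2, baseAmplitude = 1000,
                           ampGain = c(attend_in = 1, attend_nearby = 1,
                                       attend_away = 1),
                           freqShiftHz = c(attend_in = 0, attend_nearby = 0,
                                           attend_away = 0)) {
  if (baseFreqHz < 35 || baseFreqHz > 120)
    stop("oscillator frequency must lie within 35-120 Hz")
  if (spatialSdUm <= 0) stop("spatialSdUm must be positive")
  if (any(ampGain <= 0)) stop("amplitude gains must be positive")
  structure(list(domain = domain, centerDepthUm = centerDepthUm,
                 spatialSdUm = spatialSdUm, baseFreqHz = baseFreqHz,
                 freqJitterSdHz = freqJitterSdHz,
                 baseAmplitude = baseAmplitude, ampGain = ampGain,
                 freqShiftHz = freqShiftHz), class = "OscillatorSpec")
}

groundTruthDefaults <- function() {
  list(
    nChannels = 16L, pitchUm = 100, fsRaw = 5000, borderUm = 550,
    performance = 0.85,
    oscillators = list(
      ## frequencies: pooled medians at the three hotspots; SG shifts chosen
      ## so the three SG condition medians are 68.2/66.3/66.0 Hz; amplitude
      ## gains are the square roots of the reported power modulations
      SG = oscillatorSpec("SG", 300, 120, 67.0,
        ampGain = c(attend_in = sqrt(1.381), attend_nearby = sqrt(1.128),
                    attend_away = 1),
        freqShiftHz = c(attend_in = 1.2, attend_nearby = -0.7,
                        attend_away = -1.0)),
      G_upper = oscillatorSpec("G_upper", 800, 120, 70.7,
        ampGain = c(attend_in = sqrt(1.285), attend_nearby = sqrt(1.075),
                    attend_away = 1)),
      IG = oscillatorSpec("IG", 1300, 100, 65.3,
        ampGain = c(attend_in = sqrt(1.160), attend_nearby = sqrt(0.959),
                    attend_away = 1))),
    jitterTauMs = 200,
    rampMs = 200,
    burst = list(logSd = 0.25, tauMs = 40),
    farReturn = list(depthsUm = c(-3000, 4500), sdUm = 400),
    evoked = list(amplitude = 2000, offsetUm = 150, sdUm = 100,
                  onsetDelayMs = 30, decayMs = 50),
    spiking = list(baseRateHz = 50, kappa = 1.2, crossKappa = 0.1,
                   spikeAmpV = 60e-6, phi0 = 0,
                   rateBumpDepthUm = 800, rateBumpSdUm = 400,
                   rateBumpFactor = 0.5),
    baseline = list(sharedSdAm3 = 300, tauMs = 40),
    noise = list(oneOverFExponent = 1, sdAm3 = 150, sensorSdV = 0.5e-6),
    coupling = list(pullPerS = c(attend_in = 4, attend_nearby = 2.5,
                                 attend_away = 2.5)),
    gridStepUm = 20, gridMarginUm = 200,
    seed = 1L)
}

#' Build the synthetic-column ground truth
#'
#' Returns the fully populated generator configuration; unspecified entries
#' take the package defaults (three oscillators at 67.0, 70.7 and 65.3 Hz
#' with the default attention gains, border at 550 um, 16 channels at 100 um
#' pitch, 5 kHz raw rate). The configuration is deterministic given
#' \code{seed}.
#'
#' @param config named list overriding any subset of the defaults (merged
#'   recursively)
#' @return list of class "GroundTruth"
#' @export
buildGroundTruth <- function(config = list()) {
  gt <- utils::modifyList(groundTruthDefaults(), config)
  for (o in gt$oscillators) {
    if (o$baseFreqHz < 35 || o$baseFreqHz > 120)
      stop("oscillator frequency must lie within 35-120 Hz")
    if (o$spatialSdUm <= 0) stop("spatialSdUm must be positive")
    if (any(o$ampGain <= 0)) stop("amplitude gains must be positive")
  }
  span <- (gt$nChannels - 1L) * gt$pitchUm
  ctrs <- vapply(gt$oscillators, function(o) o$centerDepthUm, numeric(1))
  doms <- c(SG = "SG", G_upper = "G", IG = "IG")[names(gt$oscillators)]
  want <- ifelse(ctrs < gt$borderUm, "SG",
                 ifelse(ctrs <= gt$borderUm + 500, "G", "IG"))
  if (!identical(unname(doms), unname(want)))
    stop("oscillator center depths must lie in their distinct laminar domains")
  if (max(ctrs) > span) stop("oscillator depths must lie within the probe span")
  gt$probe <- probeGeometry(gt$nChannels, gt$pitchUm)
  structure(gt, class = "GroundTruth")
}

#' @export
print.GroundTruth <- function(x, ...) {
  f <- vapply(x$oscillators, function(o) o$baseFreqHz, numeric(1))
  cat(sprintf(
    "GroundTruth: %d-channel column, border %g um, oscillators %s Hz, seed %d\n",
    x$nChannels, x$borderUm, paste(sprintf("%.1f", f), collapse = "/"),
    x$seed))
  invisible(x)
}

## Balanced oscillator depth profile: a compact Gaussian lobe inside the
## column plus two distant return lobes (above the pia and deep in the white
## matter, half the mass each) through which the current loop closes.
## Peak-normalized to 1; integrates to zero over the fine grid, so each
## oscillator injects no net current.
oscillatorDepthProfile <- function(z, centerUm, sdUm, farReturn) {
  g <- stats::dnorm(z, centerUm, sdUm)
  ret <- (stats::dnorm(z, farReturn$depthsUm[1L], farReturn$sdUm) +
          stats::dnorm(z, farReturn$depthsUm[2L], farReturn$sdUm)) / 2
  p <- g - ret
  p / stats::dnorm(0, 0, sdUm)
}

## Fine depth grid: covers the far return lobes (+- 3 SD) as well as the
## cortical span, so profiles integrate to ~0 on the grid.
fineGrid <- function(gt) {
  span <- (gt$nChannels - 1L) * gt$pitchUm
  lo <- min(-gt$gridMarginUm, gt$farReturn$depthsUm[1L] - 3 * gt$farReturn$sdUm)
  hi <- max(span + gt$gridMarginUm,
            gt$farReturn$depthsUm[2L] + 3 * gt$farReturn$sdUm)
  seq(lo, hi, by = gt$gridStepUm)
}

## Oscillator phase time courses for one trial (uses the current RNG
## stream). SG and IG phases are weakly pulled toward the granular phase
## (Kuramoto-style) with a condition-dependent strength.
oscillatorPhases <- function(gt, attention, nSamp, dtMs) {
  eps <- gt$coupling$pullPerS[[attention]] * dtMs / 1000
  phases <- vector("list", length(gt$oscillators))
  names(phases) <- names(gt$oscillators)
  finst <- lapply(gt$oscillators, function(o) {
    f0 <- o$baseFreqHz + o$freqShiftHz[[attention]]
    f0 + ouProcess(nSamp, o$freqJitterSdHz, gt$jitterTauMs, dtMs)
  })
  phi0 <- stats::runif(length(gt$oscillators), 0, 2 * pi)
  ## granular reference phase: plain integration
  gIdx <- which(names(gt$oscillators) == "G_upper")
  phases[[gIdx]] <- phi0[gIdx] +
    cumsum(2 * pi * finst[[gIdx]] * dtMs / 1000)
  for (k in seq_along(gt$oscillators)) {
    if (k == gIdx) next
    th <- numeric(nSamp)
    th[1L] <- phi0[k]
    dth <- 2 * pi * finst[[k]] * dtMs / 1000
    thG <- phases[[gIdx]]
    if (eps > 0) {
      for (i in 2:nSamp)
        th[i] <- th[i - 1L] + dth[i] + eps * sin(thG[i - 1L] - th[i - 1L])
    } else {
      th <- phi0[k] + cumsum(dth)
    }
    phases[[k]] <- th
  }
  phases
}

## Stimulus-induced amplitude envelope: 0 during baseline, raised-cosine
## ramp after stimulus onset, 1 for the rest of the trial.
inducedEnvelope <- function(epochs, nSamp, fs, rampMs) {
  t <- (seq_len(nSamp) - 1L) / fs * 1000
  e <- numeric(nSamp)
  on <- epochs@stimOnsetMs
  ramp <- t >= on & t < on + rampMs
  e[ramp] <- 0.5 * (1 - cos(pi * (t[ramp] - on) / rampMs))
  e[t >= on + rampMs] <- 1
  e
}

#' Synthesize the true CSD of one trial on the fine depth grid
#'
#' True CSD = sum of the three oscillators (amplitude-modulated sinusoids
#' with balanced difference-of-Gaussians depth profiles, condition gains and
#' frequency shifts applied), plus the evoked onset source/sink template
#' after stimulus onset, plus domain-shared low-frequency baseline activity,
#' plus 1/f noise. Uses the current RNG stream; seed it (or use
#' \code{\link{simulateSession}}) for reproducibility.
#'
#' @param gt a \code{\link{buildGroundTruth}} result
#' @param condition a \linkS4class{Condition} or attention label
#' @param epochs optional \linkS4class{TrialEpochs} (default: standard trial
#'   at \code{gt$fsRaw})
#' @return list of class "TrueCsd": \code{zUm} (fine grid), \code{data}
#'   (grid x samples, A/m^3), \code{fs}, \code{phases} (per oscillator),
#'   \code{epochs}, \code{condition}
#' @export
synthesizeGroundTruthCsd <- function(gt, condition = "attend_in",
                                     epochs = NULL) {
  if (is.character(condition)) condition <- condition(condition)
  if (is.null(epochs)) epochs <- trialEpochs(gt$fsRaw)
  fs <- epochs@fsRaw
  nSamp <- round(epochs@mcBoundsMs[length(epochs@mcBoundsMs)] * fs / 1000)
  dtMs <- 1000 / fs
  z <- fineGrid(gt)
  att <- condition@attention
  phases <- oscillatorPhases(gt, att, nSamp, dtMs)
  env <- inducedEnvelope(epochs, nSamp, fs, gt$rampMs)
  data <- matrix(0, length(z), nSamp)
  for (k in seq_along(gt$oscillators)) {
    o <- gt$oscillators[[k]]
    prof <- oscillatorDepthProfile(z, o$centerDepthUm, o$spatialSdUm,
                                   gt$farReturn)
    amp <- o$baseAmplitude * o$ampGain[[att]]
    ## stochastic gamma bursting: lognormal amplitude envelope, normalized
    ## so the mean squared amplitude (hence gamma power) is gain^2-scaled
    burst <- if (gt$burst$logSd > 0) {
      x <- ouProcess(nSamp, gt$burst$logSd, gt$burst$tauMs, dtMs)
      exp(x - gt$burst$logSd^2)
    } else rep(1, nSamp)
    data <- data + outer(prof, amp * env * burst * sin(phases[[k]]))
  }
  if (gt$evoked$amplitude > 0 && condition@rfStimPresent) {
    ev <- gt$evoked
    profEv <- exp(-(z - (gt$borderUm - ev$offsetUm))^2 / (2 * ev$sdUm^2)) -
              exp(-(z - (gt$borderUm + ev$offsetUm))^2 / (2 * ev$sdUm^2))
    tMs <- (seq_len(nSamp) - 1L) * dtMs
    tau <- (tMs - epochs@stimOnsetMs - ev$onsetDelayMs) / ev$decayMs
    h <- ifelse(tau > 0, tau * exp(1 - tau), 0)
    data <- data + ev$amplitude * outer(profEv, h)
  }
  if (gt$baseline$sharedSdAm3 > 0) {
    span <- (gt$nChannels - 1L) * gt$pitchUm
    ranges <- list(SG = c(0, gt$borderUm),
                   G = c(gt$borderUm, gt$borderUm + 500),
                   IG = c(gt$borderUm + 500, span))
    for (rg in ranges) {
      s <- ouProcess(nSamp, gt$baseline$sharedSdAm3, gt$baseline$tauMs, dtMs)
      ## uniform within the domain: baseline correlation blocks are sharp
      ## at the domain borders, as the refinement stage expects
      prof <- as.numeric(z >= rg[1L] & z <= rg[2L])
      data <- data + outer(prof, s)
    }
  }
  if (gt$noise$sdAm3 > 0) {
    ## background noise lives in the cortical tissue around the probe
    span <- (gt$nChannels - 1L) * gt$pitchUm
    for (i in which(z >= -gt$gridMarginUm & z <= span + gt$gridMarginUm))
      data[i, ] <- data[i, ] + oneOverFNoise(nSamp, fs,
                                             gt$noise$oneOverFExponent,
                                             gt$noise$sdAm3)
  }
  structure(list(zUm = z, data = data, fs = fs, phases = phases,
                 epochs = epochs, condition = condition),
            class = "TrueCsd")
}

#' Forward-model electrode potentials from a true CSD
#'
#' Potential at each electrode = depth integral of the fine-grid CSD against
#' the disc-source kernel (the same volume-conductor model the spline iCSD
#' inverts); exactly linear in the CSD.
#'
#' @param trueCsd a \code{\link{synthesizeGroundTruthCsd}} result
#' @param probe a \linkS4class{ProbeGeometry}
#' @param params an \code{\link{icsdParams}} list
#' @return channels x samples matrix of potentials (V) at the raw rate
#' @export
forwardModelLfp <- function(trueCsd, probe, params = icsdParams()) {
  d <- depthsUm(probe)
  if (min(trueCsd$zUm) > min(d) || max(trueCsd$zUm) < max(d))
    stop("fine depth grid does not cover the probe span")
  K <- discForwardOperator(d, trueCsd$zUm, params)
  K %*% trueCsd$data
}

## Biphasic ~1 ms spike waveform (Gaussian-windowed 1.5 kHz cycle); zero
## mean, energy concentrated above 400 Hz.
spikeWaveform <- function(fs, ampV) {
  t <- seq(-6e-4, 6e-4, by = 1 / fs)
  ampV * sin(2 * pi * 1500 * t) * exp(-t^2 / (2 * 2.5e-4^2))
}

#' Synthesize the spiking high-band trace of one channel
#'
#' Inhomogeneous point process with rate
#' \eqn{r(t) \propto \exp(\kappa\cos(\phi_{dom}(t)-\phi_0) +
#' \kappa_x \sum_{other}\cos\phi)} normalized to the channel's mean rate,
#' where \eqn{\phi_{dom}} is the phase of the channel's own domain
#' oscillator; each event adds a biphasic ~1 ms waveform with energy above
#' 400 Hz.
#'
#' @param gt a \code{\link{buildGroundTruth}} result
#' @param trueCsd a \code{\link{synthesizeGroundTruthCsd}} result (supplies
#'   the oscillator phases)
#' @param channel channel index on the probe
#' @return numeric vector (V) at the raw rate
#' @export
synthesizeSpiking <- function(gt, trueCsd, channel) {
  d <- depthsUm(gt$probe)
  if (channel < 1L || channel > length(d)) stop("channel outside the probe")
  sp <- gt$spiking
  depth <- d[channel]
  dom <- if (depth < gt$borderUm) "SG"
         else if (depth <= gt$borderUm + 500) "G_upper" else "IG"
  nSamp <- ncol(trueCsd$data)
  fs <- trueCsd$fs
  r0 <- sp$baseRateHz *
    (1 + sp$rateBumpFactor *
       exp(-(depth - sp$rateBumpDepthUm)^2 / (2 * sp$rateBumpSdUm^2)))
  if (r0 <= 0) return(numeric(nSamp))
  drive <- sp$kappa * cos(trueCsd$phases[[dom]] - sp$phi0)
  if (sp$crossKappa > 0) {
    for (other in setdiff(names(trueCsd$phases), dom))
      drive <- drive + sp$crossKappa * cos(trueCsd$phases[[other]])
  }
  rate <- exp(drive)
  rate <- r0 * rate / mean(rate)
  events <- which(stats::runif(nSamp) < rate / fs)
  x <- numeric(nSamp)
  if (length(events)) {
    w <- spikeWaveform(fs, sp$spikeAmpV)
    half <- (length(w) - 1L) %/% 2L
    for (e in events) {
      i0 <- max(1L, e - half); i1 <- min(nSamp, e + half)
      x[i0:i1] <- x[i0:i1] + w[(i0 - e + half + 1L):(i1 - e + half + 1L)]
    }
  }
  x
}

#' Simulate a complete session
#'
#' Generates \code{nTrialsPerCondition} trials per attention condition in
#' seed-randomized order. Each broadband trial is the forward-modelled LFP
#' of the true CSD plus per-channel spiking and white sensor noise. The
#' whole session is deterministic given \code{gt$seed}.
#'
#' @param gt a \code{\link{buildGroundTruth}} result
#' @param nTrialsPerCondition named integer vector, e.g.
#'   \code{c(attend_in = 10, attend_nearby = 10, attend_away = 10)}
#' @param params an \code{\link{icsdParams}} list for the forward model
#' @return a \linkS4class{Session}
#' @export
simulateSession <- function(gt,
                            nTrialsPerCondition = c(attend_in = 10,
                                                    attend_nearby = 10,
                                                    attend_away = 10),
                            params = icsdParams()) {
  if (gt$fsRaw < 4000)
    stop("fsRaw too low for the synthesized spiking band (need >= 4,000 Hz)")
  set.seed(gt$seed)
  labels <- rep(names(nTrialsPerCondition), nTrialsPerCondition)
  labels <- sample(labels)
  trials <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    cond <- condition(labels[i])
    epochs <- trialEpochs(gt$fsRaw)
    tc <- synthesizeGroundTruthCsd(gt, cond, epochs)
    broadband <- forwardModelLfp(tc, gt$probe, params)
    for (ch in seq_len(gt$nChannels))
      broadband[ch, ] <- broadband[ch, ] + synthesizeSpiking(gt, tc, ch)
    if (gt$noise$sensorSdV > 0)
      broadband <- broadband +
        matrix(stats::rnorm(length(broadband), 0, gt$noise$sensorSdV),
               nrow = nrow(broadband))
    trials[[i]] <- broadbandTrial(broadband, gt$fsRaw, epochs, cond)
  }
  session(gt$probe, trials, performance = gt$performance,
          metadata = list(generator = "laminarGamma synthetic column",
                          seed = gt$seed))
}
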