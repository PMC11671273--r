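## End-to-end pipeline driver: preprocess -> iCSD -> layers -> hotspots ->
## dominant frequency / power / phase coherence -> statistics -> report.

#' Default pipeline configuration
#'
#' @return named list: \code{gammaBandHz} (hotspot/attention analyses,
#'   42.5-130.5 Hz), \code{esaBandHz} (ESA preference profiles, 28-78 Hz),
#'   \code{detectBand} (re-derive the gamma band from the mean corrected
#'   PSD instead of the preset), \code{performanceMin} (session filter for
#'   attention analyses, 0.65), \code{icsd} (\code{\link{icsdParams}}),
#'   \code{withPhc}, \code{withEsa} (stage switches)
#' @export
pipelineConfig <- function() {
  list(gammaBandHz = c(42.5, 130.5), esaBandHz = c(28, 78),
       detectBand = FALSE, performanceMin = 0.65, icsd = icsdParams(),
       withPhc = TRUE, withEsa = TRUE)
}

## Mean gamma power of one channel over a window, averaged across trials.
gammaPowerAtChannel <- function(trials, channel, bank, bandHz, window,
                                condition = NULL) {
  if (!is.null(condition))
    trials <- Filter(function(tr) tr@condition@attention == condition, trials)
  if (length(trials) == 0L) return(NA_real_)
  gb <- bankSubset(bank, bandHz)
  mean(vapply(trials, function(tr) {
    win <- if (is.character(window)) epochWindow(tr@epochs, window) else window
    mean(psdSpectrum(waveletTransform(tr@data[channel, ], gb), win))
  }, numeric(1)))
}

## Per-trial dominant frequencies (1 / median accepted period per trial).
perTrialFrequencies <- function(csdTrials, channel, condition = NULL) {
  if (!is.null(condition))
    csdTrials <- Filter(function(tr) tr@condition@attention == condition,
                        csdTrials)
  out <- vapply(csdTrials, function(tr) {
    nb <- bandpassGamma(tr@data[channel, ], tr@fs)
    pa <- analyticPhaseAmplitude(nb, tr@fs)
    cs <- detectGammaTroughs(pa$phase, pa$amplitude,
                             epochWindow(tr@epochs, "mc23"), tr@fs)
    p <- cs$periodsS[cs$accepted]
    if (length(p) == 0L) NA_real_ else 1 / stats::median(p)
  }, numeric(1))
  out[is.finite(out)]
}

#' Analyze one session
#'
#' Runs the full analysis chain on a \linkS4class{Session}: LFP/ESA
#' extraction, spline iCSD with spatial smoothing, evoked-onset layer
#' identification with correlation-based refinement, gamma-power depth
#' profile and hotspot detection (attend-in trials), hotspot inclusion
#' checks, dominant gamma frequency per hotspot and condition, attention
#' power modulation, and (optionally) CSD-ESA phase-coherence profiles with
#' normalized domain preferences. Attention analyses are skipped (flagged)
#' when the session performance is below \code{performanceMin}.
#'
#' @param session a \linkS4class{Session}
#' @param config a \code{\link{pipelineConfig}} list (entries may be
#'   overridden)
#' @return a list of results (see the worked example in the package README)
#' @export
analyzeSession <- function(session, config = pipelineConfig()) {
  config <- utils::modifyList(pipelineConfig(), config)
  probe <- session@probe
  trials <- Filter(function(tr) tr@condition@correct, session@trials)
  if (length(trials) == 0L) stop("pipeline: no correct trials")
  conditions <- vapply(trials, function(tr) tr@condition@attention,
                       character(1))

  lfp <- lapply(trials, extractLfp, probe = probe)
  fm <- buildForwardMatrix(probe, config$icsd)
  csd <- lapply(lfp, function(l)
    smoothDepthProfile(invertSplineIcsd(l, fm), config$icsd))

  ## --- layer identification -------------------------------------------------
  evoked <- evokedOnsetCsd(lfp, fm, config$icsd)
  border0 <- detectPolarityInversion(evoked)
  corr <- baselineCsdCorrelationMatrix(csd)
  border <- refineBorderFromCorrelation(corr, border0, probe)
  assignment <- assignDomains(border, probe, method = "refined")

  ## --- gamma band and power profile ----------------------------------------
  bank <- buildWaveletBank(5, 160, 8, 1000)
  bandHz <- config$gammaBandHz
  attIn <- csd[conditions == "attend_in"]
  if (isTRUE(config$detectBand)) {
    psds <- rowMeans(vapply(attIn, function(tr) {
      colMeans(t(vapply(seq_len(nrow(tr@data)), function(ch)
        psdSpectrum(waveletTransform(tr@data[ch, ], bank),
                    epochWindow(tr@epochs, "mc23")),
        numeric(length(bank$freqs)))))
    }, numeric(length(bank$freqs))))
    bandHz <- determineGammaBand(psds, bank$freqs)
  }
  profile <- gammaPowerDepthProfile(csd, bank, bandHz,
                                    condition = "attend_in")
  hotspots <- detectHotspots(profile, assignment)

  ## --- hotspot inclusion (MC2/3 power >= 2.5 x baseline power) --------------
  hsTab <- hotspotTable(hotspots)
  hsTab$included <- vapply(seq_len(nrow(hsTab)), function(i) {
    ch <- hsTab$channel[i]
    if (is.na(ch)) return(FALSE)
    pb <- gammaPowerAtChannel(csd, ch, bank, bandHz, "baseline")
    checkHotspotInclusion(hsTab$power[i], pb)
  }, logical(1))

  ## --- dominant gamma frequency per hotspot and condition -------------------
  freqs <- list()
  condsPresent <- unique(conditions)
  for (dm in c("SG", "G", "IG")) {
    ch <- hotspotChannel(hotspots, dm)
    if (is.na(ch)) next
    freqs[[dm]] <- list(
      pooled = tryCatch(
        dominantFrequencyOfChannel(csd, ch)$freqHz, error = function(e) NA_real_),
      byCondition = vapply(condsPresent, function(cc) tryCatch(
        dominantFrequencyOfChannel(csd, ch, cc)$freqHz,
        error = function(e) NA_real_), numeric(1)))
  }

  ## --- attention analyses (performance-gated) -------------------------------
  attentionSkipped <- session@performance < config$performanceMin
  attention <- NULL
  if (!attentionSkipped &&
      all(c("attend_in", "attend_away") %in% condsPresent)) {
    attention <- lapply(c(SG = "SG", G = "G", IG = "IG"), function(dm) {
      ch <- hotspotChannel(hotspots, dm)
      if (is.na(ch)) return(NULL)
      pin <- gammaPowerAtChannel(csd, ch, bank, bandHz, "mc23", "attend_in")
      paw <- gammaPowerAtChannel(csd, ch, bank, bandHz, "mc23", "attend_away")
      pnb <- gammaPowerAtChannel(csd, ch, bank, bandHz, "mc23",
                                 "attend_nearby")
      list(channel = ch,
           powerPctIn = 100 * (pin - paw) / paw,
           powerPctNearby = if (is.na(pnb)) NA_real_
                            else 100 * (pnb - paw) / paw)
    })
  }

  ## --- phase coherence -------------------------------------------------------
  phc <- NULL
  if (isTRUE(config$withPhc) && isTRUE(config$withEsa)) {
    esa <- lapply(trials, extractEsa, probe = probe)
    esaIn <- esa[conditions == "attend_in"]
    csdIn <- csd[conditions == "attend_in"]
    esaPower <- gammaPowerDepthProfile(esaIn, bank, bandHz)
    esaChannels <- selectEsaChannels(esaPower)
    profs <- list()
    for (i in seq_len(nrow(hsTab))) {
      if (!hsTab$included[i]) next
      dm <- hsTab$domain[i]
      profs[[dm]] <- spectrolaminarPhcProfile(
        csdIn, esaIn, hsTab$channel[i], bank, config$esaBandHz,
        kind = "csd_esa", targetChannels = esaChannels)
    }
    pref <- if (length(profs) == 3L)
      normalizedDomainPreference(lapply(profs[c("SG", "G", "IG")],
                                        phcGammaSummary)) else NULL
    phc <- list(esaChannels = esaChannels, esaPower = esaPower,
                profiles = profs, preference = pref)
  }

  ## --- single-session statistics --------------------------------------------
  stats <- list()
  chans <- stats::setNames(vapply(c("SG", "G", "IG"),
                                  function(dm) hotspotChannel(hotspots, dm),
                                  integer(1)), c("SG", "G", "IG"))
  if (!anyNA(chans)) {
    groups <- lapply(chans, function(ch) perTrialFrequencies(csd, ch))
    if (all(lengths(groups) >= 2L))
      stats$frequencyAcrossHotspots <- compareIndependentGroups(groups)
  }
  if (!attentionSkipped && !is.na(chans[["SG"]]) &&
      length(condsPresent) >= 2L) {
    byCond <- lapply(stats::setNames(condsPresent, condsPresent),
                     function(cc) perTrialFrequencies(csd, chans[["SG"]], cc))
    if (all(lengths(byCond) >= 2L))
      stats$sgFrequencyAcrossConditions <- compareIndependentGroups(byCond)
  }

  list(border = border, borderInitial = border0, assignment = assignment,
       bandHz = bandHz, profile = profile, hotspots = hsTab,
       frequencies = freqs, attention = attention,
       attentionSkipped = attentionSkipped, phc = phc, stats = stats,
       corr = corr, nTrials = length(trials))
}

statsToJsonable <- function(s) {
  lapply(s, function(r) {
    list(test = r$test, statistic = r$statistic, df = r$df, p = r$p,
         n = r$n,
         posthoc = if (is.data.frame(r$posthoc)) r$posthoc else
           lapply(r$posthoc, identity))
  })
}

#' Run the full pipeline on a session directory
#'
#' Reads a session (see \code{\link{readSession}}), runs
#' \code{\link{analyzeSession}} and writes the report: CSV tables
#' (gamma-power depth profile, hotspots, dominant frequencies, attention
#' power modulation, PhC gamma summaries) plus a JSON bundle with the layer
#' assignment and statistics. Deterministic given session and config.
#'
#' @param sessionDir session directory
#' @param outDir report directory (created)
#' @param config a \code{\link{pipelineConfig}} list
#' @return \code{outDir}, invisibly
#' @export
runFullPipeline <- function(sessionDir, outDir, config = pipelineConfig()) {
  sess <- readSession(sessionDir)
  res <- analyzeSession(sess, config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  utils::write.csv(data.frame(channel = seq_along(res$profile),
                              depthUm = depthsUm(res$assignment),
                              domain = domainOf(res$assignment),
                              gammaPower = res$profile),
                   file.path(outDir, "gamma_power_profile.csv"),
                   row.names = FALSE)
  utils::write.csv(res$hotspots, file.path(outDir, "hotspots.csv"),
                   row.names = FALSE)

  freqRows <- list()
  for (dm in names(res$frequencies)) {
    f <- res$frequencies[[dm]]
    freqRows[[dm]] <- data.frame(
      domain = dm, condition = c("pooled", names(f$byCondition)),
      freqHz = c(f$pooled, unname(f$byCondition)))
  }
  if (length(freqRows))
    utils::write.csv(do.call(rbind, freqRows),
                     file.path(outDir, "dominant_frequency.csv"),
                     row.names = FALSE)

  if (!is.null(res$attention)) {
    att <- do.call(rbind, lapply(names(res$attention), function(dm) {
      a <- res$attention[[dm]]
      if (is.null(a)) return(NULL)
      data.frame(domain = dm, channel = a$channel,
                 powerPctAttendIn = a$powerPctIn,
                 powerPctAttendNearby = a$powerPctNearby)
    }))
    if (!is.null(att))
      utils::write.csv(att, file.path(outDir, "attention_power.csv"),
                       row.names = FALSE)
  }

  if (!is.null(res$phc) && length(res$phc$profiles)) {
    phcTab <- do.call(cbind, lapply(res$phc$profiles, phcGammaSummary))
    out <- data.frame(channel = seq_len(nrow(phcTab)), phcTab)
    utils::write.csv(out, file.path(outDir, "phc_gamma_summary.csv"),
                     row.names = FALSE)
  }

  jsonlite::write_json(
    list(border = res$border, borderInitial = res$borderInitial,
         bandHz = res$bandHz, domains = domainOf(res$assignment),
         attentionSkipped = res$attentionSkipped,
         nTrials = res$nTrials, stats = statsToJsonable(res$stats)),
    file.path(outDir, "report.json"), auto_unbox = TRUE, digits = NA,
    na = "null", pretty = TRUE, force = TRUE)
  invisible(outDir)
}
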