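# Shared fixture builders; everything is generated in code at test time.

# Broadband trial whose channels all carry the same signal.
uniformBroadband <- function(x, fs, nCh = 4L, attention = "attend_in") {
  broadbandTrial(matrix(rep(x, nCh), nrow = nCh, byrow = TRUE), fs,
                 trialEpochs(fs), condition(attention))
}

# Derived trial (1 kHz) from a channels x samples matrix.
makeDerived <- function(class, data, attention = "attend_in",
                        leverReleaseMs = NA_real_) {
  derivedTrial(class, data, depthsUm = (seq_len(nrow(data)) - 1) * 100,
               trialEpochs(1000, leverReleaseMs = leverReleaseMs),
               condition(attention))
}

# Full-length (4,570 ms) 1 kHz multichannel matrix of white noise.
noiseMatrix <- function(nCh, sd = 1) matrix(rnorm(nCh * 4570, 0, sd), nCh)

# Small noiseless ground truth for construction-level checks.
quietGroundTruth <- function(seed = 1L, extra = list()) {
  cfg <- utils::modifyList(list(
    seed = seed,
    noise = list(sdAm3 = 0, sensorSdV = 0),
    baseline = list(sharedSdAm3 = 0),
    evoked = list(amplitude = 0),
    burst = list(logSd = 0),
    spiking = list(baseRateHz = 0)), extra)
  buildGroundTruth(cfg)
}
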