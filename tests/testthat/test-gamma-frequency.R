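test_that("gamma band-pass keeps 70 Hz and suppresses 20 Hz by >= 20 dB", {
  t <- (0:4569) / 1000
  y70 <- bandpassGamma(sin(2 * pi * 70 * t))
  expect_lt(abs(max(y70[2000:2500]) - 1), 0.05)
  y20 <- bandpassGamma(sin(2 * pi * 20 * t))
  expect_lt(sd(y20[2000:2500]) / sd(sin(2 * pi * 20 * t)), 10^(-20 / 20))
  expect_equal(max(abs(bandpassGamma(numeric(2000)))), 0)
  expect_error(bandpassGamma(numeric(2000), fs = 500), "1,000 Hz")
})

test_that("analytic phase advances 2 pi per cycle with unit envelope", {
  t <- (0:2999) / 1000
  pa <- analyticPhaseAmplitude(cos(2 * pi * 70 * t))
  expect_equal(mean(pa$amplitude[500:2500]), 1, tolerance = 1e-3)
  u <- laminarGamma:::unwrapPhase(pa$phase[500:2500])
  expect_equal(diff(range(u)) / (2 * pi), 2000 / 1000 * 70, tolerance = 0.01)
  ## amplitude scales, phase does not
  pa3 <- analyticPhaseAmplitude(3 * cos(2 * pi * 70 * t))
  expect_equal(pa3$amplitude, 3 * pa$amplitude, tolerance = 1e-10)
  expect_equal(pa3$phase[500:2500], pa$phase[500:2500], tolerance = 1e-8)
  expect_equal(analyticPhaseAmplitude(numeric(100))$amplitude, rep(0, 100))
})

test_that("trough detection respects episodes, interpolation and period bounds", {
  fs <- 1000
  ## amplitude-modulated 70 Hz tone over the full trial
  t <- (0:4569) / fs
  x <- (1 + 0.3 * sin(2 * pi * 1.9 * t)) * sin(2 * pi * 70 * t)
  nb <- bandpassGamma(x)
  pa <- analyticPhaseAmplitude(nb)
  cs <- detectGammaTroughs(pa$phase, pa$amplitude, c(2570, 4570))
  expect_gt(sum(cs$accepted), 30)
  expect_lt(max(abs(cs$periodsS[cs$accepted] - 1 / 70)), 1e-4)

  ## an above-median run shorter than 40 ms yields no troughs
  n <- 2000
  phase <- ((2 * pi * 70 * (0:(n - 1)) / fs + pi) %% (2 * pi)) - pi
  amp <- rep(1, n); amp[300:329] <- 10          # 30 ms burst only
  cs2 <- detectGammaTroughs(phase, amp, c(0, n))
  expect_equal(length(cs2$troughTimesMs), 0L)
  amp[300:349] <- 10                            # 50 ms burst
  cs3 <- detectGammaTroughs(phase, amp, c(0, n))
  expect_gt(length(cs3$troughTimesMs), 2L)
  expect_lt(max(abs(cs3$periodsS - 1 / 70)), 1e-4)

  ## constant phase: no crossings
  cs4 <- detectGammaTroughs(rep(0, n), amp, c(0, n))
  expect_equal(length(cs4$troughTimesMs), 0L)
})

test_that("dominant frequency is the reciprocal median of accepted periods", {
  mkcs <- function(periods) structure(
    list(troughTimesMs = numeric(0), periodsS = periods,
         accepted = periods >= 1 / 120 & periods <= 1 / 35),
    class = "CycleSeries")
  expect_equal(dominantFrequencyFromPeriods(mkcs(rep(1 / 70, 10)))$freqHz, 70)
  expect_equal(dominantFrequencyFromPeriods(mkcs(c(1 / 60, 1 / 70, 1 / 80)))$freqHz, 70)
  ## out-of-band periods are discarded before the median
  expect_equal(dominantFrequencyFromPeriods(mkcs(c(1 / 30, 1 / 70, 1 / 70)))$freqHz, 70)
  expect_error(dominantFrequencyFromPeriods(mkcs(1 / 30)), "no accepted")
  ## even count: midpoint of the two central periods
  expect_equal(dominantFrequencyFromPeriods(mkcs(c(1 / 60, 1 / 80)))$freqHz,
               1 / ((1 / 60 + 1 / 80) / 2))
})

test_that("the estimator is consistent for noiseless AM sinusoids", {
  fs <- 1000; t <- (0:4569) / fs
  for (f in c(40, 75, 110)) {
    x <- (1 + 0.4 * sin(2 * pi * 3.1 * t + 1)) * sin(2 * pi * f * t)
    tr <- makeDerived("CsdTrial", matrix(rep(x, 2), 2, byrow = TRUE))
    est <- dominantFrequencyOfChannel(list(tr), 1)$freqHz
    expect_lt(abs(est - f) / f, 0.005)
  }
})
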