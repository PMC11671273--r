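test_that("phase-locking value behaves on identical, shifted and random phases", {
  set.seed(12)
  ph <- matrix(runif(20 * 50, -pi, pi), 20)
  expect_equal(phaseCoherenceTf(ph, ph), rep(1, 50))
  ## a fixed per-trial offset still gives PhC = 1
  expect_equal(phaseCoherenceTf(ph, ph - pi / 3), rep(1, 50))
  ## adding a common constant to one side changes nothing
  expect_equal(phaseCoherenceTf(ph + 1.1, ph), phaseCoherenceTf(ph, ph))
  expect_error(phaseCoherenceTf(ph[1, , drop = FALSE], ph[1, , drop = FALSE]),
               "at least 2")
  ## bounds
  a <- matrix(runif(10 * 100, -pi, pi), 10)
  b <- matrix(runif(10 * 100, -pi, pi), 10)
  v <- phaseCoherenceTf(a, b)
  expect_true(all(v >= 0 & v <= 1))
})

test_that("expected PLV matches the closed form and its limits", {
  expect_equal(expectedPlv(1), sqrt(pi) / 2)
  expect_equal(expectedPlv(100), 0.0886, tolerance = 1e-3)
  expect_lt(expectedPlv(1e8), 1e-3)
  expect_error(expectedPlv(0), "at least 1")
})

test_that("normalized preference ratios are scale-invariant and sum to one", {
  pref <- normalizedDomainPreference(list(c(1, 0.6), c(1, 0.3), c(1, 0.1)))
  expect_equal(pref[, 1], c(SG = 1 / 3, G = 1 / 3, IG = 1 / 3))
  expect_equal(unname(pref[, 2]), c(0.6, 0.3, 0.1))
  scaled <- normalizedDomainPreference(list(c(5, 3), c(5, 1.5), c(5, 0.5)))
  expect_equal(unname(scaled[, 2]), c(0.6, 0.3, 0.1))
  ## nonpositive sums are masked
  neg <- normalizedDomainPreference(list(c(-1), c(0.5), c(0.2)))
  expect_true(all(is.na(neg[, 1])))
})

test_that("cross-session averaging is a depth-aligned median with 2/3 coverage", {
  p <- function(v, d) stats::setNames(v, d)
  same <- replicate(4, p(c(1, 2, 3), c(-100, 0, 100)), simplify = FALSE)
  avg <- averageProfilesAcrossSessions(same)
  expect_equal(unname(avg), c(1, 2, 3))
  ## one outlier among 5 sessions does not move the median
  five <- c(same, list(p(c(50, 60, 70), c(-100, 0, 100))))
  expect_equal(unname(averageProfilesAcrossSessions(five)), c(1, 2, 3))
  ## a depth present in 3 of 6 sessions is omitted (3 < ceiling(12/3) = 4)
  six <- c(five, list(p(1, -300)))
  partial <- lapply(1:3, function(i) p(c(9, 9), c(-200, -100)))
  mixed <- c(six[1:3], partial)
  avg2 <- averageProfilesAcrossSessions(mixed)
  expect_true(is.na(avg2[["-200"]]))
  expect_error(averageProfilesAcrossSessions(same[1]), "at least 2")
})

## Construct trial-aligned CsdTrials in which channels 1 and 2 share a 70 Hz
## rhythm (channel 2 lagged), channel 3 carries independent noise.
phcFixture <- function(nTrials = 12, seed = 13) {
  set.seed(seed)
  lapply(seq_len(nTrials), function(k) {
    t <- (0:4569) / 1000
    phi <- runif(1, 0, 2 * pi)
    shared <- sin(2 * pi * 70 * t + phi) + rnorm(4570, 0, 0.3)
    lag <- sin(2 * pi * 70 * t + phi - pi / 4) + rnorm(4570, 0, 0.3)
    ind <- rnorm(4570)
    makeDerived("CsdTrial", rbind(shared, lag, ind, rnorm(4570)))
  })
}

test_that("spectrolaminar profiles separate locked from independent channels", {
  trials <- phcFixture()
  bank <- buildWaveletBank()
  prof <- spectrolaminarPhcProfile(trials, trials, refChannel = 1, bank,
                                   bandHz = c(60, 80), kind = "csd_esa",
                                   targetChannels = 2:4)
  g <- phcGammaSummary(prof)
  expect_gt(g[2], 0.5)                      # locked channel
  expect_lt(abs(g[3]), 0.1)                 # independent channel
  expect_true(is.na(g[1]))                  # not a target

  ## csd_csd excludes the reference and both adjacent channels
  prof2 <- spectrolaminarPhcProfile(trials, trials, refChannel = 2, bank,
                                    bandHz = c(60, 80), kind = "csd_csd")
  expect_true(all(is.na(phcValues(prof2)[1:3, ])))
  expect_false(anyNA(phcValues(prof2)[4, ]))

  ## shuffling the trial pairing destroys the coherence
  shuffled <- trials[c(2:length(trials), 1)]
  prof3 <- spectrolaminarPhcProfile(trials, shuffled, refChannel = 1, bank,
                                    bandHz = c(60, 80), kind = "csd_esa",
                                    targetChannels = 2L)
  expect_lt(phcGammaSummary(prof3)[2], 0.15)
})

test_that("attention contrast selects the max-coherence partner and compares conditions", {
  mk <- function(noiseSd, nTrials, seed) {
    set.seed(seed)
    lapply(seq_len(nTrials), function(k) {
      t <- (0:4569) / 1000
      phi <- runif(1, 0, 2 * pi)
      ref <- sin(2 * pi * 70 * t + phi) + rnorm(4570, 0, 0.2)
      good <- sin(2 * pi * 70 * t + phi + 0.4) + rnorm(4570, 0, noiseSd)
      weak <- sin(2 * pi * 70 * t + runif(1, 0, 2 * pi)) + rnorm(4570, 0, 1)
      makeDerived("CsdTrial", rbind(ref, rnorm(4570), weak, good))
    })
  }
  bank <- buildWaveletBank()
  res <- attentionPhcContrast(mk(0.3, 10, 14), mk(1.5, 10, 15),
                              refChannel = 1, partnerChannels = 3:4,
                              bank, bandHz = c(60, 80))
  expect_equal(res$partner, 4L)
  expect_gt(res$phcAttendIn, res$phcAttendNearby)
})
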