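test_that("ground truth defaults carry the three oscillator frequencies", {
  gt <- buildGroundTruth()
  f <- vapply(gt$oscillators, function(o) o$baseFreqHz, numeric(1))
  expect_equal(unname(f), c(67.0, 70.7, 65.3))
  ## attend-in supragranular frequency is base + shift = 68.2 Hz
  expect_equal(gt$oscillators$SG$baseFreqHz +
                 gt$oscillators$SG$freqShiftHz[["attend_in"]], 68.2)
  expect_error(buildGroundTruth(list(oscillators = list(
    G_upper = list(baseFreqHz = 200)))), "35-120")
  ## determinism of the configuration
  expect_identical(buildGroundTruth(list(seed = 4L)),
                   buildGroundTruth(list(seed = 4L)))
})

test_that("a lone oscillator is a balanced profile with the configured gain", {
  gt <- quietGroundTruth(extra = list(
    oscillators = list(SG = list(baseAmplitude = 0),
                       IG = list(baseAmplitude = 0))))
  set.seed(21)
  tcIn <- synthesizeGroundTruthCsd(gt, "attend_in")
  set.seed(21)
  tcAway <- synthesizeGroundTruthCsd(gt, "attend_away")
  dz <- tcIn$zUm[2] - tcIn$zUm[1]
  ## depth integral ~ 0 at every instant, relative to the peak amplitude
  sums <- colSums(tcIn$data[, 3000:3010]) * dz
  expect_lt(max(abs(sums)) / max(abs(tcIn$data)), 1e-6)
  ## amplitude ratio between conditions equals the configured gain
  win <- 10000:20000
  zi <- which.min(abs(tcIn$zUm - 800))
  ratio <- sd(tcIn$data[zi, win]) / sd(tcAway$data[zi, win])
  expect_equal(ratio, sqrt(1.285), tolerance = 1e-6)
})

test_that("successive trials share parameters but not noise", {
  gt <- buildGroundTruth(list(seed = 6L))
  set.seed(6)
  a <- synthesizeGroundTruthCsd(gt, "attend_in")
  b <- synthesizeGroundTruthCsd(gt, "attend_in")
  expect_false(isTRUE(all.equal(a$data, b$data)))
  expect_equal(dim(a$data), dim(b$data))
})

test_that("forward model is linear and peaks at the source electrode", {
  pr <- probeGeometry(16)
  z <- seq(0, 1500, by = 20)
  zero <- structure(list(zUm = z, data = matrix(0, length(z), 3), fs = 5000),
                    class = "TrueCsd")
  expect_equal(max(abs(forwardModelLfp(zero, pr))), 0)
  point <- matrix(0, length(z), 1)
  point[which.min(abs(z - 700)), 1] <- 1           # at electrode 8
  tc <- structure(list(zUm = z, data = point, fs = 5000), class = "TrueCsd")
  phi <- forwardModelLfp(tc, pr)[, 1]
  expect_equal(which.max(phi), 8L)
  expect_true(all(diff(phi[8:16]) < 0) && all(diff(phi[1:8]) > 0))
  tc2 <- structure(list(zUm = z, data = 2 * point, fs = 5000),
                   class = "TrueCsd")
  expect_equal(forwardModelLfp(tc2, pr), 2 * phi |> matrix(ncol = 1),
               tolerance = 1e-12)
  short <- structure(list(zUm = z[1:10], data = point[1:10, , drop = FALSE],
                          fs = 5000), class = "TrueCsd")
  expect_error(forwardModelLfp(short, pr), "cover")
})

test_that("spiking is a rate-modulated point process on the local phase", {
  gt <- buildGroundTruth(list(seed = 8L,
                              noise = list(sdAm3 = 0, sensorSdV = 0)))
  set.seed(8)
  tc <- synthesizeGroundTruthCsd(gt, "attend_in")
  ## silent channel for zero base rate
  gt0 <- buildGroundTruth(list(seed = 8L, spiking = list(baseRateHz = 0)))
  expect_equal(max(abs(synthesizeSpiking(gt0, tc, 4))), 0)
  ## events appear at a plausible overall rate
  set.seed(9)
  x <- synthesizeSpiking(gt, tc, 4)
  expect_gt(sum(abs(x) > 0), 100)
  expect_error(synthesizeSpiking(gt, tc, 99), "channel")
})

test_that("sessions are balanced, labelled and reproducible from the seed", {
  gt <- buildGroundTruth(list(seed = 10L))
  s1 <- simulateSession(gt, c(attend_in = 3, attend_nearby = 3,
                              attend_away = 3))
  expect_equal(length(s1@trials), 9L)
  att <- vapply(s1@trials, function(tr) tr@condition@attention, character(1))
  expect_equal(as.integer(table(att)[c("attend_in", "attend_nearby",
                                       "attend_away")]), rep(3L, 3))
  s2 <- simulateSession(gt, c(attend_in = 3, attend_nearby = 3,
                              attend_away = 3))
  expect_identical(s1@trials[[1]]@data, s2@trials[[1]]@data)
  expect_error(simulateSession(buildGroundTruth(list(fsRaw = 3000))),
               "fsRaw too low")
})
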