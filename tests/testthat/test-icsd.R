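test_that("disc potential kernel matches its closed form and limits", {
  p <- icsdParams()
  expect_equal(discPotentialKernel(0, p), 500e-6 / (2 * 0.4))   # R/(2 sigma)
  expect_lt(discPotentialKernel(1e7, p) / discPotentialKernel(0, p),
            1e-4)                                                # dz -> Inf
  tiny <- icsdParams(discRadiusUm = 1e-6)
  expect_lt(discPotentialKernel(300, tiny), 1e-12)              # R -> 0
})

test_that("forward matrix has the expected shape, sign and scaling", {
  pr <- probeGeometry(16)
  fm <- buildForwardMatrix(pr)
  expect_equal(dim(fm$F), c(16L, 16L))
  phiUniform <- fm$F %*% rep(1, 16)
  expect_true(all(phiUniform > 0))
  expect_gt(min(phiUniform[7:10]), max(phiUniform[c(1, 16)]))   # central max
  fmHalf <- buildForwardMatrix(pr, icsdParams(conductivitySm = 0.2))
  expect_equal(fmHalf$F, 2 * fm$F, tolerance = 1e-12)
  ## grid refinement changes F by < 0.1%
  fmFine <- buildForwardMatrix(pr, icsdParams(gridStepUm = 2.5))
  expect_lt(max(abs(fmFine$F - fm$F)) / max(abs(fm$F)), 1e-3)
})

test_that("inversion is the exact inverse of the forward matrix", {
  pr <- probeGeometry(16)
  fm <- buildForwardMatrix(pr)
  set.seed(11)
  for (i in 1:20) {
    c0 <- rnorm(16)
    phi <- fm$F %*% c0
    lfp <- makeDerived("LfpTrial", matrix(rep(phi, 5), 16))
    rec <- trialData(invertSplineIcsd(lfp, fm))[, 1]
    expect_lt(max(abs(rec - c0)) / max(abs(c0)), 1e-8)
  }
  zero <- makeDerived("LfpTrial", matrix(0, 16, 100))
  expect_equal(max(abs(trialData(invertSplineIcsd(zero, fm)))), 0)
})

test_that("CSD output is linear in the LFP input", {
  pr <- probeGeometry(16)
  fm <- buildForwardMatrix(pr)
  set.seed(2)
  m <- matrix(rnorm(16 * 50), 16)
  c1 <- trialData(invertSplineIcsd(makeDerived("LfpTrial", m), fm))
  c2 <- trialData(invertSplineIcsd(makeDerived("LfpTrial", 2.5 * m), fm))
  expect_equal(c2, 2.5 * c1, tolerance = 1e-12)
})

test_that("depth smoothing uses a unit-sum truncated Gaussian", {
  pr <- probeGeometry(16)
  const <- makeDerived("CsdTrial", matrix(3.2, 16, 10))
  sm <- smoothDepthProfile(const)
  expect_equal(trialData(sm), trialData(const), tolerance = 1e-12)

  ## impulse far from the probe ends: plain truncated, normalized Gaussian
  imp <- matrix(0, 24, 1); imp[12, 1] <- 1
  smi <- trialData(smoothDepthProfile(makeDerived("CsdTrial", imp)))[, 1]
  d <- (0:23) * 100
  w <- exp(-(d - 1100)^2 / (2 * 200^2))
  w[abs(d - 1100) > 500] <- 0
  expect_equal(smi[7:17], (w / sum(w))[7:17], tolerance = 1e-12)

  set.seed(3)
  rough <- makeDerived("CsdTrial", matrix(rnorm(16), 16, 1))
  tv <- function(x) sum(abs(diff(x)))
  expect_lt(tv(trialData(smoothDepthProfile(rough))[, 1]),
            tv(trialData(rough)[, 1]))
})

test_that("fine-grid forward model round-trips through the inversion", {
  ## smooth synthetic CSD supported inside the probe span
  pr <- probeGeometry(16)
  fm <- buildForwardMatrix(pr)
  z <- seq(0, 1500, by = 20)
  prof <- exp(-(z - 600)^2 / (2 * 180^2)) - 0.5 * exp(-(z - 1000)^2 / (2 * 220^2))
  tc <- structure(list(zUm = z, data = matrix(prof, ncol = 1), fs = 5000),
                  class = "TrueCsd")
  phi <- forwardModelLfp(tc, pr)
  lfp <- makeDerived("LfpTrial", matrix(rep(phi, 5), 16))
  rec <- trialData(invertSplineIcsd(lfp, fm))[, 1]
  truth <- approx(z, prof, depthsUm(pr))$y
  relRms <- sqrt(mean((rec - truth)^2)) / sqrt(mean(truth^2))
  expect_lt(relRms, 0.02)
})

test_that("evoked-onset map averages eligible trials only", {
  pr <- probeGeometry(16)
  fm <- buildForwardMatrix(pr)
  set.seed(4)
  m <- noiseMatrix(16)
  mk <- function(data, rf) derivedTrial("LfpTrial", data,
    depthsUm = depthsUm(pr), trialEpochs(1000),
    condition("attend_in", rfStimPresent = rf))
  one <- evokedOnsetCsd(list(mk(m, TRUE)), fm)
  expect_equal(dim(one$csd), c(16L, 250L))
  ## N identical eligible trials give the single-trial map; an ineligible
  ## trial with different data must not change it
  many <- evokedOnsetCsd(list(mk(m, TRUE), mk(m, TRUE),
                              mk(noiseMatrix(16), FALSE)), fm)
  expect_equal(many$csd, one$csd, tolerance = 1e-12)
  expect_error(evokedOnsetCsd(list(mk(m, FALSE)), fm), "no eligible")
})
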