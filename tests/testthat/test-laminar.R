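mkEvoked <- function(profile) {
  structure(list(csd = matrix(profile, length(profile), 250),
                 depthsUm = (seq_along(profile) - 1) * 100,
                 timesMs = 0:249), class = "EvokedCsdMap")
}

test_that("polarity inversion picks the most superficial source/sink pair", {
  ## (+, +, -, -, ...) over the first channels: border between ch 2 and 3
  b <- detectPolarityInversion(mkEvoked(c(1, 1, -1, -1, 0.5, -0.5, 0, 0)))
  expect_equal(b, 150)
  expect_error(detectPolarityInversion(mkEvoked(rep(1, 8))), "no source")
  expect_error(detectPolarityInversion(mkEvoked(c(1, -1, 1, -1))),
               "at least 6")
})

test_that("baseline correlation matrix recovers shared-signal structure", {
  set.seed(5)
  ## identical low-frequency signals on all channels -> r = 1
  slow <- cumsum(rnorm(4570)) / 10
  same <- lapply(1:3, function(i)
    makeDerived("CsdTrial", matrix(rep(slow, 4), 4, byrow = TRUE) +
                  matrix(rnorm(4 * 4570, 0, 1e-8), 4)))
  cm <- baselineCsdCorrelationMatrix(same)
  expect_equal(unname(cm[1, 2]), 1, tolerance = 1e-3)
  expect_equal(diag(cm), rep(1, 4))

  ## independent channels: median correlation near zero
  indep <- lapply(1:50, function(i) makeDerived("CsdTrial", noiseMatrix(6)))
  cmi <- baselineCsdCorrelationMatrix(indep)
  offdiag <- cmi[upper.tri(cmi)]
  expect_lt(median(abs(offdiag)), 0.1)
  expect_lt(max(abs(offdiag)), 0.15)
  expect_error(baselineCsdCorrelationMatrix(indep[1]), "at least 2")
})

test_that("correlation refinement finds a two-block edge and falls back on ties", {
  pr <- probeGeometry(16)
  ## perfect two-block matrix with the edge between channels 7 and 8
  blocks <- matrix(0.05, 16, 16)
  blocks[1:7, 1:7] <- 0.9; blocks[8:16, 8:16] <- 0.9; diag(blocks) <- 1
  for (init in c(450, 650, 850)) {
    expect_equal(refineBorderFromCorrelation(blocks, init, pr), 650)
  }
  uniform <- matrix(0.5, 16, 16); diag(uniform) <- 1
  expect_equal(refineBorderFromCorrelation(uniform, 750, pr), 750)
})

test_that("domain assignment partitions channels with a half-open granular band", {
  pr <- probeGeometry(16)
  asg <- assignDomains(750, pr)
  expect_equal(domainChannels(asg, "SG"), 1:8)     # depths 0-700
  expect_equal(domainChannels(asg, "G"), 9:13)     # depths 800-1250
  expect_equal(domainChannels(asg, "IG"), 14:16)
  expect_equal(sum(lengths(lapply(c("SG", "G", "IG"),
                                  domainChannels, assignment = asg))), 16L)
  ## a channel exactly at the border is granular
  asg2 <- assignDomains(800, pr)
  expect_equal(domainOf(asg2)[9], "G")
  ## border above the probe: no supragranular channels
  asg3 <- assignDomains(-50, pr)
  expect_equal(sum(domainOf(asg3) == "SG"), 0L)
  expect_true(all(domainOf(asg3) %in% c("G", "IG")))
})

test_that("assignment validity rejects inconsistent labellings", {
  expect_error(new("LaminarAssignment", borderUm = 500,
                   domains = c("G", "SG"), depthsUm = c(0, 600),
                   method = "polarity"), "strictly above|within")
})
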