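test_that("trial epochs follow the task structure and the lever-release rule", {
  ep <- trialEpochs(5000)
  expect_equal(ep@baselineMs, c(0, 1050))
  expect_equal(ep@stimOnsetMs, 1050)
  expect_equal(ep@staticEndMs, 1570)
  expect_equal(diff(ep@mcBoundsMs), rep(1000, 3))
  expect_equal(ep@analysisEndMs, 4570)

  ## release 200 ms into MC3: analysis stops 150 ms before it
  rel <- 1570 + 2000 + 200
  ep2 <- trialEpochs(1000, leverReleaseMs = rel)
  expect_equal(ep2@analysisEndMs, rel - 150)
  expect_equal(epochWindow(ep2, "mc23"), c(2570, rel - 150))

  ## release outside the analysed window: analysis runs to the end of MC3
  ep3 <- trialEpochs(1000, leverReleaseMs = 1570 + 3000 + 100)
  expect_equal(ep3@analysisEndMs, 4570)
})

test_that("conditions carry exactly one valid attention label", {
  expect_error(condition("attend_elsewhere"), "attention")
  expect_equal(condition("attend_nearby")@attention, "attend_nearby")
})

test_that("epoch slicing is half-open and concatenation-exact", {
  set.seed(1)
  tr <- makeDerived("LfpTrial", noiseMatrix(4))
  expect_equal(ncol(sliceEpoch(tr, "baseline")), 1050)
  expect_equal(ncol(sliceEpoch(tr, c(0, 0))), 0)
  expect_error(sliceEpoch(tr, c(0, 99999)), "outside")
  joined <- cbind(sliceEpoch(tr, c(0, 700)), sliceEpoch(tr, c(700, 1500)))
  expect_identical(joined, sliceEpoch(tr, c(0, 1500)))
  ## mc23 ends 150 ms before a lever release inside MC3
  tr2 <- makeDerived("CsdTrial", noiseMatrix(4), leverReleaseMs = 3770)
  expect_equal(ncol(sliceEpoch(tr2, "mc23")), 3620 - 2570)
})

test_that("session round-trips through the directory format at float32", {
  set.seed(42)
  pr <- probeGeometry(4)
  trials <- lapply(c("attend_in", "attend_away"), function(att)
    broadbandTrial(matrix(rnorm(4 * 5000), 4), 5000, trialEpochs(5000),
                   condition(att)))
  s <- session(pr, trials, performance = 0.82,
               metadata = list(seed = 42))
  dir <- withr::local_tempdir()
  writeSession(s, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  s2 <- readSession(dir)
  expect_equal(length(s2@trials), 2L)
  expect_equal(s2@performance, 0.82)
  expect_equal(s2@trials[[1]]@condition@attention, "attend_in")
  ## float32 rounding only
  expect_lt(max(abs(s2@trials[[1]]@data - s@trials[[1]]@data)), 1e-6)
  expect_equal(s2@trials[[2]]@epochs@analysisEndMs,
               s@trials[[2]]@epochs@analysisEndMs)
})

test_that("session invariants are enforced on write and read", {
  pr <- probeGeometry(4)
  bad <- broadbandTrial(matrix(0, 3, 100), 5000, trialEpochs(5000),
                        condition("attend_in"))
  expect_error(session(pr, list(bad)), "channel count")
  ok <- broadbandTrial(matrix(0, 4, 100), 5000, trialEpochs(5000),
                       condition("attend_in"))
  s <- session(pr, list(ok))
  dir <- withr::local_tempdir()
  writeSession(s, dir)
  unlink(file.path(dir, "trial_0001.f32"))
  expect_error(readSession(dir), "missing trial binary")
})

test_that("a low-performance session still loads (filtering is downstream)", {
  pr <- probeGeometry(4)
  ok <- broadbandTrial(matrix(0, 4, 100), 5000, trialEpochs(5000),
                       condition("attend_in"))
  dir <- withr::local_tempdir()
  writeSession(session(pr, list(ok), performance = 0.60), dir)
  expect_equal(readSession(dir)@performance, 0.60)
})
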