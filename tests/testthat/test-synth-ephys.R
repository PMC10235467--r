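test_that("rate profile is baseline-flat when the fold change is 1", {
  pr <- simulateRateProfile(ephysParams(baselineRate = 4.2, foldChange = 1),
                            sweepProtocol())
  expect_true(all(pr == 4.2))
  expect_equal(length(pr), 150000)
})

test_that("rate profile confines the response to the light window plus decay", {
  p <- ephysParams(baselineRate = 4, foldChange = 2, decayTau = 10)
  proto <- sweepProtocol()
  pr <- simulateRateProfile(p, proto)
  dt <- attr(pr, "dt")
  t <- (seq_along(pr) - 0.5) * dt
  expect_true(all(pr[t < 50] == 4))
  expect_true(all(pr[t >= 50 & t < 55] == 8))
  # closed form 10 s after light-off: r * (1 + (k-1) * exp(-1))
  i <- which.min(abs(t - 65))
  expect_equal(pr[i], 4 * (1 + 1 * exp(-(t[i] - 55) / 10)))
  # continuity at light-off
  expect_lt(abs(pr[which(t >= 55)[1]] - 8), 0.01)
  # tau = 0: immediate return to baseline
  pr0 <- simulateRateProfile(ephysParams(baselineRate = 4, foldChange = 2,
                                         decayTau = 0), proto)
  expect_true(all(pr0[t >= 55] == 4))
  # never below r * min(1, k) for a suppressive response
  prs <- simulateRateProfile(ephysParams(baselineRate = 4, foldChange = 0.5,
                                         decayTau = 10), proto)
  expect_true(all(prs >= 4 * 0.5 - 1e-12))
})

test_that("spike trains are empty at zero rate and reproducible under a seed", {
  proto <- sweepProtocol()
  expect_length(spikeTimes(simulateSpikeTrain(constProfile(0, 150), proto,
                                              seed = 1)), 0)
  a <- simulateSpikeTrain(simulateRateProfile(ephysParams(), proto), proto,
                          seed = 7)
  b <- simulateSpikeTrain(simulateRateProfile(ephysParams(), proto), proto,
                          seed = 7)
  expect_identical(spikeTimes(a), spikeTimes(b))
  expect_true(all(diff(spikeTimes(a)) >= 0.002))
})

test_that("spike counts match the dead-time-corrected analytic expectation", {
  proto <- sweepProtocol(preDark = 40, lightOn = 5, postDark = 5,
                         binWidth = 5)
  pr <- constProfile(4.2, 50)
  for (refr in c(0, 0.002)) {
    counts <- vapply(1:200, function(s)
      length(simulateSpikeTrain(pr, proto, refractory = refr, seed = s)), 0)
    expected <- 4.2 * 50 / (1 + 4.2 * refr)
    se <- sd(counts) / sqrt(200)
    expect_lt(abs(mean(counts) - expected), 3 * se)
  }
})

test_that("rendered traces carry the DC light step and exact spike count", {
  proto <- shortProtocol()
  flat <- renderVoltageTrace(spikeTrain(numeric(), proto),
                             ephysParams(noiseSd = 0, lightDc = 5,
                                         resting = -50),
                             samplingRate = 2000)
  v <- traceVoltage(flat)
  t <- (seq_along(v) - 1) / 2000
  expect_true(all(v[t < 10] == -50))
  expect_true(all(abs(v[t > 10.01 & t < 14.99] - (-45)) < 1e-12))
  expect_true(all(v[t > 15.01] == -50))

  set.seed(11)
  truth <- sort(runif(20, 0.5, 19.5))
  truth <- truth[c(TRUE, diff(truth) > 0.05)]   # well separated
  tr <- renderVoltageTrace(spikeTrain(truth, proto), ephysParams(),
                           samplingRate = 2000, seed = 12)
  det <- detectSpikes(tr)
  expect_length(det, length(truth))
  expect_true(all(matchDistances(spikeTimes(det), truth) <= 0.001))

  tr2 <- renderVoltageTrace(spikeTrain(truth, proto), ephysParams(),
                            samplingRate = 2000, seed = 12)
  expect_identical(traceVoltage(tr), traceVoltage(tr2))
  expect_error(renderVoltageTrace(spikeTrain(truth, proto), ephysParams(),
                                  samplingRate = 500), "1 kHz")
})

test_that("cohort simulation is deterministic and labels cells correctly", {
  p <- ephysParamsFor("p12c", "blue")
  proto <- sweepProtocol()
  coh <- simulateEphysCohort(p, nCells = 1, protocol = proto,
                             masterSeed = 5, render = FALSE)
  expect_length(coh, 5)
  ids <- vapply(coh, function(x) x@meta$cellId, "")
  expect_length(unique(ids), 1)
  expect_equal(vapply(coh, function(x) x@meta$sweep, 0), 1:5)
  zts <- vapply(coh, function(x) x@meta$ztHour, 0)
  expect_true(all(zts >= 0 & zts <= 16))

  coh2 <- simulateEphysCohort(p, nCells = 1, protocol = proto,
                              masterSeed = 5, render = FALSE)
  expect_identical(lapply(coh, spikeTimes), lapply(coh2, spikeTimes))
})

test_that("the generator-analysis chain recovers the generative fold change", {
  # spike-level convergence of the FF-ratio estimator to k
  p <- ephysParamsFor("p12c", "blue")   # k = 1.958
  proto <- sweepProtocol()
  coh <- simulateEphysCohort(p, nCells = 40, protocol = proto,
                             masterSeed = 17, render = FALSE)
  ratios <- vapply(coh, function(st) ffRatio(computeFFRatio(st)), 0)
  cells <- vapply(coh, function(st) st@meta$cellId, "")
  gs <- aggregateGroup(ratios, cells, "p12c", 450)
  expect_lt(abs(groupMean(gs) - 1.958), 3 * groupSem(gs) + 0.02)
})
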