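test_that("noise-only traces yield zero events", {
  tr <- renderVoltageTrace(spikeTrain(numeric(), shortProtocol()),
                           ephysParams(), samplingRate = 2000, seed = 21)
  expect_length(detectSpikes(tr), 0)
})

test_that("two spikes inside the refractory floor merge with a collision warning", {
  proto <- shortProtocol()
  tr <- renderVoltageTrace(spikeTrain(c(8, 8.001, 12), proto),
                           ephysParams(), samplingRate = 10000, seed = 22)
  expect_warning(det <- detectSpikes(tr), "collision")
  expect_length(det, 2)
  expect_true(all(diff(spikeTimes(det)) >= 0.002))
})

test_that("binning follows the half-open protocol grid and conserves spikes", {
  proto <- sweepProtocol()
  # empty train
  b0 <- binSpikeCounts(spikeTrain(numeric(), proto))
  expect_true(all(c(b0$pre, b0$light, b0$post) == 0))
  # boundary convention: light onset belongs to light-on, light-off to post
  b1 <- binSpikeCounts(spikeTrain(c(50, 55), proto))
  expect_equal(b1$light, 1)
  expect_equal(b1$post[1], 1)
  expect_true(all(b1$pre == 0))
  # uniform 1 spike/s
  b2 <- binSpikeCounts(spikeTrain(seq(0.5, 149.5, by = 1), proto))
  expect_equal(b2$pre, rep(10, 5))
  expect_equal(b2$light, 5)
  expect_equal(b2$post, rep(10, 5))
  # conservation on random trains
  for (s in 1:10) {
    st <- simulateSpikeTrain(constProfile(3, 150), proto, seed = s)
    b <- binSpikeCounts(st)
    expect_equal(sum(b$pre) + b$light + sum(b$post),
                 sum(spikeTimes(st) < 105))
  }
  # spikes outside the protocol window breach the invariant
  bad <- spikeTrain(10, shortProtocol())
  bad@times <- 25
  expect_error(binSpikeCounts(bad), "outside the protocol")
})

test_that("FF ratio is a rate ratio with the documented conventions", {
  proto <- sweepProtocol()
  # exactly periodic 4 Hz -> stationary ratio 1
  ff <- computeFFRatio(spikeTrain(seq(0.125, 149.875, by = 0.25), proto))
  expect_equal(ffRatio(ff), 1)
  expect_equal(baselineRate(ff), 4)
  expect_equal(postStimulusBins(computeFFRatio(
    spikeTrain(seq(0.125, 149.875, by = 0.25), proto))), rep(1, 5))
  # 10 baseline spikes (0.2 Hz), 3 light-on spikes (0.6 Hz) -> 3.0
  st <- spikeTrain(c(seq(2.5, 47.5, by = 5), 51, 52, 53), proto)
  ff2 <- computeFFRatio(st)
  expect_equal(ffRatio(ff2), 3)
  expect_equal(baselineRate(ff2), 0.2)
  # post bin 1 with 4 spikes against a 0.2 Hz baseline -> 2.0
  st3 <- spikeTrain(c(seq(2.5, 47.5, by = 5), 56, 57, 58, 59), proto)
  expect_equal(computePostStimulusProfile(st3)[1], 2)
  # zero baseline -> undefined with a warning
  expect_warning(ff4 <- computeFFRatio(spikeTrain(c(51, 52), proto)),
                 "undefined")
  expect_true(is.na(ffRatio(ff4)))
})

test_that("baseline firing rate is the pre-window count over its duration", {
  proto <- sweepProtocol()
  st <- spikeTrain(seq(0, 49.9, length.out = 210), proto)
  expect_equal(computeBaselineFF(st), 4.2)
  expect_equal(computeBaselineFF(spikeTrain(numeric(), proto)), 0)
})

test_that("group aggregation averages sweeps within cell then cells", {
  # one cell, five identical sweeps
  g1 <- aggregateGroup(rep(1.5, 5), rep("c1", 5), "p12c", 450)
  expect_equal(groupMean(g1), 1.5)
  expect_true(is.na(groupSem(g1)))
  expect_equal(g1@n, 1L)
  # three cells {1, 2, 3}
  g2 <- aggregateGroup(c(1, 2, 3), c("a", "b", "c"), "p12c", 450)
  expect_equal(groupMean(g2), 2)
  expect_equal(groupSem(g2), 1 / sqrt(3))
  # undefined sweeps are dropped; fully-undefined cells are excluded
  g3 <- aggregateGroup(c(1, NA, 3, NA, NA), c("a", "a", "b", "b", "c"),
                       "p12c", 450)
  expect_equal(g3@n, 2L)
  expect_equal(g3@nExcluded, 1L)
  expect_equal(groupMean(g3), 2)
  expect_error(aggregateGroup(c(NA, NA), c("a", "b")), "no cells")
})

test_that("detection on generator output is near-perfect at default noise", {
  proto <- sweepProtocol()
  p <- ephysParamsFor("p12c", "blue")
  nTrue <- 0; nDet <- 0; nHit <- 0
  for (s in 1:3) {
    st <- simulateSpikeTrain(simulateRateProfile(p, proto), proto,
                             seed = 100 + s)
    tr <- renderVoltageTrace(st, p, samplingRate = 10000, seed = 200 + s)
    det <- detectSpikes(tr)
    d <- matchDistances(spikeTimes(det), spikeTimes(st))
    nTrue <- nTrue + length(st)
    nDet <- nDet + length(det)
    nHit <- nHit + sum(d <= 0.001)
  }
  expect_gte(nHit / nTrue, 0.99)          # sensitivity
  expect_gte(nHit / nDet, 0.99)           # precision
})

test_that("baseline shows no ZT correlation in generated cohorts", {
  res <- runEphysPipeline(list(seed = 31, genotypes = "p12c",
                               colors = "blue", n_cells = 25,
                               render = FALSE))
  bz <- res$baselineZt
  expect_gt(bz$p[bz$genotype == "p12c"], 0.1)
  expect_lt(abs(bz$pearsonR[bz$genotype == "p12c"]), 0.4)
})
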