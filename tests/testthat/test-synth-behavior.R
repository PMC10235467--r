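test_that("forced arousal and forced sleep-through behave exactly", {
  sched <- pulseSchedule()
  p1 <- behaviorParams(arousalProb = 1)
  p0 <- behaviorParams(arousalProb = 0)
  for (s in 1:3) {
    v1 <- simulateFlyActivity(p1, sched, seed = s)
    ev <- attr(v1, "pulseEvents")
    for (k in which(ev$asleepAtOnset)) {
      win <- ev$onset[k]:(ev$onset[k] + sched@duration - 1)
      expect_gte(sum(v1[win]), 1)
    }
    v0 <- simulateFlyActivity(p0, sched, seed = s)
    ev0 <- attr(v0, "pulseEvents")
    for (k in which(ev0$asleepAtOnset)) {
      win <- ev0$onset[k]:(ev0$onset[k] + sched@duration - 1)
      expect_equal(sum(v0[win]), 0)
    }
  }
})

test_that("fly activity is reproducible under a fixed seed", {
  p <- behaviorParamsFor("p12c", "UV", 10)
  v1 <- simulateFlyActivity(p, pulseSchedule(), seed = 9)
  v2 <- simulateFlyActivity(p, pulseSchedule(), seed = 9)
  expect_identical(as.integer(v1), as.integer(v2))
  expect_identical(attr(v1, "asleep"), attr(v2, "asleep"))
})

test_that("generated sleep bouts satisfy the 5-min rule exactly", {
  p <- behaviorParamsFor("p12c", "UV", 10)
  agree <- 0; total <- 0
  for (s in 1:5) {
    v <- simulateFlyActivity(p, pulseSchedule(), seed = 40 + s)
    truth <- attr(v, "asleep")
    called <- sleepState(classifySleep(as.integer(v)))
    bouts <- sleepBouts(classifySleep(as.integer(v)))
    expect_true(all(bouts$duration >= 5))
    agree <- agree + sum(truth == called)
    total <- total + length(truth)
  }
  expect_gte(agree / total, 0.99)
})

test_that("monitor cohorts fill channels, flag unused ones, and split at 32", {
  p <- behaviorParamsFor("p12c", "UV", 10)
  sched <- pulseSchedule()
  rec <- simulateDamCohort(p, 32, sched, masterSeed = 3)
  expect_s4_class(rec, "DamRecord")
  expect_true(all(colSums(damCounts(rec)) > 0))
  expect_equal(sum(damLightStatus(rec)), 3 * 3 * 5)

  rec8 <- simulateDamCohort(p, 8, sched, masterSeed = 3)
  expect_equal(rec8@meta$unusedChannels, 9:32)
  expect_true(all(damCounts(rec8)[, 9:32] == 0))

  recs <- simulateDamCohort(p, 40, sched, masterSeed = 3)
  expect_length(recs, 2)
  expect_s4_class(recs[[1]], "DamRecord")
})

test_that("cohort monitor files are byte-identical under a fixed master seed", {
  p <- behaviorParamsFor("p12c", "UV", 10)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  writeDamFile(simulateDamCohort(p, 8, pulseSchedule(), masterSeed = 77), p1)
  writeDamFile(simulateDamCohort(p, 8, pulseSchedule(), masterSeed = 77), p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("the aroused fraction converges to the generative probability", {
  p <- behaviorParamsFor("p12c", "UV", 10)   # p = 0.8503
  sched <- pulseSchedule()
  nElig <- 0; nArous <- 0
  for (s in 1:3) {
    rec <- simulateDamCohort(p, 32, sched, masterSeed = 500 + s)
    oc <- scorePulseArousal(rec, sched)
    nElig <- nElig + sum(oc$asleep)
    nArous <- nArous + sum(oc$aroused)
  }
  expect_gte(nElig, 200)
  phat <- nArous / nElig
  se <- sqrt(0.8503 * (1 - 0.8503) / nElig)
  expect_lt(abs(phat - 0.8503), 3 * se)
})
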