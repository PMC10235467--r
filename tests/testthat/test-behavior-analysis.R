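test_that("sleep classification applies the 5-min inactivity rule", {
  # all-zero hour: one 60-min bout
  s1 <- classifySleep(rep(0L, 60))
  expect_true(all(sleepState(s1)))
  expect_equal(sleepBouts(s1), data.frame(start = 1L, duration = 60L))
  # 7-min zero run at minutes 10-16: exactly those minutes asleep
  x <- rep(2L, 26); x[10:16] <- 0L
  expect_equal(which(sleepState(classifySleep(x))), 10:16)
  # a 4-min run is not sleep
  y <- rep(2L, 20); y[8:11] <- 0L
  expect_false(any(sleepState(classifySleep(y))))
  expect_equal(nrow(sleepBouts(classifySleep(y))), 0)
})

test_that("pulse scoring applies the denominator, arousal and dead-fly rules", {
  sched <- pulseSchedule(nights = 1)
  nMin <- 1440
  ts <- as.POSIXct("2024-01-01 08:00:00", tz = "UTC") + 60 * (0:(nMin - 1))
  onset <- 18 * 60 + 1
  cnt <- matrix(0L, nMin, 32)
  # fly 1: asleep at onset, responds during the pulse
  cnt[, 1] <- 1L; cnt[(onset - 30):(onset + 20), 1] <- 0L
  cnt[onset + 2, 1] <- 3L
  # fly 2: asleep at onset, sleeps through
  cnt[, 2] <- 1L; cnt[(onset - 30):(onset + 30), 2] <- 0L
  # fly 3: active in the minute before the pulse -> not in denominator
  cnt[, 3] <- 1L; cnt[(onset - 30):(onset + 20), 3] <- 0L
  cnt[onset - 1, 3] <- 2L; cnt[onset + 1, 3] <- 2L
  # fly 4: dead (never any counts)
  rec <- damRecord(cnt, ts)
  oc <- scorePulseArousal(rec, sched)
  p1 <- oc[oc$fly == 1 & oc$pulse == 1, ]
  expect_true(p1$asleep && p1$aroused)
  p2 <- oc[oc$fly == 2 & oc$pulse == 1, ]
  expect_true(p2$asleep && !p2$aroused)
  p3 <- oc[oc$fly == 3 & oc$pulse == 1, ]
  expect_false(p3$asleep)
  expect_true(all(oc$dead[oc$fly == 4]))
  expect_false(any(oc$asleep[oc$fly == 4]))
  # pulse outside the recording is an error
  expect_error(scorePulseArousal(rec, pulseSchedule(nights = 2)),
               "outside the recording")
})

test_that("hand-counted arousal percentages are reproduced exactly", {
  # 8 flies, 6 asleep at onset, 3 of those aroused -> 50%
  oc <- data.frame(fly = 1:8, night = 1, pulse = 1,
                   asleep = rep(c(TRUE, FALSE), c(6, 2)),
                   aroused = rep(c(TRUE, FALSE), c(3, 5)),
                   dead = FALSE)
  sm <- summarizeArousal(oc)
  expect_equal(arousalTotalPct(sm), 50)
  # all pulses at 100%
  oc2 <- expand.grid(fly = 1:4, night = 1:3, pulse = 1:3)
  oc2$asleep <- TRUE; oc2$aroused <- TRUE; oc2$dead <- FALSE
  expect_equal(arousalTotalPct(summarizeArousal(oc2)), 100)
  # pulses at 80/60/70% with equal denominators -> total 70%
  oc3 <- expand.grid(fly = 1:10, night = 1, pulse = 1:3)
  oc3$asleep <- TRUE
  oc3$aroused <- with(oc3, (pulse == 1 & fly <= 8) |
                        (pulse == 2 & fly <= 6) | (pulse == 3 & fly <= 7))
  oc3$dead <- FALSE
  sm3 <- summarizeArousal(oc3)
  expect_equal(arousalTotalPct(sm3), 70)
  expect_equal(sort(sm3@perPulse$pctAroused), c(60, 70, 80))
  # empty denominator everywhere is an error
  oc4 <- data.frame(fly = 1, night = 1, pulse = 1, asleep = FALSE,
                    aroused = FALSE, dead = FALSE)
  expect_error(summarizeArousal(oc4), "empty")
})

test_that("scoring is order-independent over pulses", {
  p <- behaviorParamsFor("cry-null", "blue", 10)
  rec <- simulateDamCohort(p, 16, pulseSchedule(), masterSeed = 8)
  oc <- scorePulseArousal(rec, pulseSchedule())
  sm <- summarizeArousal(oc)
  ocShuffled <- oc[sample(nrow(oc)), ]
  smS <- summarizeArousal(ocShuffled)
  expect_equal(arousalTotalPct(smS), arousalTotalPct(sm))
  expect_equal(smS@perPulse, sm@perPulse)
})
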