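#' @importFrom stats rexp rgeom
NULL

#' Simulate one fly's beam-crossing record
#'
#' Alternating-renewal sleep/wake model on a 1-min grid under 12:12 LD
#' entrainment: sleep bouts are 5 min plus an exponential tail (so every
#' generated bout satisfies the 5-min sleep criterion), wake-bout means
#' are set so the stationary asleep fraction matches the day/night sleep
#' propensities, and every awake minute emits at least one beam crossing
#' (1 + Poisson counts). At each scheduled pulse onset a fly that is in
#' a sleep bout awakens with probability \code{arousalProb}; if aroused
#' it stays active for a geometric number of minutes (mean
#' \code{arousalActiveMin}), otherwise its bout is carried through the
#' pulse window. The response of a sleeping fly to a pulse is therefore
#' exactly Bernoulli(\code{arousalProb}).
#'
#' @param params a \code{\link{BehaviorParams}}
#' @param schedule a \code{\link{PulseSchedule}}
#' @param days number of 24-h days to simulate (>= \code{schedule@nights})
#' @param seed optional integer seed; fixed seed gives an identical record
#' @return integer vector of per-minute counts starting at ZT0, with
#'   attributes \code{asleep} (ground-truth per-minute sleep state) and
#'   \code{pulseEvents} (data.frame: night, pulse, onset minute,
#'   asleep-at-onset, eligibility under the 5-min prior-sleep rule, and
#'   the Bernoulli arousal outcome)
#' @export
simulateFlyActivity <- function(params, schedule, days = schedule@nights,
                                seed = NULL) {
  stopifnot(is(params, "BehaviorParams"), is(schedule, "PulseSchedule"))
  validObject(params); validObject(schedule)
  if (days < schedule@nights)
    stop("days must cover all pulse nights in the schedule")
  nMin <- as.integer(days * 1440)
  # pulse onset minutes (1-based; minute i spans ZT (i-1)/60)
  onsets <- integer(); onNight <- integer(); onPulse <- integer()
  for (night in seq_len(schedule@nights)) {
    for (j in seq_along(schedule@ztHours)) {
      i <- (night - 1L) * 1440L + as.integer(schedule@ztHours[j] * 60) + 1L
      onsets <- c(onsets, i); onNight <- c(onNight, night)
      onPulse <- c(onPulse, j)
    }
  }
  if (any(onsets + schedule@duration - 1L > nMin))
    stop("pulse schedule extends beyond the simulated days")
  mS <- params@meanSleepBout
  wakeMean <- function(propAsleep) mS * (1 - propAsleep) / propAsleep
  drawSleep <- function() 5L + as.integer(round(rexp(1, 1 / (mS - 5 + 1e-9))))
  drawWake <- function(zt) {
    m <- wakeMean(if (zt < 12) params@daySleepProp else params@nightSleepProp)
    max(1L, as.integer(round(rexp(1, 1 / m))))
  }
  run <- function() {
    asleep <- logical(nMin)
    state <- "sleep"; rem <- 0L   # toggles to a wake bout at minute 1 (ZT0)
    evAsleep <- logical(length(onsets))
    evEligible <- logical(length(onsets))
    evAroused <- rep(NA, length(onsets))
    prevNight <- NA
    for (i in seq_len(nMin)) {
      zt <- ((i - 1L) / 60) %% 24
      isNight <- zt >= 12
      # a wake bout spanning a lights-on/off transition is redrawn from
      # the new phase's distribution, so each phase reaches its stated
      # stationary sleep fraction
      if (!is.na(prevNight) && isNight != prevNight && state == "wake" &&
          rem > 0L) {
        m <- wakeMean(if (isNight) params@nightSleepProp
                      else params@daySleepProp)
        rem <- max(1L, as.integer(round(rexp(1, 1 / m))))
      }
      prevNight <- isNight
      ev <- match(i, onsets)
      if (!is.na(ev)) {
        if (state == "sleep") {
          evAsleep[ev] <- TRUE
          evEligible[ev] <- i > 5L && all(asleep[(i - 5L):(i - 1L)])
          if (runif(1) < params@arousalProb) {
            evAroused[ev] <- TRUE
            state <- "wake"
            rem <- 1L + rgeom(1, 1 / params@arousalActiveMin)
          } else {
            evAroused[ev] <- FALSE
            rem <- max(rem, as.integer(schedule@duration))
          }
        }
      }
      if (rem == 0L) {
        if (state == "sleep") {
          state <- "wake"; rem <- drawWake(zt)
        } else {
          state <- "sleep"; rem <- drawSleep()
        }
      }
      asleep[i] <- state == "sleep"
      rem <- rem - 1L
    }
    counts <- integer(nMin)
    nAwake <- sum(!asleep)
    counts[!asleep] <- 1L + rpois(nAwake, max(0, params@meanActivity - 1))
    list(counts = counts, asleep = asleep,
         events = data.frame(night = onNight, pulse = onPulse,
                             onset = onsets, asleepAtOnset = evAsleep,
                             eligible = evEligible, aroused = evAroused))
  }
  res <- withSeed(seed, run())
  structure(res$counts, asleep = res$asleep, pulseEvents = res$events)
}

#' Simulate a monitor cohort and package it as DAM records
#'
#' One channel per fly; channels beyond \code{nFlies} are zero-filled and
#' flagged in the metadata. More than 32 flies are split across several
#' monitors. Each fly's seed derives deterministically from the master
#' seed, so a fixed master seed reproduces the cohort (and its written
#' monitor file) byte for byte. The monitor's light-status column marks
#' every pulse minute.
#'
#' @param params a \code{\link{BehaviorParams}} for this condition
#' @param nFlies cohort size
#' @param schedule a \code{\link{PulseSchedule}}
#' @param masterSeed integer master seed
#' @param genotype genotype label stored in the metadata
#' @param days days to simulate (default: the schedule's pulse nights)
#' @param start clock time of the first minute (ZT0 of day 1)
#' @return a \code{\link{DamRecord}} for \code{nFlies <= 32}, otherwise a
#'   list of records. The per-fly generator ground truth is kept in
#'   \code{meta$truth}.
#' @export
simulateDamCohort <- function(params, nFlies, schedule, masterSeed,
                              genotype = "p12c", days = schedule@nights,
                              start = as.POSIXct("2024-01-01 08:00:00",
                                                 tz = "UTC")) {
  stopifnot(nFlies >= 1)
  if (nFlies > 32) {
    nMon <- ceiling(nFlies / 32)
    return(lapply(seq_len(nMon), function(k) {
      lo <- (k - 1L) * 32L + 1L
      simulateDamCohort(params, min(32L, nFlies - lo + 1L), schedule,
                        seedFrom(masterSeed, genotype, "monitor", k),
                        genotype = genotype, days = days, start = start)
    }))
  }
  nMin <- as.integer(days * 1440)
  counts <- matrix(0L, nMin, 32)
  truth <- vector("list", nFlies)
  for (f in seq_len(nFlies)) {
    v <- simulateFlyActivity(params, schedule, days = days,
                             seed = seedFrom(masterSeed, genotype, "fly", f))
    counts[, f] <- as.integer(v)
    truth[[f]] <- list(asleep = attr(v, "asleep"),
                       pulseEvents = attr(v, "pulseEvents"))
  }
  light <- integer(nMin)
  for (night in seq_len(schedule@nights)) {
    for (h in schedule@ztHours) {
      i <- (night - 1L) * 1440L + as.integer(h * 60) + 1L
      light[i:(i + schedule@duration - 1L)] <- 1L
    }
  }
  timestamps <- start + 60 * (seq_len(nMin) - 1)
  damRecord(counts, timestamps, lightStatus = light,
            monitor = sprintf("%s_M01", genotype),
            meta = list(ztStart = 0, genotype = genotype,
                        wavelength = schedule@wavelength,
                        intensity = schedule@intensity,
                        nFlies = nFlies,
                        unusedChannels = if (nFlies < 32)
                          (nFlies + 1L):32L else integer(),
                        truth = truth))
}
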