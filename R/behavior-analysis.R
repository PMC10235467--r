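#' Classify sleep from one fly's per-minute counts
#'
#' Applies the standard Drosophila sleep criterion: a minute is asleep
#' iff it lies inside a maximal run of at least \code{minBout}
#' consecutive zero-count minutes (default 5 min of inactivity).
#'
#' @param counts integer vector of per-minute beam crossings
#' @param minBout minimum inactivity run length (minutes) that counts as
#'   sleep
#' @return a \code{\link{SleepSeries}}
#' @examples
#' x <- c(rep(2, 9), rep(0, 7), rep(3, 10))
#' which(sleepState(classifySleep(x)))   # minutes 10-16
#' @export
classifySleep <- function(counts, minBout = 5) {
  stopifnot(all(counts >= 0))
  zero <- counts == 0
  asleep <- logical(length(counts))
  bouts <- data.frame(start = integer(), duration = integer())
  if (any(zero)) {
    r <- rle(zero)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= minBout
    for (i in which(keep)) asleep[starts[i]:ends[i]] <- TRUE
    bouts <- data.frame(start = starts[keep],
                        duration = r$lengths[keep])
  }
  new("SleepSeries", asleep = asleep, bouts = bouts)
}

#' Score per-pulse arousal for every fly of a monitor
#'
#' For each scheduled pulse, a fly enters the denominator iff it was
#' asleep at pulse onset (all five minutes before the onset have zero
#' counts); it counts as aroused iff at least one beam crossing occurs
#' within the pulse window. Flies with zero counts over the final 24 h
#' of the record are excluded as dead (unused zero-filled channels are
#' excluded the same way).
#'
#' @param record a \code{\link{DamRecord}}
#' @param schedule the \code{\link{PulseSchedule}} applied to the monitor
#' @param priorSleepMin minutes of pre-onset inactivity defining "asleep
#'   at onset"
#' @return data.frame with one row per fly x pulse: \code{fly},
#'   \code{night}, \code{pulse}, \code{asleep} (in denominator),
#'   \code{aroused}; dead/empty channels carry \code{dead = TRUE} and
#'   are excluded from both counts
#' @export
scorePulseArousal <- function(record, schedule, priorSleepMin = 5) {
  stopifnot(is(record, "DamRecord"), is(schedule, "PulseSchedule"))
  cn <- record@counts
  m <- nrow(cn)
  zt <- damZt(record)
  ztStart <- record@meta$ztStart %||% 0
  # pulse onset minute indices
  onsets <- integer(); onNight <- integer(); onPulse <- integer()
  for (night in seq_len(schedule@nights)) {
    for (j in seq_along(schedule@ztHours)) {
      tgt <- (night - 1) * 24 + schedule@ztHours[j]
      i <- as.integer(round((tgt - ztStart) * 60)) + 1L
      if (i < 1L || i + schedule@duration - 1L > m)
        stop(sprintf("pulse at night %d ZT%g lies outside the recording",
                     night, schedule@ztHours[j]))
      onsets <- c(onsets, i); onNight <- c(onNight, night)
      onPulse <- c(onPulse, j)
    }
  }
  dead <- colSums(cn[max(1L, m - 1439L):m, , drop = FALSE]) == 0
  out <- vector("list", 32L)
  for (f in seq_len(32L)) {
    v <- cn[, f]
    asleep <- vapply(onsets, function(i)
      i > priorSleepMin && all(v[(i - priorSleepMin):(i - 1L)] == 0L),
      logical(1))
    aroused <- vapply(seq_along(onsets), function(k) {
      i <- onsets[k]
      asleep[k] && any(v[i:(i + schedule@duration - 1L)] > 0L)
    }, logical(1))
    out[[f]] <- data.frame(fly = f, night = onNight, pulse = onPulse,
                           asleep = asleep & !dead[f],
                           aroused = aroused & !dead[f],
                           dead = dead[f])
  }
  do.call(rbind, out)
}

#' Summarize arousal outcomes for one condition
#'
#' Per-pulse percent aroused (aroused / asleep-at-onset flies) for every
#' night x pulse, a denominator-weighted total (total aroused / total
#' denominator over all pulses; the default), an unweighted mean of the
#' per-pulse percentages, and per-night means for the night-consistency
#' check.
#'
#' @param outcomes data.frame from \code{\link{scorePulseArousal}}
#' @param genotype,wavelength,intensity labels stored on the summary
#' @return an \code{\link{ArousalSummary}}
#' @examples
#' oc <- data.frame(fly = 1:8, night = 1, pulse = 1,
#'                  asleep = rep(c(TRUE, FALSE), c(6, 2)),
#'                  aroused = rep(c(TRUE, FALSE), c(3, 5)), dead = FALSE)
#' arousalTotalPct(summarizeArousal(oc))   # 50
#' @export
summarizeArousal <- function(outcomes, genotype = "", wavelength = NA_real_,
                             intensity = NA_real_) {
  oc <- outcomes[!outcomes$dead, , drop = FALSE]
  if (nrow(oc) == 0 || sum(oc$asleep) == 0)
    stop("no sleeping flies in any pulse denominator: empty summary")
  key <- interaction(oc$night, oc$pulse, drop = FALSE)
  nAsleep <- tapply(oc$asleep, key, sum)
  nAroused <- tapply(oc$aroused, key, sum)
  nights <- as.integer(sub("\\..*", "", names(nAsleep)))
  pulses <- as.integer(sub(".*\\.", "", names(nAsleep)))
  perPulse <- data.frame(
    night = nights, pulse = pulses,
    nAsleep = as.integer(nAsleep), nAroused = as.integer(nAroused),
    pctAroused = ifelse(nAsleep > 0, 100 * nAroused / nAsleep, NA_real_))
  perPulse <- perPulse[order(perPulse$night, perPulse$pulse), ]
  rownames(perPulse) <- NULL
  totalPct <- 100 * sum(perPulse$nAroused) / sum(perPulse$nAsleep)
  perNight <- tapply(perPulse$pctAroused, perPulse$night,
                     mean, na.rm = TRUE)
  new("ArousalSummary", genotype = genotype, wavelength = wavelength,
      intensity = intensity, perPulse = perPulse, totalPct = totalPct,
      totalPctUnweighted = mean(perPulse$pctAroused, na.rm = TRUE),
      perNight = as.numeric(perNight))
}
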