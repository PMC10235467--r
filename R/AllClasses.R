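#' @import methods
NULL

# ---- sweep protocol ---------------------------------------------------------

#' Light-stimulation sweep protocol
#'
#' Describes one current-clamp sweep of the light-evoked firing assay:
#' a dark baseline window, a short monochromatic light pulse, and an
#' inter-pulse dark recovery window. The analysis windows (10-s bins,
#' 5-s light-on window) are derived from these durations.
#'
#' @slot preDark seconds of darkness before the stimulus (baseline window)
#' @slot lightOn seconds of light stimulation
#' @slot postDark seconds of darkness after the stimulus
#' @slot nSweeps number of continuously repeated sweeps per recording
#' @slot binWidth width in seconds of the firing-rate analysis bins
#' @slot wavelength stimulus wavelength in nm (365, 405, 450 or 635)
#' @slot intensity stimulus irradiance in uW/cm^2
#' @name SweepProtocol-class
#' @rdname SweepProtocol
#' @exportClass SweepProtocol
setClass("SweepProtocol",
  representation(
    preDark = "numeric", lightOn = "numeric", postDark = "numeric",
    nSweeps = "numeric", binWidth = "numeric",
    wavelength = "numeric", intensity = "numeric"
  ),
  prototype(
    preDark = 50, lightOn = 5, postDark = 95, nSweeps = 5,
    binWidth = 10, wavelength = 450, intensity = 200
  )
)

setValidity("SweepProtocol", function(object) {
  msg <- character()
  durs <- c(object@preDark, object@lightOn, object@postDark, object@binWidth)
  if (any(!is.finite(durs)) || any(durs <= 0))
    msg <- c(msg, "all durations (preDark, lightOn, postDark, binWidth) must be > 0")
  else {
    if (abs(object@preDark / object@binWidth -
            round(object@preDark / object@binWidth)) > 1e-9)
      msg <- c(msg, "binWidth must divide preDark")
    if (object@lightOn > object@binWidth)
      msg <- c(msg, "lightOn must not exceed binWidth")
  }
  if (object@nSweeps < 1) msg <- c(msg, "nSweeps must be >= 1")
  if (is.finite(object@wavelength) &&
      !object@wavelength %in% c(365, 405, 450, 635))
    msg <- c(msg, "wavelength must be one of 365, 405, 450, 635 nm")
  if (length(msg)) msg else TRUE
})

#' @param preDark,lightOn,postDark,nSweeps,binWidth,wavelength,intensity see slots
#' @return a \code{SweepProtocol} object
#' @examples
#' sweepProtocol()                      # the default 50/5/95 s protocol
#' sweepProtocol(wavelength = 365)
#' @rdname SweepProtocol
#' @export
sweepProtocol <- function(preDark = 50, lightOn = 5, postDark = 95,
                          nSweeps = 5, binWidth = 10,
                          wavelength = 450, intensity = 200) {
  new("SweepProtocol", preDark = preDark, lightOn = lightOn,
      postDark = postDark, nSweeps = nSweeps, binWidth = binWidth,
      wavelength = wavelength, intensity = intensity)
}

#' Total sweep duration in seconds
#' @param protocol a \code{SweepProtocol}
#' @return numeric, \code{preDark + lightOn + postDark}
#' @export
protocolDuration <- function(protocol) {
  protocol@preDark + protocol@lightOn + protocol@postDark
}

setMethod("show", "SweepProtocol", function(object) {
  cat(sprintf(
    "SweepProtocol: %g s dark | %g s light (%g nm, %g uW/cm2) | %g s dark; %g sweeps, %g s bins\n",
    object@preDark, object@lightOn, object@wavelength, object@intensity,
    object@postDark, object@nSweeps, object@binWidth))
})

# ---- ephys generator parameters --------------------------------------------

#' Generative parameters for one genotype x wavelength ephys condition
#'
#' Parameters of the tonic-firing model used to synthesize l-LNv voltage
#' traces: a baseline tonic rate, a multiplicative light-on fold change,
#' an exponential post-stimulus decay constant, an absolute refractory
#' period, and the waveform/noise parameters used when rendering traces.
#'
#' @slot baselineRate tonic firing rate in darkness, Hz
#' @slot foldChange light-on rate multiplier (dimensionless, > 0)
#' @slot decayTau post-stimulus decay time constant in seconds; 0 means the
#'   rate returns to baseline immediately at light-off
#' @slot refractory absolute refractory period, seconds
#' @slot spikeAmp rendered spike amplitude, mV
#' @slot noiseSd standard deviation of Gaussian membrane noise, mV
#' @slot lightDc DC depolarization during the light window, mV
#' @slot resting resting membrane potential, mV
#' @name EphysParams-class
#' @rdname EphysParams
#' @exportClass EphysParams
setClass("EphysParams",
  representation(
    baselineRate = "numeric", foldChange = "numeric", decayTau = "numeric",
    refractory = "numeric", spikeAmp = "numeric", noiseSd = "numeric",
    lightDc = "numeric", resting = "numeric"
  ),
  prototype(
    baselineRate = 4.2, foldChange = 1.958, decayTau = 25,
    refractory = 0.002, spikeAmp = 40, noiseSd = 1.5,
    lightDc = 5, resting = -50
  )
)

setValidity("EphysParams", function(object) {
  msg <- character()
  if (object@baselineRate <= 0) msg <- c(msg, "baselineRate must be > 0")
  if (object@foldChange <= 0) msg <- c(msg, "foldChange must be > 0")
  if (object@decayTau < 0) msg <- c(msg, "decayTau must be >= 0")
  if (object@refractory < 0) msg <- c(msg, "refractory must be >= 0")
  if (object@baselineRate * object@refractory >= 1)
    msg <- c(msg, "baselineRate * refractory must be < 1")
  if (length(msg)) msg else TRUE
})

#' @param baselineRate,foldChange,decayTau,refractory,spikeAmp,noiseSd,lightDc,resting
#'   see slots
#' @return an \code{EphysParams} object
#' @examples
#' ephysParams(baselineRate = 4.2, foldChange = 1.958, decayTau = 25)
#' @rdname EphysParams
#' @export
ephysParams <- function(baselineRate = 4.2, foldChange = 1.958,
                        decayTau = 25, refractory = 0.002, spikeAmp = 40,
                        noiseSd = 1.5, lightDc = 5, resting = -50) {
  new("EphysParams", baselineRate = baselineRate, foldChange = foldChange,
      decayTau = decayTau, refractory = refractory, spikeAmp = spikeAmp,
      noiseSd = noiseSd, lightDc = lightDc, resting = resting)
}

setMethod("show", "EphysParams", function(object) {
  cat(sprintf(
    "EphysParams: %.2f Hz baseline, x%.3f during light, tau %.1f s, refractory %.0f ms\n",
    object@baselineRate, object@foldChange, object@decayTau,
    object@refractory * 1000))
})

# ---- voltage trace ----------------------------------------------------------

#' A uniformly sampled membrane-potential trace
#'
#' One sweep's membrane potential (mV) sampled at a fixed rate, with the
#' stimulation protocol that framed it and recording metadata (genotype,
#' wavelength, ZT hour, cell id, sweep index).
#'
#' @slot samplingRate samples per second
#' @slot voltage membrane potential in mV, one value per sample
#' @slot protocol the \code{SweepProtocol} the trace was recorded under
#' @slot meta named list of recording metadata
#' @name VoltageTrace-class
#' @rdname VoltageTrace
#' @exportClass VoltageTrace
setClass("VoltageTrace",
  representation(samplingRate = "numeric", voltage = "numeric",
                 protocol = "SweepProtocol", meta = "list"))

setValidity("VoltageTrace", function(object) {
  msg <- character()
  if (length(object@samplingRate) != 1 || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (any(!is.finite(object@voltage)))
    msg <- c(msg, "voltage must be finite (no NA/NaN/Inf samples)")
  wl <- object@meta$wavelength
  if (!is.null(wl) && !is.na(wl) && !wl %in% c(365, 405, 450, 635))
    msg <- c(msg, "meta wavelength must be one of 365, 405, 450, 635 nm")
  sw <- object@meta$sweep
  if (!is.null(sw) && !is.na(sw) && sw < 1)
    msg <- c(msg, "meta sweep index must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param samplingRate,voltage,protocol,meta see slots
#' @return a \code{VoltageTrace}
#' @rdname VoltageTrace
#' @export
voltageTrace <- function(voltage, samplingRate, protocol = sweepProtocol(),
                         meta = list()) {
  new("VoltageTrace", samplingRate = samplingRate, voltage = voltage,
      protocol = protocol, meta = meta)
}

#' @param trace a \code{VoltageTrace}
#' @return \code{samplingRate}: the sampling rate in Hz;
#'   \code{traceVoltage}: the voltage vector in mV;
#'   \code{traceMeta}: the metadata list.
#' @rdname VoltageTrace
#' @export
samplingRate <- function(trace) trace@samplingRate

#' @rdname VoltageTrace
#' @export
traceVoltage <- function(trace) trace@voltage

#' @rdname VoltageTrace
#' @export
traceMeta <- function(trace) trace@meta

setMethod("show", "VoltageTrace", function(object) {
  cat(sprintf("VoltageTrace: %d samples @ %g kHz (%.1f s)",
              length(object@voltage), object@samplingRate / 1000,
              length(object@voltage) / object@samplingRate))
  m <- object@meta
  if (!is.null(m$genotype))
    cat(sprintf("  [%s, %s nm, cell %s, sweep %s]",
                m$genotype, m$wavelength %||% "?", m$cellId %||% "?",
                m$sweep %||% "?"))
  cat("\n")
})

# ---- spike train ------------------------------------------------------------

#' Ordered spike times for one sweep
#'
#' Spike times in seconds from sweep start, together with the protocol
#' that frames them and the source recording's metadata.
#'
#' @slot times strictly increasing spike times in seconds
#' @slot protocol the framing \code{SweepProtocol}
#' @slot meta recording metadata copied from the source trace
#' @name SpikeTrain-class
#' @rdname SpikeTrain
#' @exportClass SpikeTrain
setClass("SpikeTrain",
  representation(times = "numeric", protocol = "SweepProtocol",
                 meta = "list"))

setValidity("SpikeTrain", function(object) {
  msg <- character()
  tt <- object@times
  if (length(tt) && any(diff(tt) <= 0))
    msg <- c(msg, "spike times must be strictly increasing")
  dur <- protocolDuration(object@protocol)
  if (length(tt) && (min(tt) < 0 || max(tt) >= dur + 1e-9))
    msg <- c(msg, sprintf("spike times must lie within [0, %g)", dur))
  if (length(msg)) msg else TRUE
})

#' @param times,protocol,meta see slots
#' @return a \code{SpikeTrain}
#' @rdname SpikeTrain
#' @export
spikeTrain <- function(times, protocol = sweepProtocol(), meta = list()) {
  new("SpikeTrain", times = as.numeric(times), protocol = protocol,
      meta = meta)
}

#' @param x a \code{SpikeTrain}
#' @return \code{spikeTimes}: numeric vector of spike times in seconds
#' @rdname SpikeTrain
#' @export
spikeTimes <- function(x) x@times

setMethod("show", "SpikeTrain", function(object) {
  dur <- protocolDuration(object@protocol)
  cat(sprintf("SpikeTrain: %d spikes over %g s (mean %.2f Hz)\n",
              length(object@times), dur, length(object@times) / dur))
})

setMethod("length", "SpikeTrain", function(x) length(x@times))

# ---- FF result --------------------------------------------------------------

#' Firing-frequency ratio result for one sweep
#'
#' @slot ratio light-on rate / baseline rate (dimensionless); \code{NA}
#'   when the baseline window contained no spikes
#' @slot postBins post-stimulus rate ratios, one per analysis bin
#'   (rate in the bin / baseline rate)
#' @slot baselineRate pre-stimulus firing rate, Hz
#' @name FFResult-class
#' @rdname FFResult
#' @exportClass FFResult
setClass("FFResult",
  representation(ratio = "numeric", postBins = "numeric",
                 baselineRate = "numeric"))

setValidity("FFResult", function(object) {
  msg <- character()
  if (!is.na(object@ratio) && object@ratio < 0)
    msg <- c(msg, "ratio must be >= 0")
  if (object@baselineRate < 0) msg <- c(msg, "baselineRate must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param x an \code{FFResult}
#' @return \code{ffRatio}: the light/baseline rate ratio;
#'   \code{postStimulusBins}: the post-stimulus ratio profile;
#'   \code{baselineRate}: the baseline rate in Hz.
#' @rdname FFResult
#' @export
ffRatio <- function(x) x@ratio

#' @rdname FFResult
#' @export
postStimulusBins <- function(x) x@postBins

#' @rdname FFResult
#' @export
baselineRate <- function(x) x@baselineRate

setMethod("show", "FFResult", function(object) {
  cat(sprintf("FFResult: ratio %.3f (baseline %.2f Hz); post bins: %s\n",
              object@ratio, object@baselineRate,
              paste(sprintf("%.2f", object@postBins), collapse = " ")))
})

# ---- group summary ----------------------------------------------------------

#' Per-group summary of per-cell values
#'
#' Mean and SEM over cells of a per-cell statistic (each cell's value is
#' the mean over its sweeps), for one genotype x wavelength group.
#' SEM is sample SD / sqrt(n) and is \code{NA} for n = 1.
#'
#' @slot genotype group genotype label
#' @slot wavelength stimulus wavelength, nm
#' @slot n number of cells contributing
#' @slot mean group mean of per-cell values
#' @slot sem standard error of the mean (\code{NA} when n = 1)
#' @slot values the per-cell values
#' @slot nExcluded cells excluded for having no valid sweeps
#' @name GroupSummary-class
#' @rdname GroupSummary
#' @exportClass GroupSummary
setClass("GroupSummary",
  representation(genotype = "character", wavelength = "numeric",
                 n = "integer", mean = "numeric", sem = "numeric",
                 values = "numeric", nExcluded = "integer"))

setValidity("GroupSummary", function(object) {
  msg <- character()
  if (object@n != length(object@values))
    msg <- c(msg, "n must equal the number of per-cell values")
  if (object@n >= 2) {
    expect <- stats::sd(object@values) / sqrt(object@n)
    if (!isTRUE(all.equal(object@sem, expect)))
      msg <- c(msg, "sem must be sample SD / sqrt(n) for n >= 2")
  } else if (!is.na(object@sem)) {
    msg <- c(msg, "sem must be NA for n = 1")
  }
  if (length(msg)) msg else TRUE
})

#' @param x a \code{GroupSummary}
#' @return \code{groupValues}: the raw per-cell values;
#'   \code{groupMean} / \code{groupSem}: group mean and SEM.
#' @rdname GroupSummary
#' @export
groupValues <- function(x) x@values

#' @rdname GroupSummary
#' @export
groupMean <- function(x) x@mean

#' @rdname GroupSummary
#' @export
groupSem <- function(x) x@sem

setMethod("show", "GroupSummary", function(object) {
  cat(sprintf("GroupSummary: %s @ %g nm, n = %d, mean %.3f +/- %.3f SEM",
              object@genotype, object@wavelength, object@n, object@mean,
              object@sem))
  if (object@nExcluded > 0)
    cat(sprintf(" (%d cell(s) excluded)", object@nExcluded))
  cat("\n")
})

# ---- DAM record -------------------------------------------------------------

#' One activity monitor's beam-crossing record
#'
#' Per-minute infrared beam-crossing counts for the 32 channels of one
#' Drosophila activity monitor, with the monitor's light-status column
#' and a zeitgeber-time reference.
#'
#' @slot monitor monitor identifier
#' @slot timestamps POSIXct, one per minute, strictly increasing
#' @slot counts integer matrix, minutes x 32 channels, counts >= 0
#' @slot lightStatus integer vector (1 = monitor light on during that minute)
#' @slot meta named list; \code{ztStart} gives the zeitgeber hour of the
#'   first minute (ZT0 = lights-on of the entrainment cycle)
#' @name DamRecord-class
#' @rdname DamRecord
#' @exportClass DamRecord
setClass("DamRecord",
  representation(monitor = "character", timestamps = "POSIXct",
                 counts = "matrix", lightStatus = "integer", meta = "list"))

setValidity("DamRecord", function(object) {
  msg <- character()
  m <- nrow(object@counts)
  if (ncol(object@counts) != 32)
    msg <- c(msg, "counts must have 32 channels (columns)")
  if (length(object@timestamps) != m)
    msg <- c(msg, "one timestamp per minute required")
  if (m > 1 && any(diff(as.numeric(object@timestamps)) <= 0))
    msg <- c(msg, "timestamps must be strictly increasing")
  if (length(object@lightStatus) != m)
    msg <- c(msg, "lightStatus must have one entry per minute")
  cc <- object@counts
  if (m > 0 && (any(cc < 0) || any(cc != round(cc))))
    msg <- c(msg, "counts must be non-negative integers")
  if (length(msg)) msg else TRUE
})

#' @param monitor,timestamps,counts,lightStatus,meta see slots
#' @return a \code{DamRecord}
#' @rdname DamRecord
#' @export
damRecord <- function(counts, timestamps, lightStatus = NULL,
                      monitor = "M01", meta = list(ztStart = 0)) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(lightStatus)) lightStatus <- integer(nrow(counts))
  if (is.null(meta$ztStart)) meta$ztStart <- 0
  rec <- new("DamRecord", monitor = monitor, timestamps = timestamps,
             counts = counts, lightStatus = as.integer(lightStatus),
             meta = meta)
  if (nrow(counts) > 1) {
    d <- diff(as.numeric(timestamps))
    if (any(d != 60))
      warning(sprintf("non-uniform timestamp spacing at %d position(s); gaps are kept, not filled",
                      sum(d != 60)))
  }
  rec
}

#' @param record a \code{DamRecord}
#' @return \code{damCounts}: the minutes x 32 count matrix;
#'   \code{damZt}: zeitgeber hour (in [0, 24)) of each minute;
#'   \code{damLightStatus}: the light-status column.
#' @rdname DamRecord
#' @export
damCounts <- function(record) record@counts

#' @rdname DamRecord
#' @export
damLightStatus <- function(record) record@lightStatus

#' @rdname DamRecord
#' @export
damZt <- function(record) {
  zt0 <- record@meta$ztStart %||% 0
  (zt0 + (seq_len(nrow(record@counts)) - 1) / 60) %% 24
}

setMethod("show", "DamRecord", function(object) {
  cat(sprintf("DamRecord %s: %d min x 32 channels, %d pulse minute(s)\n",
              object@monitor, nrow(object@counts),
              sum(object@lightStatus > 0)))
})

# ---- pulse schedule ---------------------------------------------------------

#' Nighttime light-pulse schedule for the arousal assay
#'
#' @slot ztHours zeitgeber hours of pulse onsets within the subjective night
#' @slot duration pulse duration, minutes
#' @slot nights number of consecutive pulse nights
#' @slot wavelength pulse wavelength, nm
#' @slot intensity pulse irradiance, uW/cm^2
#' @name PulseSchedule-class
#' @rdname PulseSchedule
#' @exportClass PulseSchedule
setClass("PulseSchedule",
  representation(ztHours = "numeric", duration = "numeric",
                 nights = "numeric", wavelength = "numeric",
                 intensity = "numeric"),
  prototype(ztHours = c(18, 19, 20), duration = 5, nights = 3,
            wavelength = 365, intensity = 10))

setValidity("PulseSchedule", function(object) {
  msg <- character()
  zt <- sort(object@ztHours)
  if (any(zt < 12 | zt >= 24))
    msg <- c(msg, "pulses must lie within the subjective night (ZT12-24)")
  if (length(zt) > 1 && any(diff(zt) * 60 < object@duration))
    msg <- c(msg, "pulses must not overlap")
  if (object@duration <= 0) msg <- c(msg, "duration must be > 0")
  if (object@nights < 1) msg <- c(msg, "nights must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param ztHours,duration,nights,wavelength,intensity see slots
#' @return a \code{PulseSchedule}
#' @examples
#' pulseSchedule()  # three 5-min pulses at ZT18/19/20 for three nights
#' @rdname PulseSchedule
#' @export
pulseSchedule <- function(ztHours = c(18, 19, 20), duration = 5, nights = 3,
                          wavelength = 365, intensity = 10) {
  new("PulseSchedule", ztHours = ztHours, duration = duration,
      nights = nights, wavelength = wavelength, intensity = intensity)
}

setMethod("show", "PulseSchedule", function(object) {
  cat(sprintf(
    "PulseSchedule: %d-min pulses at ZT %s, %g nights (%g nm, %g uW/cm2)\n",
    object@duration, paste(object@ztHours, collapse = "/"), object@nights,
    object@wavelength, object@intensity))
})

# ---- behavior generator parameters -----------------------------------------

#' Generative parameters for one genotype x wavelength x intensity
#' behavior condition
#'
#' @slot arousalProb per-pulse probability that a sleeping fly awakens
#' @slot nightSleepProp stationary fraction of night minutes spent asleep
#' @slot daySleepProp stationary fraction of day minutes spent asleep
#' @slot meanActivity mean beam crossings per awake minute (>= 1 enforced
#'   per minute so wake minutes are always detectable)
#' @slot meanSleepBout mean sleep-bout length, minutes (>= 5)
#' @slot arousalActiveMin mean minutes of activity after an evoked awakening
#' @name BehaviorParams-class
#' @rdname BehaviorParams
#' @exportClass BehaviorParams
setClass("BehaviorParams",
  representation(arousalProb = "numeric", nightSleepProp = "numeric",
                 daySleepProp = "numeric", meanActivity = "numeric",
                 meanSleepBout = "numeric", arousalActiveMin = "numeric"),
  prototype(arousalProb = 0.85, nightSleepProp = 0.85, daySleepProp = 0.2,
            meanActivity = 3, meanSleepBout = 45, arousalActiveMin = 10))

setValidity("BehaviorParams", function(object) {
  msg <- character()
  if (object@arousalProb < 0 || object@arousalProb > 1)
    msg <- c(msg, "arousalProb must lie in [0, 1]")
  if (object@meanSleepBout < 5)
    msg <- c(msg, "meanSleepBout must be >= 5 min")
  for (p in c(object@nightSleepProp, object@daySleepProp))
    if (p <= 0 || p >= 1)
      msg <- c(msg, "sleep propensities must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' @param arousalProb,nightSleepProp,daySleepProp,meanActivity,meanSleepBout,arousalActiveMin
#'   see slots
#' @return a \code{BehaviorParams} object
#' @rdname BehaviorParams
#' @export
behaviorParams <- function(arousalProb = 0.85, nightSleepProp = 0.85,
                           daySleepProp = 0.2, meanActivity = 3,
                           meanSleepBout = 45, arousalActiveMin = 10) {
  new("BehaviorParams", arousalProb = arousalProb,
      nightSleepProp = nightSleepProp, daySleepProp = daySleepProp,
      meanActivity = meanActivity, meanSleepBout = meanSleepBout,
      arousalActiveMin = arousalActiveMin)
}

setMethod("show", "BehaviorParams", function(object) {
  cat(sprintf(
    "BehaviorParams: p(arousal) = %.4f, night sleep %.0f%%, bout %g min\n",
    object@arousalProb, 100 * object@nightSleepProp, object@meanSleepBout))
})

# ---- sleep series -----------------------------------------------------------

#' Sleep classification of one fly's activity record
#'
#' @slot asleep logical, one entry per recorded minute
#' @slot bouts data.frame with columns \code{start} (1-based minute index)
#'   and \code{duration} (minutes), one row per sleep bout
#' @name SleepSeries-class
#' @rdname SleepSeries
#' @exportClass SleepSeries
setClass("SleepSeries",
  representation(asleep = "logical", bouts = "data.frame"))

setValidity("SleepSeries", function(object) {
  b <- object@bouts
  if (nrow(b) && sum(b$duration) != sum(object@asleep))
    "bout durations must sum to the number of asleep minutes" else TRUE
})

#' @param x a \code{SleepSeries}
#' @return \code{sleepState}: logical per-minute sleep vector;
#'   \code{sleepBouts}: the bout table.
#' @rdname SleepSeries
#' @export
sleepState <- function(x) x@asleep

#' @rdname SleepSeries
#' @export
sleepBouts <- function(x) x@bouts

setMethod("show", "SleepSeries", function(object) {
  cat(sprintf("SleepSeries: %d/%d minutes asleep in %d bout(s)\n",
              sum(object@asleep), length(object@asleep),
              nrow(object@bouts)))
})

# ---- arousal summary --------------------------------------------------------

#' Arousal summary for one genotype x wavelength x intensity condition
#'
#' @slot genotype genotype label
#' @slot wavelength pulse wavelength, nm
#' @slot intensity pulse irradiance, uW/cm^2
#' @slot perPulse data.frame (night, pulse, nAsleep, nAroused, pctAroused)
#' @slot totalPct denominator-weighted total percent aroused over all pulses
#' @slot totalPctUnweighted unweighted mean of the per-pulse percentages
#' @slot perNight per-night mean percent aroused
#' @name ArousalSummary-class
#' @rdname ArousalSummary
#' @exportClass ArousalSummary
setClass("ArousalSummary",
  representation(genotype = "character", wavelength = "numeric",
                 intensity = "numeric", perPulse = "data.frame",
                 totalPct = "numeric", totalPctUnweighted = "numeric",
                 perNight = "numeric"))

setValidity("ArousalSummary", function(object) {
  p <- c(object@totalPct, object@perPulse$pctAroused)
  p <- p[!is.na(p)]
  if (length(p) && (any(p < 0) || any(p > 100)))
    "percentages must lie in [0, 100]" else TRUE
})

#' @param x an \code{ArousalSummary}
#' @return \code{arousalTotalPct}: the weighted total percent aroused;
#'   \code{arousalPerPulse}: the per-pulse table.
#' @rdname ArousalSummary
#' @export
arousalTotalPct <- function(x) x@totalPct

#' @rdname ArousalSummary
#' @export
arousalPerPulse <- function(x) x@perPulse

setMethod("show", "ArousalSummary", function(object) {
  cat(sprintf(
    "ArousalSummary: %s @ %g nm, %g uW/cm2 -> %.1f%% aroused (%d pulses)\n",
    object@genotype, object@wavelength, object@intensity, object@totalPct,
    nrow(object@perPulse)))
})
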