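#' Detect action potentials in a voltage trace
#'
#' High-passes the trace by subtracting a short running mean (removes
#' the resting potential, slow drift and the DC light step), thresholds
#' at a robust multiple of the filtered signal's median absolute
#' deviation, and takes the peak of each suprathreshold excursion as the
#' event time. Excursions narrower than \code{minWidth} are discarded as
#' noise; events closer together than the refractory floor are merged to
#' the taller peak with a collision warning. Runs of constant samples at
#' the trace extremes raise a saturation warning.
#'
#' @param trace a \code{\link{VoltageTrace}} sampled at >= 1 kHz
#' @param thresholdK threshold as a multiple of the MAD of the
#'   high-passed signal
#' @param minSeparation refractory floor in seconds: no two events
#'   closer than this
#' @param minWidth minimum suprathreshold duration in seconds for a
#'   candidate event
#' @param hpWindow running-mean window of the high-pass stage, seconds
#' @return a \code{\link{SpikeTrain}} with the trace's protocol and
#'   metadata
#' @examples
#' st <- spikeTrain(c(10, 20, 60), sweepProtocol())
#' tr <- renderVoltageTrace(st, ephysParams(), samplingRate = 2000, seed = 1)
#' spikeTimes(detectSpikes(tr))
#' @export
detectSpikes <- function(trace, thresholdK = 5, minSeparation = 0.002,
                         minWidth = 3e-4, hpWindow = 0.005) {
  stopifnot(is(trace, "VoltageTrace"))
  fs <- trace@samplingRate
  if (fs < 1000) stop("detectSpikes requires a sampling rate of >= 1 kHz")
  v <- trace@voltage
  n <- length(v)
  # high-pass: subtract centred running mean (cumsum-based, O(n))
  w <- max(3L, round(hpWindow * fs))
  if (w %% 2L == 0L) w <- w + 1L
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, v))
  lo <- pmax(0L, seq_len(n) - half - 1L)
  hi <- pmin(n, seq_len(n) + half)
  hp <- v - (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
  # saturation check: long runs of identical samples at the extremes
  ext <- v == max(v) | v == min(v)
  if (any(ext)) {
    r <- rle(ext)
    satRun <- r$lengths >= max(2L, round(0.005 * fs)) & r$values
    if (any(satRun)) {
      starts <- cumsum(c(1L, r$lengths))[which(satRun)]
      warning(sprintf("possible saturated/clipped segment(s) near t = %s s",
                      paste(sprintf("%.3f", (starts - 1) / fs),
                            collapse = ", ")))
    }
  }
  # robust noise scale; strided subsample keeps the median cheap on
  # long traces without biasing the estimate
  stride <- max(1L, n %/% 300000L)
  thr <- thresholdK * stats::mad(hp[seq(1L, n, by = stride)])
  if (thr <= 0) thr <- 0.5 * max(abs(hp))  # noise-free trace
  if (thr <= 0)
    return(spikeTrain(numeric(), protocol = trace@protocol,
                      meta = trace@meta))
  above <- hp >= thr
  if (!any(above))
    return(spikeTrain(numeric(), protocol = trace@protocol,
                      meta = trace@meta))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= max(1L, round(minWidth * fs))
  starts <- starts[keep]; ends <- ends[keep]
  if (!length(starts))
    return(spikeTrain(numeric(), protocol = trace@protocol,
                      meta = trace@meta))
  # one event per suprathreshold excursion, splitting an excursion into
  # sub-peaks where two prominent maxima are separated by a deep valley
  # (two overlapping spike waveforms fused into one run)
  subPeaks <- function(a, b) {
    x <- hp[a:b]
    m <- length(x)
    if (m < 3) return(a - 1L + which.max(x))
    loc <- which(x >= c(-Inf, x[-m]) & x > c(x[-1], -Inf) &
                   x >= 0.5 * max(x))
    if (length(loc) < 2) return(a - 1L + which.max(x))
    keepPk <- loc[1]
    for (j in loc[-1]) {
      prev <- keepPk[length(keepPk)]
      valley <- min(x[prev:j])
      if (valley < 0.5 * min(x[prev], x[j])) keepPk <- c(keepPk, j)
      else if (x[j] > x[prev]) keepPk[length(keepPk)] <- j
    }
    a - 1L + keepPk
  }
  peakIdx <- unlist(mapply(subPeaks, starts, ends, SIMPLIFY = FALSE))
  peakAmp <- hp[peakIdx]
  # enforce the refractory floor: merge events closer than minSeparation,
  # keeping the taller peak
  minSep <- minSeparation * fs
  accIdx <- peakIdx[1]; accAmp <- peakAmp[1]
  collisions <- 0L
  if (length(peakIdx) > 1) {
    for (i in 2:length(peakIdx)) {
      if (peakIdx[i] - accIdx[length(accIdx)] < minSep) {
        collisions <- collisions + 1L
        if (peakAmp[i] > accAmp[length(accAmp)]) {
          accIdx[length(accIdx)] <- peakIdx[i]
          accAmp[length(accAmp)] <- peakAmp[i]
        }
      } else {
        accIdx <- c(accIdx, peakIdx[i])
        accAmp <- c(accAmp, peakAmp[i])
      }
    }
  }
  if (collisions > 0)
    warning(sprintf("%d event collision(s) within the %.0f-ms refractory floor; merged to the taller peak",
                    collisions, minSeparation * 1000))
  spikeTrain((accIdx - 1L) / fs, protocol = trace@protocol,
             meta = trace@meta)
}

#' Bin spike counts on the protocol grid
#'
#' Counts spikes in half-open bins \code{[start, end)} aligned to the
#' sweep protocol: \code{preDark/binWidth} baseline bins, the light-on
#' window, and the same number of post-stimulus bins starting at
#' light-off. A spike at exactly light-onset belongs to the light-on
#' window.
#'
#' @param spikes a \code{\link{SpikeTrain}} with its protocol attached
#' @return list with elements \code{pre} (baseline bin counts),
#'   \code{light} (count in the light-on window) and \code{post}
#'   (post-stimulus bin counts)
#' @export
binSpikeCounts <- function(spikes) {
  stopifnot(is(spikes, "SpikeTrain"))
  p <- spikes@protocol
  tt <- spikes@times
  dur <- protocolDuration(p)
  if (length(tt) && (min(tt) < 0 || max(tt) >= dur))
    stop("spike times outside the protocol window")
  nb <- round(p@preDark / p@binWidth)
  tOn <- p@preDark
  tOff <- tOn + p@lightOn
  countIn <- function(a, b) sum(tt >= a & tt < b)
  pre <- vapply(seq_len(nb), function(i)
    countIn((i - 1) * p@binWidth, i * p@binWidth), 0)
  light <- countIn(tOn, tOff)
  post <- vapply(seq_len(nb), function(i)
    countIn(tOff + (i - 1) * p@binWidth, tOff + i * p@binWidth), 0)
  list(pre = pre, light = light, post = post)
}

#' Light-on / baseline firing-frequency ratio for one sweep
#'
#' Both windows are converted to rates before dividing:
#' \code{ratio = (light count / lightOn) / (pre count / preDark)}. The
#' post-stimulus profile divides each post bin's rate by the same
#' baseline rate. A sweep with zero baseline spikes has an undefined
#' ratio (\code{NA} with a warning) and is excluded from aggregation.
#'
#' @param spikes a \code{\link{SpikeTrain}}
#' @return an \code{\link{FFResult}}
#' @examples
#' # 10 baseline spikes (0.2 Hz) and 3 light-on spikes (0.6 Hz) -> ratio 3
#' st <- spikeTrain(c(seq(2, 47, by = 5), 51, 52, 53), sweepProtocol())
#' ffRatio(computeFFRatio(st))
#' @export
computeFFRatio <- function(spikes) {
  b <- binSpikeCounts(spikes)
  p <- spikes@protocol
  baseRate <- sum(b$pre) / p@preDark
  lightRate <- b$light / p@lightOn
  if (sum(b$pre) == 0) {
    warning("zero baseline spikes: FF ratio undefined for this sweep")
    ratio <- NA_real_
    post <- rep(NA_real_, length(b$post))
  } else {
    ratio <- lightRate / baseRate
    post <- (b$post / p@binWidth) / baseRate
  }
  new("FFResult", ratio = ratio, postBins = post, baselineRate = baseRate)
}

#' Post-stimulus firing-ratio profile
#'
#' Rate in each post-stimulus bin divided by the baseline rate, one
#' value per 10-s bin after light-off.
#'
#' @param spikes a \code{\link{SpikeTrain}}
#' @return numeric vector of post-stimulus rate ratios
#' @export
computePostStimulusProfile <- function(spikes) {
  postStimulusBins(computeFFRatio(spikes))
}

#' Baseline firing rate of one sweep
#'
#' Spike count in the pre-stimulus dark window divided by its duration.
#' An empty window gives 0 Hz.
#'
#' @param spikes a \code{\link{SpikeTrain}}
#' @return baseline firing rate, Hz
#' @export
computeBaselineFF <- function(spikes) {
  b <- binSpikeCounts(spikes)
  sum(b$pre) / spikes@protocol@preDark
}

#' Aggregate per-sweep values into a group summary
#'
#' Per-cell values are the mean over that cell's valid (non-\code{NA})
#' sweeps; cells with no valid sweep are excluded and counted. The group
#' mean and SEM (sample SD / sqrt(n); \code{NA} for n = 1) are taken
#' over cells.
#'
#' @param values per-sweep values (e.g. FF ratios); \code{NA} marks an
#'   undefined sweep
#' @param cellId cell identifier per sweep, parallel to \code{values}
#' @param genotype,wavelength labels stored on the summary
#' @return a \code{\link{GroupSummary}}
#' @examples
#' aggregateGroup(c(1, 2, 3), c("a", "b", "c"), "p12c", 450)
#' @export
aggregateGroup <- function(values, cellId, genotype = "", wavelength = NA_real_) {
  stopifnot(length(values) == length(cellId))
  perCell <- tapply(values, cellId, function(v) {
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  })
  perCell <- as.numeric(perCell)
  excluded <- sum(is.na(perCell))
  perCell <- perCell[!is.na(perCell)]
  if (!length(perCell))
    stop("no cells with valid sweeps in this group")
  n <- length(perCell)
  new("GroupSummary", genotype = genotype, wavelength = wavelength,
      n = as.integer(n), mean = mean(perCell),
      sem = if (n >= 2) stats::sd(perCell) / sqrt(n) else NA_real_,
      values = perCell, nExcluded = as.integer(excluded))
}
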