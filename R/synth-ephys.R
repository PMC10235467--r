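#' @importFrom stats rpois runif rnorm mad sd
NULL

#' Instantaneous firing-rate profile for one sweep
#'
#' Piecewise rate model of the tonic l-LNv response to a light pulse:
#' baseline rate \eqn{r} in the pre-stimulus dark, \eqn{r k} during the
#' light window, and an exponential relaxation
#' \eqn{r (1 + (k - 1) e^{-(t - t_{off})/\tau})} back to baseline after
#' light-off. \eqn{\tau = 0} means an immediate return to baseline. The
#' profile is continuous at light-off whenever \eqn{\tau > 0} and never
#' falls below \eqn{r \min(1, k)}.
#'
#' @param params an \code{\link{EphysParams}} (uses \code{baselineRate},
#'   \code{foldChange}, \code{decayTau})
#' @param protocol a \code{\link{SweepProtocol}}
#' @param dt profile resolution in seconds; rates are evaluated at bin
#'   midpoints
#' @return numeric vector of rates (Hz) covering the sweep, with
#'   attributes \code{dt} and \code{duration}
#' @examples
#' pr <- simulateRateProfile(ephysParams(foldChange = 2), sweepProtocol())
#' range(pr)
#' @export
simulateRateProfile <- function(params, protocol, dt = 1e-3) {
  stopifnot(is(params, "EphysParams"), is(protocol, "SweepProtocol"))
  validObject(params); validObject(protocol)
  dur <- protocolDuration(protocol)
  n <- round(dur / dt)
  t <- (seq_len(n) - 0.5) * dt
  r <- params@baselineRate
  k <- params@foldChange
  tOn <- protocol@preDark
  tOff <- tOn + protocol@lightOn
  rate <- rep(r, n)
  rate[t >= tOn & t < tOff] <- r * k
  post <- t >= tOff
  if (params@decayTau > 0) {
    rate[post] <- r * (1 + (k - 1) * exp(-(t[post] - tOff) / params@decayTau))
  }
  structure(rate, dt = dt, duration = dur)
}

#' Simulate a spike train from a rate profile
#'
#' Inhomogeneous Poisson process with an absolute refractory (dead-time)
#' period, built by thinning: candidate events are drawn from a
#' homogeneous process at the profile maximum, retained with probability
#' \eqn{r(t)/r_{max}}, and then pruned so that no inter-spike interval
#' falls below the refractory period (non-paralyzable dead time). For a
#' constant rate \eqn{r} the expected output rate is
#' \eqn{r / (1 + r \tau_d)} with dead time \eqn{\tau_d}.
#'
#' @param profile rate profile from \code{\link{simulateRateProfile}}
#' @param protocol the framing \code{\link{SweepProtocol}}
#' @param refractory absolute refractory period in seconds
#' @param seed optional integer seed; fixed seed gives an identical train
#' @param meta metadata list copied onto the result
#' @return a \code{\link{SpikeTrain}}
#' @export
simulateSpikeTrain <- function(profile, protocol, refractory = 0.002,
                               seed = NULL, meta = list()) {
  stopifnot(is.numeric(profile), all(profile >= 0))
  dt <- attr(profile, "dt") %||% 1e-3
  dur <- attr(profile, "duration") %||% (length(profile) * dt)
  rmax <- max(profile)
  if (refractory > 0 && rmax * refractory >= 1)
    warning("refractory period too long for the requested peak rate; realized rate will saturate")
  times <- withSeed(seed, {
    if (rmax == 0) numeric() else {
      nCand <- rpois(1, rmax * dur)
      cand <- sort(runif(nCand, 0, dur))
      idx <- pmin(length(profile), floor(cand / dt) + 1L)
      keep <- runif(nCand) < profile[idx] / rmax
      cand[keep]
    }
  })
  if (refractory > 0 && length(times) > 1) {
    accepted <- numeric(length(times))
    nAcc <- 1L
    accepted[1] <- times[1]
    last <- times[1]
    for (tt in times[-1]) {
      if (tt - last >= refractory) {
        nAcc <- nAcc + 1L
        accepted[nAcc] <- tt
        last <- tt
      }
    }
    times <- accepted[seq_len(nAcc)]
  }
  spikeTrain(times, protocol = protocol, meta = meta)
}

# stereotyped biphasic action-potential template sampled at `fs`;
# peak (= the spike time) at sample `peak`
.spikeTemplate <- function(fs, amp) {
  # 1 ms positive lobe centred on the peak, 1 ms negative after-lobe
  halfUp <- round(0.0005 * fs)
  nDown <- round(0.001 * fs)
  up <- amp * sin(pi * (seq_len(2 * halfUp + 1) - 1) / (2 * halfUp))
  down <- -0.3 * amp * sin(pi * seq_len(nDown) / (nDown + 1))
  list(shape = c(up, down), peak = halfUp + 1L)
}

#' Render a voltage trace from a spike train
#'
#' Builds a synthetic membrane-potential recording: resting potential
#' plus Gaussian membrane noise, a DC depolarization step during the
#' light window, and a stereotyped 2-ms biphasic spike waveform of the
#' stated amplitude inserted at each spike time. Traces rendered this
#' way are recovered by \code{\link{detectSpikes}} at default settings
#' with each event within 1 ms of its insertion time.
#'
#' @param spikes a \code{\link{SpikeTrain}}
#' @param params an \code{\link{EphysParams}} (waveform/noise parameters)
#' @param samplingRate samples per second; must be at least 1 kHz to
#'   resolve the spike waveform
#' @param seed optional integer seed for the membrane noise
#' @return a \code{\link{VoltageTrace}} carrying the spike train's
#'   protocol and metadata
#' @export
renderVoltageTrace <- function(spikes, params, samplingRate = 10000,
                               seed = NULL) {
  stopifnot(is(spikes, "SpikeTrain"), is(params, "EphysParams"))
  if (samplingRate < 1000)
    stop("samplingRate below 1 kHz cannot resolve the 2-ms spike waveform")
  protocol <- spikes@protocol
  dur <- protocolDuration(protocol)
  n <- round(dur * samplingRate)
  v <- withSeed(seed, {
    if (params@noiseSd > 0) rnorm(n, params@resting, params@noiseSd)
    else rep(params@resting, n)
  })
  # DC depolarization while the light is on
  onIdx <- floor(protocol@preDark * samplingRate) + 1L
  offIdx <- floor((protocol@preDark + protocol@lightOn) * samplingRate)
  v[onIdx:offIdx] <- v[onIdx:offIdx] + params@lightDc
  tmpl <- .spikeTemplate(samplingRate, params@spikeAmp)
  L <- length(tmpl$shape)
  for (st in spikes@times) {
    i0 <- round(st * samplingRate) + 1L - (tmpl$peak - 1L)
    src <- seq_len(L)
    dst <- i0 + src - 1L
    ok <- dst >= 1L & dst <= n
    v[dst[ok]] <- v[dst[ok]] + tmpl$shape[src[ok]]
  }
  voltageTrace(v, samplingRate = samplingRate, protocol = protocol,
               meta = spikes@meta)
}

#' Simulate a cohort of recordings for one genotype x wavelength condition
#'
#' Generates \code{nCells} cells of \code{protocol@nSweeps} sweeps each.
#' Every sweep gets its own seed derived deterministically from the
#' master seed, the genotype, the cell and the sweep index
#' (\code{\link{seedFrom}}), so cohorts are reproducible sweep-for-sweep.
#' Each cell's recording ZT hour is drawn uniformly from
#' \code{ztRange}; the generative model has no time-of-day effect.
#'
#' @param params an \code{\link{EphysParams}} for this condition
#' @param nCells number of cells
#' @param protocol a \code{\link{SweepProtocol}}
#' @param masterSeed integer master seed
#' @param genotype genotype label stored in the metadata
#' @param samplingRate trace sampling rate, Hz
#' @param render if \code{TRUE} return rendered \code{VoltageTrace}s;
#'   if \code{FALSE} return the underlying \code{SpikeTrain}s (fast path
#'   for large replicate studies, bypassing waveform rendering)
#' @param ztRange range of recording ZT hours, drawn uniformly per cell
#' @return a list of \code{nCells * nSweeps} traces (or spike trains),
#'   each carrying genotype, wavelength, cell id, sweep index and ZT hour
#'   in its metadata
#' @export
simulateEphysCohort <- function(params, nCells, protocol, masterSeed,
                                genotype = "p12c", samplingRate = 10000,
                                render = TRUE, ztRange = c(0, 16)) {
  stopifnot(nCells >= 1)
  profile <- simulateRateProfile(params, protocol)
  out <- vector("list", nCells * protocol@nSweeps)
  j <- 0L
  for (cell in seq_len(nCells)) {
    cellId <- sprintf("%s_c%02d", genotype, cell)
    zt <- withSeed(seedFrom(masterSeed, genotype, cell, "zt"),
                   runif(1, ztRange[1], ztRange[2]))
    for (sweep in seq_len(protocol@nSweeps)) {
      meta <- list(genotype = genotype, wavelength = protocol@wavelength,
                   intensity = protocol@intensity, ztHour = zt,
                   cellId = cellId, sweep = sweep)
      st <- simulateSpikeTrain(profile, protocol,
                               refractory = params@refractory,
                               seed = seedFrom(masterSeed, genotype, cell,
                                               sweep, "train"),
                               meta = meta)
      j <- j + 1L
      out[[j]] <- if (render) {
        renderVoltageTrace(st, params, samplingRate = samplingRate,
                           seed = seedFrom(masterSeed, genotype, cell,
                                           sweep, "noise"))
      } else st
    }
  }
  out
}
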