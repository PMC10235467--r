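#' @importFrom stats cor.test complete.cases
NULL

#' Read a pipeline configuration file
#'
#' YAML configuration driving end-to-end runs. Recognized fields:
#' \code{mode} (ephys / behavior / both), \code{seed},
#' \code{genotypes}, \code{control}, \code{colors},
#' \code{intensities}, \code{n_cells}, \code{n_flies},
#' \code{sampling_rate}, \code{render}, \code{output_dir}, plus
#' optional \code{protocol} / \code{schedule} overrides and
#' \code{ephys_params} / \code{behavior_params} rows overriding the
#' default parameter tables.
#'
#' @param path YAML file path
#' @return a named list (validated lazily by the run functions)
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such config file: '%s'", path))
  yaml::read_yaml(path)
}

.configEphys <- function(config) {
  cfg <- list(
    genotypes = config$genotypes %||%
      c("p12c", "gl60j", "cry-null", "gl60j-cry-null", "rh7-null"),
    control = config$control %||% "p12c",
    colors = config$colors %||% "blue",
    nCells = config$n_cells %||% 16,
    samplingRate = config$sampling_rate %||% 10000,
    render = config$render %||% TRUE,
    seed = config$seed,
    q = config$fdr_q %||% 0.1,
    tail = config$tail %||% "greater",
    outputDir = config$output_dir,
    paramTable = config$paramTable %||% defaultEphysParamTable())
  if (is.null(cfg$seed)) stop("config must supply a seed for simulation")
  po <- config$protocol %||% list()
  cfg$protocolArgs <- po
  missing <- setdiff(cfg$genotypes, unique(cfg$paramTable$genotype))
  if (length(missing))
    stop(sprintf("no ephys parameters defined for genotype(s): %s",
                 paste(missing, collapse = ", ")))
  if (!cfg$control %in% cfg$genotypes)
    stop("control genotype must be among the configured genotypes")
  cfg
}

#' Run the light-evoked firing pipeline end to end
#'
#' Simulate -> (render -> detect) -> bin -> FF ratio -> aggregate ->
#' test, for every configured genotype x color condition. With
#' \code{render = TRUE} (the default) every sweep is rendered as a
#' 10-kHz voltage trace and passed through spike detection; with
#' \code{render = FALSE} the FF statistics are computed directly from
#' the simulated spike trains (fast path for large replicate studies;
#' detection is separately validated at >= 99 percent sensitivity and
#' precision).
#'
#' Comparisons form one FDR family per color: control vs each mutant,
#' one-tailed in the configured direction (default: control greater).
#'
#' @param config named list (see \code{\link{readPipelineConfig}});
#'   \code{seed} is required
#' @return list with \code{perSweep}, \code{perCell}, \code{groups},
#'   \code{comparisons}, \code{baselineZt} (per-genotype correlation of
#'   baseline rate with recording ZT) and \code{excluded} tables; all
#'   tables are also written as TSV when \code{output_dir} is set
#' @examples
#' res <- runEphysPipeline(list(seed = 7, genotypes = c("p12c", "gl60j"),
#'                              colors = "blue", n_cells = 3,
#'                              render = FALSE))
#' res$groups
#' @export
runEphysPipeline <- function(config) {
  cfg <- .configEphys(config)
  perSweep <- list()
  for (color in cfg$colors) {
    for (gt in cfg$genotypes) {
      params <- ephysParamsFor(gt, color, table = cfg$paramTable)
      protocol <- do.call(sweepProtocol,
                          c(cfg$protocolArgs,
                            list(wavelength = wavelengthNm(color))))
      nCells <- if (length(cfg$nCells) > 1)
        cfg$nCells[[gt]] else cfg$nCells
      objs <- simulateEphysCohort(
        params, nCells, protocol, masterSeed = cfg$seed, genotype = gt,
        samplingRate = cfg$samplingRate, render = cfg$render)
      rows <- lapply(objs, function(obj) {
        st <- if (is(obj, "VoltageTrace")) detectSpikes(obj) else obj
        ff <- suppressWarnings(computeFFRatio(st))
        m <- st@meta
        data.frame(genotype = gt, color = color,
                   wavelength = protocol@wavelength, cell = m$cellId,
                   sweep = m$sweep, ztHour = m$ztHour,
                   ratio = ffRatio(ff), baselineRate = baselineRate(ff),
                   stringsAsFactors = FALSE)
      })
      perSweep[[paste(gt, color)]] <- do.call(rbind, rows)
    }
  }
  perSweep <- do.call(rbind, perSweep)
  rownames(perSweep) <- NULL

  # per-cell means over valid sweeps
  key <- interaction(perSweep$genotype, perSweep$color, perSweep$cell,
                     drop = TRUE)
  perCell <- do.call(rbind, lapply(split(perSweep, key), function(d) {
    ok <- !is.na(d$ratio)
    data.frame(genotype = d$genotype[1], color = d$color[1],
               wavelength = d$wavelength[1], cell = d$cell[1],
               ztHour = d$ztHour[1], nSweeps = nrow(d),
               nValidSweeps = sum(ok),
               meanRatio = if (any(ok)) mean(d$ratio[ok]) else NA_real_,
               meanBaseline = mean(d$baselineRate),
               stringsAsFactors = FALSE)
  }))
  rownames(perCell) <- NULL

  groups <- list(); excluded <- list()
  for (color in cfg$colors) {
    for (gt in cfg$genotypes) {
      d <- perSweep[perSweep$genotype == gt & perSweep$color == color, ]
      gs <- aggregateGroup(d$ratio, d$cell, genotype = gt,
                           wavelength = d$wavelength[1])
      groups[[paste(gt, color)]] <- data.frame(
        genotype = gt, color = color, wavelength = gs@wavelength,
        n = gs@n, meanRatio = gs@mean, sem = gs@sem,
        nExcluded = gs@nExcluded, stringsAsFactors = FALSE)
      if (gs@nExcluded > 0)
        excluded[[paste(gt, color)]] <- data.frame(
          genotype = gt, color = color, nExcluded = gs@nExcluded)
    }
  }
  groups <- do.call(rbind, groups); rownames(groups) <- NULL
  excluded <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(genotype = character(), color = character(),
               nExcluded = integer())

  # one FDR family per color: control vs each mutant
  comparisons <- list()
  for (color in cfg$colors) {
    ctrl <- perCell[perCell$genotype == cfg$control &
                      perCell$color == color &
                      !is.na(perCell$meanRatio), "meanRatio"]
    fam <- list()
    for (gt in setdiff(cfg$genotypes, cfg$control)) {
      mut <- perCell[perCell$genotype == gt & perCell$color == color &
                       !is.na(perCell$meanRatio), "meanRatio"]
      fam[[gt]] <- adaptiveTwoSampleTest(
        ctrl, mut, tail = cfg$tail,
        label = sprintf("%s vs %s | %s FF ratio", cfg$control, gt, color))
    }
    if (length(fam)) {
      fam <- do.call(rbind, fam)
      fam <- adjustComparisonFamily(fam, q = cfg$q)
      fam$color <- color
      comparisons[[color]] <- fam
    }
  }
  comparisons <- if (length(comparisons)) do.call(rbind, comparisons) else
    NULL
  if (!is.null(comparisons)) rownames(comparisons) <- NULL

  # descriptive baseline-vs-ZT report (the design cannot test time of
  # day formally; this mirrors the scatter-plot check)
  baselineZt <- do.call(rbind, lapply(split(perCell, perCell$genotype),
    function(d) {
      d <- d[complete.cases(d[, c("meanBaseline", "ztHour")]), ]
      if (nrow(d) >= 3) {
        ct <- stats::cor.test(d$ztHour, d$meanBaseline)
        data.frame(genotype = d$genotype[1], n = nrow(d),
                   pearsonR = unname(ct$estimate), p = ct$p.value)
      } else data.frame(genotype = d$genotype[1], n = nrow(d),
                        pearsonR = NA_real_, p = NA_real_)
    }))
  rownames(baselineZt) <- NULL

  out <- list(perSweep = perSweep, perCell = perCell, groups = groups,
              comparisons = comparisons, baselineZt = baselineZt,
              excluded = excluded)
  if (!is.null(cfg$outputDir)) .writeTables(out, cfg$outputDir, "ephys")
  out
}

.configBehavior <- function(config) {
  cfg <- list(
    genotypes = config$genotypes %||%
      c("p12c", "gl60j", "cry-null", "gl60j-cry-null", "rh7-null"),
    control = config$control %||% "p12c",
    colors = config$colors %||% "UV",
    intensities = config$intensities %||% 10,
    nFlies = config$n_flies %||% 32,
    seed = config$seed,
    q = config$fdr_q %||% 0.1,
    tail = config$tail %||% "greater",
    outputDir = config$output_dir,
    paramTable = config$paramTable %||% defaultBehaviorParamTable())
  if (is.null(cfg$seed)) stop("config must supply a seed for simulation")
  cfg$scheduleArgs <- config$schedule %||% list()
  missing <- setdiff(cfg$genotypes, unique(cfg$paramTable$genotype))
  if (length(missing))
    stop(sprintf("no behavior parameters defined for genotype(s): %s",
                 paste(missing, collapse = ", ")))
  cfg
}

#' Run the light-pulse arousal pipeline end to end
#'
#' Simulate monitor records -> 5-min sleep scoring -> per-pulse arousal
#' -> condition summaries -> tests, for every configured genotype x
#' color x intensity condition. Comparisons form one FDR family per
#' color x intensity: control vs each mutant on the nine per-pulse
#' percentages, one-tailed in the configured direction.
#'
#' @param config named list; \code{seed} is required
#' @return list with \code{summaries} (one row per condition, including
#'   per-night means for the night-consistency check),
#'   \code{comparisons}, and \code{records} (the simulated
#'   \code{DamRecord}s, named by condition)
#' @examples
#' res <- runBehaviorPipeline(list(seed = 7, colors = "UV",
#'                                 genotypes = c("p12c", "gl60j-cry-null"),
#'                                 n_flies = 16))
#' res$summaries
#' @export
runBehaviorPipeline <- function(config) {
  cfg <- .configBehavior(config)
  summaries <- list(); perPulseAll <- list(); records <- list()
  for (color in cfg$colors) {
    for (intensity in cfg$intensities) {
      for (gt in cfg$genotypes) {
        params <- behaviorParamsFor(gt, color, intensity,
                                    table = cfg$paramTable)
        schedule <- do.call(pulseSchedule,
                            c(cfg$scheduleArgs,
                              list(wavelength = wavelengthNm(color),
                                   intensity = intensity)))
        rec <- simulateDamCohort(
          params, cfg$nFlies, schedule,
          masterSeed = seedFrom(cfg$seed, color, intensity),
          genotype = gt)
        outcomes <- scorePulseArousal(rec, schedule)
        sm <- summarizeArousal(outcomes, genotype = gt,
                               wavelength = schedule@wavelength,
                               intensity = intensity)
        keyName <- paste(gt, color, intensity)
        records[[keyName]] <- rec
        nights <- sm@perNight
        summaries[[keyName]] <- data.frame(
          genotype = gt, color = color, wavelength = sm@wavelength,
          intensity = intensity, nFlies = cfg$nFlies,
          nDead = length(unique(outcomes$fly[outcomes$dead &
                                               outcomes$fly <= cfg$nFlies])),
          nPulseEvents = sum(outcomes$asleep),
          totalPct = sm@totalPct,
          totalPctUnweighted = sm@totalPctUnweighted,
          night1 = nights[1], night2 = nights[2], night3 = nights[3],
          stringsAsFactors = FALSE)
        pp <- sm@perPulse
        pp$genotype <- gt; pp$color <- color; pp$intensity <- intensity
        perPulseAll[[keyName]] <- pp
      }
    }
  }
  summaries <- do.call(rbind, summaries); rownames(summaries) <- NULL
  perPulseAll <- do.call(rbind, perPulseAll); rownames(perPulseAll) <- NULL

  comparisons <- list()
  for (color in cfg$colors) {
    for (intensity in cfg$intensities) {
      ctrl <- perPulseAll[perPulseAll$genotype == cfg$control &
                            perPulseAll$color == color &
                            perPulseAll$intensity == intensity,
                          "pctAroused"]
      fam <- list()
      for (gt in setdiff(cfg$genotypes, cfg$control)) {
        mut <- perPulseAll[perPulseAll$genotype == gt &
                             perPulseAll$color == color &
                             perPulseAll$intensity == intensity,
                           "pctAroused"]
        if (length(ctrl) >= 3 && length(mut) >= 3)
          fam[[gt]] <- adaptiveTwoSampleTest(
            ctrl, mut, tail = cfg$tail,
            label = sprintf("%s vs %s | %s %g uW/cm2 arousal",
                            cfg$control, gt, color, intensity))
      }
      if (length(fam)) {
        fam <- adjustComparisonFamily(do.call(rbind, fam), q = cfg$q)
        fam$color <- color; fam$intensity <- intensity
        comparisons[[paste(color, intensity)]] <- fam
      }
    }
  }
  comparisons <- if (length(comparisons)) do.call(rbind, comparisons) else
    NULL
  if (!is.null(comparisons)) rownames(comparisons) <- NULL

  out <- list(summaries = summaries, perPulse = perPulseAll,
              comparisons = comparisons, records = records)
  if (!is.null(cfg$outputDir))
    .writeTables(out[c("summaries", "perPulse", "comparisons")],
                 cfg$outputDir, "behavior")
  out
}

.writeTables <- function(tables, dir, prefix) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    if (is.data.frame(tb))
      writeResultsTsv(tb, file.path(dir, sprintf("%s_%s.tsv", prefix, nm)))
  }
  invisible(dir)
}
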