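.WAVELENGTH_NM <- c(UV = 365, violet = 405, blue = 450, red = 635)

#' Wavelength lookup by color name
#'
#' @param color one of \code{"UV"}, \code{"violet"}, \code{"blue"},
#'   \code{"red"}
#' @return wavelength in nm
#' @export
wavelengthNm <- function(color) {
  unname(.WAVELENGTH_NM[match.arg(color, names(.WAVELENGTH_NM))])
}

#' Default ephys generative parameter table
#'
#' One row per genotype x wavelength: the genotype's tonic baseline rate
#' (Hz), the light-on fold change for that wavelength, and the
#' post-stimulus decay constant (s). Fold changes are the published
#' group-mean FF ratios for each genotype and color; baselines are the
#' published group-average basal rates. Decay constants are qualitative
#' reconstructions of the reported persistence (sustained firing up to
#' ~20-30 s after blue light in controls, shorter for violet/UV, none
#' for red; short or absent in the mutants) - no measured time constants
#' exist, so these defaults shape only the post-stimulus profile, never
#' the light-window ratio.
#'
#' @return data.frame with columns \code{genotype}, \code{color},
#'   \code{wavelength}, \code{baselineRate}, \code{foldChange},
#'   \code{decayTau}
#' @examples
#' subset(defaultEphysParamTable(), color == "blue")
#' @export
defaultEphysParamTable <- function() {
  genotypes <- c("p12c", "gl60j", "cry-null", "gl60j-cry-null", "rh7-null")
  baselines <- c(4.2, 3.6, 3.9, 5.2, 2.4)
  fold <- rbind(  #         UV  violet  blue    red
    "p12c"           = c(1.667, 1.899, 1.958, 1.197),
    "gl60j"          = c(1.129, 1.016, 1.213, 1.060),
    "cry-null"       = c(1.099, 1.390, 1.066, 1.040),
    "gl60j-cry-null" = c(1.328, 0.994, 1.026, 0.981),
    "rh7-null"       = c(1.115, 1.056, 1.289, 1.074))
  tau <- rbind(
    "p12c"           = c(6, 12, 25, 0),
    "gl60j"          = c(5, 5, 5, 0),
    "cry-null"       = c(5, 5, 5, 0),
    "gl60j-cry-null" = c(5, 5, 5, 0),
    "rh7-null"       = c(5, 5, 5, 0))
  colors <- names(.WAVELENGTH_NM)
  out <- expand.grid(genotype = genotypes, color = colors,
                     stringsAsFactors = FALSE)
  out$wavelength <- .WAVELENGTH_NM[out$color]
  gi <- match(out$genotype, genotypes)
  ci <- match(out$color, colors)
  out$baselineRate <- baselines[gi]
  out$foldChange <- fold[cbind(gi, ci)]
  out$decayTau <- tau[cbind(gi, ci)]
  rownames(out) <- NULL
  out
}

#' Default behavior generative parameter table
#'
#' Per-pulse arousal probabilities for every genotype x wavelength x
#' intensity condition (the published total average proportion of
#' sleeping flies that awaken), plus the shared sleep-structure
#' parameters of the generator.
#'
#' @return data.frame with columns \code{genotype}, \code{color},
#'   \code{wavelength}, \code{intensity}, \code{arousalProb}
#' @examples
#' subset(defaultBehaviorParamTable(), color == "UV" & intensity == 10)
#' @export
defaultBehaviorParamTable <- function() {
  genotypes <- c("p12c", "gl60j", "cry-null", "gl60j-cry-null", "rh7-null")
  low <- rbind(   #          UV  violet    blue    red
    "p12c"           = c(0.8503, 0.6519, 0.6375, 0.7036),
    "gl60j"          = c(0.3379, 0.3132, 0.3147, 0.3170),
    "cry-null"       = c(0.8199, 0.5766, 0.4928, 0.5992),
    "gl60j-cry-null" = c(0.1705, 0.2189, 0.2268, 0.2641),
    "rh7-null"       = c(0.4767, 0.4086, 0.1794, 0.6283))
  high <- rbind(
    "p12c"           = c(0.7905, 0.7954, 0.7480, 0.3611),
    "gl60j"          = c(0.7097, 0.7091, 0.6392, 0.2145),
    "cry-null"       = c(0.7119, 0.7597, 0.4706, 0.3443),
    "gl60j-cry-null" = c(0.5701, 0.4067, 0.5631, 0.2023),
    "rh7-null"       = c(0.4800, 0.2372, 0.2961, 0.3132))
  colors <- names(.WAVELENGTH_NM)
  out <- expand.grid(genotype = genotypes, color = colors,
                     intensity = c(10, 400), stringsAsFactors = FALSE)
  out$wavelength <- .WAVELENGTH_NM[out$color]
  gi <- match(out$genotype, genotypes)
  ci <- match(out$color, colors)
  out$arousalProb <- ifelse(out$intensity == 10,
                            low[cbind(gi, ci)], high[cbind(gi, ci)])
  rownames(out) <- NULL
  out[, c("genotype", "color", "wavelength", "intensity", "arousalProb")]
}

#' Look up ephys generator parameters for one condition
#'
#' @param genotype,color condition labels as in
#'   \code{\link{defaultEphysParamTable}}
#' @param table parameter table (rows as the default table); override to
#'   run counterfactual or null simulations
#' @param ... further arguments (refractory, noise, waveform) passed to
#'   \code{\link{ephysParams}}
#' @return an \code{\link{EphysParams}}
#' @export
ephysParamsFor <- function(genotype, color, table = defaultEphysParamTable(),
                           ...) {
  row <- table[table$genotype == genotype & table$color == color, ]
  if (nrow(row) != 1)
    stop(sprintf("no ephys parameters for genotype '%s', color '%s'",
                 genotype, color))
  ephysParams(baselineRate = row$baselineRate, foldChange = row$foldChange,
              decayTau = row$decayTau, ...)
}

#' Look up behavior generator parameters for one condition
#'
#' @param genotype,color,intensity condition labels as in
#'   \code{\link{defaultBehaviorParamTable}}
#' @param table parameter table; override for null simulations
#' @param ... further arguments (sleep structure) passed to
#'   \code{\link{behaviorParams}}
#' @return a \code{\link{BehaviorParams}}
#' @export
behaviorParamsFor <- function(genotype, color, intensity = 10,
                              table = defaultBehaviorParamTable(), ...) {
  row <- table[table$genotype == genotype & table$color == color &
                 table$intensity == intensity, ]
  if (nrow(row) != 1)
    stop(sprintf("no behavior parameters for genotype '%s', color '%s', intensity %g",
                 genotype, color, intensity))
  behaviorParams(arousalProb = row$arousalProb, ...)
}
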