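#' @importFrom stats t.test var.test wilcox.test p.adjust sd var
#' @importFrom nortest ad.test
NULL

#' Normality-gated two-sample test
#'
#' The inference path used for every pairwise comparison: both samples
#' are screened with the Anderson-Darling normality test at alpha =
#' 0.05; if both pass, an F-test on the variances (alpha = 0.05)
#' selects a pooled-variance or Welch two-sample t-test; if either
#' sample fails the gate (or is too small for the Anderson-Darling
#' statistic, n < 8, or has zero variance), the one-tailed Mann-Whitney
#' U-test is used instead. The full decision trail is recorded in the
#' returned row.
#'
#' The \code{tail} is the alternative for \code{x} relative to \code{y}:
#' \code{"greater"} tests whether \code{x} tends to exceed \code{y}.
#' Direction is always supplied explicitly by the caller, never
#' inferred from the data.
#'
#' @param x,y numeric samples, each of length >= 3
#' @param tail alternative hypothesis for \code{x} vs \code{y}
#' @param label comparison label carried into the results table
#' @param alphaNormal alpha of the Anderson-Darling gate
#' @param alphaVar alpha of the F-test variance gate
#' @return a one-row data.frame: \code{label}, \code{nX}, \code{nY},
#'   \code{adPX}, \code{adPY}, \code{varP}, \code{test} (one of
#'   \code{"t pooled"}, \code{"t Welch"}, \code{"mann-whitney"},
#'   \code{"degenerate"}), \code{tail}, \code{statistic}, \code{p}
#' @examples
#' set.seed(1)
#' adaptiveTwoSampleTest(rnorm(20, 2), rnorm(20, 0), tail = "greater")
#' @export
adaptiveTwoSampleTest <- function(x, y,
                                  tail = c("greater", "less", "two.sided"),
                                  label = "", alphaNormal = 0.05,
                                  alphaVar = 0.05) {
  tail <- match.arg(tail)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3 || length(y) < 3)
    stop("adaptiveTwoSampleTest requires at least 3 observations per sample")
  row <- data.frame(label = label, nX = length(x), nY = length(y),
                    adPX = NA_real_, adPY = NA_real_, varP = NA_real_,
                    test = NA_character_, tail = tail,
                    statistic = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    row$test <- "degenerate"
    return(row)
  }
  adP <- function(v) {
    if (length(v) < 8 || stats::var(v) == 0) return(NA_real_)
    nortest::ad.test(v)$p.value
  }
  row$adPX <- adP(x); row$adPY <- adP(y)
  normal <- !is.na(row$adPX) && !is.na(row$adPY) &&
    row$adPX > alphaNormal && row$adPY > alphaNormal
  if (normal) {
    ft <- stats::var.test(x, y)
    row$varP <- ft$p.value
    pooled <- ft$p.value > alphaVar
    tt <- stats::t.test(x, y, alternative = tail, var.equal = pooled)
    row$test <- if (pooled) "t pooled" else "t Welch"
    row$statistic <- unname(tt$statistic)
    row$p <- tt$p.value
  } else {
    exact <- length(x) <= 20 && length(y) <= 20 &&
      !anyDuplicated(c(x, y))
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = tail, exact = exact,
                         correct = TRUE))
    row$test <- "mann-whitney"
    row$statistic <- unname(wt$statistic)
    row$p <- wt$p.value
  }
  row
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, min-cumulated from the largest
#' rank down) with rejection flags at the given FDR threshold.
#'
#' @param p vector of raw p-values in [0, 1]
#' @param q FDR threshold for the rejection flags
#' @return data.frame with columns \code{p}, \code{pAdj},
#'   \code{rejected}; zero rows for empty input
#' @examples
#' bhFdrAdjust(c(0.01, 0.02, 0.2, 0.9))
#' @export
bhFdrAdjust <- function(p, q = 0.1) {
  if (length(p) == 0)
    return(data.frame(p = numeric(), pAdj = numeric(),
                      rejected = logical()))
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  pAdj <- stats::p.adjust(p, method = "BH")
  data.frame(p = p, pAdj = pAdj, rejected = !is.na(pAdj) & pAdj <= q)
}

#' Significance tier of an FDR-adjusted p-value
#'
#' Tiers follow the figure-annotation convention: \code{*} for p < 0.1,
#' \code{**} for p < 0.05, \code{***} for p < 0.01, \code{ns}
#' otherwise. Boundaries are exclusive (p = 0.1 is \code{ns}).
#'
#' @param p adjusted p-value(s) in [0, 1]
#' @return character vector of tiers
#' @examples
#' significanceTier(c(0.09, 0.03, 0.005, 0.1))
#' @export
significanceTier <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.01, "***",
                ifelse(p < 0.05, "**",
                       ifelse(p < 0.1, "*", "ns"))))
}

#' Apply FDR adjustment and tiers to a comparison family
#'
#' Convenience wrapper for a family of \code{adaptiveTwoSampleTest}
#' rows: adds \code{pAdj}, \code{rejected} (at the FDR threshold) and
#' \code{tier} columns. Call once per family (e.g. all pairwise
#' comparisons of one wavelength x metric panel).
#'
#' @param comparisons data.frame with a raw \code{p} column
#' @param q FDR threshold
#' @return the data.frame with adjustment columns appended
#' @export
adjustComparisonFamily <- function(comparisons, q = 0.1) {
  adj <- bhFdrAdjust(comparisons$p, q = q)
  comparisons$pAdj <- adj$pAdj
  comparisons$rejected <- adj$rejected
  comparisons$tier <- significanceTier(comparisons$pAdj)
  comparisons
}
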