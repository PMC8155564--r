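## Doublet detection: decide which MS2 spectra contain cross-linked peptides
## and extract peptide-mass hypotheses from stump-ion doublets.

.PROTON <- 1.007276
.C13 <- 1.0033548

## cap quadratic peak pairing; keep the most intense peaks
.trimPeaks <- function(spectrum, maxPeaks = 2000L) {
  p <- spectrum@peaks
  if (nrow(p) <= maxPeaks) return(spectrum)
  keep <- sort(order(p[, 2L], decreasing = TRUE)[seq_len(maxPeaks)])
  initialize(spectrum, peaks = p[keep, , drop = FALSE])
}

#' Find stump-ion doublets in a spectrum
#'
#' Scans all peak pairs (i < j) and charge states z for a spacing of
#' (heavy - light)/z within the doublet tolerance. Each hit implies the
#' neutral mass of one cross-linked peptide:
#' `mass = mz_light * z - z * proton - lightMass`. Complementarity (the same
#' mass inferred from the heavy peak) holds by construction of the spacing
#' test. Results are deduplicated by (mass rounded to 1e-4, charge).
#'
#' @param spectrum An [Ms2Spectrum-class].
#' @param linker A [CrosslinkerSpec-class].
#' @param chargeRange Integer charges to try; default 1 to
#'   (precursor charge - 1), a fragment cannot out-charge its precursor.
#' @param tol Doublet [Tolerance-class] (numeric = ppm, applied to the
#'   heavier peak m/z). Default 10 ppm.
#' @param maxPeaks Spectra with more peaks are trimmed to the most intense
#'   `maxPeaks` before pairing.
#' @return data.frame with columns `peptideNeutralMass`, `charge`,
#'   `lightMz`, `heavyMz`, `lightIdx`, `heavyIdx`, `completeness` ("full").
#' @export
findDoublets <- function(spectrum, linker, chargeRange = NULL,
                         tol = tolerance(10, "ppm"), maxPeaks = 2000L) {
  if (is.numeric(tol)) tol <- tolerance(tol, "ppm")
  if (is.null(chargeRange)) {
    z <- precursorCharge(spectrum)
    chargeRange <- if (is.na(z) || z < 2L) 1:3 else seq_len(max(1L, z - 1L))
  }
  spectrum <- .trimPeaks(spectrum, maxPeaks)
  p <- spectrum@peaks
  n <- nrow(p)
  empty <- data.frame(peptideNeutralMass = numeric(), charge = integer(),
                      lightMz = numeric(), heavyMz = numeric(),
                      lightIdx = integer(), heavyIdx = integer(),
                      completeness = character(), stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  mz <- p[, 1L]
  delta <- doubletDelta(linker)
  res <- list()
  for (z in chargeRange) {
    target <- mz + delta / z
    w <- vapply(target, function(t) toDa(tol, at = t), 0)
    lo <- findInterval(target - w, mz, left.open = TRUE) + 1L
    hi <- findInterval(target + w, mz)
    for (i in which(hi >= lo)) {
      for (j in lo[i]:hi[i]) {
        if (j <= i) next
        mass <- mz[i] * z - z * .PROTON - linker@lightMass
        if (mass <= 0) next
        res[[length(res) + 1L]] <- c(mass, z, mz[i], mz[j], i, j)
      }
    }
  }
  if (!length(res)) return(empty)
  m <- do.call(rbind, res)
  df <- data.frame(peptideNeutralMass = m[, 1L], charge = as.integer(m[, 2L]),
                   lightMz = m[, 3L], heavyMz = m[, 4L],
                   lightIdx = as.integer(m[, 5L]), heavyIdx = as.integer(m[, 6L]),
                   completeness = "full", stringsAsFactors = FALSE)
  df <- df[!duplicated(paste(round(df$peptideNeutralMass, 4L), df$charge)), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

.canonicalPair <- function(m1, m2) {
  cbind(alpha = pmax(m1, m2), beta = pmin(m1, m2))
}

.dedupHypotheses <- function(df) {
  if (!nrow(df)) return(df)
  key <- paste(round(df$massAlpha, 3L), round(df$massBeta, 3L))
  df <- df[!duplicated(key), , drop = FALSE]
  rownames(df) <- NULL
  df
}

.emptyHypotheses <- function() {
  data.frame(massAlpha = numeric(), massBeta = numeric(),
             mode = character(), completeness = character(),
             partnerIons = integer(), stringsAsFactors = FALSE)
}

#' Evidence-mode peptide mass pairs
#'
#' Evidence mode requires ions from both peptides. Two cases are emitted:
#' (a) two full doublets whose masses, plus the intact linker mass, match
#' the precursor mass within `tD`; (b) one full doublet plus a lone peak
#' interpreted as the light or the heavy stump ion of the partner peptide
#' (both interpretations at every charge in `chargeRange`) satisfying the
#' same relation. Lone-partner candidates are drawn from the most intense
#' unassigned peaks.
#'
#' @param doublets Output of [findDoublets()].
#' @param spectrum The [Ms2Spectrum-class] the doublets came from.
#' @param precursorMass Neutral precursor mass to test against (Da).
#' @param linker A [CrosslinkerSpec-class].
#' @param tD Precursor-relation [Tolerance-class] (numeric = ppm, relative
#'   to the precursor mass). Default 5 ppm.
#' @param chargeRange Charges for lone partner ions.
#' @param minPeptideMass Partner masses below this are discarded (Da).
#' @param maxSinglePeaks Lone-partner search is limited to this many of the
#'   most intense unassigned peaks.
#' @return data.frame of hypotheses: `massAlpha` >= `massBeta`, `mode`,
#'   `completeness` ("full", "light_only", "heavy_only"), `partnerIons`.
#' @export
detectEvidencePairs <- function(doublets, spectrum, precursorMass, linker,
                                tD = tolerance(5, "ppm"), chargeRange = 1:3,
                                minPeptideMass = 300,
                                maxSinglePeaks = 200L) {
  if (is.numeric(tD)) tD <- tolerance(tD, "ppm")
  w <- toDa(tD, at = precursorMass)
  out <- list()
  nd <- nrow(doublets)
  if (nd == 0L) return(.emptyHypotheses())
  masses <- doublets$peptideNeutralMass
  ## (a) full + full (i == j covers homodimeric pairs)
  for (i in seq_len(nd)) {
    for (j in i:nd) {
      .bumpCounter("doubletPairOps")
      if (abs(masses[i] + masses[j] + linker@intactMass - precursorMass) <= w) {
        cp <- .canonicalPair(masses[i], masses[j])
        out[[length(out) + 1L]] <- data.frame(
          massAlpha = cp[1L, "alpha"], massBeta = cp[1L, "beta"],
          mode = "evidence", completeness = "full", partnerIons = 4L,
          stringsAsFactors = FALSE)
      }
    }
  }
  ## (b) full doublet + lone partner stump ion
  p <- spectrum@peaks
  assigned <- unique(c(doublets$lightIdx, doublets$heavyIdx))
  un <- setdiff(seq_len(nrow(p)), assigned)
  if (length(un) > maxSinglePeaks)
    un <- un[order(p[un, 2L], decreasing = TRUE)[seq_len(maxSinglePeaks)]]
  if (length(un)) {
    stumps <- c(light_only = linker@lightMass, heavy_only = linker@heavyMass)
    for (i in seq_len(nd)) {
      for (z in chargeRange) {
        for (s in seq_along(stumps)) {
          implied <- p[un, 1L] * z - z * .PROTON - stumps[[s]]
          .bumpCounter("doubletPairOps", length(un))
          ok <- implied >= minPeptideMass &
            abs(masses[i] + implied + linker@intactMass - precursorMass) <= w
          for (m2 in implied[ok]) {
            cp <- .canonicalPair(masses[i], m2)
            out[[length(out) + 1L]] <- data.frame(
              massAlpha = cp[1L, "alpha"], massBeta = cp[1L, "beta"],
              mode = "evidence", completeness = names(stumps)[s],
              partnerIons = 1L, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(out)) return(.emptyHypotheses())
  .dedupHypotheses(do.call(rbind, out))
}

#' Indication-mode peptide mass pairs
#'
#' When only one doublet is complete, the partner peptide mass is inferred
#' from the precursor: `m2 = precursorMass - intactMass - m1`. The four
#' light/heavy single-ion combinations of the inferred partner are matched
#' against the spectrum purely as annotation (`partnerIons` counts them);
#' emission does not require an observed partner ion.
#'
#' @inheritParams detectEvidencePairs
#' @param spectrum Optional spectrum for partner-ion annotation.
#' @return data.frame of hypotheses (`completeness` = "inferred").
#' @export
detectIndicationPairs <- function(doublets, precursorMass, linker,
                                  tD = tolerance(5, "ppm"),
                                  spectrum = NULL, chargeRange = 1:3,
                                  minPeptideMass = 300,
                                  peakTol = tolerance(10, "ppm")) {
  if (!nrow(doublets)) return(.emptyHypotheses())
  out <- list()
  for (i in seq_len(nrow(doublets))) {
    .bumpCounter("doubletPairOps")
    m1 <- doublets$peptideNeutralMass[i]
    m2 <- precursorMass - linker@intactMass - m1
    if (m2 < minPeptideMass) next
    nIons <- 0L
    if (!is.null(spectrum)) {
      for (stump in c(linker@lightMass, linker@heavyMass)) {
        for (z in chargeRange) {
          if (!is.null(matchPeak(spectrum, neutralToMz(m2 + stump, z),
                                 peakTol)))
            nIons <- nIons + 1L
        }
      }
    }
    cp <- .canonicalPair(m1, m2)
    out[[length(out) + 1L]] <- data.frame(
      massAlpha = cp[1L, "alpha"], massBeta = cp[1L, "beta"],
      mode = "indication", completeness = "inferred",
      partnerIons = nIons, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(.emptyHypotheses())
  .dedupHypotheses(do.call(rbind, out))
}

#' Annotate linker diagnostic ions
#'
#' Diagnostic ions are linker-derived fragments with no peptide attached.
#' Their presence is strong supporting evidence that a spectrum is a
#' cross-link spectrum, but it is advisory: a diagnostic ion alone never
#' admits a spectrum to the search, and by default their absence never
#' excludes one.
#'
#' @param spectrum An [Ms2Spectrum-class].
#' @param linker A [CrosslinkerSpec-class].
#' @param tol Peak-match [Tolerance-class] (numeric = ppm).
#' @return Named logical vector, one element per configured diagnostic ion
#'   (empty when the linker has none), with attribute `any`.
#' @export
detectDiagnosticIons <- function(spectrum, linker, tol = tolerance(10, "ppm")) {
  ions <- linker@diagnosticIons
  hit <- vapply(ions, function(mz) !is.null(matchPeak(spectrum, mz, tol)),
                FALSE)
  names(hit) <- format(ions)
  attr(hit, "any") <- length(hit) > 0L && any(hit)
  hit
}

#' Alternative precursor hypotheses
#'
#' Monoisotopic precursor assignment can be off by one or more C13 isotopes,
#' especially for heavy cross-linked precursors. Offsets 0, -1, ...,
#' -maxOffsets are applied as neutral-mass shifts of k x 1.0033548 Da. In
#' `"ms1"` mode a hypothesis is kept only when a peak exists at the shifted
#' precursor m/z in the supplied MS1 scan; in `"assumed"` mode all are kept.
#'
#' @param spectrum An [Ms2Spectrum-class].
#' @param maxOffsets Non-negative number of isotope offsets to consider.
#' @param mode `"assumed"` or `"ms1"`.
#' @param ms1Spectrum [Ms2Spectrum-class] holding the MS1 peaks (required
#'   for `"ms1"` mode).
#' @param tol MS1 peak-match tolerance.
#' @param charge Precursor charge to assume (default: recorded).
#' @return data.frame with `neutralMass`, `isotopeOffset`, `verifiedInMs1`.
#' @export
precursorHypotheses <- function(spectrum, maxOffsets = 2L,
                                mode = c("assumed", "ms1"),
                                ms1Spectrum = NULL,
                                tol = tolerance(10, "ppm"),
                                charge = precursorCharge(spectrum)) {
  mode <- match.arg(mode)
  stopifnot(maxOffsets >= 0L)
  if (mode == "ms1" && is.null(ms1Spectrum))
    stop("'ms1' mode requires an MS1 spectrum")
  base <- precursorNeutralMass(spectrum, charge)
  offs <- 0:(-maxOffsets)
  mass <- base + offs * .C13
  verified <- rep(NA, length(offs))
  keep <- rep(TRUE, length(offs))
  if (mode == "ms1") {
    for (i in seq_along(offs)) {
      mzShift <- neutralToMz(mass[i], charge)
      verified[i] <- !is.null(matchPeak(ms1Spectrum, mzShift, tol))
    }
    keep <- verified | offs == 0L   # the recorded precursor is always kept
  }
  data.frame(neutralMass = mass[keep], isotopeOffset = as.integer(offs[keep]),
             verifiedInMs1 = verified[keep])
}

#' Detect cross-link mass-pair hypotheses in a spectrum
#'
#' Runs doublet detection and emits peptide mass-pair hypotheses in the
#' requested mode. `"combined"` is the union of evidence and indication
#' hypotheses (deduplicated on the canonical rounded mass pair, evidence
#' rows kept on collision). A spectrum with no hypotheses is classified as a
#' non-cross-link spectrum and skipped by the search.
#'
#' @param spectrum An [Ms2Spectrum-class].
#' @param linker A [CrosslinkerSpec-class].
#' @param mode `"evidence"`, `"indication"` or `"combined"`.
#' @param precursorMass Neutral precursor mass to test against; defaults to
#'   the spectrum's recorded precursor.
#' @param doubletTol,tD,peakTol Tolerances (numeric = ppm).
#' @param chargeRange Doublet/lone-ion charges; default 1 to precursor
#'   charge - 1.
#' @param minPeptideMass Minimum peptide mass (Da).
#' @param requireDiagnostic If `TRUE` and the linker defines diagnostic
#'   ions, spectra without any matched diagnostic ion return no hypotheses.
#' @param doublets Precomputed [findDoublets()] output (doublets do not
#'   depend on the precursor hypothesis, so callers iterating alternative
#'   precursors can reuse them); `NULL` computes them.
#' @return Hypothesis data.frame (see [detectEvidencePairs()]), possibly
#'   empty, with the matched doublet table in attribute `doublets`.
#' @export
detect <- function(spectrum, linker,
                   mode = c("combined", "evidence", "indication"),
                   precursorMass = NULL,
                   doubletTol = tolerance(10, "ppm"),
                   tD = tolerance(5, "ppm"),
                   peakTol = tolerance(10, "ppm"),
                   chargeRange = NULL, minPeptideMass = 300,
                   requireDiagnostic = FALSE, doublets = NULL) {
  mode <- match.arg(mode)
  if (is.null(precursorMass)) precursorMass <- precursorNeutralMass(spectrum)
  if (is.null(chargeRange)) {
    z <- precursorCharge(spectrum)
    chargeRange <- if (is.na(z) || z < 2L) 1:3 else seq_len(max(1L, z - 1L))
  }
  if (requireDiagnostic && length(linker@diagnosticIons)) {
    if (!attr(detectDiagnosticIons(spectrum, linker, peakTol), "any"))
      return(structure(.emptyHypotheses(), doublets = NULL))
  }
  dbl <- if (is.null(doublets))
    findDoublets(spectrum, linker, chargeRange, doubletTol) else doublets
  ev <- if (mode %in% c("evidence", "combined"))
    detectEvidencePairs(dbl, spectrum, precursorMass, linker, tD,
                        chargeRange, minPeptideMass)
  else .emptyHypotheses()
  ind <- if (mode %in% c("indication", "combined"))
    detectIndicationPairs(dbl, precursorMass, linker, tD, spectrum,
                          chargeRange, minPeptideMass, peakTol)
  else .emptyHypotheses()
  structure(.dedupHypotheses(rbind(ev, ind)), doublets = dbl)
}
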