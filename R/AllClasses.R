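#' @import methods
NULL

## ---------------------------------------------------------------------------
## Tolerance
## ---------------------------------------------------------------------------

#' Mass tolerance in Da or ppm
#'
#' A tolerance carries a positive value and a unit. ppm tolerances are
#' converted to Da relative to the mass (or m/z) they are applied to via
#' [toDa()].
#'
#' @slot value Positive numeric tolerance value.
#' @slot unit `"ppm"` or `"Da"`.
#' @export
#' @examples
#' tol <- tolerance(10, "ppm")
#' toDa(tol, at = 1000)   # 0.01 Da at m/z 1000
setClass("Tolerance",
  representation(value = "numeric", unit = "character"),
  validity = function(object) {
    if (length(object@value) != 1L || !is.finite(object@value) ||
        object@value <= 0)
      return("tolerance value must be a single positive number")
    if (!object@unit %in% c("ppm", "Da"))
      return("tolerance unit must be 'ppm' or 'Da'")
    TRUE
  }
)

#' @param value Positive numeric tolerance value.
#' @param unit `"ppm"` or `"Da"`.
#' @rdname Tolerance-class
#' @export
tolerance <- function(value, unit = c("ppm", "Da")) {
  unit <- match.arg(unit)
  new("Tolerance", value = as.numeric(value), unit = unit)
}

#' Convert a tolerance to an absolute window in Da
#'
#' @param tol A [Tolerance-class] object.
#' @param at The mass or m/z (Da) the tolerance is applied to; required for
#'   ppm units, ignored for Da.
#' @return Half-window width in Da.
#' @export
toDa <- function(tol, at = NULL) {
  stopifnot(is(tol, "Tolerance"))
  if (tol@unit == "Da") return(tol@value)
  if (is.null(at)) stop("ppm tolerance needs a reference mass ('at')")
  tol@value * 1e-6 * abs(at)
}

setMethod("show", "Tolerance", function(object) {
  cat(sprintf("Tolerance: %g %s\n", object@value, object@unit))
})

## ---------------------------------------------------------------------------
## CrosslinkerSpec
## ---------------------------------------------------------------------------

#' MS-cleavable cross-linker definition
#'
#' Chemistry of a symmetric MS-cleavable cross-linker. On collisional
#' activation the linker breaks asymmetrically into a lighter and a heavier
#' stump, each staying on one peptide; the two complementary fragments sum to
#' the intact linker mass, and the heavy-light mass difference is the
#' signature used for doublet detection.
#'
#' @slot name Linker name.
#' @slot intactMass Intact linker mass (Da), the residue mass added between
#'   the two linked residues.
#' @slot lightMass,heavyMass Monoisotopic masses (Da) of the lighter and
#'   heavier cleavage stump.
#' @slot reactiveResidues Character vector of reactive amino-acid letters.
#' @slot ntermReactive,ctermReactive Logical; whether the protein N-/C-terminus
#'   is reactive.
#' @slot diagnosticIons Numeric m/z values of linker-derived diagnostic ions
#'   (possibly empty).
#' @export
#' @examples
#' dssoLinker()
#' doubletDelta(dssoLinker())
setClass("CrosslinkerSpec",
  representation(
    name = "character",
    intactMass = "numeric",
    lightMass = "numeric",
    heavyMass = "numeric",
    reactiveResidues = "character",
    ntermReactive = "logical",
    ctermReactive = "logical",
    diagnosticIons = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    if (object@lightMass >= object@heavyMass)
      msg <- c(msg, "lightMass must be smaller than heavyMass")
    if (abs(object@lightMass + object@heavyMass - object@intactMass) > 1e-4)
      msg <- c(msg,
        "light + heavy stump masses must sum to the intact linker mass (within 1e-4 Da)")
    if (length(object@reactiveResidues) == 0L &&
        !object@ntermReactive && !object@ctermReactive)
      msg <- c(msg, "linker must react with at least one residue or terminus")
    if (length(msg)) msg else TRUE
  }
)

#' @param name Linker name.
#' @param intactMass,lightMass,heavyMass Masses in Da (see slots).
#' @param reactiveResidues Character vector of reactive residue letters.
#' @param ntermReactive,ctermReactive Logical terminus reactivity flags.
#' @param diagnosticIons Numeric m/z values (may be empty).
#' @rdname CrosslinkerSpec-class
#' @export
crosslinkerSpec <- function(name, intactMass, lightMass, heavyMass,
                            reactiveResidues = "K",
                            ntermReactive = FALSE, ctermReactive = FALSE,
                            diagnosticIons = numeric()) {
  new("CrosslinkerSpec", name = name, intactMass = intactMass,
      lightMass = lightMass, heavyMass = heavyMass,
      reactiveResidues = reactiveResidues,
      ntermReactive = ntermReactive, ctermReactive = ctermReactive,
      diagnosticIons = as.numeric(diagnosticIons))
}

#' Built-in linker presets
#'
#' DSSO (disuccinimidyl sulfoxide) and DSBU (disuccinimidyl dibutyric urea)
#' presets with stump masses derived from the elemental compositions of the
#' cleavage fragments. Both are lysine-reactive.
#'
#' @return A [CrosslinkerSpec-class].
#' @export
dssoLinker <- function() {
  crosslinkerSpec("DSSO",
    intactMass = 158.00377, lightMass = 54.01057, heavyMass = 103.99320,
    reactiveResidues = "K")
}

#' @rdname dssoLinker
#' @export
dsbuLinker <- function() {
  crosslinkerSpec("DSBU",
    intactMass = 196.08479, lightMass = 85.05276, heavyMass = 111.03203,
    reactiveResidues = "K")
}

#' Doublet mass difference of a cleavable linker
#'
#' @param linker A [CrosslinkerSpec-class].
#' @return heavy - light stump mass (Da); the m/z spacing of a stump doublet
#'   at charge z is this value divided by z.
#' @export
doubletDelta <- function(linker) {
  stopifnot(is(linker, "CrosslinkerSpec"))
  linker@heavyMass - linker@lightMass
}

#' @rdname CrosslinkerSpec-class
#' @param object,linker A `CrosslinkerSpec`.
#' @export
intactMass <- function(linker) linker@intactMass

#' @rdname CrosslinkerSpec-class
#' @export
lightMass <- function(linker) linker@lightMass

#' @rdname CrosslinkerSpec-class
#' @export
heavyMass <- function(linker) linker@heavyMass

#' @rdname CrosslinkerSpec-class
#' @export
reactiveResidues <- function(linker) linker@reactiveResidues

#' @rdname CrosslinkerSpec-class
#' @export
diagnosticIons <- function(linker) linker@diagnosticIons

setMethod("show", "CrosslinkerSpec", function(object) {
  cat(sprintf("CrosslinkerSpec '%s'\n", object@name))
  cat(sprintf("  intact %.5f Da, stumps %.5f / %.5f Da (delta %.5f)\n",
              object@intactMass, object@lightMass, object@heavyMass,
              doubletDelta(object)))
  cat(sprintf("  reactive: %s%s%s\n",
              paste(object@reactiveResidues, collapse = ""),
              if (object@ntermReactive) " +protein-N-term" else "",
              if (object@ctermReactive) " +protein-C-term" else ""))
  if (length(object@diagnosticIons))
    cat("  diagnostic ions:", paste(format(object@diagnosticIons),
                                    collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## Ms2Spectrum
## ---------------------------------------------------------------------------

#' A centroided MS2 spectrum
#'
#' Peak list plus precursor descriptor. Peaks are stored as a two-column
#' matrix (`mz`, `intensity`) sorted ascending by m/z with strictly positive
#' intensities. The neutral precursor mass is derived as
#' `precursorMz * z - z * proton`.
#'
#' @slot scanId Scan identifier (MGF TITLE).
#' @slot precursorMz Precursor m/z.
#' @slot precursorCharge Integer precursor charge (>= 1); `NA` if the file
#'   did not record one (charge states are then enumerated downstream).
#' @slot retentionTime Seconds, or `NA`.
#' @slot ionMobility 1/K0, pass-through only, or `NA`.
#' @slot peaks Numeric matrix with columns `mz`, `intensity`.
#' @slot metadata Named list of unrecognised header fields.
#' @export
setClass("Ms2Spectrum",
  representation(
    scanId = "character",
    precursorMz = "numeric",
    precursorCharge = "integer",
    retentionTime = "numeric",
    ionMobility = "numeric",
    peaks = "matrix",
    metadata = "list"
  ),
  validity = function(object) {
    msg <- character()
    p <- object@peaks
    if (ncol(p) != 2L)
      msg <- c(msg, "peaks must be a two-column (mz, intensity) matrix")
    if (nrow(p) > 0L) {
      if (is.unsorted(p[, 1L]))
        msg <- c(msg, "peaks must be sorted ascending by m/z")
      if (any(p[, 2L] <= 0))
        msg <- c(msg, "peak intensities must be positive")
    }
    if (!is.na(object@precursorCharge) && object@precursorCharge < 1L)
      msg <- c(msg, "precursor charge must be >= 1")
    if (length(msg)) msg else TRUE
  }
)

#' @param scanId,precursorMz,precursorCharge,retentionTime,ionMobility,metadata
#'   See slots.
#' @param peaks Two-column numeric matrix or data.frame (mz, intensity);
#'   rows are sorted by m/z on construction.
#' @rdname Ms2Spectrum-class
#' @export
ms2Spectrum <- function(scanId, precursorMz, precursorCharge, peaks,
                        retentionTime = NA_real_, ionMobility = NA_real_,
                        metadata = list()) {
  peaks <- as.matrix(peaks)
  if (ncol(peaks) != 2L) stop("'peaks' must have two columns (mz, intensity)")
  colnames(peaks) <- c("mz", "intensity")
  storage.mode(peaks) <- "double"
  if (nrow(peaks)) peaks <- peaks[order(peaks[, 1L]), , drop = FALSE]
  new("Ms2Spectrum", scanId = as.character(scanId),
      precursorMz = as.numeric(precursorMz),
      precursorCharge = as.integer(precursorCharge),
      retentionTime = as.numeric(retentionTime),
      ionMobility = as.numeric(ionMobility),
      peaks = peaks, metadata = metadata)
}

#' @rdname Ms2Spectrum-class
#' @param x An `Ms2Spectrum`.
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))

#' @rdname Ms2Spectrum-class
#' @export
setMethod("peaks", "Ms2Spectrum", function(x) x@peaks)

#' @rdname Ms2Spectrum-class
#' @export
scanId <- function(x) x@scanId

#' @rdname Ms2Spectrum-class
#' @export
precursorMz <- function(x) x@precursorMz

#' @rdname Ms2Spectrum-class
#' @export
precursorCharge <- function(x) x@precursorCharge

#' Neutral (uncharged) precursor mass of a spectrum
#'
#' @param x An [Ms2Spectrum-class].
#' @param charge Charge to assume; defaults to the recorded precursor charge.
#' @return Neutral mass in Da.
#' @export
precursorNeutralMass <- function(x, charge = precursorCharge(x)) {
  if (is.na(charge)) stop("spectrum has no precursor charge; supply one")
  mzToNeutral(x@precursorMz, charge)
}

setMethod("show", "Ms2Spectrum", function(object) {
  cat(sprintf("Ms2Spectrum '%s': %d peaks, precursor m/z %.4f (%s+)\n",
              object@scanId, nrow(object@peaks), object@precursorMz,
              ifelse(is.na(object@precursorCharge), "?",
                     object@precursorCharge)))
})

## ---------------------------------------------------------------------------
## CandidateIndex
## ---------------------------------------------------------------------------

#' Mass-searchable index of linkable candidate peptides
#'
#' Holds the unique digested peptides (target and decoy) that carry at least
#' one valid cross-link position for a given linker, sorted ascending by
#' neutral mass for binary-search range queries.
#'
#' @slot peptides data.frame with columns `sequence`, `mods` (list of named
#'   numeric mass shifts), `neutralMass`, `isDecoy`, `linkPositions` (list of
#'   integer vectors), `locations` (list of data.frames with `accession`,
#'   `start`), `nOccurrences` (total protein occurrences).
#' @slot linker The [CrosslinkerSpec-class] the link positions refer to.
#' @export
setClass("CandidateIndex",
  representation(peptides = "data.frame", linker = "CrosslinkerSpec"),
  validity = function(object) {
    p <- object@peptides
    need <- c("sequence", "mods", "neutralMass", "isDecoy",
              "linkPositions", "locations", "nOccurrences")
    if (!all(need %in% names(p)))
      return(paste("peptides table must have columns:",
                   paste(need, collapse = ", ")))
    if (nrow(p) > 1L && is.unsorted(p$neutralMass))
      return("peptides must be sorted ascending by neutralMass")
    if (nrow(p) && any(lengths(p$linkPositions) == 0L))
      return("every indexed peptide needs at least one link position")
    TRUE
  }
)

#' @rdname CandidateIndex-class
#' @param index A `CandidateIndex`.
#' @export
nPeptides <- function(index) nrow(index@peptides)

#' @rdname CandidateIndex-class
#' @export
indexLinker <- function(index) index@linker

setMethod("show", "CandidateIndex", function(object) {
  p <- object@peptides
  cat(sprintf("CandidateIndex: %d linkable peptides (%d decoy) for linker '%s'\n",
              nrow(p), sum(p$isDecoy), object@linker@name))
  if (nrow(p))
    cat(sprintf("  mass range %.4f - %.4f Da\n",
                min(p$neutralMass), max(p$neutralMass)))
})

#' @rdname CandidateIndex-class
#' @param i Row indices.
#' @export
setMethod("[", "CandidateIndex", function(x, i, j, ..., drop = TRUE) {
  initialize(x, peptides = x@peptides[i, , drop = FALSE])
})
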