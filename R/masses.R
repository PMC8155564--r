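## Monoisotopic mass bookkeeping. All masses in Da.

#' Physical constants used throughout the package
#'
#' Monoisotopic masses in Dalton: the proton mass used for m/z <-> neutral
#' mass conversion, the C13-C12 mass difference used for isotope-offset
#' precursor hypotheses, and the mass of water added to a residue chain to
#' form a free peptide.
#'
#' @format Named numeric vector with elements `proton`, `c13`, `water`.
#' @export
#' @examples
#' xlmsConstants["proton"]
xlmsConstants <- c(
  proton = 1.007276,
  c13    = 1.0033548,
  water  = 18.0105646863
)

## standard IUPAC monoisotopic residue masses for the 20 proteinogenic
## amino acids (residue = amino acid - water)
.RESIDUE_MASS <- c(
  G =  57.02146372, A =  71.03711379, S =  87.03202841, P =  97.05276385,
  V =  99.06841392, T = 101.04767847, C = 103.00918448, L = 113.08406398,
  I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857751,
  K = 128.09496302, E = 129.04259309, M = 131.04048509, H = 137.05891186,
  F = 147.06841392, R = 156.10111102, Y = 163.06332853, W = 186.07931295
)

#' Monoisotopic residue masses
#'
#' @return Named numeric vector of the 20 proteinogenic residue masses (Da).
#' @export
#' @examples
#' residueMasses()[["G"]]
residueMasses <- function() .RESIDUE_MASS

#' Monoisotopic neutral mass of a peptide
#'
#' Sum of residue masses plus one water, plus any modification mass shifts.
#' Modifications are given as a numeric vector of mass shifts (Da) named by
#' the 1-based residue position they sit on; positions must lie inside the
#' sequence. An unnamed numeric vector is interpreted as per-position shifts
#' applied at the positions given by its indices of non-zero entries only if
#' named -- pass a named vector.
#'
#' @param sequence Amino-acid string over the 20-letter alphabet.
#' @param modifications Named numeric vector, names are 1-based positions,
#'   values are mass shifts in Da. `NULL` for none.
#' @return Neutral monoisotopic mass in Da.
#' @export
#' @examples
#' peptideMass("G")                      # glycine, 75.03203 Da
#' peptideMass("PEPTIDE")
#' peptideMass("ACDK", c(`2` = 57.02146))
peptideMass <- function(sequence, modifications = NULL) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L)
    stop("'sequence' must be a non-empty amino-acid string")
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  m <- .RESIDUE_MASS[aa]
  if (anyNA(m))
    stop("unknown residue(s) in sequence: ",
         paste(unique(aa[is.na(m)]), collapse = ", "))
  total <- sum(m) + xlmsConstants[["water"]]
  if (!is.null(modifications) && length(modifications)) {
    pos <- as.integer(names(modifications))
    if (anyNA(pos) || any(pos < 1L) || any(pos > length(aa)))
      stop("modification positions must be 1-based indices into the sequence")
    total <- total + sum(modifications)
  }
  unname(total)
}

## vectorised residue-prefix masses used by the fragment generator
.residueVector <- function(sequence) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  m <- .RESIDUE_MASS[aa]
  if (anyNA(m))
    stop("unknown residue(s) in sequence: ",
         paste(unique(aa[is.na(m)]), collapse = ", "))
  unname(m)
}

#' Convert between m/z and neutral mass
#'
#' `mzToNeutral()` computes `mz * z - z * proton`; `neutralToMz()` inverts it.
#'
#' @param mz,mass Numeric m/z or neutral mass values (Da).
#' @param charge Positive integer charge state.
#' @return Numeric vector.
#' @export
mzToNeutral <- function(mz, charge) {
  mz * charge - charge * xlmsConstants[["proton"]]
}

#' @rdname mzToNeutral
#' @export
neutralToMz <- function(mass, charge) {
  (mass + charge * xlmsConstants[["proton"]]) / charge
}
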