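## In-silico tryptic digestion, modification expansion, decoy generation,
## FASTA I/O.

#' Digestion and modification parameters
#'
#' Tryptic cleavage after K or R, except before proline. Fixed modifications
#' are applied to every matching residue; variable modifications are expanded
#' combinatorially up to `maxVariableMods` per peptide. Mass shifts are
#' monoisotopic Da, named by the residue letter they apply to.
#'
#' @param missedCleavages Maximum missed cleavages (>= 0).
#' @param minLength,maxLength Peptide length bounds (residues).
#' @param fixedModifications Named numeric vector residue -> mass shift.
#'   Default: carbamidomethylation of cysteine (+57.02146 Da).
#' @param variableModifications Named numeric vector residue -> mass shift.
#'   Default: oxidation of methionine (+15.99491 Da).
#' @param maxVariableMods Maximum number of variable modifications carried by
#'   one peptide.
#' @return A list of class `DigestionParams`.
#' @export
#' @examples
#' digestionParams(missedCleavages = 1)
digestionParams <- function(missedCleavages = 2L,
                            minLength = 5L, maxLength = 30L,
                            fixedModifications = c(C = 57.02146374),
                            variableModifications = c(M = 15.99491462),
                            maxVariableMods = 2L) {
  stopifnot(missedCleavages >= 0L, minLength >= 1L, minLength <= maxLength,
            maxVariableMods >= 0L)
  structure(list(
    missedCleavages = as.integer(missedCleavages),
    minLength = as.integer(minLength),
    maxLength = as.integer(maxLength),
    fixedModifications = fixedModifications,
    variableModifications = variableModifications,
    maxVariableMods = as.integer(maxVariableMods)
  ), class = "DigestionParams")
}

## cleavage boundary positions (end of each fragment) for trypsin:
## after K/R unless followed by P; the protein C-terminus is always an end
.trypticEnds <- function(aa) {
  n <- length(aa)
  if (n == 0L) return(integer())
  cut <- which(aa %in% c("K", "R"))
  cut <- cut[cut == n | aa[pmin(cut + 1L, n)] != "P"]
  sort(unique(c(cut, n)))
}

## expand one peptide window into its modification variants
.modVariants <- function(sequence, params) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  fixed <- numeric(0)
  fm <- params$fixedModifications
  if (length(fm)) {
    pos <- which(aa %in% names(fm))
    if (length(pos)) fixed <- stats::setNames(unname(fm[aa[pos]]),
                                              as.character(pos))
  }
  variants <- list(fixed)
  vm <- params$variableModifications
  if (length(vm) && params$maxVariableMods > 0L) {
    vpos <- which(aa %in% names(vm))
    kmax <- min(length(vpos), params$maxVariableMods)
    if (kmax > 0L) {
      for (k in seq_len(kmax)) {
        combos <- utils::combn(vpos, k, simplify = FALSE)
        for (cb in combos) {
          shifts <- stats::setNames(unname(vm[aa[cb]]), as.character(cb))
          variants[[length(variants) + 1L]] <- c(fixed, shifts)
        }
      }
    }
  }
  variants
}

#' Digest a protein sequence in silico
#'
#' Enumerates all tryptic peptides (cleavage after K/R, not before P) obeying
#' the missed-cleavage and length bounds, then expands fixed and variable
#' modifications. One row is returned per (peptide window, modification
#' variant).
#'
#' @param sequence Protein amino-acid string.
#' @param params A [digestionParams()] object.
#' @param accession Protein accession recorded in the output.
#' @param isDecoy Logical flag propagated to the output.
#' @return data.frame with columns `sequence`, `accession`, `start` (1-based
#'   position of the peptide in the protein), `nMissed`, `mods` (list column
#'   of named numeric mass shifts), `neutralMass`, `isDecoy`,
#'   `ctermProtein` (peptide ends at the protein C-terminus).
#' @export
#' @examples
#' digest("AKRC", digestionParams(missedCleavages = 0, minLength = 1,
#'                                fixedModifications = NULL))
digest <- function(sequence, params = digestionParams(),
                   accession = "protein", isDecoy = FALSE) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  ends <- .trypticEnds(aa)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  nfrag <- length(ends)
  out <- list()
  for (i in seq_len(nfrag)) {
    for (mc in 0:params$missedCleavages) {
      j <- i + mc
      if (j > nfrag) break
      from <- starts[i]; to <- ends[j]
      len <- to - from + 1L
      if (len < params$minLength || len > params$maxLength) next
      pep <- paste(aa[from:to], collapse = "")
      for (mods in .modVariants(pep, params)) {
        out[[length(out) + 1L]] <- list(
          sequence = pep, accession = accession, start = from,
          nMissed = mc, mods = mods,
          neutralMass = peptideMass(pep, mods),
          isDecoy = isDecoy, ctermProtein = (to == length(aa)))
      }
    }
  }
  if (!length(out))
    return(data.frame(sequence = character(), accession = character(),
                      start = integer(), nMissed = integer(),
                      mods = I(list()), neutralMass = numeric(),
                      isDecoy = logical(), ctermProtein = logical()))
  df <- data.frame(
    sequence = vapply(out, `[[`, "", "sequence"),
    accession = vapply(out, `[[`, "", "accession"),
    start = vapply(out, `[[`, 0L, "start"),
    nMissed = vapply(out, `[[`, 0L, "nMissed"),
    neutralMass = vapply(out, `[[`, 0, "neutralMass"),
    isDecoy = vapply(out, `[[`, FALSE, "isDecoy"),
    ctermProtein = vapply(out, `[[`, FALSE, "ctermProtein"),
    stringsAsFactors = FALSE)
  df$mods <- lapply(out, `[[`, "mods")
  df
}

#' Digest a whole protein database
#'
#' @param proteins Named character vector (accession -> sequence) or an
#'   `AAStringSet`.
#' @param params A [digestionParams()].
#' @param decoyPrefix Accessions starting with this prefix are flagged decoy.
#' @return Row-bound [digest()] output over all proteins.
#' @export
digestDatabase <- function(proteins, params = digestionParams(),
                           decoyPrefix = "REV_") {
  proteins <- .asProteinVector(proteins)
  res <- lapply(seq_along(proteins), function(i) {
    acc <- names(proteins)[i]
    digest(proteins[[i]], params, accession = acc,
           isDecoy = startsWith(acc, decoyPrefix))
  })
  do.call(rbind, res)
}

#' Generate a reversed decoy database
#'
#' One decoy per target protein by full sequence reversal; decoy accessions
#' carry the reserved prefix. Peptides present in both target and decoy space
#' are counted as target downstream (see [buildCandidateIndex()]).
#'
#' @param proteins Named character vector or `AAStringSet` of target proteins.
#' @param prefix Decoy accession prefix.
#' @return Named character vector of decoy proteins, same length as input.
#' @export
#' @examples
#' makeDecoyDatabase(c(P1 = "ABCK"))
makeDecoyDatabase <- function(proteins, prefix = "REV_") {
  if (!length(proteins)) stop("target database is empty")
  proteins <- .asProteinVector(proteins)
  rev <- vapply(strsplit(proteins, "", fixed = TRUE),
                function(x) paste(rev(x), collapse = ""), "")
  names(rev) <- paste0(prefix, names(proteins))
  rev
}

.asProteinVector <- function(proteins) {
  if (is(proteins, "AAStringSet")) {
    v <- as.character(proteins)
    names(v) <- sub("\\s.*$", "", names(proteins))
    return(v)
  }
  if (!is.character(proteins) || is.null(names(proteins)))
    stop("'proteins' must be a named character vector or AAStringSet")
  proteins
}

#' Read / write protein FASTA
#'
#' Thin wrappers around Biostrings. The accession is the first
#' whitespace-delimited token of the header line.
#'
#' @param path FASTA file path.
#' @return `readFasta()`: named character vector accession -> sequence.
#' @export
readFasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  v <- as.character(set)
  names(v) <- sub("\\s.*$", "", names(set))
  v
}

#' @rdname readFasta
#' @param proteins Named character vector accession -> sequence.
#' @export
writeFasta <- function(proteins, path) {
  set <- Biostrings::AAStringSet(proteins)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
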