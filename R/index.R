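## Candidate peptide index: link positions and mass range queries.

.modsKey <- function(mods) {
  if (!length(mods)) return("")
  o <- order(as.integer(names(mods)))
  paste(names(mods)[o], sprintf("%.5f", unname(mods)[o]),
        sep = ":", collapse = ";")
}

#' Valid cross-link positions within a peptide
#'
#' A residue is linkable if it is reactive for the linker and is not the
#' C-terminal residue of the tryptic peptide -- a cross-linked K/R cannot be
#' cleaved by trypsin -- except when the peptide sits at the protein
#' C-terminus. If the linker is protein-N-terminus reactive, position 1 of a
#' protein-N-terminal peptide is also linkable.
#'
#' @param sequence Peptide string.
#' @param linker A [CrosslinkerSpec-class].
#' @param ctermProtein Peptide ends at the protein C-terminus.
#' @param ntermProtein Peptide starts at protein position 1.
#' @return Integer vector of 1-based linkable positions (possibly empty).
#' @export
#' @examples
#' linkPositions("ACKDK", dssoLinker())           # internal K only
#' linkPositions("ACK", dssoLinker(), ctermProtein = TRUE)
linkPositions <- function(sequence, linker, ctermProtein = FALSE,
                          ntermProtein = FALSE) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(aa)
  pos <- which(aa %in% linker@reactiveResidues)
  if (!ctermProtein) pos <- pos[pos != n]
  if (linker@ntermReactive && ntermProtein) pos <- union(1L, pos)
  sort(pos)
}

#' Build a mass-searchable candidate index
#'
#' Aggregates a digested peptide table (target plus decoy rows, as produced
#' by [digestDatabase()]) into unique (sequence, modification) peptides,
#' keeps only those with at least one valid link position for the linker, and
#' sorts them by neutral mass. A peptide occurring in both target and decoy
#' databases is counted as target.
#'
#' @param peptides Output of [digest()] / [digestDatabase()].
#' @param linker A [CrosslinkerSpec-class].
#' @return A [CandidateIndex-class].
#' @export
buildCandidateIndex <- function(peptides, linker) {
  stopifnot(is(linker, "CrosslinkerSpec"))
  if (!nrow(peptides))
    return(new("CandidateIndex",
               peptides = data.frame(sequence = character(), mods = I(list()),
                                     neutralMass = numeric(),
                                     isDecoy = logical(),
                                     linkPositions = I(list()),
                                     locations = I(list()),
                                     nOccurrences = integer(),
                                     pepId = integer()),
               linker = linker))
  key <- paste(peptides$sequence,
               vapply(peptides$mods, .modsKey, ""), sep = "|")
  groups <- split(seq_len(nrow(peptides)), key)
  rows <- lapply(groups, function(ix) {
    first <- ix[1L]
    locs <- data.frame(accession = peptides$accession[ix],
                       start = peptides$start[ix],
                       isDecoy = peptides$isDecoy[ix],
                       stringsAsFactors = FALSE)
    anyTarget <- any(!locs$isDecoy)
    if (anyTarget) locs <- locs[!locs$isDecoy, , drop = FALSE]
    lp <- linkPositions(peptides$sequence[first], linker,
                        ctermProtein = any(peptides$ctermProtein[ix]),
                        ntermProtein = any(peptides$start[ix] == 1L))
    list(sequence = peptides$sequence[first],
         mods = peptides$mods[[first]],
         neutralMass = peptides$neutralMass[first],
         isDecoy = !anyTarget,
         linkPositions = lp,
         locations = locs[, c("accession", "start")],
         nOccurrences = nrow(locs))
  })
  keep <- vapply(rows, function(r) length(r$linkPositions) > 0L, FALSE)
  rows <- rows[keep]
  if (!length(rows))
    return(buildCandidateIndex(peptides[0, , drop = FALSE], linker))
  df <- data.frame(
    sequence = vapply(rows, `[[`, "", "sequence"),
    neutralMass = vapply(rows, `[[`, 0, "neutralMass"),
    isDecoy = vapply(rows, `[[`, FALSE, "isDecoy"),
    nOccurrences = vapply(rows, `[[`, 0L, "nOccurrences"),
    stringsAsFactors = FALSE)
  df$mods <- lapply(rows, `[[`, "mods")
  df$linkPositions <- lapply(rows, `[[`, "linkPositions")
  df$locations <- lapply(rows, `[[`, "locations")
  df <- df[order(df$neutralMass), , drop = FALSE]
  rownames(df) <- NULL
  df$pepId <- seq_len(nrow(df))
  new("CandidateIndex", peptides = df, linker = linker)
}

#' Range query into a candidate index
#'
#' Returns all indexed peptides whose neutral mass lies within the tolerance
#' of the query mass. ppm tolerances are taken relative to the query mass.
#' Binary search over the sorted mass vector.
#'
#' @param index A [CandidateIndex-class].
#' @param mass Query neutral mass (Da).
#' @param tol A [Tolerance-class] (or numeric, interpreted as ppm).
#' @return Subset of the peptides table (data.frame), possibly empty.
#' @export
queryIndex <- function(index, mass, tol = tolerance(10, "ppm")) {
  if (is.numeric(tol)) tol <- tolerance(tol, "ppm")
  w <- toDa(tol, at = mass)
  m <- index@peptides$neutralMass
  lo <- findInterval(mass - w, m, left.open = TRUE) + 1L
  hi <- findInterval(mass + w, m)
  if (hi < lo) return(index@peptides[0, , drop = FALSE])
  index@peptides[lo:hi, , drop = FALSE]
}
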