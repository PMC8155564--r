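## Candidate scoring, peptide pairing under the precursor-mass constraint,
## and best-CSM selection per spectrum.

.decoyClass <- function(decoyA, decoyB) {
  if (!decoyA && !decoyB) "TT" else if (decoyA && decoyB) "DD" else "TD"
}

.decoyRank <- c(TT = 0L, TD = 1L, DD = 2L)

## score one indexed peptide against a spectrum at its best link position;
## memoised per spectrum through 'cache' (an environment keyed by pepId)
.scorePeptide <- function(pepRow, spectrum, linker, model, ms2Tol,
                          cache = NULL) {
  key <- as.character(pepRow$pepId)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  best <- NULL
  for (lp in pepRow$linkPositions[[1L]]) {
    frags <- theoreticalFragments(pepRow$sequence, lp, linker, model,
                                  mods = pepRow$mods[[1L]])
    if (!nrow(frags)) next
    .bumpCounter("fragmentMatchOps")
    sc <- amandaScore(spectrum, frags, ms2Tol)
    if (is.null(best) || sc[["score"]] > best$amandaScore) {
      best <- list(pepId = pepRow$pepId, sequence = pepRow$sequence,
                   mods = pepRow$mods[[1L]], linkPos = lp,
                   amandaScore = sc[["score"]], matched = sc[["matched"]],
                   nTheoretical = sc[["nTheoretical"]],
                   explainedIntensity = sc[["explainedIntensity"]],
                   neutralMass = pepRow$neutralMass,
                   isDecoy = pepRow$isDecoy,
                   nOccurrences = pepRow$nOccurrences,
                   locations = pepRow$locations[[1L]])
    }
  }
  if (!is.null(cache)) cache[[key]] <- best
  best
}

#' Score candidate peptides for one hypothesized peptide mass
#'
#' Queries the candidate index for peptides whose (fixed/variable modified)
#' neutral mass matches the hypothesized mass -- the stump mass was already
#' subtracted during doublet inference -- scores each candidate at every
#' valid link position keeping the best position, and returns the top-N hits
#' by score.
#'
#' @param index A [CandidateIndex-class].
#' @param peptideMass Hypothesized neutral peptide mass (Da).
#' @param spectrum The [Ms2Spectrum-class] being searched.
#' @param massTol Candidate mass [Tolerance-class] (numeric = ppm).
#' @param topN Number of hits to keep.
#' @param model A [fragmentModel()].
#' @param ms2Tol MS2 fragment-match tolerance.
#' @param cache Optional environment memoising per-peptide scores within one
#'   spectrum.
#' @return List of peptide hits sorted by descending score (length <= topN);
#'   each hit is a list with `pepId`, `sequence`, `mods`, `linkPos`,
#'   `amandaScore`, `matched`, `nTheoretical`, `explainedIntensity`,
#'   `neutralMass`, `isDecoy`, `nOccurrences`, `locations`.
#' @export
searchCandidates <- function(index, peptideMass, spectrum,
                             massTol = tolerance(20, "ppm"), topN = 5L,
                             model = fragmentModel(),
                             ms2Tol = tolerance(10, "ppm"), cache = NULL) {
  cand <- queryIndex(index, peptideMass, massTol)
  if (!nrow(cand)) return(list())
  hits <- vector("list", nrow(cand))
  for (r in seq_len(nrow(cand)))
    hits[[r]] <- .scorePeptide(cand[r, , drop = FALSE], spectrum,
                               indexLinker(index), model, ms2Tol, cache)
  hits <- Filter(Negate(is.null), hits)
  if (!length(hits)) return(list())
  ord <- order(vapply(hits, `[[`, 0, "amandaScore"),
               vapply(hits, `[[`, "", "sequence"), decreasing = c(TRUE, FALSE),
               method = "radix")
  hits[ord][seq_len(min(topN, length(hits)))]
}

## intra iff the two location sets share a protein accession (shared-peptide
## ambiguity resolved conservatively towards intra)
.linkClass <- function(locA, locB) {
  if (length(intersect(locA$accession, locB$accession))) "intra" else "inter"
}

.csmTiebreakKey <- function(csm) {
  ## lexicographic tie-break material, larger-is-better handled by caller
  list(annika = csm$annikaScore,
       sumExplained = csm$explainedAlpha + csm$explainedBeta,
       decoyRank = .decoyRank[[csm$decoyClass]],
       seqs = paste(csm$sequenceAlpha, csm$sequenceBeta))
}

.betterCsm <- function(a, b) {
  ## TRUE if a should be preferred over b
  if (is.null(b)) return(TRUE)
  if (a$annikaScore != b$annikaScore) return(a$annikaScore > b$annikaScore)
  ea <- a$explainedAlpha + a$explainedBeta
  eb <- b$explainedAlpha + b$explainedBeta
  if (ea != eb) return(ea > eb)
  ra <- .decoyRank[[a$decoyClass]]; rb <- .decoyRank[[b$decoyClass]]
  if (ra != rb) return(ra < rb)
  ka <- paste(a$sequenceAlpha, a$sequenceBeta)
  kb <- paste(b$sequenceAlpha, b$sequenceBeta)
  ka < kb
}

#' Combine two hit lists into the best cross-link spectrum match
#'
#' Forms all pairs (a, b) from the two hit lists, keeps those satisfying the
#' precursor mass relation
#' `|mass(a) + mass(b) + intactMass - precursorMass| <= T_D`, scores each
#' pair with the minimum of the two peptide scores, and returns the
#' highest-scoring pair. The higher-scoring peptide becomes alpha. Ties are
#' broken by higher summed explained intensity, then TT over TD over DD,
#' then lexicographically on the sequences. A peptide can be paired with
#' itself only if it occurs at least twice in the database or
#' `allowHomodimers` is set.
#'
#' @param hitsAlpha,hitsBeta Hit lists from [searchCandidates()].
#' @param precursorMass Neutral precursor mass (Da).
#' @param linker A [CrosslinkerSpec-class].
#' @param tD Precursor-relation [Tolerance-class] (numeric = ppm).
#' @param allowHomodimers Allow pairing a single-copy peptide with itself.
#' @return A CSM (list) or `NULL`; see [searchSpectrum()] for fields.
#' @export
combineAndSelect <- function(hitsAlpha, hitsBeta, precursorMass, linker,
                             tD = tolerance(5, "ppm"),
                             allowHomodimers = FALSE) {
  if (is.numeric(tD)) tD <- tolerance(tD, "ppm")
  if (!length(hitsAlpha) || !length(hitsBeta)) return(NULL)
  w <- toDa(tD, at = precursorMass)
  best <- NULL
  for (a in hitsAlpha) {
    for (b in hitsBeta) {
      .bumpCounter("candidatePairOps")
      if (a$pepId == b$pepId && a$nOccurrences < 2L && !allowHomodimers)
        next
      err <- a$neutralMass + b$neutralMass + linker@intactMass - precursorMass
      if (abs(err) > w) next
      if (a$amandaScore >= b$amandaScore) { al <- a; be <- b }
      else { al <- b; be <- a }
      csm <- list(
        sequenceAlpha = al$sequence, sequenceBeta = be$sequence,
        modsAlpha = .modsKey(al$mods), modsBeta = .modsKey(be$mods),
        linkPosAlpha = al$linkPos, linkPosBeta = be$linkPos,
        massAlpha = al$neutralMass, massBeta = be$neutralMass,
        scoreAlpha = al$amandaScore, scoreBeta = be$amandaScore,
        annikaScore = min(al$amandaScore, be$amandaScore),
        matchedAlpha = al$matched, matchedBeta = be$matched,
        explainedAlpha = al$explainedIntensity,
        explainedBeta = be$explainedIntensity,
        decoyAlpha = al$isDecoy, decoyBeta = be$isDecoy,
        decoyClass = .decoyClass(al$isDecoy, be$isDecoy),
        linkClass = .linkClass(al$locations, be$locations),
        precursorErrorPpm = err / precursorMass * 1e6,
        pepIdAlpha = al$pepId, pepIdBeta = be$pepId,
        locationsAlpha = al$locations, locationsBeta = be$locations)
      if (.betterCsm(csm, best)) best <- csm
    }
  }
  best
}

#' Search one spectrum for its best cross-link spectrum match
#'
#' Iterates the alternative precursor hypotheses and, for each, the detector
#' mass-pair hypotheses; candidates for both peptide masses are scored and
#' paired under the precursor constraint; the single best CSM over all
#' hypotheses is returned (one CSM per spectrum).
#'
#' @param spectrum An [Ms2Spectrum-class].
#' @param index A [CandidateIndex-class] over target + decoy peptides.
#' @param mode Detector mode (`"combined"`, `"evidence"`, `"indication"`).
#' @param topN Candidates kept per peptide mass.
#' @param doubletTol,tD,ms2Tol,massTol Tolerances (numeric = ppm): doublet
#'   spacing, precursor relation, MS2 fragment match, candidate mass query.
#'   A ppm `massTol` is evaluated at the precursor mass and applied as an
#'   absolute Da window, because hypothesis masses carry the absolute error
#'   of the doublet peaks they derive from (an inferred partner inherits
#'   the other peptide's error).
#' @param maxIsotopeOffsets Isotope offsets for alternative precursors.
#' @param minPeptideMass Minimum peptide mass (Da).
#' @param model A [fragmentModel()].
#' @param allowHomodimers See [combineAndSelect()].
#' @param requireDiagnostic See [detect()].
#' @return One-row data.frame (the CSM) or `NULL` if the spectrum has no
#'   doublet hypothesis or no pair satisfies the constraints. Columns
#'   include the two sequences, link positions, scores, `annikaScore`,
#'   `decoyClass`, `linkClass`, `mode`, `isotopeOffset`,
#'   `precursorErrorPpm`, and list columns `locationsAlpha`/`locationsBeta`.
#' @export
searchSpectrum <- function(spectrum, index,
                           mode = c("combined", "evidence", "indication"),
                           topN = 5L,
                           doubletTol = tolerance(10, "ppm"),
                           tD = tolerance(5, "ppm"),
                           ms2Tol = tolerance(10, "ppm"),
                           massTol = tolerance(20, "ppm"),
                           maxIsotopeOffsets = 2L, minPeptideMass = 300,
                           model = fragmentModel(),
                           allowHomodimers = FALSE,
                           requireDiagnostic = FALSE) {
  mode <- match.arg(mode)
  linker <- indexLinker(index)
  charges <- if (is.na(precursorCharge(spectrum))) 2:6 else
    precursorCharge(spectrum)
  cache <- new.env(parent = emptyenv())
  best <- NULL
  bestMeta <- NULL
  for (z in charges) {
    hyps <- precursorHypotheses(spectrum, maxIsotopeOffsets, "assumed",
                                charge = z)
    chargeRange <- seq_len(max(1L, z - 1L))
    dbl <- findDoublets(spectrum, linker, chargeRange, doubletTol)
    for (h in seq_len(nrow(hyps))) {
      massP <- hyps$neutralMass[h]
      pairs <- detect(spectrum, linker, mode, precursorMass = massP,
                      doubletTol = doubletTol, tD = tD, peakTol = ms2Tol,
                      chargeRange = chargeRange,
                      minPeptideMass = minPeptideMass,
                      requireDiagnostic = requireDiagnostic, doublets = dbl)
      ## hypothesis masses inherit the absolute (Da) error of the doublet
      ## peaks they came from -- and an inferred partner inherits the error
      ## of the *other* peptide's doublet -- so the candidate window is a
      ## ppm tolerance evaluated at the precursor-mass scale, applied in Da
      queryTol <- if (is.numeric(massTol)) tolerance(massTol, "ppm") else
        massTol
      if (queryTol@unit == "ppm")
        queryTol <- tolerance(toDa(queryTol, at = massP), "Da")
      for (r in seq_len(nrow(pairs))) {
        hitsA <- searchCandidates(index, pairs$massAlpha[r], spectrum,
                                  queryTol, topN, model, ms2Tol, cache)
        hitsB <- searchCandidates(index, pairs$massBeta[r], spectrum,
                                  queryTol, topN, model, ms2Tol, cache)
        csm <- combineAndSelect(hitsA, hitsB, massP, linker, tD,
                                allowHomodimers)
        if (!is.null(csm) && .betterCsm(csm, best)) {
          best <- csm
          bestMeta <- list(mode = pairs$mode[r],
                           completeness = pairs$completeness[r],
                           isotopeOffset = hyps$isotopeOffset[h],
                           charge = z)
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  .csmAsDataFrame(best, spectrum, bestMeta)
}

.csmAsDataFrame <- function(csm, spectrum, meta) {
  df <- data.frame(
    scanId = scanId(spectrum), charge = meta$charge,
    sequenceAlpha = csm$sequenceAlpha, sequenceBeta = csm$sequenceBeta,
    modsAlpha = csm$modsAlpha, modsBeta = csm$modsBeta,
    linkPosAlpha = csm$linkPosAlpha, linkPosBeta = csm$linkPosBeta,
    massAlpha = csm$massAlpha, massBeta = csm$massBeta,
    scoreAlpha = csm$scoreAlpha, scoreBeta = csm$scoreBeta,
    annikaScore = csm$annikaScore,
    matchedAlpha = csm$matchedAlpha, matchedBeta = csm$matchedBeta,
    explainedAlpha = csm$explainedAlpha, explainedBeta = csm$explainedBeta,
    decoyAlpha = csm$decoyAlpha, decoyBeta = csm$decoyBeta,
    decoyClass = csm$decoyClass, linkClass = csm$linkClass,
    mode = meta$mode, completeness = meta$completeness,
    isotopeOffset = meta$isotopeOffset,
    precursorErrorPpm = csm$precursorErrorPpm,
    stringsAsFactors = FALSE)
  df$locationsAlpha <- list(csm$locationsAlpha)
  df$locationsBeta <- list(csm$locationsBeta)
  df
}

.emptyCsmFrame <- function() {
  df <- data.frame(
    scanId = character(), charge = integer(),
    sequenceAlpha = character(), sequenceBeta = character(),
    modsAlpha = character(), modsBeta = character(),
    linkPosAlpha = integer(), linkPosBeta = integer(),
    massAlpha = numeric(), massBeta = numeric(),
    scoreAlpha = numeric(), scoreBeta = numeric(),
    annikaScore = numeric(),
    matchedAlpha = numeric(), matchedBeta = numeric(),
    explainedAlpha = numeric(), explainedBeta = numeric(),
    decoyAlpha = logical(), decoyBeta = logical(),
    decoyClass = character(), linkClass = character(),
    mode = character(), completeness = character(),
    isotopeOffset = integer(), precursorErrorPpm = numeric(),
    stringsAsFactors = FALSE)
  df$locationsAlpha <- list()
  df$locationsBeta <- list()
  df
}

#' Search a list of spectra
#'
#' Applies [searchSpectrum()] to each spectrum (optionally in parallel;
#' spectra are independent, so results do not depend on the worker count)
#' and row-binds the per-spectrum best CSMs into one table sorted by
#' descending score.
#'
#' @param spectra List of [Ms2Spectrum-class] objects.
#' @param index A [CandidateIndex-class].
#' @param ... Passed to [searchSpectrum()].
#' @param threads Worker processes (forked; 1 = serial).
#' @return CSM data.frame (zero rows if nothing was identified).
#' @export
searchSpectra <- function(spectra, index, ..., threads = 1L) {
  run <- function(sp) searchSpectrum(sp, index, ...)
  res <- if (threads > 1L)
    parallel::mclapply(spectra, run, mc.cores = threads)
  else lapply(spectra, run)
  res <- Filter(Negate(is.null), res)
  if (!length(res)) return(.emptyCsmFrame())
  out <- do.call(rbind, res)
  out <- out[order(-out$annikaScore, out$sequenceAlpha, out$sequenceBeta), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
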