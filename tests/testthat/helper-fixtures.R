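## Shared fixtures and the independent exhaustive-search oracle.

PROTON <- 1.007276

spec <- function(mz, intensity = rep(100, length(mz)), precMz = 1000,
                 z = 3L, id = "s") {
  ms2Spectrum(id, precMz, z, cbind(mz, intensity))
}

## canonical unordered residue-pair key (re-derived here, independent of the
## package internals)
pairKey <- function(pa, xa, pb, xb) {
  a <- paste0(pa, ":", xa)
  b <- paste0(pb, ":", xb)
  ifelse(a <= b, paste(a, b, sep = "--"), paste(b, a, sep = "--"))
}

truthKeys <- function(truth) {
  unique(pairKey(truth$proteinA, truth$absPosA, truth$proteinB,
                 truth$absPosB))
}

crosslinkKeys <- function(xl) {
  pairKey(xl$proteinA, xl$positionA, xl$proteinB, xl$positionB)
}

## small simulated world shared by several tests
simWorld <- function(seed, nProteins = 6, proteinLength = 150, nSpectra = 30,
                     ...) {
  p <- simulationParams(seed = seed, nProteins = nProteins,
                        proteinLength = proteinLength, nSpectra = nSpectra,
                        entrapmentFactor = 0, ...)
  db <- generateDatabase(p)
  g <- generateSpectra(db, p)
  index <- buildCandidateIndex(
    digestDatabase(c(db$targets, makeDecoyDatabase(db$targets)),
                   p$digestion),
    p$linker)
  list(params = p, db = db, spectra = g$spectra, truth = g$truth,
       index = index)
}

## TRUE when at least one planted doublet survived the m/z jitter and is
## detectable at the doublet tolerance -- the population on which the
## doublet-driven search can be compared to the exhaustive oracle
doubletsPresent <- function(sp, tr) {
  d <- findDoublets(sp, dssoLinker(),
                    seq_len(max(1L, precursorCharge(sp) - 1L)))
  any(abs(d$peptideNeutralMass - tr$massA) <= 20e-6 * tr$massA) ||
    any(abs(d$peptideNeutralMass - tr$massB) <= 20e-6 * tr$massB)
}

## Independent oracle: exhaustive all-pairs search. Ignores doublets
## entirely; enumerates every peptide pair in the index, honours only the
## precursor mass relation (over the same isotope-offset hypotheses), scores
## with the same per-peptide score, and applies the same tie-breaks.
exhaustiveSearch <- function(spectrum, index, tDppm = 5, ms2TolPpm = 10,
                             maxOffsets = 2L, allowHomodimers = FALSE) {
  peps <- index@peptides
  linker <- indexLinker(index)
  n <- nrow(peps)
  scores <- vector("list", n)
  for (i in seq_len(n)) {
    best <- NULL
    for (lp in peps$linkPositions[[i]]) {
      fr <- theoreticalFragments(peps$sequence[i], lp, linker,
                                 mods = peps$mods[[i]])
      sc <- amandaScore(spectrum, fr, tolerance(ms2TolPpm, "ppm"))
      if (is.null(best) || sc[["score"]] > best$score)
        best <- list(score = sc[["score"]], lp = lp,
                     explained = sc[["explainedIntensity"]])
    }
    scores[[i]] <- best
  }
  decoyRank <- c(TT = 0L, TD = 1L, DD = 2L)
  z <- precursorCharge(spectrum)
  best <- NULL
  for (off in 0:(-maxOffsets)) {
    massP <- precursorNeutralMass(spectrum) + off * 1.0033548
    w <- tDppm * 1e-6 * massP
    for (i in seq_len(n)) {
      for (j in i:n) {
        if (i == j && peps$nOccurrences[i] < 2L && !allowHomodimers) next
        err <- peps$neutralMass[i] + peps$neutralMass[j] +
          intactMass(linker) - massP
        if (abs(err) > w) next
        si <- scores[[i]]; sj <- scores[[j]]
        if (si$score >= sj$score) { al <- i; be <- j; sal <- si; sbe <- sj }
        else { al <- j; be <- i; sal <- sj; sbe <- si }
        dc <- classifyCsm(peps$isDecoy[al], peps$isDecoy[be])
        cand <- list(annika = min(si$score, sj$score),
                     sumExplained = si$explained + sj$explained,
                     decoyRank = decoyRank[[dc]],
                     seqA = peps$sequence[al], seqB = peps$sequence[be],
                     lpA = sal$lp, lpB = sbe$lp,
                     pepA = peps$pepId[al], pepB = peps$pepId[be])
        better <- if (is.null(best)) TRUE
          else if (cand$annika != best$annika) cand$annika > best$annika
          else if (cand$sumExplained != best$sumExplained)
            cand$sumExplained > best$sumExplained
          else if (cand$decoyRank != best$decoyRank)
            cand$decoyRank < best$decoyRank
          else paste(cand$seqA, cand$seqB) < paste(best$seqA, best$seqB)
        if (better) best <- cand
      }
    }
  }
  best
}
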