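## Synthetic cross-link data generator: FASTA databases, MS2 spectra with
## planted stump doublets and fragment ladders, and ground-truth tables.

#' Simulation parameters
#'
#' Defines the conditions the generator emulates: a small protein database
#' with lysine-rich sequences (so tryptic peptides carry linkable sites),
#' stepped-collision-energy-like MS2 spectra containing the stump-ion
#' doublets of both peptides plus partial b/y ladders with light/heavy stump
#' variants, log-normal peak intensities, uniform noise peaks, Gaussian ppm
#' mass error on planted peaks, and occasional +1-isotope precursor
#' misassignment.
#'
#' @param seed Integer seed fixing the full output byte-for-byte.
#' @param nProteins Number of target proteins.
#' @param proteinLength Residues per protein.
#' @param nSpectra Number of MS2 spectra to generate.
#' @param linker A [CrosslinkerSpec-class].
#' @param coverage Fraction of theoretical fragment ions planted, in [0, 1].
#' @param doubletProb Probability that a peptide's stump doublet (both light
#'   and heavy peaks) is planted, per peptide.
#' @param noisePeaks Mean of the Poisson noise-peak count.
#' @param intensityMeanlog,intensitySdlog Log-normal intensity parameters
#'   (arbitrary units), shared by signal and noise peaks.
#' @param ppmError Standard deviation of the Gaussian m/z error applied to
#'   planted peaks (ppm).
#' @param chargeProbs Named numeric vector of precursor charge
#'   probabilities; cross-linked precursors are predominantly 3+ and higher.
#' @param isotopeErrorProb Probability that the recorded precursor is the
#'   first isotope (+1 C13) instead of the monoisotopic peak.
#' @param entrapmentFactor Entrapment database size as a multiple of the
#'   target database.
#' @param digestion [digestionParams()] used for peptide sampling (variable
#'   modifications are not planted; fixed modifications are).
#' @return List of class `SimulationParams`.
#' @export
simulationParams <- function(seed = 1L, nProteins = 20L, proteinLength = 300L,
                             nSpectra = 500L, linker = dssoLinker(),
                             coverage = 0.7, doubletProb = 0.9,
                             noisePeaks = 50, intensityMeanlog = 10,
                             intensitySdlog = 1, ppmError = 5,
                             chargeProbs = c(`3` = 0.5, `4` = 0.35,
                                             `5` = 0.15),
                             isotopeErrorProb = 0.05,
                             entrapmentFactor = 4,
                             digestion = digestionParams()) {
  if (is.character(linker))
    linker <- switch(toupper(linker), DSSO = dssoLinker(),
                     DSBU = dsbuLinker(),
                     stop("unknown linker preset: ", linker))
  stopifnot(is(linker, "CrosslinkerSpec"),
            coverage >= 0, coverage <= 1, doubletProb >= 0, doubletProb <= 1,
            isotopeErrorProb >= 0, isotopeErrorProb <= 1,
            abs(sum(chargeProbs) - 1) < 1e-9)
  structure(as.list(environment()), class = "SimulationParams")
}

## lysine-boosted residue alphabet; no C/M so planted peptides carry no
## variable modifications and fixed-mod bookkeeping stays out of the truth
.simAlphabet <- function() {
  aa <- c("A", "D", "E", "F", "G", "H", "I", "K", "L", "N", "P", "Q", "R",
          "S", "T", "V", "W", "Y")
  prob <- rep(1, length(aa))
  prob[aa == "K"] <- 3.0   # boosted: linkable sites in most tryptic peptides
  prob[aa == "R"] <- 1.5
  prob[aa == "P"] <- 0.5
  list(aa = aa, prob = prob / sum(prob))
}

## sample one element (safe for length-1 vectors)
.sample1 <- function(x) x[sample.int(length(x), 1L)]

.randomProtein <- function(length, alphabet) {
  paste(sample(alphabet$aa, length, replace = TRUE, prob = alphabet$prob),
        collapse = "")
}

.trypticSet <- function(sequence, minLength) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  ends <- .trypticEnds(aa)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  peps <- substring(sequence, starts, ends)
  unique(peps[nchar(peps) >= minLength])
}

#' Generate target and entrapment protein databases
#'
#' Targets are random proteins over a lysine-boosted alphabet. Entrapment
#' proteins are residue-shuffled copies of the targets, re-shuffled until
#' their tryptic peptides (at or above the digestion minimum length) are
#' disjoint from the target tryptic peptide space.
#'
#' @param params A [simulationParams()].
#' @param targetPath,entrapmentPath Optional FASTA output paths.
#' @return List with named character vectors `targets` (accessions
#'   `SIM_Txxx`) and `entrapment` (`SIM_Exxx`,
#'   `entrapmentFactor * nProteins` sequences).
#' @export
generateDatabase <- function(params = simulationParams(),
                             targetPath = NULL, entrapmentPath = NULL) {
  set.seed(params$seed)
  alphabet <- .simAlphabet()
  n <- params$nProteins
  targets <- character(n)
  if (n > 0)
    targets <- vapply(seq_len(n), function(i)
      .randomProtein(params$proteinLength, alphabet), "")
  names(targets) <- sprintf("SIM_T%03d", seq_len(n))
  minLen <- params$digestion$minLength
  targetPeps <- unique(unlist(lapply(targets, .trypticSet, minLen)))
  nEntrap <- round(params$entrapmentFactor * n)
  entrap <- character(nEntrap)
  if (nEntrap > 0) {
    for (i in seq_len(nEntrap)) {
      src <- strsplit(targets[[((i - 1L) %% max(n, 1L)) + 1L]], "",
                      fixed = TRUE)[[1L]]
      for (try in 1:50) {
        cand <- paste(sample(src), collapse = "")
        if (!length(intersect(.trypticSet(cand, minLen), targetPeps))) break
      }
      entrap[i] <- cand
    }
  }
  names(entrap) <- sprintf("SIM_E%03d", seq_len(nEntrap))
  if (!is.null(targetPath)) writeFasta(targets, targetPath)
  if (!is.null(entrapmentPath) && nEntrap > 0)
    writeFasta(entrap, entrapmentPath)
  list(targets = targets, entrapment = entrap)
}

## digest targets for planting: fixed mods only, linkable peptides only
.plantablePeptides <- function(targets, params) {
  dp <- params$digestion
  dp$variableModifications <- NULL
  peps <- digestDatabase(targets, dp)
  if (!nrow(peps)) return(peps)
  lp <- lapply(seq_len(nrow(peps)), function(i)
    linkPositions(peps$sequence[i], params$linker,
                  ctermProtein = peps$ctermProtein[i],
                  ntermProtein = peps$start[i] == 1L))
  peps$linkPositions <- lp
  peps <- peps[lengths(lp) > 0L, , drop = FALSE]
  ## plant only peptides with a unique database location so the ground-truth
  ## residue pair is well defined
  tab <- table(peps$sequence)
  peps[peps$sequence %in% names(tab)[tab == 1L], , drop = FALSE]
}

#' Generate synthetic cross-linked MS2 spectra with ground truth
#'
#' For each spectrum two linkable tryptic peptides are sampled from the
#' target database; the precursor is computed exactly from the mass
#' relation `mA + mB + intactMass`; both stump doublet peaks are planted
#' per peptide with probability `doubletProb`; a `coverage` fraction of the
#' theoretical b/y fragment groups is planted (site-containing fragments as
#' light and/or heavy stump variants); Poisson-many noise peaks are drawn
#' uniformly in m/z; planted peak m/z values receive Gaussian ppm error;
#' with probability `isotopeErrorProb` the recorded precursor is shifted to
#' the first isotope.
#'
#' @param database Output of [generateDatabase()] (or a list with element
#'   `targets`).
#' @param params A [simulationParams()].
#' @param mgfPath Optional MGF output path.
#' @param truthPath Optional ground-truth TSV output path.
#' @return List with `spectra` (list of [Ms2Spectrum-class]) and `truth`
#'   (data.frame: `scanId`, `sequenceA`, `sequenceB`, `proteinA`,
#'   `proteinB`, `startA`, `startB`, `linkPosA`, `linkPosB`, `absPosA`,
#'   `absPosB`, `massA`, `massB`, `charge`, `doubletA`, `doubletB`,
#'   `isotopeShift`, `precursorMz`).
#' @export
generateSpectra <- function(database, params = simulationParams(),
                            mgfPath = NULL, truthPath = NULL) {
  set.seed(params$seed + 7919L)   # decoupled from database generation
  peps <- .plantablePeptides(database$targets, params)
  if (nrow(peps) < 2L) stop("database yields fewer than two linkable peptides")
  linker <- params$linker
  proton <- xlmsConstants[["proton"]]
  nS <- params$nSpectra
  spectra <- vector("list", nS)
  truth <- vector("list", nS)
  model <- fragmentModel(charges = 1L)
  for (s in seq_len(nS)) {
    ix <- sample(nrow(peps), 2L, replace = FALSE)
    rowA <- peps[ix[1L], ]; rowB <- peps[ix[2L], ]
    lpA <- .sample1(rowA$linkPositions[[1L]])
    lpB <- .sample1(rowB$linkPositions[[1L]])
    mA <- rowA$neutralMass; mB <- rowB$neutralMass
    M <- mA + mB + linker@intactMass
    z <- as.integer(sample(names(params$chargeProbs), 1L,
                           prob = params$chargeProbs))
    isoShift <- stats::rbinom(1L, 1L, params$isotopeErrorProb)
    precMz <- neutralToMz(M + isoShift * xlmsConstants[["c13"]], z)
    mzs <- numeric()
    dblA <- stats::runif(1) < params$doubletProb
    dblB <- stats::runif(1) < params$doubletProb
    for (pp in list(list(m = mA, on = dblA), list(m = mB, on = dblB))) {
      if (!pp$on) next
      zd <- if (z > 2L) sample(1:2, 1L, prob = c(0.7, 0.3)) else 1L
      mzs <- c(mzs, (pp$m + linker@lightMass + zd * proton) / zd,
                    (pp$m + linker@heavyMass + zd * proton) / zd)
    }
    for (pp in list(list(row = rowA, lp = lpA), list(row = rowB, lp = lpB))) {
      fr <- theoreticalFragments(pp$row$sequence, pp$lp, linker, model,
                                 mods = pp$row$mods[[1L]])
      if (!nrow(fr)) next
      ## each theoretical ion (stump variants are separate ions) is planted
      ## independently with probability 'coverage'
      keep <- stats::runif(nrow(fr)) < params$coverage
      mzs <- c(mzs, fr$mz[keep])
    }
    if (params$ppmError > 0 && length(mzs))
      mzs <- mzs * (1 + stats::rnorm(length(mzs), 0,
                                     params$ppmError * 1e-6))
    nNoise <- stats::rpois(1L, params$noisePeaks)
    if (nNoise > 0)
      mzs <- c(mzs, stats::runif(nNoise, 100, precMz))
    ints <- stats::rlnorm(length(mzs), params$intensityMeanlog,
                          params$intensitySdlog)
    id <- sprintf("sim_%05d", s)
    spectra[[s]] <- ms2Spectrum(id, precMz, z, cbind(mzs, ints))
    truth[[s]] <- data.frame(
      scanId = id,
      sequenceA = rowA$sequence, sequenceB = rowB$sequence,
      proteinA = rowA$accession, proteinB = rowB$accession,
      startA = rowA$start, startB = rowB$start,
      linkPosA = lpA, linkPosB = lpB,
      absPosA = rowA$start + lpA - 1L, absPosB = rowB$start + lpB - 1L,
      massA = mA, massB = mB, charge = z,
      doubletA = dblA, doubletB = dblB,
      isotopeShift = isoShift, precursorMz = precMz,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  if (is.null(truth))
    truth <- data.frame(scanId = character())
  if (!is.null(mgfPath)) writeMgf(spectra, mgfPath)
  if (!is.null(truthPath))
    utils::write.table(truth, truthPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  list(spectra = spectra, truth = truth)
}

#' Unique planted residue pairs of a ground-truth table
#'
#' @param truth Truth data.frame from [generateSpectra()].
#' @return Character vector of canonical unordered residue-pair keys
#'   (`"prot:pos--prot:pos"`).
#' @export
truthResiduePairs <- function(truth) {
  if (!nrow(truth)) return(character())
  unique(.residuePairKey(truth$proteinA, truth$absPosA,
                         truth$proteinB, truth$absPosB))
}
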