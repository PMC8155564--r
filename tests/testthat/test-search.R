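lk <- dssoLinker()

test_that("theoretical fragments enumerate stump variants at the link site", {
  fr <- theoreticalFragments("ACK", 3, lk, fragmentModel(charges = 1))
  expect_equal(nrow(fr), 6L)
  expect_setequal(fr$ion[fr$variant == ""], c("b1", "b2"))
  expect_setequal(paste(fr$ion, fr$variant)[fr$variant != ""],
                  c("y1 light", "y1 heavy", "y2 light", "y2 heavy"))
  # light and heavy variant of one fragment differ by exactly heavy - light
  y1 <- fr[fr$ion == "y1", ]
  expect_equal(y1$mz[y1$variant == "heavy"] - y1$mz[y1$variant == "light"],
               doubletDelta(lk), tolerance = 1e-9)
  # b2 must carry the carbamidomethyl shift when C is modified
  frMod <- theoreticalFragments("ACK", 3, lk, fragmentModel(charges = 1),
                                mods = c(`2` = 57.02146374))
  expect_equal(frMod$mz[frMod$ion == "b2"] - fr$mz[fr$ion == "b2"],
               57.02146374, tolerance = 1e-9)
  # single-residue peptide has no internal ions
  expect_equal(nrow(theoreticalFragments("K", 1, lk)), 0L)
  expect_error(theoreticalFragments("ACK", 5, lk), "link position")
})

test_that("fragment m/z values agree with manual prefix-sum arithmetic", {
  fr <- theoreticalFragments("ACDK", 4, lk, fragmentModel(charges = 1))
  rm <- residueMasses()
  expect_equal(fr$mz[fr$ion == "b1"], rm[["A"]] + PROTON, tolerance = 1e-9)
  expect_equal(fr$mz[fr$ion == "b3"], rm[["A"]] + rm[["C"]] + rm[["D"]] +
                 PROTON, tolerance = 1e-9)
  y2light <- rm[["D"]] + rm[["K"]] + xlmsConstants[["water"]] +
    lightMass(lk) + PROTON
  expect_equal(fr$mz[fr$ion == "y2" & fr$variant == "light"], y2light,
               tolerance = 1e-9)
})

test_that("binomial score has the closed-form value at k = n", {
  # n = 10, k = 10, p = 0.01, full explained intensity -> exactly 20
  mz <- seq(200, 290, 10)
  sp <- spec(mz, rep(5, 10))
  # p = nPeaks * 2 * tolDa / range = 10 * 2 * tolDa / 90 = 0.01
  tolDa <- 0.01 * 90 / 20
  fr <- data.frame(mz = mz, ion = paste0("b", 1:10), charge = 1,
                   variant = "", group = paste0("b", 1:10))
  sc <- amandaScore(sp, fr, tolerance(tolDa, "Da"))
  expect_equal(unname(sc["matched"]), 10)
  expect_equal(unname(sc["explainedIntensity"]), 1.0)
  expect_equal(unname(sc["score"]), 20.0, tolerance = 1e-9)
})

test_that("binomial tail matches an independent term-summation oracle", {
  binomTail <- function(k, n, p) {
    # explicit summation of binomial terms, no distribution call
    sum(vapply(k:n, function(i)
      choose(n, i) * p^i * (1 - p)^(n - i), 0))
  }
  set.seed(13)
  for (rep in 1:50) {
    n <- sample(5:40, 1)
    k <- sample(0:n, 1)
    p <- runif(1, 1e-4, 0.5)
    got <- pbinom(k - 1, n, p, lower.tail = FALSE)
    expect_equal(got, binomTail(max(k, 0), n, p), tolerance = 1e-9)
  }
  # zero matches -> probability 1 -> score 0
  sp <- spec(c(100, 200))
  fr <- data.frame(mz = c(900, 950), ion = c("b1", "b2"), charge = 1,
                   variant = "", group = c("b1", "b2"))
  expect_equal(unname(amandaScore(sp, fr)["score"]), 0)
})

test_that("amanda score is reproduced by direct recomputation on real fragments", {
  w <- simWorld(41, nSpectra = 5)
  sp <- w$spectra[[1]]
  peps <- w$index@peptides
  row <- peps[which.max(peps$neutralMass), ]
  fr <- theoreticalFragments(row$sequence, row$linkPositions[[1]][1], lk,
                             mods = row$mods[[1]])
  sc <- amandaScore(sp, fr, tolerance(10, "ppm"))
  p <- peaks(sp)
  # independent recomputation: match each fragment by linear scan
  matchedPeaks <- integer(); matchedGroups <- character()
  for (r in seq_len(nrow(fr))) {
    w0 <- 10e-6 * fr$mz[r]
    d <- abs(p[, 1] - fr$mz[r])
    if (min(d) <= w0) {
      ok <- which(d <= w0)
      bestIx <- ok[order(d[ok], -p[ok, 2])][1]
      matchedPeaks <- c(matchedPeaks, bestIx)
      matchedGroups <- c(matchedGroups, fr$group[r])
    }
  }
  k <- length(unique(matchedGroups))
  expect_equal(unname(sc["matched"]), k)
  rng <- max(p[, 1]) - min(p[, 1])
  pm <- min(max(nrow(p) * 2 * (10e-6 * (max(p[, 1]) + min(p[, 1])) / 2) / rng,
                1e-6), 0.5)
  expl <- sum(p[unique(matchedPeaks), 2]) / sum(p[, 2])
  want <- max(0, -log10(pbinom(k - 1, nrow(fr), pm, lower.tail = FALSE)) *
                expl)
  expect_equal(unname(sc["score"]), want, tolerance = 1e-12)
})

test_that("adding far-away noise peaks never increases the score of a fixed match set", {
  mz <- seq(200, 290, 10)
  sp0 <- spec(mz, rep(5, 10))
  fr <- data.frame(mz = mz, ion = paste0("b", 1:10), charge = 1,
                   variant = "", group = paste0("b", 1:10))
  scores <- vapply(c(0, 5, 20, 80), function(nNoise) {
    noise <- if (nNoise > 0) seq(1000, 1500, length.out = nNoise) else
      numeric(0)
    sp <- spec(sort(c(mz, noise)), c(rep(5, 10), rep(3, nNoise)))
    unname(amandaScore(sp, fr, tolerance(10, "ppm"))["score"])
  }, 0)
  expect_true(all(diff(scores) <= 1e-12))
})

test_that("searchCandidates scores every link position and keeps the best, truncated to topN", {
  w <- simWorld(43, nSpectra = 10, coverage = 1, noisePeaks = 0,
                ppmError = 0, doubletProb = 1, isotopeErrorProb = 0)
  tr <- w$truth[1, ]
  sp <- w$spectra[[1]]
  hits <- searchCandidates(w$index, tr$massA, sp, tolerance(10, "ppm"),
                           topN = 5)
  expect_true(length(hits) >= 1)
  expect_equal(hits[[1]]$sequence, tr$sequenceA)
  expect_equal(hits[[1]]$linkPos, tr$linkPosA)
  scores <- vapply(hits, `[[`, 0, "amandaScore")
  expect_true(all(diff(scores) <= 0))
  expect_lte(length(searchCandidates(w$index, tr$massA, sp,
                                     tolerance(10, "ppm"), topN = 1)), 1L)
})

test_that("the AnnikaScore is the minimum of the two peptide scores and pairing is symmetric", {
  w <- simWorld(45, nSpectra = 10, coverage = 1, noisePeaks = 0,
                ppmError = 0, doubletProb = 1, isotopeErrorProb = 0)
  tr <- w$truth[2, ]
  sp <- w$spectra[[2]]
  massP <- precursorNeutralMass(sp)
  hitsA <- searchCandidates(w$index, tr$massA, sp, tolerance(10, "ppm"))
  hitsB <- searchCandidates(w$index, tr$massB, sp, tolerance(10, "ppm"))
  csm <- combineAndSelect(hitsA, hitsB, massP, lk, tolerance(5, "ppm"))
  expect_equal(csm$annikaScore, min(csm$scoreAlpha, csm$scoreBeta))
  expect_gte(csm$scoreAlpha, csm$scoreBeta)
  # swapping hit lists yields the same CSM
  csm2 <- combineAndSelect(hitsB, hitsA, massP, lk, tolerance(5, "ppm"))
  expect_equal(csm2$sequenceAlpha, csm$sequenceAlpha)
  expect_equal(csm2$sequenceBeta, csm$sequenceBeta)
  expect_equal(csm2$annikaScore, csm$annikaScore)
})

test_that("pairs violating the precursor relation are excluded even with maximal scores", {
  hit <- function(seq, mass, score) {
    list(pepId = abs(round(mass)), sequence = seq, mods = NULL, linkPos = 1L,
         amandaScore = score, matched = 5, nTheoretical = 10,
         explainedIntensity = 0.5, neutralMass = mass, isDecoy = FALSE,
         nOccurrences = 1L,
         locations = data.frame(accession = "P", start = 1L))
  }
  a <- hit("AAKA", 1000, 100)
  b <- hit("CCKC", 1400, 100)   # sum violates the relation below
  expect_null(combineAndSelect(list(a), list(b),
                               1000 + 1500 + intactMass(lk), lk,
                               tolerance(5, "ppm")))
  c <- hit("DDKD", 1500, 10)
  csm <- combineAndSelect(list(a, b), list(c),
                          1000 + 1500 + intactMass(lk), lk,
                          tolerance(5, "ppm"))
  expect_equal(csm$sequenceAlpha, "AAKA")
})

test_that("self-pairing requires multiple occurrences or the homodimer flag", {
  single <- list(pepId = 1L, sequence = "AAKA", mods = NULL, linkPos = 3L,
                 amandaScore = 50, matched = 5, nTheoretical = 10,
                 explainedIntensity = 0.5, neutralMass = 1000,
                 isDecoy = FALSE, nOccurrences = 1L,
                 locations = data.frame(accession = "P", start = 1L))
  massP <- 2 * 1000 + intactMass(lk)
  expect_null(combineAndSelect(list(single), list(single), massP, lk,
                               tolerance(5, "ppm")))
  expect_false(is.null(combineAndSelect(list(single), list(single), massP,
                                        lk, tolerance(5, "ppm"),
                                        allowHomodimers = TRUE)))
  multi <- single; multi$nOccurrences <- 2L
  expect_false(is.null(combineAndSelect(list(multi), list(multi), massP, lk,
                                        tolerance(5, "ppm"))))
})

test_that("clean planted spectra are recovered end-to-end by searchSpectrum", {
  w <- simWorld(47, nSpectra = 15, coverage = 1, noisePeaks = 0,
                ppmError = 0, doubletProb = 1, isotopeErrorProb = 0)
  for (i in seq_along(w$spectra)) {
    csm <- searchSpectrum(w$spectra[[i]], w$index)
    tr <- w$truth[i, ]
    expect_false(is.null(csm))
    expect_setequal(c(csm$sequenceAlpha, csm$sequenceBeta),
                    c(tr$sequenceA, tr$sequenceB))
    expect_equal(csm$decoyClass, "TT")
  }
})

test_that("doublet-driven search equals the exhaustive all-pairs oracle", {
  w <- simWorld(49, nProteins = 2, proteinLength = 100, nSpectra = 20,
                doubletProb = 1,
                digestion = digestionParams(missedCleavages = 1))
  expect_lte(sum(!w$index@peptides$isDecoy), 50)
  agree <- 0L; total <- 0L
  for (i in seq_along(w$spectra)) {
    # compare only where a planted doublet survived the jitter: without one
    # the doublet-driven search has no input by design
    if (!doubletsPresent(w$spectra[[i]], w$truth[i, ])) next
    total <- total + 1L
    csm <- searchSpectrum(w$spectra[[i]], w$index)
    oracle <- exhaustiveSearch(w$spectra[[i]], w$index)
    if (is.null(csm) && is.null(oracle)) { agree <- agree + 1L; next }
    if (!is.null(csm) && !is.null(oracle) &&
        csm$sequenceAlpha == oracle$seqA && csm$sequenceBeta == oracle$seqB &&
        abs(csm$annikaScore - oracle$annika) < 1e-9)
      agree <- agree + 1L
  }
  expect_gte(total, 15L)
  expect_gte(agree / total, 0.99)
})

test_that("searchSpectra output is independent of the thread count", {
  w <- simWorld(51, nSpectra = 8)
  r1 <- searchSpectra(w$spectra, w$index, threads = 1)
  r2 <- searchSpectra(w$spectra, w$index, threads = 2)
  expect_equal(r1, r2)
})

test_that("spectra without hypotheses yield no CSM", {
  sp <- spec(c(300, 400, 500), precMz = 900, z = 3)
  w <- simWorld(53, nSpectra = 2)
  expect_null(searchSpectrum(sp, w$index))
})
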