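lk <- dssoLinker()

test_that("findDoublets infers the planted peptide mass from stump pairs", {
  # M = 1000 Da with DSSO stumps at z = 1
  sp1 <- spec(c(1055.017846, 1105.000476), precMz = 900, z = 4)
  d1 <- findDoublets(sp1, lk, chargeRange = 1)
  expect_equal(nrow(d1), 1L)
  expect_equal(d1$peptideNeutralMass, 1000, tolerance = 1e-4)
  expect_equal(d1$charge, 1L)
  # same peptide at z = 2
  sp2 <- spec(c(528.012561, 553.003876), precMz = 900, z = 4)
  d2 <- findDoublets(sp2, lk, chargeRange = 1:3)
  expect_true(any(abs(d2$peptideNeutralMass - 1000) < 1e-4 & d2$charge == 2L))
  # empty spectrum
  expect_equal(nrow(findDoublets(spec(numeric(0), numeric(0)), lk, 1:3)), 0L)
})

test_that("doublet inference recovers masses at charges 1-4 within 1e-4 Da", {
  for (linker in list(dssoLinker(), dsbuLinker())) {
    for (z in 1:4) {
      for (M in c(800.123, 1500.5, 2404.789)) {
        mzL <- (M + lightMass(linker) + z * PROTON) / z
        mzH <- (M + heavyMass(linker) + z * PROTON) / z
        d <- findDoublets(spec(sort(c(mzL, mzH)), precMz = 1200, z = 5),
                          linker, chargeRange = 1:4)
        hit <- d[abs(d$peptideNeutralMass - M) < 1e-4 & d$charge == z, ]
        expect_equal(nrow(hit), 1L)
      }
    }
  }
})

test_that("full doublets carry complementary light/heavy mass estimates", {
  w <- simWorld(31, nSpectra = 20, ppmError = 3)
  for (sp in w$spectra[1:10]) {
    d <- findDoublets(sp, lk, 1:2)
    for (r in seq_len(nrow(d))) {
      mLight <- d$lightMz[r] * d$charge[r] - d$charge[r] * PROTON -
        lightMass(lk)
      mHeavy <- d$heavyMz[r] * d$charge[r] - d$charge[r] * PROTON -
        heavyMass(lk)
      # tolerance applied to the heavy peak m/z, scaled to neutral mass
      expect_lt(abs(mLight - mHeavy),
                10e-6 * d$heavyMz[r] * d$charge[r] + 1e-9)
    }
  }
})

test_that("evidence pairs satisfy the precursor mass relation", {
  # doublets for 1000 and 1500 Da peptides; precursor = sum + intact linker
  precM <- 1000 + 1500 + intactMass(lk)
  mzs <- sort(c((1000 + lightMass(lk) + PROTON), (1000 + heavyMass(lk) + PROTON),
                (1500 + lightMass(lk) + PROTON), (1500 + heavyMass(lk) + PROTON)))
  sp <- spec(mzs, precMz = (precM + 3 * PROTON) / 3, z = 3)
  dbl <- findDoublets(sp, lk, 1)
  ev <- detectEvidencePairs(dbl, sp, precM, lk, tolerance(0.01, "Da"),
                            chargeRange = 1)
  expect_equal(nrow(ev[ev$completeness == "full", ]), 1L)
  expect_equal(ev$massAlpha[1], 1500, tolerance = 1e-4)
  expect_equal(ev$massBeta[1], 1000, tolerance = 1e-4)
  # violating precursor -> nothing
  ev2 <- detectEvidencePairs(dbl, sp, 2660, lk, tolerance(0.01, "Da"),
                             chargeRange = 1)
  expect_equal(nrow(ev2[ev2$completeness == "full", ]), 0L)
})

test_that("a full doublet plus a lone partner stump ion forms partial evidence", {
  precM <- 1000 + 1500 + intactMass(lk)
  # full doublet for 1000; only the heavy ion of the 1500 partner
  mzs <- sort(c(1000 + lightMass(lk) + PROTON, 1000 + heavyMass(lk) + PROTON,
                1500 + heavyMass(lk) + PROTON))
  sp <- spec(mzs, precMz = (precM + 3 * PROTON) / 3, z = 3)
  dbl <- findDoublets(sp, lk, 1)
  expect_equal(nrow(dbl), 1L)
  ev <- detectEvidencePairs(dbl, sp, precM, lk, tolerance(0.01, "Da"),
                            chargeRange = 1)
  expect_true(any(ev$completeness == "heavy_only" &
                    abs(ev$massAlpha - 1500) < 1e-3))
  # the light interpretation of that peak is inconsistent and must not emit
  expect_false(any(ev$completeness == "light_only"))
})

test_that("indication mode infers the partner mass by subtraction", {
  precM <- 2658.00377
  sp <- spec(c(1055.017846, 1105.000476),
             precMz = (precM + 3 * PROTON) / 3, z = 3)
  dbl <- findDoublets(sp, lk, 1)
  ind <- detectIndicationPairs(dbl, precM, lk, spectrum = sp,
                               chargeRange = 1)
  expect_equal(nrow(ind), 1L)
  expect_equal(ind$massAlpha, 1500, tolerance = 1e-4)
  # partner below the minimum peptide mass -> no pair
  ind2 <- detectIndicationPairs(dbl, 1000 + intactMass(lk) + 200, lk,
                                minPeptideMass = 300)
  expect_equal(nrow(ind2), 0L)
})

test_that("mode lattice: combined contains evidence and indication hypotheses", {
  w <- simWorld(33, nSpectra = 25)
  hypKey <- function(h) paste(round(h$massAlpha, 3), round(h$massBeta, 3))
  for (sp in w$spectra) {
    ev <- detect(sp, lk, "evidence")
    ind <- detect(sp, lk, "indication")
    comb <- detect(sp, lk, "combined")
    expect_true(all(hypKey(ev) %in% hypKey(comb)))
    expect_true(all(hypKey(ind) %in% hypKey(comb)))
  }
})

test_that("noise-free planted doublets are recovered exactly", {
  w <- simWorld(35, nSpectra = 25, coverage = 0, doubletProb = 1,
                noisePeaks = 0, ppmError = 0, isotopeErrorProb = 0)
  for (i in seq_along(w$spectra)) {
    sp <- w$spectra[[i]]
    tr <- w$truth[i, ]
    d <- findDoublets(sp, dssoLinker(), seq_len(tr$charge - 1))
    got <- round(sort(unique(d$peptideNeutralMass)), 4)
    want <- round(sort(unique(c(tr$massA, tr$massB))), 4)
    expect_equal(got, want)
  }
})

test_that("every emitted evidence pair re-satisfies the sum rule post hoc", {
  w <- simWorld(37, nSpectra = 20)
  for (i in seq_along(w$spectra)) {
    sp <- w$spectra[[i]]
    massP <- precursorNeutralMass(sp)
    ev <- detect(sp, lk, "evidence", tD = tolerance(5, "ppm"))
    for (r in seq_len(nrow(ev)))
      expect_lt(abs(ev$massAlpha[r] + ev$massBeta[r] + intactMass(lk) -
                      massP),
                5e-6 * massP + 1e-9)
  }
})

test_that("diagnostic ions annotate but never gate by default", {
  dlk <- crosslinkerSpec("diag", 158.00377, 54.01057, 103.99320,
                         reactiveResidues = "K",
                         diagnosticIons = c(222.111, 333.222))
  sp <- spec(c(222.1110, 500))
  ann <- detectDiagnosticIons(sp, dlk)
  expect_true(ann[[1]])
  expect_false(ann[[2]])
  expect_true(attr(ann, "any"))
  expect_length(detectDiagnosticIons(sp, dssoLinker()), 0L)
  # diagnostic peak alone does not admit a spectrum (no doublets -> empty)
  expect_equal(nrow(detect(sp, dlk, "combined", precursorMass = 2000)), 0L)
  # strict flag excludes spectra without the diagnostic ion
  spNoDiag <- spec(c(1055.017846, 1105.000476), precMz = 900, z = 4)
  expect_gt(nrow(detect(spNoDiag, dlk, "combined", precursorMass = 2658.00377,
                        chargeRange = 1)), 0L)
  expect_equal(nrow(detect(spNoDiag, dlk, "combined",
                           precursorMass = 2658.00377, chargeRange = 1,
                           requireDiagnostic = TRUE)), 0L)
})

test_that("alternative precursor hypotheses apply C13 offsets", {
  sp <- spec(c(500), precMz = (2658.00377 + 3 * PROTON) / 3, z = 3)
  h <- precursorHypotheses(sp, maxOffsets = 2)
  expect_equal(nrow(h), 3L)
  expect_equal(h$isotopeOffset, c(0L, -1L, -2L))
  expect_equal(h$neutralMass[2], 2657.00042, tolerance = 1e-5)
  expect_equal(nrow(precursorHypotheses(sp, maxOffsets = 0)), 1L)
  expect_error(precursorHypotheses(sp, 2, "ms1"), "MS1")
  # ms1-verified mode keeps only offsets with a matching MS1 peak
  ms1 <- spec(c((2657.00042 + 3 * PROTON) / 3), precMz = 0, z = 1)
  h2 <- precursorHypotheses(sp, 2, "ms1", ms1Spectrum = ms1)
  expect_setequal(h2$isotopeOffset, c(0L, -1L))
  expect_true(h2$verifiedInMs1[h2$isotopeOffset == -1L])
})
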