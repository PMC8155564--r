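test_that("decoy classification follows the at-least-one-decoy rule", {
  expect_equal(classifyCsm(FALSE, FALSE), "TT")
  expect_equal(classifyCsm(FALSE, TRUE), "TD")
  expect_equal(classifyCsm(TRUE, FALSE), "TD")
  expect_equal(classifyCsm(TRUE, TRUE), "DD")
  expect_equal(classifyCsm(c(FALSE, TRUE), c(TRUE, TRUE)), c("TD", "DD"))
})

## build a CSM row resolving to given residue pairs
csmRow <- function(scan, seqA, seqB, lpA, lpB, accA, startA, accB, startB,
                   score, decoyClass = "TT") {
  df <- data.frame(scanId = scan, sequenceAlpha = seqA, sequenceBeta = seqB,
                   linkPosAlpha = lpA, linkPosBeta = lpB,
                   annikaScore = score, decoyClass = decoyClass,
                   stringsAsFactors = FALSE)
  df$locationsAlpha <- list(data.frame(accession = accA, start = startA,
                                       stringsAsFactors = FALSE))
  df$locationsBeta <- list(data.frame(accession = accB, start = startB,
                                      stringsAsFactors = FALSE))
  df
}

test_that("CSMs merging on the same residue pair form one cross-link with the max score", {
  csms <- rbind(
    csmRow("s1", "KLER", "AAKDR", 1, 3, "P", 10, "Q", 18, 100),
    csmRow("s2", "AKLER", "AAKDR", 2, 3, "P", 9, "Q", 18, 150),  # substring case
    csmRow("s3", "AAKDR", "KLER", 3, 1, "Q", 18, "P", 10, 120),  # swapped order
    csmRow("s4", "GGKGG", "HHKHH", 3, 3, "R", 1, "R", 40, 80))   # intra link
  xl <- groupCrosslinks(csms)
  expect_equal(nrow(xl), 2L)
  main <- xl[xl$proteinA == "P", ]
  expect_equal(main$score, 150)
  expect_equal(main$nCsms, 3L)
  expect_equal(main$positionA, 10L)
  expect_equal(main$positionB, 20L)
  expect_equal(main$linkClass, "inter")
  expect_equal(xl$linkClass[xl$proteinA == "R"], "intra")
})

test_that("cross-link grouping is idempotent", {
  w <- simWorld(61, nSpectra = 25)
  csms <- searchSpectra(w$spectra, w$index)
  xl1 <- groupCrosslinks(csms)
  # flatten back to member CSMs and regroup
  back <- csms[sort(unique(unlist(xl1$csmRows))), , drop = FALSE]
  xl2 <- groupCrosslinks(back)
  expect_setequal(crosslinkKeys(xl1), crosslinkKeys(xl2))
  expect_equal(sort(xl1$score), sort(xl2$score))
})

test_that("a peptide mapping to several proteins joins every residue-pair group", {
  csm <- csmRow("s1", "SHARKED", "AAKDR", 3, 3, "P", 5, "Q", 1, 50)
  csm$locationsAlpha <- list(data.frame(accession = c("P", "X"),
                                        start = c(5L, 100L)))
  xl <- groupCrosslinks(csm)
  expect_equal(nrow(xl), 2L)
  expect_setequal(crosslinkKeys(xl),
                  c(pairKey("P", 7, "Q", 3), pairKey("X", 102, "Q", 3)))
  expect_error(groupCrosslinks(csmRow("s", "A", "B", 1, 1, "P", 1, "Q", 1,
                                      1)[, -which(names(csmRow("s", "A",
                                      "B", 1, 1, "P", 1, "Q", 1, 1)) ==
                                      "locationsAlpha")]))
})

test_that("single-pass FDR scan equals a quadratic recount oracle", {
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(50:200, 1)
    items <- data.frame(score = round(rexp(n, 1 / 10), 2),
                        decoy = runif(n) < 0.15)
    got <- estimateFdr(items, c(0.01, 0.05))
    # quadratic recount at every rank
    for (r in sample(seq_len(n), 10)) {
      above <- got$score >= got$score[r]
      d <- sum(got$decoy[above]); t <- sum(!got$decoy[above])
      want <- if (t == 0) NA_real_ else d / t
      expect_equal(got$estFdr[r], want)
    }
    # label semantics: high iff inside the deepest prefix with FDR <= 1%
    okHigh <- which(!is.na(got$estFdr) & got$estFdr <= 0.01)
    nHigh <- if (length(okHigh)) max(okHigh) else 0L
    expect_equal(which(got$confidence == "high"),
                 seq_len(nHigh), ignore_attr = TRUE)
  }
})

test_that("FDR thresholds are nested and tie groups pass all-or-none", {
  set.seed(19)
  items <- data.frame(score = sample(rep(1:30, each = 4)),
                      decoy = runif(120) < 0.2)
  got <- estimateFdr(items, c(0.01, 0.05))
  hi <- got$confidence == "high"
  med <- got$confidence %in% c("high", "medium")
  expect_true(all(med[hi]))
  # items with equal scores share one label
  for (s in unique(got$score))
    expect_length(unique(got$confidence[got$score == s]), 1L)
  # no decoys -> everything high
  clean <- data.frame(score = 10:1, decoy = FALSE)
  expect_true(all(estimateFdr(clean)$confidence == "high"))
  # empty input -> empty output
  expect_equal(nrow(estimateFdr(clean[0, ])), 0L)
})

test_that("the (D+1)/T estimator is more conservative than D/T", {
  items <- data.frame(score = 100:1,
                      decoy = c(rep(FALSE, 60), TRUE, rep(FALSE, 39)))
  dt <- estimateFdr(items, c(0.01, 0.05), estimator = "dt")
  dt1 <- estimateFdr(items, c(0.01, 0.05), estimator = "dt1")
  expect_gte(sum(dt$confidence == "high"), sum(dt1$confidence == "high"))
  expect_true(all(dt1$estFdr >= dt$estFdr, na.rm = TRUE))
})

test_that("intra/inter separation makes labels invariant to the other class", {
  set.seed(23)
  intra <- data.frame(score = round(rexp(80, 1 / 20), 2),
                      decoy = runif(80) < 0.1, linkClass = "intra")
  inter <- data.frame(score = round(rexp(60, 1 / 20), 2),
                      decoy = runif(60) < 0.1, linkClass = "inter")
  both <- separatedFdr(rbind(intra, inter))
  # flooding with low-scoring inter decoys must not change intra labels
  flood <- data.frame(score = runif(1000, 0, 0.01), decoy = TRUE,
                      linkClass = "inter")
  flooded <- separatedFdr(rbind(intra, inter, flood))
  keyOf <- function(x) paste(x$score, x$decoy)
  intraBefore <- both[both$linkClass == "intra", ]
  intraAfter <- flooded[flooded$linkClass == "intra", ]
  expect_equal(intraBefore$confidence[order(keyOf(intraBefore))],
               intraAfter$confidence[order(keyOf(intraAfter))])
  expect_equal(nrow(flooded), nrow(intra) + nrow(inter) + nrow(flood))
  # only-intra dataset: identical to unsplit validation
  onlyIntra <- separatedFdr(intra)
  unsplit <- estimateFdr(intra)
  expect_equal(onlyIntra$confidence, unsplit$confidence)
})

test_that("CSM-level and cross-link-level validation are independent", {
  # one residue pair supported by two CSMs: a weak one and a strong one,
  # plus decoys that reject the weak CSM at CSM level
  csms <- rbind(
    csmRow("s1", "AAKK", "CCKK", 1, 1, "P", 1, "Q", 1, 100),
    csmRow("s2", "AAKK", "CCKK", 1, 1, "P", 1, "Q", 1, 5),
    csmRow("d1", "DDKK", "EEKK", 1, 1, "REV_P", 7, "Q", 30, 8,
           decoyClass = "TD"),
    csmRow("d2", "FFKK", "GGKK", 1, 1, "REV_P", 9, "Q", 40, 7,
           decoyClass = "TD"))
  out <- validateAll(csms, fdrConfig(csmThresholds = c(0.01, 0.05),
                                     crosslinkThresholds = c(0.5, 0.5)))
  weak <- out$csms[out$csms$scanId == "s2", ]
  expect_equal(weak$confidence, "rejected")
  xl <- out$crosslinks
  strong <- xl[xl$proteinA == "P" & !xl$decoy, ]
  # cross-link level: 1 target vs 2 decoys at scores below -> still passes 50%
  expect_equal(strong$confidence, "high")
  expect_equal(strong$score, 100)
  # no decoys -> all high at both levels
  clean <- csms[1:2, ]
  outClean <- validateAll(clean)
  expect_true(all(outClean$csms$confidence == "high"))
  expect_true(all(outClean$crosslinks$confidence == "high"))
})
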