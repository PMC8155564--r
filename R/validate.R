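## Target-decoy validation: CSM -> cross-link grouping and FDR estimation
## at both levels, optionally with intra/inter separation.

#' FDR configuration
#'
#' Two estimated-FDR thresholds per level: results at or better than the
#' lower threshold are labelled `high` confidence, results at or better
#' than the higher threshold `medium`, everything else `rejected`.
#'
#' @param csmThresholds,crosslinkThresholds Numeric `(high, medium)`
#'   fractions; defaults `c(0.01, 0.05)`.
#' @param separateIntraInter Validate intra- and inter-protein links
#'   independently (horizontal split, then reconcatenation).
#' @param estimator `"dt"` for decoys/targets (assumes the number of false
#'   positives is no higher than the number of decoys) or `"dt1"` for
#'   (decoys + 1)/targets.
#' @return List of class `FdrConfig`.
#' @export
fdrConfig <- function(csmThresholds = c(0.01, 0.05),
                      crosslinkThresholds = c(0.01, 0.05),
                      separateIntraInter = FALSE,
                      estimator = c("dt", "dt1")) {
  estimator <- match.arg(estimator)
  stopifnot(length(csmThresholds) == 2L, csmThresholds[1] <= csmThresholds[2],
            length(crosslinkThresholds) == 2L,
            crosslinkThresholds[1] <= crosslinkThresholds[2])
  structure(list(csmThresholds = csmThresholds,
                 crosslinkThresholds = crosslinkThresholds,
                 separateIntraInter = isTRUE(separateIntraInter),
                 estimator = estimator),
            class = "FdrConfig")
}

#' Decoy class of a CSM
#'
#' A hit is a decoy when at least one of the two cross-linked peptides
#' originates from the decoy database: `TT` (neither), `TD` (exactly one),
#' `DD` (both). For FDR purposes TD and DD both count as decoy.
#'
#' @param decoyAlpha,decoyBeta Logical decoy flags of the two peptides.
#' @return `"TT"`, `"TD"` or `"DD"` (vectorised).
#' @export
classifyCsm <- function(decoyAlpha, decoyBeta) {
  ifelse(!decoyAlpha & !decoyBeta, "TT",
         ifelse(decoyAlpha & decoyBeta, "DD", "TD"))
}

## canonical unordered residue-pair key
.residuePairKey <- function(accA, posA, accB, posB) {
  a <- paste0(accA, ":", posA)
  b <- paste0(accB, ":", posB)
  ifelse(a <= b, paste(a, b, sep = "--"), paste(b, a, sep = "--"))
}

#' Group cross-link spectrum matches into cross-links
#'
#' A cross-link is the unique unordered pair of linked protein residues;
#' all CSMs resolving to the same absolute residue pair are merged -- in
#' particular, a peptide that is a substring of a longer peptide places the
#' link at the same absolute position and joins the same cross-link. A CSM
#' whose peptides map to several proteins joins every residue-pair group it
#' supports. The cross-link score is the maximum member CSM score; a
#' cross-link is decoy if any member CSM is not TT.
#'
#' @param csms CSM data.frame from [searchSpectra()] (needs list columns
#'   `locationsAlpha`/`locationsBeta` and `linkPosAlpha`/`linkPosBeta`).
#' @return data.frame with one row per unique residue pair: `proteinA`,
#'   `positionA`, `proteinB`, `positionB`, `score`, `nCsms`, `linkClass`,
#'   `decoy`, `csmRows` (list of member row indices into `csms`),
#'   `bestCsmRow`.
#' @export
groupCrosslinks <- function(csms) {
  empty <- data.frame(proteinA = character(), positionA = integer(),
                      proteinB = character(), positionB = integer(),
                      score = numeric(), nCsms = integer(),
                      linkClass = character(), decoy = logical(),
                      bestCsmRow = integer(), stringsAsFactors = FALSE)
  empty$csmRows <- list()
  if (!nrow(csms)) return(empty)
  recs <- list()
  for (r in seq_len(nrow(csms))) {
    locA <- csms$locationsAlpha[[r]]
    locB <- csms$locationsBeta[[r]]
    if (is.null(locA) || !nrow(locA) || is.null(locB) || !nrow(locB))
      stop("CSM row ", r, " has a peptide with no protein location")
    for (ia in seq_len(nrow(locA))) {
      for (ib in seq_len(nrow(locB))) {
        accA <- locA$accession[ia]
        posA <- locA$start[ia] + csms$linkPosAlpha[r] - 1L
        accB <- locB$accession[ib]
        posB <- locB$start[ib] + csms$linkPosBeta[r] - 1L
        recs[[length(recs) + 1L]] <- data.frame(
          key = .residuePairKey(accA, posA, accB, posB),
          accA = accA, posA = posA, accB = accB, posB = posB,
          row = r, stringsAsFactors = FALSE)
      }
    }
  }
  recs <- do.call(rbind, recs)
  ## order the pair members canonically for reporting
  swap <- paste0(recs$accA, ":", recs$posA) > paste0(recs$accB, ":", recs$posB)
  tmpA <- recs$accA[swap]; tmpP <- recs$posA[swap]
  recs$accA[swap] <- recs$accB[swap]; recs$posA[swap] <- recs$posB[swap]
  recs$accB[swap] <- tmpA; recs$posB[swap] <- tmpP
  groups <- split(recs, recs$key)
  out <- lapply(groups, function(g) {
    rows <- unique(g$row)
    scores <- csms$annikaScore[rows]
    best <- rows[which.max(scores)]
    df <- data.frame(
      proteinA = g$accA[1L], positionA = g$posA[1L],
      proteinB = g$accB[1L], positionB = g$posB[1L],
      score = max(scores), nCsms = length(rows),
      linkClass = if (g$accA[1L] == g$accB[1L]) "intra" else "inter",
      decoy = any(csms$decoyClass[rows] != "TT"),
      bestCsmRow = best, stringsAsFactors = FALSE)
    df$csmRows <- list(rows)
    df
  })
  out <- do.call(rbind, out)
  out <- out[order(-out$score, out$proteinA, out$positionA,
                   out$proteinB, out$positionB), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Estimate FDR by descending-score scan and assign confidence labels
#'
#' Items are ranked by descending score; at each rank the estimated FDR is
#' decoys/targets among items at or above that score (ranks with zero
#' targets are skipped). All items above the lowest score cutoff at which
#' the FDR is within a threshold receive the corresponding label; tied
#' scores pass or fail as a whole group (the FDR is evaluated at the bottom
#' of the tie group). Decoy items are labelled but are never reported as
#' identifications downstream.
#'
#' @param items data.frame with a `score` column and a logical decoy
#'   indicator.
#' @param thresholds `(high, medium)` FDR fractions.
#' @param decoyCol Name of the logical decoy column.
#' @param estimator `"dt"` (decoys/targets) or `"dt1"` ((decoys+1)/targets).
#' @return `items` sorted by descending score with added columns `estFdr`
#'   (the estimated FDR at the item's rank) and `confidence`
#'   (`high`/`medium`/`rejected`).
#' @export
estimateFdr <- function(items, thresholds = c(0.01, 0.05),
                        decoyCol = "decoy", estimator = c("dt", "dt1")) {
  estimator <- match.arg(estimator)
  if (!nrow(items)) {
    items$estFdr <- numeric(0)
    items$confidence <- character(0)
    return(items)
  }
  items <- items[order(-items$score), , drop = FALSE]
  rownames(items) <- NULL
  dec <- items[[decoyCol]]
  cumD <- cumsum(dec)
  cumT <- cumsum(!dec)
  fdr <- ifelse(cumT == 0, NA_real_,
                if (estimator == "dt") cumD / cumT else (cumD + 1) / cumT)
  ## all-or-none at tied scores: evaluate at the bottom row of each tie group
  n <- nrow(items)
  grpEnd <- ave(seq_len(n), items$score, FUN = max)  # bottom of each tie group
  fdrAtGroup <- fdr[grpEnd]
  passes <- function(thr) {
    ok <- which(!is.na(fdrAtGroup) & fdrAtGroup <= thr)
    if (!length(ok)) return(logical(n))
    seq_len(n) <= max(ok)
  }
  hi <- passes(thresholds[1])
  med <- passes(thresholds[2])
  items$estFdr <- fdrAtGroup
  items$confidence <- ifelse(hi, "high", ifelse(med, "medium", "rejected"))
  items
}

#' Intra/inter-separated FDR
#'
#' Applies a horizontal split on `linkClass`, validates the intra and inter
#' subsets independently with [estimateFdr()], then reconcatenates. Labels
#' within one class are invariant to any change in the other class.
#'
#' @inheritParams estimateFdr
#' @param items data.frame with `score`, a decoy column and `linkClass`.
#' @return Labelled items (intra block first, each sorted by score).
#' @export
separatedFdr <- function(items, thresholds = c(0.01, 0.05),
                         decoyCol = "decoy", estimator = "dt") {
  parts <- lapply(c("intra", "inter"), function(cl) {
    sub <- items[items$linkClass == cl, , drop = FALSE]
    estimateFdr(sub, thresholds, decoyCol, estimator)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Validate CSMs and cross-links
#'
#' Estimates the FDR independently at the CSM level (on all CSMs) and at
#' the cross-link level (on the grouped cross-links) and attaches
#' confidence labels at both levels. The two levels are independent: a
#' cross-link may pass at the link level even when its best CSM is rejected
#' at the CSM level.
#'
#' @param csms CSM data.frame from [searchSpectra()].
#' @param config An [fdrConfig()].
#' @return List with elements `csms` (labelled, column `decoy` added) and
#'   `crosslinks` (labelled, see [groupCrosslinks()]).
#' @export
validateAll <- function(csms, config = fdrConfig()) {
  csms$decoy <- csms$decoyClass != "TT"
  csms$score <- csms$annikaScore
  labelCsm <- if (config$separateIntraInter) separatedFdr else estimateFdr
  csms <- labelCsm(csms, config$csmThresholds, "decoy", config$estimator)
  links <- groupCrosslinks(csms)
  labelXl <- if (config$separateIntraInter) separatedFdr else estimateFdr
  links <- labelXl(links, config$crosslinkThresholds, "decoy",
                   config$estimator)
  list(csms = csms, crosslinks = links)
}
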