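## Binomial probability score for one peptide against one spectrum.

#' Probability-based peptide-spectrum score
#'
#' Scores how unlikely the observed fragment matches are to have arisen by
#' chance. Each theoretical fragment is treated as an independent Bernoulli
#' trial with success probability
#' `p = clamp(nPeaks * 2 * tolDa / (mzMax - mzMin), 1e-6, 0.5)` -- the
#' fraction of the spectrum's m/z range covered by match windows. With `n`
#' theoretical fragments of which `k` matched, the chance probability is the
#' binomial tail `P(X >= k | n, p)`; the score is
#' `-log10(P) * explainedIntensityFraction`, floored at 0. Both stump
#' variants of a site-containing fragment count toward `n`; matching either
#' (or both) counts once toward `k` via the fragment `group`.
#'
#' @param spectrum An [Ms2Spectrum-class].
#' @param fragments Output of [theoreticalFragments()] (non-empty).
#' @param tol MS2 match [Tolerance-class] (numeric = ppm). For ppm units the
#'   window used in `p` is evaluated at the centre of the spectrum's m/z
#'   range.
#' @return Numeric vector: `score`, `matched` (k over fragment groups),
#'   `nTheoretical` (n, counting variants), `explainedIntensity` (matched
#'   peak intensity / total intensity), `pChance`.
#' @export
#' @examples
#' sp <- ms2Spectrum("s1", 500, 2, cbind(c(200, 300), c(10, 20)))
#' fr <- theoreticalFragments("ACDK", 4, dssoLinker())
#' amandaScore(sp, fr)
amandaScore <- function(spectrum, fragments, tol = tolerance(10, "ppm")) {
  if (is.numeric(tol)) tol <- tolerance(tol, "ppm")
  if (!nrow(fragments)) stop("fragment list must be non-empty")
  p <- spectrum@peaks
  empty <- c(score = 0, matched = 0, nTheoretical = nrow(fragments),
             explainedIntensity = 0, pChance = 1)
  if (!nrow(p)) return(empty)
  mz <- p[, 1L]
  targets <- fragments$mz
  w <- if (tol@unit == "Da") rep(tol@value, length(targets)) else
    tol@value * 1e-6 * targets
  lo <- findInterval(targets - w, mz, left.open = TRUE) + 1L
  hi <- findInterval(targets + w, mz)
  matchedIdx <- integer()
  matchedGroups <- character()
  for (r in which(hi >= lo)) {
    cand <- lo[r]:hi[r]
    d <- abs(mz[cand] - targets[r])
    best <- cand[d == min(d)]
    if (length(best) > 1L) best <- best[which.max(p[best, 2L])]
    matchedIdx <- c(matchedIdx, best)
    matchedGroups <- c(matchedGroups, fragments$group[r])
  }
  n <- nrow(fragments)
  k <- length(unique(matchedGroups))
  if (k == 0L) return(empty)
  mzMin <- mz[1L]; mzMax <- mz[length(mz)]
  range <- mzMax - mzMin
  tolDa <- toDa(tol, at = (mzMin + mzMax) / 2)
  pMatch <- if (range <= 0) 0.5 else
    min(max(nrow(p) * 2 * tolDa / range, 1e-6), 0.5)
  tail <- stats::pbinom(k - 1L, n, pMatch, lower.tail = FALSE)
  explained <- sum(p[unique(matchedIdx), 2L]) / sum(p[, 2L])
  score <- max(0, -log10(tail) * explained)
  c(score = score, matched = k, nTheoretical = n,
    explainedIntensity = explained, pChance = tail)
}
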