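## Theoretical fragment generation for cross-linked peptides.

#' Fragment ion model
#'
#' @param series Ion series to generate ("b", "y").
#' @param charges Fragment charge states.
#' @param includeIntactPartner If `TRUE`, additionally generate fragments
#'   carrying the intact linker plus the whole partner peptide. Off by
#'   default: stepped-HCD spectra of cleavable linkers are dominated by the
#'   cleaved stump species, and a small theoretical count keeps the binomial
#'   score discriminative.
#' @return A list of class `FragmentModel`.
#' @export
fragmentModel <- function(series = c("b", "y"), charges = 1:2,
                          includeIntactPartner = FALSE) {
  series <- match.arg(series, c("b", "y"), several.ok = TRUE)
  if (!length(series)) stop("at least one ion series must be enabled")
  structure(list(series = series, charges = as.integer(charges),
                 includeIntactPartner = isTRUE(includeIntactPartner)),
            class = "FragmentModel")
}

#' Theoretical fragments of a cross-linked peptide
#'
#' Generates b/y ions at the configured charges. Fragments containing the
#' link site are emitted twice -- once with the light and once with the
#' heavy stump mass added -- because the cleavable linker leaves either
#' stump on the peptide; fragments not containing the link site are emitted
#' unmodified. Rows duplicated in m/z (to 1e-6) are merged.
#'
#' @param sequence Peptide string.
#' @param linkPosition 1-based index of the linked residue.
#' @param linker A [CrosslinkerSpec-class].
#' @param model A [fragmentModel()].
#' @param mods Named numeric modification shifts (position -> Da).
#' @param partnerMass Neutral mass of the partner peptide; only used when
#'   `model$includeIntactPartner` is `TRUE`.
#' @return data.frame with columns `mz`, `ion` (e.g. "b2"), `charge`,
#'   `variant` ("", "light", "heavy", "intact"), `group` (fragment identity
#'   shared by the stump variants of one ion).
#' @export
#' @examples
#' theoreticalFragments("ACK", 3, dssoLinker(),
#'                      fragmentModel(charges = 1))
theoreticalFragments <- function(sequence, linkPosition, linker,
                                 model = fragmentModel(), mods = NULL,
                                 partnerMass = NULL) {
  res <- .residueVector(sequence)
  n <- length(res)
  if (linkPosition < 1L || linkPosition > n)
    stop("link position ", linkPosition, " outside peptide of length ", n)
  if (n < 2L)
    return(data.frame(mz = numeric(), ion = character(), charge = integer(),
                      variant = character(), group = character(),
                      stringsAsFactors = FALSE))
  shift <- numeric(n)
  if (!is.null(mods) && length(mods))
    shift[as.integer(names(mods))] <- unname(mods)
  resMod <- res + shift
  water <- xlmsConstants[["water"]]
  idx <- seq_len(n - 1L)
  vNeutral <- numeric(0); vIon <- character(0); vSite <- logical(0)
  for (ser in model$series) {
    if (ser == "b") {
      vNeutral <- c(vNeutral, cumsum(resMod)[idx])
      vIon <- c(vIon, paste0("b", idx))
      vSite <- c(vSite, linkPosition <= idx)
    } else {
      vNeutral <- c(vNeutral, cumsum(rev(resMod))[idx] + water)
      vIon <- c(vIon, paste0("y", idx))
      vSite <- c(vSite, linkPosition >= n - idx + 1L)
    }
  }
  out <- list()
  for (z in model$charges) {
    grp <- paste0(vIon, "^", z)
    plain <- !vSite
    out[[length(out) + 1L]] <- list(
      mz = neutralToMz(vNeutral[plain], z), ion = vIon[plain],
      charge = rep(z, sum(plain)), variant = rep("", sum(plain)),
      group = grp[plain])
    for (v in c("light", "heavy")) {
      stump <- if (v == "light") linker@lightMass else linker@heavyMass
      out[[length(out) + 1L]] <- list(
        mz = neutralToMz(vNeutral[vSite] + stump, z), ion = vIon[vSite],
        charge = rep(z, sum(vSite)), variant = rep(v, sum(vSite)),
        group = grp[vSite])
    }
    if (model$includeIntactPartner && !is.null(partnerMass))
      out[[length(out) + 1L]] <- list(
        mz = neutralToMz(vNeutral[vSite] + linker@intactMass + partnerMass,
                         z),
        ion = vIon[vSite], charge = rep(z, sum(vSite)),
        variant = rep("intact", sum(vSite)), group = grp[vSite])
  }
  df <- data.frame(
    mz = unlist(lapply(out, `[[`, "mz")),
    ion = unlist(lapply(out, `[[`, "ion")),
    charge = unlist(lapply(out, `[[`, "charge")),
    variant = unlist(lapply(out, `[[`, "variant")),
    group = unlist(lapply(out, `[[`, "group")),
    stringsAsFactors = FALSE)
  df <- df[!duplicated(round(df$mz, 6L)), , drop = FALSE]
  df <- df[order(df$mz), , drop = FALSE]
  rownames(df) <- NULL
  df
}
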