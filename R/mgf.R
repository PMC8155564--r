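## MGF (Mascot generic format) reader/writer and optional mzML reader.
## Dialect: required TITLE, PEPMASS, CHARGE; optional RTINSECONDS,
## ION_MOBILITY; unknown headers preserved as metadata.

#' Read centroided MS2 spectra from an MGF file
#'
#' One [Ms2Spectrum-class] per `BEGIN IONS`/`END IONS` block. The first
#' numeric value of `PEPMASS` is the precursor m/z; `CHARGE` is parsed with
#' its sign suffix. A missing `CHARGE` leaves the charge `NA`; downstream
#' search then enumerates charges 2-6.
#'
#' @param path Path to an MGF file.
#' @return List of [Ms2Spectrum-class] objects (empty list for empty file).
#' @export
readMgf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  begin <- which(lines == "BEGIN IONS")
  end <- which(lines == "END IONS")
  if (length(begin) != length(end) || any(begin > end))
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in ", path)
  out <- vector("list", length(begin))
  for (b in seq_along(begin)) {
    block <- lines[(begin[b] + 1L):(end[b] - 1L)]
    block <- block[nzchar(trimws(block))]
    isHeader <- grepl("=", block, fixed = TRUE)
    hdr <- block[isHeader]
    keys <- toupper(sub("=.*$", "", hdr))
    vals <- sub("^[^=]*=", "", hdr)
    title <- if ("TITLE" %in% keys) vals[match("TITLE", keys)] else
      paste0("scan_", b)
    if (!"PEPMASS" %in% keys)
      stop("malformed MGF block (no PEPMASS) in scan '", title, "'")
    pepmass <- suppressWarnings(
      as.numeric(strsplit(trimws(vals[match("PEPMASS", keys)]), "\\s+")[[1L]][1L]))
    if (is.na(pepmass))
      stop("malformed PEPMASS in scan '", title, "'")
    charge <- NA_integer_
    if ("CHARGE" %in% keys) {
      cv <- trimws(vals[match("CHARGE", keys)])
      sign <- if (grepl("-$", cv)) -1L else 1L
      charge <- suppressWarnings(as.integer(sub("[+-]$", "", cv))) * sign
      if (is.na(charge) || charge < 1L)
        stop("unsupported CHARGE '", cv, "' in scan '", title, "'")
    }
    rt <- if ("RTINSECONDS" %in% keys)
      as.numeric(vals[match("RTINSECONDS", keys)]) else NA_real_
    im <- if ("ION_MOBILITY" %in% keys)
      as.numeric(vals[match("ION_MOBILITY", keys)]) else NA_real_
    known <- c("TITLE", "PEPMASS", "CHARGE", "RTINSECONDS", "ION_MOBILITY")
    meta <- as.list(vals[!keys %in% known])
    names(meta) <- keys[!keys %in% known]
    pk <- block[!isHeader]
    if (length(pk)) {
      fields <- strsplit(trimws(pk), "\\s+")
      mz <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 1L)))
      it <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
      if (anyNA(mz) || anyNA(it))
        stop("malformed peak line in scan '", title, "'")
      peakMat <- cbind(mz = mz, intensity = it)
    } else {
      peakMat <- cbind(mz = numeric(), intensity = numeric())
    }
    out[[b]] <- ms2Spectrum(title, pepmass, charge, peakMat,
                            retentionTime = rt, ionMobility = im,
                            metadata = meta)
  }
  out
}

#' Write spectra to MGF
#'
#' Emits keys in the order TITLE, PEPMASS, CHARGE, RTINSECONDS,
#' ION_MOBILITY; m/z and intensities with six decimals, so a write/read
#' round trip preserves them to 1e-6.
#'
#' @param spectra List of [Ms2Spectrum-class] objects.
#' @param path Output file path.
#' @export
writeMgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    lines <- c("BEGIN IONS",
               paste0("TITLE=", sp@scanId),
               sprintf("PEPMASS=%.6f", sp@precursorMz))
    if (!is.na(sp@precursorCharge))
      lines <- c(lines, sprintf("CHARGE=%d+", sp@precursorCharge))
    if (!is.na(sp@retentionTime))
      lines <- c(lines, sprintf("RTINSECONDS=%.4f", sp@retentionTime))
    if (!is.na(sp@ionMobility))
      lines <- c(lines, sprintf("ION_MOBILITY=%.4f", sp@ionMobility))
    for (k in names(sp@metadata))
      lines <- c(lines, paste0(k, "=", sp@metadata[[k]]))
    p <- sp@peaks
    if (nrow(p))
      lines <- c(lines, sprintf("%.6f %.6f", p[, 1L], p[, 2L]))
    lines <- c(lines, "END IONS", "")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read MS2 spectra from mzML (optional backend)
#'
#' Same interface as [readMgf()], backed by the mzR package. Only MS level-2
#' scans are returned. MGF remains the reference dialect; this reader is a
#' convenience for converted vendor data.
#'
#' @param path Path to an mzML file.
#' @return List of [Ms2Spectrum-class] objects.
#' @export
readMzML <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the 'mzR' package")
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  hd <- mzR::header(handle)
  ms2 <- which(hd$msLevel == 2L)
  out <- vector("list", length(ms2))
  for (i in seq_along(ms2)) {
    r <- ms2[i]
    pk <- mzR::peaks(handle, r)
    pk <- pk[pk[, 2L] > 0, , drop = FALSE]
    charge <- hd$precursorCharge[r]
    out[[i]] <- ms2Spectrum(
      scanId = if (!is.null(hd$spectrumId)) hd$spectrumId[r] else
        paste0("scan_", hd$acquisitionNum[r]),
      precursorMz = hd$precursorMZ[r],
      precursorCharge = if (is.na(charge) || charge < 1) NA_integer_ else charge,
      peaks = pk,
      retentionTime = hd$retentionTime[r])
  }
  out
}

#' Best matching peak within a tolerance
#'
#' Binary search for the peak closest in m/z to the target within the
#' tolerance window. Ties on |delta m/z| are broken towards the more intense
#' peak.
#'
#' @param spectrum An [Ms2Spectrum-class] (peaks sorted by m/z).
#' @param targetMz Target m/z.
#' @param tol A [Tolerance-class] (numeric = ppm). ppm is relative to the
#'   target m/z.
#' @return One-row matrix (`mz`, `intensity`) with attribute `index`, or
#'   `NULL` when no peak qualifies.
#' @export
matchPeak <- function(spectrum, targetMz, tol = tolerance(10, "ppm")) {
  if (is.numeric(tol)) tol <- tolerance(tol, "ppm")
  p <- spectrum@peaks
  if (!nrow(p)) return(NULL)
  w <- toDa(tol, at = targetMz)
  mz <- p[, 1L]
  lo <- findInterval(targetMz - w, mz, left.open = TRUE) + 1L
  hi <- findInterval(targetMz + w, mz)
  if (hi < lo) return(NULL)
  cand <- lo:hi
  d <- abs(mz[cand] - targetMz)
  best <- cand[d == min(d)]
  if (length(best) > 1L) best <- best[which.max(p[best, 2L])]
  out <- p[best, , drop = FALSE]
  attr(out, "index") <- best
  out
}
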