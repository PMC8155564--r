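## End-to-end run orchestration, flat config files, result tables, and the
## xiView-style cross-link export.

#' Full run configuration
#'
#' Collects every tunable of the pipeline. Tolerances are given in ppm
#' (numbers) for the flat config file; coordinate convention everywhere is
#' 1-based inclusive residue positions.
#'
#' @param linker A [CrosslinkerSpec-class] or a preset name
#'   (`"DSSO"`/`"DSBU"`).
#' @param digestion A [digestionParams()].
#' @param mode Detector mode.
#' @param topN Candidates kept per peptide mass.
#' @param ms2TolPpm,doubletTolPpm,precursorTolPpm,massTolPpm Tolerances:
#'   fragment match, doublet spacing, precursor relation (T_D), candidate
#'   mass query.
#' @param fdr `(high, medium)` thresholds applied at both levels.
#' @param separateIntraInter Validate intra/inter links separately.
#' @param isotopeOffsets Alternative precursor isotope offsets.
#' @param minPeptideMass Minimum peptide mass (Da).
#' @param allowHomodimers Allow self-pairing of single-copy peptides.
#' @param requireDiagnostic Require a diagnostic ion for detection.
#' @param decoyPrefix Reserved decoy accession prefix.
#' @param threads Worker processes for the spectrum loop.
#' @return List of class `RunConfig`.
#' @export
runConfig <- function(linker = dssoLinker(), digestion = digestionParams(),
                      mode = c("combined", "evidence", "indication"),
                      topN = 5L, ms2TolPpm = 10, doubletTolPpm = 10,
                      precursorTolPpm = 5, massTolPpm = 20,
                      fdr = c(0.01, 0.05), separateIntraInter = FALSE,
                      isotopeOffsets = 2L, minPeptideMass = 300,
                      allowHomodimers = FALSE, requireDiagnostic = FALSE,
                      decoyPrefix = "REV_", threads = 1L) {
  mode <- match.arg(mode)
  if (is.character(linker))
    linker <- switch(toupper(linker), DSSO = dssoLinker(),
                     DSBU = dsbuLinker(),
                     stop("unknown linker preset: ", linker))
  stopifnot(is(linker, "CrosslinkerSpec"), topN >= 1L,
            ms2TolPpm > 0, doubletTolPpm > 0, precursorTolPpm > 0,
            massTolPpm > 0, length(fdr) == 2L, fdr[1] <= fdr[2],
            isotopeOffsets >= 0L, threads >= 1L)
  structure(list(linker = linker, digestion = digestion, mode = mode,
                 topN = as.integer(topN), ms2TolPpm = ms2TolPpm,
                 doubletTolPpm = doubletTolPpm,
                 precursorTolPpm = precursorTolPpm, massTolPpm = massTolPpm,
                 fdr = fdr, separateIntraInter = isTRUE(separateIntraInter),
                 isotopeOffsets = as.integer(isotopeOffsets),
                 minPeptideMass = minPeptideMass,
                 allowHomodimers = isTRUE(allowHomodimers),
                 requireDiagnostic = isTRUE(requireDiagnostic),
                 decoyPrefix = decoyPrefix, threads = as.integer(threads)),
            class = "RunConfig")
}

.modsVectorToString <- function(v) {
  if (is.null(v) || !length(v)) return("")
  paste(names(v), sprintf("%.8f", unname(v)), sep = ":", collapse = ",")
}

.modsStringToVector <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  stats::setNames(vapply(parts, function(p) as.numeric(p[2L]), 0),
                  vapply(parts, `[`, "", 1L))
}

#' Write / read a flat run configuration file
#'
#' INI-style sections (`[linker]`, `[digestion]`, `[detector]`, `[search]`,
#' `[fdr]`, `[run]`) with `key = value` lines. The file round-trips through
#' [readRunConfig()] to an equivalent [runConfig()].
#'
#' @param config A [runConfig()].
#' @param path Output path.
#' @export
writeRunConfig <- function(config, path) {
  lk <- config$linker
  dg <- config$digestion
  lines <- c(
    "[linker]",
    paste0("name = ", lk@name),
    sprintf("intact_mass = %.8f", lk@intactMass),
    sprintf("light_mass = %.8f", lk@lightMass),
    sprintf("heavy_mass = %.8f", lk@heavyMass),
    paste0("reactive_residues = ", paste(lk@reactiveResidues, collapse = "")),
    paste0("nterm_reactive = ", lk@ntermReactive),
    paste0("cterm_reactive = ", lk@ctermReactive),
    paste0("diagnostic_ions = ",
           paste(sprintf("%.5f", lk@diagnosticIons), collapse = ",")),
    "",
    "[digestion]",
    paste0("missed_cleavages = ", dg$missedCleavages),
    paste0("min_length = ", dg$minLength),
    paste0("max_length = ", dg$maxLength),
    paste0("fixed_modifications = ",
           .modsVectorToString(dg$fixedModifications)),
    paste0("variable_modifications = ",
           .modsVectorToString(dg$variableModifications)),
    paste0("max_variable_mods = ", dg$maxVariableMods),
    "",
    "[detector]",
    paste0("mode = ", config$mode),
    paste0("doublet_tol_ppm = ", config$doubletTolPpm),
    paste0("isotope_offsets = ", config$isotopeOffsets),
    paste0("min_peptide_mass = ", config$minPeptideMass),
    paste0("require_diagnostic = ", config$requireDiagnostic),
    "",
    "[search]",
    paste0("top_n = ", config$topN),
    paste0("ms2_tol_ppm = ", config$ms2TolPpm),
    paste0("precursor_tol_ppm = ", config$precursorTolPpm),
    paste0("mass_tol_ppm = ", config$massTolPpm),
    paste0("allow_homodimers = ", config$allowHomodimers),
    "",
    "[fdr]",
    paste0("thresholds = ", paste(config$fdr, collapse = ",")),
    paste0("separate_intra_inter = ", config$separateIntraInter),
    "",
    "[run]",
    paste0("decoy_prefix = ", config$decoyPrefix),
    paste0("threads = ", config$threads))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- ""
  kv <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("\\[|\\]", "", ln)
    } else {
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      kv[[paste(section, key, sep = ".")]] <- val
    }
  }
  g <- function(key, default = NULL) {
    if (!is.null(kv[[key]])) kv[[key]] else default
  }
  diag <- g("linker.diagnostic_ions", "")
  linker <- crosslinkerSpec(
    name = g("linker.name", "custom"),
    intactMass = as.numeric(g("linker.intact_mass")),
    lightMass = as.numeric(g("linker.light_mass")),
    heavyMass = as.numeric(g("linker.heavy_mass")),
    reactiveResidues = strsplit(g("linker.reactive_residues", "K"), "")[[1L]],
    ntermReactive = as.logical(g("linker.nterm_reactive", "FALSE")),
    ctermReactive = as.logical(g("linker.cterm_reactive", "FALSE")),
    diagnosticIons = if (nzchar(diag))
      as.numeric(strsplit(diag, ",")[[1L]]) else numeric())
  digestion <- digestionParams(
    missedCleavages = as.integer(g("digestion.missed_cleavages", 2L)),
    minLength = as.integer(g("digestion.min_length", 5L)),
    maxLength = as.integer(g("digestion.max_length", 30L)),
    fixedModifications =
      .modsStringToVector(g("digestion.fixed_modifications", "")),
    variableModifications =
      .modsStringToVector(g("digestion.variable_modifications", "")),
    maxVariableMods = as.integer(g("digestion.max_variable_mods", 2L)))
  runConfig(
    linker = linker, digestion = digestion,
    mode = g("detector.mode", "combined"),
    topN = as.integer(g("search.top_n", 5L)),
    ms2TolPpm = as.numeric(g("search.ms2_tol_ppm", 10)),
    doubletTolPpm = as.numeric(g("detector.doublet_tol_ppm", 10)),
    precursorTolPpm = as.numeric(g("search.precursor_tol_ppm", 5)),
    massTolPpm = as.numeric(g("search.mass_tol_ppm", 20)),
    fdr = as.numeric(strsplit(g("fdr.thresholds", "0.01,0.05"), ",")[[1L]]),
    separateIntraInter =
      as.logical(g("fdr.separate_intra_inter", "FALSE")),
    isotopeOffsets = as.integer(g("detector.isotope_offsets", 2L)),
    minPeptideMass = as.numeric(g("detector.min_peptide_mass", 300)),
    allowHomodimers = as.logical(g("search.allow_homodimers", "FALSE")),
    requireDiagnostic = as.logical(g("detector.require_diagnostic", "FALSE")),
    decoyPrefix = g("run.decoy_prefix", "REV_"),
    threads = as.integer(g("run.threads", 1L)))
}

.locString <- function(loc) {
  paste(loc$accession, loc$start, sep = ":", collapse = ";")
}

.locFromString <- function(s) {
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  data.frame(accession = vapply(parts, `[`, "", 1L),
             start = as.integer(vapply(parts, `[`, "", 2L)),
             stringsAsFactors = FALSE)
}

#' Write / read the CSM result table
#'
#' Tab-separated, header row, UTF-8, "." decimal. Protein locations are
#' serialised as `accession:start` pairs joined by `;`; [readCsmTable()]
#' restores the list columns so the table can be re-grouped with
#' [groupCrosslinks()].
#'
#' @param csms CSM data.frame.
#' @param path File path.
#' @export
writeCsmTable <- function(csms, path) {
  out <- csms
  out$locationsAlpha <- vapply(csms$locationsAlpha, .locString, "")
  out$locationsBeta <- vapply(csms$locationsBeta, .locString, "")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCsmTable
#' @export
readCsmTable <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(scanId = "character"))
  df$locationsAlpha <- lapply(df$locationsAlpha, .locFromString)
  df$locationsBeta <- lapply(df$locationsBeta, .locFromString)
  df
}

#' Write the cross-link result table
#'
#' @param crosslinks Cross-link data.frame from [validateAll()].
#' @param path File path.
#' @export
writeCrosslinkTable <- function(crosslinks, path) {
  out <- crosslinks
  out$csmRows <- vapply(crosslinks$csmRows,
                        function(x) paste(x, collapse = ";"), "")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full cross-link search pipeline
#'
#' Reads spectra (MGF, or mzML by extension) and a protein FASTA, generates
#' reversed decoys, digests and indexes candidates, detects doublets and
#' searches every spectrum for its best CSM, validates at CSM and
#' cross-link level, and writes `csms.tsv`, `crosslinks.tsv` and `run.log`
#' (version, full config echo, spectra tallies) to the output directory.
#' Spectra are processed independently; the result tables are identical
#' for any thread count (canonical ordering: descending score, then alpha,
#' then beta sequence).
#'
#' @param spectraPath Path to an MGF (or mzML) file.
#' @param fastaPath Path(s) to target FASTA file(s); multiple paths (e.g. a
#'   target and an entrapment database) are concatenated.
#' @param config A [runConfig()].
#' @param outDir Output directory (created if needed); `NULL` writes no
#'   files.
#' @return Invisibly, a list with `csms`, `crosslinks`, `tallies`,
#'   `config`.
#' @export
runSearch <- function(spectraPath, fastaPath, config = runConfig(),
                      outDir = NULL) {
  for (p in c(spectraPath, fastaPath))
    if (!file.exists(p)) stop("input not found: ", p)
  spectra <- if (grepl("\\.mzml$", spectraPath, ignore.case = TRUE))
    readMzML(spectraPath) else readMgf(spectraPath)
  proteins <- do.call(c, lapply(fastaPath, readFasta))
  targetsPlusDecoys <- c(proteins,
                         makeDecoyDatabase(proteins, config$decoyPrefix))
  peps <- digestDatabase(targetsPlusDecoys, config$digestion,
                         config$decoyPrefix)
  index <- buildCandidateIndex(peps, config$linker)
  csms <- searchSpectra(
    spectra, index, mode = config$mode, topN = config$topN,
    doubletTol = tolerance(config$doubletTolPpm, "ppm"),
    tD = tolerance(config$precursorTolPpm, "ppm"),
    ms2Tol = tolerance(config$ms2TolPpm, "ppm"),
    massTol = tolerance(config$massTolPpm, "ppm"),
    maxIsotopeOffsets = config$isotopeOffsets,
    minPeptideMass = config$minPeptideMass,
    allowHomodimers = config$allowHomodimers,
    requireDiagnostic = config$requireDiagnostic,
    threads = config$threads)
  validated <- validateAll(csms, fdrConfig(config$fdr, config$fdr,
                                           config$separateIntraInter))
  ## canonical ordering for reproducible multi-threaded output
  vc <- validated$csms
  vc <- vc[order(-vc$annikaScore, vc$sequenceAlpha, vc$sequenceBeta), ,
           drop = FALSE]
  rownames(vc) <- NULL
  validated$crosslinks <- groupCrosslinks(vc)
  validated$crosslinks <- (if (config$separateIntraInter) separatedFdr
                           else estimateFdr)(
    validated$crosslinks, config$fdr, "decoy")
  validated$csms <- vc
  tallies <- c(spectraRead = length(spectra),
               spectraSearched = length(spectra),
               csms = nrow(vc),
               csmsHigh = sum(vc$confidence == "high" & !vc$decoy),
               crosslinks = nrow(validated$crosslinks),
               crosslinksHigh = sum(validated$crosslinks$confidence == "high" &
                                      !validated$crosslinks$decoy))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeCsmTable(validated$csms, file.path(outDir, "csms.tsv"))
    writeCrosslinkTable(validated$crosslinks,
                        file.path(outDir, "crosslinks.tsv"))
    cfgPath <- file.path(outDir, "config.ini")
    writeRunConfig(config, cfgPath)
    log <- c(sprintf("xlms version %s",
                     as.character(utils::packageVersion("xlms"))),
             sprintf("spectra file: %s", spectraPath),
             sprintf("fasta: %s", paste(fastaPath, collapse = ", ")),
             paste(names(tallies), tallies, sep = " = "),
             "", "# configuration", readLines(cfgPath))
    writeLines(log, file.path(outDir, "run.log"))
  }
  invisible(list(csms = validated$csms, crosslinks = validated$crosslinks,
                 tallies = tallies, config = config))
}

.CONF_ORDER <- c(rejected = 0L, medium = 1L, high = 2L)

#' Export validated cross-links in xiView-compatible CSV
#'
#' One row per cross-link at or above the requested confidence, with
#' 1-based positions; `AbsPos` is the linked residue position within the
#' protein (`PepPos + LinkPos - 1`). Peptide-level fields come from the
#' cross-link's best CSM. Decoy cross-links are excluded unless
#' `includeDecoys`.
#'
#' @param crosslinks Validated cross-link data.frame (from [runSearch()] or
#'   [validateAll()]).
#' @param csms The CSM table the cross-links were grouped from.
#' @param path Output CSV path (`NULL` returns the data.frame only).
#' @param minConfidence `"high"` or `"medium"`.
#' @param includeDecoys Include decoy cross-links.
#' @return The exported data.frame, invisibly if `path` is given.
#' @export
exportXiview <- function(crosslinks, csms, path = NULL,
                         minConfidence = c("medium", "high"),
                         includeDecoys = FALSE) {
  minConfidence <- match.arg(minConfidence)
  keep <- .CONF_ORDER[crosslinks$confidence] >= .CONF_ORDER[[minConfidence]]
  if (!includeDecoys) keep <- keep & !crosslinks$decoy
  xl <- crosslinks[keep, , drop = FALSE]
  rows <- lapply(seq_len(nrow(xl)), function(i) {
    csm <- csms[xl$bestCsmRow[i], , drop = FALSE]
    ## orient the CSM's alpha/beta onto the cross-link's residue pair
    locA <- csm$locationsAlpha[[1L]]
    posA <- locA$start + csm$linkPosAlpha - 1L
    alphaIsFirst <- any(locA$accession == xl$proteinA[i] &
                          posA == xl$positionA[i])
    if (alphaIsFirst) {
      s1 <- "Alpha"; s2 <- "Beta"
    } else {
      s1 <- "Beta"; s2 <- "Alpha"
    }
    pick <- function(side, what) csm[[paste0(what, side)]]
    loc1 <- pick(s1, "locations")[[1L]]
    loc2 <- pick(s2, "locations")[[1L]]
    i1 <- which(loc1$accession == xl$proteinA[i] &
                  loc1$start + pick(s1, "linkPos") - 1L == xl$positionA[i])[1L]
    i2 <- which(loc2$accession == xl$proteinB[i] &
                  loc2$start + pick(s2, "linkPos") - 1L == xl$positionB[i])[1L]
    data.frame(
      Protein1 = xl$proteinA[i], Protein2 = xl$proteinB[i],
      PepSeq1 = pick(s1, "sequence"), PepSeq2 = pick(s2, "sequence"),
      PepPos1 = loc1$start[i1], PepPos2 = loc2$start[i2],
      LinkPos1 = pick(s1, "linkPos"), LinkPos2 = pick(s2, "linkPos"),
      AbsPos1 = xl$positionA[i], AbsPos2 = xl$positionB[i],
      Charge = csm$charge, Score = xl$score[i],
      Decoy1 = pick(s1, "decoy"), Decoy2 = pick(s2, "decoy"),
      stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(Protein1 = character(), Protein2 = character(),
               PepSeq1 = character(), PepSeq2 = character(),
               PepPos1 = integer(), PepPos2 = integer(),
               LinkPos1 = integer(), LinkPos2 = integer(),
               AbsPos1 = integer(), AbsPos2 = integer(),
               Charge = integer(), Score = numeric(),
               Decoy1 = logical(), Decoy2 = logical(),
               stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}
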