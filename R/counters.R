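## Lightweight operation counters used to verify the search cost model:
## the pairing work is proportional to (number of considered doublet pairs)
## x (number of spectra) and does not grow with database size.

.xlmsCounters <- new.env(parent = emptyenv())

#' Operation counters
#'
#' `resetOpCounters()` zeroes the instrumentation counters;
#' `opCounters()` returns them. `doubletPairOps` counts doublet-pair (and
#' doublet-plus-single-ion) combination evaluations in the detector;
#' `candidatePairOps` counts candidate peptide pairings in the search;
#' `fragmentMatchOps` counts scored candidate/link-position combinations.
#'
#' @return `opCounters()`: named numeric vector.
#' @export
resetOpCounters <- function() {
  assign("doubletPairOps", 0, envir = .xlmsCounters)
  assign("candidatePairOps", 0, envir = .xlmsCounters)
  assign("fragmentMatchOps", 0, envir = .xlmsCounters)
  invisible(NULL)
}

#' @rdname resetOpCounters
#' @export
opCounters <- function() {
  c(doubletPairOps = get0("doubletPairOps", envir = .xlmsCounters, ifnotfound = 0),
    candidatePairOps = get0("candidatePairOps", envir = .xlmsCounters, ifnotfound = 0),
    fragmentMatchOps = get0("fragmentMatchOps", envir = .xlmsCounters, ifnotfound = 0))
}

.bumpCounter <- function(name, by = 1) {
  cur <- get0(name, envir = .xlmsCounters, ifnotfound = 0)
  assign(name, cur + by, envir = .xlmsCounters)
}
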