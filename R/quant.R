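## MS1 extracted-ion chromatography and relative glycoform quantification.
## The relative peak intensity of an Sda glycoform versus its precursor
## glycoform on the same peptide is AUC(Sda) / (AUC(Sda) + AUC(precursor)),
## with AUCs summed over the configured charge states. Within one LC-MS run
## this ratio is a reproducible relative measure even though absolute
## ionization/detection efficiencies differ between glycoforms.

#' Extracted ion chromatogram (MS1)
#'
#' One point per MS1 scan in the retention-time window: the summed intensity
#' of peaks within `tolPpm` of the target m/z. Extraction is of the
#' monoisotopic peak only.
#'
#' @param run an [MsRun-class] with MS1 scans
#' @param mz target m/z
#' @param tolPpm tolerance in ppm (default 10, the MS1 search tolerance)
#' @param rtWindow optional numeric(2) retention-time window in minutes
#' @return data.frame (`rt`, `intensity`) with attributes `mz` and `tolPpm`
#' @export
xic <- function(run, mz, tolPpm = 10, rtWindow = NULL) {
  idx <- which(msLevels(run) == 1L)
  if (!length(idx)) stop("run contains no MS1 scans")
  if (!is.null(rtWindow)) {
    if (length(rtWindow) != 2L || rtWindow[1] >= rtWindow[2])
      stop("empty RT window")
    rt <- retentionTimes(run)[idx]
    idx <- idx[rt >= rtWindow[1] & rt <= rtWindow[2]]
    if (!length(idx)) stop("empty RT window")
  }
  rows <- lapply(run@scans[idx], function(sc) {
    within <- abs(sc@mz - mz) <= mz * tolPpm * 1e-6
    data.frame(rt = sc@rt, intensity = sum(sc@intensity[within]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "mz") <- mz
  attr(out, "tolPpm") <- tolPpm
  out
}

#' Area under an XIC trace
#'
#' Trapezoidal integration over retention time; non-negative and additive
#' over disjoint RT partitions.
#'
#' @param trace data.frame with `rt` and `intensity` (>= 2 points)
#' @return area in intensity * minutes
#' @export
aucTrace <- function(trace) {
  if (nrow(trace) < 2L) stop("AUC needs at least 2 trace points")
  pracma::trapz(trace$rt, trace$intensity)
}

#' Glycoform pair for relative quantification
#'
#' Pairs an Sda glycoform (A) with its precursor glycoform (B) on a shared
#' peptide; by construction glycan(A) = glycan(B) + 1 HexNAc.
#'
#' @param peptide shared peptide sequence
#' @param glycanB precursor-glycoform [GlycanComposition-class]
#' @param glycoClass `"N"` or `"O"`
#' @param charges charge states whose AUCs are summed (default 2:3)
#' @param mods applied modification data.frame shared by both glycoforms
#' @return a `GlycoformPair` list
#' @export
glycoformPair <- function(peptide, glycanB, glycoClass = c("N", "O"),
                          charges = 2:3, mods = NULL) {
  glycoClass <- match.arg(glycoClass)
  glycanA <- .glycanAdd(glycanB, hexnac = 1L)
  structure(list(peptide = peptide, glycanA = glycanA, glycanB = glycanB,
                 glycoClass = glycoClass, charges = as.integer(charges),
                 mods = mods),
            class = "GlycoformPair")
}

#' Relative peak intensity of an Sda glycoform
#'
#' Extracts MS1 XICs of the two glycoforms of a [glycoformPair()] at every
#' configured charge, integrates the AUCs, sums them per glycoform and
#' returns `100 * AUC_A / (AUC_A + AUC_B)` (percent). The complement
#' property holds: value(A vs B) + value(B vs A) = 100. When both AUCs are
#' zero the ratio is undefined and reported as NA.
#'
#' An Sda-extended composition can be isomeric with a bisecting-GlcNAc
#' glycoform; the result is therefore flagged `ambiguous` unless MS2
#' evidence for the Sda diagnostic ion (m/z 860.3143) near glycoform A's
#' precursor is supplied via `diagnosticCandidates` (see
#' [flagCandidates()]) or `diagnosticConfirmed = TRUE`.
#'
#' @param run an [MsRun-class] with MS1 scans
#' @param pair a [glycoformPair()]
#' @param tolPpm XIC tolerance in ppm (default 10)
#' @param rtWindow optional RT window passed to [xic()]
#' @param diagnosticCandidates optional candidate table from
#'   [flagCandidates()] used to resolve composition ambiguity
#' @param diagnosticConfirmed set TRUE when Sda identity of glycoform A is
#'   already established (e.g. by an accepted PSM with the 860.31 flag)
#' @return a one-row data.frame: `peptide`, `glycanA`, `glycanB`, `aucA`,
#'   `aucB`, `percentSda`, `ambiguous`
#' @export
relativePeakIntensity <- function(run, pair, tolPpm = 10, rtWindow = NULL,
                                  diagnosticCandidates = NULL,
                                  diagnosticConfirmed = FALSE) {
  pm <- peptideMass(pair$peptide, pair$mods)
  mA <- pm + glycanMass(pair$glycanA)
  mB <- pm + glycanMass(pair$glycanB)
  sumAuc <- function(m) {
    sum(vapply(pair$charges, function(z) {
      aucTrace(xic(run, .massToMz(m, z), tolPpm = tolPpm,
                   rtWindow = rtWindow))
    }, numeric(1)))
  }
  aucA <- sumAuc(mA); aucB <- sumAuc(mB)
  pct <- if (aucA + aucB == 0) NA_real_ else 100 * aucA / (aucA + aucB)
  confirmed <- isTRUE(diagnosticConfirmed)
  if (!confirmed && !is.null(diagnosticCandidates) &&
      nrow(diagnosticCandidates)) {
    mzA <- .massToMz(mA, pair$charges)
    confirmed <- any(vapply(seq_len(nrow(diagnosticCandidates)), function(i)
      any(abs(diagnosticCandidates$precursorMz[i] - mzA) <= 2.5),
      logical(1)))
  }
  data.frame(peptide = pair$peptide,
             glycanA = glycanName(pair$glycanA),
             glycanB = glycanName(pair$glycanB),
             aucA = aucA, aucB = aucB, percentSda = pct,
             ambiguous = !confirmed, stringsAsFactors = FALSE)
}
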