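## Run-wide MS2 chromatogram of the Sda diagnostic oxonium ion. Screening
## every MS2 scan for m/z 860.3143 (NeuAc1Hex1HexNAc2)+ discovers candidate
## Sda-carrying precursors independently of the database search; candidates
## are only confirmed downstream by matching (a diagnostic peak alone cannot
## rule out unrelated co-isolated ions).

#' MS2 diagnostic-ion trace
#'
#' One point per MS2 scan in the run: the intensity of the most intense peak
#' within `tolPpm` of `targetMz`, or 0 when none lies within tolerance. The
#' default 20 ppm window (about +/-0.017 at m/z 860) also covers the ion
#' when it is measured slightly high, around m/z 860.32. MS1 scans never
#' contribute.
#'
#' @param run an [MsRun-class] with MS2 scans
#' @param targetMz diagnostic ion m/z (default 860.3143, the Sda oxonium)
#' @param tolPpm match tolerance in ppm (default 20, the MS2 tolerance)
#' @return data.frame (`scanNum`, `rt`, `intensity`) with attributes
#'   `targetMz` and `tolPpm`
#' @export
ms2DiagnosticTrace <- function(run, targetMz = 860.3143, tolPpm = 20) {
  idx <- which(msLevels(run) == 2L)
  if (!length(idx)) stop("run contains no MS2 scans")
  rows <- lapply(run@scans[idx], function(sc) {
    within <- abs(sc@mz - targetMz) <= targetMz * tolPpm * 1e-6
    data.frame(scanNum = sc@scanNum, rt = sc@rt,
               intensity = if (any(within)) max(sc@intensity[within]) else 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "targetMz") <- targetMz
  attr(out, "tolPpm") <- tolPpm
  out
}

#' Candidate scans from a diagnostic trace
#'
#' Scans whose diagnostic-ion intensity is nonzero and at least
#' `minIntensity`, annotated with precursor m/z and charge, sorted by
#' intensity (descending). Scans from the same precursor are de-duplicated:
#' candidates within +/-2.5 m/z (the 5 m/z isolation window) and +/-0.2 min
#' of a stronger candidate are grouped under it.
#'
#' @param trace output of [ms2DiagnosticTrace()]
#' @param run the [MsRun-class] the trace was computed from
#' @param minIntensity minimum diagnostic-ion intensity (default 0: all
#'   scans with a nonzero diagnostic peak)
#' @param groupMzTol,groupRtTol de-duplication windows (m/z units, minutes)
#' @return data.frame: `scanNum`, `rt`, `intensity`, `precursorMz`,
#'   `precursorCharge`, `nScans` (number of grouped scans)
#' @export
flagCandidates <- function(trace, run, minIntensity = 0,
                           groupMzTol = 2.5, groupRtTol = 0.2) {
  hits <- trace[trace$intensity > 0 & trace$intensity >= minIntensity, ,
                drop = FALSE]
  if (!nrow(hits)) return(.emptyCandidates())
  scanIdx <- match(hits$scanNum,
                   vapply(run@scans, slot, integer(1), "scanNum"))
  hits$precursorMz <- vapply(run@scans[scanIdx], slot, numeric(1),
                             "precursorMz")
  hits$precursorCharge <- vapply(run@scans[scanIdx], slot, integer(1),
                                 "precursorCharge")
  hits <- hits[order(-hits$intensity), , drop = FALSE]
  taken <- rep(FALSE, nrow(hits))
  out <- list()
  for (i in seq_len(nrow(hits))) {
    if (taken[i]) next
    grp <- !taken &
      abs(hits$precursorMz - hits$precursorMz[i]) <= groupMzTol &
      abs(hits$rt - hits$rt[i]) <= groupRtTol
    taken[grp] <- TRUE
    row <- hits[i, , drop = FALSE]
    row$nScans <- sum(grp)
    out[[length(out) + 1L]] <- row
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.emptyCandidates <- function() {
  data.frame(scanNum = integer(), rt = numeric(), intensity = numeric(),
             precursorMz = numeric(), precursorCharge = integer(),
             nScans = integer())
}
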