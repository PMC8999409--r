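#' Run the full Sda glycoproteomic pipeline on a run
#'
#' Ties the stages together in the order of the workflow: the MS2
#' diagnostic-ion screen, glycopeptide-spectrum matching with target-decoy
#' FDR, and relative glycoform quantification of every accepted Sda PSM
#' against its -1 HexNAc precursor glycoform (with composition-ambiguity
#' resolution from the screen). Identical inputs and configuration give
#' identical results.
#'
#' @param run an [MsRun-class]
#' @param proteins named character vector of target protein sequences
#'   (default: the synthetic carrier collection, [sdaProteins()])
#' @param glycanLibrary glycan library data.frame
#' @param config a [searchConfig()]
#' @param quantCharges charge states summed during quantification
#' @return list with `screen` (candidate table), `psms` (all matches),
#'   `accepted`, `fdr`, `quant` (one row per quantified Sda glycoform pair)
#'   and `counts` (the verification funnel)
#' @export
runPipeline <- function(run, proteins = sdaProteins(),
                        glycanLibrary = readGlycanLibrary(),
                        config = searchConfig(), quantCharges = 2:3) {
  trace <- ms2DiagnosticTrace(run, tolPpm = config$ms2TolPpm)
  screen <- flagCandidates(trace, run)
  cands <- generateCandidates(proteins, glycanLibrary, config)
  psms <- matchRun(run, cands, config)
  flt <- fdrFilter(psms, config$scoreCutoff)
  accepted <- flt$accepted

  sdaHits <- accepted[accepted$sda, , drop = FALSE]
  quant <- NULL
  if (nrow(sdaHits) && any(msLevels(run) == 1L)) {
    keys <- !duplicated(sdaHits[c("peptide", "glycanName")])
    quant <- do.call(rbind, lapply(which(keys), function(i) {
      hit <- sdaHits[i, ]
      gA <- .libGlycan(glycanLibrary, hit$glycanName)
      pair <- glycoformPair(hit$peptide, .glycanAdd(gA, hexnac = -1L),
                            glycoClass = hit$glycoClass,
                            charges = quantCharges,
                            mods = .applyMods(hit$peptide,
                                              config$modifications, hit$nOx))
      cbind(protein = hit$protein,
            relativePeakIntensity(run, pair,
                                  diagnosticCandidates = screen,
                                  diagnosticConfirmed = hit$flagSda860))
    }))
  }
  counts <- c(ms2Triplets = length(.ms2Triplets(run)),
              screenCandidates = nrow(screen), psms = nrow(psms),
              verified = sum(psms$verified), accepted = nrow(accepted),
              acceptedSda = nrow(sdaHits))
  list(screen = screen, psms = psms, accepted = accepted, fdr = flt$fdr,
       quant = quant, counts = counts)
}
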