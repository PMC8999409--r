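## Readers and writers: MGF (text peak lists, written here since the format
## is a few key-value pairs per scan), mzML through the mzR backend when
## available, ground truth as JSON, and TSV reports mirroring the
## glycoprotein/glycosite summary tables of the workflow.

#' Write a run as MGF
#'
#' MS2 scans are written as `BEGIN IONS` blocks with `TITLE`, `SCANS`,
#' `RTINSECONDS`, `PEPMASS`, `CHARGE` and a non-standard `NCE` key that this
#' package's reader understands. MS1 scans carry no peak-list representation
#' in MGF and are skipped with a warning when present.
#'
#' @param run an [MsRun-class]
#' @param path output file
#' @export
writeMgf <- function(run, path) {
  lv <- msLevels(run)
  if (any(lv == 1L))
    warning("MGF holds MS2 scans only; ", sum(lv == 1L),
            " MS1 scans skipped (use writeMzML to keep them)")
  con <- file(path, "w")
  on.exit(close(con))
  for (sc in run@scans[lv == 2L]) {
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=scan=", sc@scanNum),
      paste0("SCANS=", sc@scanNum),
      paste0("RTINSECONDS=", format(sc@rt * 60, digits = 10)),
      paste0("PEPMASS=", format(sc@precursorMz, digits = 12)),
      paste0("CHARGE=", sc@precursorCharge, "+"),
      if (!is.na(sc@nce)) paste0("NCE=", sc@nce),
      sprintf("%.6f %.4f", sc@mz, sc@intensity),
      "END IONS", ""), con)
  }
  invisible(path)
}

#' Read an MGF file
#'
#' @param path MGF file with `RTINSECONDS`, `PEPMASS` and `CHARGE` per scan;
#'   a scan lacking a retention time is an error naming the offending scan
#' @return an [MsRun-class] (MS2 scans only)
#' @export
readMgf <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !any(lines == "BEGIN IONS"))
    stop("empty or malformed MGF file: ", path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends)) stop("unbalanced BEGIN/END IONS")
  scans <- vector("list", length(begins))
  counter <- 0L
  for (b in seq_along(begins)) {
    block <- lines[(begins[b] + 1L):(ends[b] - 1L)]
    kv <- grepl("=", block, fixed = TRUE)
    keys <- sub("=.*$", "", block[kv])
    vals <- sub("^[^=]*=", "", block[kv])
    getv <- function(key) if (key %in% keys) vals[match(key, keys)] else NA
    title <- getv("TITLE")
    rtSec <- getv("RTINSECONDS")
    if (is.na(rtSec))
      stop("MGF scan ", if (!is.na(title)) title else b,
           " lacks RTINSECONDS")
    pep <- getv("PEPMASS")
    if (is.na(pep))
      stop("MGF scan ", if (!is.na(title)) title else b, " lacks PEPMASS")
    z <- getv("CHARGE")
    nce <- getv("NCE")
    scanId <- getv("SCANS")
    peakLines <- block[!kv]
    peakLines <- peakLines[nzchar(trimws(peakLines))]
    pk <- if (length(peakLines)) {
      m <- do.call(rbind, strsplit(trimws(peakLines), "[ \t]+"))
      cbind(as.numeric(m[, 1]), as.numeric(m[, 2]))
    } else cbind(numeric(), numeric())
    counter <- counter + 1L
    scans[[b]] <- MsScan(
      scanNum = if (!is.na(scanId)) as.integer(scanId) else counter,
      msLevel = 2L, rt = as.numeric(rtSec) / 60,
      mz = pk[, 1], intensity = pk[, 2],
      precursorMz = as.numeric(sub("\\s.*$", "", pep)),
      precursorCharge = if (!is.na(z)) as.integer(sub("\\+$", "", z))
                        else NA_integer_,
      nce = if (!is.na(nce)) as.numeric(nce) else NA_real_)
  }
  MsRun(scans, metadata = list(source = path))
}

#' Write a run as mzML (mzR backend)
#'
#' Preserves both MS levels, retention times, precursor metadata and
#' collision energies. Requires the `mzR` package.
#'
#' @param run an [MsRun-class]
#' @param path output mzML file
#' @export
writeMzML <- function(run, path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("writing mzML requires the mzR package")
  scans <- run@scans
  n <- length(scans)
  pks <- lapply(scans, function(sc) cbind(mz = sc@mz, intensity = sc@intensity))
  num <- function(f) vapply(scans, f, numeric(1))
  int <- function(f) vapply(scans, f, integer(1))
  lv <- int(function(sc) sc@msLevel)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = int(function(sc) sc@scanNum),
    msLevel = lv, polarity = 1L,
    peaksCount = vapply(pks, nrow, integer(1)),
    totIonCurrent = num(function(sc) sum(sc@intensity)),
    retentionTime = num(function(sc) sc@rt * 60),
    basePeakMZ = num(function(sc)
      if (length(sc@mz)) sc@mz[which.max(sc@intensity)] else 0),
    basePeakIntensity = num(function(sc)
      if (length(sc@intensity)) max(sc@intensity) else 0),
    collisionEnergy = num(function(sc) sc@nce),
    ionisationEnergy = 0,
    lowMZ = num(function(sc) if (length(sc@mz)) min(sc@mz) else 0),
    highMZ = num(function(sc) if (length(sc@mz)) max(sc@mz) else 0),
    precursorScanNum = ifelse(lv == 2L, 0L, NA_integer_),
    precursorMZ = num(function(sc) sc@precursorMz),
    precursorCharge = int(function(sc) sc@precursorCharge),
    precursorIntensity = ifelse(lv == 2L, 0, NA_real_),
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", int(function(sc) sc@scanNum)),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = num(function(sc) sc@precursorMz),
    isolationWindowLowerOffset = ifelse(lv == 2L, 2.5, NA_real_),
    isolationWindowUpperOffset = ifelse(lv == 2L, 2.5, NA_real_),
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_)
  mzR::writeMSData(pks, path, header = hdr)
  invisible(path)
}

#' Read spectra from mzML or MGF
#'
#' Dispatches on file extension. mzML reading uses the mzR backend and
#' preserves MS level, retention time, precursor m/z and charge, and
#' collision energy; scans are ordered by retention time.
#'
#' @param path `.mzML` or `.mgf` file
#' @return an [MsRun-class]
#' @export
readSpectra <- function(path) {
  if (grepl("\\.mgf$", path, ignore.case = TRUE)) return(readMgf(path))
  if (!grepl("\\.mzml$", path, ignore.case = TRUE))
    stop("unsupported spectra format: ", path)
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the mzR package")
  f <- mzR::openMSfile(path)
  on.exit(mzR::close(f))
  hdr <- mzR::header(f)
  if (!nrow(hdr)) stop("empty mzML file: ", path)
  scans <- lapply(seq_len(nrow(hdr)), function(i) {
    pk <- mzR::peaks(f, i)
    if (is.null(dim(pk))) pk <- matrix(pk, ncol = 2)
    lv <- hdr$msLevel[i]
    if (lv == 2L && (is.na(hdr$precursorMZ[i]) || hdr$precursorMZ[i] <= 0))
      stop("MS2 scan ", hdr$acquisitionNum[i], " lacks precursor metadata")
    MsScan(hdr$acquisitionNum[i], lv, hdr$retentionTime[i] / 60,
           pk[, 1], pk[, 2],
           precursorMz = if (lv == 2L) hdr$precursorMZ[i] else NA_real_,
           precursorCharge = if (lv == 2L) hdr$precursorCharge[i]
                             else NA_integer_,
           nce = if (lv == 2L && !is.na(hdr$collisionEnergy[i]))
                   hdr$collisionEnergy[i] else NA_real_)
  })
  MsRun(scans, metadata = list(source = path))
}

#' Write ground truth as JSON
#'
#' @param truth the `truth` element of [simulateRun()]'s result
#' @param path output JSON file
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Write the PSM report
#'
#' TSV mirroring the summary-table layout of the workflow: shortened
#' protein ID, peptide, residue range, glycosite, glycan composition and
#' class, plus the machine columns (score, precursor ppm error, verification
#' flags, scan numbers).
#'
#' @param accepted accepted PSM data.frame (see [fdrFilter()])
#' @param path output TSV
#' @export
writePsmReport <- function(accepted, path) {
  rep <- data.frame(
    protein = accepted$protein, peptide = accepted$peptide,
    residues = paste0(accepted$start, "-", accepted$end),
    glycosite = accepted$glycosite, glycan = accepted$glycanName,
    glycoClass = accepted$glycoClass, sda = accepted$sda,
    score = round(accepted$score, 2),
    ppmError = round(accepted$ppmErrorPrec, 2),
    flagPepHexNAc = accepted$flagPepHexNAc, flagPep = accepted$flagPep,
    flagNeuAcPair = accepted$flagNeuAcPair,
    flagSda860 = accepted$flagSda860, rescued = accepted$rescued,
    scanNums = accepted$scanNums, stringsAsFactors = FALSE)
  utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the quantification report
#'
#' @param results data.frame of [relativePeakIntensity()] rows
#' @param path output TSV
#' @export
writeQuantReport <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Synthetic protein collection for the simulated samples
#'
#' Short synthetic carrier sequences, each embedding one or two of the
#' documented glycopeptides between tryptic cleavage sites. These are *not*
#' the real UniProt sequences (which are not shipped); they exist so that
#' digestion, candidate generation and decoy construction can run
#' self-contained. The FASTA lives in `extdata/synthetic_proteins.fasta`.
#'
#' @return named character vector of sequences
#' @export
sdaProteins <- function() {
  readProteinFasta(system.file("extdata", "synthetic_proteins.fasta",
                               package = "GlycoSda"))
}
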