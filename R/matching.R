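## Glycopeptide-spectrum matching. Each selected precursor is acquired as an
## NCE 20/30/40 triplet; candidates within the MS1 tolerance are scored
## against the whole triplet, the best candidate per precursor is retained,
## verification rules are applied (peptide+HexNAc ion for N-glycopeptides,
## bare peptide ion for O-glycopeptides, NeuAc oxonium pair 274.09/292.10
## for sialylated glycans), and target-decoy FDR is estimated from reversed
## sequences.

## score = sum over matched theoretical ions of
##           classWeight * log10(1 + 100 * I / basepeak),
## summed over the NCE triplet. This is the package's own documented score;
## cutoffs from proprietary search engines are not portable to it.
.SCORE_WEIGHTS <- c(glycosidic = 1, oxonium = 0.5, backbone = 1)

#' Search configuration
#'
#' Defaults mirror the workflow's settings: 10 ppm MS1 and 20 ppm MS2
#' tolerance, trypsin with two missed cleavages, methylthio on Cys (static)
#' and up to two Met oxidations (variable), precursor charges 2-7. The score
#' cutoff lives on the package's own score scale (see [fdrFilter()]); its
#' default of 8 was calibrated once on simulated null runs so that decoy and
#' noise matches score well below it while planted identities score far
#' above.
#'
#' @param ms1TolPpm,ms2TolPpm mass tolerances in ppm (strictly positive)
#' @param scoreCutoff acceptance cutoff on the package score
#' @param protease protease name for digestion
#' @param missedCleavages maximum missed cleavages
#' @param chargeRange precursor charges considered
#' @param maxOxidation maximum variable Met oxidations per peptide
#' @param modifications modification set (see [defaultModifications()])
#' @return a `SearchConfig` list
#' @export
searchConfig <- function(ms1TolPpm = 10, ms2TolPpm = 20, scoreCutoff = 8,
                         protease = "trypsin", missedCleavages = 2L,
                         chargeRange = 2:7, maxOxidation = 2L,
                         modifications = defaultModifications()) {
  stopifnot(ms1TolPpm > 0, ms2TolPpm > 0)
  structure(list(ms1TolPpm = ms1TolPpm, ms2TolPpm = ms2TolPpm,
                 scoreCutoff = scoreCutoff, protease = protease,
                 missedCleavages = missedCleavages, chargeRange = chargeRange,
                 maxOxidation = maxOxidation, modifications = modifications),
            class = "SearchConfig")
}

## positions of N-sequons (N-X-S/T, X != P) in a peptide
.sequonSites <- function(pep) {
  res <- strsplit(pep, "")[[1]]
  n <- length(res)
  if (n < 3L) return(integer())
  i <- which(res == "N")
  i <- i[i + 2L <= n]
  i[res[i + 1L] != "P" & res[i + 2L] %in% c("S", "T")]
}

#' Build the glycopeptide candidate search space
#'
#' Digests every protein (targets plus reversed decoys when `decoys = TRUE`),
#' keeps peptides bearing an N-sequon (crossed with N-class library glycans)
#' or a Ser/Thr (crossed with O-class glycans), and expands variable Met
#' oxidation up to `config$maxOxidation`.
#'
#' @param proteins named character vector of protein sequences
#' @param glycanLibrary data.frame from [readGlycanLibrary()]
#' @param config a [searchConfig()]
#' @param decoys append reversed-sequence decoys (default TRUE)
#' @param lengthBounds passed to [digest()] (pronase only unless given)
#' @return data.frame of candidates, one row per
#'   (peptide, modification state, glycan) with precomputed neutral mass
#' @export
generateCandidates <- function(proteins, glycanLibrary = readGlycanLibrary(),
                               config = searchConfig(), decoys = TRUE,
                               lengthBounds = NULL) {
  if (!nrow(glycanLibrary)) stop("empty glycan library")
  if (!length(proteins)) stop("empty protein collection")
  if (decoys) proteins <- withDecoys(proteins)
  nlib <- glycanLibrary[glycanLibrary$class == "N", , drop = FALSE]
  olib <- glycanLibrary[glycanLibrary$class == "O", , drop = FALSE]

  peps <- do.call(rbind, lapply(names(proteins), function(id)
    digest(proteins[[id]], config$protease,
           missedCleavages = config$missedCleavages,
           lengthBounds = lengthBounds, protein_id = id)))
  peps <- peps[!duplicated(peps[c("sequence", "protein")]), , drop = FALSE]

  rows <- list()
  for (i in seq_len(nrow(peps))) {
    pep <- peps$sequence[i]
    res <- strsplit(pep, "")[[1]]
    if (any(!res %in% names(.aaMass()))) next
    nOxMax <- min(config$maxOxidation, sum(res == "M"))
    seqons <- .sequonSites(pep)
    hasST <- any(res %in% c("S", "T"))
    for (nOx in 0:nOxMax) {
      mods <- .applyMods(pep, config$modifications, nOx)
      basePm <- peptideMass(pep, mods)
      addLib <- function(lib, cls, site) {
        if (!nrow(lib)) return()
        for (j in seq_len(nrow(lib))) {
          rows[[length(rows) + 1L]] <<- data.frame(
            protein = peps$protein[i], peptide = pep,
            start = peps$start[i], end = peps$end[i],
            glycoClass = cls, glycanName = lib$name[j],
            hex = lib$hex[j], hexnac = lib$hexnac[j],
            neuac = lib$neuac[j], dhex = lib$dhex[j],
            sda = lib$sda[j], nOx = nOx, glycosite = site,
            neutralMass = basePm + lib$mass[j],
            decoy = startsWith(peps$protein[i], "decoy_"),
            stringsAsFactors = FALSE)
        }
      }
      if (length(seqons)) addLib(nlib, "N", seqons[1L])
      if (hasST) addLib(olib, "O", which(res %in% c("S", "T"))[1L])
    }
  }
  if (!length(rows))
    stop("no glycopeptide candidates (no sequon or Ser/Thr peptides)")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## candidate row -> Glycopeptide
.candidateGp <- function(cand, config = searchConfig()) {
  Glycopeptide(cand$peptide,
               GlycanComposition(cand$hex, cand$hexnac, cand$neuac, cand$dhex),
               glycoClass = cand$glycoClass, glycosite = cand$glycosite,
               mods = .applyMods(cand$peptide, config$modifications, cand$nOx),
               sda = cand$sda)
}

## nearest observed peak within tol (ppm) of each target m/z;
## returns list(matched = logical, intensity = numeric)
.matchPeaks <- function(targets, mz, intensity, tolPpm) {
  if (!length(mz))
    return(list(matched = rep(FALSE, length(targets)),
                intensity = rep(0, length(targets))))
  idx <- findInterval(targets, mz)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(mz))
  dLo <- abs(mz[lo] - targets)
  dHi <- abs(mz[hi] - targets)
  best <- ifelse(dLo <= dHi, lo, hi)
  d <- abs(mz[best] - targets)
  matched <- d <= targets * tolPpm * 1e-6
  list(matched = matched, intensity = ifelse(matched, intensity[best], 0))
}

## group the MS2 scans of a run into stepped-NCE triplets (consecutive MS2
## scans sharing the same precursor m/z)
.ms2Triplets <- function(run) {
  idx <- which(msLevels(run) == 2L)
  if (!length(idx)) stop("run contains no MS2 scans")
  groups <- list()
  cur <- idx[1L]
  curMz <- run@scans[[idx[1L]]]@precursorMz
  for (i in idx[-1L]) {
    pmz <- run@scans[[i]]@precursorMz
    if (abs(pmz - curMz) < 0.005 && length(cur) < 3L) {
      cur <- c(cur, i)
    } else {
      groups[[length(groups) + 1L]] <- cur
      cur <- i; curMz <- pmz
    }
  }
  groups[[length(groups) + 1L]] <- cur
  groups
}

## score one candidate against one triplet; also computes verification flags
.scoreCandidate <- function(gp, scans, config) {
  score <- 0; nMatched <- 0L
  pm <- peptideMass(gp)
  pepHexNAcMz <- .massToMz(pm + .MASS$hexnac, 1:2)
  pepMz <- .massToMz(pm, 1:2)
  neuacMz <- c(oxoniumMz(GlycanComposition(neuac = 1), 1L),
               oxoniumMz(GlycanComposition(neuac = 1), 0L))
  sdaMz <- oxoniumMz(GlycanComposition(hex = 1, hexnac = 2, neuac = 1))
  flagPepHexNAc <- FALSE; flagPep <- FALSE
  flagNeuAcPair <- c(FALSE, FALSE); flagSda <- FALSE
  for (sc in scans) {
    theo <- theoreticalSpectrum(gp, sc@nce)
    m <- .matchPeaks(theo$mz, sc@mz, sc@intensity, config$ms2TolPpm)
    if (any(m$matched)) {
      base <- max(sc@intensity)
      rel <- 100 * m$intensity[m$matched] / base
      score <- score + sum(.SCORE_WEIGHTS[theo$class[m$matched]] *
                             log10(1 + rel))
      nMatched <- nMatched + sum(m$matched)
    }
    chk <- function(mzs) any(.matchPeaks(mzs, sc@mz, sc@intensity,
                                         config$ms2TolPpm)$matched)
    flagPepHexNAc <- flagPepHexNAc || chk(pepHexNAcMz)
    flagPep <- flagPep || chk(pepMz)
    flagNeuAcPair <- flagNeuAcPair |
      c(chk(neuacMz[1]), chk(neuacMz[2]))
    flagSda <- flagSda || chk(sdaMz)
  }
  list(score = score, nMatched = nMatched,
       flagPepHexNAc = flagPepHexNAc, flagPep = flagPep,
       flagNeuAcPair = all(flagNeuAcPair), flagSda860 = flagSda)
}

## required verification rules: N-class -> peptide+HexNAc ion, O-class ->
## bare peptide ion, any NeuAc-containing glycan -> both 274.09 and 292.10
.verified <- function(cand, flags) {
  ok <- if (cand$glycoClass == "N") flags$flagPepHexNAc else flags$flagPep
  if (cand$neuac > 0L) ok <- ok && flags$flagNeuAcPair
  ok
}

#' Match a run against a candidate space
#'
#' For every stepped-NCE MS2 triplet, candidates whose precursor m/z at the
#' scan's charge lies within the MS1 tolerance are scored against the
#' triplet; the best verified candidate per precursor is retained (ties are
#' broken deterministically by matched-ion count, then peptide, then glycan
#' name). Verification flags are computed from the spectra, never asserted.
#'
#' @param run an [MsRun-class] with MS2 scans
#' @param candidates data.frame from [generateCandidates()]
#' @param config a [searchConfig()]
#' @return data.frame of glycopeptide-spectrum matches (one row per
#'   precursor triplet that had at least one candidate in tolerance) with
#'   scores, ppm errors, verification flags, `verified` and `decoy` columns
#' @export
matchRun <- function(run, candidates, config = searchConfig()) {
  groups <- .ms2Triplets(run)
  psms <- list()
  gpCache <- new.env(parent = emptyenv())
  for (grp in groups) {
    scansG <- run@scans[grp]
    s1 <- scansG[[1L]]
    zs <- if (!is.na(s1@precursorCharge)) s1@precursorCharge
          else config$chargeRange
    hits <- NULL
    for (z in zs) {
      obsNeutral <- (s1@precursorMz - .MASS$proton) * z
      ppm <- (obsNeutral - candidates$neutralMass) /
        candidates$neutralMass * 1e6
      sel <- which(abs(ppm) <= config$ms1TolPpm)
      if (length(sel))
        hits <- rbind(hits, data.frame(idx = sel, z = z, ppm = ppm[sel]))
    }
    if (is.null(hits)) next
    scored <- lapply(seq_len(nrow(hits)), function(k) {
      cand <- candidates[hits$idx[k], ]
      key <- paste(cand$peptide, cand$glycanName, cand$nOx, cand$glycoClass,
                   sep = "|")
      gp <- if (!is.null(gpCache[[key]])) gpCache[[key]]
            else gpCache[[key]] <- .candidateGp(cand, config)
      fl <- .scoreCandidate(gp, scansG, config)
      c(fl, list(cand = cand, z = hits$z[k], ppm = hits$ppm[k],
                 ok = .verified(cand, fl)))
    })
    ord <- order(-vapply(scored, function(s) s$ok, logical(1)),
                 -vapply(scored, `[[`, numeric(1), "score"),
                 -vapply(scored, `[[`, integer(1), "nMatched"),
                 vapply(scored, function(s) s$cand$peptide, character(1)),
                 vapply(scored, function(s) s$cand$glycanName, character(1)))
    best <- scored[[ord[1L]]]
    cand <- best$cand
    psms[[length(psms) + 1L]] <- data.frame(
      scanNums = paste(vapply(scansG, slot, integer(1), "scanNum"),
                       collapse = ";"),
      rt = s1@rt, precursorMz = s1@precursorMz, z = best$z,
      protein = cand$protein, peptide = cand$peptide,
      start = cand$start, end = cand$end, glycosite = cand$glycosite,
      glycanName = cand$glycanName, glycoClass = cand$glycoClass,
      sda = cand$sda, nOx = cand$nOx,
      score = best$score, nMatched = best$nMatched, ppmErrorPrec = best$ppm,
      flagPepHexNAc = best$flagPepHexNAc, flagPep = best$flagPep,
      flagNeuAcPair = best$flagNeuAcPair, flagSda860 = best$flagSda860,
      verified = best$ok, decoy = cand$decoy, rescued = FALSE,
      stringsAsFactors = FALSE)
  }
  if (!length(psms)) return(.emptyPsms())
  out <- do.call(rbind, psms)
  rownames(out) <- NULL
  out
}

.emptyPsms <- function() {
  data.frame(scanNums = character(), rt = numeric(), precursorMz = numeric(),
             z = integer(), protein = character(), peptide = character(),
             start = integer(), end = integer(), glycosite = integer(),
             glycanName = character(), glycoClass = character(),
             sda = logical(), nOx = integer(), score = numeric(),
             nMatched = integer(), ppmErrorPrec = numeric(),
             flagPepHexNAc = logical(), flagPep = logical(),
             flagNeuAcPair = logical(), flagSda860 = logical(),
             verified = logical(), decoy = logical(), rescued = logical(),
             stringsAsFactors = FALSE)
}

#' Target-decoy FDR filtering with glycoform rescue
#'
#' The accepted set is the verified target PSMs with score at or above the
#' cutoff; the FDR estimate is (verified decoys above cutoff) / (verified
#' targets above cutoff). With zero targets above the cutoff the FDR is
#' undefined and reported as NA. When `rescue = TRUE`, verified
#' below-cutoff target PSMs whose peptide is already in the accepted set are
#' added as alternative glycoforms of an accepted peptide (flagged
#' `rescued`); rescue can only ever add PSMs of already-accepted peptides.
#'
#' @param psms data.frame from [matchRun()]
#' @param scoreCutoff acceptance cutoff (package score scale)
#' @param rescue enable alternative-glycoform rescue (default TRUE)
#' @return list with `accepted` (data.frame), `fdr` (proportion, NA when
#'   undefined), `nTarget`, `nDecoy`
#' @export
fdrFilter <- function(psms, scoreCutoff = searchConfig()$scoreCutoff,
                      rescue = TRUE) {
  above <- psms$verified & psms$score >= scoreCutoff
  nTarget <- sum(above & !psms$decoy)
  nDecoy <- sum(above & psms$decoy)
  fdr <- if (nTarget == 0L) NA_real_ else nDecoy / nTarget
  accepted <- psms[above & !psms$decoy, , drop = FALSE]
  if (rescue && nrow(accepted)) {
    keep <- psms$verified & !psms$decoy & psms$score < scoreCutoff &
      psms$peptide %in% accepted$peptide
    if (any(keep)) {
      resc <- psms[keep, , drop = FALSE]
      resc$rescued <- TRUE
      accepted <- rbind(accepted, resc)
    }
  }
  rownames(accepted) <- NULL
  list(accepted = accepted, fdr = fdr, nTarget = nTarget, nDecoy = nDecoy)
}
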