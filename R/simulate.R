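## Ground-truth run simulator. Emulates the acquisition scheme of the
## workflow: MS1 survey scans over m/z 600-2000, data-dependent selection of
## precursors with charge 2-7 through a 5 m/z isolation window, and a
## stepped-NCE 20/30/40 HCD triplet per selected precursor. Planted species
## elute as Gaussian chromatographic peaks with 4-isotope envelopes from a
## simple averagine-style model; all randomness flows from the manifest
## seed.

.defaultInstrument <- function() list(
  mzRange = c(600, 2000),       # MS1 survey range
  ms1Interval = 0.05,           # minutes per duty cycle (~3 s)
  nce = c(20, 30, 40),          # stepped collision energies per precursor
  isolationWindow = 5,          # m/z units
  chargeRange = 2:7,
  selectionThreshold = 5e3,     # minimum apex intensity for MS2 selection
  ppmJitterSd = 2,              # per-peak mass-error SD, ppm
  ms2Scale = 0.2)               # fragment intensity relative to precursor

.defaultNoise <- function() list(
  ms1Peaks = 40,                # expected noise peaks per MS1 scan
  ms2Peaks = 25,                # expected noise peaks per MS2 scan
  logMean = log(100), logSd = 1,   # log-normal noise intensities
  ms2Rate = 0.05)               # noise-precursor MS2 triplets per cycle

#' Build a simulation manifest
#'
#' @param species data.frame of planted glycoforms, as produced by
#'   [plantedSpecies()]; may have zero rows (pure-noise run)
#' @param instrument,noise named lists overriding the instrument and noise
#'   defaults (see the methods vignette)
#' @param gradient numeric(2) gradient window in minutes (default 0-90)
#' @param seed integer seed; mandatory
#' @return a [RunManifest-class]
#' @export
runManifest <- function(species = plantedSpecies(), instrument = list(),
                        noise = list(), gradient = c(0, 90), seed) {
  if (missing(seed)) stop("a seed is mandatory")
  inst <- utils::modifyList(.defaultInstrument(), instrument)
  nz <- utils::modifyList(.defaultNoise(), noise)
  new("RunManifest", species = species, instrument = inst, noise = nz,
      gradient = as.numeric(gradient), seed = as.integer(seed))
}

#' Planted-species table
#'
#' Assembles (or starts empty) the species table of a [runManifest()]. Each
#' row is one glycoform of one glycopeptide: the peptide, its glycan (looked
#' up in the library for counts and the Sda annotation), an abundance
#' (arbitrary units: MS1 apex height), a retention time and Gaussian peak
#' sigma, and the charge states with their relative weights.
#'
#' @param protein,peptide,glycanName,glycoClass character vectors
#' @param abundance,rt numeric vectors
#' @param sigma Gaussian elution sigma in minutes (default 0.085, i.e. FWHM
#'   0.2 min)
#' @param charges,chargeWeights comma-separated strings per species, e.g.
#'   `"2,3"` and `"0.3,0.7"`
#' @param pairId,fraction optional glycoform-pair bookkeeping: species with
#'   the same `pairId` form an Sda/precursor pair and `fraction` records the
#'   planted Sda fraction of the pair total
#' @param library glycan library for composition lookup
#' @return data.frame, one row per planted glycoform
#' @export
plantedSpecies <- function(protein = character(), peptide = character(),
                           glycanName = character(), glycoClass = character(),
                           abundance = numeric(), rt = numeric(),
                           sigma = 0.085, charges = "2,3",
                           chargeWeights = "0.3,0.7",
                           pairId = NA_character_, fraction = NA_real_,
                           library = readGlycanLibrary()) {
  n <- length(peptide)
  if (!n)
    return(data.frame(id = character(), protein = character(),
                      peptide = character(), glycanName = character(),
                      glycoClass = character(), hex = integer(),
                      hexnac = integer(), neuac = integer(), dhex = integer(),
                      sda = logical(), abundance = numeric(), rt = numeric(),
                      sigma = numeric(), charges = character(),
                      chargeWeights = character(), pairId = character(),
                      fraction = numeric(), stringsAsFactors = FALSE))
  li <- match(glycanName, library$name)
  if (anyNA(li)) stop("glycan(s) not in library: ",
                      paste(glycanName[is.na(li)], collapse = ", "))
  data.frame(id = paste0(protein, "|", peptide, "|", glycanName),
             protein = protein, peptide = peptide, glycanName = glycanName,
             glycoClass = glycoClass,
             hex = library$hex[li], hexnac = library$hexnac[li],
             neuac = library$neuac[li], dhex = library$dhex[li],
             sda = library$sda[li],
             abundance = abundance, rt = rt,
             sigma = rep_len(sigma, n),
             charges = rep_len(charges, n),
             chargeWeights = rep_len(chargeWeights, n),
             pairId = rep_len(pairId, n), fraction = rep_len(fraction, n),
             stringsAsFactors = FALSE)
}

## isotope envelope, 4 isotopes, relative to the monoisotopic peak:
## averagine-style Poisson model with lambda proportional to neutral mass
.isoEnvelope <- function(neutralMass) {
  lambda <- neutralMass * 4.7e-4
  stats::dpois(0:3, lambda) / stats::dpois(0, lambda)
}

.speciesGp <- function(sp) {
  Glycopeptide(sp$peptide,
               GlycanComposition(sp$hex, sp$hexnac, sp$neuac, sp$dhex),
               glycoClass = sp$glycoClass, mods = .applyMods(sp$peptide),
               sda = sp$sda)
}

#' Simulate a ground-truth run
#'
#' Generates a centroided [MsRun-class] from a manifest: Gaussian elution
#' profiles with 4-isotope envelopes on MS1 scans, NCE 20/30/40 MS2 triplets
#' (built from [theoreticalSpectrum()]) for every planted species whose apex
#' intensity exceeds the selection threshold, log-normal noise peaks on both
#' MS levels and occasional noise-precursor MS2 triplets. Deterministic
#' given the manifest seed: identical manifests yield identical runs.
#'
#' @param manifest a [runManifest()]
#' @return list with `run` (an [MsRun-class]) and `truth` (ground truth:
#'   `species` with theoretical m/z, `ms2` mapping every planted MS2 scan to
#'   its species, and the seed)
#' @export
simulateRun <- function(manifest) {
  stopifnot(is(manifest, "RunManifest"))
  inst <- manifest@instrument; nz <- manifest@noise
  sp <- manifest@species
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
  }
  set.seed(manifest@seed)

  nSp <- nrow(sp)
  spCharges <- lapply(seq_len(nSp), function(i)
    as.integer(strsplit(sp$charges[i], ",")[[1]]))
  spWeights <- lapply(seq_len(nSp), function(i) {
    w <- as.numeric(strsplit(sp$chargeWeights[i], ",")[[1]])
    w / sum(w)
  })
  spMass <- numeric(nSp); spGp <- vector("list", nSp)
  theoCache <- vector("list", nSp)
  for (i in seq_len(nSp)) {
    spGp[[i]] <- .speciesGp(sp[i, ])
    spMass[i] <- peptideMass(spGp[[i]]) + glycanMass(spGp[[i]]@glycan)
    topZ <- spCharges[[i]][which.max(spWeights[[i]])]
    topMz <- .massToMz(spMass[i], topZ)
    if (topMz < inst$mzRange[1] || topMz > inst$mzRange[2])
      stop("species ", sp$id[i], " m/z ", round(topMz, 2),
           " outside instrument range")
  }

  jitter <- function(mz) mz * (1 + stats::rnorm(length(mz), 0,
                                                inst$ppmJitterSd) * 1e-6)
  times <- seq(manifest@gradient[1], manifest@gradient[2],
               by = inst$ms1Interval)
  scansOut <- vector("list", 0L)
  truthMs2 <- list()
  scanNum <- 0L

  for (t in times) {
    ## ---- MS1 survey scan ----
    mzAcc <- list(); intAcc <- list()
    elution <- if (nSp) sp$abundance * exp(-(t - sp$rt)^2 / (2 * sp$sigma^2))
               else numeric()
    for (i in seq_len(nSp)) {
      if (elution[i] < 1) next
      iso <- .isoEnvelope(spMass[i])
      for (k in seq_along(spCharges[[i]])) {
        z <- spCharges[[i]][k]
        I <- elution[i] * spWeights[[i]][k]
        if (I < 1) next
        mzk <- (spMass[i] + (0:3) * .MASS$neutron) / z + .MASS$proton
        keep <- mzk >= inst$mzRange[1] & mzk <= inst$mzRange[2]
        mzAcc[[length(mzAcc) + 1L]] <- jitter(mzk[keep])
        intAcc[[length(intAcc) + 1L]] <- I * iso[keep]
      }
    }
    nNoise <- stats::rpois(1, nz$ms1Peaks)
    if (nNoise) {
      mzAcc[[length(mzAcc) + 1L]] <- stats::runif(nNoise, inst$mzRange[1],
                                                  inst$mzRange[2])
      intAcc[[length(intAcc) + 1L]] <- stats::rlnorm(nNoise, nz$logMean,
                                                     nz$logSd)
    }
    scanNum <- scanNum + 1L
    scansOut[[length(scansOut) + 1L]] <-
      MsScan(scanNum, 1L, t, unlist(mzAcc) %||% numeric(),
             unlist(intAcc) %||% numeric())

    ## ---- data-dependent MS2 triplets ----
    for (i in seq_len(nSp)) {
      topK <- which.max(spWeights[[i]])
      z <- spCharges[[i]][topK]
      I <- elution[i] * spWeights[[i]][topK]
      if (I < inst$selectionThreshold) next
      precMz <- jitter(.massToMz(spMass[i], z))
      if (is.null(theoCache[[i]])) {
        theoCache[[i]] <- lapply(inst$nce, function(nce)
          theoreticalSpectrum(spGp[[i]], nce))
        names(theoCache[[i]]) <- as.character(inst$nce)
      }
      for (nce in inst$nce) {
        theo <- theoCache[[i]][[as.character(nce)]]
        fint <- theo$weight * I * inst$ms2Scale *
          stats::rlnorm(nrow(theo), 0, 0.1)
        fmz <- jitter(theo$mz)
        nN2 <- stats::rpois(1, nz$ms2Peaks)
        if (nN2) {
          fmz <- c(fmz, stats::runif(nN2, 120, inst$mzRange[2]))
          fint <- c(fint, stats::rlnorm(nN2, nz$logMean, nz$logSd))
        }
        scanNum <- scanNum + 1L
        scansOut[[length(scansOut) + 1L]] <-
          MsScan(scanNum, 2L, t + 1e-4 * (scanNum %% 100), fmz, fint,
                 precursorMz = precMz, precursorCharge = z, nce = nce)
        truthMs2[[length(truthMs2) + 1L]] <-
          data.frame(scanNum = scanNum, speciesId = sp$id[i], nce = nce)
      }
    }
    ## occasional noise-precursor triplet
    if (stats::runif(1) < nz$ms2Rate) {
      precMz <- stats::runif(1, inst$mzRange[1], inst$mzRange[2])
      z <- sample(inst$chargeRange, 1L)
      for (nce in inst$nce) {
        nN2 <- stats::rpois(1, nz$ms2Peaks)
        scanNum <- scanNum + 1L
        scansOut[[length(scansOut) + 1L]] <-
          MsScan(scanNum, 2L, t + 1e-4 * (scanNum %% 100),
                 stats::runif(nN2, 120, inst$mzRange[2]),
                 stats::rlnorm(nN2, nz$logMean, nz$logSd),
                 precursorMz = precMz, precursorCharge = z, nce = nce)
      }
    }
  }

  truthSpecies <- sp
  if (nSp) {
    truthSpecies$topCharge <- vapply(seq_len(nSp), function(i)
      spCharges[[i]][which.max(spWeights[[i]])], integer(1))
    truthSpecies$theoreticalMz <- .massToMz(spMass, truthSpecies$topCharge)
    truthSpecies$neutralMass <- spMass
  }
  truth <- list(species = truthSpecies,
                ms2 = if (length(truthMs2)) do.call(rbind, truthMs2)
                      else data.frame(scanNum = integer(),
                                      speciesId = character(),
                                      nce = numeric()),
                seed = manifest@seed)
  list(run = MsRun(scansOut,
                   metadata = list(seed = manifest@seed,
                                   gradient = manifest@gradient)),
       truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- presets ------------------------------------------------------------

## sample presets: five HEK293 transfectant emulations plus the two Cad
## erythrocyte samples and a bisecting-GlcNAc isomer control. Planted Sda
## fractions encode the study conditions: cad_a plants 12% on the GLPA
## O-glycopeptide and 18% on the B3AT N-glycopeptide; cad_b plants 0.1% on
## GLPA; mock and rs7224888 plant precursor glycoforms only.
.PRESETS <- c("mock", "hek_wt", "hek_rs7224888", "hek_rs148441237",
              "hek_rs61743617", "cad_a", "cad_b", "control_bisecting")

#' Preset simulation manifests
#'
#' Named presets emulating the study samples. `mock` and `hek_rs7224888`
#' plant only non-Sda precursor glycoforms (the inactivating missense
#' variant); `hek_wt`, `hek_rs148441237` and `hek_rs61743617` plant the Sda
#' glycoforms on the TM9S3 N-glycopeptide (both antennae extended,
#' NeuAc2Hex5HexNAc6) and the TFR1 core 1 O-glycopeptide. `cad_a` plants the
#' GLPA DTYAATPR O-glycoform pair at a 12% Sda fraction and the B3AT
#' N-glycoform pair at 18%; `cad_b` plants GLPA at 0.1%.
#' `control_bisecting` plants the isomeric NeuAc2Hex5HexNAc5dHex composition
#' annotated as a bisecting-GlcNAc structure, which produces no 860.31
#' fragment.
#'
#' @param name one of `"mock"`, `"hek_wt"`, `"hek_rs7224888"`,
#'   `"hek_rs148441237"`, `"hek_rs61743617"`, `"cad_a"`, `"cad_b"`,
#'   `"control_bisecting"`
#' @param seed integer seed for [simulateRun()]
#' @param library glycan library
#' @return a [RunManifest-class]
#' @export
presetManifest <- function(name, seed, library = readGlycanLibrary()) {
  if (!name %in% .PRESETS) stop("unknown preset name: ", name)
  base <- 1e6
  pairRows <- function(protein, peptide, cls, glyB, glyA, rtB, fraction,
                       charges, weights, pairId) {
    ab <- c(A = fraction * base, B = (1 - fraction) * base)
    keep <- ab > 0
    plantedSpecies(
      protein = rep(protein, sum(keep)),
      peptide = rep(peptide, sum(keep)),
      glycanName = c(glyA, glyB)[keep],
      glycoClass = rep(cls, sum(keep)),
      abundance = ab[keep], rt = c(rtB + 0.5, rtB)[keep],
      charges = charges, chargeWeights = weights,
      pairId = pairId, fraction = fraction, library = library)
  }
  sp <- switch(name,
    mock = ,
    hek_rs7224888 = rbind(
      pairRows("TM9S3", "IVDVNLTSEGK", "N", "NeuAc2Hex5HexNAc4",
               "NeuAc2Hex5HexNAc6", 25, 0, "2,3", "0.3,0.7", "TM9S3_N"),
      pairRows("TFR1", "LAGTESPVREEPGEDFPAAR", "O", "NeuAc2Hex1HexNAc1",
               "NeuAc2Hex1HexNAc2", 32, 0, "2,3", "0.3,0.7", "TFR1_O")),
    hek_wt = ,
    hek_rs148441237 = ,
    hek_rs61743617 = rbind(
      pairRows("TM9S3", "IVDVNLTSEGK", "N", "NeuAc2Hex5HexNAc4",
               "NeuAc2Hex5HexNAc6", 25, 1, "2,3", "0.3,0.7", "TM9S3_N"),
      pairRows("TFR1", "LAGTESPVREEPGEDFPAAR", "O", "NeuAc2Hex1HexNAc1",
               "NeuAc2Hex1HexNAc2", 32, 1, "2,3", "0.3,0.7", "TFR1_O")),
    cad_a = rbind(
      pairRows("GLPA", "DTYAATPR", "O", "NeuAc2Hex1HexNAc1",
               "NeuAc2Hex1HexNAc2", 22, 0.12, "2", "1", "GLPA_O"),
      pairRows("B3AT", "LSVPDGFKVSNSSAR", "N", "NeuAc2Hex5HexNAc4",
               "NeuAc2Hex5HexNAc5", 30, 0.18, "2,3", "0.3,0.7", "B3AT_N")),
    cad_b =
      pairRows("GLPA", "DTYAATPR", "O", "NeuAc2Hex1HexNAc1",
               "NeuAc2Hex1HexNAc2", 22, 0.001, "2", "1", "GLPA_O"),
    control_bisecting =
      pairRows("B3AT", "LSVPDGFKVSNSSAR", "N", "NeuAc2Hex5HexNAc4dHex",
               "NeuAc2Hex5HexNAc5dHex_bisecting", 30, 0.18, "2,3",
               "0.3,0.7", "B3AT_N_bisecting"))
  ## the doubly-extended TM9S3 glycoform at z=2 sits at m/z 1894, z=3 at
  ## 1262.53: both inside the 600-2000 survey range
  runManifest(species = sp, seed = seed)
}

#' Names of the available presets
#' @export
presetNames <- function() .PRESETS
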