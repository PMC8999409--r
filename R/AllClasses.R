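#' @include AllGenerics.R
NULL

## Central S4 classes. Glycan identity is composition-level throughout:
## linkage and topology are not modelled, so an Sda-extended antenna and a
## bisecting GlcNAc share a GlycanComposition and are distinguished only by
## the per-library-entry `sda` annotation (see oxoniumIons()).

#' Glycan composition
#'
#' Counts of the four monosaccharide residue classes used for glycopeptide
#' mass arithmetic: hexose (Hex), N-acetylhexosamine (HexNAc),
#' N-acetylneuraminic acid (NeuAc) and deoxyhexose (dHex/Fuc). Composition is
#' the unit of glycan identity; a total count of zero denotes "no glycan".
#'
#' @slot hex,hexnac,neuac,dhex non-negative integer residue counts
#'
#' @examples
#' g <- GlycanComposition(hex = 5, hexnac = 4, neuac = 2)
#' glycanMass(g)
#' @export
setClass("GlycanComposition",
  representation(hex = "integer", hexnac = "integer",
                 neuac = "integer", dhex = "integer"),
  prototype(hex = 0L, hexnac = 0L, neuac = 0L, dhex = 0L))

setValidity("GlycanComposition", function(object) {
  counts <- c(object@hex, object@hexnac, object@neuac, object@dhex)
  if (length(counts) != 4L || anyNA(counts))
    return("all four residue counts must be single non-missing integers")
  if (any(counts < 0L))
    return("negative residue counts are not allowed")
  TRUE
})

#' @param hex,hexnac,neuac,dhex non-negative residue counts
#' @rdname GlycanComposition-class
#' @export
GlycanComposition <- function(hex = 0, hexnac = 0, neuac = 0, dhex = 0) {
  stopifnot(hex >= 0, hexnac >= 0, neuac >= 0, dhex >= 0,
            hex == round(hex), hexnac == round(hexnac),
            neuac == round(neuac), dhex == round(dhex))
  new("GlycanComposition", hex = as.integer(hex), hexnac = as.integer(hexnac),
      neuac = as.integer(neuac), dhex = as.integer(dhex))
}

#' Glycopeptide
#'
#' A peptide with resolved modifications, a glycan composition, a
#' glycosylation class and a candidate attachment site. N-glycopeptides must
#' carry the sequon Asn-X-Ser/Thr (X != Pro) at the glycosite;
#' O-glycopeptides require Ser or Thr within the site range. Site indices are
#' 1-based within the peptide.
#'
#' @slot peptide character(1), one-letter residue codes
#' @slot mods data.frame with columns `pos`, `delta`, `name` (applied
#'   modification instances; `delta` in Da)
#' @slot glycan a [GlycanComposition-class]
#' @slot glycoClass `"N"` or `"O"`
#' @slot glycosite integer site index (N) or index range (O; ambiguous sites
#'   allowed); may be empty when unlocalised
#' @slot sda logical(1): whether this glycoform is annotated as carrying the
#'   Sda epitope (drives prediction of the m/z 860.3143 oxonium ion)
#'
#' @export
setClass("Glycopeptide",
  representation(peptide = "character", mods = "data.frame",
                 glycan = "GlycanComposition", glycoClass = "character",
                 glycosite = "integer", sda = "logical"),
  prototype(mods = data.frame(pos = integer(), delta = numeric(),
                              name = character()),
            glycoClass = "N", glycosite = integer(), sda = FALSE))

setValidity("Glycopeptide", function(object) {
  pep <- object@peptide
  if (length(pep) != 1L || !nzchar(pep)) return("peptide must be non-empty")
  res <- strsplit(pep, "")[[1]]
  if (!all(res %in% names(.aaMass())))
    return(paste0("unknown residue code(s): ",
                  paste(unique(setdiff(res, names(.aaMass()))), collapse = ",")))
  if (!object@glycoClass %in% c("N", "O"))
    return("glycoClass must be 'N' or 'O'")
  site <- object@glycosite
  if (length(site)) {
    if (any(site < 1L) || any(site > length(res)))
      return("glycosite outside peptide")
    if (object@glycoClass == "N") {
      i <- site[1L]
      if (res[i] != "N") return("N-glycosite must be Asn")
      if (i + 2L <= length(res) &&
          (res[i + 1L] == "P" || !res[i + 2L] %in% c("S", "T")))
        return("N-glycosite lacks the Asn-X-Ser/Thr sequon (X != Pro)")
    } else {
      rng <- seq(min(site), max(site))
      if (!any(res[rng] %in% c("S", "T")))
        return("O-glycosite range contains no Ser/Thr")
    }
  }
  if (nrow(object@mods)) {
    if (any(object@mods$pos < 1L) || any(object@mods$pos > length(res)))
      return("modification position outside peptide")
  }
  TRUE
})

#' @param peptide one-letter sequence
#' @param glycan a [GlycanComposition-class] (or NULL for none)
#' @param glycoClass `"N"` or `"O"`
#' @param glycosite site index or range (1-based within the peptide)
#' @param mods data.frame of applied modifications (`pos`, `delta`, `name`)
#' @param sda logical: Sda-positive glycoform annotation
#' @rdname Glycopeptide-class
#' @export
Glycopeptide <- function(peptide, glycan = GlycanComposition(),
                         glycoClass = c("N", "O"), glycosite = integer(),
                         mods = NULL, sda = FALSE) {
  if (is.null(mods))
    mods <- data.frame(pos = integer(), delta = numeric(), name = character())
  new("Glycopeptide", peptide = peptide, glycan = glycan,
      glycoClass = match.arg(glycoClass),
      glycosite = as.integer(glycosite), mods = mods, sda = isTRUE(sda))
}

#' A single centroided mass spectrum
#'
#' @slot scanNum integer scan number (unique within a run)
#' @slot msLevel 1L or 2L
#' @slot rt retention time in minutes
#' @slot mz,intensity centroided peak list (same length, mz ascending)
#' @slot precursorMz,precursorCharge precursor metadata (NA on MS1 scans)
#' @slot nce normalized collision energy in percent (NA on MS1 scans)
#' @export
setClass("MsScan",
  representation(scanNum = "integer", msLevel = "integer", rt = "numeric",
                 mz = "numeric", intensity = "numeric",
                 precursorMz = "numeric", precursorCharge = "integer",
                 nce = "numeric"),
  prototype(precursorMz = NA_real_, precursorCharge = NA_integer_,
            nce = NA_real_))

setValidity("MsScan", function(object) {
  if (length(object@mz) != length(object@intensity))
    return("mz and intensity lengths differ")
  if (is.unsorted(object@mz)) return("peaks must be sorted by m/z")
  if (object@msLevel == 2L && is.na(object@precursorMz))
    return("MS2 scan lacks precursor m/z")
  TRUE
})

MsScan <- function(scanNum, msLevel, rt, mz, intensity,
                   precursorMz = NA_real_, precursorCharge = NA_integer_,
                   nce = NA_real_) {
  o <- order(mz)
  new("MsScan", scanNum = as.integer(scanNum), msLevel = as.integer(msLevel),
      rt = rt, mz = mz[o], intensity = intensity[o],
      precursorMz = precursorMz, precursorCharge = as.integer(precursorCharge),
      nce = nce)
}

#' A time-ordered collection of scans
#'
#' @slot scans list of [MsScan-class], ordered by retention time
#' @slot metadata free-form list (acquisition description, seed, ...)
#' @export
setClass("MsRun",
  representation(scans = "list", metadata = "list"),
  prototype(metadata = list()))

setValidity("MsRun", function(object) {
  if (!all(vapply(object@scans, is, logical(1), "MsScan")))
    return("all elements of scans must be MsScan objects")
  rt <- vapply(object@scans, slot, numeric(1), "rt")
  if (is.unsorted(rt)) return("scans must be ordered by retention time")
  TRUE
})

MsRun <- function(scans, metadata = list()) {
  rt <- vapply(scans, slot, numeric(1), "rt")
  new("MsRun", scans = scans[order(rt)], metadata = metadata)
}

#' Simulation manifest for a ground-truth run
#'
#' Describes the planted glycopeptide species, the instrument emulation
#' (MS1 m/z range 600-2000, stepped-NCE 20/30/40 MS2 triplets, 5 m/z
#' isolation window, precursor charges 2-7) and the noise model. Built by
#' [runManifest()] or [presetManifest()].
#'
#' @slot species data.frame, one row per planted glycoform
#' @slot instrument,noise parameter lists
#' @slot gradient numeric(2), gradient start/end in minutes
#' @slot seed integer seed (mandatory; every stochastic field derives from it)
#' @export
setClass("RunManifest",
  representation(species = "data.frame", instrument = "list",
                 noise = "list", gradient = "numeric", seed = "integer"))

setValidity("RunManifest", function(object) {
  sp <- object@species
  if (nrow(sp)) {
    if (any(sp$abundance <= 0)) return("abundances must be > 0")
    if (any(sp$rt < object@gradient[1]) || any(sp$rt > object@gradient[2]))
      return("species retention times must lie within the gradient")
  }
  if (is.na(object@seed)) return("seed is mandatory")
  TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "GlycanComposition", function(object) {
  cat("GlycanComposition:", glycanName(object),
      sprintf("(%.4f Da)\n", glycanMass(object)))
})

setMethod("show", "Glycopeptide", function(object) {
  cat(sprintf("Glycopeptide (%s-linked%s): %s + %s\n",
              object@glycoClass, if (object@sda) ", Sda" else "",
              object@peptide, glycanName(object@glycan)))
  if (length(object@glycosite))
    cat("  glycosite (within peptide):",
        paste(range(object@glycosite), collapse = "-"), "\n")
  if (nrow(object@mods))
    cat("  mods:", paste(sprintf("%s@%d", object@mods$name, object@mods$pos),
                         collapse = ", "), "\n")
})

setMethod("show", "MsRun", function(object) {
  lv <- msLevels(object)
  cat(sprintf("MsRun: %d scans (%d MS1, %d MS2), RT %.2f-%.2f min\n",
              length(object@scans), sum(lv == 1L), sum(lv == 2L),
              if (length(object@scans)) min(retentionTimes(object)) else NA,
              if (length(object@scans)) max(retentionTimes(object)) else NA))
})

setMethod("show", "RunManifest", function(object) {
  cat(sprintf("RunManifest: %d planted species, gradient %g-%g min, seed %d\n",
              nrow(object@species), object@gradient[1], object@gradient[2],
              object@seed))
})

## ---- accessors ----------------------------------------------------------

#' @rdname MsRun-class
#' @param x an `MsRun`
#' @export
setMethod("scans", "MsRun", function(x) x@scans)

#' @rdname MsRun-class
#' @export
setMethod("msLevels", "MsRun",
          function(x) vapply(x@scans, slot, integer(1), "msLevel"))

#' @rdname MsRun-class
#' @export
setMethod("retentionTimes", "MsRun",
          function(x) vapply(x@scans, slot, numeric(1), "rt"))

#' @rdname Glycopeptide-class
#' @param x a `Glycopeptide`
#' @export
setMethod("peptide", "Glycopeptide", function(x) x@peptide)

#' @rdname Glycopeptide-class
#' @export
setMethod("glycan", "Glycopeptide", function(x) x@glycan)

#' @rdname Glycopeptide-class
#' @export
setMethod("glycoClass", "Glycopeptide", function(x) x@glycoClass)
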