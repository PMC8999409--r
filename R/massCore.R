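## Single authoritative monoisotopic mass table. Every module computes
## through these constants; nothing else defines a mass.

.MASS <- list(
  water  = 18.01056469,
  proton = 1.00727646688,
  neutron = 1.0033548378,   # C13-C12 spacing used for isotope envelopes
  hex    = 162.05282343,
  hexnac = 203.07937253,
  neuac  = 291.09541652,
  dhex   = 146.05790881,
  atom = c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
           O = 15.9949146221, S = 31.97207069)
)

## residue monoisotopic masses, 20 standard amino acids, consistent with the
## elemental atom table above; Ile/Leu are distinct codes with identical
## (isomeric) mass
.AA_MASS <- c(
  G = 57.02146372, A = 71.03711379, S = 87.03202841, P = 97.05276385,
  V = 99.06841391, T = 101.04767847, C = 103.00918448, L = 113.08406398,
  I = 113.08406398, N = 114.04292745, D = 115.02694303, Q = 128.05857751,
  K = 128.09496302, E = 129.04259309, M = 131.04048460, H = 137.05891186,
  F = 147.06841391, R = 156.10111103, Y = 163.06332854, W = 186.07931295)

.aaMass <- function() .AA_MASS

#' Monoisotopic mass constants
#'
#' Returns the single authoritative table of monoisotopic constants used by
#' every mass computation in the package: residue masses for the 20 standard
#' amino acids, water (18.010565 Da), the proton (1.007276 Da) and the four
#' glycan residue classes Hex (162.052824), HexNAc (203.079373), NeuAc
#' (291.095417) and dHex (146.057909).
#'
#' @return a named list with elements `residues`, `water`, `proton`, `hex`,
#'   `hexnac`, `neuac`, `dhex`, `atom`
#' @export
massConstants <- function() {
  c(list(residues = .AA_MASS), .MASS)
}

#' Mass delta of an elemental formula
#'
#' Parses a Hill-style elemental formula over C, H, N, O and S and returns
#' its monoisotopic mass, e.g. for defining modification deltas. The two
#' defaults of the workflow are methylthio on Cys, `CH2S` = +45.9877 Da
#' (static), and oxidation of Met, `O` = +15.9949 Da (variable).
#'
#' @param formula character(1), e.g. `"CH2S"`, `"O"`, `"C2H3NO"`; the empty
#'   string gives 0
#' @return mass delta in Da
#' @examples
#' modificationMass("CH2S")  # 45.9877
#' modificationMass("O")     # 15.9949
#' @export
modificationMass <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  if (!nzchar(formula)) return(0)
  if (grepl("[^CHNOS0-9]", formula))
    stop("unknown element symbol in formula: ", formula)
  m <- gregexpr("([CHNOS])([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  if (!nzchar(paste(parts, collapse = "")) ||
      nchar(paste(parts, collapse = "")) != nchar(formula))
    stop("malformed formula: ", formula)
  sum(vapply(parts, function(p) {
    el <- substr(p, 1L, 1L)
    n <- substr(p, 2L, nchar(p))
    .MASS$atom[[el]] * if (nzchar(n)) as.integer(n) else 1L
  }, numeric(1)))
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue masses plus water plus any applied modification deltas.
#'
#' @param x peptide sequence (character(1), one-letter codes) or a
#'   [Glycopeptide-class] (whose mods are applied; the glycan is *not*
#'   included -- see [precursorMz()])
#' @param mods optional data.frame of applied modifications with columns
#'   `pos` and `delta`; every `pos` must index a residue of the peptide
#' @return neutral monoisotopic mass in Da
#' @examples
#' peptideMass("IVDVNLTSEGK")  # 1173.6241
#' @export
setMethod("peptideMass", "character", function(x, mods = NULL) {
  stopifnot(length(x) == 1L)
  if (!nzchar(x)) stop("empty peptide sequence")
  res <- strsplit(x, "")[[1]]
  bad <- setdiff(res, names(.AA_MASS))
  if (length(bad))
    stop("unknown residue code(s): ", paste(bad, collapse = ","))
  m <- sum(.AA_MASS[res]) + .MASS$water
  if (!is.null(mods) && nrow(mods)) {
    if (any(mods$pos < 1L) || any(mods$pos > length(res)))
      stop("modification targets a residue absent from the peptide")
    m <- m + sum(mods$delta)
  }
  m
})

#' @rdname peptideMass-character-method
#' @export
setMethod("peptideMass", "Glycopeptide",
          function(x, ...) peptideMass(x@peptide, mods = x@mods))

#' Neutral monoisotopic glycan mass
#'
#' Additive in the residue counts; the empty composition has mass 0.
#'
#' @param x a [GlycanComposition-class]
#' @return neutral monoisotopic mass in Da
#' @examples
#' glycanMass(GlycanComposition(hex = 5, hexnac = 4, neuac = 2))  # 2204.7724
#' @export
setMethod("glycanMass", "GlycanComposition", function(x) {
  x@hex * .MASS$hex + x@hexnac * .MASS$hexnac +
    x@neuac * .MASS$neuac + x@dhex * .MASS$dhex
})

## neutral mass -> m/z at charge z
.massToMz <- function(m, z) (m + z * .MASS$proton) / z

#' Glycopeptide precursor m/z
#'
#' `(peptideMass + glycanMass + z * proton) / z`, strictly decreasing in `z`
#' for fixed neutral mass. Reproduces the printed precursors of the workflow,
#' e.g. IVDVNLTSEGK + NeuAc2Hex5HexNAc4 at z = 3 gives m/z 1127.14 and the
#' Sda-extended NeuAc2Hex5HexNAc6 form gives 1262.53.
#'
#' @param x a [Glycopeptide-class]
#' @param z positive integer charge (1-7 in this workflow)
#' @return m/z
#' @export
setMethod("precursorMz", "Glycopeptide", function(x, z, ...) {
  z <- as.integer(z)
  if (any(z < 1L)) stop("charge must be >= 1")
  .massToMz(peptideMass(x) + glycanMass(x@glycan), z)
})

#' Glycan oxonium-ion m/z
#'
#' Singly protonated glycan fragment cation: `glycanMass + proton -
#' waterLosses * water`. The NeuAc oxonium at m/z 292.10 and its water loss
#' at 274.09 are the sialylation diagnostics; the composition
#' NeuAc1Hex1HexNAc2 at m/z 860.3143 is the Sda-epitope diagnostic.
#'
#' @param x a non-empty [GlycanComposition-class]
#' @param waterLosses non-negative count of neutral water losses
#' @return m/z of the singly charged fragment
#' @examples
#' oxoniumMz(GlycanComposition(hex = 1, hexnac = 2, neuac = 1))  # 860.3143
#' oxoniumMz(GlycanComposition(neuac = 1), waterLosses = 1)      # 274.09
#' @export
setMethod("oxoniumMz", "GlycanComposition", function(x, waterLosses = 0L) {
  stopifnot(waterLosses >= 0L)
  if (glycanTotal(x) == 0L) stop("empty glycan composition has no oxonium ion")
  glycanMass(x) + .MASS$proton - waterLosses * .MASS$water
})

#' @rdname GlycanComposition-class
#' @param g a `GlycanComposition`
#' @export
glycanTotal <- function(g) g@hex + g@hexnac + g@neuac + g@dhex

#' @rdname GlycanComposition-class
#' @export
glycanName <- function(g) {
  if (glycanTotal(g) == 0L) return("none")
  parts <- c(
    if (g@neuac) paste0("NeuAc", g@neuac),
    if (g@hex) paste0("Hex", g@hex),
    if (g@hexnac) paste0("HexNAc", g@hexnac),
    if (g@dhex) paste0("dHex", g@dhex))
  paste(parts, collapse = "")
}

## is a a sub-composition of b (componentwise <=)?
.glycanContains <- function(b, a) {
  b@hex >= a@hex && b@hexnac >= a@hexnac &&
    b@neuac >= a@neuac && b@dhex >= a@dhex
}

## componentwise addition, used to build glycoform pairs (Sda = +1 HexNAc)
.glycanAdd <- function(g, hex = 0L, hexnac = 0L, neuac = 0L, dhex = 0L) {
  GlycanComposition(g@hex + hex, g@hexnac + hexnac,
                    g@neuac + neuac, g@dhex + dhex)
}

#' Parts-per-million mass error
#'
#' `(observed - theoretical) / theoretical * 1e6`.
#' @param observed,theoretical m/z values
#' @export
ppmError <- function(observed, theoretical) {
  (observed - theoretical) / theoretical * 1e6
}

#' Default modification set
#'
#' The workflow's defaults: static methylthio on Cys (+45.9877 Da) and
#' variable oxidation of Met (+15.9949 Da).
#'
#' @return list with `static` and `variable` data.frames (columns `residue`,
#'   `delta`, `name`)
#' @export
defaultModifications <- function() {
  list(
    static = data.frame(residue = "C", delta = modificationMass("CH2S"),
                        name = "Methylthio"),
    variable = data.frame(residue = "M", delta = modificationMass("O"),
                          name = "Oxidation"))
}

## resolve a modification set against a concrete peptide: static mods applied
## at every target residue, plus `nOx` oxidations on the first Met residues
.applyMods <- function(pep, modset = defaultModifications(), nOx = 0L) {
  res <- strsplit(pep, "")[[1]]
  out <- data.frame(pos = integer(), delta = numeric(), name = character())
  for (i in seq_len(nrow(modset$static))) {
    pos <- which(res == modset$static$residue[i])
    if (length(pos))
      out <- rbind(out, data.frame(pos = pos, delta = modset$static$delta[i],
                                   name = modset$static$name[i]))
  }
  if (nOx > 0L) {
    pos <- which(res == "M")
    if (length(pos) < nOx) stop("not enough Met residues for ", nOx, " oxidations")
    out <- rbind(out, data.frame(pos = pos[seq_len(nOx)],
                                 delta = modificationMass("O"),
                                 name = "Oxidation"))
  }
  out[order(out$pos), , drop = FALSE]
}
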