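## HCD fragment prediction at tiered collision energies. At NCE 20 the
## glycan fragments glycosidically while the peptide stays intact (Y-ion
## ladder + oxonium B-ions); at NCE 30/40 the peptide backbone additionally
## fragments into b/y ions. Relative intensities are flat within an ion
## class, with per-tier class weights (the acquisition gives no intensity
## model; weights are configuration).

## per-NCE-tier class weights for predicted intensities
.TIER_WEIGHTS <- list(
  `20` = c(glycosidic = 1.0, oxonium = 1.0, backbone = 0.05),
  `30` = c(glycosidic = 0.3, oxonium = 0.3, backbone = 1.0),
  `40` = c(glycosidic = 0.3, oxonium = 0.3, backbone = 1.0))

.fragmentRow <- function(label, mz, z, class) {
  data.frame(label = label, mz = mz, z = as.integer(z), class = class,
             stringsAsFactors = FALSE)
}

#' Glycosidic Y-ion ladder of a glycopeptide
#'
#' Enumerates every fragment that retains the intact peptide plus a
#' sub-composition of the glycan (all componentwise sub-compositions).
#' N-glycopeptide ladders retain at least one HexNAc (the core GlcNAc) down
#' to the peptide+HexNAc ion; O-glycopeptide ladders additionally include the
#' bare peptide ion, which O-glycans release readily.
#'
#' @param gp a [Glycopeptide-class] with a non-empty glycan
#' @param charges fragment charges to emit (default 1:2)
#' @return data.frame of fragments: `label`, `mz`, `z`, `class`
#' @examples
#' gp <- Glycopeptide("IVDVNLTSEGK",
#'                    GlycanComposition(hex = 5, hexnac = 6, neuac = 2),
#'                    glycoClass = "N", glycosite = 5)
#' lad <- glycosidicLadder(gp)
#' lad[lad$label == "peptide+HexNAc1" & lad$z == 1, "mz"]  # 1377.71
#' @export
glycosidicLadder <- function(gp, charges = c(1L, 2L)) {
  g <- gp@glycan
  if (glycanTotal(g) == 0L) stop("glycopeptide has an empty glycan")
  pm <- peptideMass(gp)
  minHexnac <- if (gp@glycoClass == "N") 1L else 0L
  subs <- expand.grid(hex = 0:g@hex, hexnac = minHexnac:g@hexnac,
                      neuac = 0:g@neuac, dhex = 0:g@dhex)
  rows <- lapply(seq_len(nrow(subs)), function(i) {
    gc <- GlycanComposition(subs$hex[i], subs$hexnac[i],
                            subs$neuac[i], subs$dhex[i])
    lbl <- if (glycanTotal(gc) == 0L) "peptide"
           else paste0("peptide+", glycanName(gc))
    do.call(rbind, lapply(charges, function(z)
      .fragmentRow(lbl, .massToMz(pm + glycanMass(gc), z), z, "glycosidic")))
  })
  out <- do.call(rbind, rows)
  if (gp@glycoClass == "N") {
    ## bare peptide is not part of the N-ladder
  } else if (!"peptide" %in% out$label) {
    out <- rbind(out, do.call(rbind, lapply(charges, function(z)
      .fragmentRow("peptide", .massToMz(pm, z), z, "glycosidic"))))
  }
  rownames(out) <- NULL
  out
}

## the configured oxonium signature set; each entry is emitted when it is a
## sub-composition of the fragmenting glycan (860.3143 additionally requires
## the Sda annotation -- see below)
.OXONIUM_SIGNATURES <- function() list(
  list(name = "HexNAc",  g = GlycanComposition(hexnac = 1), loss = 0L),
  list(name = "HexNAc-H2O", g = GlycanComposition(hexnac = 1), loss = 1L),
  list(name = "Hex1HexNAc1", g = GlycanComposition(hex = 1, hexnac = 1), loss = 0L),
  list(name = "NeuAc",   g = GlycanComposition(neuac = 1), loss = 0L),
  list(name = "NeuAc-H2O", g = GlycanComposition(neuac = 1), loss = 1L),
  list(name = "NeuAc1Hex1HexNAc1",
       g = GlycanComposition(hex = 1, hexnac = 1, neuac = 1), loss = 0L),
  list(name = "NeuAc1Hex1HexNAc2",
       g = GlycanComposition(hex = 1, hexnac = 2, neuac = 1), loss = 0L))

#' Oxonium (B-) ions of a glycan
#'
#' Emits the configured oxonium signature set intersected with the
#' sub-compositions of `g`: HexNAc (204.0867), its water loss, Hex+HexNAc
#' (366.14), NeuAc (292.10), NeuAc-H2O (274.09) and NeuAc+Hex+HexNAc
#' (657.23) whenever the residues are present. The Sda diagnostic
#' NeuAc1Hex1HexNAc2 ion at m/z 860.3143 is emitted only when the
#' composition contains the sub-unit (>=1 NeuAc, >=1 Hex, >=2 HexNAc) *and*
#' the glycoform is annotated Sda-positive: a bisecting-GlcNAc isomer shares
#' the composition but does not produce the ion.
#'
#' Oxonium m/z values depend only on the glycan, never on the peptide.
#'
#' @param g a non-empty [GlycanComposition-class]
#' @param sda logical: Sda-positive annotation of the glycoform (library
#'   `sda` column)
#' @return data.frame of fragments (`label`, `mz`, `z`, `class`); singly
#'   charged
#' @export
oxoniumIons <- function(g, sda = FALSE) {
  if (glycanTotal(g) == 0L) stop("empty glycan composition")
  rows <- lapply(.OXONIUM_SIGNATURES(), function(sig) {
    if (!.glycanContains(g, sig$g)) return(NULL)
    if (sig$name == "NeuAc1Hex1HexNAc2" && !isTRUE(sda)) return(NULL)
    .fragmentRow(sig$name, oxoniumMz(sig$g, sig$loss), 1L, "oxonium")
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- .fragmentRow(character(), numeric(), integer(),
                                        character())
  rownames(out) <- NULL
  out
}

#' Peptide backbone b/y ions
#'
#' Full b1..b(n-1) and y1..y(n-1) ladders. Complementarity holds by
#' construction: as singly charged ions, `b_i + y_(n-i)` equals the neutral
#' peptide mass plus two protons.
#'
#' @param pep peptide sequence (length >= 2)
#' @param mods applied modification data.frame (`pos`, `delta`)
#' @param charges fragment charges (default 1)
#' @return data.frame of fragments
#' @export
backboneIons <- function(pep, mods = NULL, charges = 1L) {
  res <- strsplit(pep, "")[[1]]
  n <- length(res)
  if (n < 2L) stop("peptide must have at least 2 residues")
  delta <- numeric(n)
  if (!is.null(mods) && nrow(mods)) delta[mods$pos] <- delta[mods$pos] + mods$delta
  cum <- cumsum(.AA_MASS[res] + delta)
  rows <- list()
  for (i in seq_len(n - 1L)) {
    bNeutral <- cum[i]                       # b ion: residues 1..i, no water
    yNeutral <- cum[n] - cum[n - i] + .MASS$water
    for (z in charges) {
      rows[[length(rows) + 1L]] <-
        .fragmentRow(paste0("b", i), .massToMz(bNeutral, z), z, "backbone")
      rows[[length(rows) + 1L]] <-
        .fragmentRow(paste0("y", i), .massToMz(yNeutral, z), z, "backbone")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Theoretical HCD spectrum of a glycopeptide at one NCE tier
#'
#' Combines the glycosidic ladder, oxonium ions and backbone b/y ions with
#' the tier's class weights as predicted relative intensities.
#'
#' @param gp a [Glycopeptide-class]
#' @param nce 20, 30 or 40
#' @param yCharges,bbCharges fragment charges for Y-ions and b/y ions
#' @return data.frame: `label`, `mz`, `z`, `class`, `weight`
#' @export
theoreticalSpectrum <- function(gp, nce, yCharges = c(1L, 2L), bbCharges = 1L) {
  w <- .TIER_WEIGHTS[[as.character(nce)]]
  if (is.null(w)) stop("NCE tier must be 20, 30 or 40")
  frags <- rbind(
    glycosidicLadder(gp, charges = yCharges),
    oxoniumIons(gp@glycan, sda = gp@sda),
    backboneIons(gp@peptide, gp@mods, charges = bbCharges))
  frags$weight <- unname(w[frags$class])
  frags
}
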