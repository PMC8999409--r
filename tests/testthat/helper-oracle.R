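# Independent brute-force mass oracle: sums atom counts from elemental
# formulas with its own atomic mass table. Deliberately shares no code with
# the package's residue-mass arithmetic.

.orAtom <- c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
             O = 15.9949146221, S = 31.97207069)

.orResidueFormula <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1), I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1), Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1))

.orGlycanFormula <- list(
  hex    = c(C = 6, H = 10, O = 5),
  hexnac = c(C = 8, H = 13, N = 1, O = 5),
  neuac  = c(C = 11, H = 17, N = 1, O = 8),
  dhex   = c(C = 6, H = 10, O = 4))

.orFormulaMass <- function(counts) sum(.orAtom[names(counts)] * counts)

# neutral monoisotopic glycopeptide mass by atom-count summation
oracleGlycopeptideMass <- function(pep, hex = 0, hexnac = 0, neuac = 0,
                                   dhex = 0) {
  res <- strsplit(pep, "")[[1]]
  m <- sum(vapply(res, function(r) .orFormulaMass(.orResidueFormula[[r]]),
                  numeric(1)))
  m <- m + .orFormulaMass(c(H = 2, O = 1))     # condensation water
  m + hex * .orFormulaMass(.orGlycanFormula$hex) +
    hexnac * .orFormulaMass(.orGlycanFormula$hexnac) +
    neuac * .orFormulaMass(.orGlycanFormula$neuac) +
    dhex * .orFormulaMass(.orGlycanFormula$dhex)
}

# random peptide / composition generators for property tests
randomPeptide <- function(n) {
  paste(sample(names(.orResidueFormula), n, replace = TRUE), collapse = "")
}

randomComposition <- function() {
  GlycanComposition(hex = sample(0:6, 1), hexnac = sample(0:6, 1),
                    neuac = sample(0:3, 1), dhex = sample(0:2, 1))
}

# minimal hand-built run: one MS1 scan and/or MS2 scans from explicit peaks
makeScan <- function(scanNum, msLevel, rt, mz, intensity,
                     precursorMz = NA_real_, precursorCharge = NA_integer_,
                     nce = NA_real_) {
  GlycoSda:::MsScan(scanNum, msLevel, rt, mz, intensity,
                    precursorMz = precursorMz,
                    precursorCharge = precursorCharge, nce = nce)
}

makeRun <- function(scans) GlycoSda:::MsRun(scans)

# a "recorded" MS2 triplet for a glycopeptide: theoretical peaks rendered at
# the three NCE tiers with flat class-weight intensities
tripletScans <- function(gp, precursorMz, z, rt = 10, scan0 = 1L,
                         drop = character()) {
  scans <- list()
  for (k in 1:3) {
    nce <- c(20, 30, 40)[k]
    theo <- theoreticalSpectrum(gp, nce)
    if (length(drop)) theo <- theo[!theo$label %in% drop, ]
    scans[[k]] <- makeScan(scan0 + k - 1L, 2L, rt + k * 1e-3,
                           theo$mz, 1000 * theo$weight,
                           precursorMz = precursorMz, precursorCharge = z,
                           nce = nce)
  }
  scans
}
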