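test_that("peptide and glycan masses reproduce hand-derived values", {
  expect_equal(round(peptideMass("IVDVNLTSEGK"), 4), 1173.6241)
  expect_equal(round(peptideMass("G"), 4), 75.0320)
  expect_error(peptideMass(""), "empty")
  expect_error(peptideMass("AXZ"), "unknown residue")

  expect_equal(round(glycanMass(GlycanComposition(hex = 5, hexnac = 4,
                                                  neuac = 2)), 4), 2204.7724)
  expect_identical(glycanMass(GlycanComposition()), 0)
  expect_equal(round(glycanMass(GlycanComposition(hex = 1, hexnac = 2,
                                                  neuac = 1)), 4), 859.3070)
  expect_error(GlycanComposition(hex = -1), "not.*TRUE|negative")
})

test_that("printed precursor and oxonium anchors reproduce at stated rounding", {
  tm9s3 <- function(hexnac) Glycopeptide(
    "IVDVNLTSEGK", GlycanComposition(hex = 5, hexnac = hexnac, neuac = 2),
    glycoClass = "N", glycosite = 5)
  expect_equal(round(precursorMz(tm9s3(4), 3), 2), 1127.14)
  expect_equal(round(precursorMz(tm9s3(6), 3), 2), 1262.53)
  glpa <- Glycopeptide("DTYAATPR",
                       GlycanComposition(hex = 1, hexnac = 2, neuac = 2),
                       glycoClass = "O", glycosite = 2)
  expect_equal(round(precursorMz(glpa, 2), 2), 1022.92)

  sda <- GlycanComposition(hex = 1, hexnac = 2, neuac = 1)
  expect_equal(round(oxoniumMz(sda), 4), 860.3143)
  expect_equal(round(oxoniumMz(GlycanComposition(neuac = 1)), 2), 292.10)
  expect_equal(round(oxoniumMz(GlycanComposition(neuac = 1),
                               waterLosses = 1), 2), 274.09)
  expect_error(oxoniumMz(GlycanComposition()), "empty")
  expect_error(precursorMz(glpa, 0), "charge")
})

test_that("modification masses come from elemental formulas", {
  expect_equal(round(modificationMass("CH2S"), 4), 45.9877)
  expect_equal(round(modificationMass("O"), 4), 15.9949)
  expect_identical(modificationMass(""), 0)
  expect_error(modificationMass("XeF4"), "unknown element")
  defaults <- defaultModifications()
  expect_equal(defaults$static$residue, "C")
  expect_equal(round(defaults$variable$delta, 4), 15.9949)
})

test_that("glycopeptide mass is additive and matches the atom-count oracle", {
  set.seed(11)
  for (i in 1:200) {
    pep <- randomPeptide(sample(4:18, 1))
    g <- randomComposition()
    gp <- Glycopeptide(pep, g, glycoClass = "O")
    total <- precursorMz(gp, 1) - massConstants()$proton
    expect_equal(total, peptideMass(pep) + glycanMass(g), tolerance = 1e-10)
    expect_equal(total,
                 oracleGlycopeptideMass(pep, g@hex, g@hexnac, g@neuac,
                                        g@dhex),
                 tolerance = 1e-6)
  }
})

test_that("precursor m/z decreases in charge and neutral mass is charge-invariant", {
  set.seed(12)
  p <- massConstants()$proton
  for (i in 1:50) {
    gp <- Glycopeptide(randomPeptide(sample(5:15, 1)), randomComposition(),
                       glycoClass = "O")
    mzs <- precursorMz(gp, 1:7)
    expect_true(all(diff(mzs) < 0))
    neutral <- (1:7) * mzs - (1:7) * p
    expect_lt(max(neutral) - min(neutral), 1e-9)
  }
})

test_that("modifications must target residues present in the peptide", {
  mods <- data.frame(pos = 5L, delta = 15.9949, name = "Oxidation")
  expect_error(peptideMass("AGK", mods), "absent")
  withMod <- peptideMass("AGKAM", mods)
  expect_equal(withMod, peptideMass("AGKAM") + 15.9949, tolerance = 1e-9)
})
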