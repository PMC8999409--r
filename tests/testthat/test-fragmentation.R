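tm9s3Sda <- Glycopeptide("IVDVNLTSEGK",
                         GlycanComposition(hex = 5, hexnac = 6, neuac = 2),
                         glycoClass = "N", glycosite = 5, sda = TRUE)
glpaSda <- Glycopeptide("DTYAATPR",
                        GlycanComposition(hex = 1, hexnac = 2, neuac = 2),
                        glycoClass = "O", glycosite = 2, sda = TRUE)

test_that("glycosidic ladders contain the documented Y ions", {
  lad <- glycosidicLadder(tm9s3Sda)
  pepHexNAc <- lad[lad$label == "peptide+HexNAc1" & lad$z == 1, ]
  expect_equal(round(pepHexNAc$mz, 2), 1377.71)
  # N-class ladder never drops below peptide+HexNAc
  expect_false("peptide" %in% lad$label)

  ladO <- glycosidicLadder(glpaSda)
  pep <- ladO[ladO$label == "peptide" & ladO$z == 1, ]
  expect_equal(round(pep$mz, 4), 894.4316)

  minimal <- glycosidicLadder(
    Glycopeptide("DTYAATPR", GlycanComposition(hexnac = 1),
                 glycoClass = "O", glycosite = 2), charges = 1)
  expect_setequal(minimal$label, c("peptide+HexNAc1", "peptide"))
  minimalN <- glycosidicLadder(
    Glycopeptide("IVDVNLTSEGK", GlycanComposition(hexnac = 1),
                 glycoClass = "N", glycosite = 5), charges = 1)
  expect_setequal(minimalN$label, "peptide+HexNAc1")

  expect_error(glycosidicLadder(
    Glycopeptide("DTYAATPR", GlycanComposition(), glycoClass = "O",
                 glycosite = 2)), "empty glycan")
})

test_that("every Y ion equals the precursor m/z of its sub-glycoform", {
  set.seed(31)
  for (i in 1:10) {
    g <- randomComposition()
    if (glycanTotal(g) == 0) g <- GlycanComposition(hexnac = 2, hex = 1)
    gp <- Glycopeptide(randomPeptide(8), g, glycoClass = "O")
    lad <- glycosidicLadder(gp, charges = 1:2)
    pm <- peptideMass(gp)
    p <- massConstants()$proton
    # every Y ion carries the intact peptide: neutral fragment mass is the
    # peptide mass plus a non-negative glycan remainder
    remainder <- lad$mz * lad$z - lad$z * p - pm
    expect_true(all(remainder >= -1e-9))
    # the full-glycan Y ion coincides with the precursor m/z at each charge
    full <- lad[lad$label == paste0("peptide+", glycanName(g)), ]
    expect_equal(full$mz, precursorMz(gp, full$z), tolerance = 1e-10)
  }
})

test_that("oxonium prediction follows composition and the Sda annotation", {
  sda <- oxoniumIons(GlycanComposition(hex = 5, hexnac = 6, neuac = 2),
                     sda = TRUE)
  expect_true(any(round(sda$mz, 4) == 860.3143))
  expect_true(any(round(sda$mz, 2) == 292.10))
  expect_true(any(round(sda$mz, 2) == 274.09))

  highMan <- oxoniumIons(GlycanComposition(hex = 5, hexnac = 2))
  expect_false(any(round(highMan$mz, 2) %in% c(274.09, 292.10, 860.31)))

  # biantennary precursor: sialylated but not Sda-annotated
  bi <- oxoniumIons(GlycanComposition(hex = 5, hexnac = 4, neuac = 2),
                    sda = FALSE)
  expect_true(any(round(bi$mz, 2) == 292.10))
  expect_false(any(round(bi$mz, 4) == 860.3143))

  # isomeric bisecting-GlcNAc composition, not Sda: no 860.31 either
  bis <- oxoniumIons(GlycanComposition(hex = 5, hexnac = 5, neuac = 2,
                                       dhex = 1), sda = FALSE)
  expect_false(any(round(bis$mz, 4) == 860.3143))
  expect_error(oxoniumIons(GlycanComposition()), "empty")
})

test_that("oxonium ions are peptide-independent", {
  g <- GlycanComposition(hex = 1, hexnac = 2, neuac = 2)
  a <- theoreticalSpectrum(Glycopeptide("DTYAATPR", g, "O", 2, sda = TRUE), 20)
  b <- theoreticalSpectrum(Glycopeptide("SALDTAAR", g, "O", 5, sda = TRUE), 20)
  expect_identical(a[a$class == "oxonium", c("label", "mz")],
                   b[b$class == "oxonium", c("label", "mz")])
})

test_that("b/y ladders are complete and complementary", {
  bb <- backboneIons("GG")
  expect_equal(round(bb$mz[bb$label == "b1"], 4), 58.0287)
  expect_equal(round(bb$mz[bb$label == "y1"], 4), 76.0393)

  anyK <- backboneIons("LVAEK")
  expect_equal(round(anyK$mz[anyK$label == "y1"], 4), 147.1128)

  set.seed(32)
  p <- massConstants()$proton
  for (i in 1:20) {
    pep <- randomPeptide(sample(3:15, 1))
    n <- nchar(pep)
    bb <- backboneIons(pep)
    expect_equal(nrow(bb), 2 * (n - 1))
    M <- peptideMass(pep)
    for (k in seq_len(n - 1)) {
      bi <- bb$mz[bb$label == paste0("b", k)]
      yi <- bb$mz[bb$label == paste0("y", n - k)]
      expect_equal(bi + yi, M + 2 * p, tolerance = 1e-9)
    }
  }
  expect_error(backboneIons("K"), "at least 2")
})

test_that("NCE tiers carry the configured class weights", {
  s20 <- theoreticalSpectrum(glpaSda, 20)
  expect_setequal(unique(s20$weight[s20$class != "backbone"]), 1)
  expect_setequal(unique(s20$weight[s20$class == "backbone"]), 0.05)
  s30 <- theoreticalSpectrum(glpaSda, 30)
  expect_setequal(unique(s30$weight[s30$class == "backbone"]), 1)
  expect_setequal(unique(s30$weight[s30$class != "backbone"]), 0.3)
  expect_error(theoreticalSpectrum(glpaSda, 25), "NCE tier")
})
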