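# candidate space over the synthetic carrier proteins, shared across blocks
cfg <- searchConfig()
lib <- readGlycanLibrary()
cands <- generateCandidates(sdaProteins(), lib, cfg)

glpaSda <- Glycopeptide("DTYAATPR",
                        GlycanComposition(hex = 1, hexnac = 2, neuac = 2),
                        glycoClass = "O", glycosite = 2, sda = TRUE)
tm9s3Sda <- Glycopeptide("IVDVNLTSEGK",
                         GlycanComposition(hex = 5, hexnac = 6, neuac = 2),
                         glycoClass = "N", glycosite = 5, sda = TRUE)

test_that("candidate generation pairs sequon/Ser-Thr peptides with class-matched glycans", {
  tm <- cands[cands$peptide == "IVDVNLTSEGK" & !cands$decoy, ]
  expect_gte(sum(tm$glycoClass == "N"), 2)
  expect_true(all(tm$glycanName[tm$glycoClass == "N"] %in%
                    lib$name[lib$class == "N"]))

  # the B3AT peptide: sequon at the Asn of the N-S-S motif (position 11)
  b3 <- cands[cands$peptide == "LSVPDGFKVSNSSAR" & cands$glycoClass == "N", ]
  expect_true(nrow(b3) > 0)
  expect_true(all(b3$glycosite == 11L))

  # peptides without sequon get no N-candidates
  noSeq <- cands[cands$glycoClass == "N", "peptide"]
  expect_false("DTYAATPR" %in% noSeq)
  expect_error(generateCandidates(sdaProteins(), lib[0, ], cfg),
               "empty glycan library")
})

test_that("a planted triplet is matched to its identity with computed flags", {
  pmz <- precursorMz(glpaSda, 2)
  run <- makeRun(tripletScans(glpaSda, pmz, 2L))
  psms <- matchRun(run, cands, cfg)
  expect_equal(nrow(psms), 1L)
  expect_equal(psms$peptide, "DTYAATPR")
  expect_equal(psms$glycanName, "NeuAc2Hex1HexNAc2")
  expect_equal(psms$glycoClass, "O")
  expect_true(psms$verified)
  expect_true(psms$flagPep && psms$flagNeuAcPair && psms$flagSda860)
  expect_lt(abs(psms$ppmErrorPrec), cfg$ms1TolPpm)
  expect_error(matchRun(makeRun(list(makeScan(1L, 1L, 5, 100, 1))),
                        cands, cfg), "no MS2")
})

test_that("precursor tolerance is enforced", {
  pmz <- precursorMz(glpaSda, 2) * (1 + 5e-6)   # inject a 5 ppm shift
  run <- makeRun(tripletScans(glpaSda, pmz, 2L))
  tight <- searchConfig(ms1TolPpm = 0.1)
  expect_equal(nrow(matchRun(run, cands, tight)), 0L)
  # at the default 10 ppm the shifted precursor still matches
  expect_equal(nrow(matchRun(run, cands, cfg)), 1L)
})

test_that("verification rules reject spectra missing their required ions", {
  pmz <- precursorMz(tm9s3Sda, 3)
  # remove the peptide+HexNAc Y ion: N-glycopeptide rule must fire
  runNoY1 <- makeRun(tripletScans(tm9s3Sda, pmz, 3L,
                                  drop = "peptide+HexNAc1"))
  psms <- matchRun(runNoY1, cands, cfg)
  best <- psms[psms$peptide == "IVDVNLTSEGK", ]
  expect_true(all(!best$verified))
  expect_equal(nrow(fdrFilter(psms, cfg$scoreCutoff)$accepted), 0L)

  # remove the NeuAc oxonium pair: sialylation rule must fire
  runNoOx <- makeRun(tripletScans(tm9s3Sda, pmz, 3L,
                                  drop = c("NeuAc", "NeuAc-H2O")))
  psms2 <- matchRun(runNoOx, cands, cfg)
  expect_true(all(!psms2$verified[psms2$peptide == "IVDVNLTSEGK"]))

  # intact spectra are accepted
  runOk <- makeRun(tripletScans(tm9s3Sda, pmz, 3L))
  psms3 <- matchRun(runOk, cands, cfg)
  expect_true(any(psms3$verified & psms3$peptide == "IVDVNLTSEGK" &
                    psms3$glycanName == "NeuAc2Hex5HexNAc6"))
})

test_that("the score ignores peak order and off-tolerance noise", {
  pmz <- precursorMz(glpaSda, 2)
  base <- tripletScans(glpaSda, pmz, 2L)
  s0 <- matchRun(makeRun(base), cands, cfg)$score
  # append junk peaks far from every theoretical ion
  noisy <- lapply(base, function(sc) {
    makeScan(sc@scanNum, 2L, sc@rt,
             c(sc@mz, 123.456, 433.219, 777.77),
             c(sc@intensity, 400, 350, 420),
             precursorMz = sc@precursorMz,
             precursorCharge = sc@precursorCharge, nce = sc@nce)
  })
  s1 <- matchRun(makeRun(noisy), cands, cfg)$score
  expect_equal(s0, s1, tolerance = 1e-12)
})

test_that("FDR arithmetic, monotonicity and rescue behave as specified", {
  mk <- function(n, score, decoy, peptide = "AAAK") {
    data.frame(score = rep(score, n), decoy = decoy, verified = TRUE,
               peptide = peptide, rescued = FALSE, sda = FALSE)
  }
  psms <- rbind(mk(200, 400, FALSE), mk(1, 400, TRUE))
  f <- fdrFilter(psms, 300, rescue = FALSE)
  expect_equal(f$fdr, 0.005)
  expect_equal(f$nTarget, 200L)

  empty <- fdrFilter(psms, 500, rescue = FALSE)
  expect_true(is.na(empty$fdr))
  expect_equal(nrow(empty$accepted), 0L)

  set.seed(41)
  rnd <- data.frame(score = runif(300, 0, 100),
                    decoy = runif(300) < 0.3, verified = TRUE,
                    peptide = replicate(300, randomPeptide(6)),
                    rescued = FALSE, sda = FALSE)
  cutoffs <- seq(0, 100, by = 10)
  stats <- t(vapply(cutoffs, function(ct) {
    f <- fdrFilter(rnd, ct, rescue = FALSE)
    c(f$nTarget, f$nDecoy)
  }, numeric(2)))
  expect_true(all(diff(stats[, 1]) <= 0))   # numerator and denominator
  expect_true(all(diff(stats[, 2]) <= 0))   # never rise with the cutoff

  # rescue only ever adds PSMs whose peptide is already accepted
  psmsR <- rbind(mk(2, 400, FALSE, "SHAREDK"),
                 mk(1, 50, FALSE, "SHAREDK"),
                 mk(1, 50, FALSE, "OTHERK"))
  fr <- fdrFilter(psmsR, 300, rescue = TRUE)
  expect_equal(nrow(fr$accepted), 3L)
  expect_true(all(fr$accepted$peptide == "SHAREDK"))
  expect_true(any(fr$accepted$rescued))
})
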