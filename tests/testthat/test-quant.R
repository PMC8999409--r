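# MS1-only run with two co-planted glycoforms as Gaussian elution profiles
gaussianRun <- function(mzA, hA, rtA, mzB, hB, rtB, sigma = 0.085,
                        from = 20, to = 26, by = 0.02, scale = 1) {
  ts <- seq(from, to, by = by)
  makeRun(lapply(seq_along(ts), function(i) {
    t <- ts[i]
    makeScan(i, 1L, t, c(mzA, mzB),
             scale * c(hA * exp(-(t - rtA)^2 / (2 * sigma^2)),
                       hB * exp(-(t - rtB)^2 / (2 * sigma^2))))
  }))
}

test_that("AUC integration matches closed forms", {
  flat <- data.frame(rt = seq(0, 1, 0.01), intensity = 0)
  expect_equal(aucTrace(flat), 0)

  rect <- data.frame(rt = seq(0, 2, 0.001), intensity = 5)
  expect_equal(aucTrace(rect), 10, tolerance = 1e-9)

  rt <- seq(-5, 5, 0.01)
  gauss <- data.frame(rt = rt, intensity = dnorm(rt))
  expect_equal(aucTrace(gauss), 1, tolerance = 1e-3)

  # additive over disjoint RT partitions
  cut <- 251
  expect_equal(aucTrace(gauss[1:cut, ]) + aucTrace(gauss[cut:nrow(gauss), ]),
               aucTrace(gauss), tolerance = 1e-12)
  expect_error(aucTrace(gauss[1, ]), "at least 2")
})

test_that("XIC extracts only peaks within tolerance and honors the RT window", {
  run <- gaussianRun(1127.1395, 1e6, 22, 1262.5257, 1e6, 23)
  on <- xic(run, 1127.1395, tolPpm = 10)
  expect_equal(nrow(on), sum(msLevels(run) == 1L))
  expect_gt(max(on$intensity), 9e5)
  # 50 ppm off-target at 0.01 ppm tolerance: nothing extracted
  off <- xic(run, 1127.1395 * (1 + 5e-5), tolPpm = 0.01)
  expect_true(all(off$intensity == 0))
  expect_error(xic(run, 1127.1395, rtWindow = c(5, 2)), "empty RT window")
  expect_error(xic(makeRun(list(makeScan(1L, 2L, 1, 100, 1,
                                         precursorMz = 500,
                                         precursorCharge = 2L, nce = 20))),
                   1127), "no MS1")
})

test_that("presence/absence XIC pattern distinguishes mock-like from wt-like runs", {
  mzPre <- 1127.1395; mzSda <- 1262.5257
  mockLike <- gaussianRun(mzPre, 1e6, 22, mzSda, 0, 23)
  expect_true(all(xic(mockLike, mzSda)$intensity == 0))
  expect_gt(max(xic(mockLike, mzPre)$intensity), 0)
  wtLike <- gaussianRun(mzPre, 0, 22, mzSda, 1e6, 23)
  expect_true(all(xic(wtLike, mzPre)$intensity == 0))
  expect_gt(max(xic(wtLike, mzSda)$intensity), 0)
})

test_that("relative peak intensity recovers planted fractions and their complement", {
  pre <- GlycanComposition(hex = 1, hexnac = 1, neuac = 2)
  pair <- glycoformPair("DTYAATPR", pre, glycoClass = "O", charges = 2)
  pm <- peptideMass("DTYAATPR")
  p <- massConstants()$proton
  mzB <- (pm + glycanMass(pre) + 2 * p) / 2
  mzA <- (pm + glycanMass(pair$glycanA) + 2 * p) / 2
  expect_equal(round(mzA, 2), 1022.92)     # pair invariant: A = B + HexNAc

  run <- gaussianRun(mzA, 0.12e6, 22.5, mzB, 0.88e6, 22)
  q <- relativePeakIntensity(run, pair, diagnosticConfirmed = TRUE)
  expect_equal(q$percentSda, 12, tolerance = 0.02)
  expect_false(q$ambiguous)
  # complement: the precursor's share is 100 - the Sda share
  expect_equal(100 * q$aucB / (q$aucA + q$aucB), 100 - q$percentSda,
               tolerance = 1e-9)
})

test_that("relative peak intensity is scale invariant and NA when both AUCs vanish", {
  pre <- GlycanComposition(hex = 1, hexnac = 1, neuac = 2)
  pair <- glycoformPair("DTYAATPR", pre, glycoClass = "O", charges = 2)
  pm <- peptideMass("DTYAATPR")
  p <- massConstants()$proton
  mzB <- (pm + glycanMass(pre) + 2 * p) / 2
  mzA <- (pm + glycanMass(pair$glycanA) + 2 * p) / 2
  r1 <- gaussianRun(mzA, 0.3e6, 22.5, mzB, 0.7e6, 22)
  r2 <- gaussianRun(mzA, 0.3e6, 22.5, mzB, 0.7e6, 22, scale = 137)
  q1 <- relativePeakIntensity(r1, pair, diagnosticConfirmed = TRUE)
  q2 <- relativePeakIntensity(r2, pair, diagnosticConfirmed = TRUE)
  expect_equal(q1$percentSda, q2$percentSda, tolerance = 1e-12)

  blank <- gaussianRun(500, 0, 22, 600, 0, 23)
  qb <- relativePeakIntensity(blank, pair, diagnosticConfirmed = TRUE)
  expect_true(is.na(qb$percentSda))
})

test_that("composition ambiguity is resolved only by diagnostic-ion evidence", {
  pre <- GlycanComposition(hex = 5, hexnac = 4, neuac = 2, dhex = 1)
  pair <- glycoformPair("LSVPDGFKVSNSSAR", pre, glycoClass = "N",
                        charges = 3)
  pm <- peptideMass("LSVPDGFKVSNSSAR",
                    data.frame(pos = 1L, delta = 0, name = "none"))
  p <- massConstants()$proton
  mzA <- (pm + glycanMass(pair$glycanA) + 3 * p) / 3
  mzB <- (pm + glycanMass(pre) + 3 * p) / 3
  run <- gaussianRun(mzA, 0.18e6, 30.5, mzB, 0.82e6, 30)

  q0 <- relativePeakIntensity(run, pair)
  expect_true(q0$ambiguous)                      # no MS2 evidence supplied

  near <- data.frame(scanNum = 1L, rt = 30.5, intensity = 500,
                     precursorMz = mzA + 1, precursorCharge = 3L,
                     nScans = 1L)
  q1 <- relativePeakIntensity(run, pair, diagnosticCandidates = near)
  expect_false(q1$ambiguous)

  far <- near; far$precursorMz <- mzA + 50
  q2 <- relativePeakIntensity(run, pair, diagnosticCandidates = far)
  expect_true(q2$ambiguous)
})
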