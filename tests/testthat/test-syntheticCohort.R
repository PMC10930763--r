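test_that("cohortConfig validates its invariants", {
  expect_error(cohortConfig(nSamples = 0), "positive")
  expect_error(cohortConfig(informativeFraction = 0), "informativeFraction")
  expect_error(cohortConfig(nSamples = 20, patchesPerBag = 4,
                            informativeFraction = 0.1), ">= 1")
  expect_error(cohortConfig(nSites = 3), "5 sites")
  expect_error(cohortConfig(nSamples = 8, nSites = 10), "exceed")
  expect_error(cohortConfig(censoringRate = 1), "censoringRate")
  expect_error(cohortConfig(nGenes = 2, coxCoefficients = c(1, 2)), "entry per gene")
})

test_that("generateExpression is deterministic with the documented distribution", {
  cfg <- cohortConfig(nSamples = 8, nGenes = 1, featureDim = 4,
                      patchesPerBag = 4, nSites = 5, seed = 13)
  e1 <- generateExpression(cfg)
  e2 <- generateExpression(cfg)
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(1L, 8L))
  # law of large numbers: sample mean within 3 standard errors of config mean
  big <- cohortConfig(nSamples = 10000, nGenes = 3, featureDim = 8,
                      patchesPerBag = 4, coxCoefficients = c(1, 0, 0, .2, .3, .5),
                      seed = 19)
  eb <- generateExpression(big)
  se <- big$geneSds / sqrt(10000)
  expect_true(all(abs(rowMeans(eb) - big$geneMeans) < 3 * se))
})

test_that("generateBags plants an exactly recoverable signal", {
  # zero-noise, all-informative limit: patch projections equal standardized
  # expression to machine precision
  cfg <- cohortConfig(nSamples = 25, nGenes = 2, featureDim = 8,
                      patchesPerBag = 6, informativeFraction = 1, noiseSd = 0,
                      nSites = 5, coxCoefficients = c(1, 0, .2, .3, .5), seed = 3)
  e <- generateExpression(cfg)
  b <- generateBags(e, cfg)
  z <- t(scale(t(e)))
  for (g in 1:2) {
    proj <- vapply(seq_len(25), function(i)
      mean(bagFeatures(b$bags[[i]]) %*% b$signalDirections[, g]), 0)
    expect_equal(proj, unname(z[g, ]), tolerance = 1e-12)
  }
  # signal directions are orthonormal
  expect_equal(crossprod(b$signalDirections), diag(2), tolerance = 1e-12,
               ignore_attr = TRUE)
  # forced informative count
  cfg2 <- cohortConfig(nSamples = 10, nGenes = 1, featureDim = 6,
                       patchesPerBag = 10, informativeFraction = 0.3,
                       nSites = 5, coxCoefficients = c(1, .2, .3, .5), seed = 4)
  b2 <- generateBags(generateExpression(cfg2), cfg2)
  expect_true(all(vapply(b2$informativeMask, sum, 0L) == 3L))
  expect_error(generateBags(matrix(0, 2, 3), cfg2), "dimensions")
})

test_that("informative-vs-noise projection contrast is proportional to expression", {
  cfg <- cohortConfig(nSamples = 500, nGenes = 1, featureDim = 16,
                      patchesPerBag = 20, informativeFraction = 0.5,
                      noiseSd = 0.1, nSites = 8,
                      coxCoefficients = c(1, .2, .3, .5), seed = 8)
  e <- generateExpression(cfg)
  b <- generateBags(e, cfg)
  z <- as.numeric(scale(e[1, ]))
  contrast <- vapply(seq_len(500), function(i) {
    f <- bagFeatures(b$bags[[i]]) %*% b$signalDirections[, 1]
    mean(f[b$informativeMask[[i]]]) - mean(f[!b$informativeMask[[i]]])
  }, 0)
  slope <- coef(lm(contrast ~ z))[["z"]]
  expect_lt(abs(slope - 1), 0.05)         # slope recovered within 5%
})

test_that("generateSurvival inverts the Cox model it claims", {
  # null model: expression unrelated to survival
  cfgN <- cohortConfig(nSamples = 2000, nGenes = 1, featureDim = 4,
                       patchesPerBag = 4, nSites = 5,
                       coxCoefficients = c(0, 0, 0, 0), seed = 31)
  eN <- generateExpression(cfgN)
  clN <- generateSurvival(eN, cfgN)
  expect_true(all(clN$os_months > 0))
  expect_true(all(clN$os_event %in% 0:1))
  cN <- concordanceIndex(clN$os_months, clN$os_event, eN[1, ])
  expect_lt(abs(cN - 0.5), 0.02)
  # forced zero censoring
  cfg0 <- cohortConfig(nSamples = 50, nGenes = 1, featureDim = 4,
                       patchesPerBag = 4, nSites = 5, censoringRate = 0,
                       coxCoefficients = c(1, .2, .3, .5), seed = 5)
  cl0 <- generateSurvival(generateExpression(cfg0), cfg0)
  expect_true(all(cl0$os_event == 1))
  # empirical censoring matches the target
  cfgC <- cohortConfig(nSamples = 4000, nGenes = 1, featureDim = 4,
                       patchesPerBag = 4, nSites = 5, censoringRate = 0.4,
                       coxCoefficients = c(1, .2, .3, .5), seed = 6)
  clC <- generateSurvival(generateExpression(cfgC), cfgC)
  expect_lt(abs(mean(1 - clC$os_event) - 0.4), 0.03)
})

test_that("cohort assembly keeps samples aligned and sites unequal", {
  coh <- tinyCohort(seed = 99)
  clin <- clinicalTable(coh)
  expr <- expressionMatrix(coh)
  bags <- cohortBags(coh)
  expect_identical(vapply(bags, sampleId, ""), colnames(expr))
  expect_identical(clin$sample_id, colnames(expr))
  expect_identical(vapply(bags, bagSite, ""), clin$site)
  expect_gt(length(unique(table(clin$site))), 1)  # unequal site sizes
  # regeneration with the same config is identical
  coh2 <- tinyCohort(seed = 99)
  expect_identical(expressionMatrix(coh2), expr)
  expect_identical(bagFeatures(cohortBags(coh2)[[7]]), bagFeatures(bags[[7]]))
})

test_that("generateTiles emits the four documented kinds deterministically", {
  tl <- generateTiles(nPerKind = 1, seed = 12, side = 64)
  labs <- vapply(tl, `[[`, "", "label")
  expect_setequal(labs, c("background", "sharp", "blurred", "checkerboard"))
  bg <- tl[[which(labs == "background")]]$pixels
  expect_equal(length(unique(as.numeric(bg))), 1L)  # all pixels equal
  expect_true(all(vapply(tl, function(x) all(x$pixels >= 0 & x$pixels <= 255), NA)))
  # two-stain tile ODs are rank-2 up to noise: third singular value tiny
  sharp <- generateTiles(nPerKind = 1, seed = 12, odNoiseSd = 0.005)[[2]]
  od <- wsiSurrogate:::rgbToOd(sharp$pixels)
  sv <- svd(od)$d
  expect_lt(sv[3] / sv[1], 0.05)
  # identical PNG bytes for identical seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeTiles(generateTiles(nPerKind = 1, seed = 4, side = 48), d1)
  writeTiles(generateTiles(nPerKind = 1, seed = 4, side = 48), d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_identical(lapply(f1, readBin, "raw", 1e6), lapply(f2, readBin, "raw", 1e6))
})

test_that("cohort tables round-trip through the TSV writers", {
  coh <- tinyCohort(seed = 15)
  d <- withr::local_tempdir()
  writeExpressionTSV(expressionMatrix(coh), file.path(d, "expr.tsv"))
  e2 <- readExpressionTSV(file.path(d, "expr.tsv"))
  expect_equal(e2, expressionMatrix(coh), tolerance = 1e-9)
  writeClinicalTSV(clinicalTable(coh), file.path(d, "clin.tsv"))
  c2 <- readClinicalTSV(file.path(d, "clin.tsv"))
  expect_equal(c2$os_months, clinicalTable(coh)$os_months, tolerance = 1e-9)
  writeBags(cohortBags(coh)[1:3], file.path(d, "bags"))
  b2 <- readBags(file.path(d, "bags"))
  expect_equal(bagFeatures(b2[[2]]), bagFeatures(cohortBags(coh)[[2]]),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_identical(sampleId(b2[[2]]), sampleId(cohortBags(coh)[[2]]))
})
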