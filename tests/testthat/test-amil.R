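test_that("attentionScores matches scalar re-evaluation and its contracts", {
  set.seed(2)
  h1 <- matrix(rnorm(256), 1)
  V <- matrix(rnorm(128 * 256, sd = 0.1), 128)
  w <- rnorm(128, sd = 0.1)
  expect_equal(attentionScores(h1, V, w), 1)
  h4 <- matrix(rep(rnorm(256), each = 4), 4)
  expect_equal(attentionScores(h4, V, w), rep(0.25, 4))
  for (r in 1:10) {
    h <- matrix(rnorm(3 * 256), 3)
    a <- attentionScores(h, V, w)
    expect_equal(a, bruteAttention(h, V, w), tolerance = 1e-6)
    expect_equal(sum(a), 1, tolerance = 1e-12)
    expect_true(all(a > 0))
  }
  h <- matrix(rnorm(2 * 256), 2); h[1, 1] <- NA
  expect_error(attentionScores(h, V, w), "finite")
})

test_that("attentionPool selects, averages and stays permutation invariant", {
  set.seed(3)
  h <- matrix(rnorm(3 * 256), 3)
  expect_equal(attentionPool(h, c(1, 0, 0)), h[1, ], tolerance = 1e-12)
  expect_equal(attentionPool(h, rep(1 / 3, 3)), colMeans(h), tolerance = 1e-12)
  a <- c(0.2, 0.5, 0.3)
  perm <- c(3, 1, 2)
  expect_equal(attentionPool(h[perm, ], a[perm]), attentionPool(h, a),
               tolerance = 1e-12)
  expect_error(attentionPool(h, c(0.5, 0.5)), "match")
  expect_error(attentionPool(h, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("sampleWeights implements inverse-frequency bin weighting", {
  expect_equal(sampleWeights(c(0.1, 0.2, 0.3, 0.9), weightBins = 2),
               c(2/3, 2/3, 2/3, 2))
  # uniform occupancy -> all weights 1
  expect_equal(sampleWeights(seq(0.05, 0.95, by = 0.1), weightBins = 10),
               rep(1, 10))
  set.seed(4)
  for (r in 1:10) {
    y <- runif(sample(5:50, 1))
    expect_equal(mean(sampleWeights(y)), 1, tolerance = 1e-12)
  }
  expect_error(sampleWeights(numeric()), "empty")
})

test_that("balancedMSE reduces to plain MSE with unit weights", {
  expect_equal(balancedMSE(c(1, 2), c(1, 2)), 0)
  expect_equal(balancedMSE(c(1, 2), c(0, 1)), 1)             # residuals (1,1)
  expect_equal(balancedMSE(c(1, 5), c(0, 0), w = c(2, 0)), 1)
  set.seed(6)
  y <- runif(20); yh <- runif(20)
  expect_equal(balancedMSE(y, yh), mean((y - yh)^2), tolerance = 1e-12)
  expect_error(balancedMSE(1:3, 1:2), "mismatch")
})

test_that("coxLoss equals brute-force enumerated risk sets and is shift invariant", {
  expect_equal(coxLoss(c(1, 2, 3), c(1, 1, 0), c(0, 0, 0)),
               (log(3) + log(2)) / 2, tolerance = 1e-12)
  expect_equal(coxLoss(5, 1, 2.7), 0, tolerance = 1e-12)
  set.seed(8)
  for (r in 1:30) {
    n <- sample(2:8, 1)
    t <- sample(1:5, n, replace = TRUE)
    e <- rbinom(n, 1, 0.7); if (sum(e) == 0) e[1] <- 1
    s <- rnorm(n)
    expect_equal(coxLoss(t, e, s), bruteCoxNegPLL(t, e, s), tolerance = 1e-9)
    expect_equal(coxLoss(t, e, s + 3.7), coxLoss(t, e, s), tolerance = 1e-9)
  }
  expect_error(coxLoss(1:3, c(0, 0, 0), rnorm(3)), "event")
})

test_that("training is reproducible and inference is order/batch independent", {
  coh <- tinyCohort(seed = 23)
  bags <- cohortBags(coh)
  y <- expressionMatrix(coh)["gene001", ]
  cfg <- trainConfig(epochs = 4, seed = 5)
  m1 <- trainAmil(bags, targets = y, config = cfg)
  m2 <- trainAmil(bags, targets = y, config = cfg)
  expect_identical(m1@history, m2@history)       # bitwise-identical history
  expect_identical(m1@weights$W1, m2@weights$W1)
  # inference determinism
  p1 <- amilForward(m1, bags[[3]])$prediction
  expect_identical(p1, amilForward(m1, bags[[3]])$prediction)
  expect_gt(p1, 0); expect_lt(p1, 1)             # logistic output range
  # MIL permutation invariance of the forward pass
  f <- bagFeatures(bags[[3]])
  shuffled <- patchBag(sampleId(bags[[3]]), f[sample(nrow(f)), ],
                       bagSite(bags[[3]]))
  expect_equal(amilForward(m1, shuffled)$prediction, p1, tolerance = 1e-6)
  # scaler round trip
  pr <- predictAmil(m1, bags[1:4])
  pi <- predictAmil(m1, bags[1:4], inverseTransform = TRUE)
  expect_equal((pi - m1@scaler[["min"]]) /
                 (m1@scaler[["max"]] - m1@scaler[["min"]]), pr,
               tolerance = 1e-9)
  expect_true(all(pr > 0 & pr < 1))
  # feature-dimension mismatch is caught
  badBag <- patchBag("X", matrix(rnorm(12), 3, 4))
  expect_error(amilForward(m1, badBag), "dimension")
})

test_that("per-bag attention always normalizes across a trained model", {
  coh <- tinyCohort(seed = 31)
  m <- trainAmil(cohortBags(coh), targets = expressionMatrix(coh)["gene001", ],
                 config = trainConfig(epochs = 2, seed = 2))
  att <- attentionMap(m, cohortBags(coh))
  expect_true(all(abs(vapply(att, sum, 0) - 1) < 1e-9))
  expect_true(all(unlist(att) > 0))
})

test_that("training reduces the loss and learns a noise-free signal", {
  cfg <- cohortConfig(nSamples = 100, nGenes = 1, featureDim = 8,
                      patchesPerBag = 12, informativeFraction = 0.5,
                      noiseSd = 0, nSites = 6,
                      coxCoefficients = c(1, .2, .3, .5), seed = 44)
  coh <- simulateCohort(cfg)
  y <- expressionMatrix(coh)["gene001", ]
  tr <- 1:75; te <- 76:100
  # small cohort: stretch epochs so the optimizer gets a step count
  # comparable to the full-size protocol
  m <- trainAmil(cohortBags(coh)[tr], targets = y[tr],
                 config = trainConfig(epochs = 80, seed = 3))
  expect_lt(m@history[length(m@history)], m@history[1])
  pr <- predictAmil(m, cohortBags(coh)[te])
  expect_gte(cor(pr, y[te]), 0.95)               # noise-free recovery
})

test_that("survival-mode training needs events and respects them per batch", {
  coh <- tinyCohort(seed = 52)
  clin <- clinicalTable(coh)
  expect_error(trainAmil(cohortBags(coh), times = clin$os_months,
                         events = rep(0, nrow(clin)),
                         config = trainConfig(loss = "cox", epochs = 1)),
               "event")
  m <- trainAmil(cohortBags(coh), times = clin$os_months,
                 events = clin$os_event,
                 config = trainConfig(loss = "cox", epochs = 3, seed = 9))
  expect_length(m@history, 3)
  expect_true(all(is.finite(m@history)))
  expect_error(predictAmil(m, cohortBags(coh), inverseTransform = TRUE),
               "scaler")
})

test_that("a trained model round-trips through the text checkpoint", {
  coh <- tinyCohort(seed = 61)
  m <- trainAmil(cohortBags(coh), targets = expressionMatrix(coh)["gene002", ],
                 config = trainConfig(epochs = 2, seed = 4))
  d <- withr::local_tempdir()
  writeAmilModel(m, file.path(d, "ckpt"))
  m2 <- readAmilModel(file.path(d, "ckpt"))
  expect_equal(predictAmil(m2, cohortBags(coh)[1:5]),
               predictAmil(m, cohortBags(coh)[1:5]), tolerance = 1e-7)
  expect_equal(m2@scaler, m@scaler, tolerance = 1e-9)
})
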