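test_that("fitCox matches brute-force partial likelihood and recovers null/planted effects", {
  # null covariate: all zeros -> beta 0, HR 1
  fit0 <- suppressWarnings(
    fitCox(c(3, 1, 4, 2, 6), c(1, 1, 0, 1, 1), rep(0, 5)))
  expect_identical(fit0@coefficients[[1]], 0)
  expect_identical(fit0@hr[[1]], 1)

  # partial log-likelihood at the optimum equals brute-force enumeration
  set.seed(7)
  for (r in 1:20) {
    n <- sample(4:8, 1)
    t <- sample(1:6, n, replace = TRUE)
    e <- rbinom(n, 1, 0.8); if (sum(e) == 0) e[1] <- 1
    x <- rnorm(n)
    fit <- tryCatch(fitCox(t, e, x), error = function(err) NULL,
                    warning = function(w) NULL)
    if (is.null(fit)) next
    expect_equal(fit@logLik, brutePartialLogLik(t, e, x, fit@coefficients),
                 tolerance = 1e-9)
  }

  # Wald machinery: CI bounds ordered, reproducible
  t <- c(5, 8, 2, 9, 4, 7, 3, 6); e <- c(1, 1, 1, 0, 1, 0, 1, 1)
  x <- c(1.2, 0.1, 2, -1, 0.5, -0.2, 1.8, 0)
  f1 <- fitCox(t, e, x); f2 <- fitCox(t, e, x)
  expect_equal(f1@coefficients, f2@coefficients, tolerance = 1e-6)
  expect_true(all(f1@ciLow <= f1@hr & f1@hr <= f1@ciHigh))
})

test_that("fitCox validates input and flags degenerate data", {
  expect_error(fitCox(1:4, c(0, 0, 0, 0), rnorm(4)), "event")
  expect_error(fitCox(1:4, c(1, 1, 0, 0), c(1, NA, 2, 3)), "finite")
  # perfect separation -> monotone-likelihood warning
  expect_warning(fitCox(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 1, 1, 1),
                        c(10, 9, 8, 3, 2, 1)), "infinite|separation")
})

test_that("bhAdjust matches the direct step-up formula and its contracts", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.37), 0.37)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  set.seed(11)
  for (r in 1:20) {
    p <- runif(sample(1:40, 1))
    adj <- bhAdjust(p)
    expect_equal(adj, bruteBH(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))  # order-preserving
  }
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("concordanceIndex equals O(n^2) pair enumeration and handles edge cases", {
  expect_equal(concordanceIndex(1:4, rep(1, 4), 4:1), 1)
  expect_equal(concordanceIndex(1:4, rep(1, 4), rep(2, 4)), 0.5)
  set.seed(5)
  for (r in 1:50) {
    n <- 50
    t <- sample(1:20, n, replace = TRUE)
    e <- rbinom(n, 1, 0.6); if (sum(e) == 0) e[1] <- 1
    s <- sample(1:8, n, replace = TRUE)
    expect_equal(concordanceIndex(t, e, s), bruteCIndex(t, e, s),
                 tolerance = 1e-12)
  }
  expect_error(concordanceIndex(c(1, 1), c(0, 0), c(1, 2)), "admissible|event")
})

test_that("logrankTest matches the hand-computed observed/expected table", {
  lr <- logrankTest(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  # by hand: O_A = 2, E_A = 1/2 + 1/3, V = 1/4 + 2/9 -> chisq = 2.882353
  expect_equal(lr$statistic, 2.882353, tolerance = 1e-6)
  expect_equal(lr$p, 0.08955507, tolerance = 1e-6)
  # identical groups -> statistic 0
  lr0 <- logrankTest(rep(c(1, 2, 5), 2), rep(c(1, 1, 0), 2),
                     rep(c("A", "B"), each = 3))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1, tolerance = 1e-9)
  # label swap invariance
  g <- c("A", "B", "A", "B", "A", "B")
  t <- c(2, 5, 1, 7, 3, 9); e <- c(1, 1, 1, 0, 1, 1)
  swapped <- ifelse(g == "A", "B", "A")
  expect_equal(logrankTest(t, e, g)$statistic,
               logrankTest(t, e, swapped)$statistic, tolerance = 1e-12)
  expect_error(logrankTest(t, e, rep("A", 6)), "two")
})

test_that("kmEstimate reproduces hand product-limit computations", {
  km <- kmEstimate(1:4, rep(1, 4))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0), tolerance = 1e-12)
  kmc <- kmEstimate(c(2, 4, 7), c(0, 0, 0))
  expect_true(all(kmc$surv == 1))
  # mixed: times (1,2,2,4,5), events (1,0,1,1,0) -> 0.8, 0.6, 0.3
  kmm <- kmEstimate(c(1, 2, 2, 4, 5), c(1, 0, 1, 1, 0))
  expect_equal(kmm$surv[kmm$n_event > 0], c(0.8, 0.6, 0.3), tolerance = 1e-12)
})

test_that("kmeans2Cutoff finds the exact optimum of every split", {
  r <- kmeans2Cutoff(c(0, 0, 0, 10, 10, 10))
  expect_equal(r$cutoff, 5)
  expect_equal(as.character(r$labels), rep(c("low", "high"), each = 3))
  r2 <- kmeans2Cutoff(c(1, 2, 9))
  expect_equal(r2$cutoff, (1.5 + 9) / 2)
  set.seed(9)
  for (rep in 1:25) {
    v <- round(rnorm(sample(5:60, 1)), 2)
    if (length(unique(v)) < 2) next
    got <- kmeans2Cutoff(v)
    want <- bruteKmeans2(v)
    expect_equal(got$wcss, want$wcss, tolerance = 1e-9)
    expect_equal(got$cutoff, want$cutoff, tolerance = 1e-9)
    # order invariance
    expect_equal(kmeans2Cutoff(rev(v))$cutoff, got$cutoff, tolerance = 1e-12)
  }
  expect_error(kmeans2Cutoff(rep(3, 5)), "constant")
})

test_that("phTest is calibrated under proportional hazards and returns valid p", {
  set.seed(21)
  rej <- logical(120)
  for (r in seq_along(rej)) {
    n <- 120
    x <- rnorm(n)
    t <- rexp(n, rate = 0.1 * exp(0.5 * x))
    cens <- rexp(n, 0.03)
    fit <- suppressWarnings(fitCox(pmin(t, cens), as.integer(t <= cens), x))
    p <- suppressWarnings(phTest(fit)$p)
    expect_true(p >= 0 && p <= 1)
    rej[r] <- p < 0.05
  }
  expect_gt(mean(rej), 0.005)  # not degenerate at 0
  expect_lt(mean(rej), 0.15)   # near nominal; tight band checked at acceptance
  expect_error(suppressWarnings(phTest(fitCox(c(1, 2, 3), c(1, 0, 0),
                                              c(1, 2, 3)))), "3 events")
})

test_that("stratifyByExpression reports group effects consistently", {
  coh <- tinyCohort(seed = 77)
  clin <- clinicalTable(coh)
  vals <- expressionMatrix(coh)["gene001", ]
  st <- stratifyByExpression(vals, clin, gene = "gene001")
  expect_s4_class(st, "StratificationResult")
  expect_true(all(table(st@groups) > 0))
  expect_gt(st@cIndex, 0.4)
  # flipping values low<->high about the cutoff inverts the HR
  st2 <- stratifyByExpression(-vals, clin, gene = "gene001")
  expect_equal(st2@hr, 1 / st@hr, tolerance = 1e-6)
  # same code path for any value vector: predicted stand-in works identically
  noisy <- vals + rnorm(length(vals), sd = 1e-6)
  st3 <- stratifyByExpression(noisy, clin, gene = "gene001")
  expect_equal(st3@hr, st@hr, tolerance = 1e-3)
})
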