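# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from first principles (explicit pair/risk-set
# enumeration, direct formulas) rather than calling the package's code paths.

# negative Breslow partial log-likelihood with explicitly enumerated risk sets
bruteCoxNegPLL <- function(times, events, scores) {
  S <- which(events == 1)
  total <- 0
  for (i in S) {
    riskSet <- which(times >= times[i])
    total <- total + scores[i] - log(sum(exp(scores[riskSet])))
  }
  -total / length(S)
}

# Breslow partial log-likelihood of a linear Cox model at coefficients beta
brutePartialLogLik <- function(times, events, X, beta) {
  lp <- as.numeric(as.matrix(X) %*% beta)
  -bruteCoxNegPLL(times, events, lp) * sum(events == 1)
}

# Harrell's C by O(n^2) pair enumeration; ties in score count 0.5; for tied
# times only event-vs-censored pairs are admissible (the censored sample is
# taken to survive at least as long)
bruteCIndex <- function(t, e, s) {
  num <- 0; den <- 0; n <- length(t)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- i; b <- j
    if (t[j] < t[i]) { a <- j; b <- i }
    if (t[a] < t[b]) {
      if (e[a] == 1) {
        den <- den + 1
        num <- num + if (s[a] > s[b]) 1 else if (s[a] == s[b]) 0.5 else 0
      }
    } else {
      if (e[a] + e[b] != 1) next
      ev <- if (e[a] == 1) a else b
      cs <- if (e[a] == 1) b else a
      den <- den + 1
      num <- num + if (s[ev] > s[cs]) 1 else if (s[ev] == s[cs]) 0.5 else 0
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

# direct BH step-up: p * m / rank with tail-minimum monotonicity
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# exhaustive 1-D two-means: evaluate every sorted split directly
bruteKmeans2 <- function(values) {
  s <- sort(values)
  n <- length(s)
  best <- list(wcss = Inf)
  for (k in 1:(n - 1)) {
    if (s[k] == s[k + 1]) next
    lo <- s[1:k]; hi <- s[(k + 1):n]
    wcss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (wcss < best$wcss)
      best <- list(wcss = wcss, cutoff = (mean(lo) + mean(hi)) / 2)
  }
  best
}

# scalar re-evaluation of the attention softmax
bruteAttention <- function(h, V, w) {
  K <- nrow(h)
  raw <- numeric(K)
  for (k in 1:K) {
    u <- numeric(nrow(V))
    for (r in seq_len(nrow(V))) u[r] <- tanh(sum(V[r, ] * h[k, ]))
    raw[k] <- sum(w * u)
  }
  exp(raw) / sum(exp(raw))
}

# exhaustive site->fold search in plain R (canonical fold ordering), for
# cross-checking the compiled optimizer on small instances
bruteFoldSearch <- function(siteBins, nFolds) {
  nSites <- nrow(siteBins)
  target <- colSums(siteBins) / nFolds
  best <- list(obj = Inf)
  rec <- function(s, assign, open) {
    if (s > nSites) {
      cnt <- matrix(0, nFolds, ncol(siteBins))
      for (i in seq_len(nSites))
        cnt[assign[i] + 1, ] <- cnt[assign[i] + 1, ] + siteBins[i, ]
      obj <- sum(sweep(cnt, 2, target)^2)
      if (obj < best$obj) best <<- list(obj = obj, assign = assign)
      return()
    }
    for (f in 0:min(open, nFolds - 1)) {
      assign[s] <- f
      rec(s + 1, assign, max(open, f + 1))
    }
  }
  rec(1, integer(nSites), 0)
  best
}

# AUC of a score against a binary label by rank-sum
rankAUC <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label); n0 <- sum(!label)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# small deterministic cohort shared by several tests
tinyCohort <- function(seed = 42, ...) {
  simulateCohort(cohortConfig(nSamples = 40, nGenes = 2, featureDim = 8,
                              patchesPerBag = 10, nSites = 6, seed = seed, ...))
}

# simulate survival with a time-varying covariate effect (beta flips sign at
# tSwitch) for the PH-power check; inverse-transform sampling on the
# piecewise cumulative hazard
simulateTimeVaryingEffect <- function(n, beta = 1.5, base = 0.1, tSwitch = 5) {
  x <- rnorm(n)
  u <- runif(n)
  h1 <- base * exp(beta * x)
  h2 <- base * exp(-beta * x)
  tt <- ifelse(-log(u) < h1 * tSwitch,
               -log(u) / h1,
               tSwitch + (-log(u) - h1 * tSwitch) / h2)
  list(times = tt, events = rep(1, n), x = x)
}
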