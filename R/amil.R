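EMBED_DIM <- 256L   # patch embedding width h_k
ATT_DIM <- 128L     # attention hidden width
BN_EPS <- 1e-5
DROPOUT_P <- 0.5

#' Training configuration for the AMIL regressor
#'
#' Defaults follow the model's training protocol: 25 epochs, minibatches of
#' 64 bags, at most 512 patches sampled per bag per epoch (uniform, without
#' replacement, redrawn each epoch; bags with fewer patches contribute all of
#' them), Adam optimization, inverse-frequency sample weights over 10
#' equal-width target bins for the balanced mean-squared-error loss.
#'
#' @param epochs training epochs.
#' @param batchSize bags per minibatch.
#' @param patchesPerEpoch max patches sampled per bag per epoch (K).
#' @param learningRate Adam learning rate.
#' @param loss `"balanced_mse"` (expression regression) or `"cox"` (survival
#'   risk score).
#' @param weightBins number of equal-width bins for balanced-MSE weights.
#' @param seed integer RNG seed controlling initialization, patch subsampling,
#'   batching and dropout.
#' @return validated list of class `trainConfig`.
#' @export
trainConfig <- function(epochs = 25L, batchSize = 64L, patchesPerEpoch = 512L,
                        learningRate = 1e-3, loss = c("balanced_mse", "cox"),
                        weightBins = 10L, seed = 1L) {
  loss <- match.arg(loss)
  stopifnot(epochs >= 1, batchSize >= 1, patchesPerEpoch >= 1,
            learningRate > 0, weightBins >= 1)
  structure(list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                 patchesPerEpoch = as.integer(patchesPerEpoch),
                 learningRate = learningRate, loss = loss,
                 weightBins = as.integer(weightBins), seed = as.integer(seed)),
            class = "trainConfig")
}

#' Attention scores over a bag's embedded patches
#'
#' Gated-tanh attention: `a_k = softmax_k( w' tanh(V h_k) )`. The scores are
#' strictly positive and sum to one over the bag.
#'
#' @param h K x 256 matrix of embedded patch vectors.
#' @param V 128 x 256 attention matrix.
#' @param w length-128 attention vector.
#' @return length-K attention vector summing to 1.
#' @export
attentionScores <- function(h, V, w) {
  h <- as.matrix(h)
  if (any(!is.finite(h)) || any(!is.finite(V)) || any(!is.finite(w)))
    stop("non-finite inputs to attention")
  s <- as.numeric(tanh(h %*% t(V)) %*% w)
  e <- exp(s - max(s))
  e / sum(e)
}

#' Attention-weighted MIL pooling
#'
#' `h_sum = sum_i a_i h_i`: collapses a bag's K x 256 embeddings into a
#' single 256-vector using attention weights that sum to one.
#'
#' @param h K x 256 matrix.
#' @param a length-K attention weights (must sum to 1 within 1e-6).
#' @return length-256 pooled vector.
#' @export
attentionPool <- function(h, a) {
  h <- as.matrix(h)
  if (length(a) != nrow(h)) stop("attention length must match patch count")
  if (abs(sum(a) - 1) > 1e-6) stop("attention weights must sum to 1")
  as.numeric(crossprod(h, a))
}

#' Inverse-frequency sample weights for balanced MSE
#'
#' Bins min-max-scaled targets into `weightBins` equal-width bins over
#' \[0, 1\] and assigns `w_i = N / (bins_occupied * count(bin_i))`, so the
#' weights average exactly 1 and rare target ranges are up-weighted.
#'
#' @param targets targets scaled to \[0, 1\].
#' @param weightBins number of equal-width bins.
#' @return weight per sample, mean exactly 1.
#' @export
sampleWeights <- function(targets, weightBins = 10L) {
  if (length(targets) == 0) stop("empty targets")
  breaks <- seq(0, 1, length.out = weightBins + 1)
  bin <- findInterval(pmin(pmax(targets, 0), 1), breaks,
                      rightmost.closed = TRUE, left.open = FALSE)
  bin[bin > weightBins] <- weightBins
  cnt <- tabulate(bin, weightBins)
  occ <- sum(cnt > 0)
  length(targets) / (occ * cnt[bin])
}

#' Balanced mean-squared error
#'
#' `(1/N) sum_i w_i (y_i - yhat_i)^2`; reduces to plain MSE when all weights
#' are 1.
#'
#' @param y,yhat observed and predicted targets.
#' @param w sample weights (default all 1).
#' @return nonnegative scalar loss.
#' @export
balancedMSE <- function(y, yhat, w = rep(1, length(y))) {
  if (length(y) != length(yhat) || length(y) != length(w))
    stop("length mismatch")
  mean(w * (y - yhat)^2)
}

#' Negative Breslow partial log-likelihood (Cox loss)
#'
#' `-(1/|S|) sum_{i in S} [ s_i - log sum_{j: t_j >= t_i} exp(s_j) ]` where
#' `S` indexes observed events and risk sets use `t_j >= t_i` (Breslow-style
#' tie handling). Invariant to adding a constant to all scores.
#'
#' @param times positive survival times.
#' @param events 0/1 event indicators; at least one event required.
#' @param scores model risk scores.
#' @return scalar loss.
#' @export
coxLoss <- function(times, events, scores) {
  stopifnot(length(times) == length(events), length(times) == length(scores))
  S <- which(events == 1)
  if (length(S) == 0) stop("Cox loss needs at least one event in the batch")
  mx <- max(scores)
  es <- exp(scores - mx)
  terms <- vapply(S, function(i)
    (scores[i] - mx) - log(sum(es[times >= times[i]])), 0)
  -mean(terms)
}

# gradient of coxLoss wrt scores (same risk-set convention)
coxLossGrad <- function(times, events, scores) {
  S <- which(events == 1)
  es <- exp(scores - max(scores))
  g <- numeric(length(scores))
  g[S] <- g[S] - 1
  for (i in S) {
    rs <- times >= times[i]
    g[rs] <- g[rs] + es[rs] / sum(es[rs])
  }
  g / length(S)
}

initAmilWeights <- function(featureDim) {
  list(W1 = matrix(rnorm(featureDim * EMBED_DIM, sd = 1 / sqrt(featureDim)),
                   featureDim, EMBED_DIM),
       b1 = numeric(EMBED_DIM),
       V = matrix(rnorm(ATT_DIM * EMBED_DIM, sd = 1 / sqrt(EMBED_DIM)),
                  ATT_DIM, EMBED_DIM),
       w = rnorm(ATT_DIM, sd = 1 / sqrt(ATT_DIM)),
       gamma = rep(1, EMBED_DIM), beta = numeric(EMBED_DIM),
       W2 = matrix(rnorm(EMBED_DIM, sd = 1 / sqrt(EMBED_DIM)), EMBED_DIM, 1),
       b2 = 0,
       runMean = numeric(EMBED_DIM), runVar = rep(1, EMBED_DIM))
}

# stacked forward over a minibatch; X: (sum K_b) x D, g: bag index per patch
amilForwardStack <- function(X, g, B, wts, training, dropMask = NULL) {
  Pre1 <- sweep(X %*% wts$W1, 2, wts$b1, "+")
  H <- pmax(Pre1, 0)
  Tm <- tanh(H %*% t(wts$V))
  s <- as.numeric(Tm %*% wts$w)
  mg <- ave(s, g, FUN = max)
  e <- exp(s - mg)
  denom <- rowsum(e, g)[, 1]
  a <- e / denom[g]
  M <- rowsum(H * a, g)
  if (training) {
    mu <- colMeans(M)
    v <- colMeans(M^2) - mu^2
  } else {
    mu <- wts$runMean
    v <- wts$runVar
  }
  xhat <- sweep(sweep(M, 2, mu), 2, sqrt(v + BN_EPS), "/")
  Z <- sweep(sweep(xhat, 2, wts$gamma, "*"), 2, wts$beta, "+")
  Zd <- if (training && !is.null(dropMask)) Z * dropMask / (1 - DROPOUT_P) else Z
  out <- as.numeric(Zd %*% wts$W2) + wts$b2
  list(Pre1 = Pre1, H = H, Tm = Tm, a = a, M = M, mu = mu, v = v,
       xhat = xhat, Zd = Zd, out = out)
}

amilBackwardStack <- function(X, g, fw, wts, dout, dropMask) {
  B <- nrow(fw$M)
  dZd <- dout %*% t(wts$W2)
  dW2 <- crossprod(fw$Zd, dout)
  db2 <- sum(dout)
  dZ <- dZd * dropMask / (1 - DROPOUT_P)
  dgamma <- colSums(dZ * fw$xhat)
  dbeta <- colSums(dZ)
  dxhat <- sweep(dZ, 2, wts$gamma, "*")
  invstd <- 1 / sqrt(fw$v + BN_EPS)
  dM <- sweep(B * dxhat -
              matrix(colSums(dxhat), B, length(invstd), byrow = TRUE) -
              fw$xhat * matrix(colSums(dxhat * fw$xhat), B, length(invstd),
                               byrow = TRUE),
              2, invstd / B, "*")
  dMg <- dM[g, , drop = FALSE]
  dH <- dMg * fw$a
  da <- rowSums(fw$H * dMg)
  Sg <- rowsum(fw$a * da, g)[, 1]
  ds <- fw$a * (da - Sg[g])
  dTm <- outer(ds, wts$w) * (1 - fw$Tm^2)
  dw <- as.numeric(crossprod(fw$Tm, ds))
  dV <- crossprod(dTm, fw$H)
  dH <- dH + dTm %*% wts$V
  dPre1 <- dH * (fw$Pre1 > 0)
  list(W1 = crossprod(X, dPre1), b1 = colSums(dPre1), V = dV, w = dw,
       gamma = dgamma, beta = dbeta, W2 = dW2, b2 = db2)
}

adamStep <- function(wts, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    wts[[nm]] <- wts[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(wts = wts, state = state)
}

#' Train the attention-MIL regressor
#'
#' Architecture: patch embedding `D -> 256` (linear + ReLU), gated-tanh
#' attention (`V`: 128 x 256, `w`: 128) with per-bag softmax, attention-sum
#' pooling to one 256-vector per bag, then batch normalization, dropout (p =
#' 0.5, training only) and a linear head. Expression models use a logistic
#' output (range (0, 1), matching min-max-scaled targets) and the balanced
#' MSE loss; survival models use an identity output and the negative Breslow
#' partial log-likelihood with risk sets formed within each minibatch.
#'
#' Per epoch, each bag contributes `min(K_bag, patchesPerEpoch)` patches
#' (uniform subsample without replacement, redrawn each epoch). Expression
#' targets are min-max scaled on the training data and the scaler stored in
#' the model. Fully reproducible given `config$seed`.
#'
#' @param bags list of [PatchBag-class].
#' @param targets per-bag expression targets (expression mode).
#' @param times,events per-bag survival outcome (survival mode).
#' @param config a [trainConfig()].
#' @return An [AmilModel-class] with per-epoch mean training loss history.
#' @export
trainAmil <- function(bags, targets = NULL, times = NULL, events = NULL,
                      config = trainConfig()) {
  stopifnot(inherits(config, "trainConfig"))
  n <- length(bags)
  D <- ncol(bags[[1]]@features)
  expressionMode <- config$loss == "balanced_mse"
  if (expressionMode) {
    if (is.null(targets) || length(targets) != n)
      stop("expression mode needs one target per bag")
    rng <- range(targets)
    if (diff(rng) == 0) stop("constant targets cannot be min-max scaled")
    scaler <- c(min = rng[1], max = rng[2])
    y01 <- (targets - rng[1]) / diff(rng)
    wts_i <- sampleWeights(y01, config$weightBins)
  } else {
    if (is.null(times) || is.null(events) || length(times) != n)
      stop("survival mode needs (time, event) per bag")
    if (sum(events) == 0) stop("survival mode needs at least one event")
    scaler <- c(min = NA_real_, max = NA_real_)
  }

  history <- numeric(config$epochs)
  withr::with_seed(config$seed, {
    wts <- initAmilWeights(D)
    zero <- lapply(wts[1:8], function(x) x * 0)
    state <- list(m = zero, v = zero)
    t <- 0L
    for (ep in seq_len(config$epochs)) {
      # per-epoch patch subsample
      feats <- lapply(bags, function(b) {
        f <- b@features
        if (nrow(f) > config$patchesPerEpoch)
          f <- f[sample.int(nrow(f), config$patchesPerEpoch), , drop = FALSE]
        f
      })
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batchSize)
      epLoss <- 0; used <- 0L
      for (st in starts) {
        idx <- ord[st:min(st + config$batchSize - 1L, n)]
        B <- length(idx)
        if (!expressionMode && sum(events[idx]) == 0) next  # unusable batch
        Xb <- do.call(rbind, feats[idx])
        gb <- rep(seq_len(B), vapply(feats[idx], nrow, 0L))
        dropMask <- matrix(rbinom(B * EMBED_DIM, 1, 1 - DROPOUT_P), B)
        fw <- amilForwardStack(Xb, gb, B, wts, training = TRUE, dropMask)
        if (expressionMode) {
          pred <- 1 / (1 + exp(-fw$out))
          res <- pred - y01[idx]
          loss <- mean(wts_i[idx] * res^2)
          dout <- matrix(2 * wts_i[idx] * res * pred * (1 - pred) / B, ncol = 1)
        } else {
          loss <- coxLoss(times[idx], events[idx], fw$out)
          dout <- matrix(coxLossGrad(times[idx], events[idx], fw$out), ncol = 1)
        }
        grads <- amilBackwardStack(Xb, gb, fw, wts, dout, dropMask)
        t <- t + 1L
        upd <- adamStep(wts[names(grads)], grads, state, config$learningRate, t)
        wts[names(grads)] <- upd$wts
        state <- upd$state
        # running batch-norm statistics (momentum 0.1)
        wts$runMean <- 0.9 * wts$runMean + 0.1 * fw$mu
        wts$runVar <- 0.9 * wts$runVar + 0.1 * fw$v
        epLoss <- epLoss + loss * B; used <- used + B
      }
      if (used == 0L) stop("no usable minibatch (all batches event-free)")
      history[ep] <- epLoss / used
    }
  })
  new("AmilModel", weights = wts,
      mode = if (expressionMode) "expression" else "survival",
      scaler = scaler, config = unclass(config), history = history)
}

#' Forward pass for a single bag (inference mode)
#'
#' Deterministic, batch-composition-independent inference: embedding,
#' attention, pooling, batch normalization with the stored running
#' statistics, no dropout, linear head with the model's output activation.
#'
#' @param model an [AmilModel-class].
#' @param bag a [PatchBag-class].
#' @return list with `prediction` (scalar, in (0, 1) for expression mode) and
#'   `attention` (per-patch weights summing to 1).
#' @export
amilForward <- function(model, bag) {
  wts <- model@weights
  if (ncol(bag@features) != nrow(wts$W1))
    stop("bag feature dimension does not match the model")
  fw <- amilForwardStack(bag@features, rep(1L, nrow(bag@features)), 1L, wts,
                         training = FALSE)
  out <- fw$out
  if (model@mode == "expression") out <- 1 / (1 + exp(-out))
  list(prediction = as.numeric(out), attention = as.numeric(fw$a))
}

#' Predict on a list of bags
#'
#' @param model an [AmilModel-class].
#' @param bags list of [PatchBag-class].
#' @param inverseTransform map expression predictions back through the stored
#'   training min/max (`y = yhat * (max - min) + min`).
#' @return named numeric vector of per-sample predictions.
#' @export
predictAmil <- function(model, bags, inverseTransform = FALSE) {
  p <- vapply(bags, function(b) amilForward(model, b)$prediction, 0)
  names(p) <- vapply(bags, function(b) b@sampleId, "")
  if (inverseTransform) {
    if (model@mode != "expression" || any(is.na(model@scaler)))
      stop("inverseTransform requires a trained expression scaler")
    p <- p * (model@scaler[["max"]] - model@scaler[["min"]]) + model@scaler[["min"]]
  }
  p
}

#' Per-patch attention weights for a list of bags
#'
#' @param model an [AmilModel-class].
#' @param bags list of [PatchBag-class].
#' @return list of per-bag attention vectors (each sums to 1).
#' @export
attentionMap <- function(model, bags) {
  lapply(bags, function(b) amilForward(model, b)$attention)
}
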