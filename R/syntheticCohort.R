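#' Configuration for a synthetic image-expression-survival cohort
#'
#' Collects and validates all parameters of the synthetic cohort generator.
#' Defaults give a desk-scale cohort: 200 samples, 32-dimensional patch
#' features, 64 patches per bag, 30% informative patches, noise sd 0.1, 10
#' unequally sized tissue-source sites, a Weibull baseline hazard and 30%
#' independent censoring. Every generated quantity is a pure function of
#' `seed`.
#'
#' @param nSamples number of samples (bags).
#' @param nGenes number of genes.
#' @param featureDim patch feature dimension (stand-in for a deep embedder's
#'   768).
#' @param patchesPerBag patches per bag.
#' @param informativeFraction fraction of patches per bag that carry the
#'   expression signal, in (0, 1].
#' @param noiseSd sd of the isotropic Gaussian patch noise (>= 0).
#' @param nSites number of tissue-source sites (>= 5).
#' @param coxCoefficients numeric vector of log-hazard effects: one per gene,
#'   followed by age (per decade), sex and stage effects.
#' @param baselineHazardScale,baselineHazardShape Weibull baseline hazard
#'   scale (months) and shape.
#' @param censoringRate target fraction of censored samples, in \[0, 1).
#' @param geneMeans,geneSds per-gene mean and sd of the Gaussian expression
#'   distribution; recycled defaults are evenly spaced.
#' @param signalScale multiplier applied to the standardized expression when
#'   shifting informative patches (default 1).
#' @param seed integer RNG seed.
#' @return validated list of class `cohortConfig`.
#' @examples
#' cfg <- cohortConfig(nSamples = 20, nGenes = 2, featureDim = 8,
#'                     patchesPerBag = 10, seed = 7)
#' @export
cohortConfig <- function(nSamples = 200L, nGenes = 2L, featureDim = 32L,
                         patchesPerBag = 64L, informativeFraction = 0.3,
                         noiseSd = 0.1, nSites = 10L,
                         coxCoefficients = c(1, rep(0, nGenes - 1), 0.2, 0.3, 0.5),
                         baselineHazardScale = 60, baselineHazardShape = 1.2,
                         censoringRate = 0.3,
                         geneMeans = 5 + seq_len(nGenes),
                         geneSds = 0.5 + 0.25 * (seq_len(nGenes) - 1),
                         signalScale = 1, seed = 1L) {
  cfg <- list(nSamples = as.integer(nSamples), nGenes = as.integer(nGenes),
              featureDim = as.integer(featureDim),
              patchesPerBag = as.integer(patchesPerBag),
              informativeFraction = informativeFraction, noiseSd = noiseSd,
              nSites = as.integer(nSites), coxCoefficients = coxCoefficients,
              baselineHazardScale = baselineHazardScale,
              baselineHazardShape = baselineHazardShape,
              censoringRate = censoringRate,
              geneMeans = rep_len(geneMeans, nGenes),
              geneSds = rep_len(geneSds, nGenes),
              signalScale = signalScale, seed = as.integer(seed))
  with(cfg, {
    if (nSamples < 1 || nGenes < 1 || featureDim < 1 || patchesPerBag < 1)
      stop("dimensions must be positive")
    if (informativeFraction <= 0 || informativeFraction > 1)
      stop("informativeFraction must be in (0, 1]")
    if (informativeFraction * patchesPerBag < 1)
      stop("informativeFraction * patchesPerBag must be >= 1")
    if (noiseSd < 0) stop("noiseSd must be nonnegative")
    if (nSites < 5) stop("at least 5 sites are required")
    if (nSites > nSamples) stop("nSites must not exceed nSamples")
    if (censoringRate < 0 || censoringRate >= 1)
      stop("censoringRate must be in [0, 1)")
    if (length(coxCoefficients) != nGenes + 3)
      stop("coxCoefficients must have one entry per gene plus age, sex, stage")
    if (baselineHazardScale <= 0 || baselineHazardShape <= 0)
      stop("baseline hazard parameters must be positive")
    if (nGenes > featureDim)
      stop("orthonormal signal directions require nGenes <= featureDim")
  })
  class(cfg) <- "cohortConfig"
  cfg
}

sampleIdsFor <- function(n) sprintf("S%04d", seq_len(n))
geneIdsFor <- function(n) sprintf("gene%03d", seq_len(n))

#' Generate ground-truth gene expression
#'
#' Genes x samples matrix of continuous expression; each gene is Gaussian
#' with its configured mean and sd. Deterministic given `config$seed`.
#'
#' @param config a [cohortConfig()].
#' @return numeric matrix with gene row names and sample column names.
#' @export
generateExpression <- function(config) {
  stopifnot(inherits(config, "cohortConfig"))
  withr::with_seed(config$seed + 101L, {
    m <- matrix(rnorm(config$nGenes * config$nSamples), config$nGenes)
    m <- m * config$geneSds + config$geneMeans
    dimnames(m) <- list(geneIdsFor(config$nGenes), sampleIdsFor(config$nSamples))
    m
  })
}

# unequal site sizes: exponential weights, every site guaranteed >= 1 sample
siteSizes <- function(nSamples, nSites) {
  w <- rexp(nSites) + 0.15
  sz <- pmax(1L, as.integer(floor(nSamples * w / sum(w))))
  i <- 0L
  while (sum(sz) != nSamples) {         # distribute the rounding remainder
    i <- i %% nSites + 1L
    if (sum(sz) < nSamples) sz[i] <- sz[i] + 1L
    else if (sz[i] > 1L) sz[i] <- sz[i] - 1L
  }
  sz
}

#' Generate MIL bags with planted expression signal
#'
#' For each sample, builds a `patchesPerBag x featureDim` feature matrix:
#' a fixed number `round(informativeFraction * patchesPerBag)` of informative
#' patches have their mean shifted along each gene's unit signal direction by
#' `signalScale` times that sample's standardized expression; all patches
#' carry isotropic Gaussian noise with sd `noiseSd`. Signal directions are
#' orthonormal across genes. Site labels are assigned in contiguous blocks of
#' unequal sizes. Deterministic given `config$seed`.
#'
#' @param expression genes x samples matrix from [generateExpression()].
#' @param config a [cohortConfig()].
#' @return list with `bags` (list of [PatchBag-class]), `signalDirections`
#'   (featureDim x nGenes), `informativeMask` (list of logical vectors) and
#'   `sites` (per-sample site labels).
#' @export
generateBags <- function(expression, config) {
  stopifnot(inherits(config, "cohortConfig"))
  if (ncol(expression) != config$nSamples || nrow(expression) != config$nGenes)
    stop("expression dimensions do not match config")
  z <- t(scale(t(expression)))             # per-gene standardization
  withr::with_seed(config$seed + 202L, {
    U <- qr.Q(qr(matrix(rnorm(config$featureDim * config$nGenes),
                        config$featureDim)))[, seq_len(config$nGenes), drop = FALSE]
    sz <- siteSizes(config$nSamples, config$nSites)
    sites <- rep(sprintf("site%02d", seq_len(config$nSites)), times = sz)
    nInf <- max(1L, as.integer(round(config$informativeFraction * config$patchesPerBag)))
    K <- config$patchesPerBag
    bags <- vector("list", config$nSamples)
    mask <- vector("list", config$nSamples)
    ids <- colnames(expression)
    for (s in seq_len(config$nSamples)) {
      feat <- matrix(rnorm(K * config$featureDim, sd = config$noiseSd),
                     K, config$featureDim)
      inf <- rep(FALSE, K)
      inf[sample.int(K, nInf)] <- TRUE
      shift <- as.numeric(U %*% (config$signalScale * z[, s]))
      feat[inf, ] <- feat[inf, , drop = FALSE] + rep(shift, each = nInf)
      bags[[s]] <- patchBag(ids[s], feat, site = sites[s])
      mask[[s]] <- inf
    }
    rownames(U) <- NULL
    colnames(U) <- rownames(expression)
    list(bags = bags, signalDirections = U, informativeMask = mask, sites = sites)
  })
}

#' Generate survival outcomes from a Cox model over expression and covariates
#'
#' Event times are drawn by inverse-transform sampling from a Weibull baseline
#' hazard `H0(t) = (t / scale)^shape` under the linear predictor
#' `beta_genes . z + beta_age (age - 65)/10 + beta_sex sex + beta_stage stage`
#' where `z` is standardized expression, sex ~ Bernoulli(0.5), stage is
#' ordinal 1-4 and age ~ Normal(65, 10). Censoring times are independent
#' exponentials whose rate is calibrated so the expected censored fraction
#' matches `censoringRate`. Deterministic given `config$seed`.
#'
#' @param expression genes x samples matrix.
#' @param config a [cohortConfig()].
#' @param sites optional per-sample site labels for the clinical table.
#' @return clinical data.frame: `sample_id, age, sex, stage, os_months,
#'   os_event, site`.
#' @export
generateSurvival <- function(expression, config, sites = NULL) {
  stopifnot(inherits(config, "cohortConfig"))
  n <- ncol(expression)
  z <- t(scale(t(expression)))
  bg <- config$coxCoefficients[seq_len(config$nGenes)]
  bc <- config$coxCoefficients[config$nGenes + 1:3]
  withr::with_seed(config$seed + 303L, {
    age <- rnorm(n, 65, 10)
    sex <- rbinom(n, 1, 0.5)
    stage <- sample(1:4, n, replace = TRUE, prob = c(0.35, 0.3, 0.2, 0.15))
    lp <- as.numeric(crossprod(z, bg)) + bc[1] * (age - 65) / 10 +
      bc[2] * sex + bc[3] * stage
    lp <- lp - mean(lp)
    u <- runif(n)
    tev <- config$baselineHazardScale *
      (-log(u) / exp(lp))^(1 / config$baselineHazardShape)
    if (config$censoringRate > 0) {
      f <- function(r) mean(1 - exp(-r * tev)) - config$censoringRate
      rate <- uniroot(f, c(1e-10, 1e3), tol = 1e-12)$root
      cens <- rexp(n, rate)
    } else {
      cens <- rep(Inf, n)
    }
    obs <- pmin(tev, cens)
    data.frame(sample_id = colnames(expression), age = age, sex = sex,
               stage = stage, os_months = pmax(obs, 1e-8),
               os_event = as.integer(tev <= cens),
               site = if (is.null(sites)) rep("site01", n) else sites,
               stringsAsFactors = FALSE)
  })
}

#' Documented stain vector sets
#'
#' `heStainVectors()` returns the standard H&E optical-density stain matrix
#' (hematoxylin, eosin columns, unit norm). `balancedStainVectors()` returns
#' a synthetic two-stain set whose channels all absorb appreciably, so that
#' pure-stain pixels survive the per-channel optical-density threshold of the
#' Macenko fit — used for planted-recovery fixtures.
#'
#' @return 3 x 2 unit-column-norm matrix (rows R, G, B).
#' @export
heStainVectors <- function() {
  m <- cbind(h = c(0.65, 0.70, 0.29), e = c(0.07, 0.99, 0.11))
  sweep(m, 2, sqrt(colSums(m^2)), "/")
}

#' @rdname heStainVectors
#' @export
balancedStainVectors <- function() {
  # blue-dominant stain first, matching the hematoxylin-first column order
  m <- cbind(s1 = c(0.30, 0.60, 0.74), s2 = c(0.70, 0.55, 0.45))
  sweep(m, 2, sqrt(colSums(m^2)), "/")
}

blobField <- function(side, nBlobs, radius) {
  cx <- runif(nBlobs, 1, side); cy <- runif(nBlobs, 1, side)
  gx <- matrix(seq_len(side), side, side)
  gy <- t(gx)
  f <- matrix(0, side, side)
  for (b in seq_len(nBlobs))
    f <- f + ((gx - cx[b])^2 + (gy - cy[b])^2 < radius^2)
  pmin(f, 1)
}

#' Generate synthetic 224x224 RGB tiles for the preprocessing stage
#'
#' Emits four kinds of tiles: `background` (uniform), `blurred` (Gaussian-
#' blurred tissue), `sharp` (two-stain tissue: blob-structured hematoxylin and
#' eosin concentrations mixed linearly in optical density with the standard
#' H&E stain vectors, plus OD noise), and `checkerboard` (2-pixel period).
#' Deterministic given `seed`.
#'
#' @param nPerKind tiles per kind.
#' @param seed RNG seed.
#' @param side tile side length in pixels.
#' @param odNoiseSd sd of additive optical-density noise on tissue tiles.
#' @param stainMatrix 3 x 2 OD stain matrix used to render tissue tiles.
#' @return list of tiles, each a list with `pixels` (side x side x 3 integer
#'   array in \[0, 255\]) and `label`.
#' @export
generateTiles <- function(nPerKind = 1L, seed = 1L, side = 224L,
                          odNoiseSd = 0.01, stainMatrix = heStainVectors()) {
  withr::with_seed(as.integer(seed) + 404L, {
    tiles <- list()
    for (i in seq_len(nPerKind)) {
      bg <- array(as.integer(round(runif(1, 215, 245))), dim = c(side, side, 3))
      tiles <- c(tiles, list(list(pixels = bg, label = "background")))

      # near-pure regions of each stain (non-overlapping blobs dominate),
      # a low-concentration background, and sharp blob boundaries for the
      # edge detector
      cH <- 0.08 + runif(1, 0.9, 1.2) * blobField(side, 14, side / 9)
      cE <- 0.08 + runif(1, 0.7, 0.9) * blobField(side, 9, side / 6)
      conc <- rbind(as.numeric(cH), as.numeric(cE))
      od <- stainMatrix %*% conc +
        matrix(rnorm(3 * side * side, sd = odNoiseSd), 3)
      od <- pmax(od, 0)
      px <- array(0L, dim = c(side, side, 3))
      for (ch in 1:3)
        px[, , ch] <- as.integer(pmin(255, pmax(0, round(256 * 10^(-od[ch, ]) - 1))))
      tiles <- c(tiles, list(list(pixels = px, label = "sharp")))

      blur <- px
      for (ch in 1:3)
        blur[, , ch] <- as.integer(round(as.matrix(
          EBImage::gblur(EBImage::Image(px[, , ch] / 255),
                         sigma = side / 28)) * 255))
      blur[] <- pmin(255L, pmax(0L, blur))
      tiles <- c(tiles, list(list(pixels = blur, label = "blurred")))

      ck <- matrix(0L, side, side)
      idx <- outer(seq_len(side), seq_len(side), function(r, c)
        ((r - 1) %/% 2 + (c - 1) %/% 2) %% 2)
      ck[idx == 1] <- 255L
      tiles <- c(tiles, list(list(pixels = array(ck, dim = c(side, side, 3)),
                                  label = "checkerboard")))
    }
    tiles
  })
}

#' Write tiles as PNG files
#'
#' @param tiles output of [generateTiles()].
#' @param dir output directory (created if absent).
#' @return invisibly, the written file paths.
#' @export
writeTiles <- function(tiles, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(tiles))
  for (i in seq_along(tiles)) {
    paths[i] <- file.path(dir, sprintf("tile%03d_%s.png", i, tiles[[i]]$label))
    png::writePNG(tiles[[i]]$pixels / 255, paths[i])
  }
  invisible(paths)
}

#' Simulate a complete synthetic cohort
#'
#' Runs [generateExpression()], [generateBags()] and [generateSurvival()] and
#' assembles the result into a [SyntheticCohort-class] whose expression and
#' clinical data live in a `SummarizedExperiment`.
#'
#' @param config a [cohortConfig()].
#' @return A [SyntheticCohort-class].
#' @examples
#' coh <- simulateCohort(cohortConfig(nSamples = 30, featureDim = 8,
#'                                    patchesPerBag = 12, seed = 3))
#' coh
#' @export
simulateCohort <- function(config) {
  expr <- generateExpression(config)
  b <- generateBags(expr, config)
  clin <- generateSurvival(expr, config, sites = b$sites)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expression = expr),
    colData = S4Vectors::DataFrame(clin, row.names = clin$sample_id))
  new("SyntheticCohort", bags = b$bags, se = se,
      signalDirections = b$signalDirections,
      informativeMask = b$informativeMask, config = unclass(config))
}
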