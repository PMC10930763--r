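#' Pipeline configuration
#'
#' Thresholds of the end-to-end analysis: predictability gate on the
#' cross-validated Pearson R (default 0.4), significance level 0.05,
#' proportional-hazards violation exclusion at p < 0.05, 5 folds.
#'
#' @param rGate cross-validated Pearson R threshold.
#' @param alpha significance level for adjusted p-values.
#' @param phAlpha PH-violation exclusion level.
#' @param nFolds number of cross-validation folds.
#' @param train a [trainConfig()].
#' @param stageEncoding `"ordinal"` or `"dummy"` stage coding in Cox models.
#' @param seed master seed.
#' @return list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(rGate = 0.4, alpha = 0.05, phAlpha = 0.05,
                           nFolds = 5L, train = trainConfig(),
                           stageEncoding = "ordinal", seed = 1L) {
  stopifnot(rGate > -1, rGate < 1, alpha > 0, alpha < 1, phAlpha > 0,
            phAlpha < 1, nFolds >= 2)
  structure(list(rGate = rGate, alpha = alpha, phAlpha = phAlpha,
                 nFolds = as.integer(nFolds), train = train,
                 stageEncoding = stageEncoding, seed = as.integer(seed)),
            class = "pipelineConfig")
}

clinicalCovariates <- function(clinical, stageEncoding = "ordinal") {
  X <- cbind(age = clinical$age, sex = as.numeric(clinical$sex))
  if (stageEncoding == "ordinal") cbind(X, stage = as.numeric(clinical$stage))
  else cbind(X, stats::model.matrix(~ factor(clinical$stage))[, -1, drop = FALSE])
}

#' Screen candidate genes for prognostic value
#'
#' Per gene: Cox regression of overall survival on the gene's expression
#' adjusted for age, sex and stage (Breslow ties); genes whose expression
#' covariate violates the proportional-hazards assumption (Schoenfeld-
#' residual test p < `phAlpha`) are excluded before Benjamini-Hochberg
#' adjustment across the remaining genes. A gene is prognostic when its 95%
#' CI excludes beta = 0 and its adjusted p is below `alpha`.
#'
#' @param expression genes x samples matrix of candidate genes.
#' @param clinical clinical data.frame (`age, sex, stage, os_months,
#'   os_event`), rows in sample order of `expression` columns.
#' @param config a [pipelineConfig()].
#' @return data.frame: `gene, beta, se, hr, ci_low, ci_high, p, ph_p,
#'   excluded_ph, adj_p, prognostic`.
#' @export
screenPrognosticGenes <- function(expression, clinical,
                                  config = pipelineConfig()) {
  stopifnot(ncol(expression) == nrow(clinical))
  covars <- clinicalCovariates(clinical, config$stageEncoding)
  res <- lapply(rownames(expression), function(g) {
    X <- cbind(gene = expression[g, ], covars)
    fit <- fitCox(clinical$os_months, clinical$os_event, X)
    php <- phTest(fit)
    data.frame(gene = g, beta = fit@coefficients[["gene"]],
               se = fit@se[["gene"]], hr = fit@hr[["gene"]],
               ci_low = fit@ciLow[["gene"]], ci_high = fit@ciHigh[["gene"]],
               p = fit@p[["gene"]], ph_p = php$p[php$covariate == "gene"])
  })
  tab <- do.call(rbind, res)
  tab$excluded_ph <- tab$ph_p < config$phAlpha
  tab$adj_p <- NA_real_
  keep <- !tab$excluded_ph
  if (any(keep)) tab$adj_p[keep] <- bhAdjust(tab$p[keep])
  ciExcludes0 <- tab$ci_low > 1 | tab$ci_high < 1   # beta CI excludes 0 <=> HR CI excludes 1
  tab$prognostic <- keep & !is.na(tab$adj_p) & tab$adj_p < config$alpha & ciExcludes0
  rownames(tab) <- NULL
  tab
}

#' Cross-validated per-gene AMIL expression models
#'
#' For each gene and fold: train the expression-mode AMIL on the bags of the
#' other folds (min-max scaler fitted on the training targets), predict the
#' held-out fold, and record the per-fold Pearson R between predictions and
#' true expression. The cross-validated R is the mean across folds; genes
#' pass the predictability gate when it exceeds `config$rGate`. Held-out
#' predictions concatenated across folds cover every sample exactly once.
#'
#' @param bags list of [PatchBag-class] in sample order.
#' @param expression genes x samples matrix (same sample order).
#' @param folds a [FoldAssignment-class].
#' @param config a [pipelineConfig()].
#' @param genes genes to model (default all rows).
#' @return list with `perGene` (per gene: `models`, `foldR`, `cvR`,
#'   `predictions` raw and inverse-transformed, aligned to samples) and
#'   `rTable` (data.frame: gene, per-fold R, cv_r, gated).
#' @export
crossvalGeneModels <- function(bags, expression, folds,
                               config = pipelineConfig(),
                               genes = rownames(expression)) {
  sf <- sampleFolds(folds)
  ids <- vapply(bags, sampleId, "")
  stopifnot(identical(ids, colnames(expression)), all(ids %in% names(sf)))
  fold <- sf[ids]
  perGene <- list()
  rows <- list()
  for (g in genes) {
    y <- expression[g, ]
    models <- vector("list", folds@nFolds)
    predRaw <- setNames(rep(NA_real_, length(ids)), ids)
    predInv <- predRaw
    foldR <- numeric(folds@nFolds)
    for (f in seq_len(folds@nFolds) - 1L) {
      tr <- which(fold != f); te <- which(fold == f)
      if (length(te) < 2) stop("fold ", f, " has fewer than 2 test samples")
      cfg <- config$train
      cfg$seed <- cfg$seed + 1000L * f + match(g, genes)
      m <- trainAmil(bags[tr], targets = y[tr], config = cfg)
      pr <- predictAmil(m, bags[te])
      predRaw[te] <- pr
      predInv[te] <- predictAmil(m, bags[te], inverseTransform = TRUE)
      foldR[f + 1L] <- cor(pr, y[te])
      models[[f + 1L]] <- m
    }
    cvR <- mean(foldR)
    perGene[[g]] <- list(models = models, foldR = foldR, cvR = cvR,
                         predictions = predRaw, predictionsInverse = predInv)
    rows[[g]] <- data.frame(gene = g, t(setNames(foldR,
                    paste0("r_fold", seq_along(foldR) - 1L))),
                    cv_r = cvR, gated = cvR > config$rGate)
  }
  list(perGene = perGene, rTable = do.call(rbind, c(rows, make.row.names = FALSE)))
}

#' Cross-validated surrogate prognostic evaluation of one gene
#'
#' Per fold: a Cox model is fitted to the *real* expression of the training
#' folds (univariate, Breslow ties) and evaluated on the *predicted*
#' expression of the held-out fold via the fitted linear predictor and
#' Harrell's C-index. Reports per-fold C, mean and sd, and additionally fits
#' the covariate-adjusted Cox model on the cross-validation-aggregated
#' predictions for the significance gate.
#'
#' @param realExpression per-sample real expression of the gene.
#' @param predictedExpression per-sample predicted expression (aggregated
#'   held-out predictions).
#' @param clinical clinical data.frame in the same sample order.
#' @param folds a [FoldAssignment-class].
#' @param config a [pipelineConfig()].
#' @return list with `foldC`, `meanC`, `sdC`, and `aggregatedFit`
#'   ([CoxFit-class] on prediction + age + sex + stage).
#' @export
surrogatePrognosisCV <- function(realExpression, predictedExpression,
                                 clinical, folds, config = pipelineConfig()) {
  sf <- sampleFolds(folds)[clinical$sample_id]
  foldC <- numeric(folds@nFolds)
  for (f in seq_len(folds@nFolds) - 1L) {
    tr <- which(sf != f); te <- which(sf == f)
    fit <- fitCox(clinical$os_months[tr], clinical$os_event[tr],
                  cbind(gene = realExpression[tr]))
    risk <- fit@coefficients[["gene"]] * predictedExpression[te]
    foldC[f + 1L] <- concordanceIndex(clinical$os_months[te],
                                      clinical$os_event[te], risk)
  }
  agg <- fitCox(clinical$os_months, clinical$os_event,
                cbind(gene = predictedExpression,
                      clinicalCovariates(clinical, config$stageEncoding)))
  list(foldC = foldC, meanC = mean(foldC), sdC = sd(foldC),
       aggregatedFit = agg)
}

#' Deploy the best cross-validation fold model on an external cohort
#'
#' Selects the fold model with the highest held-out Pearson R (ties broken
#' toward the lowest fold index), predicts expression on the external bags,
#' and evaluates: external Pearson R against measured expression, the
#' covariate-adjusted Cox fit on the predictions (prognostic when the HR CI
#' excludes 1 and p < alpha), and the proportional-hazards diagnostic.
#'
#' @param cvGene one gene's entry from `crossvalGeneModels()$perGene`.
#' @param externalBags list of [PatchBag-class] for the external cohort.
#' @param externalExpression per-sample measured expression of the gene.
#' @param externalClinical external clinical data.frame.
#' @param config a [pipelineConfig()].
#' @return list with `bestFold`, `externalR`, `passesRGate`, `fit`
#'   ([CoxFit-class]), `phP`, `prognostic`, `predictions`.
#' @export
externalValidate <- function(cvGene, externalBags, externalExpression,
                             externalClinical, config = pipelineConfig()) {
  need <- c("age", "sex", "stage", "os_months", "os_event")
  if (!all(need %in% colnames(externalClinical)))
    stop("external clinical table lacks: ",
         paste(setdiff(need, colnames(externalClinical)), collapse = ", "))
  best <- which.max(cvGene$foldR)          # ties -> lowest index
  model <- cvGene$models[[best]]
  pred <- predictAmil(model, externalBags)
  exR <- cor(pred, externalExpression)
  fit <- fitCox(externalClinical$os_months, externalClinical$os_event,
                cbind(gene = pred,
                      clinicalCovariates(externalClinical, config$stageEncoding)))
  php <- phTest(fit)
  phP <- php$p[php$covariate == "gene"]
  prognostic <- (fit@ciLow[["gene"]] > 1 || fit@ciHigh[["gene"]] < 1) &&
    fit@p[["gene"]] < config$alpha && phP > config$phAlpha
  list(bestFold = best - 1L, externalR = exR,
       passesRGate = exR > config$rGate, fit = fit, phP = phP,
       prognostic = prognostic, predictions = pred)
}

#' Direct survival benchmark from bags
#'
#' Trains the Cox-loss AMIL model per fold on the training bags (identical
#' hyperparameters to the expression models) and evaluates the predicted
#' risk score on the held-out fold with Harrell's C-index; the controlled
#' comparison for the surrogate path, consuming identical folds and bags.
#'
#' @param bags list of [PatchBag-class] in sample order.
#' @param clinical clinical data.frame in the same order.
#' @param folds a [FoldAssignment-class].
#' @param config a [pipelineConfig()].
#' @return list with `foldC`, `meanC`, `sdC`.
#' @export
benchmarkDirectSurvival <- function(bags, clinical, folds,
                                    config = pipelineConfig()) {
  sf <- sampleFolds(folds)[clinical$sample_id]
  foldC <- numeric(folds@nFolds)
  for (f in seq_len(folds@nFolds) - 1L) {
    tr <- which(sf != f); te <- which(sf == f)
    if (sum(clinical$os_event[tr]) < 1)
      stop("training fold ", f, " has no events")
    cfg <- config$train
    cfg$loss <- "cox"
    cfg$seed <- cfg$seed + 77L * (f + 1L)
    m <- trainAmil(bags[tr], times = clinical$os_months[tr],
                   events = clinical$os_event[tr], config = cfg)
    risk <- predictAmil(m, bags[te])
    foldC[f + 1L] <- concordanceIndex(clinical$os_months[te],
                                      clinical$os_event[te], risk)
  }
  list(foldC = foldC, meanC = mean(foldC), sdC = sd(foldC))
}

#' Run the full surrogate-biomarker pipeline on a cohort
#'
#' End to end: screen candidate genes for prognostic value, assign
#' site-preserved folds per gene target, train cross-validated AMIL
#' expression models, gate genes by cross-validated Pearson R, evaluate
#' surrogate prognostic value (per-fold C-index of real-trained Cox models on
#' predicted expression), run the direct survival benchmark on the same
#' folds, and stratify samples by real and predicted expression through the
#' identical code path.
#'
#' @param cohort a [SyntheticCohort-class] (or compatible object with bags,
#'   expression, clinical).
#' @param config a [pipelineConfig()].
#' @param genes genes to carry through model training (default: prognostic
#'   genes from the screen; falls back to all genes when none pass).
#' @return list of stage results (`screen`, `folds`, `cv`, `surrogate`,
#'   `direct`, `stratification`).
#' @export
runPipeline <- function(cohort, config = pipelineConfig(), genes = NULL) {
  expr <- expressionMatrix(cohort)
  clin <- clinicalTable(cohort)
  bags <- cohortBags(cohort)
  screen <- screenPrognosticGenes(expr, clin, config)
  if (is.null(genes)) {
    genes <- screen$gene[screen$prognostic]
    if (length(genes) == 0) genes <- screen$gene
  }
  survFolds <- cohortFolds(cohort, "survival", nFolds = config$nFolds,
                           seed = config$seed)
  cv <- crossvalGeneModels(bags, expr, survFolds, config, genes = genes)
  gated <- cv$rTable$gene[cv$rTable$gated]
  surrogate <- list(); strat <- list()
  for (g in gated) {
    surrogate[[g]] <- surrogatePrognosisCV(expr[g, ],
      cv$perGene[[g]]$predictionsInverse, clin, survFolds, config)
    strat[[g]] <- list(
      real = stratifyByExpression(expr[g, ], clin, gene = g,
                                  stageEncoding = config$stageEncoding),
      predicted = stratifyByExpression(cv$perGene[[g]]$predictionsInverse,
                                       clin, gene = g,
                                       stageEncoding = config$stageEncoding))
  }
  direct <- benchmarkDirectSurvival(bags, clin, survFolds, config)
  list(screen = screen, folds = survFolds, cv = cv, surrogate = surrogate,
       direct = direct, stratification = strat)
}

#' Assemble a machine-readable report bundle
#'
#' Collects the pipeline stages into TSV tables (screen table, R table,
#' C-index table, stratification comparison with the per-gene difference in
#' C-index between predicted- and real-expression stratification) plus
#' Kaplan-Meier data series per risk group, and writes them with a JSON
#' summary.
#'
#' @param results output of [runPipeline()].
#' @param dir output directory (created if absent).
#' @param clinical clinical table used for KM series (optional; KM series
#'   are skipped when absent).
#' @return invisibly, the report list.
#' @export
runReport <- function(results, dir, clinical = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(d, f) utils::write.table(d, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  wt(results$screen, "screen.tsv")
  wt(results$cv$rTable, "pearson_r.tsv")
  cidx <- do.call(rbind, lapply(names(results$surrogate), function(g) {
    s <- results$surrogate[[g]]
    data.frame(gene = g, mean_c = s$meanC, sd_c = s$sdC,
               t(setNames(s$foldC, paste0("c_fold", seq_along(s$foldC) - 1L))))
  }))
  if (!is.null(cidx)) wt(cidx, "cindex.tsv")
  stratTab <- do.call(rbind, lapply(names(results$stratification), function(g) {
    st <- results$stratification[[g]]
    data.frame(gene = g,
               real_hr = st$real@hr, real_ci_low = st$real@ciLow,
               real_ci_high = st$real@ciHigh, real_p = st$real@p,
               real_c = st$real@cIndex,
               pred_hr = st$predicted@hr, pred_ci_low = st$predicted@ciLow,
               pred_ci_high = st$predicted@ciHigh, pred_p = st$predicted@p,
               pred_c = st$predicted@cIndex,
               delta_c = st$predicted@cIndex - st$real@cIndex)
  }))
  if (!is.null(stratTab)) wt(stratTab, "stratification.tsv")
  km <- NULL
  if (!is.null(clinical) && length(results$stratification)) {
    km <- lapply(results$stratification, function(st) {
      lapply(split(seq_len(nrow(clinical)), st$predicted@groups), function(ix)
        kmEstimate(clinical$os_months[ix], clinical$os_event[ix]))
    })
  }
  summary <- list(
    n_screened = nrow(results$screen),
    n_prognostic = sum(results$screen$prognostic),
    n_gated = sum(results$cv$rTable$gated),
    direct_c_mean = results$direct$meanC,
    direct_c_sd = results$direct$sdC,
    fold_objective = foldObjective(results$folds))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(cindex = cidx, stratification = stratTab, km = km,
                 summary = summary))
}
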