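#' @import methods
#' @importFrom stats coef complete.cases cor pchisq predict quantile rbinom
#'   rexp rnorm runif sd setNames uniroot var
#' @importFrom utils head
NULL

#' PatchBag: one sample's bag of patch feature vectors
#'
#' The multiple-instance-learning "bag": a `K x D` matrix of patch-level
#' feature vectors for one whole-slide image, together with the sample
#' identifier and the tissue-source site that contributed the sample.
#'
#' @slot sampleId character(1) sample identifier.
#' @slot features numeric matrix, one row per patch, one column per feature
#'   dimension. Must be finite and have at least one row.
#' @slot site character(1) tissue-source-site label.
#'
#' @seealso [patchBag()], [generateBags()]
#' @export
setClass("PatchBag",
  representation(sampleId = "character", features = "matrix", site = "character"))

setValidity("PatchBag", function(object) {
  msg <- NULL
  if (length(object@sampleId) != 1L) msg <- c(msg, "sampleId must be length 1")
  if (length(object@site) != 1L) msg <- c(msg, "site must be length 1")
  if (nrow(object@features) < 1L) msg <- c(msg, "bag must contain at least one patch")
  if (!is.numeric(object@features) || any(!is.finite(object@features)))
    msg <- c(msg, "features must be finite numeric")
  if (is.null(msg)) TRUE else msg
})

#' Construct a PatchBag
#'
#' @param sampleId sample identifier.
#' @param features K x D numeric matrix of patch features.
#' @param site tissue-source-site label.
#' @return A [PatchBag-class] object.
#' @examples
#' patchBag("S1", matrix(rnorm(20), 4, 5), site = "site01")
#' @export
patchBag <- function(sampleId, features, site = "unknown") {
  new("PatchBag", sampleId = as.character(sampleId),
      features = as.matrix(features), site = as.character(site))
}

#' @describeIn PatchBag-class number of patches in the bag
#' @param x,object a `PatchBag`
#' @export
setMethod("length", "PatchBag", function(x) nrow(x@features))

setMethod("show", "PatchBag", function(object) {
  cat("PatchBag", object@sampleId, "-", nrow(object@features), "patches x",
      ncol(object@features), "features, site", object@site, "\n")
})

#' StainModel: Macenko stain matrix plus reference concentrations
#'
#' Holds the two optical-density stain vectors (hematoxylin first, eosin
#' second, unit Euclidean norm, nonnegative entries) estimated by the Macenko
#' procedure, and the per-stain 99th-percentile concentrations used to match
#' concentration ranges between images during normalization.
#'
#' @slot stainMatrix 3 x 2 matrix; columns are unit-norm OD stain vectors.
#' @slot maxConcentrations numeric(2), per-stain reference concentration.
#' @seealso [macenkoFit()], [macenkoApply()], [referenceStainModel()]
#' @export
setClass("StainModel",
  representation(stainMatrix = "matrix", maxConcentrations = "numeric"))

setValidity("StainModel", function(object) {
  msg <- NULL
  if (!all(dim(object@stainMatrix) == c(3L, 2L)))
    msg <- c(msg, "stainMatrix must be 3 x 2")
  else {
    nrm <- sqrt(colSums(object@stainMatrix^2))
    if (any(abs(nrm - 1) > 1e-6)) msg <- c(msg, "stain vectors must have unit norm")
    if (any(object@stainMatrix < -1e-12)) msg <- c(msg, "stain vectors must be nonnegative")
  }
  if (length(object@maxConcentrations) != 2L ||
      any(!is.finite(object@maxConcentrations)))
    msg <- c(msg, "maxConcentrations must be finite numeric(2)")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "StainModel", function(object) {
  cat("StainModel (OD stain vectors, columns = H, E):\n")
  m <- object@stainMatrix
  dimnames(m) <- list(c("R", "G", "B"), c("hematoxylin", "eosin"))
  print(round(m, 4))
  cat("max concentrations:", round(object@maxConcentrations, 4), "\n")
})

#' SyntheticCohort: a fully simulated image-expression-survival cohort
#'
#' Container for one synthetic cohort: bags of patch features per sample,
#' ground-truth expression and clinical data held in a
#' [SummarizedExperiment::SummarizedExperiment] (assay `"expression"`,
#' clinical variables in `colData`), the planted unit signal directions per
#' gene, and the per-bag mask of informative (signal-carrying) patches.
#'
#' @slot bags list of [PatchBag-class], one per sample, in sample order.
#' @slot se SummarizedExperiment with the genes x samples expression assay and
#'   clinical columns `sample_id, age, sex, stage, os_months, os_event, site`.
#' @slot signalDirections feature_dim x n_genes matrix of orthonormal unit
#'   vectors along which informative patches are shifted.
#' @slot informativeMask list of logical vectors (one per bag) marking the
#'   informative patches.
#' @slot config the `cohortConfig()` list the cohort was generated from.
#' @seealso [simulateCohort()]
#' @export
setClass("SyntheticCohort",
  representation(bags = "list", se = "SummarizedExperiment",
                 signalDirections = "matrix", informativeMask = "list",
                 config = "list"))

setValidity("SyntheticCohort", function(object) {
  msg <- NULL
  n <- length(object@bags)
  if (ncol(object@se) != n) msg <- c(msg, "one expression column per bag required")
  if (length(object@informativeMask) != n)
    msg <- c(msg, "one informative mask per bag required")
  ids <- vapply(object@bags, function(b) b@sampleId, character(1))
  if (!identical(ids, colnames(object@se)))
    msg <- c(msg, "bag sample ids must match expression/clinical sample ids")
  cd <- SummarizedExperiment::colData(object@se)
  need <- c("sample_id", "age", "sex", "stage", "os_months", "os_event", "site")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, paste("clinical data must contain:", paste(need, collapse = ", ")))
  else {
    if (!all(cd$os_event %in% c(0, 1))) msg <- c(msg, "os_event must be 0/1")
    if (any(cd$os_months <= 0)) msg <- c(msg, "survival times must be positive")
  }
  nrms <- sqrt(colSums(object@signalDirections^2))
  if (any(abs(nrms - 1) > 1e-8)) msg <- c(msg, "signal directions must be unit norm")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort:", length(object@bags), "samples,",
      nrow(object@se), "genes,",
      nrow(object@bags[[1]]@features), "patches/bag x",
      ncol(object@bags[[1]]@features), "features,",
      length(unique(clinicalTable(object)$site)), "sites\n")
  cat("events:", sum(clinicalTable(object)$os_event), "/", length(object@bags), "\n")
})

#' FoldAssignment: site-preserved cross-validation folds
#'
#' Maps every tissue-source site (and hence every sample) to exactly one of
#' `nFolds` cross-validation folds, balancing the per-fold representation of
#' target-variable quantile bins. Fold indices are 0-based.
#'
#' @slot nFolds integer(1), number of folds (5 by default upstream).
#' @slot siteToFold named integer vector, site -> fold.
#' @slot sampleToFold named integer vector, sample id -> fold (derived).
#' @slot quantileEdges numeric, interior quantile cut points of the target.
#' @slot bins named integer vector, sample id -> quantile bin (0-based).
#' @slot objective numeric(1), achieved sum of squared per-fold bin-count
#'   deviations from the balanced ideal.
#' @seealso [assignFolds()], [quantileBins()], [validateFolds()]
#' @export
setClass("FoldAssignment",
  representation(nFolds = "integer", siteToFold = "integer",
                 sampleToFold = "integer", quantileEdges = "numeric",
                 bins = "integer", objective = "numeric"))

setValidity("FoldAssignment", function(object) {
  msg <- NULL
  if (any(object@siteToFold < 0L | object@siteToFold >= object@nFolds))
    msg <- c(msg, "fold indices out of range")
  if (is.null(names(object@siteToFold)) || is.null(names(object@sampleToFold)))
    msg <- c(msg, "siteToFold and sampleToFold must be named")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "FoldAssignment", function(object) {
  cat("FoldAssignment:", length(object@sampleToFold), "samples,",
      length(object@siteToFold), "sites ->", object@nFolds, "folds\n")
  print(table(fold = object@sampleToFold))
  cat("bin-balance objective:", round(object@objective, 3), "\n")
})

#' AmilModel: trained attention-MIL regressor
#'
#' Parameters of the attention-based multiple-instance-learning model: the
#' patch embedding layer (D -> 256, ReLU), the gated-sum attention module
#' (V: 128 x 256, w: 128), and the prediction head (batch normalization,
#' dropout at training time, linear 256 -> 1 with logistic output for
#' expression targets or identity output for survival risk scores).
#'
#' @slot weights named list of parameter matrices/vectors.
#' @slot mode `"expression"` or `"survival"`.
#' @slot scaler numeric(2) `c(min, max)` of the training targets (expression
#'   mode), used to invert min-max scaling at prediction time; `NA` otherwise.
#' @slot config the `trainConfig()` the model was trained with.
#' @slot history per-epoch mean training loss.
#' @seealso [trainAmil()], [predictAmil()]
#' @export
setClass("AmilModel",
  representation(weights = "list", mode = "character", scaler = "numeric",
                 config = "list", history = "numeric"))

setMethod("show", "AmilModel", function(object) {
  cat("AmilModel (", object@mode, " mode): D=", ncol(object@weights$W1),
      ", trained ", length(object@history), " epochs, final loss ",
      signif(utils::tail(object@history, 1), 4), "\n", sep = "")
})

#' CoxFit: summary of a Breslow-ties Cox proportional-hazards fit
#'
#' @slot coefficients named numeric, log-hazard ratios.
#' @slot se named numeric, standard errors.
#' @slot hr named numeric, hazard ratios `exp(beta)`.
#' @slot ciLow,ciHigh named numeric, Wald 95% CI bounds on the HR scale.
#' @slot p named numeric, Wald p-values.
#' @slot logLik numeric(1), partial log-likelihood at the optimum.
#' @slot converged logical(1).
#' @slot model the underlying `survival::coxph` fit (for diagnostics).
#' @seealso [fitCox()]
#' @export
setClass("CoxFit",
  representation(coefficients = "numeric", se = "numeric", hr = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", p = "numeric",
                 logLik = "numeric", converged = "logical", model = "ANY"))

setValidity("CoxFit", function(object) {
  msg <- NULL
  ok <- is.finite(object@ciLow) & is.finite(object@ciHigh)
  if (any(object@ciLow[ok] > object@ciHigh[ok])) msg <- c(msg, "CI bounds out of order")
  if (any(object@hr[is.finite(object@hr)] <= 0)) msg <- c(msg, "HR must be positive")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "CoxFit", function(object) {
  cat("CoxFit (Breslow ties), logLik =", round(object@logLik, 3),
      if (!object@converged) "[NOT CONVERGED]", "\n")
  print(data.frame(beta = round(object@coefficients, 4), se = round(object@se, 4),
                   HR = round(object@hr, 4), ci_low = round(object@ciLow, 4),
                   ci_high = round(object@ciHigh, 4), p = signif(object@p, 4)))
})

#' StratificationResult: risk-group stratification of one gene
#'
#' Result of splitting a cohort into low/high groups at the exact 1-D
#' two-cluster cutoff of a gene's (real or predicted) expression and
#' evaluating the groups with covariate-adjusted Cox regression, the log-rank
#' test, and Harrell's C-index.
#'
#' @slot gene character(1).
#' @slot cutoff numeric(1), midpoint between the two cluster means.
#' @slot groups factor of "low"/"high" per sample.
#' @slot hr,ciLow,ciHigh,p high-vs-low hazard ratio with 95% CI and Wald p
#'   from Cox regression adjusted for age, sex and stage.
#' @slot logrankP unadjusted two-group log-rank p-value.
#' @slot cIndex Harrell's C of the adjusted model's linear predictor.
#' @slot fit the underlying [CoxFit-class].
#' @seealso [stratifyByExpression()], [kmeans2Cutoff()]
#' @export
setClass("StratificationResult",
  representation(gene = "character", cutoff = "numeric", groups = "factor",
                 hr = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 p = "numeric", logrankP = "numeric", cIndex = "numeric",
                 fit = "CoxFit"))

setValidity("StratificationResult", function(object) {
  msg <- NULL
  if (nlevels(object@groups) != 2L || any(tabulate(object@groups, 2L) == 0L))
    msg <- c(msg, "both risk groups must be non-empty")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "StratificationResult", function(object) {
  cat("StratificationResult for", object@gene, "- cutoff", round(object@cutoff, 4), "\n")
  cat("  high vs low: HR", round(object@hr, 3),
      sprintf("[%.3f, %.3f]", object@ciLow, object@ciHigh),
      "p =", signif(object@p, 3), "\n")
  cat("  log-rank p =", signif(object@logrankP, 3),
      " C-index =", round(object@cIndex, 3), "\n")
})
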