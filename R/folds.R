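#' Bin samples into 5 quantiles of the target variable
#'
#' Computes the 20/40/60/80th-percentile cut points of the target and assigns
#' every sample a bin in 0..4. In the survival case (`events` supplied), the
#' cut points are computed on the event times of uncensored samples only;
#' censored samples are then binned by their censoring time against the same
#' edges, so censoring times beyond the last edge land in the top bin.
#'
#' @param target per-sample target values (expression, or observed time in
#'   the survival case).
#' @param events optional 0/1 event indicators; when supplied, quantile edges
#'   come from `target[events == 1]` only.
#' @param nBins number of quantile bins (default 5).
#' @return list with `bins` (integer 0-based per sample) and `edges`
#'   (`nBins - 1` interior cut points).
#' @export
quantileBins <- function(target, events = NULL, nBins = 5L) {
  basis <- if (is.null(events)) target else target[events == 1]
  if (length(unique(basis)) < nBins)
    stop("too few distinct target values to form ", nBins, " quantile bins")
  edges <- quantile(basis, probs = seq_len(nBins - 1) / nBins, names = FALSE)
  bins <- findInterval(target, edges, left.open = TRUE)
  list(bins = as.integer(bins), edges = edges)
}

roundRobinAssignment <- function(siteBinCounts, nFolds) {
  ord <- order(rowSums(siteBinCounts), decreasing = TRUE)
  a <- integer(nrow(siteBinCounts))
  a[ord] <- (seq_along(ord) - 1L) %% nFolds
  a
}

localSearchFolds <- function(siteBinCounts, nFolds, seed, restarts = 100L) {
  nSites <- nrow(siteBinCounts)
  evalObj <- function(a) foldObjectiveCpp(siteBinCounts, a, nFolds)
  improve <- function(a) {
    obj <- evalObj(a)
    repeat {
      moved <- FALSE
      for (s in seq_len(nSites)) {
        for (f in 0:(nFolds - 1L)) {
          if (f == a[s]) next
          cand <- a; cand[s] <- f
          o <- evalObj(cand)
          if (o < obj - 1e-12) { a <- cand; obj <- o; moved <- TRUE }
        }
      }
      if (!moved) break
    }
    list(a = a, obj = obj)
  }
  best <- improve(roundRobinAssignment(siteBinCounts, nFolds))
  withr::with_seed(seed, {
    for (r in seq_len(restarts)) {
      start <- c(sample(0:(nFolds - 1L)),                     # every fold opened
                 sample(0:(nFolds - 1L), nSites - nFolds, replace = TRUE))[
                   sample.int(nSites)]
      res <- improve(start)
      if (res$obj < best$obj - 1e-12) best <- res
    }
  })
  best
}

#' Site-preserved, quantile-balanced fold assignment
#'
#' Assigns every tissue-source site — and hence every sample — to exactly one
#' of `nFolds` cross-validation folds (site integrity is a hard constraint),
#' minimizing the sum over folds and quantile bins of squared deviations of
#' the per-fold bin counts from the balanced ideal `total(bin) / nFolds`.
#' Instances with at most `exhaustiveLimit` sites are solved exactly by
#' exhaustive search over canonical assignments (compiled); larger instances
#' use seeded multi-start local search (single-site reassignment moves,
#' accepting improvements, 100 restarts) that always includes the round-robin
#' assignment as one start.
#'
#' @param sites per-sample site labels.
#' @param bins per-sample 0-based quantile bins from [quantileBins()].
#' @param nFolds number of folds (default 5).
#' @param seed RNG seed for the local search.
#' @param sampleIds optional per-sample ids (defaults to `names(sites)` or
#'   `S0001...`).
#' @param exhaustiveLimit max number of sites for exact search (default 12).
#' @param quantileEdges optional edges to record in the result.
#' @return A [FoldAssignment-class].
#' @export
assignFolds <- function(sites, bins, nFolds = 5L, seed = 1L, sampleIds = NULL,
                        exhaustiveLimit = 12L, quantileEdges = numeric()) {
  stopifnot(length(sites) == length(bins))
  nFolds <- as.integer(nFolds)
  siteLevels <- sort(unique(as.character(sites)))
  if (length(siteLevels) < nFolds)
    stop("need at least as many sites as folds")
  if (is.null(sampleIds)) sampleIds <- names(sites)
  if (is.null(sampleIds)) sampleIds <- sampleIdsFor(length(sites))
  nBins <- max(bins) + 1L
  cnt <- matrix(0L, length(siteLevels), nBins,
                dimnames = list(siteLevels, NULL))
  for (i in seq_along(sites))
    cnt[as.character(sites[i]), bins[i] + 1L] <-
      cnt[as.character(sites[i]), bins[i] + 1L] + 1L
  if (length(siteLevels) <= exhaustiveLimit) {
    sol <- exhaustiveFoldSearch(cnt, nFolds)
    a <- as.integer(sol$assignment); obj <- sol$objective
  } else {
    sol <- localSearchFolds(cnt, nFolds, seed)
    a <- sol$a; obj <- sol$obj
  }
  siteToFold <- setNames(a, siteLevels)
  sampleToFold <- setNames(siteToFold[as.character(sites)], sampleIds)
  new("FoldAssignment", nFolds = nFolds, siteToFold = siteToFold,
      sampleToFold = sampleToFold, quantileEdges = quantileEdges,
      bins = setNames(as.integer(bins), sampleIds), objective = obj)
}

#' Validate a fold assignment
#'
#' Checks site integrity (no site's samples span two folds), consistency of
#' the derived sample map, fold-index range, per-fold sizes and per-fold bin
#' counts. Fails loudly, listing offending sites.
#'
#' @param assignment a [FoldAssignment-class].
#' @param sites per-sample site labels (same order as used in
#'   [assignFolds()]).
#' @param bins per-sample bins.
#' @return invisibly, a list with `foldSizes` and the `foldBinCounts` matrix.
#' @export
validateFolds <- function(assignment, sites, bins) {
  stopifnot(is(assignment, "FoldAssignment"))
  sf <- assignment@sampleToFold
  bad <- character()
  for (s in unique(as.character(sites))) {
    f <- unique(sf[as.character(sites) == s])
    if (length(f) != 1L) bad <- c(bad, s)
    else if (f != assignment@siteToFold[[s]]) bad <- c(bad, s)
  }
  if (length(bad))
    stop("site integrity violated for site(s): ", paste(bad, collapse = ", "))
  if (any(sf < 0L | sf >= assignment@nFolds)) stop("fold index out of range")
  fb <- matrix(0L, assignment@nFolds, max(bins) + 1L)
  for (i in seq_along(sites)) fb[sf[i] + 1L, bins[i] + 1L] <- fb[sf[i] + 1L, bins[i] + 1L] + 1L
  invisible(list(foldSizes = tabulate(sf + 1L, assignment@nFolds),
                 foldBinCounts = fb))
}

#' Fold assignment for a cohort
#'
#' Convenience wrapper: builds quantile bins for a gene-expression or
#' survival target from a cohort's clinical/expression data and assigns
#' site-preserved folds.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param target `"survival"` or a gene id present in the expression matrix.
#' @param nFolds number of folds.
#' @param seed RNG seed.
#' @return A [FoldAssignment-class].
#' @export
cohortFolds <- function(cohort, target = "survival", nFolds = 5L, seed = 1L) {
  clin <- clinicalTable(cohort)
  if (identical(target, "survival")) {
    qb <- quantileBins(clin$os_months, clin$os_event, nBins = nFolds)
  } else {
    qb <- quantileBins(expressionMatrix(cohort)[target, ], nBins = nFolds)
  }
  assignFolds(clin$site, qb$bins, nFolds = nFolds, seed = seed,
              sampleIds = clin$sample_id, quantileEdges = qb$edges)
}
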