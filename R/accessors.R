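#' Accessors for cohort and fold objects
#'
#' `expressionMatrix()` returns the genes x samples expression matrix;
#' `clinicalTable()` the clinical data.frame; `cohortBags()` the list of
#' [PatchBag-class]; `sampleFolds()` the named sample -> fold map;
#' `foldObjective()` the achieved bin-balance objective.
#'
#' @param object a [SyntheticCohort-class] or [FoldAssignment-class].
#' @return See the individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("expressionMatrix", function(object) standardGeneric("expressionMatrix"))

#' @rdname accessors
#' @export
setMethod("expressionMatrix", "SyntheticCohort", function(object)
  SummarizedExperiment::assay(object@se, "expression"))

#' @rdname accessors
#' @export
setGeneric("clinicalTable", function(object) standardGeneric("clinicalTable"))

#' @rdname accessors
#' @export
setMethod("clinicalTable", "SyntheticCohort", function(object)
  as.data.frame(SummarizedExperiment::colData(object@se)))

#' @rdname accessors
#' @export
setGeneric("cohortBags", function(object) standardGeneric("cohortBags"))

#' @rdname accessors
#' @export
setMethod("cohortBags", "SyntheticCohort", function(object) object@bags)

#' @rdname accessors
#' @export
setGeneric("sampleFolds", function(object) standardGeneric("sampleFolds"))

#' @rdname accessors
#' @export
setMethod("sampleFolds", "FoldAssignment", function(object) object@sampleToFold)

#' @rdname accessors
#' @export
setGeneric("foldObjective", function(object) standardGeneric("foldObjective"))

#' @rdname accessors
#' @export
setMethod("foldObjective", "FoldAssignment", function(object) object@objective)

#' @rdname accessors
#' @export
setGeneric("bagFeatures", function(object) standardGeneric("bagFeatures"))

#' @rdname accessors
#' @export
setMethod("bagFeatures", "PatchBag", function(object) object@features)

#' @rdname accessors
#' @export
setGeneric("bagSite", function(object) standardGeneric("bagSite"))

#' @rdname accessors
#' @export
setMethod("bagSite", "PatchBag", function(object) object@site)

#' @rdname accessors
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setMethod("sampleId", "PatchBag", function(object) object@sampleId)

#' @rdname accessors
#' @export
setGeneric("stainMatrix", function(object) standardGeneric("stainMatrix"))

#' @rdname accessors
#' @export
setMethod("stainMatrix", "StainModel", function(object) object@stainMatrix)

#' @rdname accessors
#' @export
setGeneric("maxConcentrations", function(object) standardGeneric("maxConcentrations"))

#' @rdname accessors
#' @export
setMethod("maxConcentrations", "StainModel", function(object) object@maxConcentrations)
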