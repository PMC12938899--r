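#' Accessors for NpxExperiment
#'
#' `npx()` returns the NPX value matrix (proteins x samples, `NA` at missing
#' cells); `missingMask()` and `belowLodMask()` the conformable logical
#' masks; `sampleGroup()` the per-sample group factor; `subjectId()` the
#' per-sample subject identifier; `proteinIds()` the protein identifiers.
#'
#' @param object an [NpxExperiment-class].
#' @return matrix, factor or character vector as described.
#' @name npx-accessors
NULL

#' @rdname npx-accessors
#' @export
setGeneric("npx", function(object) standardGeneric("npx"))
#' @rdname npx-accessors
#' @export
setGeneric("missingMask", function(object) standardGeneric("missingMask"))
#' @rdname npx-accessors
#' @export
setGeneric("belowLodMask", function(object) standardGeneric("belowLodMask"))
#' @rdname npx-accessors
#' @export
setGeneric("sampleGroup", function(object) standardGeneric("sampleGroup"))
#' @rdname npx-accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname npx-accessors
#' @export
setGeneric("proteinIds", function(object) standardGeneric("proteinIds"))

#' @rdname npx-accessors
#' @export
setMethod("npx", "NpxExperiment", function(object)
  SummarizedExperiment::assay(object, "npx"))
#' @rdname npx-accessors
#' @export
setMethod("missingMask", "NpxExperiment", function(object)
  SummarizedExperiment::assay(object, "missing"))
#' @rdname npx-accessors
#' @export
setMethod("belowLodMask", "NpxExperiment", function(object)
  SummarizedExperiment::assay(object, "belowLOD"))
#' @rdname npx-accessors
#' @export
setMethod("sampleGroup", "NpxExperiment", function(object)
  SummarizedExperiment::colData(object)$group)
#' @rdname npx-accessors
#' @export
setMethod("subjectId", "NpxExperiment", function(object)
  SummarizedExperiment::colData(object)$subject_id)
#' @rdname npx-accessors
#' @export
setMethod("proteinIds", "NpxExperiment", function(object) rownames(object))

#' Variable importance in projection (VIP)
#'
#' @param object a fitted projection model (see [fitPLSDA()]).
#' @param ... unused.
#' @return named numeric vector of VIP scores; the mean squared VIP equals 1
#'   by construction.
#' @export
setGeneric("vip", function(object, ...) standardGeneric("vip"))

#' Selection frequencies of an MCCV run
#'
#' @param object an [MccvResult-class].
#' @return named numeric vector: fraction of splits each protein was
#'   selected in.
#' @export
setGeneric("selectionFreq", function(object) standardGeneric("selectionFreq"))

#' @rdname selectionFreq
#' @export
setMethod("selectionFreq", "MccvResult", function(object) object@selection_freq)

#' Pooled out-of-fold AUC of an MCCV run
#'
#' @param object an [MccvResult-class].
#' @return length-1 numeric: AUC over per-subject median held-out
#'   probabilities, with the bootstrap CI in attribute `"ci"`.
#' @export
setGeneric("pooledAuc", function(object) standardGeneric("pooledAuc"))

#' @rdname pooledAuc
#' @export
setMethod("pooledAuc", "MccvResult", function(object) {
  out <- object@pooled_oof_auc
  attr(out, "ci") <- object@pooled_oof_ci
  out
})

#' Per-split AUCs of an MCCV run
#'
#' @param object an [MccvResult-class].
#' @return numeric vector of held-out test-set AUCs, one per split.
#' @export
setGeneric("perSplitAuc", function(object) standardGeneric("perSplitAuc"))

#' @rdname perSplitAuc
#' @export
setMethod("perSplitAuc", "MccvResult", function(object) object@per_split_auc)

#' Consensus panel membership
#'
#' @param object a [ConsensusPanel-class].
#' @return character vector of panel protein ids.
#' @export
setGeneric("panelProteins", function(object) standardGeneric("panelProteins"))

#' @rdname panelProteins
#' @export
setMethod("panelProteins", "ConsensusPanel", function(object) object@panel)

#' Stable per-selector protein sets
#'
#' @param object a [ConsensusPanel-class].
#' @return named list of proteins at or above the stability threshold, one
#'   element per selector.
#' @export
setGeneric("stableSets", function(object) standardGeneric("stableSets"))

#' @rdname stableSets
#' @export
setMethod("stableSets", "ConsensusPanel", function(object) object@stable_sets)
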