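#' Accessors for ConsensusResult
#'
#' @param x a `ConsensusResult`.
#' @param k cluster number; defaults to the chosen k.
#' @return `consensusMatrix` the samples x samples consensus matrix for `k`;
#'   `pacValues` the named PAC-by-k vector; `chosenK` the selected k;
#'   `clusterAssignments` the named assignment vector (at `k`);
#'   `silhouetteWidth` the named silhouette vector; `coreSamples` the ids of
#'   samples flagged as core.
#' @name ConsensusResult-accessors
NULL

#' @rdname ConsensusResult-accessors
#' @export
setGeneric("consensusMatrix", function(x, k = NULL) standardGeneric("consensusMatrix"))

#' @rdname ConsensusResult-accessors
#' @export
setGeneric("pacValues", function(x) standardGeneric("pacValues"))

#' @rdname ConsensusResult-accessors
#' @export
setGeneric("chosenK", function(x) standardGeneric("chosenK"))

#' @rdname ConsensusResult-accessors
#' @export
setGeneric("clusterAssignments", function(x, k = NULL) standardGeneric("clusterAssignments"))

#' @rdname ConsensusResult-accessors
#' @export
setGeneric("silhouetteWidth", function(x) standardGeneric("silhouetteWidth"))

#' @rdname ConsensusResult-accessors
#' @export
setGeneric("coreSamples", function(x) standardGeneric("coreSamples"))

#' Accessors for MacroGroups
#'
#' @param x a `MacroGroups`.
#' @return `groupLabels` the named Macro1/2/3 label vector; `cluster1Id` the
#'   id of the higher-M2 cluster; `unassignedSamples` core GBM samples of the
#'   low-M2 cluster, which receive no Macro label.
#' @name MacroGroups-accessors
NULL

#' @rdname MacroGroups-accessors
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname MacroGroups-accessors
#' @export
setGeneric("cluster1Id", function(x) standardGeneric("cluster1Id"))

#' @rdname MacroGroups-accessors
#' @export
setGeneric("unassignedSamples", function(x) standardGeneric("unassignedSamples"))

#' Accessors for ConcordanceResult
#'
#' @param x a `ConcordanceResult`.
#' @return `aucValue` the area under the rho-ROC curve; `rocPoints` the
#'   (fpr, tpr) step points; `geneStats` the per-gene rho/p/label table.
#' @name ConcordanceResult-accessors
NULL

#' @rdname ConcordanceResult-accessors
#' @export
setGeneric("aucValue", function(x) standardGeneric("aucValue"))

#' @rdname ConcordanceResult-accessors
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))

#' @rdname ConcordanceResult-accessors
#' @export
setGeneric("geneStats", function(x) standardGeneric("geneStats"))
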