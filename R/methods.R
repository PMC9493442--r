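#' @rdname ConsensusResult-accessors
#' @aliases consensusMatrix,ConsensusResult-method
setMethod("consensusMatrix", "ConsensusResult", function(x, k = NULL) {
  if (is.null(k)) k <- x@chosenK
  M <- x@consensusMatrices[[as.character(k)]]
  if (is.null(M)) stop("no consensus matrix for k = ", k)
  M
})

#' @rdname ConsensusResult-accessors
#' @aliases pacValues,ConsensusResult-method
setMethod("pacValues", "ConsensusResult", function(x) x@pacByK)

#' @rdname ConsensusResult-accessors
#' @aliases chosenK,ConsensusResult-method
setMethod("chosenK", "ConsensusResult", function(x) x@chosenK)

#' @rdname ConsensusResult-accessors
#' @aliases clusterAssignments,ConsensusResult-method
setMethod("clusterAssignments", "ConsensusResult", function(x, k = NULL) {
  if (is.null(k) || identical(as.integer(k), x@chosenK)) return(x@assignments)
  a <- x@assignmentsByK[[as.character(k)]]
  if (is.null(a)) stop("no assignments for k = ", k)
  a
})

#' @rdname ConsensusResult-accessors
#' @aliases silhouetteWidth,ConsensusResult-method
setMethod("silhouetteWidth", "ConsensusResult", function(x) x@silhouette)

#' @rdname ConsensusResult-accessors
#' @aliases coreSamples,ConsensusResult-method
setMethod("coreSamples", "ConsensusResult", function(x) {
  names(x@coreFlag)[x@coreFlag]
})

setMethod("show", "ConsensusResult", function(object) {
  n <- length(object@assignments)
  cat("ConsensusResult\n")
  cat("  samples:", n, "\n")
  cat("  k tried:", paste(names(object@pacByK), collapse = ", "), "\n")
  cat("  PAC:", paste(sprintf("%s=%.3f", names(object@pacByK), object@pacByK),
                      collapse = ", "), "\n")
  cat("  chosen k:", object@chosenK, "\n")
  if (n) {
    tab <- table(object@assignments)
    cat("  cluster sizes:", paste(sprintf("%s:%d", names(tab), tab),
                                  collapse = ", "), "\n")
    cat("  core samples:", sum(object@coreFlag), "of", n, "\n")
  }
  invisible(object)
})

#' @rdname MacroGroups-accessors
#' @aliases groupLabels,MacroGroups-method
setMethod("groupLabels", "MacroGroups", function(x) x@labels)

#' @rdname MacroGroups-accessors
#' @aliases cluster1Id,MacroGroups-method
setMethod("cluster1Id", "MacroGroups", function(x) x@cluster1Id)

#' @rdname MacroGroups-accessors
#' @aliases unassignedSamples,MacroGroups-method
setMethod("unassignedSamples", "MacroGroups", function(x) x@unassigned)

setMethod("show", "MacroGroups", function(object) {
  tab <- table(factor(object@labels, c("Macro1", "Macro2", "Macro3")))
  cat("MacroGroups\n")
  cat(sprintf("  Macro1 (GBM, high M2): %d\n", tab[["Macro1"]]))
  cat(sprintf("  Macro2 (LGG, high M2): %d\n", tab[["Macro2"]]))
  cat(sprintf("  Macro3 (LGG, low M2):  %d\n", tab[["Macro3"]]))
  cat(sprintf("  unassigned (GBM, low-M2 cluster): %d\n",
              length(object@unassigned)))
  invisible(object)
})

#' @rdname ConcordanceResult-accessors
#' @aliases aucValue,ConcordanceResult-method
setMethod("aucValue", "ConcordanceResult", function(x) x@auc)

#' @rdname ConcordanceResult-accessors
#' @aliases rocPoints,ConcordanceResult-method
setMethod("rocPoints", "ConcordanceResult", function(x) x@rocPoints)

#' @rdname ConcordanceResult-accessors
#' @aliases geneStats,ConcordanceResult-method
setMethod("geneStats", "ConcordanceResult", function(x) x@geneStats)

setMethod("show", "ConcordanceResult", function(object) {
  cat("ConcordanceResult\n")
  cat("  genes scored:", nrow(object@geneStats), "\n")
  cat("  genes in ROC:", object@nIncluded, "\n")
  cat(sprintf("  AUC: %.4f\n", object@auc))
  invisible(object)
})
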