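#' @import methods
NULL

#' ConsensusResult: consensus clustering of immune-fraction profiles
#'
#' Container for the output of [consensusCluster()]: one consensus matrix per
#' candidate cluster number k, the proportion of ambiguous clustering (PAC)
#' for each k, the chosen k, per-sample cluster assignments at the chosen k,
#' silhouette widths on the consensus dissimilarity, and the core-sample
#' flags used to restrict downstream analyses to well-clustered samples.
#'
#' @slot consensusMatrices named list of samples x samples matrices, one per
#'   k; entries in \[0,1\], symmetric, unit diagonal.
#' @slot assignmentsByK named list of integer vectors (sample -> cluster) per k.
#' @slot pacByK named numeric vector, PAC value per k.
#' @slot chosenK integer(1), the k minimising PAC (ties to the smallest k).
#' @slot assignments named integer vector at the chosen k.
#' @slot silhouette named numeric vector of silhouette widths in \[-1,1\].
#' @slot coreFlag named logical vector; TRUE for samples in the top
#'   `keepFrac` of silhouette widths within their cluster.
#'
#' @seealso [consensusCluster()], [computePac()], [selectK()],
#'   [selectCoreSamples()]
#' @export
setClass("ConsensusResult",
  representation(
    consensusMatrices = "list",
    assignmentsByK = "list",
    pacByK = "numeric",
    chosenK = "integer",
    assignments = "integer",
    silhouette = "numeric",
    coreFlag = "logical"
  )
)

setValidity("ConsensusResult", function(object) {
  msg <- character()
  for (k in names(object@consensusMatrices)) {
    M <- object@consensusMatrices[[k]]
    if (!isTRUE(all.equal(M, t(M), tolerance = 1e-8)))
      msg <- c(msg, sprintf("consensus matrix for k=%s is not symmetric", k))
    if (any(M < -1e-12 | M > 1 + 1e-12))
      msg <- c(msg, sprintf("consensus matrix for k=%s has entries outside [0,1]", k))
    if (any(abs(diag(M) - 1) > 1e-8))
      msg <- c(msg, sprintf("consensus matrix for k=%s diagonal is not 1", k))
  }
  if (length(object@pacByK) && (any(object@pacByK < 0) || any(object@pacByK > 1)))
    msg <- c(msg, "PAC values must lie in [0,1]")
  if (length(object@silhouette) &&
      any(object@silhouette < -1 - 1e-8 | object@silhouette > 1 + 1e-8))
    msg <- c(msg, "silhouette widths must lie in [-1,1]")
  if (length(object@assignments) && is.null(names(object@assignments)))
    msg <- c(msg, "assignments must be named by sample id")
  if (length(msg)) msg else TRUE
})

#' MacroGroups: histology-refined cluster labels
#'
#' Sample labels after crossing the two immune-fraction clusters with
#' histology: GBM samples of the high-M2 cluster are Macro1, LGG samples of
#' the high-M2 cluster Macro2, and LGG samples of the low-M2 cluster Macro3.
#' GBM samples falling in the low-M2 cluster are reported as unassigned.
#'
#' @slot labels named character vector over core samples; values in
#'   `c("Macro1","Macro2","Macro3")`.
#' @slot cluster1Id integer(1), the cluster with the higher mean M2 fraction.
#' @slot unassigned character vector of core GBM samples in cluster 2.
#' @export
setClass("MacroGroups",
  representation(
    labels = "character",
    cluster1Id = "integer",
    unassigned = "character"
  )
)

setValidity("MacroGroups", function(object) {
  msg <- character()
  if (length(object@labels) &&
      !all(object@labels %in% c("Macro1", "Macro2", "Macro3")))
    msg <- c(msg, "labels must be Macro1/Macro2/Macro3")
  if (length(object@labels) && is.null(names(object@labels)))
    msg <- c(msg, "labels must be named by sample id")
  if (length(msg)) msg else TRUE
})

#' ConcordanceResult: rho-ROC concordance of an index with hit-gene signatures
#'
#' Per-gene Spearman correlations of expression with the Macro index, used as
#' classifier scores to separate positive from negative hit genes, with the
#' resulting ROC curve and AUC.
#'
#' @slot geneStats data.frame with columns `gene`, `rho`, `p`, `label`
#'   ("positive_hit"/"negative_hit"), `included`.
#' @slot rocPoints data.frame with columns `fpr`, `tpr`, ordered by threshold.
#' @slot auc numeric(1) in \[0,1\].
#' @slot nIncluded integer(1), genes entering the ROC after the significance
#'   filter.
#' @export
setClass("ConcordanceResult",
  representation(
    geneStats = "data.frame",
    rocPoints = "data.frame",
    auc = "numeric",
    nIncluded = "integer"
  )
)

setValidity("ConcordanceResult", function(object) {
  msg <- character()
  if (length(object@auc) != 1 || object@auc < 0 || object@auc > 1)
    msg <- c(msg, "auc must be a single value in [0,1]")
  if (!all(c("gene", "rho", "p", "label", "included") %in%
           colnames(object@geneStats)))
    msg <- c(msg, "geneStats lacks required columns")
  if (length(msg)) msg else TRUE
})
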