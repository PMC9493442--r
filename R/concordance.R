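## rho-ROC concordance: how well the Macro index separates the positive
## from the negative hit genes of a signature, using each gene's Spearman
## correlation with the index as its classifier score.

#' ROC curve and AUC from scores and binary labels
#'
#' Threshold sweep over the scores; AUC by the rank (Mann-Whitney)
#' formulation with tie correction, which the trapezoid over the step curve
#' equals on tie-free input.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels 0/1 (or logical) class labels.
#' @return list: `points` data.frame (`threshold`, `fpr`, `tpr`) ordered by
#'   decreasing threshold, and `auc`.
#' @export
rocCurve <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("need both classes present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) mean(scores[labels == 0] >= t), numeric(1)),
    tpr = vapply(thr, function(t) mean(scores[labels == 1] >= t), numeric(1))
  )
  list(points = pts, auc = auc)
}

#' Concordance of the Macro index with a hit-gene signature
#'
#' For every hit gene present in the expression matrix, computes the
#' Spearman rho of its expression with the per-sample index. Genes whose
#' correlation is significant at `sigAlpha` are retained (set `keepAll =
#' TRUE` to skip the filter), positive hits labeled 1 and negative hits 0,
#' and the rho values are used as ROC scores.
#'
#' @param expr genes x samples matrix.
#' @param index named per-sample index values (e.g. [computeMacroIndex()]).
#' @param positiveHits,negativeHits gene-id vectors.
#' @param sigAlpha significance cutoff on the per-gene correlation p.
#' @param keepAll retain non-significant genes too.
#' @param samples optional sample-id subset (e.g. one Macro group) on which
#'   the correlations are computed.
#' @param minPerClass minimum present genes per class.
#' @return a [ConcordanceResult-class].
#' @export
signatureConcordanceAuc <- function(expr, index, positiveHits, negativeHits,
                                    sigAlpha = 0.05, keepAll = FALSE,
                                    samples = NULL, minPerClass = 5) {
  if (!is.null(samples)) {
    expr <- expr[, samples, drop = FALSE]
    index <- index[samples]
  } else index <- index[colnames(expr)]
  pos <- intersect(positiveHits, rownames(expr))
  neg <- intersect(negativeHits, rownames(expr))
  nDropped <- (length(positiveHits) - length(pos)) +
    (length(negativeHits) - length(neg))
  if (nDropped > 0)
    message(nDropped, " hit gene(s) absent from the matrix were dropped")
  if (length(pos) < minPerClass || length(neg) < minPerClass)
    stop("too few hit genes present: ", length(pos), " positive, ",
         length(neg), " negative (need >= ", minPerClass, " each)")
  genes <- c(pos, neg)
  st <- lapply(genes, function(g) spearmanCor(expr[g, ], index))
  gs <- data.frame(
    gene = genes,
    rho = vapply(st, `[[`, numeric(1), "rho"),
    p = vapply(st, `[[`, numeric(1), "p"),
    label = rep(c("positive_hit", "negative_hit"),
                c(length(pos), length(neg))),
    stringsAsFactors = FALSE
  )
  gs$included <- if (keepAll) TRUE else gs$p < sigAlpha
  inc <- gs[gs$included, , drop = FALSE]
  if (!any(inc$label == "positive_hit") || !any(inc$label == "negative_hit"))
    stop("one class empty after the significance filter (",
         sum(inc$label == "positive_hit"), " positive, ",
         sum(inc$label == "negative_hit"), " negative included)")
  roc <- rocCurve(inc$rho, inc$label == "positive_hit")
  new("ConcordanceResult", geneStats = gs, rocPoints = roc$points,
      auc = roc$auc, nIncluded = as.integer(nrow(inc)))
}
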