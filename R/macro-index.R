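## The Macro index — the mean log2-transformed TPM of the five
## leukotriene-synthesis / PI3K-gamma genes — plus median splitting,
## rank-sum differential expression and aggregate signature scores.

#' Compute the Macro index
#'
#' Per sample, the mean of `log2(TPM + 1)` over the index genes PIK3R5,
#' PIK3R6, ALOX5, ALOX5AP and ALOX15B. The pseudocount handles zero TPM;
#' genes outside the index list never influence the value. By default at
#' least 4 of the 5 genes must be present, otherwise an error names the
#' missing genes.
#'
#' @param expr genes x samples TPM matrix.
#' @param genes index gene list.
#' @param minPresent minimum number of index genes that must be found.
#' @return named numeric vector of index values with attributes `genesUsed`
#'   and `nGenesFound`.
#' @export
computeMacroIndex <- function(expr, genes = macroIndexGenes(),
                              minPresent = 4) {
  found <- intersect(genes, rownames(expr))
  if (length(found) < minPresent)
    stop("only ", length(found), " of ", length(genes),
         " index genes present (need >= ", minPresent, "); missing: ",
         paste(setdiff(genes, found), collapse = ", "))
  idx <- colMeans(log2(expr[found, , drop = FALSE] + 1))
  attr(idx, "genesUsed") <- found
  attr(idx, "nGenesFound") <- length(found)
  idx
}

#' Split samples at the median
#'
#' Values strictly above the median are `"high"`, values at or below it
#' `"low"` (deterministic; median-equal samples go low). A constant vector
#' yields an all-low split with a warning.
#'
#' @param values named per-sample numeric vector.
#' @return named character vector of `"high"`/`"low"` labels.
#' @export
splitByMedian <- function(values) {
  med <- stats::median(values)
  lab <- ifelse(values > med, "high", "low")
  if (all(lab == "low"))
    warning("degenerate split: all values at or below the median")
  stats::setNames(lab, names(values))
}

#' Rank-sum differential expression between two groups
#'
#' Per gene: log2 fold change as the difference of mean `log2(TPM + 1)`
#' between the high and low groups, a two-sided Wilcoxon rank-sum p-value,
#' and Benjamini-Hochberg adjusted q-values.
#'
#' @param expr genes x samples matrix.
#' @param groups named vector over samples with values `"high"`/`"low"`.
#' @param minPerGroup minimum samples per group.
#' @return data.frame: `gene`, `log2FC`, `p`, `q`, sorted by decreasing
#'   `log2FC`.
#' @export
differentialExpression <- function(expr, groups, minPerGroup = 3) {
  g <- groups[colnames(expr)]
  if (!all(g %in% c("high", "low"))) stop("groups must be 'high'/'low'")
  if (sum(g == "high") < minPerGroup || sum(g == "low") < minPerGroup)
    stop("need >= ", minPerGroup, " samples per group")
  hi <- g == "high"
  l2 <- log2(expr + 1)
  lfc <- rowMeans(l2[, hi, drop = FALSE]) - rowMeans(l2[, !hi, drop = FALSE])
  p <- apply(expr, 1, function(v) wilcoxonRankSum(v[hi], v[!hi])$p)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene = rownames(expr), log2FC = unname(lfc),
                    p = unname(p), q = unname(q), stringsAsFactors = FALSE)
  out[order(-out$log2FC, out$gene), , drop = FALSE]
}

#' Top and bottom hit-gene signatures from a DE table
#'
#' The `n` genes with the largest log2 fold change form the positive hits,
#' the `n` most negative the negative hits; ties are broken by gene id.
#'
#' @param de data.frame from [differentialExpression()].
#' @param n signature size per direction.
#' @return list with `positive_hits` and `negative_hits` (disjoint).
#' @export
hitSignatures <- function(de, n = 150) {
  if (2 * n > nrow(de)) stop("n too large: need 2n <= number of genes")
  ordUp <- de$gene[order(-de$log2FC, de$gene)]
  ordDn <- de$gene[order(de$log2FC, de$gene)]
  list(positive_hits = ordUp[seq_len(n)], negative_hits = ordDn[seq_len(n)])
}

#' Aggregate expression score of a gene set
#'
#' Each gene's `log2(TPM + 1)` is z-scored across samples (zero-variance
#' genes dropped with a warning) and the per-sample mean over the set genes
#' is returned — the "overall expression" of a signature.
#'
#' @param expr genes x samples matrix.
#' @param genes gene-id vector.
#' @return named per-sample numeric score.
#' @export
aggregateSignatureScore <- function(expr, genes) {
  found <- intersect(genes, rownames(expr))
  if (!length(found)) stop("none of the signature genes are present")
  l2 <- log2(expr[found, , drop = FALSE] + 1)
  sds <- apply(l2, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance gene(s) dropped from the signature")
    l2 <- l2[sds > 0, , drop = FALSE]
    if (!nrow(l2)) stop("all signature genes have zero variance")
  }
  z <- t(scale(t(l2)))
  colMeans(z)
}
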