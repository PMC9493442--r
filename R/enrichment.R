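## Single-sample GSEA pathway activity and preranked GSEA with permutation
## significance. Both walk an expression- or metric-ranked gene list and
## accumulate a weighted in-set vs out-set running sum; they are the scoring
## backbone for pathway matrices and ranked-list enrichment.

.presentSets <- function(sets, universe, minSize = 2, maxSize = Inf) {
  pres <- lapply(sets, function(g) unique(g[g %in% universe]))
  nMissing <- sum(lengths(sets) - lengths(pres))
  if (nMissing > 0)
    message(nMissing, " gene(s) absent from the matrix were dropped from sets")
  keep <- lengths(pres) >= minSize & lengths(pres) <= maxSize
  if (any(!keep))
    warning(sum(!keep), " set(s) skipped (outside size bounds after lookup): ",
            paste(utils::head(names(pres)[!keep], 5), collapse = ", "))
  pres[keep]
}

#' Single-sample GSEA scores
#'
#' For each sample, genes are ranked by expression (descending, average
#' ranks for ties) and each set scored by the sum over list positions of the
#' difference between the weighted in-set ECDF (weights `rank^alpha`) and
#' the unweighted out-set ECDF. After all samples are scored, every score is
#' divided by the global range of the score matrix (the customary ssGSEA
#' normalization), so scores are comparable across sets and samples.
#'
#' @param expr genes x samples matrix; any strictly monotone per-sample
#'   transform of expression gives identical scores (rank-based).
#' @param sets named list of gene-id vectors.
#' @param alpha rank-weighting exponent.
#' @param normalize divide by the global score range (set `FALSE` for raw
#'   running-sum scores).
#' @param minSize sets with fewer present genes are skipped with a warning.
#' @return sets x samples score matrix.
#' @export
ssgseaScore <- function(expr, sets, alpha = 0.25, normalize = TRUE,
                        minSize = 2) {
  pres <- .presentSets(sets, rownames(expr), minSize = minSize)
  if (!length(pres)) stop("no scorable gene sets (all below minimum size)")
  N <- nrow(expr)
  scores <- matrix(NA_real_, length(pres), ncol(expr),
                   dimnames = list(names(pres), colnames(expr)))
  setIdx <- lapply(pres, function(g) match(g, rownames(expr)))
  for (j in seq_len(ncol(expr))) {
    r <- rank(expr[, j], ties.method = "average")   # N = highest expression
    ord <- order(expr[, j], decreasing = TRUE)      # walk list top-down
    rOrd <- r[ord]
    inSet <- matrix(FALSE, N, length(pres))
    for (s in seq_along(pres)) inSet[match(setIdx[[s]], ord), s] <- TRUE
    w <- abs(rOrd)^alpha
    for (s in seq_along(pres)) {
      hit <- inSet[, s]
      pin <- cumsum(ifelse(hit, w, 0)) / sum(w[hit])
      pout <- cumsum(!hit) / (N - sum(hit))
      scores[s, j] <- sum(pin - pout)
    }
  }
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  scores
}

#' Build a ranked gene list
#'
#' Ranks genes either by the Spearman rho of each gene with a per-sample
#' target vector (e.g. the Macro index) or by log2 fold change between two
#' groups (difference of mean `log2(TPM + 1)`). The list is sorted in
#' descending metric order with ties broken by gene id.
#'
#' @param expr genes x samples matrix.
#' @param target per-sample numeric vector (for `metricKind =
#'   "spearman_rho"`); must be non-constant.
#' @param groups named vector over samples with values `"high"`/`"low"`
#'   (for `metricKind = "logFC"`).
#' @param metricKind ranking metric.
#' @return data.frame with columns `gene`, `metric`, ordered descending;
#'   attribute `metricKind`.
#' @export
buildRankedList <- function(expr, target = NULL, groups = NULL,
                            metricKind = c("spearman_rho", "logFC")) {
  metricKind <- match.arg(metricKind)
  if (ncol(expr) < 3) stop("need at least 3 samples")
  if (metricKind == "spearman_rho") {
    if (is.null(target)) stop("spearman_rho ranking needs a target vector")
    if (!is.null(names(target))) target <- target[colnames(expr)]
    if (length(target) != ncol(expr) || anyNA(target))
      stop("target must cover every sample")
    if (stats::sd(target) == 0) stop("zero-variance target")
    rt <- rank(target, ties.method = "average")
    metric <- apply(expr, 1, function(g) {
      rg <- rank(g, ties.method = "average")
      if (stats::sd(rg) == 0) return(0)
      stats::cor(rg, rt)
    })
  } else {
    if (is.null(groups)) stop("logFC ranking needs group labels")
    g <- if (is.null(names(groups))) groups else groups[colnames(expr)]
    if (!all(g %in% c("high", "low"))) stop("groups must be 'high'/'low'")
    l2 <- log2(expr + 1)
    metric <- rowMeans(l2[, g == "high", drop = FALSE]) -
      rowMeans(l2[, g == "low", drop = FALSE])
  }
  ord <- order(-metric, rownames(expr))
  out <- data.frame(gene = rownames(expr)[ord], metric = unname(metric[ord]),
                    stringsAsFactors = FALSE)
  attr(out, "metricKind") <- metricKind
  out
}

## ES of one set at hit positions `pos` (sorted) in a list of length N with
## per-position weights |metric|^p; returns the signed maximum deviation of
## the running sum and the position where it is attained.
.gseaES <- function(absWp, pos, N) {
  m <- length(pos)
  inc <- numeric(N)
  inc[pos] <- absWp[pos] / sum(absWp[pos])
  dec <- rep(1 / (N - m), N)
  dec[pos] <- 0
  rs <- cumsum(inc - dec)
  i <- which.max(abs(rs))
  list(es = rs[i], at = i)
}

#' Preranked GSEA with permutation significance
#'
#' Classical weighted Kolmogorov-Smirnov-like enrichment on a ranked list:
#' hit increments proportional to `|metric|^weightP` normalized over the
#' set, miss decrements `1/(N - |S|)`; ES is the signed maximum deviation of
#' the running sum. Nominal p comes from gene-label permutations preserving
#' set size, one-sided on the sign of the observed ES, with the
#' `(r + 1)/(n + 1)` estimator; when `exact = TRUE` and the number of
#' distinct placements is small, all placements are enumerated instead and p
#' is the exact tail fraction. NES divides ES by the mean `|permuted ES|` of
#' the same sign, and FDR q uses the customary sign-stratified NES ratio.
#'
#' @param rankedList output of [buildRankedList()] (columns `gene`,
#'   `metric`).
#' @param sets named list of gene-id vectors.
#' @param nPerm permutations per set (>= 100).
#' @param weightP metric-weighting exponent (0 gives the unweighted KS
#'   statistic with ES in \[-1,1\]).
#' @param seed integer seed for the permutation stream.
#' @param minSize,maxSize set-size bounds after restricting to list genes.
#' @param exact enumerate all `choose(N, |S|)` placements when feasible
#'   (<= `exactLimit`); overrides `nPerm` for such sets.
#' @param exactLimit largest enumeration size for `exact` mode.
#' @return data.frame per set: `set`, `size`, `es`, `nes`, `p`, `q`, and a
#'   list column `leadingEdge`.
#' @export
prerankedGsea <- function(rankedList, sets, nPerm = 1000, weightP = 1,
                          seed = 1, minSize = 5, maxSize = 500,
                          exact = FALSE, exactLimit = 2e5) {
  if (!exact && nPerm < 100) stop("need nPerm >= 100")
  genes <- rankedList$gene
  N <- length(genes)
  pres <- .presentSets(sets, genes, minSize = minSize, maxSize = maxSize)
  if (!length(pres)) stop("no scorable gene sets")
  if (any(lengths(pres) == N))
    stop("a set equal to the entire list has an undefined miss decrement")
  absWp <- abs(rankedList$metric)^weightP

  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)

  res <- data.frame(set = names(pres), size = lengths(pres), es = NA_real_,
                    nes = NA_real_, p = NA_real_, q = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  res$leadingEdge <- vector("list", nrow(res))
  permNes <- vector("list", nrow(res))
  for (s in seq_along(pres)) {
    pos <- sort(match(pres[[s]], genes))
    obs <- .gseaES(absWp, pos, N)
    m <- length(pos)
    if (exact && choose(N, m) <= exactLimit) {
      placements <- utils::combn(N, m)
      esPerm <- apply(placements, 2, function(pp) .gseaES(absWp, pp, N)$es)
      p <- if (obs$es >= 0) mean(esPerm >= obs$es - 1e-12)
           else mean(esPerm <= obs$es + 1e-12)
    } else {
      esPerm <- vapply(seq_len(nPerm), function(i)
        .gseaES(absWp, sort(sample.int(N, m)), N)$es, numeric(1))
      r <- if (obs$es >= 0) sum(esPerm >= obs$es) else sum(esPerm <= obs$es)
      p <- (r + 1) / (length(esPerm) + 1)
    }
    sameSign <- if (obs$es >= 0) esPerm[esPerm >= 0] else esPerm[esPerm < 0]
    nes <- if (length(sameSign)) obs$es / mean(abs(sameSign)) else NA_real_
    normPos <- mean(abs(esPerm[esPerm >= 0]))
    normNeg <- mean(abs(esPerm[esPerm < 0]))
    permNes[[s]] <- ifelse(esPerm >= 0,
                           esPerm / ifelse(is.nan(normPos), 1, normPos),
                           esPerm / ifelse(is.nan(normNeg), 1, normNeg))
    le <- if (obs$es >= 0) genes[intersect(pos, seq_len(obs$at))]
          else genes[intersect(pos, obs$at:N)]
    res$es[s] <- obs$es
    res$nes[s] <- nes
    res$p[s] <- p
    res$leadingEdge[[s]] <- le
  }

  allPermNes <- unlist(permNes)
  for (s in seq_len(nrow(res))) {
    nes <- res$nes[s]
    if (is.na(nes)) next
    if (nes >= 0) {
      num <- mean(allPermNes[allPermNes >= 0] >= nes)
      den <- sum(res$nes >= nes, na.rm = TRUE) /
        max(sum(res$nes >= 0, na.rm = TRUE), 1)
    } else {
      num <- mean(allPermNes[allPermNes < 0] <= nes)
      den <- sum(res$nes <= nes, na.rm = TRUE) /
        max(sum(res$nes < 0, na.rm = TRUE), 1)
    }
    res$q[s] <- min(1, max(0, if (den > 0) num / den else 1))
  }
  res
}
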