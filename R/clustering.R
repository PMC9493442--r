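## Consensus clustering of immune-fraction profiles: PAM under a
## 1 - Pearson dissimilarity with repeated subsampling, PAC-based selection
## of the cluster number, silhouette widths on the consensus dissimilarity,
## and the histology crossing that yields the Macro1/2/3 groups.

#' Filter an immune-fraction matrix before clustering
#'
#' Drops samples whose deconvolution p-value exceeds `pCutoff` (when
#' p-values are supplied) and then drops cell types whose fraction is zero
#' in strictly more than half of the remaining samples.
#'
#' @param fr cell-types x samples fraction matrix.
#' @param pvals optional named per-sample p-values.
#' @param pCutoff sample-level p-value cutoff.
#' @param zeroFracCutoff cell types zero in > this fraction of samples are
#'   dropped (strict inequality).
#' @return filtered matrix, with attributes `droppedSamples` and
#'   `droppedCellTypes`.
#' @export
filterFractionMatrix <- function(fr, pvals = NULL, pCutoff = 0.05,
                                 zeroFracCutoff = 0.5) {
  droppedSamples <- character()
  if (!is.null(pvals)) {
    pv <- pvals[colnames(fr)]
    keep <- !is.na(pv) & pv <= pCutoff
    droppedSamples <- colnames(fr)[!keep]
    fr <- fr[, keep, drop = FALSE]
  }
  if (!ncol(fr)) stop("no samples left after the p-value filter")
  zeroFrac <- rowMeans(fr == 0)
  keepCt <- zeroFrac <= zeroFracCutoff  # "over half" is strict >
  droppedCellTypes <- rownames(fr)[!keepCt]
  fr <- fr[keepCt, , drop = FALSE]
  if (!nrow(fr)) stop("all cell types removed by the zero-fraction filter")
  attr(fr, "droppedSamples") <- droppedSamples
  attr(fr, "droppedCellTypes") <- droppedCellTypes
  fr
}

.pearsonDissimilarity <- function(X) {
  ## X: samples x features; d(i,j) = 1 - Pearson(x_i, x_j)
  sds <- apply(X, 1, stats::sd)
  if (any(sds == 0))
    stop("constant profile (undefined correlation) for sample(s): ",
         paste(rownames(X)[sds == 0], collapse = ", "))
  D <- 1 - stats::cor(t(X))
  D[D < 0] <- 0
  diag(D) <- 0
  D
}

#' Proportion of ambiguous clustering
#'
#' The fraction of off-diagonal consensus entries strictly between `u1` and
#' `u2`; minimised over k to choose the number of clusters.
#'
#' @param M symmetric consensus matrix with entries in \[0,1\].
#' @param u1,u2 ambiguity interval bounds, `0 <= u1 < u2 <= 1`.
#' @return PAC in \[0,1\].
#' @export
computePac <- function(M, u1 = 0.1, u2 = 0.9) {
  if (!(u1 >= 0 && u1 < u2 && u2 <= 1)) stop("need 0 <= u1 < u2 <= 1")
  if (!isTRUE(all.equal(M, t(M), tolerance = 1e-8)))
    stop("consensus matrix must be symmetric")
  off <- M[upper.tri(M)]
  mean(off > u1 & off < u2)
}

#' Choose k by minimal PAC
#'
#' @param pacByK named numeric vector mapping k to PAC.
#' @return the k with minimal PAC; ties broken towards the smallest k.
#' @export
selectK <- function(pacByK) {
  ks <- as.integer(names(pacByK))
  ks <- ks[order(ks)]
  pac <- pacByK[as.character(ks)]
  ks[which.min(pac)]  # which.min takes the first minimum, i.e. smallest k
}

#' Silhouette widths from a distance matrix
#'
#' `s(i) = (b - a) / max(a, b)` with `a` the mean distance of sample i to
#' its own cluster (excluding itself) and `b` the smallest mean distance to
#' any other cluster. Members of singleton clusters get `s = 0`.
#'
#' @param D symmetric distance matrix (samples x samples).
#' @param assignments named integer cluster vector over the samples of `D`.
#' @return named numeric vector of silhouette widths in \[-1,1\].
#' @export
silhouetteWidths <- function(D, assignments) {
  ids <- rownames(D)
  if (is.null(ids)) ids <- names(assignments)
  a <- assignments[ids]
  cl <- sort(unique(a))
  if (length(cl) < 2) stop("silhouette needs at least 2 clusters")
  s <- stats::setNames(numeric(length(ids)), ids)
  for (i in seq_along(ids)) {
    own <- a == a[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    ai <- mean(D[i, own & seq_along(ids) != i])
    bi <- min(vapply(setdiff(cl, a[i]),
                     function(k) mean(D[i, a == k]), numeric(1)))
    s[i] <- if (max(ai, bi) == 0) 0 else (bi - ai) / max(ai, bi)
  }
  s
}

#' Flag the core samples of each cluster
#'
#' Within every cluster, the `ceiling(keepFrac * n)` samples with the
#' largest silhouette widths are kept; ties at the cutoff are broken by
#' sample id order, so the selection is deterministic.
#'
#' @param silhouette named numeric silhouette vector.
#' @param assignments named integer cluster vector.
#' @param keepFrac fraction of each cluster to keep.
#' @return named logical vector, `TRUE` for core samples.
#' @export
selectCoreSamples <- function(silhouette, assignments, keepFrac = 0.75) {
  ids <- names(assignments)
  core <- stats::setNames(logical(length(ids)), ids)
  for (k in unique(assignments)) {
    members <- ids[assignments == k]
    nKeep <- ceiling(keepFrac * length(members))
    ord <- members[order(-silhouette[members], members)]
    core[ord[seq_len(nKeep)]] <- TRUE
  }
  core
}

#' Consensus clustering with PAM and a Pearson dissimilarity
#'
#' For each candidate k, samples are repeatedly subsampled, partitioned with
#' PAM under `d(i,j) = 1 - Pearson(x_i, x_j)`, and co-clustering counts are
#' accumulated; the consensus entry is the co-clustered count divided by the
#' co-sampled count. The final partition for each k is PAM on `1 - M_k`.
#' PAC is computed per k, the minimising k chosen, silhouette widths taken
#' on the consensus dissimilarity of the chosen k, and core samples flagged.
#'
#' @param X samples x features matrix (e.g. the transposed, filtered
#'   immune-fraction matrix).
#' @param kRange candidate cluster numbers.
#' @param nResample number of subsampling iterations per k.
#' @param subsampleFrac fraction of samples per iteration.
#' @param seed integer seed for the subsampling stream.
#' @param u1,u2 PAC ambiguity bounds.
#' @param keepFrac core-sample fraction per cluster.
#' @return a [ConsensusResult-class].
#' @export
consensusCluster <- function(X, kRange = 2:6, nResample = 1000,
                             subsampleFrac = 0.8, seed = 1,
                             u1 = 0.1, u2 = 0.9, keepFrac = 0.75) {
  n <- nrow(X)
  if (is.null(rownames(X))) rownames(X) <- sprintf("sample%03d", seq_len(n))
  if (ncol(X) < 2) stop("need at least 2 features")
  if (n < 2 * max(kRange))
    stop("need at least 2 * max(kRange) samples")
  D <- .pearsonDissimilarity(X)
  ids <- rownames(X)
  nSub <- max(ceiling(subsampleFrac * n), max(kRange) + 1)

  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  subsamples <- lapply(seq_len(nResample), function(i) sort(sample.int(n, nSub)))

  cosampled <- matrix(0, n, n)
  for (s in subsamples) cosampled[s, s] <- cosampled[s, s] + 1

  Ms <- list(); asgK <- list(); pac <- numeric()
  for (k in kRange) {
    conn <- matrix(0, n, n)
    for (s in subsamples) {
      cl <- cluster::pam(stats::as.dist(D[s, s]), k = k, diss = TRUE,
                         pamonce = 5, cluster.only = TRUE)
      for (g in unique(cl)) {
        m <- s[cl == g]
        conn[m, m] <- conn[m, m] + 1
      }
    }
    M <- ifelse(cosampled > 0, conn / pmax(cosampled, 1), 0)
    diag(M) <- 1
    dimnames(M) <- list(ids, ids)
    asg <- cluster::pam(stats::as.dist(1 - M), k = k, diss = TRUE,
                        pamonce = 5, cluster.only = TRUE)
    Ms[[as.character(k)]] <- M
    asgK[[as.character(k)]] <- stats::setNames(as.integer(asg), ids)
    pac[as.character(k)] <- computePac(M, u1, u2)
  }

  kStar <- selectK(pac)
  Mstar <- Ms[[as.character(kStar)]]
  asg <- asgK[[as.character(kStar)]]
  sil <- silhouetteWidths(1 - Mstar, asg)
  core <- selectCoreSamples(sil, asg, keepFrac)

  new("ConsensusResult",
      consensusMatrices = Ms, assignmentsByK = asgK, pacByK = pac,
      chosenK = as.integer(kStar), assignments = asg, silhouette = sil,
      coreFlag = core)
}

#' Cross clusters with histology into Macro1/2/3 groups
#'
#' The cluster with the higher mean M2 fraction is "cluster 1". Core GBM
#' samples of cluster 1 become Macro1, core LGG samples of cluster 1 Macro2,
#' and core LGG samples of cluster 2 Macro3. Core GBM samples of cluster 2
#' receive no label and are reported as unassigned.
#'
#' @param assignments named 2-cluster assignment vector.
#' @param coreFlag named logical core-sample vector.
#' @param clinical data.frame with `sample_id` and `histology`
#'   ("GBM"/"LGG").
#' @param m2 named per-sample M2 fraction.
#' @return a [MacroGroups-class].
#' @export
assignMacroGroups <- function(assignments, coreFlag, clinical, m2) {
  cl <- sort(unique(assignments))
  if (length(cl) != 2) stop("Macro group assignment requires exactly 2 clusters")
  if (!all(c("sample_id", "histology") %in% colnames(clinical)))
    stop("clinical table must provide sample_id and histology")
  ids <- names(assignments)
  hist <- stats::setNames(clinical$histology, clinical$sample_id)[ids]
  if (anyNA(hist)) stop("histology missing for some clustered samples")
  means <- vapply(cl, function(k) mean(m2[ids[assignments == k]]), numeric(1))
  if (abs(diff(means)) < .Machine$double.eps^0.5)
    stop("clusters have identical mean M2 fraction; orientation undecidable")
  c1 <- cl[which.max(means)]
  core <- ids[coreFlag[ids]]
  inC1 <- assignments[core] == c1
  isGBM <- hist[core] == "GBM"
  labels <- character(0)
  labels[core[inC1 & isGBM]] <- "Macro1"
  labels[core[inC1 & !isGBM]] <- "Macro2"
  labels[core[!inC1 & !isGBM]] <- "Macro3"
  unassigned <- core[!inC1 & isGBM]
  labels <- labels[!is.na(labels)]
  new("MacroGroups", labels = labels, cluster1Id = as.integer(c1),
      unassigned = as.character(unassigned))
}
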