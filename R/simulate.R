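## Synthetic glioma-like cohort with known ground truth: cell-type mixtures
## with Dirichlet fractions drawn from two latent archetypes (M2-high vs
## M2-low), five designated index genes tracking the M2 fraction, planted
## up/down hit-gene signatures, three noisy immune-fraction "algorithms",
## survival with an index-dependent hazard, and binary alterations with a
## logistic link on the M2 fraction.

.CELL_TYPES <- c("Macrophage_M2", "T_cell_CD8", "B_cell", "NK_cell", "Monocyte",
                 "T_cell_CD4", "Dendritic", "Mast_cell")

#' The five Macro index genes
#'
#' PIK3R5 and PIK3R6 (class I PI3K gamma regulatory subunits) and ALOX5,
#' ALOX5AP, ALOX15B (leukotriene-synthesis lipoxygenase pathway).
#'
#' @return character(5).
#' @export
macroIndexGenes <- function() c("PIK3R5", "PIK3R6", "ALOX5", "ALOX5AP", "ALOX15B")

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe the study conditions the package is validated under:
#' a 300-sample cohort mixing two archetypes in equal proportion, with the
#' M2-high archetype centred near 60% M2 macrophage content and the M2-low
#' archetype near 5%, five-fold elevated marker genes, moderate log-normal
#' measurement noise, five index genes whose log2 expression rises with the
#' M2 fraction, 150 up- and 150 down-regulated hit genes, and an exponential
#' survival model whose log hazard is linear in the standardized index.
#'
#' @param nGenes total genes.
#' @param nSamples cohort size.
#' @param nCellTypes number of mixed cell types (first is the M2 macrophage).
#' @param dirichletAlphaHigh,dirichletAlphaLow Dirichlet concentration per
#'   cell type for the M2-high / M2-low archetype (recycled to `nCellTypes`).
#' @param mixingProportion probability a sample is drawn from the M2-high
#'   archetype.
#' @param signatureStrength fold elevation of marker genes in their own cell
#'   type (> 1).
#' @param noiseSigma sd of multiplicative log-normal noise on the bulk matrix.
#' @param indexGeneEffect slope b of index-gene log2 expression on the M2
#'   fraction.
#' @param indexIntercept intercept a of the same relation.
#' @param indexNoise sd of the index genes' log2-scale noise.
#' @param nHitUp,nHitDn number of planted up-/down-regulated hit genes.
#' @param hitEffect log2-scale shift per sd of M2 fraction for hit genes.
#' @param fractionNoise sd of the log-scale noise that turns the true
#'   fraction matrix into the three per-algorithm estimates.
#' @param survivalBeta log hazard ratio per sd of the index signal.
#' @param baselineHazard events per day at index signal 0.
#' @param censorRate target fraction of censored observations in \[0,1).
#' @param pGBMHigh,pGBMLow probability of GBM histology given the M2-high /
#'   M2-low archetype.
#' @param nAlterations number of binary alteration features (the first half
#'   carry the planted log-odds slope, the rest are null).
#' @param alterationLogOdds planted log-odds slope on the standardized M2
#'   fraction.
#' @param nMarkersPerType marker genes per cell type.
#' @param seed integer seed; mandatory, the generator is fully reproducible.
#' @return a validated `list` of class `SimulationConfig`.
#' @export
simulationConfig <- function(nGenes = 1200L, nSamples = 300L, nCellTypes = 5L,
                             dirichletAlphaHigh = c(12, 2, 2, 2, 2),
                             dirichletAlphaLow = c(1, 5, 5, 5, 5),
                             mixingProportion = 0.5,
                             signatureStrength = 5,
                             noiseSigma = 0.25,
                             indexGeneEffect = 4,
                             indexIntercept = 2,
                             indexNoise = 0.5,
                             nHitUp = 150L, nHitDn = 150L,
                             hitEffect = 1,
                             fractionNoise = 0.15,
                             survivalBeta = 0.8,
                             baselineHazard = 1 / 1000,
                             censorRate = 0.3,
                             pGBMHigh = 0.5, pGBMLow = 0.1,
                             nAlterations = 10L,
                             alterationLogOdds = 2,
                             nMarkersPerType = 20L,
                             seed) {
  if (missing(seed)) stop("a seed is mandatory in the simulation config")
  cfg <- list(
    nGenes = as.integer(nGenes), nSamples = as.integer(nSamples),
    nCellTypes = as.integer(nCellTypes),
    dirichletAlphaHigh = rep_len(dirichletAlphaHigh, nCellTypes),
    dirichletAlphaLow = rep_len(dirichletAlphaLow, nCellTypes),
    mixingProportion = mixingProportion,
    signatureStrength = signatureStrength, noiseSigma = noiseSigma,
    indexGeneEffect = indexGeneEffect, indexIntercept = indexIntercept,
    indexNoise = indexNoise,
    nHitUp = as.integer(nHitUp), nHitDn = as.integer(nHitDn),
    hitEffect = hitEffect, fractionNoise = fractionNoise,
    survivalBeta = survivalBeta, baselineHazard = baselineHazard,
    censorRate = censorRate, pGBMHigh = pGBMHigh, pGBMLow = pGBMLow,
    nAlterations = as.integer(nAlterations),
    alterationLogOdds = alterationLogOdds,
    nMarkersPerType = as.integer(nMarkersPerType),
    seed = as.integer(seed)
  )
  with(cfg, {
    if (nGenes < 1 || nSamples < 1 || nCellTypes < 1 || nHitUp < 1 || nHitDn < 1)
      stop("all counts must be >= 1")
    if (any(dirichletAlphaHigh <= 0) || any(dirichletAlphaLow <= 0))
      stop("dirichlet alpha must be > 0")
    if (censorRate < 0 || censorRate >= 1) stop("censorRate must be in [0,1)")
    if (nCellTypes > nGenes / 10)
      stop("too few markers per cell type: need nCellTypes <= nGenes/10")
  })
  class(cfg) <- "SimulationConfig"
  cfg
}

.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = length(alpha))
  sweep(g, 2, colSums(g), "/")
}

.renormCols <- function(m) sweep(m, 2, colSums(m), "/")

## uniform censoring bound giving the target censoring fraction:
## P(U < T) with U ~ Unif(0, c) is mean(pmin(T, c))/c; solve for c.
.censorBound <- function(times, rate) {
  if (rate <= 0) return(Inf)
  f <- function(cc) mean(pmin(times, cc)) / cc - rate
  upper <- max(times) * 2
  if (f(upper) > 0) return(upper)
  stats::uniroot(f, lower = min(times) / 1e3, upper = upper)$root
}

.simSurvival <- function(lp, baselineHazard, censorRate) {
  n <- length(lp)
  t_event <- stats::rexp(n, rate = baselineHazard * exp(lp))
  cmax <- .censorBound(t_event, censorRate)
  t_cens <- if (is.finite(cmax)) stats::runif(n, 0, cmax) else rep(Inf, n)
  list(time = pmin(t_event, t_cens), event = as.integer(t_event <= t_cens))
}

#' Simulate a glioma-like cohort with ground truth
#'
#' Bulk expression is a signature-matrix x fraction-matrix product on the
#' linear scale, rescaled so each sample column sums to 1e6 (TPM convention),
#' with multiplicative log-normal noise. The five index genes are then
#' regenerated so that `log2(TPM+1) = a + b * f_M2 + noise`; hit genes get a
#' log2-scale shift of `+/- hitEffect` per sd of the M2 fraction. Three
#' fraction "algorithms" are independent noisy views of the true fraction
#' matrix. OS/PFI are exponential with log hazard `survivalBeta` per sd of
#' the index signal, under independent uniform censoring. Alteration
#' features are Bernoulli with log odds linear in the standardized M2
#' fraction.
#'
#' @param cfg a [simulationConfig()].
#' @return list with `expr` (genes x samples TPM), `fractions` (list of three
#'   cell-type x sample matrices `algoA`/`algoB`/`algoC` plus per-sample
#'   `pvals`), `clinical` (data.frame), `geneSets` (hit signatures, one
#'   planted pathway and random pathways), `alterations` (0/1 feature x
#'   sample matrix), and `truth` (true fractions, archetypes, index/hit gene
#'   lists, planted slopes, the signature matrix).
#' @export
simulateCohort <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(cfg$seed)
  C <- cfg$nCellTypes
  G <- cfg$nGenes
  n <- cfg$nSamples
  cellTypes <- rep_len(.CELL_TYPES, C)[seq_len(C)]
  sampleIds <- sprintf("S%04d", seq_len(n))

  idx <- macroIndexGenes()
  geneIds <- c(idx, sprintf("G%05d", seq_len(G - length(idx))))
  markerPool <- setdiff(geneIds, idx)
  markers <- split(markerPool[seq_len(C * cfg$nMarkersPerType)],
                   rep(seq_len(C), each = cfg$nMarkersPerType))

  ## signature matrix: shared log-normal base, markers elevated in own type
  base <- stats::rlnorm(G, meanlog = log(50), sdlog = 1)
  S <- matrix(base, nrow = G, ncol = C, dimnames = list(geneIds, cellTypes))
  for (ct in seq_len(C))
    S[markers[[ct]], ct] <- S[markers[[ct]], ct] * cfg$signatureStrength

  ## archetypes and true fractions
  archetype <- ifelse(stats::runif(n) < cfg$mixingProportion, "M2high", "M2low")
  F <- matrix(NA_real_, C, n, dimnames = list(cellTypes, sampleIds))
  hi <- archetype == "M2high"
  if (any(hi)) F[, hi] <- .rdirichlet(sum(hi), cfg$dirichletAlphaHigh)
  if (any(!hi)) F[, !hi] <- .rdirichlet(sum(!hi), cfg$dirichletAlphaLow)
  fM2 <- F[1, ]

  ## bulk: mixture, TPM rescale, multiplicative noise
  bulk <- S %*% F
  bulk <- sweep(bulk, 2, colSums(bulk), "/") * 1e6
  if (cfg$noiseSigma > 0)
    bulk <- bulk * exp(matrix(stats::rnorm(G * n, 0, cfg$noiseSigma), G, n))
  dimnames(bulk) <- list(geneIds, sampleIds)

  ## hit genes: log2-scale shift proportional to the standardized M2 fraction
  zf <- as.vector(scale(fM2))
  hitPool <- setdiff(markerPool, unlist(markers))
  hitUp <- hitPool[seq_len(cfg$nHitUp)]
  hitDn <- hitPool[cfg$nHitUp + seq_len(cfg$nHitDn)]
  shift <- function(rows, sgn) {
    l2 <- log2(bulk[rows, , drop = FALSE] + 1) +
      outer(rep(sgn * cfg$hitEffect, length(rows)), zf)
    pmax(2^l2 - 1, 0)
  }
  bulk[hitUp, ] <- shift(hitUp, +1)
  bulk[hitDn, ] <- shift(hitDn, -1)

  ## index genes: log2(TPM+1) = a + b * f_M2 + noise
  l2idx <- cfg$indexIntercept + cfg$indexGeneEffect * matrix(fM2, 5, n, byrow = TRUE) +
    matrix(stats::rnorm(5 * n, 0, cfg$indexNoise), 5, n)
  bulk[idx, ] <- pmax(2^l2idx - 1, 0)

  ## three fraction algorithms = independent noisy views of F
  noisyView <- function() {
    Fn <- F * exp(matrix(stats::rnorm(C * n, 0, cfg$fractionNoise), C, n))
    .renormCols(Fn)
  }
  fractions <- list(algoA = noisyView(), algoB = noisyView(), algoC = noisyView(),
                    pvals = stats::setNames(stats::runif(n, 0.001, 0.049), sampleIds))

  ## clinical: histology depends on archetype; survival on the index signal
  pGBM <- ifelse(hi, cfg$pGBMHigh, cfg$pGBMLow)
  histology <- ifelse(stats::runif(n) < pGBM, "GBM", "LGG")
  whoGrade <- ifelse(histology == "GBM", "IV", sample(c("II", "III"), n, TRUE))
  lp <- cfg$survivalBeta * as.vector(scale(cfg$indexGeneEffect * fM2))
  os <- .simSurvival(lp, cfg$baselineHazard, cfg$censorRate)
  pfi <- .simSurvival(lp, cfg$baselineHazard * 2, cfg$censorRate)
  clinical <- data.frame(
    sample_id = sampleIds,
    histology = histology,
    who_grade = whoGrade,
    transcriptome_subtype = sample(c("Classical", "Mesenchymal", "Proneural",
                                     "Neural"), n, TRUE),
    os_time = os$time, os_event = os$event,
    pfi_time = pfi$time, pfi_event = pfi$event,
    age = round(stats::rnorm(n, 50, 12)),
    gender = sample(c("Male", "Female"), n, TRUE),
    archetype = archetype,
    stringsAsFactors = FALSE
  )

  ## alterations: first half planted with a logistic link on z(f_M2)
  nAlt <- cfg$nAlterations
  kinds <- c("mut", "gain", "loss")
  altIds <- sprintf("ALTGENE%02d_%s", seq_len(nAlt),
                    rep_len(kinds, nAlt))
  slopes <- c(rep(cfg$alterationLogOdds, ceiling(nAlt / 2)),
              rep(0, nAlt - ceiling(nAlt / 2)))
  alt <- t(vapply(slopes, function(b)
    stats::rbinom(n, 1, stats::plogis(b * zf)), numeric(n)))
  dimnames(alt) <- list(altIds, sampleIds)

  ## gene sets: the hit signatures, one pathway planted inside the up-hits,
  ## and random pathways for contrast
  planted <- sample(hitUp, 30)
  rnd <- lapply(seq_len(10), function(i) sample(hitPool[-seq_len(cfg$nHitUp + cfg$nHitDn)], 30))
  geneSets <- c(list(HIT_UP = hitUp, HIT_DN = hitDn, PLANTED_PATHWAY = planted),
                stats::setNames(rnd, sprintf("RANDOM_%02d", seq_len(10))))

  truth <- list(
    fractions = F, archetype = stats::setNames(archetype, sampleIds),
    m2Fraction = fM2,
    indexGenes = idx, indexSlope = cfg$indexGeneEffect,
    hitUp = hitUp, hitDn = hitDn,
    survivalBeta = cfg$survivalBeta,
    alterationSlopes = stats::setNames(slopes, altIds),
    signatureMatrix = S, markers = markers
  )

  list(expr = bulk, fractions = fractions, clinical = clinical,
       geneSets = geneSets, alterations = alt, truth = truth, config = cfg)
}

#' Non-negative least-squares deconvolution of bulk mixtures
#'
#' Reference-based stand-in for external immune deconvolution tools: each
#' sample column is regressed on the cell-type signature matrix under
#' non-negativity, and the weights are renormalized to sum to one.
#'
#' @param bulk genes x samples matrix.
#' @param signatures genes x cell-types matrix (full column rank; gene
#'   rownames must be present in `bulk`).
#' @return cell-types x samples fraction matrix with columns summing to 1.
#' @export
nnlsDeconvolve <- function(bulk, signatures) {
  if (is.null(rownames(signatures)) || !all(rownames(signatures) %in% rownames(bulk)))
    stop("all signature genes must be present in the bulk matrix")
  if (qr(signatures)$rank < ncol(signatures))
    stop("signature matrix is rank deficient")
  B <- bulk[rownames(signatures), , drop = FALSE]
  C <- ncol(signatures)
  out <- matrix(NA_real_, C, ncol(B),
                dimnames = list(colnames(signatures), colnames(B)))
  degenerate <- FALSE
  for (j in seq_len(ncol(B))) {
    if (all(B[, j] == 0)) {
      out[, j] <- rep(1 / C, C)
      degenerate <- TRUE
      next
    }
    w <- pracma::lsqnonneg(signatures, B[, j])$x
    s <- sum(w)
    if (s <= 0) {
      out[, j] <- rep(1 / C, C)
      degenerate <- TRUE
    } else out[, j] <- w / s
  }
  if (degenerate)
    warning("degenerate sample column(s): uniform fractions assigned")
  out
}

#' Published contingency tables of clinical features by Macro group
#'
#' The cross-tabulations of gender, histology, WHO grade and transcriptome
#' subtype against the Macro1/2/3 groups for the TCGA, Rembrandt and CGGA693
#' cohorts, as printed in the source study. Histology and WHO-grade tables
#' compare Macro2 vs Macro3 only (Macro1 is 100% glioblastoma / WHO IV by
#' construction); gender and subtype tables span all three groups.
#'
#' @return named list of integer matrices with row/column labels.
#' @export
table1Fixtures <- function() {
  f <- function(v, nr, rn, cn)
    matrix(as.integer(v), nrow = nr, byrow = TRUE, dimnames = list(rn, cn))
  m23 <- c("Macro2", "Macro3")
  m123 <- c("Macro1", "Macro2", "Macro3")
  list(
    tcga_gender = f(c(88, 85, 98, 44, 66, 73), 2, c("Male", "Female"), m123),
    tcga_histology = f(c(61, 44, 33, 55, 42, 58), 3,
                       c("Astrocytoma", "Oligoastrocytoma", "Oligodendroglioma"), m23),
    tcga_who = f(c(47, 93, 89, 64), 2, c("WHO II", "WHO III"), m23),
    tcga_subtype = f(c(40, 21, 2, 6, 12, 58, 16, 49, 70, 57, 20, 2), 4,
                     c("Classic", "Neural", "Proneural", "Mesenchymal"), m123),
    rembrandt_gender = f(c(62, 36, 41, 37, 12, 32), 2, c("Male", "Female"), m123),
    rembrandt_histology = f(c(23, 12, 12, 31, 2, 1), 3,
                            c("Astrocytoma", "Oligodendroglioma", "Mixed"), m23),
    rembrandt_who = f(c(23, 46, 30, 22), 2, c("WHO II", "WHO III"), m23),
    cgga_gender = f(c(58, 64, 21, 36, 42, 15), 2, c("Male", "Female"), m123),
    cgga_histology = f(c(34, 10, 53, 12, 4, 1, 13, 12, 2, 1), 5,
                       c("Astrocytoma", "Anaplastic astrocytoma",
                         "Oligodendroglioma", "Anaplastic oligodendroglioma",
                         "Anaplastic oligoastrocytoma"), m23),
    cgga_who = f(c(38, 11, 68, 25), 2, c("WHO II", "WHO III"), m23)
  )
}
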