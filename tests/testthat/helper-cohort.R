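# Shared fixtures, built in code. The default synthetic cohort is expensive
# enough to build once and reuse across test files.

.cohortCache <- new.env(parent = emptyenv())

cachedCohort <- function(name = "default", ...) {
  if (is.null(.cohortCache[[name]])) {
    .cohortCache[[name]] <- simulateCohort(simulationConfig(...))
  }
  .cohortCache[[name]]
}

defaultCohort <- function() cachedCohort("default", seed = 101)

# small expression toy with known values
toyExpr <- function(nGenes = 6, nSamples = 4, seed = 5) {
  set.seed(seed)
  m <- matrix(round(runif(nGenes * nSamples, 0, 100), 2), nGenes, nSamples,
              dimnames = list(paste0("g", seq_len(nGenes)),
                              paste0("s", seq_len(nSamples))))
  m
}

# two archetype profiles with opposite shapes, well separated under a
# 1 - Pearson dissimilarity
separatedProfiles <- function(nPerGroup = 20, nFeatures = 5, noise = 0.3,
                              seed = 3) {
  set.seed(seed)
  p1 <- seq(1, 5, length.out = nFeatures)
  p2 <- rev(p1)
  X <- rbind(
    matrix(p1, nPerGroup, nFeatures, byrow = TRUE),
    matrix(p2, nPerGroup, nFeatures, byrow = TRUE)
  ) + matrix(rnorm(2 * nPerGroup * nFeatures, 0, noise), 2 * nPerGroup)
  rownames(X) <- sprintf("p%03d", seq_len(2 * nPerGroup))
  list(X = X, labels = rep(1:2, each = nPerGroup))
}
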