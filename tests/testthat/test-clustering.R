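test_that("fraction filtering applies the p-value and zero-fraction rules", {
  fr <- matrix(0.1, 5, 10, dimnames = list(paste0("ct", 1:5), paste0("s", 1:10)))
  fr["ct2", 1:6] <- 0   # zero in 6/10 -> dropped
  fr["ct3", 1:5] <- 0   # zero in exactly 5/10 -> kept (strict >)
  out <- filterFractionMatrix(fr)
  expect_false("ct2" %in% rownames(out))
  expect_true("ct3" %in% rownames(out))

  pv <- setNames(c(0.01, 0.2, rep(0.01, 8)), colnames(fr))
  out2 <- filterFractionMatrix(fr, pvals = pv)
  expect_false("s2" %in% colnames(out2))
  expect_identical(attr(out2, "droppedSamples"), "s2")

  # brute-force enumeration of the rule on a random toy
  set.seed(8)
  toy <- matrix(rbinom(100, 1, 0.5) * runif(100), 5, 20,
                dimnames = list(paste0("c", 1:5), paste0("s", 1:20)))
  keepExpected <- rownames(toy)[rowSums(toy == 0) <= 10]
  expect_identical(rownames(filterFractionMatrix(toy)), keepExpected)

  expect_error(filterFractionMatrix(matrix(0, 2, 4,
                                           dimnames = list(c("a", "b"), 1:4))),
               "all cell types")
})

test_that("PAC counts strictly-intermediate off-diagonal entries", {
  M01 <- rbind(cbind(matrix(1, 3, 3), matrix(0, 3, 3)),
               cbind(matrix(0, 3, 3), matrix(1, 3, 3)))
  expect_equal(computePac(M01), 0)

  Mhalf <- matrix(0.5, 4, 4); diag(Mhalf) <- 1
  expect_equal(computePac(Mhalf), 1)

  set.seed(2)
  R <- matrix(runif(36), 6); R <- (R + t(R)) / 2; diag(R) <- 1
  off <- R[upper.tri(R)]
  expect_equal(computePac(R, 0.1, 0.9), sum(off > 0.1 & off < 0.9) / 15)

  expect_error(computePac(matrix(runif(9), 3)), "symmetric")
  expect_error(computePac(Mhalf, 0.9, 0.1), "u1 < u2")
})

test_that("PAC is monotone under added ambiguity and selectK breaks ties low", {
  M01 <- rbind(cbind(matrix(1, 5, 5), matrix(0, 5, 5)),
               cbind(matrix(0, 5, 5), matrix(1, 5, 5)))
  pacs <- vapply(c(0, 0.15, 0.3, 0.45), function(eps) {
    M <- M01 * (1 - 2 * eps) + eps  # pulls all entries toward 0.5
    diag(M) <- 1
    computePac(M)
  }, numeric(1))
  expect_true(all(diff(pacs) >= 0))

  expect_identical(selectK(c(`2` = 0.05, `3` = 0.2)), 2L)
  expect_identical(selectK(c(`3` = 0.1, `2` = 0.1)), 2L)
  expect_identical(selectK(c(`2` = 0.3, `4` = 0.01, `3` = 0.2)), 4L)
})

test_that("silhouette widths match the brute-force formula", {
  set.seed(4)
  X <- matrix(rnorm(16), 8)
  D <- as.matrix(dist(X))
  rownames(D) <- colnames(D) <- paste0("s", 1:8)
  asg <- setNames(c(1, 1, 1, 2, 2, 2, 3, 3), rownames(D))
  s <- silhouetteWidths(D, asg)
  # independent oracle: cluster::silhouette
  sil <- cluster::silhouette(asg, dmatrix = D)
  expect_equal(unname(s), unname(sil[, "sil_width"]), tolerance = 1e-12)

  # two tight, far-apart pairs
  D2 <- as.matrix(dist(c(0, 0.01, 10, 10.01)))
  rownames(D2) <- colnames(D2) <- paste0("x", 1:4)
  s2 <- silhouetteWidths(D2, setNames(c(1, 1, 2, 2), rownames(D2)))
  expect_true(all(s2 > 0.9))

  # equidistant point has s = 0; singleton clusters get s = 0
  D3 <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3,
               dimnames = list(paste0("y", 1:3), paste0("y", 1:3)))
  s3 <- silhouetteWidths(D3, setNames(c(1, 1, 2), rownames(D3)))
  expect_equal(unname(s3[3]), 0)

  expect_error(silhouetteWidths(D3, setNames(c(1, 1, 1), rownames(D3))),
               "2 clusters")
})

test_that("core-sample selection keeps the ceiling count with deterministic ties", {
  sil <- setNames(c(0.9, 0.8, 0.7, 0.6), paste0("s", 1:4))
  asg <- setNames(rep(1L, 4), names(sil))
  # a second cluster so the input is well-formed
  sil <- c(sil, s5 = 0.5); asg <- c(asg, s5 = 2L)
  core <- selectCoreSamples(sil, asg, keepFrac = 0.75)
  expect_identical(names(core)[core], c(paste0("s", 1:3), "s5"))

  # singleton cluster keeps its sample (ceiling of 0.75)
  expect_true(core[["s5"]])

  # 8 tied widths: exactly 6 kept, lowest sample ids win
  silT <- setNames(rep(0.5, 8), sprintf("t%02d", 8:1))
  asgT <- setNames(rep(1L, 8), names(silT))
  silT <- c(silT, u1 = 0.1); asgT <- c(asgT, u1 = 2L)
  coreT <- selectCoreSamples(silT, asgT, keepFrac = 0.75)
  kept <- sort(names(coreT)[coreT & names(coreT) != "u1"])
  expect_identical(kept, sprintf("t%02d", 1:6))
})

test_that("consensus clustering separates two archetypes and respects degenerate resampling", {
  sep <- separatedProfiles(nPerGroup = 20)
  res <- consensusCluster(sep$X, kRange = 2:4, nResample = 60, seed = 5)
  expect_identical(chosenK(res), 2L)
  M <- consensusMatrix(res, 2)
  expect_true(mean(M %in% c(0, 1)) > 0.9 ||
                computePac(M) < 0.05)
  asg <- clusterAssignments(res)
  agreement <- max(mean(asg == sep$labels), mean(asg == 3 - sep$labels))
  expect_equal(agreement, 1)

  # single full-sample resample: M is the 0/1 block matrix of one PAM run
  res1 <- consensusCluster(sep$X, kRange = 2, nResample = 1,
                           subsampleFrac = 1, seed = 1)
  expect_true(all(consensusMatrix(res1, 2) %in% c(0, 1)))

  # constant profiles are rejected by name
  Xc <- sep$X; Xc[3, ] <- 2
  expect_error(consensusCluster(Xc, kRange = 2, nResample = 5, seed = 1),
               "p003")
})

test_that("consensus matrix is invariant to per-sample affine feature transforms", {
  sep <- separatedProfiles(nPerGroup = 12, seed = 11)
  res <- consensusCluster(sep$X, kRange = 2:3, nResample = 40, seed = 9)
  Xs <- sweep(sweep(sep$X, 1, runif(nrow(sep$X), 0.5, 2), "*"),
              1, runif(nrow(sep$X), -3, 3), "+")
  res2 <- consensusCluster(Xs, kRange = 2:3, nResample = 40, seed = 9)
  expect_equal(consensusMatrix(res, 2), consensusMatrix(res2, 2))
})

test_that("Macro groups cross cluster orientation with histology", {
  m2 <- setNames(c(0.6, 0.62, 0.58, 0.55, 0.5, 0.1), paste0("s", 1:6))
  asg <- setNames(c(1L, 1L, 1L, 1L, 1L, 2L), names(m2))
  core <- setNames(rep(TRUE, 6), names(m2))
  clin <- data.frame(sample_id = names(m2),
                     histology = c("GBM", "GBM", "GBM", "LGG", "LGG", "LGG"))
  mg <- assignMacroGroups(asg, core, clin, m2)
  expect_identical(as.integer(table(groupLabels(mg))[c("Macro1", "Macro2",
                                                       "Macro3")]),
                   c(3L, 2L, 1L))
  expect_identical(cluster1Id(mg), 1L)

  # orientation flips with the M2 means
  m2r <- setNames(c(0.1, 0.12, 0.08, 0.05, 0.5, 0.6), names(m2))
  mgr <- assignMacroGroups(asg, core, clin, m2r)
  expect_identical(cluster1Id(mgr), 2L)

  # undecidable orientation errors out
  m2eq <- setNames(c(rep(0.3, 6)), names(m2))
  expect_error(assignMacroGroups(asg, core, clin, m2eq), "orientation")

  expect_error(assignMacroGroups(setNames(rep(1L, 6), names(m2)), core, clin, m2),
               "2 clusters")
})

test_that("GBM samples in the low-M2 cluster stay unassigned", {
  m2 <- setNames(c(0.7, 0.6, 0.1, 0.15), paste0("s", 1:4))
  asg <- setNames(c(1L, 1L, 2L, 2L), names(m2))
  core <- setNames(rep(TRUE, 4), names(m2))
  clin <- data.frame(sample_id = names(m2),
                     histology = c("GBM", "LGG", "GBM", "LGG"))
  mg <- assignMacroGroups(asg, core, clin, m2)
  expect_identical(unassignedSamples(mg), "s3")
  expect_false("s3" %in% names(groupLabels(mg)))
})
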