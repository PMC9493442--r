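# independent running-sum oracle used against prerankedGsea
bruteES <- function(absMetric, pos, weightP = 0) {
  N <- length(absMetric)
  w <- absMetric^weightP
  inc <- numeric(N); inc[pos] <- w[pos] / sum(w[pos])
  dec <- rep(1 / (N - length(pos)), N); dec[pos] <- 0
  rs <- cumsum(inc - dec)
  rs[which.max(abs(rs))]
}

test_that("ssGSEA matches the hand-computed running sum on a 6-gene toy", {
  expr <- matrix(c(64, 32, 16, 8, 4, 2), 6,
                 dimnames = list(paste0("g", 1:6), "s1"))
  sets <- list(S = c("g1", "g4"))
  got <- ssgseaScore(expr, sets, alpha = 0.25, normalize = FALSE)
  # by hand: walking g1..g6, in-set weights rank^0.25 at ranks 6 and 3,
  # out-set ECDF steps of 1/4; the position sums collapse to 3*w1/(w1+w4)
  expected <- 3 * 6^0.25 / (6^0.25 + 3^0.25)
  expect_equal(got["S", "s1"], expected, tolerance = 1e-12)
})

test_that("ssGSEA ranks sets by where their genes sit in the expression profile", {
  set.seed(12)
  expr <- matrix(runif(10, 1, 100), 10,
                 dimnames = list(paste0("g", 1:10), "s1"))
  ord <- rownames(expr)[order(-expr[, 1])]
  sc <- ssgseaScore(expr, list(top = ord[1:3], bottom = ord[8:10]),
                    normalize = FALSE)
  expect_gt(sc["top", 1], sc["bottom", 1])
})

test_that("ssGSEA is rank-based: monotone transforms and identical columns", {
  expr <- toyExpr(nGenes = 20, nSamples = 3, seed = 7) + 1
  expr <- cbind(expr, s4 = expr[, 2])  # duplicate column
  sets <- list(A = paste0("g", 1:5), B = paste0("g", c(4, 9, 15, 20)))
  sc <- ssgseaScore(expr, sets, normalize = FALSE)
  expect_equal(sc[, "s2"], sc[, "s4"])
  sc2 <- ssgseaScore(expr^2, sets, normalize = FALSE)  # strictly monotone
  expect_equal(sc, sc2)
})

test_that("undersized sets are skipped with a warning and all-skipped errors", {
  expr <- toyExpr(nGenes = 8, seed = 3)
  expect_warning(sc <- ssgseaScore(expr, list(ok = c("g1", "g2"),
                                              tiny = "g3")),
                 "skipped")
  expect_identical(rownames(sc), "ok")
  expect_error(suppressWarnings(ssgseaScore(expr, list(tiny = "g1"))),
               "no scorable")
})

test_that("ranked lists order genes by rho or logFC with deterministic ties", {
  set.seed(15)
  expr <- matrix(rnorm(20 * 10, 10, 2), 20, 10,
                 dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:10)))
  target <- setNames(as.numeric(expr[5, ]), colnames(expr))
  rl <- buildRankedList(expr, target = target, metricKind = "spearman_rho")
  expect_identical(rl$gene[1], "g05")
  expect_equal(rl$metric[1], 1)
  # independent rho computation
  oracle <- apply(expr, 1, function(g) cor(g, target, method = "spearman"))
  expect_equal(rl$metric, unname(sort(oracle, decreasing = TRUE)),
               tolerance = 1e-12)
  expect_false(is.unsorted(rev(rl$metric)))

  g <- setNames(rep(c("high", "low"), each = 5), colnames(expr))
  exprSame <- expr; exprSame[, 6:10] <- expr[, 1:5]
  rlf <- buildRankedList(exprSame, groups = g, metricKind = "logFC")
  expect_true(all(rlf$metric == 0))
  expect_identical(rlf$gene, sort(rlf$gene))  # tie-break by gene id

  expect_error(buildRankedList(expr, target = rep(1, 10) ,
                               metricKind = "spearman_rho"),
               "zero-variance")
})

test_that("preranked ES hits the analytic extremes for singleton sets", {
  rl <- data.frame(gene = sprintf("g%02d", 1:10),
                   metric = seq(5, -4, length.out = 10))
  top <- prerankedGsea(rl, list(S = "g01"), weightP = 0, nPerm = 100,
                       minSize = 1, seed = 2)
  expect_equal(top$es, 1)
  bottom <- prerankedGsea(rl, list(S = "g10"), weightP = 0, nPerm = 100,
                          minSize = 1, seed = 2)
  expect_equal(bottom$es, -1)
  expect_equal(bottom$es, bruteES(abs(rl$metric), 10, 0))
})

test_that("exact preranked p equals exhaustive placement enumeration", {
  set.seed(33)
  rl <- data.frame(gene = sprintf("g%02d", 1:12),
                   metric = sort(rnorm(12, 0, 2), decreasing = TRUE))
  sets <- list(S = c("g01", "g03", "g07"))
  got <- prerankedGsea(rl, sets, weightP = 1, exact = TRUE, minSize = 2,
                       seed = 1)
  # oracle: all C(12,3) placements
  absM <- abs(rl$metric)
  esAll <- apply(combn(12, 3), 2, function(p) bruteES(absM, p, 1))
  esObs <- bruteES(absM, c(1, 3, 7), 1)
  pOracle <- if (esObs >= 0) mean(esAll >= esObs - 1e-12) else
    mean(esAll <= esObs + 1e-12)
  expect_equal(got$es, esObs, tolerance = 1e-12)
  expect_equal(got$p, pOracle, tolerance = 1e-12)
})

test_that("weighted ES agrees with the fgsea statistic", {
  set.seed(44)
  metric <- sort(rnorm(50, 0, 1.5), decreasing = TRUE)
  rl <- data.frame(gene = sprintf("g%02d", 1:50), metric = metric)
  pos <- c(2, 9, 17, 30, 44)
  got <- prerankedGsea(rl, list(S = rl$gene[pos]), weightP = 1, nPerm = 100,
                       seed = 3)
  oracle <- fgsea::calcGseaStat(setNames(metric, rl$gene), pos, gseaParam = 1)
  expect_equal(got$es, oracle, tolerance = 1e-9)
})

test_that("preranked invariants: ES bounds at weight 0, p floor, guards", {
  set.seed(55)
  rl <- data.frame(gene = sprintf("g%02d", 1:30),
                   metric = sort(rnorm(30), decreasing = TRUE))
  for (i in 1:10) {
    pos <- sort(sample(30, 6))
    es <- bruteES(abs(rl$metric), pos, 0)
    expect_true(es >= -1 && es <= 1)
  }
  res <- prerankedGsea(rl, list(S = rl$gene[c(1, 4, 6, 9, 12)]),
                       weightP = 0, nPerm = 100, seed = 6)
  expect_gte(res$p, 1 / 101)
  expect_lte(res$p, 1)
  expect_identical(sign(res$nes), sign(res$es))

  expect_error(prerankedGsea(rl, list(all = rl$gene), nPerm = 100,
                             maxSize = Inf, seed = 1),
               "entire list")
  expect_error(prerankedGsea(rl, list(S = rl$gene[1:5]), nPerm = 10),
               "nPerm")
})

test_that("a planted pathway outscores random sets in M2 association", {
  co <- defaultCohort()
  sets <- co$geneSets[c("PLANTED_PATHWAY", sprintf("RANDOM_%02d", 1:10))]
  sc <- suppressMessages(ssgseaScore(co$expr, sets))
  m2 <- co$truth$m2Fraction
  slope <- apply(sc, 1, function(s) coef(lm(s ~ m2))[["m2"]])
  expect_gt(slope[["PLANTED_PATHWAY"]],
            median(abs(slope[sprintf("RANDOM_%02d", 1:10)])))
})
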