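test_that("VIF reduction keeps orthogonal predictors and drops duplicates", {
  set.seed(20)
  X <- qr.Q(qr(matrix(rnorm(100 * 4), 100)))  # orthonormal columns
  colnames(X) <- paste0("p", 1:4)
  kept <- vifReduce(X)
  expect_setequal(as.character(kept), colnames(X))
  expect_true(all(attr(kept, "vif") < 1.2))  # near 1 up to sampling noise

  Xd <- cbind(X, p5 = X[, "p2"])
  kept2 <- vifReduce(Xd)
  expect_identical(attr(kept2, "dropped"), "p5")  # later-named copy goes
  expect_length(kept2, 4)
})

test_that("VIF values match the 1/(1 - R^2) brute force on correlated predictors", {
  set.seed(21)
  n <- 500
  z <- rnorm(n)
  X <- cbind(a = z + rnorm(n, 0, sqrt(1 - 0.9^2)) * 0,
             b = rnorm(n), c = rnorm(n))
  X[, "a"] <- 0.9 * scale(z) + sqrt(1 - 0.81) * scale(rnorm(n))
  X[, "b"] <- 0.9 * scale(z) + sqrt(1 - 0.81) * scale(rnorm(n))
  kept <- vifReduce(X, threshold = 50)
  vif <- attr(kept, "vif")
  for (j in colnames(X)) {
    r2 <- summary(lm(X[, j] ~ X[, setdiff(colnames(X), j)]))$r.squared
    expect_equal(unname(vif[j]), 1 / (1 - r2), tolerance = 1e-8)
  }
  # post-hoc invariant: nothing kept above threshold
  kept5 <- vifReduce(X, threshold = 5)
  expect_true(all(attr(kept5, "vif") < 5))
})

test_that("M2 regression recovers an identity response and its p-values are calibrated", {
  set.seed(22)
  n <- 200
  X <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("f", 1:4)))
  m2 <- X[, "f2"]
  fit <- suppressWarnings(fitM2Regression(m2, X, "algoA"))
  expect_equal(fit$beta[fit$feature == "f2"], 1, tolerance = 1e-10)
  expect_lt(fit$p[fit$feature == "f2"], 1e-6)

  # type-I calibration under a global null
  set.seed(23)
  ps <- replicate(300, {
    fitM2Regression(rnorm(50), matrix(rnorm(50 * 3), 50,
                                      dimnames = list(NULL, paste0("f", 1:3))))$p
  })
  rate <- mean(ps < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / length(ps)))
})

test_that("sign-consensus verdicts follow the two-of-three same-sign rule", {
  mk <- function(beta, p, tag) data.frame(feature = "f", beta = beta, p = p,
                                          algorithm = tag)
  expect_identical(consensusSignificance(list(
    mk(1, 0.01, "a"), mk(2, 0.02, "b"), mk(0.5, 0.4, "c")))$verdict, "positive")
  expect_identical(consensusSignificance(list(
    mk(1, 0.01, "a"), mk(-2, 0.02, "b"), mk(0.5, 0.4, "c")))$verdict, "none")
  expect_identical(consensusSignificance(list(
    mk(-1, 0.01, "a"), mk(-2, 0.02, "b"), mk(-0.5, 0.01, "c")))$verdict,
    "negative")
  expect_identical(consensusSignificance(list(
    mk(1, 0.01, "a"), mk(2, 0.2, "b"), mk(0.5, 0.4, "c")))$verdict, "none")
})

test_that("logistic alteration fits flag separation and behave under the null", {
  set.seed(24)
  m2 <- runif(200)
  altNull <- rbinom(200, 1, 0.4)
  fit <- fitAlterationLogistic(setNames(altNull, NULL), m2)
  expect_lt(abs(fit$beta), 0.5)
  expect_false(fit$separation)

  altSep <- as.integer(m2 > median(m2))
  fitSep <- fitAlterationLogistic(altSep, m2)
  expect_true(fitSep$separation)
  expect_true(is.na(fitSep$p))

  expect_error(fitAlterationLogistic(rep(1L, 200), m2), "classes")
})

test_that("exact r x c Fisher p-values agree with a Monte-Carlo permutation oracle", {
  # oracle: permute category labels, count tables as or less probable
  mcFisher <- function(tab, B = 40000) {
    rlab <- rep(seq_len(nrow(tab)), rowSums(tab))
    clab <- rep(seq_len(ncol(tab)), colSums(tab))
    logp <- function(t) sum(lfactorial(rowSums(t))) + sum(lfactorial(colSums(t))) -
      lfactorial(sum(t)) - sum(lfactorial(t))
    obs <- logp(tab)
    hits <- 0L
    for (b in seq_len(B)) {
      t2 <- table(factor(rlab, seq_len(nrow(tab))),
                  factor(sample(clab), seq_len(ncol(tab))))
      if (logp(t2) <= obs + 1e-7) hits <- hits + 1L
    }
    hits / B
  }
  set.seed(25)
  tab <- matrix(c(5, 2, 3, 1, 6, 4), 3, 2)
  got <- fisherExactRxC(tab)
  expect_identical(got$method, "exact")
  pMc <- mcFisher(tab)
  se <- sqrt(pMc * (1 - pMc) / 40000)
  expect_lt(abs(got$p - pMc), 3 * se)
})

test_that("Fisher p is invariant to transposition and row/column permutation", {
  set.seed(26)
  for (i in 1:5) {
    tab <- matrix(rpois(6, 8) + 1, 2, 3)
    p0 <- fisherExactRxC(tab)$p
    expect_equal(fisherExactRxC(t(tab))$p, p0, tolerance = 1e-9)
    expect_equal(fisherExactRxC(tab[, sample(3)])$p, p0, tolerance = 1e-9)
    expect_equal(fisherExactRxC(tab[2:1, ])$p, p0, tolerance = 1e-9)
  }
  expect_equal(fisherExactRxC(matrix(5, 2, 2))$p, 1)
  expect_error(fisherExactRxC(matrix(c(0, 0, 1, 2), 2)), "margin")
})

test_that("2x2 Fisher matches the sum-of-probabilities definition on random tables", {
  # independent oracle: enumerate all tables with the observed margins
  twoByTwo <- function(tab) {
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    xs <- max(0, k - n):min(k, m)
    probs <- dhyper(xs, m, n, k)
    sum(probs[probs <= dhyper(tab[1, 1], m, n, k) * (1 + 1e-7)])
  }
  set.seed(27)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 6) + 1, 2)
    expect_equal(fisherExactRxC(tab)$p, twoByTwo(tab), tolerance = 1e-9)
  }
})

test_that("Wilcoxon rank-sum: exact enumeration, ties, and monotonicity", {
  res <- wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))
  expect_identical(res$method, "exact")
  expect_equal(res$p, 0.1)  # 2 / C(6,3) two-sided

  resT <- wilcoxonRankSum(c(1, 1, 2, 3), c(1, 2, 2, 3))
  expect_identical(resT$method, "normal-approximation")
  expect_gt(resT$p, 0.5)

  set.seed(28)
  base <- rnorm(60)
  ps <- vapply(c(0.2, 0.6, 1.2), function(d)
    wilcoxonRankSum(base, rnorm(60, d))$p, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("Spearman rho matches Pearson on midranks, including ties", {
  expect_equal(spearmanCor(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearmanCor(1:10, -(1:10)^2)$rho, -1)

  x <- c(1, 2, 2, 3, 5, 5, 7)
  y <- c(2, 1, 4, 4, 6, 8, 8)
  got <- spearmanCor(x, y)
  oracle <- cor(rank(x), rank(y))  # Pearson on midranks
  expect_equal(got$rho, oracle, tolerance = 1e-12)
  expect_equal(got$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
  # t-approximation p
  tv <- oracle * sqrt((7 - 2) / (1 - oracle^2))
  expect_equal(got$p, 2 * pt(-abs(tv), 5), tolerance = 1e-12)
})

test_that("consensus under a global null calls almost nothing", {
  set.seed(29)
  nRep <- 334  # x3 features per replicate ~ 1000 feature-level draws
  verdicts <- replicate(nRep, {
    X <- matrix(rnorm(60 * 3), 60, dimnames = list(NULL, paste0("f", 1:3)))
    reports <- lapply(c("a", "b", "c"), function(tag)
      fitM2Regression(rnorm(60), X, tag))
    consensusSignificance(reports)$verdict
  })
  rate <- mean(verdicts != "none")
  expect_lt(rate, 0.01)
})

test_that("consensus recovers planted effects across three noisy fraction views", {
  set.seed(30)
  n <- 150
  nFeat <- 20
  truth <- c(rep(0.8, 5), rep(-0.8, 5), rep(0, 10))
  X <- matrix(rnorm(n * nFeat), n, dimnames = list(NULL, sprintf("f%02d", 1:nFeat)))
  m2true <- as.vector(X %*% truth) + rnorm(n, 0, 1)
  reports <- lapply(c("a", "b", "c"), function(tag)
    fitM2Regression(m2true + rnorm(n, 0, 0.3), X, tag))
  cons <- consensusSignificance(reports)
  called <- cons$verdict != "none"
  isTrue <- truth != 0
  sens <- sum(called & isTrue) / sum(isTrue)
  fdr <- if (any(called)) sum(called & !isTrue) / sum(called) else 0
  expect_gte(sens, 0.9)
  expect_lt(fdr, 0.1)
  # signs agree with the planted direction
  expect_true(all(cons$verdict[truth > 0 & called] == "positive"))
  expect_true(all(cons$verdict[truth < 0 & called] == "negative"))
})
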