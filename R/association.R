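## The regression-consensus framework tying pathway scores, gene expression
## and somatic alterations to the M2 macrophage fraction, plus the shared
## statistics kernel (exact r x c Fisher test, Wilcoxon rank-sum, Spearman).
## The consensus rule: a feature is called only when two or more fraction
## algorithms give a significant coefficient of the same sign and no
## algorithm is significant with the opposite sign.

#' Backward elimination by variance inflation factor
#'
#' Iteratively computes `VIF_j = 1 / (1 - R^2_j)` from regressing predictor
#' j on all the others and drops the largest-VIF predictor until every VIF
#' is below `threshold`. Perfectly collinear predictors get infinite VIF;
#' ties at the maximum are broken by dropping the lexicographically last
#' predictor name, so a duplicated column loses its later-named copy.
#'
#' @param X samples x predictors numeric matrix with column names.
#' @param threshold VIF cutoff.
#' @return character vector of kept predictor names, with attribute
#'   `dropped` (in drop order) and `vif` (final VIFs).
#' @export
vifReduce <- function(X, threshold = 5) {
  if (is.null(colnames(X))) stop("predictors must be named")
  if (ncol(X) < 2) stop("need at least 2 predictors")
  kept <- colnames(X)
  dropped <- character()
  vifOne <- function(j, cols) {
    y <- X[, j]
    Z <- X[, setdiff(cols, j), drop = FALSE]
    fit <- stats::lm.fit(cbind(1, Z), y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  repeat {
    if (length(kept) < 2) break
    vifs <- vapply(kept, vifOne, numeric(1), cols = kept)
    if (all(vifs < threshold)) break
    worst <- kept[vifs == max(vifs)]
    drop <- sort(worst)[length(worst)]
    dropped <- c(dropped, drop)
    kept <- setdiff(kept, drop)
  }
  vifs <- if (length(kept) >= 2) vapply(kept, vifOne, numeric(1), cols = kept)
          else stats::setNames(rep(1, length(kept)), kept)
  structure(kept, dropped = dropped, vif = vifs)
}

#' Multivariate regression of the M2 fraction on a feature block
#'
#' Ordinary least squares of the per-sample M2 fraction on all predictors
#' jointly (plus intercept), with two-sided t-test p-values per coefficient.
#' Predictors are expected to have passed [vifReduce()] first.
#'
#' @param m2 per-sample M2 fraction (named or in `X` row order).
#' @param X samples x predictors matrix.
#' @param algorithmTag label for the fraction algorithm this fit belongs to.
#' @return data.frame: `feature`, `beta`, `p`, `algorithm`.
#' @export
fitM2Regression <- function(m2, X, algorithmTag = "algo") {
  if (!is.null(names(m2)) && !is.null(rownames(X))) m2 <- m2[rownames(X)]
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1) stop("need more samples than predictors plus intercept")
  fit <- stats::lm(m2 ~ ., data = as.data.frame(X, check.names = FALSE))
  if (any(is.na(stats::coef(fit))))
    stop("singular design matrix; run vifReduce first")
  sm <- summary(fit)$coefficients
  sm <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
  ## lm backticks non-syntactic names
  feat <- gsub("^`|`$", "", rownames(sm))
  data.frame(feature = feat, beta = sm[, "Estimate"], p = sm[, "Pr(>|t|)"],
             algorithm = algorithmTag, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Sign-consensus significance across fraction algorithms
#'
#' A feature is `positive` when at least `minAgree` algorithms have
#' `p < alpha` with a positive coefficient and no algorithm is significant
#' with a negative one (and mirrored for `negative`); everything else is
#' `none`.
#'
#' @param reports list of (or a single row-bound) data.frame(s) from
#'   [fitM2Regression()] / [fitAlterationLogistic()], covering >= 2
#'   algorithms.
#' @param alpha significance level per algorithm.
#' @param minAgree minimum number of same-sign significant algorithms.
#' @return data.frame: `feature`, `nPositive`, `nNegative`, `verdict`.
#' @export
consensusSignificance <- function(reports, alpha = 0.05, minAgree = 2) {
  rep <- if (is.data.frame(reports)) reports else do.call(rbind, reports)
  feats <- unique(rep$feature)
  out <- data.frame(feature = feats, nPositive = 0L, nNegative = 0L,
                    verdict = "none", stringsAsFactors = FALSE)
  for (i in seq_along(feats)) {
    r <- rep[rep$feature == feats[i], ]
    sig <- !is.na(r$p) & r$p < alpha
    np <- sum(sig & r$beta > 0)
    nn <- sum(sig & r$beta < 0)
    out$nPositive[i] <- np
    out$nNegative[i] <- nn
    if (np >= minAgree && nn == 0) out$verdict[i] <- "positive"
    else if (nn >= minAgree && np == 0) out$verdict[i] <- "negative"
  }
  out
}

#' Logistic association of binary alterations with the M2 fraction
#'
#' Per alteration feature, fits `alteration ~ z(m2)` by logistic regression
#' with the alteration indicator as response and the standardized M2
#' fraction as sole predictor, reporting the Wald p. Complete or
#' quasi-complete separation is flagged and the p set to NA.
#'
#' @param alt features x samples 0/1 matrix (or a single 0/1 vector).
#' @param m2 per-sample M2 fraction.
#' @param algorithmTag label for the fraction algorithm.
#' @param minClass minimum samples in each alteration class.
#' @return data.frame: `feature`, `beta`, `p`, `separation`, `algorithm`.
#' @export
fitAlterationLogistic <- function(alt, m2, algorithmTag = "algo",
                                  minClass = 3) {
  if (is.null(dim(alt))) alt <- matrix(alt, nrow = 1,
                                       dimnames = list("feature",
                                                       names(alt)))
  if (!is.null(colnames(alt)) && !is.null(names(m2))) m2 <- m2[colnames(alt)]
  z <- as.vector(scale(m2))
  fitOne <- function(y) {
    if (min(sum(y == 0), sum(y == 1)) < minClass)
      stop("both alteration classes need >= ", minClass, " samples")
    fit <- suppressWarnings(stats::glm(y ~ z, family = stats::binomial()))
    sep <- !fit$converged || any(abs(stats::coef(fit)) > 15) ||
      any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8)
    sm <- summary(fit)$coefficients
    c(beta = sm["z", "Estimate"],
      p = if (sep) NA_real_ else sm["z", "Pr(>|z|)"],
      separation = as.numeric(sep))
  }
  stats <- t(apply(alt, 1, fitOne))
  data.frame(feature = rownames(alt), beta = stats[, "beta"],
             p = stats[, "p"], separation = stats[, "separation"] == 1,
             algorithm = algorithmTag, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Exact r x c Fisher test (Freeman-Halton)
#'
#' Two-sided exact test of independence on an r x c contingency table: the
#' sum of hypergeometric probabilities of all tables with the observed
#' margins whose probability does not exceed the observed one. For tables
#' whose enumeration is infeasible a seeded Monte-Carlo estimate over
#' `mcReplicates` sampled tables is used and flagged in the result.
#'
#' @param tab r x c matrix of non-negative integer counts.
#' @param workspace workspace size for the exact network algorithm.
#' @param mcReplicates Monte-Carlo sample size for the fallback.
#' @param seed seed for the Monte-Carlo fallback.
#' @return list: `p`, `method` ("exact" or "monte-carlo"), and for the
#'   fallback `se`, the binomial standard error of the estimate.
#' @export
fisherExactRxC <- function(tab, workspace = 2e6, mcReplicates = 1e6,
                           seed = 1) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("need an r x c table with r, c >= 2")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row or column margin")
  res <- tryCatch(
    stats::fisher.test(tab, workspace = workspace),
    error = function(e) NULL)
  if (!is.null(res))
    return(list(p = res$p.value, method = "exact"))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  res <- stats::fisher.test(tab, simulate.p.value = TRUE, B = mcReplicates)
  p <- res$p.value
  list(p = p, method = "monte-carlo", se = sqrt(p * (1 - p) / mcReplicates))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact null enumeration of the rank-sum when both samples are at or below
#' `exactBelowN` and tie-free; otherwise the normal approximation with tie
#' and continuity correction.
#'
#' @param x,y numeric samples.
#' @param exactBelowN exact-enumeration size threshold.
#' @return list: `statistic` (Mann-Whitney U of `x`), `p`, `method`.
#' @export
wilcoxonRankSum <- function(x, y, exactBelowN = 25) {
  useExact <- length(x) <= exactBelowN && length(y) <= exactBelowN &&
    !anyDuplicated(c(x, y))
  res <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = useExact,
                       correct = TRUE))
  list(statistic = unname(res$statistic), p = res$p.value,
       method = if (useExact) "exact" else "normal-approximation")
}

#' Spearman correlation with a t-approximation p-value
#'
#' Pearson correlation on average-ranked data; the p-value uses
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` with `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors.
#' @return list: `rho`, `p`, `n`.
#' @export
spearmanCor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  rho <- stats::cor(rank(x, ties.method = "average"),
                    rank(y, ties.method = "average"))
  if (is.na(rho)) stop("correlation undefined (constant input)")
  if (abs(rho) >= 1) return(list(rho = rho, p = 0, n = n))
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(t), df = n - 2), n = n)
}
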