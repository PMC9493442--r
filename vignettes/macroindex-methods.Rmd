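---
title: "Methods: M2 macrophage stratification and the Macro index"
author: "MacroIndex authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: M2 macrophage stratification and the Macro index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MacroIndex)
```

# Scope and model

This package implements a complete analysis chain for relating the M2
macrophage content of glioma transcriptomes to pathways, genes, somatic
alterations and clinical outcome. The central response variable throughout
is the per-sample **M2 fraction** — the estimated proportion of
alternatively activated macrophages among the modeled cell types — as
produced by one or more in-silico deconvolution algorithms. Deconvolution
itself is treated as an *input*: the external tools commonly used for it
are not reimplemented here, and `nnlsDeconvolve()` (non-negative least
squares against a cell-type signature matrix, weights renormalized to the
simplex) exists so that the synthetic benchmark has a self-contained
fraction estimator, not as a replacement for those tools.

The package's own contributions are (i) the consensus-clustering
stratification with PAC-based model selection and silhouette-based core
samples, (ii) the cross-algorithm regression consensus, (iii) the
five-gene Macro index and its rho-ROC concordance statistic, and (iv) a
ground-truth synthetic cohort that exercises all of it end to end.

# The synthetic cohort

`simulateCohort()` draws a cohort whose statistical structure matches what
the downstream analyses assume, with every latent quantity returned as
ground truth.

**Mixture model.** Each sample carries a latent archetype, M2-high or
M2-low, mixed in equal proportion by default. Cell-type fractions are
Dirichlet: concentration `(12, 2, 2, 2, 2)` for M2-high samples (mean M2
fraction 0.6, moderately concentrated) and `(1, 5, 5, 5, 5)` for M2-low
(mean 0.05, diffuse). These two regimes create the bimodal fraction
structure that a two-cluster consensus solution should recover; the
archetype separation is deliberately strong because the analyses under
test are about recovering structure, not about the detection limit. Bulk
expression is `signature matrix × fractions` on the linear scale, each
column rescaled to sum to 10^6 (the TPM convention), then perturbed by
multiplicative log-normal noise (`noiseSigma = 0.25`, a mid-range value
for bulk RNA-seq replicate variability). The signature matrix gives every
gene a shared log-normal baseline and elevates 20 marker genes per cell
type five-fold in their own type — comparable in density to the marker
panels of published reference signatures.

**Planted signal.** The five index genes are regenerated after mixing so
that `log2(TPM + 1) = a + b · f_M2 + ε` with `a = 2`, `b = 4` and
`ε ~ N(0, 0.5)`; with the M2 fraction spanning ~0.05–0.6 this yields an
index–fraction Spearman rho near 0.93, i.e. a strong but noisy marker, as
an expression-based surrogate of cell content should be. 150 up- and 150
down-regulated hit genes receive a ±1 log2-unit shift per sd of the M2
fraction, which makes them recoverable by rank-sum differential
expression at the default cohort size while leaving a realistic error
margin (a handful of the 150 are typically displaced by noise). Survival
is exponential with log hazard `0.8` per sd of the index signal under
independent uniform censoring calibrated to a 30% censoring rate (the
bound of the uniform censoring distribution is solved numerically from
the drawn event times); an exponential model with a log-linear covariate
is the simplest generative process whose Cox estimand is exact.
Alteration features are Bernoulli with log-odds slope 2 on the
standardized M2 fraction for the planted half and slope 0 for the rest.
The three fraction "algorithms" are independent log-normal perturbations
of the true fraction matrix (sd 0.15, renormalized) — the consensus rule
downstream needs three imperfect, exchangeable views, not the internals
of any particular tool.

**What the generator does not emulate.** Real glioma expression
distributions, gene–gene correlation beyond the mixture structure, batch
effects, platform differences, and single-cell droplet data. Tests passing
on this cohort therefore demonstrate correctness of the algorithms under
their stated model, not robustness to everything real cohorts do.

# Consensus clustering

`consensusCluster()` follows the resampling-consensus scheme that is
standard for immune-fraction stratification: for each candidate k
(default 2–6), samples are subsampled at 80% for `nResample` iterations
(default 1000; analyses in this package's own test and acceptance runs
use 200, which on well-separated data leaves the consensus matrix
unchanged to the third decimal), each subsample is partitioned by PAM on
`1 − Pearson`, and the consensus entry is the co-clustering count over
the co-sampling count. PAM (build + swap to convergence, as implemented
in the `cluster` package) is run once more on `1 − M_k` for the final
partition.

Numerical and convention choices:

* **PAC thresholds** `u1 = 0.1`, `u2 = 0.9` with *strict* inequalities —
  the originating convention for the proportion of ambiguous clustering.
  A perfect two-block 0/1 matrix has PAC 0, and PAC grows monotonically
  as uniform noise pulls entries into the ambiguous band.
* **k selection** is the PAC minimum with ties to the smallest k.
* **Silhouette** widths are computed on the consensus dissimilarity
  `1 − M` of the chosen k, not on the original feature distance: core
  membership should reflect the stability of a sample's assignment, which
  is exactly what the consensus matrix measures. Singleton clusters get
  width 0.
* **Core samples**: within each cluster the `ceiling(0.75 · n_c)` highest
  widths are kept; ties at the cutoff break by sample id so the selection
  is deterministic. The ceiling means a singleton cluster keeps its
  sample.
* **Degenerate input**: a constant sample profile has no defined Pearson
  correlation and is rejected by name. Negative correlations are clipped
  at distance 1 only in the sense that `1 − r` is used as-is; the
  dissimilarity may exceed 1, which PAM accepts.
* **Randomness**: one seeded stream drives all subsampling, so results
  are reproducible at fixed input order; permutation equivariance holds
  for the clustering itself but the subsample draws are tied to input
  order.

`assignMacroGroups()` orients the two clusters by mean M2 fraction
(cluster 1 = higher M2; exact ties are an error, since the orientation
would be arbitrary), then crosses orientation with histology: GBM∩cluster1
→ Macro1, LGG∩cluster1 → Macro2, LGG∩cluster2 → Macro3. GBM samples in
the low-M2 cluster do not fit the scheme and are reported separately
rather than forced into a group.

# Enrichment scoring

`ssgseaScore()` ranks genes within each sample (average ranks on ties)
and accumulates, over the descending list, the difference between the
in-set ECDF weighted by `rank^alpha` and the unweighted out-set ECDF.
`alpha = 0.25` and division of the final score matrix by its global range
follow the established single-sample GSEA convention. Being rank-based,
the scores are invariant to any strictly monotone per-sample transform,
so raw TPM is ranked directly. Genes absent from the matrix are dropped
from their sets with a reported count (the field offers no consensus on
imputing absent genes, and silently scoring partial sets without notice
would hide cohort incompatibilities); sets with fewer than 2 present
genes are skipped with a warning.

`prerankedGsea()` implements the weighted Kolmogorov–Smirnov-like
statistic: hit increments `|metric|^p` normalized over the set, miss
decrements `1/(N − |S|)`, ES the signed maximum deviation. Significance
is by gene-label permutation preserving set size, one-sided on the sign
of the observed ES, with the `(r + 1)/(n + 1)` estimator so no p-value is
ever exactly zero. When `exact = TRUE` and `choose(N, |S|)` is small the
placements are enumerated exhaustively and the p-value is the exact tail
fraction — this mode exists so the permutation machinery can be verified
against complete enumeration. NES divides ES by the mean |permuted ES| of
the same sign and the FDR q is the customary sign-stratified NES ratio.
The permutation count and weight exponent are exposed because no single
convention dominates; defaults are 1000 permutations and weight 1. A set
equal to the entire list leaves the miss decrement undefined and is an
error.

Ranked lists (`buildRankedList()`) use either the Spearman rho of each
gene with a target vector (the Macro index, typically) or the difference
of group means of `log2(TPM + 1)`; ties in the metric break by gene id so
the list order is deterministic.

# The regression consensus

The association of features (pathway scores, gene expression,
alterations) with the M2 fraction is assessed per deconvolution
algorithm and then combined by a **sign-consensus rule**: a feature is
called positive when at least two algorithms give `p < 0.05` with a
positive coefficient and no algorithm is significant with a negative one
(mirrored for negative calls). No multiple-testing correction is applied
within an algorithm — the cross-algorithm agreement requirement is the
error control, and under a global null the consensus call rate is below
1% (verified by simulation in the test suite; the analytic two-of-three
same-sign bound at α = 0.05 is ≈ 0.4%).

Collinearity among predictors is removed beforehand by **VIF backward
elimination**: repeatedly regress each predictor on the others, compute
`VIF = 1/(1 − R²)`, drop the largest until all VIFs are below 5.
Perfectly collinear predictors are treated as infinite VIF, and ties at
the maximum drop the lexicographically last name, so a duplicated column
deterministically loses its later-named copy. An AIC-driven stepwise
search could reach a similar end state, but it optimizes a different
criterion and its result depends on the model scope; direct VIF
elimination implements the stated collinearity goal reproducibly.

For binary alteration features the model is logistic with the alteration
indicator as *response* and the standardized M2 fraction as the sole
predictor. With many alteration features and one continuous fraction this
orientation needs no joint saturated model and keeps every feature's fit
independent; it estimates the same direction of association. Complete or
quasi-complete separation (detected by non-convergence, runaway
coefficients, or fitted probabilities at the boundary) is flagged and the
Wald p reported as not estimable rather than as a misleading number.

# The statistics kernel

* `fisherExactRxC()` — the Freeman–Halton exact test (sum of
  hypergeometric probabilities of all tables with the observed margins
  that are no more probable than the observed one), delegated to the
  exact network algorithm in `stats::fisher.test`; tables whose exact
  enumeration is infeasible fall back to a seeded Monte-Carlo estimate
  over 10^6 sampled tables with the binomial standard error reported.
  Zero margins are rejected. The test suite cross-checks the exact values
  against an independent Monte-Carlo permutation of category labels and
  against the sum-of-probabilities definition on 2×2 tables.
* `wilcoxonRankSum()` — exact enumeration when both groups are ≤ 25 and
  tie-free, otherwise the normal approximation with tie and continuity
  correction.
* `spearmanCor()` — Pearson on midranks with the t approximation on
  `n − 2` degrees of freedom; |rho| = 1 reports p = 0.

# The Macro index and its concordance

`computeMacroIndex()` averages `log2(TPM + 1)` over PIK3R5, PIK3R6,
ALOX5, ALOX5AP and ALOX15B. The +1 pseudocount handles zero TPM and is
the standard offset for log-transformed TPM; with it, an all-zero sample
scores exactly 0. At least 4 of the 5 genes must be present (threshold
configurable) — with fewer the index would silently change meaning, so
the function errors and names the missing genes instead of rescaling.
The same formula is applied unchanged to cell-level matrices
(single-cell preprocessing is out of scope; whatever normalized matrix
is supplied is scored as-is).

`splitByMedian()` sends values strictly above the median to "high" and
everything else to "low" — a deterministic convention; the all-equal
degenerate case warns. Differential expression between the split halves
is by Wilcoxon rank-sum with Benjamini–Hochberg adjustment; rank-sum DE
was chosen over moderated-variance linear models deliberately, to keep
the DE step assumption-light and exactly reproducible from the matrix
alone, and results are labeled accordingly. Hit signatures take the top
and bottom `n = 150` genes by log2 fold change with gene-id tie-breaks.

`signatureConcordanceAuc()` computes, per hit gene, the Spearman rho of
its expression with the index, keeps genes whose correlation is
significant at `sigAlpha = 0.05` (the significance filter reflects the
statistic's definition as concordance over *significantly* correlated
genes; a `keepAll` switch disables it, since the filter can empty a class
on null signatures — which is reported as an error naming the counts
rather than an AUC of convenience), labels positive hits 1 and negative
hits 0, and summarises by the Mann–Whitney AUC with tie correction. An
optional `samples` argument restricts the correlation to one Macro group,
for group-wise concordance. Hit genes absent from the matrix are dropped
and counted, never imputed.

# Outcome statistics

Kaplan–Meier, log-rank and Cox are delegated to the `survival` package —
`survfit` (product-limit with Greenwood variance), `survdiff` (1-df
observed-minus-expected), and `coxph` with **Efron** tie handling, the
dominant convention and the better approximation under heavy ties (the
choice is exposed). A constant covariate, or fewer than 10 events, is an
error; monotone-likelihood warnings are surfaced as a `converged = FALSE`
flag on the result.

Relapse grouping converts months at 30.44 days and years at 365.25 days.
For GBM, "early" is a progression event before 6 months and "late" a PFI
beyond 12 months, with the 6–12-month gap excluded; for LGG a single
5-year cutoff separates the groups. "Early" requires an observed event —
a sample censored at 3 months has simply not been observed long enough —
while "late" admits censored samples, whose interval already exceeds the
cutoff whatever happens afterwards.

# Pipeline and problem sizes

`runPipeline()` chains the stages through files under `outDir` (a run is
inspectable and partially re-runnable; a missing upstream artifact stops
the run naming the requirement) and writes a JSON report containing every
statistic produced, the config echo, the seed, and md5 hashes of the
written artifacts. Identical configs produce byte-identical reports.

The package's own validation runs use these problem sizes, chosen to
exercise each method well inside its asymptotic regime: the default
cohort (300 samples × 1200 genes) for clustering, index, DE, concordance
and survival properties; 200 consensus resamples; 100 samples at noise
0.2 for NNLS recovery; ~1000 feature-level null draws for the consensus
calibration; 500 simulations for Cox coverage; 100 replicates for the
null concordance AUC; and complete enumeration (C(12,3) placements) for
the preranked GSEA p-value check.

# Known limitations

* The consensus rule's error control is calibrated for exchangeable,
  independently noisy fraction estimates; strongly correlated algorithm
  errors would inflate the consensus rate.
* PAC-based k selection inherits PAC's known bias toward small k when
  clusters differ greatly in size.
* The rho-ROC significance filter couples gene inclusion to sample size;
  AUCs from cohorts of very different size are comparable only under
  `keepAll = TRUE`.
* The synthetic cohort is a model-faithfulness benchmark, not a realism
  benchmark (see above); effect sizes there are generous by design.
* Gene identifiers are treated as opaque case-sensitive symbols; no alias
  or cross-annotation mapping is attempted.
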