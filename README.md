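# MacroIndex

Tools for stratifying glioma transcriptome cohorts by tumor-associated M2
macrophage content and for scoring a five-gene leukotriene-synthesis index —
the **Macro index** — that tracks the M2 fraction and carries prognostic
information.

Tumor-associated macrophages dominate the non-tumor compartment of the
glioma microenvironment, and their alternatively activated (M2) state is
pro-tumoral. The package is aimed at computational biologists who have bulk
expression matrices (genes × samples, TPM), immune-fraction estimates from
one or more in-silico deconvolution algorithms, and clinical outcome tables,
and who want a tested, reusable implementation of the full analysis chain:

1. **Immune-fraction consensus clustering** — PAM under a
   `d(i,j) = 1 − Pearson(x_i, x_j)` dissimilarity with repeated 80%
   subsampling; the cluster number k minimises the proportion of ambiguous
   clustering, `PAC = #{ pairs with u1 < M(i,j) < u2 } / #pairs`
   (u1 = 0.1, u2 = 0.9); core samples are the top 75% of each cluster by
   silhouette width `s(i) = (b − a) / max(a, b)` on the consensus
   dissimilarity. Crossing the two clusters with histology yields the
   Macro1 (GBM, high M2), Macro2 (LGG, high M2) and Macro3 (LGG, low M2)
   groups.
2. **Regression consensus** — pathway activity by single-sample GSEA
   (rank-weighted ECDF difference, weight `rank^0.25`), predictors reduced
   to VIF < 5 by backward elimination, then the M2 fraction of *each*
   deconvolution algorithm regressed on the features jointly; a feature is
   called only when two or more algorithms agree in significant sign
   (logistic regression plays the same role for binary SNP/SCNA features).
3. **The Macro index** — per sample, the mean of `log2(TPM + 1)` over
   PIK3R5, PIK3R6, ALOX5, ALOX5AP and ALOX15B (class I PI3K-gamma
   regulatory subunits plus the lipoxygenase leukotriene-synthesis axis).
4. **rho-ROC concordance** — each hit gene of a macrophage stimulation
   signature is scored by its Spearman rho with the index; the rho values
   classify positive vs negative hits and the Mann–Whitney AUC summarises
   the concordance.
5. **Outcomes** — Kaplan–Meier, log-rank, univariate Cox (Efron ties), and
   early/late relapse groupings of the progression-free interval.

A synthetic cohort generator (`simulateCohort()`) produces
Dirichlet-mixture cohorts with known cell-type fractions, planted index
genes, 150-up/150-down hit signatures, index-dependent hazards and
logistic-linked alterations, so every stage is validated against ground
truth. Exact Freeman–Halton Fisher tests reproduce the published
contingency-table p-values bundled in `table1Fixtures()`.

## Worked example

```r
library(MacroIndex)

cfg    <- simulationConfig(nSamples = 200, seed = 42)
cohort <- simulateCohort(cfg)

fr <- filterFractionMatrix(cohort$fractions$algoA, cohort$fractions$pvals)
cc <- consensusCluster(t(fr), kRange = 2:6, nResample = 200, seed = 42)
cc
#> ConsensusResult
#>   samples: 200
#>   k tried: 2, 3, 4, 5, 6
#>   PAC: 2=0.000, 3=0.132, 4=0.123, 5=0.081, 6=0.126
#>   chosen k: 2
#>   cluster sizes: 1:93, 2:107
#>   core samples: 151 of 200
```

PAC is exactly 0 at k = 2 — every sample pair is either always or never
co-clustered — so two immune archetypes are recovered. Crossing the
clusters with histology:

```r
mg <- assignMacroGroups(clusterAssignments(cc), cc@coreFlag,
                        cohort$clinical, cohort$fractions$algoA[1, ])
mg
#> MacroGroups
#>   Macro1 (GBM, high M2): 29
#>   Macro2 (LGG, high M2): 41
#>   Macro3 (LGG, low M2):  71
#>   unassigned (GBM, low-M2 cluster): 10
```

The index recovers the latent M2 fraction, separates the planted hit
signatures perfectly, and predicts survival:

```r
idx <- computeMacroIndex(cohort$expr)
spearmanCor(idx, cohort$truth$m2Fraction)
#> Spearman rho(Macro index, true M2 fraction) = 0.908 (p = 5.93e-77)

signatureConcordanceAuc(cohort$expr, idx,
                        cohort$geneSets$HIT_UP, cohort$geneSets$HIT_DN)
#> ConcordanceResult
#>   genes scored: 300
#>   genes in ROC: 300
#>   AUC: 1.0000

groups <- splitByMedian(idx)[cohort$clinical$sample_id]
logrankTest(cohort$clinical$os_time, cohort$clinical$os_event, groups)
#> log-rank chi-square = 53.7, p = 2.32e-13
```

An index-high group with worse survival is exactly what the generator
plants (`survivalBeta = 0.8` per sd of the index signal). The published
contingency tables evaluate in milliseconds:

```r
runTable1(c("tcga_who", "tcga_gender"))
#>         table            p method
#> 1    tcga_who 3.732451e-05  exact
#> 2 tcga_gender 1.500101e-01  exact
```

`runPipeline()` chains all stages (simulate → cluster → enrich → associate
→ index → de → concordance → survival → table1) from one R-list or YAML
config and writes every intermediate table plus a JSON report.

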