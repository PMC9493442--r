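## End-to-end orchestration: simulate -> cluster -> enrich -> associate ->
## index -> de -> concordance -> survival -> table1, driven by one config
## (an R list or a YAML file). Stages communicate through files under
## `outDir` so a run is inspectable and resumable; the machine-readable
## report collects every statistic produced plus seed and input hashes.

.PIPELINE_STAGES <- c("simulate", "cluster", "enrich", "associate", "index",
                      "de", "concordance", "survival", "table1")

.m2Row <- function(fr) {
  i <- grep("M2|[Mm]acrophage", rownames(fr))
  if (!length(i)) stop("no M2 macrophage row found in the fraction matrix")
  i[1]
}

.fileHash <- function(path) unname(tools::md5sum(path))

#' Fisher tests on the published contingency tables
#'
#' Applies the exact r x c Fisher test to the named [table1Fixtures()]
#' table(s). Histology and WHO-grade fixtures already contain only the
#' Macro2/Macro3 columns, matching the published footnote that those
#' comparisons are between Macro2 and Macro3.
#'
#' @param fixtureName fixture name(s); all fixtures if `NULL`.
#' @return data.frame: `table`, `p`, `method`.
#' @export
runTable1 <- function(fixtureName = NULL) {
  fx <- table1Fixtures()
  if (is.null(fixtureName)) fixtureName <- names(fx)
  bad <- setdiff(fixtureName, names(fx))
  if (length(bad)) stop("unknown fixture(s): ", paste(bad, collapse = ", "))
  res <- lapply(fixtureName, function(nm) fisherExactRxC(fx[[nm]]))
  data.frame(table = fixtureName,
             p = vapply(res, `[[`, numeric(1), "p"),
             method = vapply(res, `[[`, character(1), "method"),
             stringsAsFactors = FALSE)
}

.normalizeConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  if (is.null(config$seed)) stop("config error: a seed is mandatory")
  config$seed <- as.integer(config$seed)
  if (is.null(config$outDir)) stop("config error: outDir is required")
  if (is.null(config$stages)) config$stages <- .PIPELINE_STAGES
  bad <- setdiff(config$stages, .PIPELINE_STAGES)
  if (length(bad)) stop("config error: unknown stage(s): ",
                        paste(bad, collapse = ", "))
  config
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on either a simulated
#' cohort (the `simulate` stage) or user-supplied TSV/GMT inputs
#' (`exprPath`, `fractionPaths`, `clinicalPath`, `gmtPath`). A stage whose
#' upstream artifact is missing stops the run with an error naming the
#' requirement; outputs written by earlier stages stay intact.
#'
#' @param config list or YAML path. Required: `seed`, `outDir`. Optional:
#'   `stages` (default: all of simulate, cluster, enrich, associate, index,
#'   de, concordance, survival, table1), `simulate` (overrides for
#'   [simulationConfig()]), `cluster` (`kRange`, `nResample`,
#'   `subsampleFrac`, `keepFrac`), `enrich` (`alpha`), `associate`
#'   (`alpha`), `concordance` (`sigAlpha`), `de` (`nHits`), input paths when
#'   `simulate` is disabled.
#' @return the run report (also written as `report.json` under `outDir`),
#'   a list with one entry per executed stage.
#' @export
runPipeline <- function(config) {
  cfg <- .normalizeConfig(config)
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  on <- function(stage) stage %in% cfg$stages
  report <- list(config = cfg[setdiff(names(cfg), "outDir")],
                 seed = cfg$seed, stages = list())
  st <- new.env(parent = emptyenv())

  if (on("simulate")) {
    simArgs <- c(cfg$simulate, list(seed = cfg$seed))
    simArgs <- simArgs[!duplicated(names(simArgs))]
    cohort <- do.call(simulationConfig, simArgs)
    cohort <- simulateCohort(cohort)
    st$expr <- cohort$expr
    st$fractions <- cohort$fractions
    st$clinical <- cohort$clinical
    st$geneSets <- cohort$geneSets
    st$alterations <- cohort$alterations
    st$truth <- cohort$truth
    writeMatrix(st$expr, file.path(cfg$outDir, "expression.tsv"))
    writeClinical(st$clinical, file.path(cfg$outDir, "clinical.tsv"))
    writeGmt(st$geneSets, file.path(cfg$outDir, "gene_sets.gmt"))
    for (nm in setdiff(names(st$fractions), "pvals"))
      writeMatrix(st$fractions[[nm]],
                  file.path(cfg$outDir, paste0("fractions_", nm, ".tsv")),
                  idColumn = "cell_type")
    report$stages$simulate <- list(
      nGenes = nrow(st$expr), nSamples = ncol(st$expr),
      nCellTypes = nrow(st$fractions[[1]]),
      archetypeCounts = as.list(table(st$clinical$archetype)))
  } else {
    if (!is.null(cfg$exprPath)) st$expr <- readMatrix(cfg$exprPath)
    if (!is.null(cfg$clinicalPath)) st$clinical <- readClinical(cfg$clinicalPath)
    if (!is.null(cfg$gmtPath)) st$geneSets <- readGmt(cfg$gmtPath)
    if (!is.null(cfg$fractionPaths)) {
      st$fractions <- lapply(cfg$fractionPaths, readMatrix)
      validateFractions(st$fractions)
    }
  }

  if (on("cluster")) {
    if (is.null(st$fractions) || is.null(st$clinical))
      stop("cluster stage requires fraction matrices and a clinical table")
    cc <- cfg$cluster
    fr <- filterFractionMatrix(st$fractions[[1]], st$fractions$pvals)
    res <- consensusCluster(t(fr),
                            kRange = if (is.null(cc$kRange)) 2:6 else cc$kRange,
                            nResample = if (is.null(cc$nResample)) 1000 else cc$nResample,
                            subsampleFrac = if (is.null(cc$subsampleFrac)) 0.8 else cc$subsampleFrac,
                            seed = cfg$seed,
                            keepFrac = if (is.null(cc$keepFrac)) 0.75 else cc$keepFrac)
    st$consensus <- res
    m2 <- st$fractions[[1]][.m2Row(st$fractions[[1]]), ]
    st$m2 <- m2
    utils::write.table(
      data.frame(sample_id = names(clusterAssignments(res)),
                 cluster = clusterAssignments(res),
                 silhouette = silhouetteWidth(res),
                 core = res@coreFlag),
      file.path(cfg$outDir, "assignments.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    writeMatrix(consensusMatrix(res),
                file.path(cfg$outDir, "consensus_matrix.tsv"),
                idColumn = "sample_id")
    utils::write.table(
      data.frame(k = names(pacValues(res)), pac = pacValues(res)),
      file.path(cfg$outDir, "pac.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    stage <- list(chosen_k = chosenK(res),
                  pac = as.list(pacValues(res)),
                  clusterSizes = as.list(table(clusterAssignments(res))),
                  nCore = sum(res@coreFlag))
    if (chosenK(res) == 2 && "histology" %in% colnames(st$clinical)) {
      mg <- assignMacroGroups(clusterAssignments(res), res@coreFlag,
                              st$clinical, m2)
      st$macroGroups <- mg
      stage$macroGroupSizes <- as.list(table(groupLabels(mg)))
      stage$nUnassigned <- length(unassignedSamples(mg))
    }
    report$stages$cluster <- stage
  }

  if (on("enrich")) {
    if (is.null(st$expr) || is.null(st$geneSets))
      stop("enrich stage requires an expression matrix and gene sets")
    alpha <- if (is.null(cfg$enrich$alpha)) 0.25 else cfg$enrich$alpha
    st$pathwayScores <- suppressMessages(
      ssgseaScore(st$expr, st$geneSets, alpha = alpha))
    writeMatrix(st$pathwayScores, file.path(cfg$outDir, "ssgsea_scores.tsv"),
                idColumn = "set_name")
    report$stages$enrich <- list(nSetsScored = nrow(st$pathwayScores),
                                 alpha = alpha)
  }

  if (on("associate")) {
    if (is.null(st$consensus))
      stop("associate stage requires the cluster stage (core samples and M2 fractions)")
    if (is.null(st$pathwayScores))
      stop("associate stage requires the enrich stage (pathway score matrix)")
    alpha <- if (is.null(cfg$associate$alpha)) 0.05 else cfg$associate$alpha
    core <- coreSamples(st$consensus)
    X <- t(st$pathwayScores[, core, drop = FALSE])
    kept <- vifReduce(X)
    reports <- lapply(setdiff(names(st$fractions), "pvals"), function(nm) {
      m2 <- st$fractions[[nm]][.m2Row(st$fractions[[nm]]), core]
      fitM2Regression(m2, X[, kept, drop = FALSE], algorithmTag = nm)
    })
    cons <- consensusSignificance(reports, alpha = alpha)
    st$association <- cons
    utils::write.table(do.call(rbind, reports),
                       file.path(cfg$outDir, "m2_regression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cons, file.path(cfg$outDir, "m2_consensus.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stage <- list(
      nFeatures = nrow(cons),
      nKeptAfterVif = length(kept),
      verdicts = as.list(table(cons$verdict)))
    if (is.null(st$alterations) && !is.null(cfg$alterationPath))
      st$alterations <- validateAlterations(readMatrix(cfg$alterationPath))
    if (!is.null(st$alterations)) {
      alt <- st$alterations
      estimable <- rowSums(alt == 1) >= 3 & rowSums(alt == 0) >= 3
      alt <- alt[estimable, , drop = FALSE]
    }
    if (!is.null(st$alterations) && nrow(alt)) {
      altReports <- lapply(setdiff(names(st$fractions), "pvals"),
                           function(nm) {
        m2a <- st$fractions[[nm]][.m2Row(st$fractions[[nm]]), colnames(alt)]
        fitAlterationLogistic(alt, m2a, algorithmTag = nm)
      })
      altCons <- consensusSignificance(altReports, alpha = alpha)
      utils::write.table(altCons,
                         file.path(cfg$outDir, "alteration_consensus.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      stage$alterationVerdicts <- as.list(table(altCons$verdict))
    }
    report$stages$associate <- stage
  }

  if (on("index")) {
    if (is.null(st$expr)) stop("index stage requires an expression matrix")
    idx <- computeMacroIndex(st$expr)
    st$index <- idx
    st$indexGroups <- splitByMedian(idx)
    utils::write.table(
      data.frame(sample_id = names(idx), macro_index = idx,
                 group = st$indexGroups),
      file.path(cfg$outDir, "macro_index.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    stage <- list(nGenesFound = attr(idx, "nGenesFound"),
                  indexMean = mean(idx), indexSd = stats::sd(idx))
    if (!is.null(st$m2)) {
      sp <- spearmanCor(idx, st$m2[names(idx)])
      stage$spearmanWithM2 <- list(rho = sp$rho, p = sp$p)
    }
    report$stages$index <- stage
  }

  if (on("de")) {
    if (is.null(st$index)) stop("de stage requires the index stage (median split)")
    de <- differentialExpression(st$expr, st$indexGroups)
    nHits <- if (is.null(cfg$de$nHits)) 150 else cfg$de$nHits
    hits <- hitSignatures(de, n = min(nHits, floor(nrow(de) / 2)))
    st$de <- de
    st$hits <- hits
    utils::write.table(de, file.path(cfg$outDir, "de_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeGmt(list(DE_UP = hits$positive_hits, DE_DN = hits$negative_hits),
             file.path(cfg$outDir, "de_signatures.gmt"))
    report$stages$de <- list(nSignificant = sum(de$q < 0.05),
                             nHitsPerDirection = length(hits$positive_hits))
  }

  if (on("concordance")) {
    if (is.null(st$index)) stop("concordance stage requires the index stage")
    pos <- st$geneSets$HIT_UP
    neg <- st$geneSets$HIT_DN
    if (is.null(pos) || is.null(neg)) {
      if (is.null(st$hits))
        stop("concordance stage requires hit signatures (HIT_UP/HIT_DN sets or the de stage)")
      pos <- st$hits$positive_hits
      neg <- st$hits$negative_hits
    }
    sigAlpha <- if (is.null(cfg$concordance$sigAlpha)) 0.05 else cfg$concordance$sigAlpha
    cr <- suppressMessages(
      signatureConcordanceAuc(st$expr, st$index, pos, neg,
                              sigAlpha = sigAlpha))
    st$concordance <- cr
    utils::write.table(geneStats(cr),
                       file.path(cfg$outDir, "concordance_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$concordance <- list(auc = aucValue(cr),
                                      nIncluded = cr@nIncluded)
  }

  if (on("survival")) {
    if (is.null(st$index) || is.null(st$clinical))
      stop("survival stage requires the index stage and a clinical table")
    need <- c("os_time", "os_event")
    if (!all(need %in% colnames(st$clinical)))
      stop("clinical table lacks os_time/os_event")
    ids <- intersect(st$clinical$sample_id, names(st$index))
    cl <- st$clinical[match(ids, st$clinical$sample_id), ]
    g <- st$indexGroups[ids]
    lr <- logrankTest(cl$os_time, cl$os_event, g)
    cox <- coxUnivariate(cl$os_time, cl$os_event,
                         as.vector(scale(st$index[ids])))
    km <- kmFit(cl$os_time, cl$os_event, g)
    for (nm in names(km))
      utils::write.table(km[[nm]],
                         file.path(cfg$outDir, paste0("km_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$survival <- list(
      logrank = lr,
      cox = cox[c("beta", "se", "p", "hr", "ciLower", "ciUpper")])
  }

  if (on("table1")) {
    t1 <- runTable1()
    utils::write.table(t1, file.path(cfg$outDir, "table1_fisher.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$table1 <- stats::setNames(as.list(t1$p), t1$table)
  }

  outputs <- list.files(cfg$outDir, full.names = TRUE)
  outputs <- outputs[!grepl("report\\.json$", outputs)]
  report$provenance <- list(
    seed = cfg$seed,
    stagesRun = intersect(.PIPELINE_STAGES, cfg$stages),
    outputHashes = stats::setNames(lapply(outputs, .fileHash),
                                   basename(outputs)))
  jsonlite::write_json(report, file.path(cfg$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
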