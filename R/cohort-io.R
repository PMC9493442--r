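## Readers, writers and validators for the tables the pipeline touches.
## Expression matrices are plain numeric matrices (genes x samples) in TPM;
## gene and sample identifiers are case-sensitive symbols, never remapped.

#' Validate an expression matrix
#'
#' Checks the invariants assumed throughout the package: a numeric matrix
#' with unique, non-empty gene rownames and sample colnames, all values
#' finite and non-negative (TPM scale).
#'
#' @param x matrix, genes x samples.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validateExpression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(x)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(x)[duplicated(rownames(x))])[1:3], collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(x)[duplicated(colnames(x))])[1:3], collapse = ", "))
  if (any(!is.finite(x))) stop("expression values must be finite")
  if (any(x < 0)) stop("expression values must be non-negative")
  invisible(x)
}

#' Validate a set of immune-fraction matrices
#'
#' A fraction set is a named list with one cell-type x sample matrix per
#' deconvolution algorithm, all fractions in \[0,1\], plus an optional named
#' `pvals` element of per-sample deconvolution p-values.
#'
#' @param fr named list of matrices (and optionally `pvals`).
#' @return `fr`, invisibly.
#' @export
validateFractions <- function(fr) {
  if (!is.list(fr) || is.null(names(fr)))
    stop("fraction set must be a named list of matrices")
  mats <- fr[setdiff(names(fr), "pvals")]
  if (!length(mats)) stop("fraction set contains no algorithm matrices")
  for (nm in names(mats)) {
    m <- mats[[nm]]
    if (!is.matrix(m) || !is.numeric(m))
      stop("fraction matrix '", nm, "' must be numeric")
    if (any(!is.finite(m)) || any(m < -1e-9) || any(m > 1 + 1e-9))
      stop("fractions in '", nm, "' must lie in [0,1]")
    if (is.null(colnames(m))) stop("fraction matrix '", nm, "' needs sample colnames")
  }
  invisible(fr)
}

#' Validate a clinical table
#'
#' Requires a `sample_id` column with unique ids; any of `histology`,
#' `who_grade`, `transcriptome_subtype`, `os_time`, `os_event`, `pfi_time`,
#' `pfi_event` may be present. Times must be non-negative and events binary.
#' Missing fields are allowed: analyses that need them fail at use, not at
#' load.
#'
#' @param clin data.frame.
#' @return `clin`, invisibly.
#' @export
validateClinical <- function(clin) {
  if (!is.data.frame(clin) || !"sample_id" %in% colnames(clin))
    stop("clinical table must be a data.frame with a 'sample_id' column")
  if (anyDuplicated(clin$sample_id)) stop("duplicate sample ids in clinical table")
  for (tc in c("os_time", "pfi_time")) {
    if (tc %in% colnames(clin)) {
      v <- clin[[tc]]
      if (any(v[!is.na(v)] < 0)) stop(tc, " must be >= 0")
    }
  }
  for (ec in c("os_event", "pfi_event")) {
    if (ec %in% colnames(clin)) {
      v <- clin[[ec]]
      if (!all(v[!is.na(v)] %in% c(0, 1))) stop(ec, " must be 0/1")
    }
  }
  invisible(clin)
}

#' Validate a binary alteration matrix
#'
#' Feature x sample indicator matrix for mutations and copy-number gains or
#' losses; strictly 0/1 with unique feature ids.
#'
#' @param alt matrix.
#' @return `alt`, invisibly.
#' @export
validateAlterations <- function(alt) {
  if (!is.matrix(alt)) stop("alteration matrix must be a matrix")
  if (!all(alt %in% c(0, 1))) stop("alteration matrix must be strictly 0/1")
  if (is.null(rownames(alt)) || anyDuplicated(rownames(alt)))
    stop("alteration matrix needs unique feature rownames")
  invisible(alt)
}

#' Read a genes-x-samples matrix from TSV
#'
#' Expects a tab-separated file with a header row of sample ids and a first
#' column of gene ids ('.' decimal, UTF-8). Duplicate gene rows are collapsed
#' by their mean with a warning; duplicate sample ids are an error.
#'
#' @param path file path.
#' @param rowsAreGenes logical; if `FALSE` the file is samples x genes and is
#'   transposed after reading.
#' @return validated numeric matrix, genes x samples.
#' @export
readMatrix <- function(path, rowsAreGenes = TRUE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2) stop("matrix file needs an id column plus data columns: ", path)
  hdr <- colnames(df)[-1]
  if (anyDuplicated(hdr))   # before data.frame subsetting uniquifies names
    stop("duplicate sample id in header of ", path, ": ",
         hdr[duplicated(hdr)][1])
  ids <- df[[1]]
  val <- df[, -1, drop = FALSE]
  colnames(val) <- hdr
  num <- suppressWarnings(vapply(val, as.numeric, numeric(nrow(val))))
  if (nrow(val) == 1) num <- matrix(num, nrow = 1, dimnames = list(NULL, colnames(val)))
  bad <- which(is.na(num) & !(val == "NA" | val == ""), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric value '%s' at row '%s', column '%s' in %s",
                 as.matrix(val)[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                 colnames(val)[bad[1, 2]], path))
  }
  m <- num
  rownames(m) <- ids
  if (!rowsAreGenes) m <- t(m)
  if (anyDuplicated(rownames(m))) {
    ndup <- sum(duplicated(rownames(m)))
    warning(ndup, " duplicate gene row(s) collapsed by mean in ", basename(path))
    m <- rowsum(m, rownames(m), reorder = FALSE) /
      as.vector(table(rownames(m))[unique(rownames(m))])
  }
  validateExpression(m)
  m
}

#' Write a matrix as TSV
#'
#' Inverse of [readMatrix()]: header row of sample ids, first column of gene
#' ids, full precision so a read/write round trip preserves values.
#'
#' @param m numeric matrix with dimnames.
#' @param path output file path.
#' @param idColumn name for the first (gene id) column.
#' @return `path`, invisibly.
#' @export
writeMatrix <- function(m, path, idColumn = "gene_id") {
  df <- data.frame(rownames(m), format(m, digits = 17, trim = TRUE,
                                       scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(idColumn, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' MSigDB dialect: one set per line, tab-separated fields `name`,
#' `description`, then gene ids. Duplicate genes within a set are collapsed;
#' empty gene lists are rejected.
#'
#' @param path file path.
#' @return named list of character vectors, with a `description` attribute
#'   (named character vector) carrying the per-set descriptions.
#' @export
readGmt <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  descs <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 3)
      stop("GMT format error at line ", i, ": expected name, description and ",
           "at least one gene (", length(f), " fields)")
    genes <- unique(f[-(1:2)])
    sets[[f[1]]] <- genes
    descs[[f[1]]] <- f[2]
  }
  if (!length(sets)) stop("empty GMT file: ", path)
  attr(sets, "description") <- descs
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets named list of character vectors.
#' @param path output file path.
#' @param descriptions optional named character vector of set descriptions;
#'   defaults to "na".
#' @return `path`, invisibly.
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "description")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a clinical phenotype table from TSV
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
readClinical <- function(path) {
  clin <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  validateClinical(clin)
  clin
}

#' Write a clinical table as TSV
#'
#' @param clin data.frame with a `sample_id` column.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeClinical <- function(clin, path) {
  utils::write.table(clin, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Restrict expression, fractions and clinical data to shared samples
#'
#' All objects are subset to the intersection of their sample ids and put in
#' identical column order. Idempotent; an intersection below `minShared`
#' samples is an error.
#'
#' @param expr genes x samples matrix.
#' @param fractions named list of cell-type x sample matrices (a fraction
#'   set; an optional `pvals` element is aligned too).
#' @param clinical data.frame with `sample_id`.
#' @param minShared minimum size of the sample intersection.
#' @return list with elements `expr`, `fractions`, `clinical`, and `dropped`
#'   (a named list of the sample ids removed from each input).
#' @export
harmonizeCohort <- function(expr, fractions, clinical, minShared = 3) {
  validateExpression(expr)
  validateFractions(fractions)
  validateClinical(clinical)
  mats <- setdiff(names(fractions), "pvals")
  shared <- Reduce(intersect, c(list(colnames(expr)),
                                lapply(fractions[mats], colnames),
                                list(clinical$sample_id)))
  if (length(shared) < minShared)
    stop("only ", length(shared), " shared sample(s) across inputs; need >= ",
         minShared)
  shared <- shared[order(match(shared, colnames(expr)))]
  dropped <- list(
    expr = setdiff(colnames(expr), shared),
    fractions = unique(unlist(lapply(fractions[mats],
                                     function(m) setdiff(colnames(m), shared)))),
    clinical = setdiff(clinical$sample_id, shared)
  )
  out <- fractions
  for (nm in mats) out[[nm]] <- fractions[[nm]][, shared, drop = FALSE]
  if (!is.null(fractions$pvals)) out$pvals <- fractions$pvals[shared]
  clin <- clinical[match(shared, clinical$sample_id), , drop = FALSE]
  rownames(clin) <- NULL
  list(expr = expr[, shared, drop = FALSE], fractions = out, clinical = clin,
       dropped = dropped)
}
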