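#' Read an expression matrix and sample annotations
#'
#' The matrix file is tab-delimited with gene identifiers in the first
#' column and one column per sample; the metadata file is tab-delimited
#' with columns \code{sample_id}, \code{group} and \code{time}. Samples are
#' matched by exact identifier; times are taken as given (no tolerance
#' merging). Missing values, samples present in only one file, or empty
#' (group, time) cells are errors naming the offenders, never silently
#' repaired.
#'
#' @param matrixPath path to the expression table.
#' @param metaPath path to the sample metadata table.
#' @return A \linkS4class{TimecourseExperiment}.
#' @export
readExpressionTable <- function(matrixPath, metaPath) {
  mat <- read.delim(matrixPath, check.names = FALSE)
  if (ncol(mat) < 2L) stop("matrix file needs a gene column plus samples")
  ids <- as.character(mat[[1L]])
  y <- as.matrix(mat[, -1L, drop = FALSE])
  storage.mode(y) <- "double"
  rownames(y) <- ids
  meta <- read.delim(metaPath, check.names = FALSE)
  need <- c("sample_id", "group", "time")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop(sprintf("metadata lacks column(s): %s", paste(miss, collapse = ", ")))
  unknown <- setdiff(meta$sample_id, colnames(y))
  if (length(unknown))
    stop(sprintf("metadata sample(s) absent from the matrix: %s",
                 paste(unknown, collapse = ", ")))
  extra <- setdiff(colnames(y), meta$sample_id)
  if (length(extra))
    stop(sprintf("matrix sample(s) absent from the metadata: %s",
                 paste(extra, collapse = ", ")))
  y <- y[, as.character(meta$sample_id), drop = FALSE]
  if (anyNA(y)) {
    bad <- which(is.na(y), arr.ind = TRUE)
    stop(sprintf("missing expression values, e.g. gene %s / sample %s",
                 rownames(y)[bad[1L, 1L]], colnames(y)[bad[1L, 2L]]))
  }
  TimecourseExperiment(y, group = meta$group, time = as.numeric(meta$time),
                       sampleIds = as.character(meta$sample_id))
}

#' Write an expression matrix and sample annotations
#'
#' Inverse of \code{\link{readExpressionTable}}; a read-write-read
#' round-trip reproduces the container exactly.
#'
#' @param x a \linkS4class{TimecourseExperiment}.
#' @param matrixPath,metaPath output file paths.
#' @return invisibly, the two paths.
#' @export
writeExpressionTable <- function(x, matrixPath, metaPath) {
  stopifnot(is(x, "TimecourseExperiment"))
  y <- assay(x)
  write.table(data.frame(gene_id = rownames(y), y, check.names = FALSE),
              matrixPath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = colnames(y),
                         group = as.character(sampleGroups(x)),
                         time = sampleTimes(x)),
              metaPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrixPath, metaPath))
}

#' Write test results and run metadata
#'
#' Writes \code{<prefix>_results.tsv} (columns gene_id, F, p_unadj,
#' p_fwer, p_fdr, significant) and \code{<prefix>_meta.json} (seed, B,
#' loss, scheme, basis specification, alpha). Output is byte-identical
#' across runs with the same inputs and seed.
#'
#' @param object a \linkS4class{PermTestResult}.
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
writeResults <- function(object, prefix) {
  stopifnot(is(object, "PermTestResult"))
  resPath <- paste0(prefix, "_results.tsv")
  metaPath <- paste0(prefix, "_meta.json")
  df <- as.data.frame(resultsTable(object))
  write.table(df, resPath, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(runParams(object), metaPath, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(c(resPath, metaPath))
}
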