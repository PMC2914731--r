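#' Construct a TimecourseExperiment
#'
#' Bundles an expression matrix (genes x samples) with per-sample group and
#' time annotations into a validated container. Samples with the same
#' numeric \code{time} form one exchangeability cell for the permutation
#' null, so times must match exactly (no tolerance merging is performed).
#'
#' @param exprs numeric matrix, genes in rows, samples in columns. Row
#'   names are used as gene identifiers (generated if absent).
#' @param group vector (coerced to factor) of group labels, one per sample.
#' @param time numeric vector of observation times, one per sample.
#' @param sampleIds optional sample identifiers (defaults to column names).
#' @return A \linkS4class{TimecourseExperiment}.
#' @examples
#' y <- matrix(rnorm(2 * 8), 2, 8,
#'             dimnames = list(c("g1", "g2"), paste0("s", 1:8)))
#' tce <- TimecourseExperiment(y, group = rep(1:2, each = 4),
#'                             time = rep(c(0, 6), 4))
#' timeDesign(tce)
#' @export
TimecourseExperiment <- function(exprs, group, time, sampleIds = NULL) {
  exprs <- as.matrix(exprs)
  if (!is.numeric(exprs)) stop("expression values must be numeric")
  n <- ncol(exprs)
  if (length(group) != n || length(time) != n)
    stop(sprintf("group (%d) and time (%d) must each have one entry per sample (%d)",
                 length(group), length(time), n))
  if (is.null(rownames(exprs)))
    rownames(exprs) <- sprintf("gene_%d", seq_len(nrow(exprs)))
  if (is.null(sampleIds))
    sampleIds <- if (!is.null(colnames(exprs))) colnames(exprs)
                 else sprintf("sample_%d", seq_len(n))
  colnames(exprs) <- sampleIds
  se <- SummarizedExperiment(
    assays = list(exprs = exprs),
    colData = DataFrame(group = factor(group), time = as.numeric(time),
                        row.names = sampleIds))
  new("TimecourseExperiment", se)
}

#' @describeIn TimecourseExperiment group factor, one level per sample.
#' @param x a \linkS4class{TimecourseExperiment}.
#' @export
sampleGroups <- function(x) colData(x)$group

#' @describeIn TimecourseExperiment numeric observation times per sample.
#' @export
sampleTimes <- function(x) colData(x)$time

#' Extract the time-sampling design
#'
#' @param x a \linkS4class{TimecourseExperiment}, or a list with elements
#'   \code{group} and \code{time}.
#' @return A \linkS4class{TimeDesign}.
#' @export
timeDesign <- function(x) {
  if (is(x, "TimecourseExperiment")) {
    g <- sampleGroups(x); tt <- sampleTimes(x)
  } else {
    g <- factor(x$group); tt <- as.numeric(x$time)
  }
  ut <- sort(unique(tt))
  counts <- table(g, factor(tt, levels = ut))
  new("TimeDesign", times = ut, groups = levels(g),
      counts = matrix(as.integer(counts), nrow = nlevels(g),
                      dimnames = list(levels(g), format(ut))))
}

setMethod("show", "TimeDesign", function(object) {
  cat(sprintf("TimeDesign: K = %d groups, L = %d time-points\n",
              length(object@groups), length(object@times)))
  cat("times:", paste(object@times, collapse = " "), "\n")
  cat("n_kl:\n")
  print(object@counts)
})

setMethod("show", "TimecourseExperiment", function(object) {
  callNextMethod()
  d <- timeDesign(object)
  cat(sprintf("design: K = %d groups x L = %d time-points, n_kl in [%d, %d]\n",
              length(d@groups), length(d@times), min(d@counts), max(d@counts)))
})
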