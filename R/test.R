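#' Permutation test for group-dependent expression time-trajectories
#'
#' The full pipeline: build the shared spline basis from the pooled sample
#' times, compute per-gene F-type statistics comparing pooled versus
#' group-wise trajectory fits under the chosen loss, generate the joint
#' permutation null by shuffling observations within each time-point (one
#' permutation per replicate, applied to all genes), and report unadjusted,
#' single-step maxT FWER-adjusted, and Benjamini-Hochberg FDR-adjusted
#' p-values.
#'
#' With \code{loss = "median"} the trajectory fits are median regression
#' splines solved by linear programming, making the test robust to
#' symmetric outlier contamination; \code{loss = "mean"} runs the
#' least-squares comparator pipeline through the identical permutation
#' machinery. \code{oneSample = TRUE} tests each gene for any time
#' dependence (flat-line null, all observations exchangeable).
#'
#' @param x a \linkS4class{TimecourseExperiment}.
#' @param p,degree,lambda basis parameters, see \code{\link{makeSplineBasis}};
#'   ignored when \code{basis} is supplied.
#' @param basis optional pre-built \linkS4class{SplineBasis}.
#' @param loss \code{"median"} (default) or \code{"mean"}.
#' @param B number of random permutations.
#' @param seed optional integer seed for the permutation stream; recorded
#'   in the result. When \code{NULL} the current RNG state is used.
#' @param alpha FWER level for the significance call
#'   (\code{p_fwer <= alpha}).
#' @param center \code{"group-mean"} removes group-wise vertical shifts
#'   (see \code{\link{centerByGroupMeans}}) before testing.
#' @param oneSample test for time dependence instead of a group effect.
#' @param floorPvalues use the (count + 1)/(B + 1) p-value estimator
#'   instead of the plain frequency (default \code{FALSE}).
#' @param permutations optional explicit permutation matrix (rows =
#'   replicates), overriding \code{B}; used e.g. for exhaustive enumeration
#'   of small designs.
#' @return A \linkS4class{PermTestResult}.
#' @examples
#' set.seed(1)
#' tt <- rep(rep(c(0, 2, 4, 8), each = 3), 2)
#' gg <- rep(1:2, each = 12)
#' y <- matrix(rnorm(20 * 24), 20, 24)
#' y[1, gg == 2] <- y[1, gg == 2] + 2 * exp(-tt[gg == 2] / 4)
#' tce <- TimecourseExperiment(y, gg, tt)
#' res <- qspermTest(tce, p = 3, B = 50, seed = 7)
#' res
#' @export
qspermTest <- function(x, p = 4, degree = 1, lambda = 0, basis = NULL,
                       loss = c("median", "mean"), B = 200, seed = NULL,
                       alpha = 0.05, center = c("none", "group-mean"),
                       oneSample = FALSE, floorPvalues = FALSE,
                       permutations = NULL) {
  stopifnot(is(x, "TimecourseExperiment"))
  loss <- match.arg(loss)
  center <- match.arg(center)
  Y <- assay(x)
  groups <- sampleGroups(x)
  times <- sampleTimes(x)
  if (center == "group-mean") Y <- centerByGroupMeans(Y, groups)
  if (is.null(basis))
    basis <- makeSplineBasis(times, p = p, degree = degree, lambda = lambda)
  scheme <- if (oneSample) "all_exchangeable" else "within_timepoint"
  if (!is.null(seed)) set.seed(seed)
  eng <- .permEngine(Y, groups, times, basis, losses = loss, B = B,
                     scheme = scheme, permutations = permutations,
                     oneSample = oneSample)
  fObs <- eng$f_obs[[loss]]
  fNull <- eng$f_null[[loss]]
  pUnadj <- unadjustedPvalues(fObs, fNull, floor = floorPvalues)
  pFwer <- adjustFwerSingleStep(fObs, fNull, floor = floorPvalues)
  res <- DataFrame(gene_id = rownames(Y), F = fObs, p_unadj = pUnadj,
                   p_fwer = pFwer, p_fdr = adjustFdr(pUnadj),
                   significant = pFwer <= alpha)
  new("PermTestResult", results = res,
      params = list(
        loss = loss, B = nrow(fNull), seed = seed, alpha = alpha,
        scheme = scheme, center = center, oneSample = oneSample,
        floorPvalues = floorPvalues,
        basis = list(p = basis@p, degree = basis@degree,
                     knots = basis@knots, lambda = basis@lambda),
        nPossiblePermutations =
          if (oneSample) factorial(length(times))
          else countPermutations(timeDesign(list(group = groups,
                                                 time = times)))))
}

#' @describeIn qspermTest per-gene results as a
#'   \link[S4Vectors]{DataFrame} (\code{gene_id}, \code{F}, \code{p_unadj},
#'   \code{p_fwer}, \code{p_fdr}, \code{significant}).
#' @param object a \linkS4class{PermTestResult}.
#' @export
resultsTable <- function(object) {
  stopifnot(is(object, "PermTestResult"))
  object@results
}

#' @describeIn qspermTest run metadata (seed, B, loss, scheme, basis
#'   specification, alpha).
#' @export
runParams <- function(object) {
  stopifnot(is(object, "PermTestResult"))
  object@params
}

#' @describeIn qspermTest identifiers of genes significant at the analysis
#'   alpha.
#' @export
significantGenes <- function(object) {
  r <- resultsTable(object)
  r$gene_id[r$significant]
}

setMethod("show", "PermTestResult", function(object) {
  r <- object@results; p <- object@params
  cat(sprintf("PermTestResult: %d genes, %s loss, B = %d (%s)\n",
              nrow(r), p$loss, p$B, p$scheme))
  cat(sprintf("significant at FWER alpha = %g: %d gene(s)\n",
              p$alpha, sum(r$significant)))
  ord <- utils::head(order(r$p_fwer, -r$F), 5L)
  print(as.data.frame(r[ord, , drop = FALSE]), digits = 4)
})
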