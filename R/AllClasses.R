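#' Time-sampling design of a grouped time-course experiment
#'
#' Summarises when samples were observed: the distinct observation times
#' \eqn{t_1 < \dots < t_L}, the group levels, and the count table
#' \eqn{n_{kl}} of observations per group and time-point. The testing
#' machinery requires every \eqn{(k, l)} cell to be occupied
#' (\eqn{n_{kl} \ge 1}) so that observations are exchangeable within each
#' time-point under the null.
#'
#' @slot times numeric vector of distinct observation times, strictly
#'   increasing (hours or any common unit).
#' @slot groups character vector of group level names (length K).
#' @slot counts integer matrix, K rows (groups) by L columns (times), with
#'   entry \eqn{n_{kl}}.
#' @exportClass TimeDesign
setClass("TimeDesign",
  representation(times = "numeric", groups = "character", counts = "matrix"))

setValidity("TimeDesign", function(object) {
  msg <- character()
  if (length(object@times) < 1L)
    msg <- c(msg, "need at least one observation time")
  if (is.unsorted(object@times, strictly = TRUE))
    msg <- c(msg, "distinct times must be strictly increasing")
  if (nrow(object@counts) != length(object@groups) ||
      ncol(object@counts) != length(object@times))
    msg <- c(msg, "counts must be K x L")
  if (any(object@counts < 1L)) {
    bad <- which(object@counts < 1L, arr.ind = TRUE)
    msg <- c(msg, sprintf(
      "every (group, time) cell needs n_kl >= 1; empty: %s",
      paste(sprintf("(%s, t=%g)", object@groups[bad[, 1L]],
                    object@times[bad[, 2L]]), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Container for a grouped time-course expression experiment
#'
#' A \linkS4class{SummarizedExperiment} whose \code{colData} carries a
#' \code{group} factor and a numeric \code{time} for every sample, with a
#' single assay of expression values (genes in rows, samples in columns).
#' Missing values are not allowed, and every (group, time) combination must
#' contain at least one sample.
#'
#' @exportClass TimecourseExperiment
setClass("TimecourseExperiment", contains = "SummarizedExperiment")

setValidity("TimecourseExperiment", function(object) {
  msg <- character()
  cd <- colData(object)
  if (!all(c("group", "time") %in% colnames(cd)))
    return("colData must contain 'group' and 'time' columns")
  if (!is.numeric(cd$time))
    msg <- c(msg, "'time' must be numeric")
  if (length(assays(object)) < 1L)
    return("one expression assay is required")
  y <- assay(object)
  if (anyNA(y) || anyNA(cd$group) || anyNA(cd$time)) {
    bad <- which(rowSums(is.na(y)) > 0L)
    msg <- c(msg, sprintf(
      "missing values are not supported (%s)",
      if (length(bad)) paste0("genes: ",
        paste(utils::head(rownames(y)[bad], 5L), collapse = ", "))
      else "in sample annotations"))
  }
  if (!length(msg)) {
    tab <- table(factor(cd$group), factor(cd$time))
    if (any(tab == 0L)) {
      bad <- which(tab == 0L, arr.ind = TRUE)
      msg <- c(msg, sprintf(
        "empty (group, time) cells: %s",
        paste(sprintf("(%s, t=%s)", rownames(tab)[bad[, 1L]],
                      colnames(tab)[bad[, 2L]]), collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Shared spline basis for trajectory fitting
#'
#' A p-dimensional B-spline function space over the observed time range,
#' with knots placed at empirical quantiles of the pooled per-sample
#' observation times. All genes and both the pooled and group-wise fits use
#' the same basis, so per-gene degrees of freedom are identical across the
#' gene family.
#'
#' @slot p integer, nominal basis dimension (number of free parameters of
#'   the fitted function class, including its constant component).
#' @slot degree integer spline degree (1 = piecewise linear, 3 = cubic).
#' @slot knots numeric, the distinct quantile knots (boundary + interior).
#' @slot boundary numeric length 2, the evaluation range.
#' @slot lambda nonnegative smoothing weight for the total-variation
#'   penalty on the fitted function's derivative (0 = regression spline).
#' @slot fullKnots numeric, the full knot vector (boundary knots repeated
#'   degree + 1 times) used for B-spline evaluation.
#' @exportClass SplineBasis
setClass("SplineBasis",
  representation(p = "integer", degree = "integer", knots = "numeric",
                 boundary = "numeric", lambda = "numeric",
                 fullKnots = "numeric"))

setValidity("SplineBasis", function(object) {
  msg <- character()
  if (object@p < 2L) msg <- c(msg, "basis dimension p must be >= 2")
  if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
  if (is.unsorted(object@knots))
    msg <- c(msg, "knots must be nondecreasing")
  if (length(msg)) msg else TRUE
})

#' Result of a permutation time-course test
#'
#' Per-gene observed F-type statistics with unadjusted permutation p-values,
#' single-step maxT FWER-adjusted p-values, Benjamini-Hochberg FDR-adjusted
#' p-values, and the significance call at the analysis alpha. The
#' \code{params} list records everything needed to reproduce the run (seed,
#' B, loss, permutation scheme, basis specification, alpha).
#'
#' @slot results a \link[S4Vectors]{DataFrame} with columns \code{gene_id},
#'   \code{F}, \code{p_unadj}, \code{p_fwer}, \code{p_fdr},
#'   \code{significant}.
#' @slot params list of run metadata.
#' @exportClass PermTestResult
setClass("PermTestResult",
  representation(results = "DataFrame", params = "list"))

#' Simulation scenario for the time-course benchmark
#'
#' Encodes one cell of the benchmark design: an outlier-contaminated
#' additive model on a fixed time grid with block-exchangeable gene-gene
#' error correlation. Non-prognostic genes have flat zero trajectories in
#' both groups; prognostic genes have group-2 trajectory
#' \eqn{\mu_2(t) = \mathrm{effectScale} \cdot e^{-t}}.
#'
#' @slot m integer, total genes.
#' @slot mProg integer, number of prognostic genes (0 for a global-null
#'   scenario).
#' @slot timeGrid numeric vector of observation times.
#' @slot nPerGroupTime integer, replicates per group per time-point.
#' @slot pi outlier probability: each observation is shifted by
#'   +magnitude or -magnitude with probability pi/2 each.
#' @slot outlierMagnitude numeric, absolute outlier shift.
#' @slot rho block-exchangeable error correlation within gene blocks.
#' @slot blockSize integer, genes per correlation block.
#' @slot model integer: 1 = outliers at all time-points, 2 = outliers only
#'   at the first and last time-points.
#' @slot effectScale numeric, amplitude of the prognostic group-2 trajectory.
#' @slot N integer, number of simulated datasets.
#' @slot B integer, permutations per dataset.
#' @slot alpha FWER level for the rejection rule.
#' @slot seed integer RNG seed for the scenario.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(m = "integer", mProg = "integer", timeGrid = "numeric",
                 nPerGroupTime = "integer", pi = "numeric",
                 outlierMagnitude = "numeric", rho = "numeric",
                 blockSize = "integer", model = "integer",
                 effectScale = "numeric", N = "integer", B = "integer",
                 alpha = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@pi < 0 || object@pi > 1)
    msg <- c(msg, "outlier probability pi must be in [0, 1]")
  if (object@rho < 0 || object@rho >= 1)
    msg <- c(msg, "block correlation rho must be in [0, 1)")
  if (!object@model %in% c(1L, 2L))
    msg <- c(msg, "model must be 1 (all time-points) or 2 (first/last only)")
  if (object@mProg > object@m)
    msg <- c(msg, "mProg cannot exceed m")
  if (object@m < 1L || object@N < 1L || object@B < 1L)
    msg <- c(msg, "m, N and B must be positive")
  if (length(object@timeGrid) < 2L ||
      is.unsorted(object@timeGrid, strictly = TRUE))
    msg <- c(msg, "timeGrid must be strictly increasing with length >= 2")
  if (object@alpha < 0 || object@alpha > 1)
    msg <- c(msg, "alpha must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Monte-Carlo summary of a simulation scenario
#'
#' Empirical rejection proportion (FWER under a global null, global power
#' when prognostic genes are present) with its binomial Monte-Carlo
#' standard error, per analysis method.
#'
#' @slot method character, one of \code{"median_perm"}, \code{"mean_perm"}.
#' @slot metric character, \code{"fwer"} or \code{"power"}.
#' @slot proportion numeric in [0, 1], the rejection proportion.
#' @slot mcSE numeric, \code{sqrt(v (1 - v) / N)}.
#' @slot rejections integer, number of datasets with >= 1 rejection.
#' @slot N integer, datasets simulated.
#' @slot config the generating \linkS4class{SimConfig}.
#' @exportClass SimSummary
setClass("SimSummary",
  representation(method = "character", metric = "character",
                 proportion = "numeric", mcSE = "numeric",
                 rejections = "integer", N = "integer",
                 config = "SimConfig"))
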