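#' Build the shared spline basis for trajectory fitting
#'
#' Constructs a p-dimensional B-spline function space over the observed
#' times, with boundary knots at the extremes and interior knots at
#' empirical quantiles of the pooled per-sample observation times (pooled
#' across all groups; replicated times count with their multiplicity).
#' For the default degree 1 the quantile levels are
#' \eqn{0, 1/(p-1), \dots, (p-2)/(p-1), 1}; for degree d they generalise to
#' \eqn{i/(p-d)} so that the basis dimension stays p. Quantiles use the
#' linear-interpolation convention (\code{type = 7}).
#'
#' The returned basis spans constants, so a flat trajectory is always
#' representable. Tied quantiles are collapsed with a warning, reducing
#' the effective dimension.
#'
#' @param x a \linkS4class{TimecourseExperiment}, a \linkS4class{TimeDesign},
#'   or a numeric vector of pooled per-sample observation times.
#' @param p nominal basis dimension (>= 2); the fitted function class has p
#'   free parameters, counting its constant component.
#' @param degree spline degree: 1 (default) gives continuous piecewise-linear
#'   fits with breaks at the interior knots; 3 gives cubic B-splines.
#' @param lambda nonnegative total-variation roughness penalty weight used
#'   by the median fit (0 = unpenalised regression spline, the default).
#' @return A \linkS4class{SplineBasis}.
#' @examples
#' b <- makeSplineBasis(rep(c(0:8, 10, 12), each = 8), p = 4)
#' b@knots  # quantile knots at levels 0, 1/3, 2/3, 1
#' @export
makeSplineBasis <- function(x, p = 4, degree = 1, lambda = 0) {
  times <- if (is(x, "TimecourseExperiment")) sampleTimes(x)
           else if (is(x, "TimeDesign")) x@times
           else as.numeric(x)
  if (!length(times)) stop("no observation times supplied")
  p <- as.integer(p); degree <- as.integer(degree)
  if (p < 2L) stop("basis dimension p must be >= 2")
  if (degree < 1L) stop("spline degree must be >= 1")
  if (p < degree + 1L)
    stop(sprintf("p = %d cannot support degree %d (need p >= degree + 1)",
                 p, degree))
  nInterior <- p - degree - 1L
  levels <- if (nInterior > 0L) seq_len(nInterior) / (p - degree) else numeric()
  bd <- range(times)
  if (bd[1] == bd[2])
    stop("degenerate design: all pooled observation times are identical")
  interior <- unname(quantile(times, levels, type = 7))
  keep <- interior > bd[1] & interior < bd[2] & !duplicated(interior)
  if (!all(keep)) {
    warning(sprintf(
      "collapsed %d tied quantile knot(s); effective dimension reduced from %d to %d",
      sum(!keep), p, p - sum(!keep)))
    interior <- interior[keep]
    p <- length(interior) + degree + 1L
  }
  basis <- new("SplineBasis", p = p, degree = degree,
               knots = c(bd[1], interior, bd[2]), boundary = bd,
               lambda = as.numeric(lambda),
               fullKnots = c(rep(bd[1], degree + 1L), interior,
                             rep(bd[2], degree + 1L)))
  ut <- sort(unique(times))
  rk <- qr(basisMatrix(basis, ut))$rank
  if (rk < p) {
    cnt <- table(times)
    stop(sprintf(
      "degenerate design: %d distinct time(s) support rank %d < p = %d basis functions (counts: %s)",
      length(ut), rk, p,
      paste(sprintf("t=%s:%d", names(cnt), as.integer(cnt)), collapse = ", ")))
  }
  basis
}

#' Evaluate a spline basis as a design matrix
#'
#' Returns the n x p design matrix whose i-th row evaluates the basis at
#' \code{times[i]}: an explicit intercept column followed by the B-spline
#' columns with the first dropped (the B-splines sum to one, so dropping one
#' keeps the matrix full rank while the spanned function space, constants
#' included, is unchanged). Identical times give identical rows, and
#' evaluation outside the knot span is an error (no extrapolation).
#'
#' @param basis a \linkS4class{SplineBasis}.
#' @param times numeric vector of evaluation times, all within the basis
#'   boundary range.
#' @return numeric matrix with \code{length(times)} rows and \code{basis@p}
#'   columns.
#' @export
basisMatrix <- function(basis, times) {
  stopifnot(is(basis, "SplineBasis"))
  times <- as.numeric(times)
  out <- times < basis@boundary[1] | times > basis@boundary[2]
  if (any(out))
    stop(sprintf("time(s) outside the basis span [%g, %g]: %s",
                 basis@boundary[1], basis@boundary[2],
                 paste(utils::head(times[out], 5L), collapse = ", ")))
  B <- splines::splineDesign(basis@fullKnots, times, ord = basis@degree + 1L)
  X <- cbind(1, B[, -1L, drop = FALSE])
  colnames(X) <- c("(Intercept)", sprintf("B%d", seq_len(ncol(B) - 1L) + 1L))
  X
}

#' Total-variation penalty operator for a spline basis
#'
#' Linear functionals of the coefficient vector whose L1 norm is the
#' roughness penalty used by the penalised median fit. For degree-1 bases
#' this is exact: row i gives the change in slope at interior knot i + 1,
#' so the penalty equals the total variation of the fitted function's
#' derivative. For higher degrees the rows are second differences of the
#' B-spline coefficients, a standard surrogate for the same functional.
#'
#' @param basis a \linkS4class{SplineBasis}.
#' @return numeric matrix with \code{basis@p} columns (possibly 0 rows when
#'   the function class has no curvature, e.g. p = 2).
#' @export
penaltyOperator <- function(basis) {
  stopifnot(is(basis, "SplineBasis"))
  p <- basis@p
  if (basis@degree == 1L) {
    if (p < 3L) return(matrix(0, 0L, p))
    k <- basis@knots  # length p for degree 1
    # node values v = C beta: v_1 = intercept, v_i = intercept + beta_i
    C <- cbind(1, rbind(0, diag(p - 1L)))
    S1 <- (diag(1 / diff(k)) %*% (cbind(0, diag(p - 1L)) -
                                  cbind(diag(p - 1L), 0)))
    S2 <- cbind(0, diag(p - 2L)) - cbind(diag(p - 2L), 0)
    unname(S2 %*% S1 %*% C)
  } else {
    nc <- p - 1L  # B-spline coefficients present in the design
    if (nc < 3L) return(matrix(0, 0L, p))
    cbind(0, diff(diag(nc), differences = 2L))
  }
}
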