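#' F-type statistic for a group effect on one gene's trajectory
#'
#' Compares the pooled (null) trajectory fit, estimated from all
#' observations of the gene regardless of group, against independent
#' group-wise fits:
#' \deqn{F = (RAE_0 - \sum_k RAE_k) / \sum_k RAE_k,}
#' where \eqn{RAE} is the attained residual-error sum of the chosen loss
#' (sum of absolute residuals for \code{"median"}, residual sum of squares
#' for \code{"mean"}). The pooled curve is a feasible candidate for every
#' group fit, so \eqn{\sum_k RAE_k \le RAE_0} and \eqn{F \ge 0}. Because
#' all genes share one basis and one design, any monotone rescaling of F
#' (degrees-of-freedom constants and the like) leaves the permutation
#' p-values and the maxT adjustment unchanged.
#'
#' If the group fits interpolate (\eqn{\sum_k RAE_k = 0}) while the pooled
#' fit does not, F is \code{Inf}, which ranks above every finite statistic
#' in the permutation comparisons; if both residual errors are 0, F is 0.
#'
#' @param y numeric vector of one gene's expressions, one per sample.
#' @param groups group labels (coerced to factor), one per sample.
#' @param times numeric observation times, one per sample.
#' @param basis a \linkS4class{SplineBasis} shared across genes.
#' @param loss \code{"median"} (robust, default) or \code{"mean"}
#'   (least-squares comparator).
#' @param gene_id optional identifier stored in the result.
#' @return An object of class \code{geneStat}: list with \code{f_value},
#'   \code{rae_null}, \code{rae_alt}, \code{loss}, \code{gene_id}.
#' @examples
#' tt <- rep(rep(c(0, 4, 8, 12), each = 2), 2)
#' gg <- rep(1:2, each = 8)
#' b <- makeSplineBasis(tt, p = 3)
#' y <- exp(-tt / 6) * (gg == 2) + rnorm(16, sd = 0.2)
#' geneFStatistic(y, gg, tt, b)$f_value
#' @export
geneFStatistic <- function(y, groups, times, basis,
                           loss = c("median", "mean"), gene_id = NULL) {
  loss <- match.arg(loss)
  groups <- factor(groups)
  X <- basisMatrix(basis, times)
  cnt <- table(groups)
  small <- cnt < ncol(X)
  if (any(small))
    stop(sprintf(
      "group(s) with fewer observations than basis parameters (p = %d): %s",
      ncol(X),
      paste(sprintf("%s (n = %d)", names(cnt)[small], cnt[small]),
            collapse = ", ")))
  fit <- .lossFitter(loss, basis)
  rae0 <- fit(y, X)
  raeAlt <- sum(vapply(levels(groups), function(g) {
    idx <- which(groups == g)
    fit(y[idx], X[idx, , drop = FALSE])
  }, 0))
  structure(list(f_value = .fRatio(rae0, raeAlt), rae_null = rae0,
                 rae_alt = raeAlt, loss = loss, gene_id = gene_id),
            class = "geneStat")
}

#' One-sample statistic: is a gene's trajectory time-dependent?
#'
#' Tests a flat trajectory \eqn{g(t) = c} against the spline alternative.
#' The null residual error is that of the best constant fit — the sample
#' median under median loss (the loss-consistent default) or the sample
#' mean under squared loss — and the alternative is the spline fit to the
#' same observations. F is the same residual-error ratio as the K-sample
#' statistic.
#'
#' @inheritParams geneFStatistic
#' @param center constant used under the null: \code{"median"} or
#'   \code{"mean"}; defaults to the estimator consistent with \code{loss}.
#' @return A \code{geneStat}.
#' @export
oneSampleStatistic <- function(y, times, basis, loss = c("median", "mean"),
                               center = NULL, gene_id = NULL) {
  loss <- match.arg(loss)
  if (is.null(center)) center <- if (loss == "median") "median" else "mean"
  center <- match.arg(center, c("median", "mean"))
  X <- basisMatrix(basis, times)
  if (length(y) < ncol(X))
    stop(sprintf("need at least p = %d observations, got %d",
                 ncol(X), length(y)))
  c0 <- if (center == "median") median(y) else mean(y)
  rae0 <- if (loss == "median") sum(abs(y - c0)) else sum((y - c0)^2)
  raeAlt <- .lossFitter(loss, basis)(y, X)
  structure(list(f_value = .fRatio(rae0, raeAlt), rae_null = rae0,
                 rae_alt = raeAlt, loss = loss, gene_id = gene_id),
            class = "geneStat")
}

#' Remove group-wise vertical shifts
#'
#' Subtracts, within each group, the group's overall sample mean of each
#' gene, so that genes differing between groups only by a constant vertical
#' offset (a typical batch artefact) no longer register a group effect.
#' Centering is idempotent.
#'
#' @param y numeric matrix (genes x samples) or vector (one gene).
#' @param groups group labels, one per sample.
#' @return centered values with the dimensions of \code{y}; within each
#'   group every gene has mean zero.
#' @export
centerByGroupMeans <- function(y, groups) {
  if (!is.factor(groups)) groups <- factor(groups)
  if (any(table(groups) == 0L) || anyNA(groups))
    stop("every group must be nonempty")
  vec <- is.null(dim(y))
  ym <- if (vec) matrix(y, nrow = 1L) else as.matrix(y)
  if (ncol(ym) != length(groups))
    stop("length of 'groups' must match the number of samples")
  for (g in levels(groups)) {
    idx <- which(groups == g)
    ym[, idx] <- ym[, idx, drop = FALSE] -
      rowMeans(ym[, idx, drop = FALSE])
  }
  if (vec) { out <- drop(ym); names(out) <- names(y); out } else ym
}

#' @export
print.geneStat <- function(x, ...) {
  cat(sprintf("%s-loss F-type statistic%s: F = %.6g (RAE0 = %.6g, RAEalt = %.6g)\n",
              x$loss, if (!is.null(x$gene_id)) paste0(" [", x$gene_id, "]") else "",
              x$f_value, x$rae_null, x$rae_alt))
  invisible(x)
}

# residual-error ratio with the infinity sentinel; tiny negative numerator
# from solver round-off is clamped at 0 (nesting guarantees F >= 0)
.fRatio <- function(rae0, raeAlt) {
  tol <- .Machine$double.eps^0.5 * (1 + abs(rae0))
  f <- ifelse(raeAlt <= tol,
              ifelse(rae0 <= tol, 0, Inf),
              (rae0 - raeAlt) / raeAlt)
  pmax(f, 0)
}

# single-gene residual-error evaluator for a loss
.lossFitter <- function(loss, basis) {
  if (loss == "median") {
    lam <- basis@lambda
    if (lam > 0) {
      D <- penaltyOperator(basis)
      function(y, X) fitMedianSpline(y, X, lambda = lam,
                                     penalty = D)$residual_error
    } else {
      function(y, X) .l1_fit_cpp(X, y, rep(1, length(y)))$objective
    }
  } else {
    function(y, X) sum(lm.fit(X, y)$residuals^2)
  }
}
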