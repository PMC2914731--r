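#' Fit one gene's trajectory under median (absolute-error) loss
#'
#' Minimises \eqn{\sum_i |y_i - X_i \beta|} (plus, when \code{lambda > 0},
#' a total-variation roughness penalty, see \code{\link{penaltyOperator}})
#' over the spline coefficient vector, solved exactly as a linear program
#' by a primal simplex on the residual-splitting formulation. This is the
#' conditional-median analogue of least squares: the fitted curve tracks
#' the median expression at each time, which is what makes the downstream
#' test robust to symmetric outlier contamination.
#'
#' L1 solutions need not have a unique coefficient vector (ties between
#' interpolating vertices); the solver returns one optimal vertex. The
#' attained objective — the only quantity the F-type statistic uses — is
#' unique at the optimum.
#'
#' @param y numeric response vector.
#' @param X design matrix with \code{length(y)} rows (see
#'   \code{\link{basisMatrix}}).
#' @param lambda nonnegative roughness penalty weight (default 0).
#' @param basis optional \linkS4class{SplineBasis} supplying the penalty
#'   operator when \code{lambda > 0}; alternatively pass \code{penalty}.
#' @param penalty optional penalty operator matrix (rows are functionals
#'   whose absolute values are penalised).
#' @return An object of class \code{geneFit}: a list with
#'   \code{coefficients}, \code{residual_error} (the unpenalised attained
#'   \eqn{\sum_i |y_i - X_i\hat\beta|}), \code{loss = "median"},
#'   \code{n_obs}, \code{iterations} and \code{rankDeficient}.
#' @examples
#' X <- cbind(1, 0:4)
#' fitMedianSpline(c(0, 1.1, 2, 2.9, 4), X)$residual_error
#' @export
fitMedianSpline <- function(y, X, lambda = 0, basis = NULL, penalty = NULL) {
  y <- as.numeric(y); X <- as.matrix(X)
  if (nrow(X) != length(y))
    stop("rows(X) must equal length(y)")
  if (nrow(X) < ncol(X))
    stop(sprintf("need at least as many observations (%d) as parameters (%d)",
                 nrow(X), ncol(X)))
  if (lambda < 0) stop("lambda must be >= 0")
  red <- .fullRankReduce(X)
  A <- red$X; n <- nrow(A)
  w <- rep(1, n); b <- y
  if (lambda > 0) {
    D <- if (!is.null(penalty)) as.matrix(penalty)
         else if (!is.null(basis)) penaltyOperator(basis)
         else stop("lambda > 0 requires a 'basis' or 'penalty' argument")
    if (ncol(D) == ncol(X) && !is.null(red$drop) && length(red$drop))
      D <- D[, -red$drop, drop = FALSE]
    if (nrow(D) > 0L) {
      A <- rbind(A, D)
      b <- c(b, rep(0, nrow(D)))
      w <- c(w, rep(lambda, nrow(D)))
    }
  }
  sol <- .l1_fit_cpp(A, b, w)
  beta <- rep(NA_real_, ncol(X))
  beta[red$keep] <- sol$coefficients
  names(beta) <- colnames(X)
  structure(list(coefficients = beta,
                 residual_error = sum(abs(y - red$X %*% sol$coefficients)),
                 loss = "median", n_obs = length(y),
                 iterations = sol$iterations,
                 rankDeficient = red$deficient),
            class = "geneFit")
}

#' Fit one gene's trajectory under squared-error loss
#'
#' Ordinary least-squares fit over the same design, used by the
#' mean-regression comparator pipeline. The residual error is the residual
#' sum of squares.
#'
#' @inheritParams fitMedianSpline
#' @return A \code{geneFit} with \code{loss = "mean"} and
#'   \code{residual_error} equal to the RSS.
#' @export
fitMeanSpline <- function(y, X) {
  y <- as.numeric(y); X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("rows(X) must equal length(y)")
  if (nrow(X) < ncol(X))
    stop(sprintf("need at least as many observations (%d) as parameters (%d)",
                 nrow(X), ncol(X)))
  red <- .fullRankReduce(X)
  fit <- lm.fit(red$X, y)
  beta <- rep(NA_real_, ncol(X))
  beta[red$keep] <- fit$coefficients
  names(beta) <- colnames(X)
  structure(list(coefficients = beta,
                 residual_error = sum(fit$residuals^2),
                 loss = "mean", n_obs = length(y),
                 iterations = NA_integer_,
                 rankDeficient = red$deficient),
            class = "geneFit")
}

#' @export
print.geneFit <- function(x, ...) {
  cat(sprintf("%s-loss spline fit: n = %d, residual error = %.6g%s\n",
              x$loss, x$n_obs, x$residual_error,
              if (isTRUE(x$rankDeficient)) " (rank-deficient design)" else ""))
  invisible(x)
}

# reduce X to a full-column-rank pivot subset (flagged), keeping column order
.fullRankReduce <- function(X) {
  qd <- qr(X)
  if (qd$rank == ncol(X))
    return(list(X = X, keep = seq_len(ncol(X)), drop = integer(),
                deficient = FALSE))
  keep <- sort(qd$pivot[seq_len(qd$rank)])
  list(X = X[, keep, drop = FALSE], keep = keep,
       drop = setdiff(seq_len(ncol(X)), keep), deficient = TRUE)
}
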