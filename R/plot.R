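#' Plot observed expressions and fitted trajectories for one gene
#'
#' A minimal diagnostic figure: observed points per group against time,
#' with the group-wise fitted curves (solid) and the pooled null curve
#' (dashed grey) under the chosen loss.
#'
#' @param x a \linkS4class{TimecourseExperiment}.
#' @param gene gene identifier (row name) or row index.
#' @param basis optional \linkS4class{SplineBasis}; defaults to the
#'   standard basis built from the pooled sample times.
#' @param loss \code{"median"} or \code{"mean"}.
#' @param nGrid number of evaluation points for the curves.
#' @param ... further arguments passed to \code{plot}.
#' @return invisibly, a list with the per-group coefficient vectors.
#' @export
plotTrajectories <- function(x, gene = 1L, basis = NULL,
                             loss = c("median", "mean"), nGrid = 200, ...) {
  stopifnot(is(x, "TimecourseExperiment"))
  loss <- match.arg(loss)
  y <- assay(x)[gene, ]
  groups <- sampleGroups(x)
  times <- sampleTimes(x)
  if (is.null(basis)) basis <- makeSplineBasis(times)
  X <- basisMatrix(basis, times)
  fit1 <- function(idx) {
    if (loss == "median") fitMedianSpline(y[idx], X[idx, , drop = FALSE],
                                          lambda = basis@lambda,
                                          basis = basis)$coefficients
    else fitMeanSpline(y[idx], X[idx, , drop = FALSE])$coefficients
  }
  coefs <- lapply(stats::setNames(levels(groups), levels(groups)),
                  function(g) fit1(which(groups == g)))
  pooled <- fit1(seq_along(y))
  tg <- seq(basis@boundary[1], basis@boundary[2], length.out = nGrid)
  Xg <- basisMatrix(basis, tg)
  cols <- seq_len(nlevels(groups)) + 1L
  graphics::plot(times, y, col = cols[as.integer(groups)],
                 pch = c(4, 1, 2, 5)[(as.integer(groups) - 1L) %% 4 + 1L],
                 xlab = "time", ylab = "expression",
                 main = if (is.character(gene)) gene
                        else rownames(assay(x))[gene], ...)
  graphics::lines(tg, Xg %*% ifelse(is.na(pooled), 0, pooled),
                  lty = 2, col = "grey40")
  for (k in seq_along(coefs))
    graphics::lines(tg, Xg %*% ifelse(is.na(coefs[[k]]), 0, coefs[[k]]),
                    col = cols[k], lwd = 2)
  graphics::legend("topright", bty = "n",
                   legend = c(levels(groups), "pooled (null)"),
                   col = c(cols, "grey40"),
                   lty = c(rep(1, length(coefs)), 2))
  invisible(coefs)
}
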