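#' The full benchmark scenario grid
#'
#' All combinations of outlier probability \code{pi} in {0, 0.05, 0.1},
#' block correlation \code{rho} in {0, 0.3, 0.6} and contamination model
#' {1, 2} — 18 cells. Model 2 with \code{pi = 0} coincides with model 1
#' (no outliers to restrict), and is kept so the grid is complete.
#'
#' @return data.frame with columns \code{model}, \code{pi}, \code{rho} and
#'   a per-cell \code{cell} index used to derive per-cell seeds.
#' @export
benchmarkScenarios <- function() {
  g <- expand.grid(pi = c(0, 0.05, 0.1), rho = c(0, 0.3, 0.6),
                   model = c(1L, 2L))[, c("model", "pi", "rho")]
  g <- g[order(g$model, g$pi, g$rho), ]
  rownames(g) <- NULL
  g$cell <- seq_len(nrow(g))
  g
}

#' Run a grid of simulation scenarios
#'
#' Evaluates empirical FWER (when \code{mProg = 0}) or global power (when
#' \code{mProg >= 1}) for every cell of a scenario grid, for one or more
#' methods, with a distinct reproducible seed per cell
#' (\code{baseSeed + cell}). The full-scale benchmark is
#' \code{runScenarioGrid(benchmarkScenarios(), m = 200, N = 200, B = 200)}
#' for FWER and the same with \code{mProg = 10} for power (see
#' \code{scripts/full_simulation.R} in the installed package sources).
#'
#' @param cells data.frame with columns \code{model}, \code{pi},
#'   \code{rho} and optionally \code{cell} (defaults to the row number).
#' @param m,mProg,N,B,alpha,nPerGroupTime scenario parameters shared by all
#'   cells, see \code{\link{simConfig}}.
#' @param methods methods to evaluate on identical datasets per cell.
#' @param baseSeed integer; cell i uses seed \code{baseSeed + cell_i}.
#' @param verbose print one line per completed cell.
#' @return data.frame, one row per cell x method, in the layout of
#'   \code{\link{summaryTable}}.
#' @export
runScenarioGrid <- function(cells = benchmarkScenarios(), m = 200,
                            mProg = 0, N = 200, B = 200, alpha = 0.05,
                            nPerGroupTime = 4,
                            methods = c("median_perm", "mean_perm"),
                            baseSeed = 1, verbose = FALSE) {
  stopifnot(all(c("model", "pi", "rho") %in% names(cells)))
  if (is.null(cells$cell)) cells$cell <- seq_len(nrow(cells))
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cfg <- simConfig(m = m, mProg = mProg, pi = cells$pi[i],
                     rho = cells$rho[i], model = cells$model[i], N = N,
                     B = B, alpha = alpha, nPerGroupTime = nPerGroupTime,
                     seed = baseSeed + cells$cell[i])
    s <- if (mProg == 0) estimateFWER(cfg, methods)
         else estimatePower(cfg, methods)
    tab <- summaryTable(s)
    tab$cell <- cells$cell[i]
    out[[i]] <- tab
    if (verbose)
      message(sprintf("cell %d (model %d, pi %g, rho %g): %s",
                      cells$cell[i], cells$model[i], cells$pi[i],
                      cells$rho[i],
                      paste(sprintf("%s %.3f", tab$method, tab$proportion),
                            collapse = ", ")))
  }
  do.call(rbind, out)
}

#' Read a scenario file
#'
#' Scenario files are YAML or JSON mappings of \code{\link{simConfig}}
#' argument names to values; unknown keys are an error.
#'
#' @param path file path ending in .yaml/.yml or .json.
#' @return A \linkS4class{SimConfig}.
#' @export
readScenario <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    yaml = , yml = {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML scenarios requires the 'yaml' package")
      yaml::read_yaml(path)
    },
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop(sprintf("unsupported scenario format '.%s' (use .yaml or .json)",
                 ext)))
  known <- names(formals(simConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop(sprintf("unknown scenario key(s): %s (known: %s)",
                 paste(bad, collapse = ", "), paste(known, collapse = ", ")))
  do.call(simConfig, vals)
}
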