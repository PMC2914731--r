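#' Create a simulation scenario
#'
#' Defaults reproduce the benchmark design: 2 groups observed at the 11
#' time-points 0..8, 10, 12 hours with 4 replicates per group per
#' time-point; standard-normal measurement errors with optional
#' block-exchangeable gene-gene correlation (blocks of 10 genes); symmetric
#' outlier contamination adding +-4 with probability pi/2 each (model 1 at
#' every time-point, model 2 only at the first and last); prognostic genes
#' carry the group-2 trajectory \eqn{1.5 e^{-t}} while group 1 stays flat
#' at zero. The median of the error law is zero for every pi, so the
#' median-regression estimand is untouched by the contamination — the
#' premise the robust test exploits.
#'
#' @param m total genes.
#' @param mProg prognostic genes (0 = global-null scenario). Placed in
#'   distinct correlation blocks (the first gene of each of the first
#'   \code{mProg} blocks).
#' @param timeGrid observation times.
#' @param nPerGroupTime replicates per group per time-point.
#' @param pi outlier probability in [0, 1].
#' @param outlierMagnitude absolute outlier shift.
#' @param rho block-exchangeable error correlation in [0, 1).
#' @param blockSize genes per correlation block.
#' @param model 1 = outliers at all time-points; 2 = first and last only.
#' @param effectScale amplitude of the prognostic group-2 trajectory.
#' @param N simulated datasets per scenario.
#' @param B permutations per dataset.
#' @param alpha FWER level of the rejection rule.
#' @param seed scenario RNG seed.
#' @return A \linkS4class{SimConfig}.
#' @export
simConfig <- function(m = 200, mProg = 0, timeGrid = c(0:8, 10, 12),
                      nPerGroupTime = 4, pi = 0, outlierMagnitude = 4,
                      rho = 0, blockSize = 10, model = 1,
                      effectScale = 1.5, N = 200, B = 200, alpha = 0.05,
                      seed = 1) {
  new("SimConfig", m = as.integer(m), mProg = as.integer(mProg),
      timeGrid = as.numeric(timeGrid),
      nPerGroupTime = as.integer(nPerGroupTime), pi = as.numeric(pi),
      outlierMagnitude = as.numeric(outlierMagnitude),
      rho = as.numeric(rho), blockSize = as.integer(blockSize),
      model = as.integer(model), effectScale = as.numeric(effectScale),
      N = as.integer(N), B = as.integer(B), alpha = as.numeric(alpha),
      seed = as.integer(seed))
}

# raw generator sharing the caller's RNG stream; draw order is fixed
# (measurement errors, block factors, outlier uniforms) so runs are
# reproducible from a single seed
.simulateRaw <- function(config) {
  tg <- config@timeGrid
  r <- config@nPerGroupTime
  nPerGroup <- length(tg) * r
  times <- rep(rep(tg, each = r), 2L)
  groups <- factor(rep(1:2, each = nPerGroup))
  n <- length(times)
  m <- config@m
  nb <- ceiling(m / config@blockSize)
  block <- rep(seq_len(nb), each = config@blockSize)[seq_len(m)]
  prog <- logical(m)
  if (config@mProg > 0L) {
    if (config@mProg > nb)
      stop(sprintf(
        "cannot place %d prognostic genes in %d distinct blocks; increase m or decrease blockSize",
        config@mProg, nb))
    prog[match(seq_len(config@mProg), block)] <- TRUE
  }
  E <- matrix(rnorm(m * n), m, n)
  if (config@rho > 0) {
    Z <- matrix(rnorm(nb * n), nb, n)
    E <- sqrt(config@rho) * Z[block, , drop = FALSE] +
         sqrt(1 - config@rho) * E
  }
  A <- matrix(0, m, n)
  if (config@pi > 0) {
    U <- matrix(runif(m * n), m, n)
    A <- config@outlierMagnitude *
      ((U >= 1 - config@pi / 2) - (U < config@pi / 2))
    if (config@model == 2L)
      A[, !(times %in% range(tg))] <- 0
  }
  Y <- A + E
  if (any(prog)) {
    g2 <- which(groups == "2")
    Y[prog, g2] <- Y[prog, g2, drop = FALSE] +
      rep(config@effectScale * exp(-times[g2]), each = sum(prog))
  }
  rownames(Y) <- sprintf("gene_%d", seq_len(m))
  list(Y = Y, groups = groups, times = times, prognostic = prog,
       outliers = A, block = block)
}

#' Generate one synthetic time-course dataset
#'
#' Draws one dataset from the scenario's outlier-contaminated additive
#' model using the \emph{current} RNG stream (call \code{set.seed} first,
#' or use \code{\link{estimateFWER}} / \code{\link{estimatePower}} which
#' seed from the config). Truth labels and the realised outlier shifts are
#' returned alongside the expression container.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list with \code{experiment}
#'   (\linkS4class{TimecourseExperiment}), \code{prognostic} (logical per
#'   gene), \code{outliers} (the realised shift matrix), \code{block}
#'   (correlation block per gene).
#' @examples
#' set.seed(11)
#' d <- simulateDataset(simConfig(m = 20, mProg = 2, pi = 0.1))
#' table(d$prognostic)
#' @export
simulateDataset <- function(config) {
  stopifnot(is(config, "SimConfig"))
  d <- .simulateRaw(config)
  list(experiment = TimecourseExperiment(d$Y, d$groups, d$times),
       prognostic = d$prognostic, outliers = d$outliers, block = d$block)
}

# shared Monte-Carlo driver; several methods analyse identical datasets and
# identical permutation draws in one pass
.runSimulation <- function(config, methods, metric) {
  stopifnot(is(config, "SimConfig"))
  methods <- match.arg(methods, c("median_perm", "mean_perm"),
                       several.ok = TRUE)
  losses <- sub("_perm$", "", methods)
  set.seed(config@seed)
  basis <- NULL
  rej <- matrix(FALSE, config@N, length(methods),
                dimnames = list(NULL, methods))
  for (i in seq_len(config@N)) {
    d <- .simulateRaw(config)
    if (is.null(basis)) basis <- makeSplineBasis(d$times)
    eng <- .permEngine(d$Y, d$groups, d$times, basis, losses = losses,
                       B = config@B, scheme = "within_timepoint")
    for (j in seq_along(methods)) {
      loss <- losses[j]
      pFwer <- adjustFwerSingleStep(eng$f_obs[[loss]], eng$f_null[[loss]])
      rej[i, j] <- any(pFwer <= config@alpha)
    }
  }
  out <- lapply(seq_along(methods), function(j) {
    v <- mean(rej[, j])
    new("SimSummary", method = methods[j], metric = metric,
        proportion = v, mcSE = sqrt(v * (1 - v) / config@N),
        rejections = as.integer(sum(rej[, j])), N = config@N,
        config = config)
  })
  names(out) <- methods
  if (length(out) == 1L) out[[1L]] else out
}

#' Empirical family-wise error rate of a scenario
#'
#' Runs the full pipeline (basis, statistics, permutation null, maxT) on
#' each of N datasets generated under the global null and reports the
#' proportion with at least one rejection at the scenario alpha, with its
#' binomial Monte-Carlo standard error. Fully reproducible from
#' \code{config@seed}.
#'
#' @param config a \linkS4class{SimConfig} with \code{mProg = 0}.
#' @param method \code{"median_perm"} (robust test), \code{"mean_perm"}
#'   (least-squares comparator), or both: multiple methods are evaluated on
#'   identical datasets and permutation draws.
#' @return A \linkS4class{SimSummary}, or a named list of them when several
#'   methods are requested.
#' @export
estimateFWER <- function(config, method = "median_perm") {
  if (config@mProg != 0L)
    stop("FWER scenarios require mProg = 0 (global null)")
  .runSimulation(config, method, "fwer")
}

#' Empirical global power of a scenario
#'
#' As \code{\link{estimateFWER}} but with prognostic genes present:
#' reports the proportion of datasets rejecting at least one null
#' hypothesis (any gene) at the scenario alpha — the global power.
#'
#' @inheritParams estimateFWER
#' @param config a \linkS4class{SimConfig} with \code{mProg >= 1}.
#' @export
estimatePower <- function(config, method = "median_perm") {
  if (config@mProg < 1L)
    stop("power scenarios require mProg >= 1")
  .runSimulation(config, method, "power")
}

setMethod("show", "SimSummary", function(object) {
  cfg <- object@config
  cat(sprintf(
    "%s %s: %.3f (MC SE %.4f; %d/%d datasets)\n",
    object@method, toupper(object@metric), object@proportion, object@mcSE,
    object@rejections, object@N))
  cat(sprintf(
    "scenario: model %d, pi = %g, rho = %g, m = %d (%d prognostic), B = %d, alpha = %g, seed = %d\n",
    cfg@model, cfg@pi, cfg@rho, cfg@m, cfg@mProg, cfg@B, cfg@alpha,
    cfg@seed))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: model %d, pi = %g, rho = %g (blocks of %d), m = %d genes (%d prognostic)\n",
    object@model, object@pi, object@rho, object@blockSize, object@m,
    object@mProg))
  cat(sprintf(
    "design: %d time-points x %d reps/group, 2 groups; N = %d, B = %d, alpha = %g, seed = %d\n",
    length(object@timeGrid), object@nPerGroupTime, object@N, object@B,
    object@alpha, object@seed))
})

#' Flatten simulation summaries to a data.frame
#'
#' @param x a \linkS4class{SimSummary} or a (possibly nested) list of them.
#' @return data.frame with one row per summary: method, metric, model, pi,
#'   rho, m, mProg, N, B, proportion, mcSE, seed.
#' @export
summaryTable <- function(x) {
  if (is(x, "SimSummary")) x <- list(x)
  x <- unlist(x, recursive = TRUE)
  do.call(rbind, lapply(x, function(s) {
    cfg <- s@config
    data.frame(method = s@method, metric = s@metric, model = cfg@model,
               pi = cfg@pi, rho = cfg@rho, m = cfg@m, mProg = cfg@mProg,
               N = s@N, B = cfg@B, proportion = s@proportion, mcSE = s@mcSE,
               seed = cfg@seed)
  }))
}
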