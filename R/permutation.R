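#' Number of distinct within-time-point permutations
#'
#' Under the null, observations are exchangeable within each time-point, so
#' the exact permutation distribution has one atom per distinct assignment
#' of group labels within each time-point: the product over time-points of
#' the multinomial coefficients \eqn{n_{\cdot l}! / \prod_k n_{kl}!}. This
#' is usually far too large to enumerate (the benchmark design gives
#' \eqn{\binom{8}{4}^{11} = 70^{11}}), which is why the null is approximated
#' by B random permutations.
#'
#' @param design a \linkS4class{TimeDesign} or
#'   \linkS4class{TimecourseExperiment}.
#' @return a double; exact whenever the count is below 2^53 (no big-integer
#'   arithmetic is used).
#' @examples
#' d <- new("TimeDesign", times = c(0, 6), groups = c("1", "2"),
#'          counts = matrix(2L, 2, 2))
#' countPermutations(d)  # choose(4, 2)^2 = 36
#' @export
countPermutations <- function(design) {
  if (is(design, "TimecourseExperiment")) design <- timeDesign(design)
  stopifnot(is(design, "TimeDesign"))
  counts <- design@counts
  prod(vapply(seq_len(ncol(counts)), function(l) {
    nk <- counts[, l]
    left <- sum(nk)
    v <- 1
    for (k in seq_along(nk)) {
      v <- v * choose(left, nk[k])
      left <- left - nk[k]
    }
    v
  }, 0))
}

#' Draw one permutation of sample indices
#'
#' For the K-sample test (\code{"within_timepoint"}) the permutation maps
#' each time-point's index set onto itself, so group labels are shuffled
#' only among samples observed at the same time — the exchangeability cell
#' under the null. For the one-sample test (\code{"all_exchangeable"}) all
#' samples are exchangeable and the permutation is unrestricted. Draws are
#' uniform over the allowed set and come from R's RNG stream (seed with
#' \code{set.seed} for reproducibility).
#'
#' @param times numeric observation times, one per sample.
#' @param scheme permutation scheme.
#' @return integer vector \code{perm} such that permuted sample i carries
#'   the original observation \code{perm[i]}.
#' @export
drawPermutation <- function(times,
                            scheme = c("within_timepoint",
                                       "all_exchangeable")) {
  scheme <- match.arg(scheme)
  n <- length(times)
  if (scheme == "all_exchangeable") return(sample.int(n))
  perm <- seq_len(n)
  for (t in unique(times)) {
    pos <- which(times == t)
    perm[pos] <- pos[sample.int(length(pos))]
  }
  perm
}

#' Permutation null matrix of F-type statistics
#'
#' Computes the observed per-gene statistics and a B x m matrix of
#' permutation replicates. One permutation per replicate is applied to all
#' genes jointly (columns move together), preserving the gene-gene
#' correlation structure that the maxT adjustment relies on. Statistics for
#' observed and permuted data are computed by the identical code path and
#' solver settings.
#'
#' The pooled-fit residual error is invariant under within-time-point
#' permutation (the (expression, time) pairs are unchanged; only group
#' labels move), as is the constant-fit null of the one-sample test, so
#' only the alternative fits are recomputed per replicate.
#'
#' @param x a \linkS4class{TimecourseExperiment}.
#' @param basis a \linkS4class{SplineBasis}; built from the pooled sample
#'   times with defaults when \code{NULL}.
#' @param B number of random permutations (ignored when
#'   \code{permutations} is supplied).
#' @param loss \code{"median"} or \code{"mean"}.
#' @param scheme permutation scheme; defaults to within-time-point for the
#'   K-sample test and all-exchangeable for the one-sample test.
#' @param seed optional integer seed applied before drawing permutations.
#' @param permutations optional matrix (rows = replicates) of explicit
#'   sample-index permutations, e.g. the exhaustive enumeration of a small
#'   design.
#' @param oneSample use the one-sample (time-dependence) statistic.
#' @return list with \code{f_obs} (length m), \code{f_null} (B x m),
#'   \code{permutations}, \code{scheme}.
#' @export
permutationNull <- function(x, basis = NULL, B = 200,
                            loss = c("median", "mean"), scheme = NULL,
                            seed = NULL, permutations = NULL,
                            oneSample = FALSE) {
  loss <- match.arg(loss)
  stopifnot(is(x, "TimecourseExperiment"))
  if (is.null(basis)) basis <- makeSplineBasis(sampleTimes(x))
  if (is.null(scheme))
    scheme <- if (oneSample) "all_exchangeable" else "within_timepoint"
  if (!is.null(seed)) set.seed(seed)
  eng <- .permEngine(assay(x), sampleGroups(x), sampleTimes(x), basis,
                     losses = loss, B = B, scheme = scheme,
                     permutations = permutations, oneSample = oneSample)
  list(f_obs = eng$f_obs[[loss]], f_null = eng$f_null[[loss]],
       permutations = eng$permutations, scheme = scheme)
}

#' Unadjusted permutation p-values
#'
#' \eqn{p_j = B^{-1} \sum_b 1\{F^*_{bj} \ge F_j\}}: the fraction of
#' replicates whose statistic for gene j reaches the observed one, ties
#' counting as extreme. With \code{floor = TRUE} the conservative
#' \eqn{(\#+1)/(B+1)} estimator is used instead, which can never return 0.
#'
#' @param fObs numeric length-m vector of observed statistics.
#' @param fNull B x m matrix of permutation statistics.
#' @param floor use the add-one estimator (default \code{FALSE}, matching
#'   the plain frequency definition).
#' @return numeric p-values, one per gene.
#' @export
unadjustedPvalues <- function(fObs, fNull, floor = FALSE) {
  .checkNullDims(fObs, fNull)
  B <- nrow(fNull)
  cnt <- colSums(fNull >= matrix(fObs, B, length(fObs), byrow = TRUE))
  if (floor) (cnt + 1) / (B + 1) else cnt / B
}

#' Single-step maxT FWER-adjusted p-values
#'
#' For each replicate b let \eqn{M_b = \max_j F^*_{bj}}; the adjusted
#' p-value of gene j is the fraction of replicates with \eqn{M_b \ge F_j}.
#' Comparing every gene against the common max-statistic distribution makes
#' the adjusted p-values monotone in the observed statistics and controls
#' the probability of any false rejection under the global null. A gene is
#' called significant when its adjusted p-value is \eqn{\le \alpha}
#' (ties-to-significant convention).
#'
#' @inheritParams unadjustedPvalues
#' @return numeric FWER-adjusted p-values, elementwise at least the
#'   unadjusted ones.
#' @examples
#' adjustFwerSingleStep(c(5, 1), rbind(c(2, 0), c(4, 1), c(6, 2)))
#' @export
adjustFwerSingleStep <- function(fObs, fNull, floor = FALSE) {
  .checkNullDims(fObs, fNull)
  B <- nrow(fNull)
  M <- apply(fNull, 1L, max)
  cnt <- vapply(fObs, function(f) sum(M >= f), 0)
  if (floor) (cnt + 1) / (B + 1) else cnt / B
}

#' Benjamini-Hochberg FDR-adjusted p-values
#'
#' Step-up adjustment of the unadjusted permutation p-values, for analyses
#' targeting the false-discovery rate instead of the FWER.
#'
#' @param p numeric p-values in [0, 1].
#' @return adjusted p-values (monotone, capped at 1).
#' @export
adjustFdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

.checkNullDims <- function(fObs, fNull) {
  if (!length(fObs) || !nrow(fNull))
    stop("empty inputs: need m >= 1 genes and B >= 1 replicates")
  if (ncol(fNull) != length(fObs))
    stop(sprintf("fNull has %d columns but fObs has length %d",
                 ncol(fNull), length(fObs)))
}

# Shared permutation engine: computes observed and replicate statistics for
# one or both losses on the same permutation stream. Exploits the
# permutation-invariance of the null (pooled or constant) fit and the fact
# that each group's design rows are a fixed multiset under the
# within-time-point scheme.
.permEngine <- function(Y, groups, times, basis, losses, B, scheme,
                        permutations = NULL, oneSample = FALSE) {
  Y <- as.matrix(Y)
  groups <- factor(groups)
  X <- basisMatrix(basis, times)
  p <- ncol(X)
  if (oneSample) {
    if (ncol(Y) < p)
      stop(sprintf("need at least p = %d observations, got %d", p, ncol(Y)))
  } else {
    cnt <- table(groups)
    small <- cnt < p
    if (any(small))
      stop(sprintf(
        "group(s) with fewer observations than basis parameters (p = %d): %s",
        p, paste(sprintf("%s (n = %d)", names(cnt)[small], cnt[small]),
                 collapse = ", ")))
  }
  if (is.null(permutations)) {
    permutations <- t(vapply(seq_len(B),
                             function(b) drawPermutation(times, scheme),
                             integer(length(times))))
  } else {
    permutations <- as.matrix(permutations)
    B <- nrow(permutations)
  }

  medianRae <- function(Xg) {
    if (basis@lambda > 0) {
      D <- penaltyOperator(basis)
      function(Yg) vapply(seq_len(ncol(Yg)), function(j)
        fitMedianSpline(Yg[, j], Xg, lambda = basis@lambda,
                        penalty = D)$residual_error, 0)
    } else {
      function(Yg) as.numeric(.l1_obj_batch_cpp(Xg, Yg))
    }
  }
  meanRae <- function(Xg) {
    Q <- qr.Q(qr(Xg))
    function(Yg) colSums(Yg^2) - colSums(crossprod(Q, Yg)^2)
  }
  raeFun <- function(loss, Xg) if (loss == "median") medianRae(Xg)
                               else meanRae(Xg)

  m <- nrow(Y)
  tY <- t(Y)
  fObs <- fNull <- stats::setNames(vector("list", length(losses)), losses)

  if (oneSample) {
    const0 <- list(
      median = function() rowSums(abs(Y - apply(Y, 1L, median))),
      mean   = function() rowSums((Y - rowMeans(Y))^2))
    for (loss in losses) {
      rae0 <- const0[[loss]]()
      alt <- raeFun(loss, X)
      fObs[[loss]] <- .fRatio(rae0, alt(tY))
      fn <- matrix(0, B, m)
      for (b in seq_len(B))
        fn[b, ] <- .fRatio(rae0, alt(tY[permutations[b, ], , drop = FALSE]))
      fNull[[loss]] <- fn
    }
  } else {
    G <- split(seq_along(groups), groups)
    fitters <- lapply(losses, function(loss) {
      list(pool = raeFun(loss, X),
           grp = lapply(G, function(idx) raeFun(loss, X[idx, , drop = FALSE])))
    })
    names(fitters) <- losses
    for (loss in losses) {
      ft <- fitters[[loss]]
      rae0 <- ft$pool(tY)
      altFor <- function(perm) {
        alt <- 0
        for (k in seq_along(G))
          alt <- alt + ft$grp[[k]](tY[perm[G[[k]]], , drop = FALSE])
        alt
      }
      fObs[[loss]] <- .fRatio(rae0, altFor(seq_along(groups)))
      fn <- matrix(0, B, m)
      for (b in seq_len(B))
        fn[b, ] <- .fRatio(rae0, altFor(permutations[b, ]))
      fNull[[loss]] <- fn
    }
  }
  list(f_obs = fObs, f_null = fNull, permutations = permutations,
       scheme = scheme, basis = basis)
}
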