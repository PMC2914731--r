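# Independent oracles and fixture builders used across the suite.

# brute-force LAD optimum: an optimal L1 fit interpolates p affinely
# independent observations, so enumerate all p-subsets
l1EnumObjective <- function(y, X) {
  n <- nrow(X); p <- ncol(X)
  best <- Inf
  for (s in utils::combn(n, p, simplify = FALSE)) {
    Xs <- X[s, , drop = FALSE]
    if (abs(det(Xs)) < 1e-10) next
    b <- solve(Xs, y[s])
    best <- min(best, sum(abs(y - X %*% b)))
  }
  best
}

# independent piecewise-linear construction: intercept, slope, and hinges
# max(0, t - k) at the interior knots
hingeDesign <- function(times, knots) {
  interior <- knots[-c(1L, length(knots))]
  H <- cbind(1, times)
  for (k in interior) H <- cbind(H, pmax(0, times - k))
  H
}

permsOf <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in permsOf(v[-i])) out <- c(out, list(c(v[i], rest)))
  out
}

# every permutation of sample indices mapping each time-point onto itself
enumerateWithinTimepoint <- function(times) {
  ut <- unique(times)
  parts <- lapply(ut, function(t) permsOf(which(times == t)))
  grid <- expand.grid(lapply(parts, seq_along))
  t(apply(grid, 1L, function(g) {
    perm <- seq_along(times)
    for (j in seq_along(parts)) {
      pos <- which(times == ut[j])
      perm[pos] <- parts[[j]][[g[j]]]
    }
    perm
  }))
}

# small two-group experiment on a short grid
toyExperiment <- function(m = 4, tg = c(0, 2, 4, 8), reps = 2, seed = 1,
                          shift2 = 0) {
  set.seed(seed)
  times <- rep(rep(tg, each = reps), 2)
  groups <- rep(1:2, each = length(tg) * reps)
  Y <- matrix(rnorm(m * length(times)), m)
  if (shift2 != 0) Y[, groups == 2] <- Y[, groups == 2] + shift2
  rownames(Y) <- sprintf("g%d", seq_len(m))
  TimecourseExperiment(Y, groups, times)
}

simGridTimes <- function(reps = 8) rep(c(0:8, 10, 12), each = reps)
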