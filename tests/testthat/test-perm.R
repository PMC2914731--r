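test_that("permutation counts match enumeration and the closed form", {
  d1 <- new("TimeDesign", times = 0, groups = c("a", "b"),
            counts = matrix(2L, 2, 1))
  expect_equal(countPermutations(d1), choose(4, 2))
  d2 <- new("TimeDesign", times = c(0, 1), groups = c("a", "b"),
            counts = matrix(1L, 2, 2))
  expect_equal(countPermutations(d2), 4)
  # benchmark design: choose(8, 4) per time-point over 11 time-points
  d3 <- new("TimeDesign", times = c(0:8, 10, 12), groups = c("a", "b"),
            counts = matrix(4L, 2, 11))
  expect_equal(countPermutations(d3), choose(8, 4)^11)
  # enumeration oracle on one time-point: distinct label assignments
  times <- rep(0, 4); labels <- c("a", "a", "b", "b")
  perms <- enumerateWithinTimepoint(times)
  assignments <- unique(apply(perms, 1, function(p) paste(labels[p],
                                                          collapse = "")))
  expect_equal(countPermutations(d1), length(assignments))
})

test_that("draws are uniform, closed within time-points, reproducible", {
  set.seed(501)
  draws <- replicate(6000, paste(drawPermutation(rep(0, 3)), collapse = ""))
  tab <- table(factor(draws, levels = apply(enumerateWithinTimepoint(rep(0, 3)),
                                            1, paste, collapse = "")))
  expect_length(tab, 6)
  expect_gt(chisq.test(tab)$p.value, 1e-3)
  times <- rep(c(0, 4, 9), times = c(3, 2, 4))
  for (i in 1:20) {
    p <- drawPermutation(times)
    for (t in unique(times))
      expect_setequal(p[times == t], which(times == t))
  }
  set.seed(99); a <- replicate(5, drawPermutation(times))
  set.seed(99); b <- replicate(5, drawPermutation(times))
  expect_identical(a, b)
  set.seed(1)
  expect_setequal(drawPermutation(times, "all_exchangeable"), 1:9)
})

test_that("maxT and unadjusted p-values match hand computations", {
  fNull <- rbind(c(2, 0), c(4, 1), c(6, 2))
  expect_equal(adjustFwerSingleStep(c(5, 1), fNull), c(1/3, 1))
  expect_equal(unadjustedPvalues(3, cbind(c(1, 3, 5, 7))), 3/4)
  expect_equal(unadjustedPvalues(2, cbind(rep(2, 5))), 1)
  # all replicates below all observed: zero, or the floor 1/(B+1)
  low <- matrix(0.1, 4, 2)
  expect_equal(adjustFwerSingleStep(c(5, 7), low), c(0, 0))
  expect_equal(adjustFwerSingleStep(c(5, 7), low, floor = TRUE),
               c(1/5, 1/5))
  # single gene: maxT degenerates to the unadjusted p-value
  f1 <- cbind(rexp(20))
  expect_identical(adjustFwerSingleStep(2, f1), unadjustedPvalues(2, f1))
  expect_error(unadjustedPvalues(numeric(), matrix(0, 0, 0)), "empty")
})

test_that("FDR adjustment matches the step-up closed form", {
  expect_equal(adjustFdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(adjustFdr(rep(1, 4)), rep(1, 4))
  expect_equal(adjustFdr(0.2), 0.2)
  expect_error(adjustFdr(c(0.5, 1.2)), "0, 1")
})

test_that("adjusted p-values dominate unadjusted ones and are monotone in F", {
  set.seed(502)
  for (i in 1:100) {
    m <- sample(2:6, 1); B <- sample(5:40, 1)
    fObs <- rexp(m); fNull <- matrix(rexp(B * m), B)
    pu <- unadjustedPvalues(fObs, fNull)
    pf <- adjustFwerSingleStep(fObs, fNull)
    expect_true(all(pf >= pu))
    ord <- order(fObs, decreasing = TRUE)
    expect_true(all(diff(pf[ord]) >= 0))
    expect_true(all(pu >= 1 / B - 1e-12 | pu == 0))
  }
})

test_that("null matrix respects joint permutation structure", {
  # expression constant within each time-point: permutations cannot move
  # anything, so every replicate statistic is exactly zero
  tt <- rep(rep(c(0, 3, 6), each = 2), 2)
  v <- c(1.2, -0.4, 2.5)
  y1 <- v[match(rep(c(0, 3, 6), each = 2), c(0, 3, 6))]
  Y <- rbind(c(y1, y1), c(2 * y1, 2 * y1))
  tce <- TimecourseExperiment(Y, rep(1:2, each = 6), tt)
  pn <- permutationNull(tce, makeSplineBasis(tt, p = 2), B = 15, seed = 3)
  expect_true(all(pn$f_obs == 0) && all(pn$f_null == 0))
  # shuffling gene order shuffles statistic columns identically
  set.seed(503)
  Y2 <- matrix(rnorm(4 * 12), 4)
  t2 <- TimecourseExperiment(Y2, rep(1:2, each = 6), tt)
  t3 <- TimecourseExperiment(Y2[4:1, ], rep(1:2, each = 6), tt)
  b <- makeSplineBasis(tt, p = 2)
  perms <- t(replicate(10, drawPermutation(tt)))
  p2 <- permutationNull(t2, b, permutations = perms)
  p3 <- permutationNull(t3, b, permutations = perms)
  expect_equal(p3$f_null, p2$f_null[, 4:1])
  expect_equal(p3$f_obs, p2$f_obs[4:1])
})

test_that("explicit permutations reproduce a manual single-replicate computation", {
  set.seed(504)
  tt <- rep(rep(c(0, 5, 10), each = 2), 2)
  gg <- rep(1:2, each = 6)
  Y <- matrix(rnorm(3 * 12), 3)
  tce <- TimecourseExperiment(Y, gg, tt)
  b <- makeSplineBasis(tt, p = 2)
  perm <- drawPermutation(tt)
  pn <- permutationNull(tce, b, permutations = rbind(perm))
  manual <- vapply(1:3, function(j)
    geneFStatistic(Y[j, perm], gg, tt, b)$f_value, 0)
  expect_equal(drop(pn$f_null), manual, tolerance = 1e-9)
})
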