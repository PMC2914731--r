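grid4 <- rep(rep(c(0, 2, 4, 8), each = 2), 2)
groups4 <- rep(1:2, each = 8)
basis4 <- makeSplineBasis(grid4, p = 3)

test_that("identical groups give F = 0; separation drives F up", {
  set.seed(401)
  y1 <- rnorm(8)
  expect_equal(geneFStatistic(c(y1, y1), groups4, grid4, basis4)$f_value, 0)
  fs <- vapply(c(2, 8, 32), function(d) {
    geneFStatistic(c(y1, y1 + d), groups4, grid4, basis4)$f_value
  }, 0)
  expect_true(all(diff(fs) > 0))
})

test_that("F matches independently recomputed residual-error sums", {
  set.seed(402)
  y <- rnorm(16)
  for (loss in c("median", "mean")) {
    st <- geneFStatistic(y, groups4, grid4, basis4, loss = loss)
    X <- basisMatrix(basis4, grid4)
    rae <- function(idx) {
      if (loss == "median") l1EnumObjective(y[idx], X[idx, , drop = FALSE])
      else sum(lm.fit(X[idx, , drop = FALSE], y[idx])$residuals^2)
    }
    r0 <- rae(1:16); r1 <- rae(which(groups4 == 1)) + rae(which(groups4 == 2))
    expect_equal(st$rae_null, r0, tolerance = 1e-8)
    expect_equal(st$rae_alt, r1, tolerance = 1e-8)
    expect_equal(st$f_value, (r0 - r1) / r1, tolerance = 1e-8)
    expect_lte(st$rae_alt, st$rae_null + 1e-10)
    expect_gte(st$f_value, 0)
  }
})

test_that("F is invariant to location, scale (median loss) and sample order", {
  set.seed(403)
  y <- rnorm(16)
  f0 <- geneFStatistic(y, groups4, grid4, basis4)$f_value
  expect_equal(geneFStatistic(y + 7, groups4, grid4, basis4)$f_value, f0,
               tolerance = 1e-9)
  expect_equal(geneFStatistic(2.5 * y, groups4, grid4, basis4)$f_value, f0,
               tolerance = 1e-9)
  o <- sample(16)
  expect_equal(geneFStatistic(y[o], groups4[o], grid4[o], basis4)$f_value,
               f0, tolerance = 1e-9)
})

test_that("mean-loss F on a saturated basis equals the ANOVA decomposition", {
  set.seed(404)
  tg <- c(0, 3, 6, 9)
  times <- rep(rep(tg, each = 3), 2)
  groups <- factor(rep(1:2, each = 12))
  y <- rnorm(24)
  bSat <- makeSplineBasis(times, p = 4)  # knots at all four times: saturated
  st <- geneFStatistic(y, groups, times, bSat, loss = "mean")
  sse0 <- sum(resid(lm(y ~ 0 + factor(times)))^2)
  sse1 <- sum(resid(lm(y ~ 0 + factor(times):groups))^2)
  expect_equal(st$f_value, (sse0 - sse1) / sse1, tolerance = 1e-8)
})

test_that("group-mean centering removes vertical shifts and is idempotent", {
  g <- rep(1:2, each = 3)
  y <- c(4, 2, 3, -2, 0, -1)  # group means 3 and -1
  cy <- centerByGroupMeans(y, g)
  expect_equal(cy, c(y[1:3] - 3, y[4:6] + 1))
  expect_equal(centerByGroupMeans(cy, g), cy)
  set.seed(405)
  y1 <- rnorm(8)
  shifted <- c(y1, y1 + 50)
  raw <- geneFStatistic(shifted, groups4, grid4, basis4)$f_value
  cent <- geneFStatistic(centerByGroupMeans(shifted, groups4), groups4,
                         grid4, basis4)$f_value
  expect_gt(raw, 10)
  expect_lt(cent, 0.5)
  expect_error(centerByGroupMeans(y, factor(g, levels = 1:3)), "nonempty")
})

test_that("one-sample statistic detects time dependence", {
  tt <- rep(c(0, 1, 2, 3), each = 2)
  b2 <- makeSplineBasis(tt, p = 2)
  expect_equal(oneSampleStatistic(rep(4, 8), tt, b2)$f_value, 0)
  trend <- 1 + 0.5 * tt   # representable exactly: infinity sentinel
  st <- oneSampleStatistic(trend, tt, b2)
  expect_identical(st$f_value, Inf)
  set.seed(406)
  y <- rnorm(8)
  expect_equal(oneSampleStatistic(y, tt, b2)$rae_null,
               sum(abs(y - median(y))))
  expect_equal(oneSampleStatistic(y, tt, b2, loss = "mean")$rae_null,
               sum((y - mean(y))^2))
  expect_equal(oneSampleStatistic(y, tt, b2, center = "mean")$rae_null,
               sum(abs(y - mean(y))))
})

test_that("undersized groups are reported by name and count", {
  tt <- c(0, 1, 2, 0, 1)
  expect_error(
    geneFStatistic(rnorm(5), c(1, 1, 1, 2, 2), tt,
                   makeSplineBasis(tt, p = 3)),
    "2 \\(n = 2\\)")
})
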