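test_that("degenerate fits behave like location estimators", {
  X1 <- matrix(1, 3, 1)
  med <- fitMedianSpline(c(1, 2, 9), X1)
  expect_equal(unname(med$coefficients), 2)   # the sample median
  expect_equal(med$residual_error, 8)
  b <- makeSplineBasis(rep(c(0, 2, 4), each = 2), p = 3)
  X <- basisMatrix(b, rep(c(0, 2, 4), each = 2))
  for (f in list(fitMedianSpline(rep(3.5, 6), X),
                 fitMeanSpline(rep(3.5, 6), X)))
    expect_lt(f$residual_error, 1e-10)        # constants are interpolated
})

test_that("median objective matches the interpolating-subset oracle", {
  set.seed(301)
  for (i in 1:25) {
    n <- sample(6:12, 1); p <- sample(2:4, 1)
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    y <- rnorm(n)
    f <- fitMedianSpline(y, X)
    expect_equal(f$residual_error, l1EnumObjective(y, X), tolerance = 1e-8)
    # the solver's vertex never loses to random candidate coefficients
    cand <- matrix(rnorm(40 * p, sd = 2), ncol = p)
    objs <- apply(cand, 1, function(b) sum(abs(y - X %*% b)))
    expect_true(all(f$residual_error <= objs + 1e-12))
  }
})

test_that("median objective agrees with an external quantile-regression fit", {
  set.seed(302)
  times <- rep(c(0:8, 10, 12), each = 4)
  X <- basisMatrix(makeSplineBasis(simGridTimes(), p = 4), times)
  for (i in 1:10) {
    y <- rnorm(44) + sample(c(-4, 0, 4), 44, TRUE, c(0.05, 0.9, 0.05))
    ours <- fitMedianSpline(y, X)$residual_error
    rq <- suppressWarnings(quantreg::rq.fit.br(X, y, tau = 0.5))
    expect_equal(ours, sum(abs(rq$residuals)), tolerance = 1e-8)
  }
})

test_that("fits are equivariant under shift and scale", {
  set.seed(303)
  X <- cbind(1, matrix(rnorm(20), 10))
  y <- rnorm(10)
  m0 <- fitMedianSpline(y, X); ls0 <- fitMeanSpline(y, X)
  m1 <- fitMedianSpline(y + 5, X)
  expect_equal(m1$residual_error, m0$residual_error, tolerance = 1e-10)
  expect_equal(drop(X %*% m1$coefficients), drop(X %*% m0$coefficients) + 5,
               tolerance = 1e-8)
  expect_equal(fitMedianSpline(3 * y, X)$residual_error,
               3 * m0$residual_error, tolerance = 1e-10)
  expect_equal(fitMeanSpline(3 * y, X)$residual_error,
               9 * ls0$residual_error, tolerance = 1e-8)
})

test_that("mean fit solves the normal equations; losses agree on symmetric data", {
  # orthogonal design: coefficients are scaled column inner products
  X <- cbind(1, c(-1, -1, 1, 1))
  y <- c(0.5, 1.5, 2.5, 5.5)
  f <- fitMeanSpline(y, X)
  expect_equal(unname(f$coefficients), c(mean(y), sum(X[, 2] * y) / 4))
  expect_equal(f$residual_error, sum((y - X %*% f$coefficients)^2))
  # three symmetric replicates per time: both fits pass through the centres
  times <- rep(c(0, 1, 2), each = 3)
  centre <- c(1, 3, 2)[match(times, c(0, 1, 2))]
  y2 <- centre + rep(c(-0.7, 0, 0.7), times = 3)
  b <- makeSplineBasis(times, p = 3)
  X2 <- basisMatrix(b, times)
  fm <- fitMedianSpline(y2, X2); fl <- fitMeanSpline(y2, X2)
  expect_equal(drop(X2 %*% fm$coefficients), drop(X2 %*% fl$coefficients),
               tolerance = 1e-8)
})

test_that("rank-deficient designs are reduced and flagged", {
  X <- cbind(1, c(0, 1, 2, 3, 4), 2 * c(0, 1, 2, 3, 4))
  y <- c(0, 1.1, 1.9, 3, 4.2)
  for (f in list(fitMedianSpline(y, X), fitMeanSpline(y, X))) {
    expect_true(f$rankDeficient)
    expect_true(anyNA(f$coefficients))
    expect_gte(f$residual_error, 0)
  }
  Xok <- X[, 1:2]
  expect_equal(fitMedianSpline(y, X)$residual_error,
               fitMedianSpline(y, Xok)$residual_error, tolerance = 1e-10)
})

test_that("the roughness penalty straightens the median fit", {
  times <- rep(c(0, 2, 4, 8, 12), each = 3)
  b <- makeSplineBasis(times, p = 5)
  X <- basisMatrix(b, times)
  y <- sin(times / 3) + rep(c(-0.1, 0, 0.1), 5)
  f0 <- fitMedianSpline(y, X, lambda = 0, basis = b)
  expect_equal(f0$residual_error, fitMedianSpline(y, X)$residual_error,
               tolerance = 1e-10)
  fBig <- fitMedianSpline(y, X, lambda = 1e6, basis = b)
  fitted <- drop(basisMatrix(b, b@knots) %*% fBig$coefficients)
  slopes <- diff(fitted) / diff(b@knots)
  expect_lt(max(abs(diff(slopes))), 1e-6)  # no remaining slope changes
  expect_gte(fBig$residual_error, f0$residual_error)
})
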