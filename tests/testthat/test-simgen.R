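test_that("uncontaminated errors are standard normal; outliers obey the law", {
  set.seed(601)
  cfg <- simConfig(m = 25, pi = 0, N = 1, B = 1)
  d <- qsperm:::.simulateRaw(cfg)
  expect_true(all(d$outliers == 0))
  draws <- as.vector(replicate(5, qsperm:::.simulateRaw(cfg)$Y))  # 11000 values
  expect_gt(ks.test(draws, "pnorm")$p.value, 1e-3)
  # model 1 variance inflation: 1 + 16 * pi
  cfg2 <- simConfig(m = 25, pi = 0.1, N = 1, B = 1)
  v <- var(as.vector(replicate(5, qsperm:::.simulateRaw(cfg2)$Y)))
  expect_lt(abs(v - (1 + 16 * 0.1)), 0.2)
  # outlier values are exactly 0 or +-magnitude, roughly symmetric
  a <- qsperm:::.simulateRaw(cfg2)$outliers
  expect_true(all(a %in% c(-4, 0, 4)))
  expect_lt(abs(mean(a != 0) - 0.1), 0.04)
})

test_that("prognostic genes carry exactly the exponential-decay group contrast", {
  cfg1 <- simConfig(m = 30, mProg = 3, pi = 0.05, rho = 0.3, seed = 5)
  cfg0 <- simConfig(m = 30, mProg = 3, pi = 0.05, rho = 0.3, seed = 5,
                    effectScale = 0)
  set.seed(5); d1 <- qsperm:::.simulateRaw(cfg1)
  set.seed(5); d0 <- qsperm:::.simulateRaw(cfg0)
  diff <- d1$Y - d0$Y
  g2 <- d1$groups == "2"
  expect_equal(sum(d1$prognostic), 3)
  expect_true(all(diff[!d1$prognostic, ] == 0))
  expect_true(all(diff[, !g2] == 0))
  expected <- rep(1.5 * exp(-d1$times[g2]), each = 3)
  expect_equal(diff[d1$prognostic, g2], matrix(expected, 3, byrow = FALSE),
               ignore_attr = TRUE)
  expect_equal(max(diff), 1.5)                       # at t = 0
  expect_lt(max(diff[, d1$times == 12 & g2]), 1e-5)  # 1.5 e^{-12} ~ 0
  # prognostic genes occupy distinct correlation blocks
  expect_equal(length(unique(d1$block[d1$prognostic])), 3)
})

test_that("block-exchangeable correlation hits its target", {
  set.seed(602)
  cfg <- simConfig(m = 20, pi = 0, rho = 0.6)
  acc <- replicate(120, qsperm:::.simulateRaw(cfg)$Y[c(1, 2, 11), ])
  within <- cor(as.vector(acc[1, , ]), as.vector(acc[2, , ]))
  between <- cor(as.vector(acc[1, , ]), as.vector(acc[3, , ]))
  expect_lt(abs(within - 0.6), 0.03)
  expect_lt(abs(between), 0.03)
})

test_that("model 2 confines outliers to the boundary time-points", {
  set.seed(603)
  cfg <- simConfig(m = 60, pi = 0.1, model = 2)
  d <- qsperm:::.simulateRaw(cfg)
  interior <- !(d$times %in% c(0, 12))
  expect_true(all(d$outliers[, interior] == 0))
  boundary <- d$outliers[, !interior]
  expect_lt(abs(mean(boundary != 0) - 0.1), 0.035)
})

test_that("the simulated container is valid and scenario errors are caught", {
  set.seed(604)
  d <- simulateDataset(simConfig(m = 6, mProg = 1, blockSize = 3))
  expect_s4_class(d$experiment, "TimecourseExperiment")
  td <- timeDesign(d$experiment)
  expect_identical(dim(td@counts), c(2L, 11L))
  expect_true(all(td@counts == 4L))
  expect_error(simConfig(pi = 1.2), "pi")
  expect_error(simConfig(rho = 1), "rho")
  expect_error(simConfig(model = 3), "model")
  expect_error(estimateFWER(simConfig(mProg = 2)), "mProg = 0")
  expect_error(estimatePower(simConfig(mProg = 0)), "mProg >= 1")
})

test_that("a massive effect is always detected; the p-value floor blocks alpha < 1/B", {
  cfg <- simConfig(m = 20, mProg = 2, timeGrid = c(0, 2, 4, 6), N = 3,
                   B = 25, effectScale = 150, seed = 77)
  s <- estimatePower(cfg, "median_perm")
  expect_equal(s@proportion, 1)
  expect_equal(s@mcSE, 0)
  # with the add-one floor no p-value can drop below 1/(B+1)
  set.seed(78)
  d <- simulateDataset(simConfig(m = 10, timeGrid = c(0, 2, 4, 6), seed = 78))
  res <- qspermTest(d$experiment, p = 3, B = 40, seed = 1,
                    floorPvalues = TRUE, alpha = 0.01)
  expect_true(all(resultsTable(res)$p_unadj >= 1 / 41))
  expect_length(significantGenes(res), 0)
})

test_that("single-gene permutation p-values are approximately uniform", {
  set.seed(605)
  tt <- rep(rep(c(0, 3, 6), each = 2), 2)
  gg <- rep(1:2, each = 6)
  b <- makeSplineBasis(tt, p = 2)
  ps <- replicate(300, {
    eng <- qsperm:::.permEngine(matrix(rnorm(12), 1), gg, tt, b, "median",
                                B = 20, scheme = "within_timepoint")
    unadjustedPvalues(eng$f_obs$median, eng$f_null$median)
  })
  # exchangeability: mean near 1/2 (discreteness and ties push it up by
  # roughly 1/(2B) plus the tie mass) and both halves carry real mass
  expect_lt(abs(mean(ps) - 0.525), 0.1)
  expect_lt(abs(mean(ps <= 0.5) - 0.5), 0.12)
})
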