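test_that("distribution preparation merges, logs and bounds as specified", {
  expect_warning(
    p <- prepareDistribution(list(c(10, 100, 1000), c(10, 100, 1000),
                                  c(10, 100, 1000))),
    "fewer than 100")
  expect_length(p@values, 9L)
  expect_true(all(p@bounds >= 1 & p@bounds <= 3))

  p2 <- suppressWarnings(prepareDistribution(list(c(-5, 0, 10, 100, 1000))))
  expect_equal(p2@nDroppedNonpositive, 2L)
  expect_length(p2@values, 3L)

  expect_error(suppressWarnings(prepareDistribution(list(c(-1, 0)))),
               "no positive values")
})

test_that("KDE mode counting matches a brute-force kernel-sum oracle", {
  uni <- withr::with_seed(31, rnorm(2000))
  pUni <- suppressWarnings(prepareDistribution(list(10^uni)))
  expect_equal(kdeModeCount(uni, 0.5, bounds = quantile(uni, c(0.05, 0.95))),
               bruteForceModeCount(uni, 0.5, quantile(uni, c(0.05, 0.95))))
  expect_equal(kdeModeCount(uni, 0.5, bounds = quantile(uni, c(0.05, 0.95))), 1L)

  bim <- withr::with_seed(32, c(rnorm(1000), rnorm(1000, 6)))
  b <- quantile(bim, c(0.05, 0.95))
  expect_equal(kdeModeCount(bim, 0.3, bounds = b),
               bruteForceModeCount(bim, 0.3, b))
  expect_equal(kdeModeCount(bim, 0.3, bounds = b), 2L)

  # over-smoothing limit
  expect_equal(kdeModeCount(bim, 100, bounds = b), 1L)
})

test_that("mode count is non-increasing in bandwidth (Gaussian kernel)", {
  samples <- withr::with_seed(33, list(
    rnorm(500), c(rnorm(300), rnorm(300, 4)),
    c(rnorm(200), rnorm(200, 3), rnorm(200, 7))))
  for (v in samples) {
    hGrid <- exp(seq(log(0.02), log(4), length.out = 40))
    counts <- vapply(hGrid, function(h) kdeModeCount(v, h), integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("critical bandwidth agrees with an exhaustive grid oracle", {
  v <- withr::with_seed(34, c(rnorm(400), rnorm(400, 5)))
  b <- quantile(v, c(0.05, 0.95))
  h <- criticalBandwidth(v, tol = 1e-3, bounds = b)
  # exhaustive oracle: finest h on a dense grid with a single in-bounds mode
  hGrid <- seq(h * 0.8, h * 1.2, length.out = 400)
  counts <- vapply(hGrid, function(hh) kdeModeCount(v, hh, b), integer(1))
  oracle <- hGrid[which(counts <= 1L)[1]]
  expect_equal(h, oracle, tolerance = 5e-3)
  # definition check at the bisection endpoint
  expect_equal(kdeModeCount(v, h * (1 + 10 * 1e-3), b), 1L)
  expect_gt(kdeModeCount(v, h * (1 - 10 * 1e-3), b), 1L)
})

test_that("separated mixtures need larger critical bandwidths than unimodal data", {
  withr::with_seed(35, {
    mix <- c(rnorm(500, -3), rnorm(500, 3))     # variance ~ 10
    uni <- rnorm(1000, 0, sd(mix))              # unimodal, equal variance
  })
  hMix <- criticalBandwidth(mix, bounds = quantile(mix, c(0.05, 0.95)))
  hUni <- criticalBandwidth(uni, bounds = quantile(uni, c(0.05, 0.95)))
  expect_gt(hMix, hUni)
  expect_lt(hUni, sd(uni))
})

test_that("critical bandwidth is location and scale equivariant", {
  v <- withr::with_seed(36, c(rnorm(300), rnorm(300, 4)))
  b <- quantile(v, c(0.05, 0.95))
  h <- criticalBandwidth(v, bounds = b)
  h2 <- criticalBandwidth(7 + 3 * v, bounds = 7 + 3 * b)
  expect_equal(h2 / h, 3, tolerance = 5e-3)
})

test_that("Hall-York p-values are reproducible and seed-sensitive", {
  x <- withr::with_seed(37, list(10^c(rnorm(400, 1.5, 0.25),
                                      rnorm(400, 3.5, 0.25))))
  p <- prepareDistribution(x)
  r1 <- hallYorkTest(p, nBoot = 100, seed = 99)
  r2 <- hallYorkTest(p, nBoot = 100, seed = 99)
  expect_identical(r1@pValue, r2@pValue)
  expect_identical(r1@hCrit, r2@hCrit)

  # uncalibrated limit: raw Silverman exceedance fraction, a multiple of 1/nBoot
  raw <- hallYorkTest(p, nBoot = 100, seed = 99, calibrate = FALSE)
  expect_equal(raw@pValue * 100, round(raw@pValue * 100))

  expect_error(hallYorkTest(p, nBoot = 50, seed = 1), "nBoot")
  expect_error(
    suppressWarnings(hallYorkTest(list(rep(10, 200)), nBoot = 100, seed = 1)),
    "degenerate")
})

test_that("clearly bimodal data are rejected, unimodal data are not", {
  # bimodal mixtures: p < 0.01
  pvBim <- vapply(1:5, function(s) {
    x <- withr::with_seed(s, 10^c(rnorm(1000, 1.5, 0.25),
                                  rnorm(1000, 3.5, 0.25)))
    hallYorkTest(prepareDistribution(list(x)), nBoot = 200, seed = s)@pValue
  }, numeric(1))
  expect_true(all(pvBim < 0.01))

  # unimodal log-normals: p > 0.05 in at least 90% of seeds
  pvUni <- vapply(1:20, function(s) {
    x <- withr::with_seed(100 + s, 10^rnorm(2000, 2.5, 0.3))
    hallYorkTest(prepareDistribution(list(x)), nBoot = 500, seed = s)@pValue
  }, numeric(1))
  expect_gte(mean(pvUni > 0.05), 0.9)
})

test_that("type-I error at alpha = 0.01 stays within calibration sanity", {
  rejections <- vapply(1:100, function(s) {
    v <- withr::with_seed(1000 + s, rnorm(400))
    prep <- new("PreparedDistribution", values = v,
                bounds = unname(quantile(v, c(0.05, 0.95))),
                nDroppedNonpositive = 0L)
    hallYorkTest(prep, nBoot = 100, seed = s)@pValue < 0.01
  }, logical(1))
  expect_lte(mean(rejections), 0.05)
})
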