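test_that("CSV event tables parse with channel metadata preserved", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(`FSC-A` = c(1e4, 2e4, 3e4), `SSC-A` = c(1e3, 2e3, 3e3),
                       `FSC-H` = c(9e3, 1.9e4, 2.8e4), `BV421-A` = c(10, 20, 30),
                       check.names = FALSE), f, row.names = FALSE)
  ev <- readEventTable(f)
  expect_equal(nEvents(ev), 3L)
  expect_equal(channelNames(ev), c("FSC-A", "SSC-A", "FSC-H", "BV421-A"))

  # header-only file is a degenerate input
  f2 <- tempfile(fileext = ".csv")
  writeLines("FSC-A,SSC-A", f2)
  expect_error(readEventTable(f2), "no events")

  expect_error(readEventTable(tempfile(fileext = ".csv")), "not found")
})

test_that("FCS files round-trip through the reader with channel aliasing", {
  mat <- eventData(makeEventTable(50, seed = 3, channel = "BV421-A"))
  f <- tempfile(fileext = ".fcs")
  writeFcsFixture(f, mat)
  ev <- readEventTable(f, channelAliases = c("BV421-A" = "tBFP-A"))
  expect_equal(nEvents(ev), 50L)
  expect_equal(channelNames(ev), c("FSC-A", "SSC-A", "FSC-H", "tBFP-A"))
  # float32 storage: agreement to single precision
  expect_equal(unname(eventData(ev)[, "tBFP-A"]), unname(mat[, "BV421-A"]),
               tolerance = 1e-6)

  # malformed input names the offending segment
  bad <- tempfile(fileext = ".fcs")
  writeLines("FCS9.9 nonsense", bad)
  expect_error(readEventTable(bad), "header")
})

test_that("live gate keeps the scatter-percentile rectangle", {
  n <- 10000
  ev <- withr::with_seed(11, EventTable(cbind(
    `FSC-A` = runif(n), `SSC-A` = runif(n), `FSC-H` = runif(n))))
  g <- gateLiveCells(ev, 1, 99)
  # brute-force oracle: direct count inside the independent quantile bounds
  ex <- eventData(ev)
  qf <- quantile(ex[, "FSC-A"], c(0.01, 0.99))
  qs <- quantile(ex[, "SSC-A"], c(0.01, 0.99))
  oracle <- sum(ex[, "FSC-A"] >= qf[1] & ex[, "FSC-A"] <= qf[2] &
                ex[, "SSC-A"] >= qs[1] & ex[, "SSC-A"] <= qs[2])
  expect_equal(length(keptIndices(g)), oracle)
  # independent channels: ~0.98^2 of events survive
  expect_gt(length(keptIndices(g)), 9500)
  expect_lt(length(keptIndices(g)), 9700)

  expect_equal(length(keptIndices(gateLiveCells(ev, 0, 100))), n)

  single <- EventTable(cbind(`FSC-A` = 1, `SSC-A` = 1, `FSC-H` = 1))
  expect_warning(g1 <- gateLiveCells(single, 1, 99), "fewer than 50")
  expect_equal(length(keptIndices(g1)), 1L)  # kept-by-convention
})

test_that("live gate is idempotent when absolute coordinates are re-applied", {
  ev <- makeEventTable(5000, seed = 5)
  g <- gateLiveCells(ev, 2, 98)
  kept <- applyGate(ev, g)
  again <- applyGate(kept, g)
  expect_equal(nEvents(again), nEvents(kept))
  expect_equal(eventData(again), eventData(kept))
})

test_that("singlet gate removes doublet mimics but keeps the line", {
  n <- 4000
  ev <- withr::with_seed(21, {
    fsc <- 10^rnorm(n, 5, 0.1)
    doublet <- seq_len(n) <= n * 0.05
    h <- 0.9 * fsc * ifelse(doublet, 0.5, 1) * exp(rnorm(n, 0, 0.01))
    EventTable(cbind(`FSC-A` = fsc, `SSC-A` = fsc, `FSC-H` = h),
               condition = list(doublet = doublet))
  })
  doublet <- ev@condition$doublet
  g <- gateSinglets(ev, bandWidthMad = 4)
  kept <- keptIndices(g)
  expect_gte(mean(which(!doublet) %in% kept), 0.95)
  expect_gte(mean(!(which(doublet) %in% kept)), 0.99)

  # exact line: zero residuals, all kept
  evLine <- EventTable(cbind(`FSC-A` = 1:100 * 100, `SSC-A` = 1:100,
                             `FSC-H` = 0.9 * (1:100) * 100))
  expect_equal(length(keptIndices(gateSinglets(evLine, 4))), 100L)

  # infinite band keeps everything
  expect_equal(length(keptIndices(gateSinglets(ev, Inf))), n)

  evConst <- EventTable(cbind(`FSC-A` = rep(1, 10), `SSC-A` = 1:10,
                              `FSC-H` = 1:10))
  expect_error(gateSinglets(evConst, 4), "cannot fit singlet gate")
})

test_that("MFI is the median with the mean-of-middle convention", {
  mk <- function(v) EventTable(cbind(`FL-A` = v))
  expect_equal(computeMfi(mk(c(1, 2, 3, 4, 100)), "FL-A"), 3)
  expect_equal(computeMfi(mk(7), "FL-A"), 7)
  expect_equal(computeMfi(mk(c(1, 2, 3, 4)), "FL-A"), 2.5)
  # invariance under permutation and appending the median
  v <- c(5, 1, 9, 3, 7)
  expect_equal(computeMfi(mk(sample(v)), "FL-A"), computeMfi(mk(v), "FL-A"))
  expect_equal(computeMfi(mk(c(v, 5)), "FL-A"), computeMfi(mk(v), "FL-A"))
  expect_error(computeMfi(mk(1:3), "nope"), "missing")
})

test_that("background subtraction averages controls and keeps negatives", {
  r <- subtractBackground(500, c(100, 120))
  expect_equal(r$mfi_background, 110)
  expect_equal(r$mfi_bg_subtracted, 390)
  expect_equal(subtractBackground(90, 100)$mfi_bg_subtracted, -10)
  expect_error(subtractBackground(500, numeric(0)), "control")
  # exact inverse: subtracting then adding back the control recovers the raw
  x <- 123.45; ctl <- 67.89
  expect_identical(subtractBackground(x, ctl)$mfi_bg_subtracted + ctl, x)
})

test_that("positivity threshold is the 99th percentile of control cells", {
  v <- withr::with_seed(9, rnorm(1000))
  ev <- EventTable(cbind(`GFP-A` = v))
  th <- positivityThreshold(ev, "GFP-A")
  # sort-based oracle (type-7 interpolation done by hand)
  sv <- sort(v)
  hIdx <- 1 + 0.99 * (1000 - 1)
  oracle <- sv[floor(hIdx)] + (hIdx - floor(hIdx)) * (sv[ceiling(hIdx)] - sv[floor(hIdx)])
  expect_equal(th, oracle)
  expect_gt(th, 2.0); expect_lt(th, 2.7)

  expect_equal(suppressWarnings(
    positivityThreshold(EventTable(cbind(`GFP-A` = rep(4, 10))), "GFP-A")), 4)
  expect_warning(positivityThreshold(EventTable(cbind(`GFP-A` = rep(4, 10))), "GFP-A"),
                 "100")
  expect_error(positivityThreshold(ev, "RFP-A"), "missing")
})

test_that("time-course scaling maps anchors to 0 and 1 and inverts exactly", {
  s <- scaleTimecourse(c(0, 5, 30, 60), c(10, 60, 110, 110), direction = "up")
  expect_equal(s@value, c(0, 0.5, 1, 1))

  # idempotence: scaling an already-scaled up-series changes nothing
  s2 <- scaleTimecourse(s@time, s@value, direction = "up")
  expect_equal(s2@value, s@value)

  d <- scaleTimecourse(c(0, 2, 30, 100), c(200, 50, 0, 0), direction = "down")
  expect_equal(d@value[2], 0.25)

  # inverse affine map reproduces the input to 1e-12 relative
  raw <- c(10, 60, 110, 110)
  sc <- scaleTimecourse(c(0, 5, 30, 60), raw, direction = "up")
  back <- sc@value * (sc@scaling$oneAnchor - sc@scaling$zeroAnchor) +
    sc@scaling$zeroAnchor
  expect_equal(back, raw, tolerance = 1e-12)

  expect_error(scaleTimecourse(c(0, 1, 2), c(1, 2, 3), direction = "up"),
               "plateau")
  expect_error(scaleTimecourse(c(1, 30), c(1, 2), direction = "up"), "t = 0")
})

test_that("fold-change normalisation requires a positive reference", {
  expect_equal(normalizeFoldChange(400, 500), 0.8)
  expect_equal(normalizeFoldChange(500, 500), 1)
  expect_error(normalizeFoldChange(400, 0), "positive")
  expect_error(normalizeFoldChange(400, -5), "positive")
})

test_that("gate coordinates survive a JSON round trip and re-apply identically", {
  ev <- makeEventTable(2000, seed = 8)
  g <- gateLiveCells(ev, 1, 99)
  f <- tempfile(fileext = ".json")
  writeGateResult(g, f)
  g2 <- readGateResult(f)
  expect_equal(g2@parameters$bounds, g@parameters$bounds)
  expect_equal(eventData(applyGate(ev, g2)), eventData(applyGate(ev, g)))
})
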