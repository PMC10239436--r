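tGridStd <- c(0, 2, 4, 8, 12, 24, 48, 72, 96, 120, 150)

test_that("closed-form repressor solutions honour their defining anchors", {
  expect_equal(repressorUp(0, 3), 0)
  expect_equal(repressorUp(3, 3), 0.5)
  expect_equal(repressorUp(6, 3), 0.75)
  expect_equal(repressorDown(0, 1.4), 1)
  expect_equal(repressorDown(log(2) / 1.4, 1.4), 0.5)
  expect_equal(repressorDown(3, log(2)), 0.125)
  # strict monotonicity
  tt <- seq(0, 50, 0.5)
  expect_true(all(diff(repressorUp(tt, 7)) > 0))
  expect_true(all(diff(repressorDown(tt, 0.3)) < 0))
})

test_that("repressor fits round-trip noiseless closed-form data", {
  for (th in c(3, 7)) {
    d <- data.frame(time = rep(0:24, 3), value = rep(repressorUp(0:24, th), 3))
    fit <- fitRepressorUp(d)
    expect_equal(fit@tHalf, th, tolerance = 1e-6)
    expect_lt(fit@tHalfSE, 1e-4)
  }
  d <- data.frame(time = tGridStd, value = repressorDown(tGridStd, 1.4))
  fit <- fitRepressorDown(d)
  expect_equal(fit@tHalf, log(2) / 1.4, tolerance = 1e-6)
  expect_equal(fit@alpha, 1.4, tolerance = 1e-6)

  expect_error(fitRepressorUp(data.frame(time = 0:10, value = rep(0, 11))),
               "no signal")
  expect_error(fitRepressorDown(data.frame(time = 0:10, value = rep(1, 11))),
               "constant")
})

test_that("repressor half-time is recovered within 10% from noisy replicates", {
  m <- KineticModel(alphaRPlus = 1.4, alphaT = 0.036, K = 0.2, n = 2)
  relErr <- vapply(1:20, function(s) {
    sim <- simulateTimecourse(m, "down", noiseCv = 0.05, nReplicates = 3,
                              seed = s)
    abs(fitRepressorDown(sim$repressor)@tHalf - log(2) / 1.4) / (log(2) / 1.4)
  }, numeric(1))
  expect_lt(median(relErr), 0.10)
})

test_that("steady-state repression Hill function behaves at its anchors", {
  expect_equal(steadyStateTarget(0, 0.3, 2), 1)
  expect_equal(steadyStateTarget(0.3, 0.3, 2), 0.5)
  expect_lt(steadyStateTarget(0.6, 0.3, 50), 1e-10)  # switch limit
  r <- seq(0, 1, 0.01)
  expect_true(all(diff(steadyStateTarget(r, 0.3, 2)) < 0))
})

test_that("steady-state response fit recovers (K, n) and flags degeneracy", {
  R <- rep(seq(0.05, 1, length.out = 12), 2)
  fit <- fitSteadyStateResponse(R, steadyStateTarget(R, 0.3, 2))
  expect_equal(fit@K, 0.3, tolerance = 1e-6)
  expect_equal(fit@n, 2, tolerance = 1e-6)
  expect_equal(fit@flag, "ok")

  flat <- fitSteadyStateResponse(R, rep(1, length(R)))
  expect_equal(flat@flag, "unidentifiable")
  expect_true(is.na(flat@K))

  # noisy recovery: K within 15%, n within 25%
  errs <- vapply(1:20, function(s) {
    y <- withr::with_seed(s, steadyStateTarget(R, 0.3, 2) *
                            exp(rnorm(length(R), 0, sqrt(log(1 + 0.05^2)))))
    f <- fitSteadyStateResponse(R, y)
    c(abs(f@K - 0.3) / 0.3, abs(f@n - 2) / 2)
  }, numeric(2))
  expect_lt(median(errs[1, ]), 0.15)
  expect_lt(median(errs[2, ]), 0.25)
})

test_that("derepression closed form and target-degradation fit agree", {
  expect_equal(derepressionClosedForm(0, 0.036, 0.2), 0.2)
  expect_equal(derepressionClosedForm(1e6, 0.036, 0.2), 1)
  expect_equal(derepressionClosedForm(log(2) / 0.036, 0.036, 0.2), 0.6)

  d <- data.frame(time = tGridStd,
                  value = derepressionClosedForm(tGridStd, 0.036, 0.2))
  fit <- fitTargetDegradation(d)
  expect_equal(fit$alphaT, 0.036, tolerance = 1e-8)
  expect_equal(fit$T0, 0.2, tolerance = 1e-8)

  expect_error(fitTargetDegradation(data.frame(time = tGridStd,
                                               value = rep(1, 11))),
               "unidentifiable")

  # 5%-CV noise: alphaT within 10%
  errs <- vapply(1:20, function(s) {
    v <- withr::with_seed(s, derepressionClosedForm(tGridStd, 0.036, 0.2) *
                            exp(rnorm(11, 0, sqrt(log(1 + 0.05^2)))))
    abs(fitTargetDegradation(data.frame(time = tGridStd, value = v))$alphaT -
          0.036) / 0.036
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("target simulation matches the unrepressed closed form", {
  # K = Inf makes f identically 1; trajectory must equal the closed form
  m <- KineticModel(alphaRPlus = 1.4, alphaT = 0.036, K = Inf, n = 2)
  grid <- seq(0, 150, 0.5)
  sim <- simulateTargetDynamics(m, "down", grid, deltaT = 0, initial = 0.2)
  expect_lt(max(abs(sim - derepressionClosedForm(grid, 0.036, 0.2))), 1e-8)
})

test_that("target simulation agrees with an independent ODE solver", {
  skip_if_not_installed("deSolve")
  m <- KineticModel(alphaRPlus = log(2) / 0.5, alphaT = 0.036, K = 0.2, n = 2)
  grid <- seq(0, 150, 1)
  mine <- simulateTargetDynamics(m, "down", grid, deltaT = 6)
  rhs <- function(t, y, p) {
    R <- if (t - 6 < 0) 1 else exp(-m@alphaRPlus * (t - 6))
    list(m@alphaT * (1 / (1 + (R / m@K)^m@n) - y))
  }
  ref <- deSolve::ode(y = 1 / (1 + (1 / m@K)^m@n), times = grid, func = rhs,
                      parms = NULL, method = "lsoda", rtol = 1e-10,
                      atol = 1e-12)[, 2]
  expect_lt(max(abs(mine - ref)), 1e-6)
})

test_that("simulated trajectories respect delay shift, QSS limit and bounds", {
  m <- KineticModel(alphaRPlus = 10, alphaT = 0.1, K = 0.2, n = 2)
  grid <- seq(0, 150, 0.5)
  # after the repressor has fully degraded, a 6 h delay equals a 6 h shift
  s0 <- simulateTargetDynamics(m, "down", grid, deltaT = 0)
  s6 <- simulateTargetDynamics(m, "down", grid, deltaT = 6)
  late <- grid >= 20
  shifted <- approx(grid + 6, s0, xout = grid[late])$y
  expect_lt(max(abs(s6[late] - shifted)), 1e-6)

  # alphaT -> large: target tracks f(R(t - deltaT)) pointwise
  mFast <- KineticModel(alphaRPlus = 0.5, alphaT = 200, K = 0.2, n = 2)
  sFast <- simulateTargetDynamics(mFast, "down", seq(0, 20, 0.5), deltaT = 0,
                                  dt = 0.002)
  fTrack <- steadyStateTarget(repressorDown(seq(0, 20, 0.5), 0.5), 0.2, 2)
  expect_lt(max(abs(sFast[-1] - fTrack[-1])), 0.01)

  # conservation of scaling
  expect_true(all(s0 >= 0 & s0 <= 1))
  up <- simulateTargetDynamics(KineticModel(tHalf = 3, alphaT = 0.036,
                                            K = 0.2, n = 2), "up", grid)
  expect_true(all(up >= 0 & up <= 1))

  # halving the step changes nothing at the reported precision
  sHalf <- simulateTargetDynamics(m, "down", grid, deltaT = 6, dt = 0.025)
  expect_lt(max(abs(s6 - sHalf)), 1e-6)
})

test_that("delay estimation recovers the truth with a well-shaped profile", {
  m <- KineticModel(alphaRPlus = log(2) / 0.5, alphaT = 0.036, K = 0.2, n = 2)
  grid <- seq(0, 150, 1)

  for (truth in c(0, 6)) {
    obs <- data.frame(time = grid,
                      value = simulateTargetDynamics(m, "down", grid,
                                                     deltaT = truth))
    fit <- estimateDelay(obs, m, "down", grid = 0:25)
    expect_equal(fit@deltaT, truth)
    expect_lt(fit@maeMin, 1e-12)
    # profile exceeds the minimum away from the truth and is monotone on
    # each side of it
    prof <- fit@maeProfile
    delays <- as.numeric(names(prof))
    expect_true(all(prof[abs(delays - truth) >= 2] > prof[[as.character(truth)]]))
    expect_true(all(diff(prof[delays >= truth]) >= 0))
    expect_true(all(diff(prof[delays <= truth]) <= 0))
  }
})

test_that("parameter recovery holds at the study design across seeds", {
  # 0-150 h design, 3 replicates, 5% multiplicative noise
  mUp <- KineticModel(tHalf = 7, alphaT = 0.036, K = 0.2, n = 2)
  mDown <- KineticModel(alphaRPlus = log(2) / 0.5, alphaT = 0.036, K = 0.2,
                        n = 2, deltaT = 6)
  res <- vapply(1:50, function(s) {
    simUp <- simulateTimecourse(mUp, "up", noiseCv = 0.05, seed = s)
    thErr <- abs(fitRepressorUp(simUp$repressor)@tHalf - 7) / 7
    simDn <- simulateTimecourse(mDown, "down", noiseCv = 0.05, seed = s + 1000)
    dFit <- estimateDelay(as.data.frame(simDn$target), mDown, "down",
                          grid = seq(0, 25, 0.5))
    c(thErr, abs(dFit@deltaT - 6))
  }, numeric(2))
  expect_lt(median(res[1, ]), 0.10)   # tHalf within 10%
  expect_lte(median(res[2, ]), 0.5)   # delay within one grid step
})
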