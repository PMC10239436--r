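# ODE model of degron-controlled repression.
#
# Repressor: dR/dt = beta_R - alpha_R * R, with alpha_R switched by the
# degrader ligand. After scaling, upregulation (ligand withdrawal) follows
# R(t) = 1 - 2^(-t / tHalf) and downregulation (ligand addition)
# R(t) = exp(-alphaRPlus * t).
# Target: dT/dt = alpha_T * (f(R(t - deltaT)) - T), with the repression
# Hill function f(R) = 1 / (1 + (R/K)^n) obtained by solving the target
# equation at steady state. The repressor is exogenous (its closed form is
# known), so a delay needs no DDE solver: f is simply evaluated at t - deltaT.

#' Scaled repressor level during upregulation
#'
#' Closed-form solution of the repressor ODE after ligand withdrawal with
#' R(0) = 0, parameterised directly by the half-time so its standard error
#' falls out of the fit: R(t) = 1 - 2^(-t/tHalf).
#'
#' @param t time (h), vectorised.
#' @param tHalf half-time to reach steady state (h, > 0).
#' @return scaled repressor level in [0, 1).
#' @examples
#' repressorUp(3, tHalf = 3)  # 0.5
#' @export
repressorUp <- function(t, tHalf) {
  .assertNumber(tHalf, "tHalf", 0, strict_lower = TRUE)
  stopifnot(all(t >= 0))
  1 - 2^(-t / tHalf)
}

#' Scaled repressor level during ligand-induced degradation
#'
#' Closed form after ligand addition with R(0) = 1 and steady state 0:
#' R(t) = exp(-alphaRPlus * t).
#'
#' @param t time (h), vectorised.
#' @param alphaRPlus degradation rate with ligand (1/h, > 0).
#' @return scaled repressor level in (0, 1].
#' @export
repressorDown <- function(t, alphaRPlus) {
  .assertNumber(alphaRPlus, "alphaRPlus", 0, strict_lower = TRUE)
  stopifnot(all(t >= 0))
  exp(-alphaRPlus * t)
}

.seriesFrame <- function(series) {
  if (is(series, "ScaledSeries"))
    data.frame(time = series@time, value = series@value)
  else if (is.data.frame(series)) {
    tcol <- intersect(c("time", "time_h"), names(series))[1]
    if (is.na(tcol) || !"value" %in% names(series))
      stop("series data.frame needs 'time' (or 'time_h') and 'value' columns",
           call. = FALSE)
    data.frame(time = series[[tcol]], value = series$value)
  } else stop("series must be a ScaledSeries or data.frame", call. = FALSE)
}

# linear interpolation of the first crossing of `level` by the replicate mean
.crossingTime <- function(time, value, level, rising = TRUE) {
  agg <- stats::aggregate(value, list(time = time), mean)
  agg <- agg[order(agg$time), ]
  v <- agg$x; tt <- agg$time
  hit <- if (rising) which(v >= level) else which(v <= level)
  hit <- hit[hit > 1]
  if (!length(hit)) return(NA_real_)
  i <- hit[1]
  tt[i - 1] + (level - v[i - 1]) / (v[i] - v[i - 1]) * (tt[i] - tt[i - 1])
}

.nlsParam <- function(fit, name) {
  co <- summary(fit)$coefficients
  c(est = co[name, "Estimate"], se = co[name, "Std. Error"])
}

#' Fit repressor upregulation kinetics
#'
#' Nonlinear least squares of R(t) = 1 - 2^(-t/tHalf) to a scaled
#' upregulation time course over all replicate points. The model is
#' parameterised directly by the half-time, so the reported standard error
#' is the half-time's.
#'
#' @param series a [ScaledSeries-class] (direction "up") or data.frame with
#'   `time` and `value`.
#' @return A [RepressorFit-class].
#' @examples
#' tt <- rep(c(0, 1, 2, 4, 8, 24), 3)
#' fitRepressorUp(data.frame(time = tt, value = repressorUp(tt, 3)))
#' @export
fitRepressorUp <- function(series) {
  d <- .seriesFrame(series)
  if (is(series, "ScaledSeries") && series@direction != "up")
    stop("series direction must be 'up'", call. = FALSE)
  if (length(unique(d$time)) < 4L)
    stop("at least 4 time points are required", call. = FALSE)
  if (all(abs(d$value) < 1e-12))
    stop("no signal: series is identically zero", call. = FALSE)
  start <- .crossingTime(d$time, d$value, 0.5, rising = TRUE)
  if (is.na(start) || start <= 0) start <- max(d$time) / 4
  fit <- tryCatch(
    minpack.lm::nlsLM(value ~ 1 - 2^(-time / tHalf), data = d,
                      start = list(tHalf = start),
                      lower = 1e-6, upper = 100),
    error = function(e) stop("repressor fit did not converge (start tHalf = ",
                             signif(start, 3), ", n = ", nrow(d), " points): ",
                             conditionMessage(e), call. = FALSE))
  p <- .nlsParam(fit, "tHalf")
  new("RepressorFit", tHalf = unname(p["est"]), tHalfSE = unname(p["se"]),
      alpha = log(2) / unname(p["est"]), direction = "up",
      residuals = as.numeric(stats::residuals(fit)), nPoints = nrow(d))
}

#' Fit repressor degradation kinetics
#'
#' Nonlinear least squares of R(t) = exp(-alphaRPlus * t) to a scaled
#' downregulation time course; the half-time ln(2)/alphaRPlus and its
#' standard error (delta method) are reported alongside the rate.
#'
#' @param series a [ScaledSeries-class] (direction "down") or data.frame.
#' @return A [RepressorFit-class].
#' @export
fitRepressorDown <- function(series) {
  d <- .seriesFrame(series)
  if (is(series, "ScaledSeries") && series@direction != "down")
    stop("series direction must be 'down'", call. = FALSE)
  if (length(unique(d$time)) < 4L)
    stop("at least 4 time points are required", call. = FALSE)
  if (stats::sd(d$value) < 1e-12)
    stop("no decay signal: series is constant", call. = FALSE)
  startT <- .crossingTime(d$time, d$value, 0.5, rising = FALSE)
  startA <- if (is.na(startT) || startT <= 0) 1 else log(2) / startT
  fit <- tryCatch(
    minpack.lm::nlsLM(value ~ exp(-a * time), data = d,
                      start = list(a = startA),
                      lower = log(2) / 100, upper = 1e3),
    error = function(e) stop("repressor fit did not converge (start alpha = ",
                             signif(startA, 3), ", n = ", nrow(d), " points): ",
                             conditionMessage(e), call. = FALSE))
  p <- .nlsParam(fit, "a")
  a <- unname(p["est"]); aSE <- unname(p["se"])
  new("RepressorFit", tHalf = log(2) / a, tHalfSE = log(2) / a^2 * aSE,
      alpha = a, direction = "down",
      residuals = as.numeric(stats::residuals(fit)), nPoints = nrow(d))
}

#' Steady-state target level as a Hill function of the repressor
#'
#' Solving the target ODE at steady state gives
#' T(R)/T(R=0) = 1 / (1 + (R/K)^n): K is the scaled repressor level
#' producing 50\% repression and n the Hill coefficient. `K = Inf` encodes
#' the no-repression limit (f = 1).
#'
#' @param R scaled repressor level (>= 0), vectorised.
#' @param K half-repression level (> 0, may be `Inf`).
#' @param n Hill coefficient (> 0).
#' @return scaled target level in (0, 1].
#' @examples
#' steadyStateTarget(c(0, 0.3, 1), K = 0.3, n = 2)
#' @export
steadyStateTarget <- function(R, K, n) {
  stopifnot(all(R >= 0), K > 0, n > 0)
  1 / (1 + (R / K)^n)
}

#' Fit the repressor-target steady-state dose response
#'
#' Least-squares fit of the repression Hill function to titration data
#' taken after the system has reached steady state: scaled repressor level
#' against target fold change relative to the unrepressed state.
#'
#' @param repressor scaled repressor levels (all replicate points).
#' @param target matching target fold changes.
#' @return A [SteadyStateFit-class]. A flat response is flagged
#'   "unidentifiable" (K unbounded) rather than fitted.
#' @export
fitSteadyStateResponse <- function(repressor, target) {
  .assertNumericVector(repressor, "repressor")
  .assertNumericVector(target, "target")
  if (length(repressor) != length(target))
    stop("repressor and target must have equal length", call. = FALSE)
  if (length(unique(repressor)) < 4L)
    stop("at least 4 distinct repressor levels are required", call. = FALSE)
  if (stats::sd(target) < 1e-10)
    return(new("SteadyStateFit", K = NA_real_, KSE = NA_real_, n = NA_real_,
               nSE = NA_real_, rSquared = NA_real_, flag = "unidentifiable"))
  d <- data.frame(R = repressor, y = target)
  kStart <- repressor[which.min(abs(target - 0.5))]
  if (kStart <= 0) kStart <- stats::median(repressor[repressor > 0])
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ 1 / (1 + (R / K)^n), data = d,
                      start = list(K = kStart, n = 2),
                      lower = c(1e-6, 1e-6), upper = c(10, 20)),
    error = function(e) NULL)
  if (is.null(fit))
    return(new("SteadyStateFit", K = NA_real_, KSE = NA_real_, n = NA_real_,
               nSE = NA_real_, rSquared = NA_real_, flag = "not-converged"))
  pk <- .nlsParam(fit, "K"); pn <- .nlsParam(fit, "n")
  res <- stats::residuals(fit)
  r2 <- 1 - sum(res^2) / sum((target - mean(target))^2)
  flag <- if (pk["est"] >= 10 * (1 - 1e-6) || pk["est"] <= 1e-6 * (1 + 1e-6))
    "at-bound" else "ok"
  new("SteadyStateFit", K = unname(pk["est"]), KSE = unname(pk["se"]),
      n = unname(pn["est"]), nSE = unname(pn["se"]), rSquared = r2, flag = flag)
}

#' Closed-form target derepression in the absence of repression
#'
#' When the repressor is removed (or never acts), the target relaxes to its
#' unrepressed steady state at its own degradation rate:
#' T(t)/T_st = 1 + (T0 - 1) * exp(-alphaT * t).
#'
#' @param t time (h), vectorised.
#' @param alphaT target degradation rate (1/h, > 0).
#' @param T0 initial scaled target level in [0, 1].
#' @return scaled target level.
#' @examples
#' derepressionClosedForm(c(0, 19.25), alphaT = 0.036, T0 = 0.2)
#' @export
derepressionClosedForm <- function(t, alphaT, T0) {
  .assertNumber(alphaT, "alphaT", 0, strict_lower = TRUE)
  .assertNumber(T0, "T0", 0, 1)
  stopifnot(all(t >= 0))
  1 + (T0 - 1) * exp(-alphaT * t)
}

#' Estimate the target degradation rate from a derepression time course
#'
#' In a system whose repressor is depleted within an hour and releases
#' repression immediately, target recovery is governed solely by the
#' target's own turnover. Fits the closed-form derepression solution with
#' the rate and initial level free, on a series normalised so that the
#' fully-recovered plateau mean equals 1.
#'
#' @param series a [ScaledSeries-class] or data.frame (`time`, `value`).
#' @return list with `alphaT`, `alphaTSE`, `T0`, `T0SE`, `residuals`,
#'   `nPoints`.
#' @export
fitTargetDegradation <- function(series) {
  d <- .seriesFrame(series)
  if (length(unique(d$time)) < 4L)
    stop("at least 4 time points are required", call. = FALSE)
  if (stats::sd(d$value) < 1e-10)
    stop("unidentifiable: series shows no recovery signal", call. = FALSE)
  t0val <- mean(d$value[d$time == min(d$time)])
  startT0 <- min(max(t0val, 0), 0.99)
  fit <- tryCatch(
    minpack.lm::nlsLM(value ~ 1 + (T0 - 1) * exp(-a * time), data = d,
                      start = list(a = 0.05, T0 = startT0),
                      lower = c(1e-6, 0), upper = c(10, 1)),
    error = function(e) stop("target degradation fit did not converge: ",
                             conditionMessage(e), call. = FALSE))
  pa <- .nlsParam(fit, "a"); pT <- .nlsParam(fit, "T0")
  list(alphaT = unname(pa["est"]), alphaTSE = unname(pa["se"]),
       T0 = unname(pT["est"]), T0SE = unname(pT["se"]),
       residuals = as.numeric(stats::residuals(fit)), nPoints = nrow(d))
}

# scaled repressor trajectory with pre-perturbation history for s < 0
.repressorAt <- function(s, model, direction) {
  if (direction == "up") {
    r <- 1 - 2^(-pmax(s, 0) / model@tHalf)
    r[s < 0] <- 0
  } else {
    r <- exp(-model@alphaRPlus * pmax(s, 0))
    r[s < 0] <- 1
  }
  r
}

.hillRepression <- function(R, K, n) 1 / (1 + (R / K)^n)

#' Simulate the target trajectory of the coupled model
#'
#' Integrates dT/dt = alphaT * (f(R(t - deltaT)) - T) with the repressor
#' evaluated from its closed form for the chosen direction (held at its
#' pre-perturbation value of 0 for "up" or 1 for "down" at negative times).
#' The ODE is linear in T, so each fixed-step RK4 step (dt = 0.05 h) is an
#' affine update computed as a vectorised recursion; halving dt changes the
#' output by < 1e-6.
#'
#' @param model a [KineticModel-class]; `K = Inf` gives the unrepressed
#'   limit f = 1.
#' @param direction repressor direction: "up" (repression run) or "down"
#'   (derepression run).
#' @param tGrid increasing time grid starting at 0 (h).
#' @param deltaT delay (h); defaults to the model's.
#' @param initial initial target level; defaults to 1 for repression runs
#'   and f(1) for derepression runs.
#' @param dt integration step (h).
#' @return numeric target trajectory at `tGrid`.
#' @examples
#' m <- KineticModel(alphaRPlus = 1.4, alphaT = 0.036, K = 0.2, n = 2)
#' simulateTargetDynamics(m, "down", tGrid = c(0, 24, 48, 96))
#' @export
simulateTargetDynamics <- function(model, direction = c("up", "down"),
                                   tGrid, deltaT = model@deltaT,
                                   initial = NULL, dt = 0.05) {
  direction <- match.arg(direction)
  stopifnot(is(model, "KineticModel"))
  .assertNumber(deltaT, "deltaT", 0)
  .assertNumericVector(tGrid, "tGrid")
  if (tGrid[1] != 0 || is.unsorted(tGrid, strictly = TRUE))
    stop("tGrid must increase strictly from 0", call. = FALSE)
  if (is.na(model@alphaT)) stop("model alphaT is required", call. = FALSE)
  if (direction == "up" && is.na(model@tHalf))
    stop("model tHalf is required for direction 'up'", call. = FALSE)
  if (direction == "down" && is.na(model@alphaRPlus))
    stop("model alphaRPlus is required for direction 'down'", call. = FALSE)

  f <- function(s) .hillRepression(.repressorAt(s - deltaT, model, direction),
                                   model@K, model@n)
  if (is.null(initial))
    initial <- if (direction == "up") 1 else .hillRepression(1, model@K, model@n)

  nStep <- ceiling(max(tGrid) / dt - 1e-9)
  times <- seq_len(nStep) * dt - dt          # left endpoints t_k
  g0 <- f(times); g1 <- f(times + dt); gm <- f(times + dt / 2)
  a <- model@alphaT
  rk4 <- function(y, g0, gm, g1) {
    k1 <- a * (g0 - y)
    k2 <- a * (gm - (y + dt / 2 * k1))
    k3 <- a * (gm - (y + dt / 2 * k2))
    k4 <- a * (g1 - (y + dt * k3))
    y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  A <- rk4(1, 0, 0, 0)                       # homogeneous multiplier
  B <- rk4(0, g0, gm, g1)                    # forcing, vectorised over steps
  traj <- c(initial,
            as.numeric(stats::filter(B, A, method = "recursive",
                                     init = initial)))
  nodes <- c(0, seq_len(nStep) * dt)
  idx <- tGrid / dt
  if (max(abs(idx - round(idx))) < 1e-8) traj[round(idx) + 1]
  else stats::approx(nodes, traj, xout = tGrid)$y
}

#' Estimate the repressor-to-target delay by MAE minimisation
#'
#' Simulates the coupled model over a grid of candidate delays and scores
#' each against the observed target series by the mean absolute error over
#' all replicate points; the delay minimising the MAE is reported (ties go
#' to the smaller delay).
#'
#' @param observed target [ScaledSeries-class] or data.frame, on the same
#'   scaling as the simulation.
#' @param model a [KineticModel-class] with rate parameters already
#'   estimated.
#' @param direction repressor direction of the experiment ("up" for a
#'   repression run, "down" for derepression).
#' @param grid candidate delays (h), default 0 to 25 in 0.5 h steps.
#' @param initial optional initial target level override.
#' @return A [DelayFit-class].
#' @export
estimateDelay <- function(observed, model, direction = c("up", "down"),
                          grid = seq(0, 25, by = 0.5), initial = NULL) {
  direction <- match.arg(direction)
  d <- .seriesFrame(observed)
  .assertNumericVector(grid, "grid")
  if (any(grid < 0)) stop("delays must be non-negative", call. = FALSE)
  tUnique <- sort(unique(d$time))
  if (tUnique[1] != 0)
    stop("observed series must start at t = 0", call. = FALSE)
  mae <- vapply(grid, function(dtau) {
    sim <- simulateTargetDynamics(model, direction, tGrid = tUnique,
                                  deltaT = dtau, initial = initial)
    simAt <- sim[match(d$time, tUnique)]
    mean(abs(d$value - simAt))
  }, numeric(1))
  names(mae) <- grid
  best <- which.min(mae)   # which.min takes the first minimum: smaller delay
  new("DelayFit", deltaT = grid[best], maeProfile = mae, maeMin = mae[[best]])
}
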