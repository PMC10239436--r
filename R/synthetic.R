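# Seeded synthetic-data generators emulating the statistical structure of
# the assays: log-normal per-cell fluorescence over an autofluorescence
# background, scatter channels with doublets, analog vs digital repression
# regimes, replicate kinetic time courses generated by the ODE model, and
# Hill-shaped dose-response tables with multiplicative noise. Every
# generator is a pure function of its arguments and seed.

#' Simulate a single-cell event population
#'
#' Generates scatter and fluorescence channels suitable for gate testing:
#' FSC-A and SSC-A are correlated log-normals; FSC-H is proportional to
#' FSC-A for singlets and halved (at equal area) for doublets; each
#' fluorescence channel is linear-space autofluorescence plus a log-normal
#' mixture expression signal.
#'
#' @param nCells number of events (>= 1).
#' @param channels named list of fluorescence channel specs; each a list
#'   with `autofluorescence = c(meanLog10, sdLog10)` and
#'   `modes = data.frame(weight, meanLog10, sdLog10)` (weights sum to 1).
#' @param doubletFraction fraction of doublet events in [0, 1].
#' @param scatter list: `fscMeanLog10`, `fscSdLog10`, `sscSlope`,
#'   `sscSdLog10`, `fschSlope`, `fschCv`.
#' @param seed RNG seed (required).
#' @return An [EventTable-class] with channels FSC-A, SSC-A, FSC-H and the
#'   fluorescence channels.
#' @examples
#' ev <- simulateEventPopulation(nCells = 1000, seed = 7)
#' ev
#' @export
simulateEventPopulation <- function(nCells = 10000L,
  channels = list(`mCherry-A` = list(
    autofluorescence = c(meanLog10 = 1.5, sdLog10 = 0.2),
    modes = data.frame(weight = 1, meanLog10 = 3.5, sdLog10 = 0.25))),
  doubletFraction = 0.05,
  scatter = list(fscMeanLog10 = 5, fscSdLog10 = 0.08, sscSlope = 0.9,
                 sscSdLog10 = 0.1, fschSlope = 0.85, fschCv = 0.03),
  seed) {
  seed <- .assertSeed(seed)
  nCells <- as.integer(nCells)
  if (nCells < 1L) stop("nCells must be >= 1", call. = FALSE)
  .assertNumber(doubletFraction, "doubletFraction", 0, 1)
  for (ch in channels) {
    if (abs(sum(ch$modes$weight) - 1) > 1e-8)
      stop("expression mode weights must sum to 1", call. = FALSE)
  }

  withr::with_seed(seed, {
    fscLog <- stats::rnorm(nCells, scatter$fscMeanLog10, scatter$fscSdLog10)
    fscA <- 10^fscLog
    sscA <- 10^(scatter$sscSlope * (fscLog - scatter$fscMeanLog10) +
                  scatter$fscMeanLog10 - 0.7 +
                  stats::rnorm(nCells, 0, scatter$sscSdLog10))
    doublet <- stats::runif(nCells) < doubletFraction
    fschA <- scatter$fschSlope * fscA * (1 - doublet / 2) *
      .noiseFactor(nCells, scatter$fschCv)
    ex <- cbind(`FSC-A` = fscA, `SSC-A` = sscA, `FSC-H` = fschA)

    for (nm in names(channels)) {
      ch <- channels[[nm]]
      af <- 10^stats::rnorm(nCells, ch$autofluorescence[["meanLog10"]],
                            ch$autofluorescence[["sdLog10"]])
      comp <- sample.int(nrow(ch$modes), nCells, replace = TRUE,
                         prob = ch$modes$weight)
      signal <- 10^stats::rnorm(nCells, ch$modes$meanLog10[comp],
                                ch$modes$sdLog10[comp])
      ex <- cbind(ex, af + signal)
      colnames(ex)[ncol(ex)] <- nm
    }
    EventTable(ex, sampleId = sprintf("sim-seed%d", seed),
               condition = list(doublet_fraction = doubletFraction))
  })
}

#' Simulate per-cell target expression under analog or digital repression
#'
#' Analog regime: each cell draws a repressor level (log-normal around
#' `rBar` with cell-to-cell CV) and its mean target level follows the
#' repression Hill function of that level, producing a unimodal,
#' intermediate distribution with negatively correlated repressor and
#' target. Digital regime: cells switch off with probability `pOff`
#' (by default a Hill function of `rBar`), independently of their own
#' repressor level, producing a bimodal mixture of background-level and
#' unrepressed-level cells with repressor-matched subpopulations.
#'
#' @param regime "analog" or "digital".
#' @param rBar mean scaled repressor level (>= 0).
#' @param cv cell-to-cell repressor CV (>= 0).
#' @param K,n repression Hill parameters.
#' @param pOff silencing probability for the digital regime; `NULL` uses
#'   `rBar^n / (K^n + rBar^n)`.
#' @param nCells number of cells.
#' @param onLevelLog10,offLevelLog10 log10 centres of the unrepressed and
#'   silenced target modes (A.F.U.).
#' @param modeSdLog10 log10 spread of the target modes.
#' @param seed RNG seed (required).
#' @return list with numeric vectors `target` (A.F.U.) and `repressor`
#'   (scaled per-cell levels).
#' @examples
#' d <- simulateRegime("digital", rBar = 0.3, cv = 0.2, K = 0.3, n = 4,
#'                     pOff = 0.5, nCells = 1000, seed = 3)
#' @export
simulateRegime <- function(regime = c("analog", "digital"), rBar, cv = 0.2,
                           K = 0.3, n = 2, pOff = NULL, nCells = 10000L,
                           onLevelLog10 = 3.5, offLevelLog10 = 1.5,
                           modeSdLog10 = 0.25, seed) {
  regime <- match.arg(regime)
  seed <- .assertSeed(seed)
  .assertNumber(rBar, "rBar", 0)
  .assertNumber(cv, "cv", 0)
  nCells <- as.integer(nCells)

  withr::with_seed(seed, {
    rCell <- rBar * .noiseFactor(nCells, cv)
    if (regime == "analog") {
      frac <- steadyStateTarget(rCell, K, n)
      target <- 10^(log10(pmax(frac, 1e-12) * 10^onLevelLog10) +
                      stats::rnorm(nCells, 0, modeSdLog10))
      # floor at the silenced/background level
      target <- pmax(target, 10^stats::rnorm(nCells, offLevelLog10, modeSdLog10))
    } else {
      if (is.null(pOff)) pOff <- rBar^n / (K^n + rBar^n)
      .assertNumber(pOff, "pOff", 0, 1)
      off <- stats::runif(nCells) < pOff
      centre <- ifelse(off, offLevelLog10, onLevelLog10)
      target <- 10^stats::rnorm(nCells, centre, modeSdLog10)
    }
    list(target = target, repressor = rCell)
  })
}

#' Simulate replicate kinetic time courses from the ODE model
#'
#' Runs the model forward: the repressor from its closed form for the
#' chosen direction, the target from [simulateTargetDynamics()], each
#' replicate point multiplied by log-normal noise of the given CV
#' (`noiseCv = 0` returns exact model values).
#'
#' @param model a [KineticModel-class].
#' @param direction "up" (repression run) or "down" (derepression run).
#' @param timePoints sampling times (h), must include 0 and at least one
#'   later point.
#' @param nReplicates number of replicates.
#' @param noiseCv multiplicative noise CV (>= 0).
#' @param deltaT delay (h); defaults to the model's.
#' @param seed RNG seed (required).
#' @return list of two [ScaledSeries-class] objects: `repressor` and
#'   `target`.
#' @examples
#' m <- KineticModel(tHalf = 7, alphaT = 0.036, K = 0.2, n = 2)
#' sim <- simulateTimecourse(m, "up", timePoints = c(0, 2, 4, 8, 24, 48),
#'                           noiseCv = 0.05, seed = 11)
#' @export
simulateTimecourse <- function(model, direction = c("up", "down"),
                               timePoints = c(0, 2, 4, 8, 12, 24, 48, 72, 96,
                                              120, 150),
                               nReplicates = 3L, noiseCv = 0.05,
                               deltaT = model@deltaT, seed) {
  direction <- match.arg(direction)
  seed <- .assertSeed(seed)
  .assertNumber(noiseCv, "noiseCv", 0)
  timePoints <- sort(unique(timePoints))
  if (length(timePoints) < 2L)
    stop("at least two distinct time points are required for fitting",
         call. = FALSE)
  if (timePoints[1] != 0) stop("timePoints must include 0", call. = FALSE)

  rTrue <- .repressorAt(timePoints, model, direction)
  tTrue <- simulateTargetDynamics(model, direction, tGrid = timePoints,
                                  deltaT = deltaT)
  nP <- length(timePoints)
  withr::with_seed(seed, {
    mk <- function(true, dir) {
      time <- rep(timePoints, nReplicates)
      repl <- rep(sprintf("r%d", seq_len(nReplicates)), each = nP)
      value <- rep(true, nReplicates) * .noiseFactor(nP * nReplicates, noiseCv)
      ScaledSeries(time, value, repl, dir,
                   scaling = list(generator = "model", noiseCv = noiseCv))
    }
    list(repressor = mk(rTrue, direction),
         target = mk(tTrue, if (direction == "up") "down" else "up"))
  })
}

#' Simulate a Hill dose-response table
#'
#' @param direction "activated" or "repressed".
#' @param xHalf,n half-effect dose and Hill coefficient of the generating
#'   curve.
#' @param floorOrCeiling floor (activated) or ceiling (repressed) of the
#'   generating curve.
#' @param doses regulator fold changes (> 0).
#' @param nReplicates replicates per dose.
#' @param noiseCv multiplicative log-normal noise CV.
#' @param seed RNG seed (required).
#' @param target target label stored in the table.
#' @return data.frame with columns `X`, `Y`, `replicate`, `target`,
#'   `direction`.
#' @examples
#' simulateDoseResponse("activated", 0.55, 2, 0.05,
#'                      doses = c(1, 0.7, 0.45, 0.25, 0.1), seed = 5)
#' @export
simulateDoseResponse <- function(direction = c("activated", "repressed"),
                                 xHalf, n, floorOrCeiling,
                                 doses = c(1, 0.7, 0.45, 0.25, 0.1),
                                 nReplicates = 3L, noiseCv = 0.05, seed,
                                 target = "target") {
  direction <- match.arg(direction)
  seed <- .assertSeed(seed)
  stopifnot(all(doses > 0))
  .assertNumber(noiseCv, "noiseCv", 0)
  yTrue <- if (direction == "activated")
    hillActivated(doses, xHalf, n, floorOrCeiling)
  else hillRepressed(doses, xHalf, n, floorOrCeiling)
  nD <- length(doses)
  withr::with_seed(seed, {
    data.frame(X = rep(doses, nReplicates),
               Y = rep(yTrue, nReplicates) * .noiseFactor(nD * nReplicates, noiseCv),
               replicate = rep(sprintf("r%d", seq_len(nReplicates)), each = nD),
               target = target, direction = direction,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a degron characterisation panel
#'
#' Generates tRFP/tBFP MFI pairs whose relative ratios centre on the given
#' per-degron A (stabilised state) and B (destabilised state), with a
#' no-degron control at 100\%. Measurements carry multiplicative log-normal
#' noise per replicate.
#'
#' @param truth data.frame with columns `degron`, `A`, `B`, `stability`
#'   ("default-stable" or "default-unstable").
#' @param noiseCv replicate noise CV (>= 0).
#' @param nReplicates replicates per condition.
#' @param tbfpMfi tBFP expression level used for all samples (A.F.U.).
#' @param maxLigand maximal ligand concentration (nM).
#' @param seed RNG seed (required).
#' @return data.frame of measurements with columns `degron`, `ligand_nM`,
#'   `trfp_mfi`, `tbfp_mfi`, `replicate` (control rows have
#'   `degron = "none"`).
#' @examples
#' truth <- data.frame(degron = "FKBP12-F36V", A = 80, B = 2,
#'                     stability = "default-stable")
#' panel <- simulateDegronPanel(truth, noiseCv = 0, seed = 2)
#' @export
simulateDegronPanel <- function(truth, noiseCv = 0.05, nReplicates = 3L,
                                tbfpMfi = 1000, maxLigand = 500, seed) {
  seed <- .assertSeed(seed)
  need <- c("degron", "A", "B", "stability")
  missing <- setdiff(need, names(truth))
  if (length(missing))
    stop("truth table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  .assertNumber(noiseCv, "noiseCv", 0)

  withr::with_seed(seed, {
    rows <- list()
    for (rep in sprintf("r%d", seq_len(nReplicates))) {
      for (lig in c(0, maxLigand))   # control line measured in both conditions
        rows[[length(rows) + 1L]] <- data.frame(
          degron = "none", ligand_nM = lig,
          trfp_mfi = tbfpMfi * .noiseFactor(1, noiseCv),
          tbfp_mfi = tbfpMfi * .noiseFactor(1, noiseCv),
          replicate = rep, stringsAsFactors = FALSE)
      for (i in seq_len(nrow(truth))) {
        stabilisedAtMax <- truth$stability[i] == "default-unstable"
        for (lig in c(0, maxLigand)) {
          stabilised <- (lig == maxLigand) == stabilisedAtMax
          pct <- if (stabilised) truth$A[i] else truth$B[i]
          rows[[length(rows) + 1L]] <- data.frame(
            degron = truth$degron[i], ligand_nM = lig,
            trfp_mfi = tbfpMfi * pct / 100 * .noiseFactor(1, noiseCv),
            tbfp_mfi = tbfpMfi * .noiseFactor(1, noiseCv),
            replicate = rep, stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}
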