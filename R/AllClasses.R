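#' @import methods
NULL

#' EventTable: single-cell flow-cytometry events
#'
#' Container for per-cell scatter and fluorescence measurements of one sample,
#' in arbitrary fluorescence units (A.F.U.) as recorded by the cytometer.
#' Rows are events (cells), columns are channels. Condition labels (cell line,
#' guide type, ligand concentration, time point, replicate, ...) travel with
#' the object as a named list.
#'
#' @slot exprs numeric matrix of per-cell values; column names are channel
#'   names and must be unique.
#' @slot sampleId single character sample identifier.
#' @slot condition named list of condition labels.
#'
#' @seealso [readEventTable()], [gateLiveCells()], [computeMfi()]
#' @export
setClass("EventTable",
  representation(exprs = "matrix", sampleId = "character", condition = "list"),
  prototype(exprs = matrix(numeric(0), 0, 0), sampleId = NA_character_,
            condition = list()))

setValidity("EventTable", function(object) {
  ex <- object@exprs
  msg <- character(0)
  if (!is.numeric(ex)) msg <- c(msg, "event values must be numeric")
  if (nrow(ex) < 1L) msg <- c(msg, "EventTable must contain at least one event")
  if (is.null(colnames(ex)) || anyDuplicated(colnames(ex)))
    msg <- c(msg, "channel names must be present and unique")
  if (length(ex) && any(!is.finite(ex)))
    msg <- c(msg, "all event values must be finite")
  for (sc in intersect(c("FSC-A", "SSC-A"), colnames(ex)))
    if (any(ex[, sc] < 0)) msg <- c(msg, sprintf("scatter channel %s must be non-negative", sc))
  if (length(object@sampleId) != 1L) msg <- c(msg, "sampleId must be length 1")
  if (length(msg)) msg else TRUE
})

#' Construct an EventTable
#'
#' @param exprs numeric matrix (events x channels) with unique column names.
#' @param sampleId sample identifier.
#' @param condition named list of condition labels.
#' @return An [EventTable-class] object.
#' @examples
#' ev <- EventTable(cbind(`FSC-A` = c(1e4, 2e4), `SSC-A` = c(5e3, 6e3),
#'                        `FSC-H` = c(9e3, 1.8e4), `BV421-A` = c(150, 320)),
#'                  sampleId = "s1")
#' nEvents(ev)
#' @export
EventTable <- function(exprs, sampleId = "sample", condition = list()) {
  new("EventTable", exprs = as.matrix(exprs), sampleId = as.character(sampleId),
      condition = condition)
}

#' GateResult: a reusable gate with explicit parameters
#'
#' Records which events a gate kept and, crucially, the absolute gate
#' coordinates (A.F.U. cutoffs or fitted line and band width) so the same
#' gate can be re-applied to every sample of an experiment.
#'
#' @slot kind "live" or "singlet".
#' @slot kept integer indices of retained events (relative to the gated input).
#' @slot nInput number of events the gate was computed on.
#' @slot parameters named list of absolute gate coordinates.
#' @export
setClass("GateResult",
  representation(kind = "character", kept = "integer", nInput = "integer",
                 parameters = "list"))

setValidity("GateResult", function(object) {
  msg <- character(0)
  if (!object@kind %in% c("live", "singlet")) msg <- c(msg, "kind must be 'live' or 'singlet'")
  if (length(object@kept) && (min(object@kept) < 1L || max(object@kept) > object@nInput))
    msg <- c(msg, "kept indices must lie within the input rows")
  if (anyDuplicated(object@kept)) msg <- c(msg, "kept indices must be unique")
  if (length(msg)) msg else TRUE
})

#' ScaledSeries: replicate-resolved scaled time course
#'
#' Background-subtracted MFI time courses rescaled to the unit interval:
#' for upregulation series the plateau (default 25-150 h) mean maps to 1 and
#' the t = 0 mean to 0; for downregulation series the pre-treatment mean maps
#' to 1 and the fully-degraded plateau mean to 0.
#'
#' @slot time numeric vector of time points (h), one per observation.
#' @slot value numeric vector of scaled values.
#' @slot replicate character replicate identifiers, one per observation.
#' @slot direction "up" or "down".
#' @slot scaling named list of scaling metadata (anchors and plateau window).
#' @seealso [scaleTimecourse()], [fitRepressorUp()], [fitTargetDegradation()]
#' @export
setClass("ScaledSeries",
  representation(time = "numeric", value = "numeric", replicate = "character",
                 direction = "character", scaling = "list"))

setValidity("ScaledSeries", function(object) {
  msg <- character(0)
  n <- length(object@time)
  if (length(object@value) != n || length(object@replicate) != n)
    msg <- c(msg, "time, value and replicate must have equal length")
  if (n < 1L) msg <- c(msg, "series must contain at least one observation")
  if (any(!is.finite(object@time)) || any(!is.finite(object@value)))
    msg <- c(msg, "time and value must be finite")
  if (!object@direction %in% c("up", "down"))
    msg <- c(msg, "direction must be 'up' or 'down'")
  if (length(msg)) msg else TRUE
})

#' Construct a ScaledSeries
#'
#' @param time,value,replicate parallel vectors (replicate defaults to "r1").
#' @param direction "up" or "down".
#' @param scaling named list of scaling metadata.
#' @return A [ScaledSeries-class] object.
#' @export
ScaledSeries <- function(time, value, replicate = "r1", direction = "up",
                         scaling = list()) {
  n <- length(time)
  new("ScaledSeries", time = as.numeric(time), value = as.numeric(value),
      replicate = rep_len(as.character(replicate), n), direction = direction,
      scaling = scaling)
}

#' KineticModel: parameters of the repressor/target ODE system
#'
#' The system is dR/dt = beta_R - alpha_R * R for the degron-controlled
#' repressor and dT/dt = alpha_T * (f(R(t - delta_t)) - T) for the scaled
#' target, with f(R) = 1 / (1 + (R/K)^n) the steady-state repression Hill
#' function. Scaling removes beta_R; the repressor follows its closed form
#' (saturating rise with half-time tHalf after ligand withdrawal,
#' exponential decay at rate alphaRPlus after ligand addition).
#'
#' @slot tHalf repressor upregulation half-time (h).
#' @slot alphaRPlus repressor degradation rate with ligand (1/h).
#' @slot alphaT target decay rate (1/h).
#' @slot K scaled repressor level giving 50\% target repression.
#' @slot n Hill coefficient of the repression function.
#' @slot deltaT delay between repressor change and target production (h).
#' @export
setClass("KineticModel",
  representation(tHalf = "numeric", alphaRPlus = "numeric", alphaT = "numeric",
                 K = "numeric", n = "numeric", deltaT = "numeric"))

setValidity("KineticModel", function(object) {
  msg <- character(0)
  chk <- function(x, nm, lo = 0) {
    if (length(x) != 1L) return(sprintf("%s must be length 1", nm))
    if (!is.na(x) && x <= lo) return(sprintf("%s must be positive", nm))
    NULL
  }
  msg <- c(msg, chk(object@tHalf, "tHalf"), chk(object@alphaRPlus, "alphaRPlus"),
           chk(object@alphaT, "alphaT"), chk(object@K, "K"), chk(object@n, "n"))
  if (!is.na(object@deltaT) && (object@deltaT < 0 || object@deltaT > 25))
    msg <- c(msg, "deltaT must lie in [0, 25] h")
  msg <- msg[!vapply(msg, is.null, logical(1))]
  if (length(msg)) unlist(msg) else TRUE
})

#' Construct a KineticModel
#'
#' @param tHalf,alphaRPlus,alphaT,K,n,deltaT model parameters; unknown
#'   parameters may be left `NA` (e.g. `tHalf` for a derepression-only model).
#' @return A [KineticModel-class] object.
#' @examples
#' m <- KineticModel(alphaRPlus = 1.4, alphaT = 0.036, K = 0.2, n = 2)
#' @export
KineticModel <- function(tHalf = NA_real_, alphaRPlus = NA_real_,
                         alphaT = NA_real_, K = NA_real_, n = NA_real_,
                         deltaT = 0) {
  new("KineticModel", tHalf = as.numeric(tHalf),
      alphaRPlus = as.numeric(alphaRPlus), alphaT = as.numeric(alphaT),
      K = as.numeric(K), n = as.numeric(n), deltaT = as.numeric(deltaT))
}

#' RepressorFit: fitted repressor kinetics
#'
#' @slot tHalf fitted half-time (h).
#' @slot tHalfSE standard error of the half-time (h).
#' @slot alpha fitted rate constant (1/h); ln(2)/tHalf.
#' @slot direction "up" (ligand withdrawal) or "down" (ligand addition).
#' @slot residuals fit residuals.
#' @slot nPoints number of data points used.
#' @export
setClass("RepressorFit",
  representation(tHalf = "numeric", tHalfSE = "numeric", alpha = "numeric",
                 direction = "character", residuals = "numeric",
                 nPoints = "integer"))

#' SteadyStateFit: Hill parameters of repressor-target dose response
#'
#' @slot K scaled repressor level at 50\% repression; @slot KSE its SE.
#' @slot n Hill coefficient; @slot nSE its SE.
#' @slot rSquared coefficient of determination over all points.
#' @slot flag "ok", "unidentifiable" or "at-bound".
#' @export
setClass("SteadyStateFit",
  representation(K = "numeric", KSE = "numeric", n = "numeric", nSE = "numeric",
                 rSquared = "numeric", flag = "character"))

#' DelayFit: MAE-minimising delay estimate
#'
#' @slot deltaT delay (h) minimising the mean absolute error.
#' @slot maeProfile named numeric vector mapping each candidate delay to its MAE.
#' @slot maeMin minimum MAE.
#' @export
setClass("DelayFit",
  representation(deltaT = "numeric", maeProfile = "numeric", maeMin = "numeric"))

setValidity("DelayFit", function(object) {
  msg <- character(0)
  if (!isTRUE(all.equal(object@maeMin, min(object@maeProfile))))
    msg <- c(msg, "maeMin must equal the minimum of the profile")
  if (length(msg)) msg else TRUE
})

#' HillFit: four-parameter Hill dose-response fit
#'
#' For targets activated by the titrated factor the ceiling is fixed at 1
#' (the unrepressed state) and the floor is fitted; for repressed targets the
#' floor is fixed at 1 and the ceiling is fitted.
#'
#' @slot xHalf half-effect regulator fold change; @slot xHalfSE its SE.
#' @slot n Hill coefficient; @slot nSE its SE.
#' @slot tMin floor; @slot tMax ceiling (one of the two is fixed at 1).
#' @slot direction "activated" or "repressed".
#' @slot rSquared coefficient of determination over all replicate points.
#' @slot flag "ok", "unidentifiable", "at-bound" or "not-converged".
#' @export
setClass("HillFit",
  representation(xHalf = "numeric", xHalfSE = "numeric", n = "numeric",
                 nSE = "numeric", tMin = "numeric", tMax = "numeric",
                 direction = "character", rSquared = "numeric",
                 flag = "character"))

#' PreparedDistribution: preprocessed values for the modality test
#'
#' Replicates merged with equal weight, non-positive values dropped (log10
#' is applied), and mode-location bounds fixed at the 5th and 95th
#' percentile of the merged values to avoid spurious modes in the tails.
#'
#' @slot values log10-transformed merged values.
#' @slot bounds numeric(2), mode-location bounds (log10 units).
#' @slot nDroppedNonpositive number of values <= 0 removed before log10.
#' @export
setClass("PreparedDistribution",
  representation(values = "numeric", bounds = "numeric",
                 nDroppedNonpositive = "integer"))

setValidity("PreparedDistribution", function(object) {
  msg <- character(0)
  if (length(object@bounds) != 2L || object@bounds[1] >= object@bounds[2])
    msg <- c(msg, "bounds must be two increasing numbers")
  if (length(object@values) &&
      (object@bounds[1] < min(object@values) || object@bounds[2] > max(object@values)))
    msg <- c(msg, "bounds must lie within the data range")
  if (any(!is.finite(object@values))) msg <- c(msg, "values must be finite")
  if (length(msg)) msg else TRUE
})

#' ModalityResult: outcome of the Hall-York unimodality test
#'
#' @slot hCrit critical bandwidth of the observed data (log10 units).
#' @slot pValue calibrated bootstrap p-value.
#' @slot nBoot number of smoothed-bootstrap resamples.
#' @slot seed RNG seed used for the bootstrap.
#' @slot bounds mode-location bounds used.
#' @slot alpha significance level for the reported decision.
#' @slot decision "unimodal" (not rejected) or "multimodal" (rejected).
#' @export
setClass("ModalityResult",
  representation(hCrit = "numeric", pValue = "numeric", nBoot = "integer",
                 seed = "integer", bounds = "numeric", alpha = "numeric",
                 decision = "character"))

setValidity("ModalityResult", function(object) {
  msg <- character(0)
  if (object@hCrit <= 0) msg <- c(msg, "hCrit must be positive")
  if (object@pValue < 0 || object@pValue > 1) msg <- c(msg, "pValue must be in [0,1]")
  if (length(msg)) msg else TRUE
})
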