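#' Number of events in an EventTable
#' @param x an [EventTable-class].
#' @return integer event count.
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' Channel names of an EventTable
#' @param x an [EventTable-class].
#' @return character vector of channel names.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' Event matrix of an EventTable
#' @param x an [EventTable-class].
#' @return numeric matrix (events x channels).
#' @export
setGeneric("eventData", function(x) standardGeneric("eventData"))

#' Indices kept by a gate
#' @param x a [GateResult-class].
#' @return integer vector of kept row indices.
#' @export
setGeneric("keptIndices", function(x) standardGeneric("keptIndices"))

#' Re-apply a recorded gate to an EventTable
#'
#' Applies the absolute gate coordinates stored in a [GateResult-class] to
#' any sample, so that the same gating coordinates are used for all files of
#' one experiment.
#'
#' @param events an [EventTable-class].
#' @param gate a [GateResult-class].
#' @return the gated [EventTable-class].
#' @export
setGeneric("applyGate", function(events, gate) standardGeneric("applyGate"))

#' @export
setMethod("nEvents", "EventTable", function(x) nrow(x@exprs))

#' @export
setMethod("channelNames", "EventTable", function(x) colnames(x@exprs))

#' @export
setMethod("eventData", "EventTable", function(x) x@exprs)

#' @export
setMethod("keptIndices", "GateResult", function(x) x@kept)

setMethod("show", "EventTable", function(object) {
  cat("EventTable '", object@sampleId, "': ", nrow(object@exprs), " events, ",
      ncol(object@exprs), " channels (", paste(colnames(object@exprs), collapse = ", "),
      ")\n", sep = "")
  if (length(object@condition))
    cat("  condition: ", paste(names(object@condition), unlist(object@condition),
                               sep = "=", collapse = ", "), "\n", sep = "")
})

setMethod("show", "GateResult", function(object) {
  cat(sprintf("GateResult (%s): kept %d / %d events (%.1f%%)\n", object@kind,
              length(object@kept), object@nInput,
              100 * length(object@kept) / object@nInput))
})

setMethod("show", "ScaledSeries", function(object) {
  cat(sprintf("ScaledSeries (%s): %d points, %d replicates, t in [%g, %g] h\n",
              object@direction, length(object@time),
              length(unique(object@replicate)), min(object@time), max(object@time)))
})

setMethod("show", "KineticModel", function(object) {
  cat("KineticModel:\n")
  cat(sprintf("  tHalf      = %g h\n  alphaRPlus = %g 1/h\n  alphaT     = %g 1/h\n",
              object@tHalf, object@alphaRPlus, object@alphaT))
  cat(sprintf("  K = %g, n = %g, deltaT = %g h\n", object@K, object@n, object@deltaT))
})

setMethod("show", "RepressorFit", function(object) {
  cat(sprintf("RepressorFit (%s): t1/2 = %.3f +/- %.3f h (alpha = %.4f 1/h, n = %d points)\n",
              object@direction, object@tHalf, object@tHalfSE, object@alpha,
              object@nPoints))
})

setMethod("show", "SteadyStateFit", function(object) {
  cat(sprintf("SteadyStateFit: K = %.3g +/- %.2g, n = %.3g +/- %.2g, R^2 = %.4f [%s]\n",
              object@K, object@KSE, object@n, object@nSE, object@rSquared,
              object@flag))
})

setMethod("show", "DelayFit", function(object) {
  cat(sprintf("DelayFit: deltaT = %g h (MAE = %.4g over %d candidate delays)\n",
              object@deltaT, object@maeMin, length(object@maeProfile)))
})

setMethod("show", "HillFit", function(object) {
  cat(sprintf("HillFit (%s): [X]1/2 = %.3g +/- %.2g, n = %.3g +/- %.2g\n",
              object@direction, object@xHalf, object@xHalfSE, object@n, object@nSE))
  cat(sprintf("  floor = %.3g, ceiling = %.3g, R^2 = %.4f [%s]\n",
              object@tMin, object@tMax, object@rSquared, object@flag))
})

setMethod("show", "PreparedDistribution", function(object) {
  cat(sprintf("PreparedDistribution: %d log10 values, mode bounds [%.3f, %.3f], %d non-positive dropped\n",
              length(object@values), object@bounds[1], object@bounds[2],
              object@nDroppedNonpositive))
})

setMethod("show", "ModalityResult", function(object) {
  cat(sprintf("Hall-York modality test: h_crit = %.4g, p = %.4g (%d bootstraps, seed %d)\n",
              object@hCrit, object@pValue, object@nBoot, object@seed))
  cat(sprintf("  decision at alpha = %g: %s\n", object@alpha, object@decision))
})
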