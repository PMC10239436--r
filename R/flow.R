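#' Read single-cell event data from FCS or CSV
#'
#' CSV event tables use a header row with exact channel names, comma
#' separation and one row per event. FCS channels are named from `$PnN` and
#' can be renamed through `channelAliases`.
#'
#' @param path path to the file.
#' @param format "auto" (by extension), "csv" or "fcs".
#' @param channelAliases optional named character vector mapping original
#'   channel names to the names used downstream, e.g.
#'   `c("BV421-A" = "tBFP-A")`.
#' @param sampleId sample identifier; defaults to the file base name.
#' @param condition named list of condition labels attached to the sample.
#' @return An [EventTable-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(`FSC-A` = c(1e4, 2e4, 3e4), `SSC-A` = c(1e3, 2e3, 3e3),
#'                      `FSC-H` = c(9e3, 1.9e4, 2.8e4), `BV421-A` = c(10, 20, 30),
#'                      check.names = FALSE), f, row.names = FALSE)
#' ev <- readEventTable(f)
#' channelNames(ev)
#' @export
readEventTable <- function(path, format = c("auto", "csv", "fcs"),
                           channelAliases = NULL, sampleId = NULL,
                           condition = list()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  if (is.null(sampleId))
    sampleId <- tools::file_path_sans_ext(basename(path))

  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE)
    if (nrow(df) == 0L) stop("no events in '", path, "'", call. = FALSE)
    if (!all(vapply(df, is.numeric, logical(1))))
      stop("malformed event CSV: non-numeric column(s) ",
           paste(names(df)[!vapply(df, is.numeric, logical(1))], collapse = ", "),
           call. = FALSE)
    ex <- as.matrix(df)
  } else {
    ex <- .readFCS(path)
    if (nrow(ex) == 0L) stop("no events in '", path, "'", call. = FALSE)
  }

  if (!is.null(channelAliases)) {
    hit <- colnames(ex) %in% names(channelAliases)
    colnames(ex)[hit] <- unname(channelAliases[colnames(ex)[hit]])
  }
  EventTable(ex, sampleId = sampleId, condition = condition)
}

.requireChannels <- function(events, channels) {
  missing <- setdiff(channels, channelNames(events))
  if (length(missing))
    stop("required channel(s) missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
}

.subsetEvents <- function(events, keep) {
  ex <- events@exprs[keep, , drop = FALSE]
  new("EventTable", exprs = ex, sampleId = events@sampleId,
      condition = events@condition)
}

#' Gate live cells on a scatter-percentile rectangle
#'
#' Keeps events inside the rectangle spanned by the `[loPct, hiPct]`
#' percentiles of FSC-A and SSC-A, a parameter-explicit surrogate for
#' automated boundary gating. The absolute A.F.U. cutoffs are recorded in
#' the returned [GateResult-class] so the identical gate coordinates can be
#' re-applied to every sample of an experiment with [applyGate()]. A single
#' event always falls inside its own percentile rectangle and is kept.
#'
#' @param events an [EventTable-class] with FSC-A and SSC-A channels.
#' @param loPct,hiPct percentile bounds, `0 <= loPct < hiPct <= 100`.
#' @return A [GateResult-class] of kind "live".
#' @examples
#' ev <- simulateEventPopulation(nCells = 2000, seed = 1)
#' g <- gateLiveCells(ev, 1, 99)
#' length(keptIndices(g))
#' @export
gateLiveCells <- function(events, loPct = 1, hiPct = 99) {
  stopifnot(is(events, "EventTable"))
  .requireChannels(events, c("FSC-A", "SSC-A"))
  .assertNumber(loPct, "loPct", 0, 100)
  .assertNumber(hiPct, "hiPct", 0, 100)
  if (loPct >= hiPct) stop("loPct must be < hiPct", call. = FALSE)
  ex <- eventData(events)
  bounds <- lapply(c(`FSC-A` = "FSC-A", `SSC-A` = "SSC-A"), function(ch)
    unname(stats::quantile(ex[, ch], c(loPct, hiPct) / 100)))
  keep <- which(ex[, "FSC-A"] >= bounds[["FSC-A"]][1] &
                ex[, "FSC-A"] <= bounds[["FSC-A"]][2] &
                ex[, "SSC-A"] >= bounds[["SSC-A"]][1] &
                ex[, "SSC-A"] <= bounds[["SSC-A"]][2])
  if (length(keep) == 0L) stop("live gate removed all events", call. = FALSE)
  if (length(keep) < 50L)
    warning("live gate kept fewer than 50 events (", length(keep), ")",
            call. = FALSE)
  new("GateResult", kind = "live", kept = as.integer(keep),
      nInput = nrow(ex),
      parameters = list(loPct = loPct, hiPct = hiPct, bounds = bounds))
}

#' Gate singlets on the FSC-H vs FSC-A line
#'
#' Doublets scatter below the linear FSC-H ~ FSC-A relationship of single
#' cells. A robust line (M-estimation with a bisquare psi, [MASS::rlm()]) is
#' fitted and events whose absolute residual exceeds `bandWidthMad` times
#' the MAD of the residuals are removed. Line and band are stored as
#' absolute coordinates for reuse across samples.
#'
#' @param events an [EventTable-class] with FSC-A and FSC-H channels.
#' @param bandWidthMad half-width of the residual band in MADs (> 0).
#' @return A [GateResult-class] of kind "singlet".
#' @export
gateSinglets <- function(events, bandWidthMad = 4) {
  stopifnot(is(events, "EventTable"))
  .requireChannels(events, c("FSC-A", "FSC-H"))
  if (!(is.numeric(bandWidthMad) && length(bandWidthMad) == 1L &&
        bandWidthMad > 0))   # Inf is the keep-everything limit
    stop("'bandWidthMad' must be a single positive number", call. = FALSE)
  ex <- eventData(events)
  a <- ex[, "FSC-A"]; h <- ex[, "FSC-H"]
  if (stats::sd(a) == 0)
    stop("cannot fit singlet gate: FSC-A is constant", call. = FALSE)
  ols <- stats::lm.fit(cbind(1, a), h)
  if (max(abs(ols$residuals)) <= 1e-9 * max(abs(h), 1)) {
    coefs <- ols$coefficients   # exact line: M-estimation scale degenerates
  } else {
    fit <- tryCatch(
      MASS::rlm(h ~ a, psi = MASS::psi.bisquare, maxit = 100),
      error = function(e) stop("cannot fit singlet gate: ", conditionMessage(e),
                               call. = FALSE))
    coefs <- stats::coef(fit)
  }
  resid <- h - (coefs[1] + coefs[2] * a)
  madRes <- stats::mad(resid)
  halfWidth <- if (is.infinite(bandWidthMad)) Inf else bandWidthMad * madRes
  # exact-line data: zero MAD, zero residuals -> keep everything on the line
  keep <- which(abs(resid) <= halfWidth + 1e-12 * max(abs(h), 1))
  if (length(keep) == 0L) stop("singlet gate removed all events", call. = FALSE)
  new("GateResult", kind = "singlet", kept = as.integer(keep),
      nInput = nrow(ex),
      parameters = list(intercept = unname(coefs[1]), slope = unname(coefs[2]),
                        madResiduals = madRes, bandWidthMad = bandWidthMad,
                        halfWidth = halfWidth))
}

#' @describeIn applyGate re-apply recorded absolute gate coordinates.
#' @export
setMethod("applyGate", signature("EventTable", "GateResult"),
  function(events, gate) {
    ex <- eventData(events)
    if (gate@kind == "live") {
      .requireChannels(events, c("FSC-A", "SSC-A"))
      b <- gate@parameters$bounds
      keep <- ex[, "FSC-A"] >= b[["FSC-A"]][1] & ex[, "FSC-A"] <= b[["FSC-A"]][2] &
              ex[, "SSC-A"] >= b[["SSC-A"]][1] & ex[, "SSC-A"] <= b[["SSC-A"]][2]
    } else {
      .requireChannels(events, c("FSC-A", "FSC-H"))
      p <- gate@parameters
      resid <- ex[, "FSC-H"] - (p$intercept + p$slope * ex[, "FSC-A"])
      keep <- abs(resid) <= p$halfWidth + 1e-12 * max(abs(ex[, "FSC-H"]), 1)
    }
    if (!any(keep)) stop("gate removed all events", call. = FALSE)
    .subsetEvents(events, which(keep))
  })

#' Median fluorescence intensity of a channel
#'
#' The MFI summarises a gated population as the median of the channel
#' values (mean-of-middle convention for even event counts).
#'
#' @param events an [EventTable-class].
#' @param channel channel name.
#' @return the MFI (A.F.U.).
#' @export
computeMfi <- function(events, channel) {
  stopifnot(is(events, "EventTable"))
  .requireChannels(events, channel)
  stats::median(eventData(events)[, channel])
}

#' Subtract autofluorescence background from an MFI
#'
#' The background is the arithmetic mean of the MFIs of one or more
#' non-fluorescent control samples of the same cell line. Negative
#' background-subtracted values are retained; downstream log transforms drop
#' them explicitly.
#'
#' @param mfiRaw raw MFI of the sample (A.F.U.).
#' @param controlMfis numeric vector of control MFIs (length >= 1).
#' @param sampleId,channel,nEvents,condition optional record metadata.
#' @return one-row data.frame with columns `sample_id`, `channel`,
#'   `mfi_raw`, `mfi_background`, `mfi_bg_subtracted`, `n_events`, followed
#'   by any condition labels.
#' @examples
#' subtractBackground(500, c(100, 120))$mfi_bg_subtracted  # 390
#' @export
subtractBackground <- function(mfiRaw, controlMfis, sampleId = NA_character_,
                               channel = NA_character_, nEvents = NA_integer_,
                               condition = list()) {
  .assertNumber(mfiRaw, "mfiRaw")
  if (length(controlMfis) < 1L)
    stop("at least one control MFI is required", call. = FALSE)
  .assertNumericVector(controlMfis, "controlMfis")
  bg <- mean(controlMfis)
  rec <- data.frame(sample_id = sampleId, channel = channel, mfi_raw = mfiRaw,
                    mfi_background = bg, mfi_bg_subtracted = mfiRaw - bg,
                    n_events = nEvents, stringsAsFactors = FALSE)
  for (nm in names(condition)) rec[[nm]] <- condition[[nm]]
  rec
}

#' Positivity threshold from non-fluorescent control cells
#'
#' Returns the 99th percentile of the control-cell channel values; cells
#' above it are scored fluorescence-positive.
#'
#' @param controlEvents an [EventTable-class] of non-fluorescent controls.
#' @param channel channel name.
#' @return threshold (A.F.U.).
#' @export
positivityThreshold <- function(controlEvents, channel) {
  stopifnot(is(controlEvents, "EventTable"))
  .requireChannels(controlEvents, channel)
  v <- eventData(controlEvents)[, channel]
  if (length(v) < 100L)
    warning("fewer than 100 control events (", length(v),
            "); threshold may be unstable", call. = FALSE)
  unname(stats::quantile(v, 0.99))
}

#' Rescale an MFI time course to the unit interval
#'
#' For upregulation series (ligand withdrawal) the mean of the plateau
#' window (default 25-150 h, where the repressor has reached steady state)
#' maps to 1 and the mean at t = 0 to 0. For downregulation series (ligand
#' addition) the pre-treatment (t = 0) mean maps to 1 and the
#' fully-degraded plateau mean to 0. The same affine map is applied to all
#' points; the anchors are stored in the result for inversion.
#'
#' @param time,value,replicate parallel vectors of the raw series
#'   (background-subtracted MFI).
#' @param direction "up" or "down".
#' @param plateauWindow numeric(2), the plateau time window in h.
#' @return A [ScaledSeries-class].
#' @examples
#' s <- scaleTimecourse(c(0, 10, 30, 50), c(10, 60, 110, 110), direction = "up")
#' s@value  # 0, 0.5, 1, 1
#' @export
scaleTimecourse <- function(time, value, replicate = "r1",
                            direction = c("up", "down"),
                            plateauWindow = c(25, 150)) {
  direction <- match.arg(direction)
  .assertNumericVector(time, "time")
  .assertNumericVector(value, "value")
  if (length(time) != length(value))
    stop("time and value must have equal length", call. = FALSE)
  if (!any(time == 0)) stop("series must cover t = 0", call. = FALSE)
  inPlateau <- time >= plateauWindow[1] & time <= plateauWindow[2]
  if (!any(inPlateau))
    stop("plateau window [", plateauWindow[1], ", ", plateauWindow[2],
         "] h contains no time points", call. = FALSE)
  t0Mean <- mean(value[time == 0])
  plateauMean <- mean(value[inPlateau])
  if (direction == "up") { zero <- t0Mean; one <- plateauMean }
  else { zero <- plateauMean; one <- t0Mean }
  if (one == zero) stop("degenerate series: anchors coincide", call. = FALSE)
  ScaledSeries(time, (value - zero) / (one - zero), replicate, direction,
               scaling = list(zeroAnchor = zero, oneAnchor = one,
                              plateauWindow = plateauWindow))
}

#' Fold change of a background-subtracted MFI relative to a reference
#'
#' @param mfiBgSubtracted background-subtracted MFI of the sample.
#' @param referenceMfi background-subtracted MFI of the unrepressed
#'   reference (must be positive).
#' @return the fold change.
#' @export
normalizeFoldChange <- function(mfiBgSubtracted, referenceMfi) {
  .assertNumber(mfiBgSubtracted, "mfiBgSubtracted")
  .assertNumber(referenceMfi, "referenceMfi")
  if (referenceMfi <= 0)
    stop("referenceMfi must be positive", call. = FALSE)
  mfiBgSubtracted / referenceMfi
}

#' Write / read gate coordinates as JSON
#'
#' Persists the absolute gate coordinates of a [GateResult-class] so one set
#' of gating coordinates can be applied across the files of an experiment.
#'
#' @param gate a [GateResult-class].
#' @param path output (input) JSON path.
#' @return `writeGateResult` the path, invisibly; `readGateResult` a
#'   [GateResult-class] with empty `kept` (coordinates only).
#' @export
writeGateResult <- function(gate, path) {
  stopifnot(is(gate, "GateResult"))
  jsonlite::write_json(list(kind = gate@kind, nInput = gate@nInput,
                            parameters = gate@parameters),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeGateResult
#' @export
readGateResult <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("GateResult", kind = x$kind, kept = integer(0),
      nInput = as.integer(x$nInput), parameters = as.list(x$parameters))
}

#' Convert a ScaledSeries to a data.frame
#'
#' @param x a [ScaledSeries-class].
#' @param ... ignored.
#' @return data.frame with columns `time_h`, `value`, `replicate`.
#' @export
as.data.frame.ScaledSeries <- function(x, ...) {
  data.frame(time_h = x@time, value = x@value, replicate = x@replicate,
             stringsAsFactors = FALSE)
}

setMethod("as.data.frame", "ScaledSeries", as.data.frame.ScaledSeries)
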