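# Degron characterisation from tRFP/tBFP reporter ratios.
#
# A degron-tagged tRFP is expressed from a bicistronic cassette with an
# untagged tBFP, so the tRFP/tBFP ratio isolates degron-dependent protein
# destabilisation from expression variability. Ratios are normalised to a
# no-degron control line and expressed as percentages; the ratio in the
# stabilised state is called A, in the destabilised state B.

#' Relative tRFP/tBFP ratio as a percentage of the no-degron control
#'
#' @param trfpMfi,tbfpMfi background-subtracted MFIs; `tbfpMfi` must be
#'   positive.
#' @param controlRatioMean mean tRFP/tBFP ratio of the no-degron control
#'   (averaged across its replicates and ligand conditions); must be positive.
#' @return percentage (100 = control level).
#' @examples
#' relativeRatioPercent(80, 100, 1)  # 80
#' @export
relativeRatioPercent <- function(trfpMfi, tbfpMfi, controlRatioMean) {
  .assertNumber(trfpMfi, "trfpMfi")
  .assertNumber(tbfpMfi, "tbfpMfi", 0, strict_lower = TRUE)
  .assertNumber(controlRatioMean, "controlRatioMean", 0, strict_lower = TRUE)
  100 * (trfpMfi / tbfpMfi) / controlRatioMean
}

#' Degron properties: leakiness, efficiency, dynamic range
#'
#' With A the relative ratio (\%) in the stabilised state and B in the
#' destabilised state: leakiness = 100 - A measures background
#' destabilisation conferred by the tag alone; efficiency = 100 - B measures
#' depletion relative to the no-degron control; the dynamic range is the
#' fold separation of the two states, reported as max(A, B) / min(A, B) so
#' that it is >= 1 regardless of which state carries the higher ratio.
#'
#' @param A,B relative ratios in percent (> 0).
#' @return data.frame with columns `A`, `B`, `leakiness`, `efficiency`,
#'   `dynamic_range`.
#' @examples
#' degronProperties(80, 2)  # leakiness 20, efficiency 98, dynamic range 40
#' @export
degronProperties <- function(A, B) {
  .assertNumber(A, "A", 0, strict_lower = TRUE)
  .assertNumber(B, "B", 0, strict_lower = TRUE)
  data.frame(A = A, B = B, leakiness = 100 - A, efficiency = 100 - B,
             dynamic_range = max(A, B) / min(A, B))
}

#' Degron metrics for a measurement panel
#'
#' Computes per-replicate A and B and the derived properties for each degron
#' in a measurement table, then summarises as mean and s.d. across
#' replicates. The stabilised condition is the maximal ligand concentration
#' for default-unstable degrons (stabilised by ligand) and the mock (0 nM)
#' condition for default-stable degrons (destabilised by ligand).
#'
#' @param measurements data.frame with columns `degron`, `ligand_nM`,
#'   `trfp_mfi`, `tbfp_mfi`, `replicate`. Rows with `degron == controlName`
#'   are the no-degron control.
#' @param stability named character vector mapping each degron to
#'   "default-stable" or "default-unstable".
#' @param controlName degron label of the no-degron control rows.
#' @return list with `perReplicate` (one row per degron x replicate) and
#'   `summary` (mean and s.d. of each metric per degron).
#' @export
degronPanelMetrics <- function(measurements, stability,
                               controlName = "none") {
  need <- c("degron", "ligand_nM", "trfp_mfi", "tbfp_mfi", "replicate")
  missing <- setdiff(need, names(measurements))
  if (length(missing))
    stop("measurement table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  ctrl <- measurements[measurements$degron == controlName, ]
  if (nrow(ctrl) == 0L)
    stop("no rows for the no-degron control '", controlName, "'", call. = FALSE)
  controlRatioMean <- mean(ctrl$trfp_mfi / ctrl$tbfp_mfi)

  degrons <- setdiff(unique(measurements$degron), controlName)
  per <- do.call(rbind, lapply(degrons, function(dg) {
    if (is.na(stability[dg]))
      stop("no stability class declared for degron '", dg, "'", call. = FALSE)
    d <- measurements[measurements$degron == dg, ]
    maxLigand <- max(d$ligand_nM)
    stabilisedAtMax <- stability[dg] == "default-unstable"
    do.call(rbind, lapply(unique(d$replicate), function(rep) {
      dr <- d[d$replicate == rep, ]
      ratio <- function(rows) {
        r <- dr[rows, ]
        if (nrow(r) == 0L)
          stop("degron '", dg, "' replicate '", rep,
               "' lacks a required ligand condition", call. = FALSE)
        mean(vapply(seq_len(nrow(r)), function(i)
          relativeRatioPercent(r$trfp_mfi[i], r$tbfp_mfi[i], controlRatioMean),
          numeric(1)))
      }
      A <- ratio(if (stabilisedAtMax) dr$ligand_nM == maxLigand else dr$ligand_nM == 0)
      B <- ratio(if (stabilisedAtMax) dr$ligand_nM == 0 else dr$ligand_nM == maxLigand)
      cbind(data.frame(degron = dg, replicate = rep, stringsAsFactors = FALSE),
            degronProperties(A, B))
    }))
  }))

  metricCols <- c("A", "B", "leakiness", "efficiency", "dynamic_range")
  summary <- do.call(rbind, lapply(split(per, per$degron), function(d) {
    out <- data.frame(degron = d$degron[1], n_replicates = nrow(d))
    for (m in metricCols) {
      out[[paste0(m, "_mean")]] <- mean(d[[m]])
      out[[paste0(m, "_sd")]] <- stats::sd(d[[m]])
    }
    out
  }))
  rownames(summary) <- NULL
  list(perReplicate = per, summary = summary)
}
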