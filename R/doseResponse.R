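# Four-parameter Hill dose-response curves for titrated transcription
# factors. X is the regulator fold change relative to the unrepressed
# (500 nM dTAG-13) state; Y the target fold change (or normalised
# phenotype). Targets activated by the factor have their ceiling fixed at 1
# (the unrepressed state) and a fitted floor; targets repressed by the
# factor have their floor fixed at 1 and a fitted ceiling.

#' Hill dose response of an activated target
#'
#' Target FC = tMin + (1 - tMin) / (1 + (xHalf / X)^n): rises from the
#' floor tMin at X = 0 to 1 at full regulator dose, with half of the
#' maximal variation at X = xHalf.
#'
#' @param X regulator fold change (> 0), vectorised.
#' @param xHalf half-effect dose (> 0).
#' @param n Hill coefficient (> 0).
#' @param tMin floor, the target fold change at X = 0.
#' @return predicted target fold change.
#' @examples
#' hillActivated(0.55, xHalf = 0.55, n = 2, tMin = 0.05)  # (1 + 0.05) / 2
#' @export
hillActivated <- function(X, xHalf, n, tMin) {
  stopifnot(all(X > 0), xHalf > 0, n > 0, tMin >= 0)
  tMin + (1 - tMin) / (1 + (xHalf / X)^n)
}

#' Hill dose response of a repressed target
#'
#' Target FC = tMax - (tMax - 1) / (1 + (xHalf / X)^n): falls from the
#' ceiling tMax at X = 0 (full derepression) to 1 at full regulator dose.
#'
#' @param X regulator fold change (> 0), vectorised.
#' @param xHalf half-effect dose (> 0).
#' @param n Hill coefficient (> 0).
#' @param tMax ceiling, the target fold change at X = 0 (>= 1).
#' @return predicted target fold change.
#' @export
hillRepressed <- function(X, xHalf, n, tMax) {
  stopifnot(all(X > 0), xHalf > 0, n > 0, tMax >= 1)
  tMax - (tMax - 1) / (1 + (xHalf / X)^n)
}

#' Fit a four-parameter Hill dose-response curve
#'
#' Plain (unweighted) nonlinear least squares over all replicate points,
#' with the direction-appropriate parameter fixed (ceiling = 1 for
#' activated targets, floor = 1 for repressed targets). Degenerate or
#' non-converging fits are flagged, never returned as silent successes.
#'
#' @param X,Y regulator and target fold changes over all replicate points;
#'   alternatively pass a data.frame with columns `X`, `Y` (and optionally
#'   `direction`) as the first argument.
#' @param direction "activated" or "repressed".
#' @return A [HillFit-class].
#' @examples
#' X <- rep(c(1, 0.7, 0.45, 0.25, 0.1), 3)
#' fitDoseResponse(X, hillActivated(X, 0.55, 2, 0.05), "activated")
#' @export
fitDoseResponse <- function(X, Y = NULL,
                            direction = c("activated", "repressed")) {
  if (is.data.frame(X)) {
    tab <- X
    if (!all(c("X", "Y") %in% names(tab)))
      stop("dose-response table needs columns 'X' and 'Y'", call. = FALSE)
    if (missing(direction) && "direction" %in% names(tab))
      direction <- unique(as.character(tab$direction))
    X <- tab$X; Y <- tab$Y
  }
  direction <- match.arg(direction)
  .assertNumericVector(X, "X"); .assertNumericVector(Y, "Y")
  if (length(X) != length(Y)) stop("X and Y must have equal length", call. = FALSE)
  if (any(X <= 0)) stop("all X must be positive", call. = FALSE)
  if (any(Y < 0)) stop("all Y must be non-negative", call. = FALSE)
  if (length(unique(X)) < 4L)
    stop("at least 4 distinct doses are required", call. = FALSE)

  blank <- function(flag) new("HillFit", xHalf = NA_real_, xHalfSE = NA_real_,
                              n = NA_real_, nSE = NA_real_, tMin = NA_real_,
                              tMax = NA_real_, direction = direction,
                              rSquared = NA_real_, flag = flag)
  if (stats::sd(Y) < 1e-10) return(blank("unidentifiable"))

  d <- data.frame(X = X, Y = Y)
  midY <- (max(Y) + min(Y)) / 2
  xStart <- X[which.min(abs(Y - midY))]
  maxX <- max(X)
  lowDoseMean <- mean(Y[X == min(X)])

  if (direction == "activated") {
    fit <- tryCatch(
      minpack.lm::nlsLM(Y ~ tMin + (1 - tMin) / (1 + (xHalf / X)^n), data = d,
                        start = list(xHalf = xStart, n = 2,
                                     tMin = min(max(lowDoseMean, 0), 1)),
                        lower = c(1e-6, 1e-6, 0), upper = c(maxX, 20, 1)),
      error = function(e) NULL)
  } else {
    fit <- tryCatch(
      minpack.lm::nlsLM(Y ~ tMax - (tMax - 1) / (1 + (xHalf / X)^n), data = d,
                        start = list(xHalf = xStart, n = 2,
                                     tMax = max(lowDoseMean, 1)),
                        lower = c(1e-6, 1e-6, 1), upper = c(maxX, 20, Inf)),
      error = function(e) NULL)
  }
  if (is.null(fit)) return(blank("not-converged"))

  px <- .nlsParam(fit, "xHalf"); pn <- .nlsParam(fit, "n")
  res <- stats::residuals(fit)
  r2 <- 1 - sum(res^2) / sum((Y - mean(Y))^2)
  xh <- unname(px["est"])
  flag <- if (xh >= maxX * (1 - 1e-6) || xh <= 1e-6 * (1 + 1e-6)) "at-bound" else "ok"
  if (direction == "activated") {
    tMin <- unname(.nlsParam(fit, "tMin")["est"]); tMax <- 1
  } else {
    tMin <- 1; tMax <- unname(.nlsParam(fit, "tMax")["est"])
  }
  new("HillFit", xHalf = xh, xHalfSE = unname(px["se"]),
      n = unname(pn["est"]), nSE = unname(pn["se"]),
      tMin = tMin, tMax = tMax, direction = direction, rSquared = r2,
      flag = flag)
}

#' Phenotype dose response from colony counts
#'
#' Scores each alkaline-phosphatase condition as the percentage of
#' undifferentiated colonies, normalises per replicate to the mean
#' percentage of the reference (unrepressed, 500 nM dTAG-13) condition, and
#' fits the activated-target Hill form against the regulator fold change
#' measured by flow cytometry before seeding.
#'
#' @param colonies data.frame with columns `condition`, `replicate`,
#'   `n_undiff`, `n_mixed`, `n_diff`.
#' @param mfiFoldChanges data.frame with columns `condition` and `X`
#'   (regulator fold change per condition).
#' @param referenceCondition condition label of the unrepressed reference.
#' @return list with `fit` (a [HillFit-class]) and `table` (the normalised
#'   per-replicate dose-response points).
#' @export
phenotypeDoseResponse <- function(colonies, mfiFoldChanges,
                                  referenceCondition = "500") {
  need <- c("condition", "replicate", "n_undiff", "n_mixed", "n_diff")
  missing <- setdiff(need, names(colonies))
  if (length(missing))
    stop("colony table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!all(c("condition", "X") %in% names(mfiFoldChanges)))
    stop("mfiFoldChanges needs columns 'condition' and 'X'", call. = FALSE)
  total <- colonies$n_undiff + colonies$n_mixed + colonies$n_diff
  if (any(total <= 0)) stop("every condition needs at least one colony", call. = FALSE)
  colonies$pct_undiff <- 100 * colonies$n_undiff / total

  refRows <- colonies$condition == referenceCondition
  if (!any(refRows))
    stop("reference condition '", referenceCondition, "' absent from colony table",
         call. = FALSE)
  refMean <- mean(colonies$pct_undiff[refRows])
  if (refMean <= 0)
    stop("reference condition has no undifferentiated colonies", call. = FALSE)
  colonies$Y <- colonies$pct_undiff / refMean

  x <- mfiFoldChanges$X[match(colonies$condition, mfiFoldChanges$condition)]
  if (any(is.na(x)))
    stop("no regulator fold change for condition(s): ",
         paste(unique(colonies$condition[is.na(x)]), collapse = ", "),
         call. = FALSE)
  tab <- data.frame(condition = colonies$condition,
                    replicate = colonies$replicate, X = x, Y = colonies$Y,
                    stringsAsFactors = FALSE)
  keep <- tab$Y >= 0 & tab$X > 0
  list(fit = fitDoseResponse(tab$X[keep], tab$Y[keep], "activated"),
       table = tab)
}
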