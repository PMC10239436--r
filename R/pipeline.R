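# Configuration-driven orchestration: a YAML config lists stages and their
# parameters; each stage reads/writes CSV or JSON under the run's output
# directory and contributes a summary to a deterministic JSON report.
# Timings and progress go to the log (stderr and optional log file), never
# into the report, so identical configs yield byte-identical reports.

.plLog <- function(logCon, level, fmt, ...) {
  msg <- sprintf("[%s] %s", level, sprintf(fmt, ...))
  message(msg)
  if (!is.null(logCon)) writeLines(sprintf("%s %s", format(Sys.time()), msg), logCon)
}

.plPath <- function(outDir, name) file.path(outDir, name)

.plReadEvents <- function(params, outDir) {
  path <- params$events
  if (!file.exists(path)) path <- .plPath(outDir, params$events)
  readEventTable(path, channelAliases = unlist(params$channel_aliases))
}

# stage registry: each handler returns list(summary = <list>, outputs = <chr>)
.plStages <- list(
  simulate_population = function(params, outDir, seed) {
    ev <- simulateEventPopulation(
      nCells = params$n_cells %||% 10000L,
      doubletFraction = params$doublet_fraction %||% 0.05,
      seed = seed)
    out <- .plPath(outDir, params$out %||% "events.csv")
    utils::write.csv(as.data.frame(eventData(ev)), out, row.names = FALSE)
    list(summary = list(n_cells = nEvents(ev), seed = seed), outputs = out)
  },
  gate = function(params, outDir, seed) {
    ev <- .plReadEvents(params, outDir)
    live <- gateLiveCells(ev, params$live_lo %||% 1, params$live_hi %||% 99)
    evLive <- applyGate(ev, live)
    singlet <- gateSinglets(evLive, params$singlet_band %||% 4)
    evKept <- applyGate(evLive, singlet)
    gatesOut <- .plPath(outDir, params$gates_out %||% "gates.json")
    jsonlite::write_json(list(live = live@parameters, singlet = singlet@parameters),
                         gatesOut, auto_unbox = TRUE, digits = NA)
    evOut <- .plPath(outDir, params$out %||% "events_gated.csv")
    utils::write.csv(as.data.frame(eventData(evKept)), evOut, row.names = FALSE)
    list(summary = list(n_input = nEvents(ev), n_live = nEvents(evLive),
                        n_singlet = nEvents(evKept)),
         outputs = c(gatesOut, evOut))
  },
  mfi = function(params, outDir, seed) {
    ev <- .plReadEvents(params, outDir)
    mfiRaw <- computeMfi(ev, params$channel)
    ctrl <- vapply(params$controls, function(p) {
      path <- if (file.exists(p)) p else .plPath(outDir, p)
      computeMfi(readEventTable(path, channelAliases = unlist(params$channel_aliases)),
                 params$channel)
    }, numeric(1))
    rec <- subtractBackground(mfiRaw, ctrl, sampleId = ev@sampleId,
                              channel = params$channel, nEvents = nEvents(ev))
    out <- .plPath(outDir, params$out %||% "mfi.csv")
    utils::write.csv(rec, out, row.names = FALSE)
    list(summary = as.list(rec[1, c("mfi_raw", "mfi_background",
                                    "mfi_bg_subtracted")]),
         outputs = out)
  },
  simulate_regime = function(params, outDir, seed) {
    sim <- simulateRegime(params$regime, rBar = params$r_bar,
                          cv = params$cv %||% 0.2, K = params$K %||% 0.3,
                          n = params$n %||% 2, pOff = params$p_off,
                          nCells = params$n_cells %||% 10000L, seed = seed)
    out <- .plPath(outDir, params$out %||% "regime.csv")
    utils::write.csv(data.frame(target = sim$target, repressor = sim$repressor),
                     out, row.names = FALSE)
    list(summary = list(regime = params$regime, n_cells = length(sim$target),
                        seed = seed),
         outputs = out)
  },
  modality = function(params, outDir, seed) {
    reps <- lapply(params$values, function(p) {
      path <- if (file.exists(p)) p else .plPath(outDir, p)
      df <- utils::read.csv(path)
      col <- params$column %||% "target"
      if (!col %in% names(df))
        stop("column '", col, "' absent from ", path, call. = FALSE)
      df[[col]]
    })
    prep <- prepareDistribution(reps)
    res <- hallYorkTest(prep, nBoot = params$n_boot %||% 500L, seed = seed,
                        alpha = params$alpha %||% 0.01)
    out <- .plPath(outDir, params$out %||% "modality.json")
    jsonlite::write_json(list(h_crit = res@hCrit, p_value = res@pValue,
                              n_boot = res@nBoot, seed = res@seed,
                              bounds = res@bounds, decision = res@decision,
                              n_dropped_nonpositive = prep@nDroppedNonpositive),
                         out, auto_unbox = TRUE, digits = NA)
    list(summary = list(p_value = res@pValue, decision = res@decision),
         outputs = out)
  },
  simulate_timecourse = function(params, outDir, seed) {
    model <- KineticModel(tHalf = params$t_half %||% NA_real_,
                          alphaRPlus = params$alpha_r_plus %||% NA_real_,
                          alphaT = params$alpha_t %||% NA_real_,
                          K = params$K %||% NA_real_, n = params$n %||% NA_real_,
                          deltaT = params$delta_t %||% 0)
    sim <- simulateTimecourse(model, direction = params$direction,
                              timePoints = unlist(params$time_points) %||%
                                c(0, 2, 4, 8, 12, 24, 48, 72, 96, 120, 150),
                              nReplicates = params$n_replicates %||% 3L,
                              noiseCv = params$noise_cv %||% 0.05, seed = seed)
    outR <- .plPath(outDir, params$out_repressor %||% "repressor.csv")
    outT <- .plPath(outDir, params$out_target %||% "target.csv")
    utils::write.csv(as.data.frame(sim$repressor), outR, row.names = FALSE)
    utils::write.csv(as.data.frame(sim$target), outT, row.names = FALSE)
    list(summary = list(direction = params$direction, seed = seed),
         outputs = c(outR, outT))
  },
  fit_repressor = function(params, outDir, seed) {
    path <- if (file.exists(params$series)) params$series
            else .plPath(outDir, params$series)
    d <- utils::read.csv(path)
    fit <- if (params$direction == "up") fitRepressorUp(d) else fitRepressorDown(d)
    out <- .plPath(outDir, params$out %||% "repressor_fit.json")
    jsonlite::write_json(list(t_half = fit@tHalf, t_half_se = fit@tHalfSE,
                              alpha = fit@alpha, direction = fit@direction,
                              n_points = fit@nPoints),
                         out, auto_unbox = TRUE, digits = NA)
    list(summary = list(t_half = fit@tHalf), outputs = out)
  },
  fit_dose_response = function(params, outDir, seed) {
    path <- if (file.exists(params$table)) params$table
            else .plPath(outDir, params$table)
    fit <- fitDoseResponse(utils::read.csv(path))
    out <- .plPath(outDir, params$out %||% "dose_response_fit.json")
    jsonlite::write_json(list(x_half = fit@xHalf, x_half_se = fit@xHalfSE,
                              n = fit@n, n_se = fit@nSE, t_min = fit@tMin,
                              t_max = fit@tMax, direction = fit@direction,
                              r_squared = fit@rSquared, flag = fit@flag),
                         out, auto_unbox = TRUE, digits = NA)
    list(summary = list(x_half = fit@xHalf, flag = fit@flag), outputs = out)
  },
  simulate_dose_response = function(params, outDir, seed) {
    tab <- simulateDoseResponse(params$direction, xHalf = params$x_half,
                                n = params$n %||% 2,
                                floorOrCeiling = params$floor_or_ceiling,
                                doses = unlist(params$doses) %||%
                                  c(1, 0.7, 0.45, 0.25, 0.1),
                                nReplicates = params$n_replicates %||% 3L,
                                noiseCv = params$noise_cv %||% 0.05, seed = seed)
    out <- .plPath(outDir, params$out %||% "dose_response.csv")
    utils::write.csv(tab, out, row.names = FALSE)
    list(summary = list(n_rows = nrow(tab), seed = seed), outputs = out)
  }
)

# stages that consume files must be able to see them at validation time or
# find them among the outputs of earlier stages
.plPreflight <- function(config, outDir) {
  declaredOutputs <- character(0)
  for (i in seq_along(config$stages)) {
    st <- config$stages[[i]]
    if (is.null(st$stage) || !st$stage %in% names(.plStages))
      stop("unknown stage '", st$stage %||% "<missing>", "' at position ", i,
           call. = FALSE)
    inputs <- unlist(st[c("events", "series", "table")], use.names = FALSE)
    inputs <- c(inputs, unlist(st$controls), unlist(st$values))
    for (p in inputs) {
      if (!file.exists(p) && !file.exists(.plPath(outDir, p)) &&
          !(p %in% declaredOutputs || basename(p) %in% basename(declaredOutputs)))
        stop("pre-flight: stage '", st$stage, "' references missing input '",
             p, "'", call. = FALSE)
    }
    for (nm in c("out", "out_repressor", "out_target", "gates_out"))
      if (!is.null(st[[nm]])) declaredOutputs <- c(declaredOutputs, st[[nm]])
    declaredOutputs <- c(declaredOutputs,
      switch(st$stage,
             simulate_population = "events.csv", gate = "events_gated.csv",
             simulate_regime = "regime.csv",
             simulate_timecourse = c("repressor.csv", "target.csv"),
             simulate_dose_response = "dose_response.csv", character(0)))
  }
  invisible(TRUE)
}

#' Run a configuration-driven analysis pipeline
#'
#' Executes the stages declared in a YAML (or list) configuration in order,
#' writing all intermediate tables under the run's output directory and a
#' deterministic JSON report (`report.json`) of parameters, seeds and
#' per-stage summaries. Path and stage-name errors are caught by pre-flight
#' validation before any computation; on a stage failure the partial report
#' is written with suffix `.partial.json` and the run aborts naming the
#' stage.
#'
#' @param config path to a YAML config or an equivalent list. Fields:
#'   `name`, `seed` (mandatory base seed for stochastic stages; stage i
#'   uses `seed + i`), `out_dir`, `stages` (list of stage entries, each
#'   with a `stage` field naming one of: simulate_population, gate, mfi,
#'   simulate_regime, modality, simulate_timecourse, fit_repressor,
#'   simulate_dose_response, fit_dose_response).
#' @param logFile optional path for a timestamped log (timings live here,
#'   not in the report).
#' @return the report, invisibly.
#' @examples
#' cfg <- list(name = "demo", seed = 1, out_dir = tempfile("run"),
#'             stages = list(
#'               list(stage = "simulate_regime", regime = "digital",
#'                    r_bar = 0.3, p_off = 0.5, n_cells = 2000),
#'               list(stage = "modality", values = list("regime.csv"),
#'                    n_boot = 100)))
#' rep <- runPipeline(cfg)
#' @export
runPipeline <- function(config, logFile = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$stages) || !length(config$stages))
    stop("config declares no stages", call. = FALSE)
  if (is.null(config$seed)) stop("config must declare a seed", call. = FALSE)
  outDir <- config$out_dir %||% "."
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logCon <- NULL
  if (!is.null(logFile)) {
    logCon <- file(logFile, "a")
    on.exit(close(logCon), add = TRUE)
  }

  .plPreflight(config, outDir)
  baseSeed <- as.integer(config$seed)
  report <- list(name = config$name %||% "pipeline-run",
                 package_version = as.character(utils::packageVersion("degronKinetics")),
                 seed = baseSeed, stages = list())
  reportPath <- .plPath(outDir, "report.json")

  for (i in seq_along(config$stages)) {
    st <- config$stages[[i]]
    stageSeed <- baseSeed + i
    .plLog(logCon, "INFO", "stage %d/%d: %s", i, length(config$stages), st$stage)
    t0 <- Sys.time()
    res <- tryCatch(.plStages[[st$stage]](st, outDir, stageSeed),
      error = function(e) {
        jsonlite::write_json(report, paste0(reportPath, ".partial.json"),
                             auto_unbox = TRUE, digits = NA)
        stop("stage '", st$stage, "' (position ", i, ") failed: ",
             conditionMessage(e), call. = FALSE)
      })
    .plLog(logCon, "INFO", "stage %s done in %.2f s", st$stage,
           as.numeric(difftime(Sys.time(), t0, units = "secs")))
    params <- st[setdiff(names(st), "stage")]
    report$stages[[i]] <- list(stage = st$stage, seed = stageSeed,
                               parameters = params, summary = res$summary,
                               outputs = basename(res$outputs))
  }
  jsonlite::write_json(report, reportPath, auto_unbox = TRUE, digits = NA)
  .plLog(logCon, "INFO", "report written to %s", reportPath)
  invisible(report)
}
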