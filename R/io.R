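#' Trace CSV round trip
#'
#' Traces are stored as tidy CSV with columns time_ms, command_mV, current,
#' sweep (full double precision), plus a JSON sidecar (`<path>.json`)
#' carrying the shared metadata (channel, solutions, seed, protocol segment
#' table). `readTraceCsv` validates the header and requires strictly
#' increasing time within each sweep.
#'
#' @param traces list of [CurrentTrace-class] (or one trace).
#' @param path CSV file path.
#' @return `writeTraceCsv`: invisibly, the path. `readTraceCsv`: list of
#'   [CurrentTrace-class].
#' @examples
#' tr <- simulateRecording(stepProtocol(c(-20, 0)),
#'                         channelPreset("cavmr-g240a"),
#'                         builtinSolutions("high-Na pipette"),
#'                         builtinSolutions("ca10-nmdg"))
#' f <- tempfile(fileext = ".csv")
#' writeTraceCsv(tr, f)
#' tr2 <- readTraceCsv(f)
#' @export
writeTraceCsv <- function(traces, path) {
  if (is(traces, "CurrentTrace")) traces <- list(traces)
  tab <- do.call(rbind, lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    data.frame(time_ms = tr@time, command_mV = tr@commandV,
               current = tr@current,
               sweep = tr@metadata$sweep %||% i)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  meta <- traces[[1]]@metadata
  meta$segments <- if (!is.null(meta$segments)) meta$segments else NULL
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname writeTraceCsv
#' @export
readTraceCsv <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("time_ms", "command_mV", "current", "sweep")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("readTraceCsv: missing column(s): ", paste(missing, collapse = ", "))
  metaPath <- paste0(path, ".json")
  meta <- if (file.exists(metaPath))
    jsonlite::read_json(metaPath, simplifyVector = TRUE) else list()
  if (!is.null(meta$segments)) meta$segments <- as.data.frame(meta$segments)
  lapply(split(tab, tab$sweep), function(sw) {
    if (any(diff(sw$time_ms) <= 0))
      stop("readTraceCsv: non-monotone time stamps in sweep ", sw$sweep[1])
    m <- meta
    m$sweep <- sw$sweep[1]
    new("CurrentTrace", time = sw$time_ms, commandV = sw$command_mV,
        current = sw$current, metadata = as.list(m))
  })
}

#' Solution config round trip
#'
#' Solutions serialize to a structured JSON config (label, role, mM per
#' species) so that recording conditions travel with the data.
#'
#' @param solutions list of [Solution-class] (or one solution).
#' @param path JSON file path.
#' @return `writeSolutionConfig`: invisibly, the path; `readSolutionConfig`:
#'   named list of [Solution-class].
#' @export
writeSolutionConfig <- function(solutions, path) {
  if (is(solutions, "Solution")) solutions <- list(solutions)
  obj <- lapply(solutions, function(s)
    list(label = s@label, role = s@role,
         concentrations_mM = as.list(s@concentrations)))
  names(obj) <- vapply(solutions, slot, character(1), "label")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSolutionConfig
#' @export
readSolutionConfig <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(obj, function(o)
    solution(o$label, unlist(o$concentrations_mM), o$role))
  names(out) <- vapply(out, slot, character(1), "label")
  out
}

#' Run the full inference pipeline from a config
#'
#' Executes simulate -> P/N leak-subtract -> ramp reversal-potential
#' extraction -> permeability-ratio inference -> aggregation for a batch of
#' synthetic cells, and writes a result table (CSV), a JSON log carrying the
#' config hash and seeds, and the per-cell values. The config is a list (or
#' JSON file path) with entries:
#' \describe{
#'   \item{preset}{channel preset name (see [channelPreset()]), or `channel`
#'     = a [SimChannelSpec-class].}
#'   \item{pipette, bath}{solution catalogue labels or [Solution-class]
#'     objects.}
#'   \item{ratio}{target ratio, e.g. "P_Ca/P_Na".}
#'   \item{nCells}{number of synthetic cells (default 5).}
#'   \item{seed}{integer master seed.}
#'   \item{noiseSd, leakConductance}{recording imperfections (defaults 0).}
#'   \item{ramp}{list(vFrom, vTo, rampDur) ramp settings (defaults -100, 100,
#'     200).}
#'   \item{outDir}{output directory; NULL = nothing written.}
#' }
#' Reruns with the same config and seed are byte-identical.
#'
#' @param config list or path to a JSON config file.
#' @return list with `table` (the aggregated [permeabilityTable()] output),
#'   `perCell` (data.frame cell, eRev, ratio value), `configHash`, `log`.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  need <- c("pipette", "bath", "ratio")
  missing <- setdiff(need, names(config))
  if (!("preset" %in% names(config) || "channel" %in% names(config)))
    missing <- c(missing, "preset (or channel)")
  if (length(missing))
    stop("runPipeline: config is missing: ", paste(missing, collapse = ", "))
  seed <- as.integer(config$seed %||% 1L)
  nCells <- config$nCells %||% 5L
  noiseSd <- config$noiseSd %||% 0
  leak <- config$leakConductance %||% 0
  rampCfg <- config$ramp %||% list(vFrom = -100, vTo = 100, rampDur = 200)
  getSol <- function(x) if (is(x, "Solution")) x else builtinSolutions(x)
  pip <- getSol(config$pipette); bat <- getSol(config$bath)
  base <- if (!is.null(config$channel)) config$channel
  else channelPreset(config$preset)
  base@noiseSd <- noiseSd
  base@leakConductance <- leak
  proto <- rampProtocol(vFrom = rampCfg$vFrom %||% -100,
                        vTo = rampCfg$vTo %||% 100,
                        rampDur = rampCfg$rampDur %||% 200)
  hashSrc <- tempfile(); on.exit(unlink(hashSrc), add = TRUE)
  hashed <- config[setdiff(names(config), "outDir")]  # where, not what
  writeLines(jsonlite::toJSON(hashed[order(names(hashed))],
                              auto_unbox = TRUE, force = TRUE), hashSrc)
  cfgHash <- unname(tools::md5sum(hashSrc))
  records <- do.call(rbind, lapply(seq_len(nCells), function(cell) {
    ch <- base
    ch@seed <- seed + 131L * cell
    fam <- simulatePNLeakFamily(proto, ch, pip, bat, nSub = 10)
    corrected <- pnSubtract(fam$main, fam$subs)
    # search for the crossing only where the channel conducts appreciably
    # (above vHalf - 2k the open fraction exceeds ~12%); below that the
    # current is dominated by noise and yields spurious crossings
    vLo <- base@gating@vHalf - 2 * base@gating@kSlope
    e <- extractErevFromRamp(corrected[[1]],
                             smoothing = if (noiseSd > 0) 25 else 0,
                             vWindow = c(vLo, rampCfg$vTo %||% 100),
                             method = if (noiseSd > 0) "linfit"
                             else "crossing")
    data.frame(cell = cell, channel = base@label, ratio = config$ratio,
               eRev = e, pipette = pip@label, bath = bat@label,
               pcaPna = config$pcaPna %||% NA_real_,
               stringsAsFactors = FALSE)
  }))
  tab <- permeabilityTable(records)
  perCell <- data.frame(cell = records$cell, eRev = records$eRev,
                        value = unlist(attr(tab, "perCell"), use.names = FALSE))
  log <- list(configHash = cfgHash, seed = seed, nCells = nCells,
              packageVersion = as.character(utils::packageVersion("ionperm")),
              timestampFree = TRUE)
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(config$outDir, "permeability_table.csv"),
                     row.names = FALSE)
    utils::write.csv(perCell, file.path(config$outDir, "per_cell.csv"),
                     row.names = FALSE)
    jsonlite::write_json(log, file.path(config$outDir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(table = tab, perCell = perCell, configHash = cfgHash, log = log)
}
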