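## Sweep-set CSV + JSON-sidecar readers/writers and run configuration.
##
## On-disk form: a CSV with column 1 `time_ms` and one column per sweep
## (`sweep_000`, `sweep_001`, ...), values written with 17 significant digits
## so the float round trip is bit-exact, plus a `.json` sidecar holding the
## protocol, units and (for synthetic data) the generating ground truth.

.sidecar_path <- function(path) paste0(sub("\\.csv$", "", path), ".json")

#' Write a sweep set to CSV + JSON sidecar
#'
#' @param sweeps a [SweepSet-class].
#' @param path CSV path; the sidecar is written next to it with a `.json`
#'   extension.
#' @return `path`, invisibly.
#' @export
writeSweepSet <- function(sweeps, path) {
  stopifnot(is(sweeps, "SweepSet"))
  v <- sweeps@voltageMv
  cols <- c(list(sprintf("%.17g", sweeps@timeMs)),
            lapply(seq_len(ncol(v)), function(j) sprintf("%.17g", v[, j])))
  names(cols) <- c("time_ms", sprintf("sweep_%03d", seq_len(ncol(v)) - 1L))
  data.table::fwrite(data.table::as.data.table(cols), path, quote = FALSE)
  gt <- sweeps@groundTruth
  gtOut <- if (length(gt)) list(
    nRrp = gt$nRrp,
    # params may be one TMParams per connection or a list of one per contact;
    # length-1 fields unbox to scalars in the JSON
    params = if (!is.null(gt$params)) {
      ps <- if (is.list(gt$params)) gt$params else list(gt$params)
      list(U = vapply(ps, methods::slot, numeric(1), "U"),
           D = vapply(ps, methods::slot, numeric(1), "D"),
           F = vapply(ps, methods::slot, numeric(1), "F"),
           A = vapply(ps, methods::slot, numeric(1), "A"),
           gMax = vapply(ps, methods::slot, numeric(1), "gMax"))
    },
    noise = if (!is.null(gt$noise)) list(sigmaMv = gt$noise@sigmaMv,
                                         tauMs = gt$noise@tauMs),
    membrane = if (!is.null(gt$membrane)) list(
      tauMemMs = gt$membrane@tauMemMs, rInputMOhm = gt$membrane@rInputMOhm,
      vRestMv = gt$membrane@vRestMv, tauSynMs = gt$membrane@tauSynMs,
      eRevMv = gt$membrane@eRevMv),
    lambda = gt$lambda) else NULL
  prot <- sweeps@protocol
  jsonlite::write_json(list(
    units = list(time = "ms", voltage = "mV"),
    protocol = list(nPulses = prot@nPulses, frequencyHz = prot@frequencyHz,
                    recoveryDelayMs = prot@recoveryDelayMs,
                    onsetMs = prot@onsetMs),
    nSweeps = ncol(v),
    groundTruth = gtOut), .sidecar_path(path),
    digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a sweep set written by [writeSweepSet()]
#'
#' @param path CSV path with its `.json` sidecar next to it.
#' @return A [SweepSet-class].
#' @export
readSweepSet <- function(path) {
  side <- .sidecar_path(path)
  if (!file.exists(side))
    stop("missing JSON sidecar for ", path, " (expected ", side, ")")
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$protocol)) stop("sidecar has no protocol block")
  if (!identical(meta$units$time, "ms") || !identical(meta$units$voltage, "mV"))
    stop("unexpected units in sidecar; expected ms / mV")
  dt <- data.table::fread(path)
  if (!"time_ms" %in% names(dt))
    stop("CSV is missing the required `time_ms` column")
  sweepCols <- setdiff(names(dt), "time_ms")
  if (length(sweepCols) < 1L) stop("CSV has no sweep columns")
  m <- as.matrix(dt[, sweepCols, with = FALSE])
  if (anyNA(m) || anyNA(dt$time_ms))
    stop("ragged or non-numeric sweep columns in ", path)
  tm <- as.numeric(dt$time_ms)
  if (any(diff(tm) <= 0)) stop("`time_ms` must be strictly increasing")
  p <- meta$protocol
  gt <- list()
  g <- meta$groundTruth
  if (!is.null(g) && length(g)) {
    gt <- list(nRrp = as.integer(g$nRrp), lambda = g$lambda)
    if (!is.null(g$params)) {
      gp <- g$params
      gt$params <- if (length(gp$U) > 1L)
        Map(function(U, D, F, A, gMax) tmParams(U, D, F, A, gMax),
            gp$U, gp$D, gp$F, gp$A, gp$gMax)
      else tmParams(U = gp$U, D = gp$D, F = gp$F, A = gp$A, gMax = gp$gMax)
    }
    if (!is.null(g$noise))
      gt$noise <- noiseParams(g$noise$sigmaMv, g$noise$tauMs)
    if (!is.null(g$membrane))
      gt$membrane <- membraneModel(g$membrane$tauMemMs, g$membrane$rInputMOhm,
                                   g$membrane$vRestMv, g$membrane$tauSynMs,
                                   g$membrane$eRevMv)
    gt <- gt[!vapply(gt, is.null, logical(1))]
  }
  sweepSet(tm, m, stimulusProtocol(p$nPulses, p$frequencyHz,
                                   p$recoveryDelayMs, p$onsetMs), gt)
}

#' Write a cohort to a directory
#'
#' One CSV + sidecar per connection (`connection_000.csv`, ...) plus a
#' `manifest.json` with the per-connection ground truth and the realized
#' cohort-mean pool size.
#'
#' @param cohort list of [SweepSet-class] objects from [generateCohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("connection_%03d.csv", seq_along(cohort) - 1L)
  for (i in seq_along(cohort))
    writeSweepSet(cohort[[i]], file.path(dir, files[i]))
  manifest <- list(
    nConnections = length(cohort),
    realizedMeanNrrp = attr(cohort, "realizedMeanNrrp"),
    connections = lapply(seq_along(cohort), function(i) {
      gt <- groundTruth(cohort[[i]])
      ps <- gt$params
      if (!is.null(ps) && !is.list(ps)) ps <- list(ps)
      list(file = files[i], nRrp = gt$nRrp,
           U = if (!is.null(ps)) vapply(ps, methods::slot, numeric(1), "U"),
           D = if (!is.null(ps)) vapply(ps, methods::slot, numeric(1), "D"),
           F = if (!is.null(ps)) vapply(ps, methods::slot, numeric(1), "F"),
           gMax = if (!is.null(ps)) vapply(ps, methods::slot, numeric(1),
                                           "gMax"))
    }))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' Default run configuration
#'
#' The defaults wiring all pipeline stages together: protocol (8 pulses at
#' 20 Hz + recovery after 500 ms), membrane (rest -65.3 mV, input resistance
#' 59.7 MOhm, tau_mem 28.2 ms), OU noise (0.22 mV, 28.2 ms), population
#' parameter distributions, the GA configuration and the estimator settings
#' (lambda grid 0-13, 50 iterations, calibration target 1.46 mV, exclusion
#' range mean +/- 2 SD of the reference amplitudes).
#'
#' @param seed integer seed recorded in the configuration.
#' @return nested list of defaults.
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(seed = as.integer(seed),
       protocol = stimulusProtocol(),
       membrane = membraneModel(),
       noise = noiseParams(),
       distributions = paramDistributions(),
       ga = gaConfig(),
       estimator = list(lambdaGrid = 0:13, iterations = 50L,
                        nConnections = 100L, nSweeps = 20L,
                        targetAmplitudeMv = 1.46,
                        referenceAmplitudeSdMv = 0.86,
                        ampRange = referenceAmplitudeRange()))
}
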