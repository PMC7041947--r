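#' P/N leak subtraction
#'
#' Removes the linear (leak) component of a main sweep using its family of
#' 1/nSub-scaled sub-sweeps. The leak estimate at each sample is
#' sum(subs) - (nSub - 1) * I_hold, where I_hold (the standing leak at the
#' holding potential) is estimated from the sub-sweeps' initial holding
#' segments; the corrected trace is main minus this estimate. For a purely
#' ohmic leak and channel-free sub-sweeps this removes the leak exactly,
#' including its standing component at the holding potential.
#'
#' @param main a [CurrentTrace-class] (or list of them, one per sweep).
#' @param subs list of sub-sweep recordings as returned in
#'   `simulatePNLeakFamily()$subs` (each parallel to `main`).
#' @param nSub number of sub-sweeps (defaults to `length(subs)`).
#' @return corrected trace(s) with `leakSubtracted = TRUE` in metadata.
#' @examples
#' fam <- simulatePNLeakFamily(stepProtocol(c(-20, 0)),
#'                             channelPreset("cavmr-g240a",
#'                                           leakConductance = 0.5),
#'                             builtinSolutions("high-Na pipette"),
#'                             builtinSolutions("ca10-nmdg"))
#' corrected <- pnSubtract(fam$main, fam$subs)
#' @export
pnSubtract <- function(main, subs, nSub = length(subs)) {
  single <- is(main, "CurrentTrace")
  if (single) {
    main <- list(main)
    subs <- lapply(subs, function(s) if (is(s, "CurrentTrace")) list(s) else s)
  }
  out <- lapply(seq_along(main), function(sw) {
    m <- main[[sw]]
    n <- length(m@current)
    subTraces <- lapply(subs, `[[`, sw)
    if (any(vapply(subTraces, function(s) length(s@current), integer(1)) != n))
      stop("pnSubtract: sub-sweep length does not match the main sweep ",
           "(sweep ", sw, ")")
    subSum <- Reduce(`+`, lapply(subTraces, traceCurrent))
    holds <- unlist(lapply(subTraces, function(s) {
      seg <- s@metadata$segments
      idx <- if (!is.null(seg)) seg$startSample[1]:seg$endSample[1]
      else seq_len(max(1L, floor(n * 0.05)))
      s@current[idx]
    }))
    iHold <- mean(holds)
    corrected <- m@current - (subSum - (nSub - 1) * iHold)
    meta <- m@metadata
    meta$leakSubtracted <- TRUE
    new("CurrentTrace", time = m@time, commandV = m@commandV,
        current = corrected, metadata = meta)
  })
  if (single) out[[1]] else out
}

#' Reversal potential from a ramp sweep
#'
#' Finds the zero-current crossing within the ramp segment of a (leak
#' subtracted) sweep. The default "crossing" method returns the command
#' potential at the sign change by linear interpolation between the
#' bracketing samples; exactly one sign change must be present (after
#' optional moving-average smoothing), otherwise an error reporting the
#' crossing count is raised. The "linfit" method -- the usual choice for
#' noisy ramps -- locates the minimum-|I| point of the smoothed current,
#' fits an ordinary least-squares line to the raw samples within a small
#' voltage window around it, and returns the line's zero; it is insensitive
#' to sample-level sign flips and unbiased as long as the I-V relation is
#' locally linear over the fit window.
#'
#' @param trace a [CurrentTrace-class] containing a ramp segment.
#' @param rampSegment segment index; defaults to the (unique) segment of
#'   kind "ramp" recorded in the trace metadata.
#' @param smoothing moving-average width in samples (0 or 1 = none).
#' @param vWindow optional c(lo, hi) command-voltage window (mV) restricting
#'   the crossing search, e.g. to the range where the channel conducts (a
#'   closed channel's noise produces spurious crossings at potentials where
#'   the true current is ~0).
#' @param method "crossing" (sample interpolation, exact for clean traces)
#'   or "linfit" (local linear regression, robust to noise).
#' @param fitWindow half-width (mV) of the linfit regression window
#'   (wide enough to hold tens of samples, narrow enough that the I-V
#'   relation stays locally linear).
#' @return numeric, reversal potential in mV.
#' @examples
#' ch <- channelPreset("cavmr-g240a")
#' ch@tauAct <- 0; ch@tauDeact <- 0
#' tr <- simulateRecording(rampProtocol(-100, 100), ch,
#'                         builtinSolutions("high-Na pipette"),
#'                         builtinSolutions("ca10-nmdg"))[[1]]
#' extractErevFromRamp(tr)
#' @export
extractErevFromRamp <- function(trace, rampSegment = NULL, smoothing = 0,
                                vWindow = NULL,
                                method = c("crossing", "linfit"),
                                fitWindow = 4) {
  method <- match.arg(method)
  seg <- trace@metadata$segments
  if (is.null(rampSegment)) {
    if (is.null(seg) || !any(seg$kind == "ramp"))
      stop("extractErevFromRamp: no ramp segment recorded in metadata; ",
           "pass rampSegment explicitly")
    rampSegment <- which(seg$kind == "ramp")[1]
  }
  idx <- seg$startSample[rampSegment]:seg$endSample[rampSegment]
  v <- trace@commandV[idx]
  i <- trace@current[idx]
  vRaw <- v; iRaw <- i
  if (smoothing > 1) {
    i <- as.numeric(stats::filter(i, rep(1 / smoothing, smoothing),
                                  sides = 2))
    keep <- !is.na(i)
    v <- v[keep]; i <- i[keep]
  }
  if (!is.null(vWindow)) {
    keep <- v >= vWindow[1] & v <= vWindow[2]
    v <- v[keep]; i <- i[keep]
  }
  if (method == "linfit") {
    v0 <- v[which.min(abs(i))]
    keep <- abs(vRaw - v0) <= fitWindow
    if (sum(keep) < 5L)
      stop("extractErevFromRamp: linfit window around ", signif(v0, 4),
           " mV contains fewer than 5 samples")
    fit <- stats::lm(iRaw[keep] ~ vRaw[keep])
    b <- stats::coef(fit)
    if (!is.finite(b[2]) || b[2] <= 0)
      stop("extractErevFromRamp: local I-V slope is not positive; ",
           "no reliable crossing near ", signif(v0, 4), " mV")
    return(unname(-b[1] / b[2]))
  }
  s <- sign(i)
  cross <- which(s[-length(s)] * s[-1] < 0 |
                   (s[-length(s)] == 0 & s[-1] != 0))
  if (i[length(i)] == 0) cross <- c(cross, length(i) - 1L)
  cross <- unique(cross)
  if (length(cross) != 1L)
    stop("extractErevFromRamp: expected exactly one zero crossing in the ",
         "ramp window, found ", length(cross),
         if (length(cross) > 1) " (increase smoothing or leak-subtract first)"
         else "")
  k <- cross[1]
  v[k] + (0 - i[k]) * (v[k + 1] - v[k]) / (i[k + 1] - i[k])
}

#' Build a current-voltage curve from a step-series sweep set
#'
#' Measures one current value per sweep within its test-step segment: the
#' signed extremum ("peak") or the mean of the final 10% of the segment
#' ("steady"). When a normalization reference (a test potential present in
#' the series) is given, all values are divided by the reference measurement
#' so that the reference point is exactly 1 ("unit" convention) or by its
#' absolute value so that inward reference currents map to -1 ("signed"
#' convention).
#'
#' @param sweeps list of [CurrentTrace-class] from a step protocol.
#' @param measure "peak" or "steady".
#' @param normalizationRef optional reference test potential (mV).
#' @param convention "unit" (reference value becomes 1) or "signed"
#'   (divide by |reference|, preserving sign).
#' @param segment test-segment index; defaults to the per-sweep
#'   `testSegment` recorded by the simulator.
#' @return data.frame with columns `V`, `I` and (when normalized)
#'   `normalized`; attribute `normalization` describes the reference.
#' @export
buildIVCurve <- function(sweeps, measure = c("peak", "steady"),
                         normalizationRef = NULL,
                         convention = c("unit", "signed"), segment = NULL) {
  measure <- match.arg(measure)
  convention <- match.arg(convention)
  rows <- lapply(sweeps, function(tr) {
    segs <- tr@metadata$segments
    k <- segment %||% tr@metadata$testSegment
    if (is.null(k) || is.na(k))
      stop("buildIVCurve: no test segment recorded; pass segment explicitly")
    idx <- segs$startSample[k]:segs$endSample[k]
    i <- tr@current[idx]
    val <- if (measure == "peak") i[which.max(abs(i))]
    else mean(i[(length(i) - max(1L, floor(length(i) * 0.1)) + 1L):length(i)])
    data.frame(V = segs$vStart[k], I = val)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(normalizationRef)) {
    j <- which(abs(out$V - normalizationRef) < 1e-9)
    if (length(j) != 1L)
      stop("buildIVCurve: normalization reference ", normalizationRef,
           " mV does not match exactly one sweep")
    ref <- if (convention == "unit") out$I[j] else abs(out$I[j])
    out$normalized <- out$I / ref
    attr(out, "normalization") <- list(referenceV = normalizationRef,
                                       convention = convention,
                                       referenceI = out$I[j])
  }
  out
}

#' Per-cell permeability ratios aggregated Table-style
#'
#' Converts per-cell reversal potentials into permeability ratios and
#' aggregates them as mean +/- SEM with n per (channel, ratio) pair. Each
#' record names its solutions and target ratio "P_X/P_Y":
#' \itemize{
#'   \item Y = "Na", X divalent (Ca, Sr): the two-ion divalent expression
#'     ([pcaPnaFromErev()]) with X's concentrations.
#'   \item Y = "Na", X monovalent (K, Cs): the extended three-ion expression
#'     ([pmPnaFromErev()]); the record must carry its `pcaPna` value,
#'     otherwise a dependency error is raised.
#'   \item Y = "Ca", X monovalent: the two-ion expression with X as the
#'     reference monovalent gives P_Ca/P_X, which is inverted; the row is
#'     footnoted (the convention used for highly Ca2+-selective channels).
#' }
#'
#' @param records data.frame with columns `cell`, `channel`, `ratio`
#'   (e.g. "P_Ca/P_Na"), `eRev` (mV), `pipette`, `bath` (catalogue labels or
#'   [Solution-class] objects in list columns), optional `pcaPna`.
#' @param constants see [physicalConstants()].
#' @return data.frame with columns `channel`, `ratio`, `mean`, `sem`, `n`,
#'   `footnote`; per-cell values in attribute `perCell`. For n = 1 the SEM is
#'   reported as 0 and footnoted.
#' @export
permeabilityTable <- function(records, constants = physicalConstants()) {
  getSol <- function(x) if (is(x, "Solution")) x else builtinSolutions(x)
  vals <- numeric(nrow(records))
  foot <- character(nrow(records))
  for (r in seq_len(nrow(records))) {
    pip <- getSol(records$pipette[[r]])
    bat <- getSol(records$bath[[r]])
    parts <- strsplit(sub("^P_", "", records$ratio[r]), "/P_")[[1]]
    if (length(parts) != 2L)
      stop("permeabilityTable: ratio must look like 'P_X/P_Y', got '",
           records$ratio[r], "'")
    x <- parts[1]; y <- parts[2]
    e <- records$eRev[r]
    zx <- unname(ionValence(x))
    if (y == "Na" && zx == 2) {
      vals[r] <- pcaPnaFromErev(e, concentrationOf(pip, "Na"),
                                concentrationOf(bat, "Na"),
                                concentrationOf(pip, x),
                                concentrationOf(bat, x), constants)
      foot[r] <- ""
    } else if (y == "Na" && zx == 1) {
      pca <- if ("pcaPna" %in% names(records)) records$pcaPna[r] else NA_real_
      if (is.na(pca))
        stop("permeabilityTable: record ", r, " (", records$ratio[r],
             ") requires a pcaPna value but none is available")
      vals[r] <- pmPnaFromErev(e, pca, concentrationOf(pip, "Na"),
                               concentrationOf(bat, "Na"),
                               concentrationOf(pip, "Ca"),
                               concentrationOf(bat, "Ca"),
                               concentrationOf(pip, x),
                               concentrationOf(bat, x), constants)
      foot[r] <- ""
    } else if (y == "Ca" && zx == 1) {
      pCaPx <- pcaPnaFromErev(e, concentrationOf(pip, x),
                              concentrationOf(bat, x),
                              concentrationOf(pip, "Ca"),
                              concentrationOf(bat, "Ca"), constants)
      vals[r] <- 1 / pCaPx
      foot[r] <- "expressed vs Ca (high Ca2+ selectivity)"
    } else stop("permeabilityTable: unsupported ratio '", records$ratio[r],
                "'")
  }
  key <- interaction(records$channel, records$ratio, drop = TRUE)
  groups <- split(seq_len(nrow(records)), key)
  rows <- lapply(groups, function(ii) {
    v <- vals[ii]
    n <- length(v)
    sem <- if (n > 1) stats::sd(v) / sqrt(n) else 0
    fo <- unique(foot[ii][nzchar(foot[ii])])
    if (n == 1) fo <- c(fo, "single cell (SEM undefined, reported as 0)")
    data.frame(channel = records$channel[ii[1]],
               ratio = records$ratio[ii[1]],
               mean = mean(v), sem = sem, n = n,
               footnote = paste(fo, collapse = "; "))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "perCell") <- split(vals, key)
  out
}

#' Reversal potential vs concentration slope
#'
#' Ordinary least squares of E_rev on log10(concentration), the standard
#' check of Nernstian behaviour (theoretical divalent comparator:
#' [nernstSlopePerDecade()] with valence 2, about 29.6 mV/decade at 298.1 K).
#' A subset of concentrations may be selected, e.g. to exclude a condition
#' in which no outward current could be resolved.
#'
#' @param conc concentrations, mM.
#' @param eRev reversal potentials, mV.
#' @param include optional concentration subset to fit (default: all).
#' @return list with `slope` (mV/decade), `interceptMv`, `slopeSe`,
#'   `rSquared`, `includedConcentrations`.
#' @examples
#' e <- nernstPotential("Ca", c(4, 10, 20), 1e-3)
#' erevConcentrationSlope(c(4, 10, 20), e)$slope  # ~29.6
#' @export
erevConcentrationSlope <- function(conc, eRev, include = NULL) {
  if (!is.null(include)) {
    keep <- conc %in% include
    conc <- conc[keep]; eRev <- eRev[keep]
  }
  if (length(unique(conc)) < 2L)
    stop("erevConcentrationSlope: need >= 2 distinct concentrations")
  fit <- stats::lm(eRev ~ log10(conc))
  sm <- suppressWarnings(summary(fit))  # exact lines trip the R^2 warning
  list(slope = unname(stats::coef(fit)[2]),
       interceptMv = unname(stats::coef(fit)[1]),
       slopeSe = unname(sm$coefficients[2, "Std. Error"]),
       rSquared = sm$r.squared,
       includedConcentrations = sort(unique(conc)))
}

#' Mole-fraction summary and monotonicity verdict
#'
#' For each bath composition of a mole-fraction series, measures the peak
#' inward current during the test step at `measureV`, normalizes by the
#' largest amplitude across the series (maximum entry = 1), and reports
#' whether the amplitude-vs-f_Ca relation is free of an interior dip (a
#' local minimum below both neighbours beyond the tolerance) -- the absence
#' of an anomalous mole-fraction effect. The default tolerance is twice the
#' estimated noise SD of the normalized amplitudes (estimated from
#' first-difference residuals of the measured sweep); for noiseless traces
#' it is 0.
#'
#' @param traceSets named list of trace lists with attribute `f_Ca`
#'   (see [generateMoleFractionSeries()]).
#' @param measureV test potential at which the amplitude is read, mV.
#' @param tolerance dip tolerance on the normalized scale; NULL = automatic.
#' @return list with `table` (data.frame f_Ca, peak, normalized),
#'   `monotonic` (logical verdict), `tolerance`.
#' @export
moleFractionSummary <- function(traceSets, measureV = -20, tolerance = NULL) {
  if (length(traceSets) < 3L)
    stop("moleFractionSummary: need >= 3 mole fractions")
  rows <- lapply(traceSets, function(tr) {
    fCa <- attr(tr, "f_Ca")
    Vs <- vapply(tr, function(s) {
      k <- s@metadata$testSegment
      s@metadata$segments$vStart[k]
    }, numeric(1))
    j <- which(abs(Vs - measureV) < 1e-9)
    if (length(j) != 1L)
      stop("moleFractionSummary: series must contain exactly one sweep at ",
           measureV, " mV (found ", length(j), "); protocols not comparable")
    s <- tr[[j]]
    k <- s@metadata$testSegment
    idx <- s@metadata$segments$startSample[k]:s@metadata$segments$endSample[k]
    i <- s@current[idx]
    peak <- abs(min(i))  # inward currents are negative
    noise <- if (length(i) > 2) stats::sd(diff(i)) / sqrt(2) else 0
    data.frame(f_Ca = fCa, peak = peak, noise = noise)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$f_Ca), ]
  ref <- max(tab$peak)
  tab$normalized <- tab$peak / ref
  if (is.null(tolerance)) tolerance <- 2 * max(tab$noise) / ref
  amp <- tab$normalized
  dip <- FALSE
  for (i in seq_along(amp)[-c(1, length(amp))])
    if (amp[i] < amp[i - 1] - tolerance && amp[i] < amp[i + 1] - tolerance)
      dip <- TRUE
  rownames(tab) <- NULL
  list(table = tab[, c("f_Ca", "peak", "normalized")],
       monotonic = !dip, tolerance = tolerance)
}
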