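#' Steady-state Boltzmann activation
#'
#' Open fraction m_inf(V) = 1 / (1 + exp(-(V - vHalf)/kSlope)); equals 0.5 at
#' V = vHalf and is strictly increasing in V.
#'
#' @param V membrane potential(s), mV.
#' @param params a [BoltzmannParams-class], or the midpoint in mV (with `k`).
#' @param k slope factor (mV), used when `params` is numeric.
#' @return numeric in (0, 1).
#' @examples
#' boltzmannActivation(-51.7, boltzmannParams(-51.7, 8))  # 0.5 at midpoint
#' @export
boltzmannActivation <- function(V, params, k = 8) {
  if (is(params, "BoltzmannParams")) {
    vh <- params@vHalf; kk <- params@kSlope
  } else {
    vh <- params; kk <- k
  }
  if (kk <= 0) stop("boltzmannActivation: slope factor must be > 0")
  1 / (1 + exp(-(V - vh) / kk))
}

#' Extract tail-current amplitudes from a prepulse-tail sweep set
#'
#' For each sweep, locates the repolarization (tail) segment at the stated
#' potential -- the final contiguous run of samples at `repolarizationV` --
#' and measures the tail amplitude as the signed peak deviation (the sample
#' of largest magnitude) from the
#' post-decay baseline within `window` ms of the tail onset. The baseline is
#' the mean current over the final 10% of the tail segment (by which time the
#' tail has decayed to its steady level). The prepulse potential is read from
#' the command value immediately preceding the tail onset.
#'
#' @param traces list of [CurrentTrace-class], one per prepulse level.
#' @param repolarizationV tail potential, mV.
#' @param window measurement window after tail onset, ms.
#' @param vTol command-match tolerance, mV.
#' @return data.frame with columns `prepulse_mV` and `amplitude` (>= 0).
#' @seealso [tailProtocol()], [fitBoltzmann()]
#' @export
extractTailAmplitudes <- function(traces, repolarizationV, window = 20,
                                  vTol = 1e-6) {
  if (is(traces, "CurrentTrace")) traces <- list(traces)
  res <- lapply(traces, function(tr) {
    cmd <- tr@commandV
    seg <- tr@metadata$segments
    if (!is.null(seg)) {
      # simulated traces carry the segment table: use the last segment at
      # the repolarization potential (robust when prepulse == tail level)
      k <- which(seg$kind != "ramp" &
                   abs(seg$vStart - repolarizationV) < vTol)
      k <- k[k > 1L]
      if (!length(k))
        stop("extractTailAmplitudes: protocol mismatch - no repolarization ",
             "segment at ", repolarizationV, " mV")
      onset <- seg$startSample[max(k)]
    } else {
      at <- abs(cmd - repolarizationV) < vTol
      if (!any(at))
        stop("extractTailAmplitudes: protocol mismatch - no samples at the ",
             "repolarization potential ", repolarizationV, " mV")
      runs <- rle(at)
      if (!runs$values[length(runs$values)])
        stop("extractTailAmplitudes: protocol mismatch - the sweep does not ",
             "end with a repolarization segment at ", repolarizationV, " mV")
      nTail <- runs$lengths[length(runs$lengths)]
      onset <- length(cmd) - nTail + 1L
      if (onset == 1L)
        stop("extractTailAmplitudes: protocol mismatch - no prepulse ",
             "precedes the repolarization segment")
    }
    idx <- onset:length(cmd)
    tailI <- tr@current[idx]
    nBase <- max(1L, floor(length(idx) * 0.1))
    baseline <- mean(tailI[(length(tailI) - nBase + 1L):length(tailI)])
    dev <- tailI[tr@time[idx] - tr@time[onset] <= window] - baseline
    amp <- dev[which.max(abs(dev))]  # signed peak deviation
    data.frame(prepulse_mV = cmd[onset - 1L], amplitude = amp)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Build a normalized activation curve from tail amplitudes
#'
#' Normalizes tail amplitudes either by their own maximum (the usual G/Gmax
#' convention, so the maximum point is exactly 1) or by an external reference
#' Gmax (used when curves recorded under several bath conditions are all
#' expressed relative to one condition's maximum).
#'
#' @param amplitudes data.frame from [extractTailAmplitudes()], or numeric
#'   amplitudes with `prepulse` supplied.
#' @param prepulse prepulse potentials (mV) when `amplitudes` is numeric.
#' @param referenceGmax optional external normalization amplitude.
#' @param sem optional per-point SEM (same length), carried through.
#' @param nCells optional cell count, carried through as an attribute.
#' @return data.frame with columns `prepulse_mV`, `G_over_Gmax`, and `sem` if
#'   supplied; attribute `n_cells`.
#' @export
activationCurve <- function(amplitudes, prepulse = NULL, referenceGmax = NULL,
                            sem = NULL, nCells = NA_integer_) {
  if (is.data.frame(amplitudes)) {
    prepulse <- amplitudes$prepulse_mV
    amp <- amplitudes$amplitude
  } else amp <- amplitudes
  stopifnot(length(prepulse) == length(amp))
  # normalize by the largest-magnitude amplitude, preserving relative sign,
  # so the maximum normalized value is exactly 1 (tail currents of one
  # recording share a direction; tiny opposite-sign values can arise when a
  # prepulse sits below the steady open fraction at the tail potential)
  ref <- if (is.null(referenceGmax)) amp[which.max(abs(amp))] else referenceGmax
  out <- data.frame(prepulse_mV = prepulse, G_over_Gmax = amp / ref)
  if (!is.null(sem)) out$sem <- sem
  attr(out, "n_cells") <- nCells
  out
}

#' Fit a Boltzmann activation curve
#'
#' Nonlinear least squares (Levenberg-Marquardt via
#' [minpack.lm::nls.lm]) of
#'
#'   G/Gmax(V) = floor + (gMax - floor) / (1 + exp(-(V - vHalf)/kSlope))
#'
#' to a normalized activation curve. The additive floor absorbs the nonzero
#' steady open fraction at the tail potential (tails measured at a potential
#' where deactivation is incomplete leave a baseline offset in the normalized
#' curve); set `fixFloor = TRUE` for the classic 3-parameter fit. Initial
#' values are deterministic: vHalf from linear interpolation of the
#' half-maximum crossing, kSlope = 8 mV, gMax = max, floor = min.
#'
#' @param curve data.frame with columns `prepulse_mV` and `G_over_Gmax`
#'   (see [activationCurve()]), needing >= 4 distinct potentials spanning the
#'   transition.
#' @param init optional [BoltzmannParams-class] initial values.
#' @param fixFloor logical; fix the floor at 0.
#' @return list with elements `params` ([BoltzmannParams-class]), `floor`,
#'   `se` (named asymptotic standard errors), `residualNorm`, `converged`,
#'   and `fit` (the nls object).
#' @examples
#' v <- seq(-140, 40, 10)
#' g <- boltzmannActivation(v, boltzmannParams(-51.7, 8))
#' fit <- fitBoltzmann(data.frame(prepulse_mV = v, G_over_Gmax = g / max(g)))
#' vHalf(fit$params)
#' @export
fitBoltzmann <- function(curve, init = NULL, fixFloor = FALSE) {
  v <- curve$prepulse_mV
  g <- curve$G_over_Gmax
  if (length(unique(v)) < 4L)
    stop("fitBoltzmann: need >= 4 distinct prepulse potentials")
  if (max(g) - min(g) < .Machine$double.eps * 8)
    stop("fitBoltzmann: degenerate (all-equal) activation data")
  if (is.null(init)) {
    half <- (max(g) + min(g)) / 2
    ord <- order(v)
    vs <- v[ord]; gs <- g[ord]
    i <- which(gs >= half)[1]
    v0 <- if (is.na(i) || i == 1L) stats::median(vs) else
      vs[i - 1] + (half - gs[i - 1]) / (gs[i] - gs[i - 1]) * (vs[i] - vs[i - 1])
    init <- boltzmannParams(vHalf = v0, kSlope = 8, gMax = max(g))
  }
  start <- c(vHalf = init@vHalf, kSlope = init@kSlope, gMax = max(g))
  if (!fixFloor) start <- c(start, floor = min(g))
  model <- function(p, V) {
    fl <- if (fixFloor) 0 else p[["floor"]]
    fl + (p[["gMax"]] - fl) / (1 + exp(-(V - p[["vHalf"]]) / p[["kSlope"]]))
  }
  fit <- minpack.lm::nls.lm(
    par = start, fn = function(p) g - model(p, v),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!fit$info %in% 1:4)
    stop("fitBoltzmann: fit failed to converge (", fit$message, ")")
  co <- fit$par
  if (co[["kSlope"]] < 0) {  # mirror solution: flip slope, swap asymptotes
    co[["kSlope"]] <- -co[["kSlope"]]
    if (!fixFloor) {
      tmp <- co[["gMax"]]; co[["gMax"]] <- co[["floor"]]; co[["floor"]] <- tmp
    }
  }
  se <- tryCatch({
    sm <- summary(fit)
    sm$coefficients[, "Std. Error"]
  }, error = function(e) stats::setNames(rep(NA_real_, length(co)),
                                         names(co)))
  list(params = boltzmannParams(vHalf = unname(co[["vHalf"]]),
                                kSlope = unname(co[["kSlope"]]),
                                gMax = unname(co[["gMax"]])),
       floor = if (fixFloor) 0 else unname(co[["floor"]]),
       se = se,
       residualNorm = sqrt(fit$deviance),
       converged = fit$info %in% 1:4,
       fit = fit)
}
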