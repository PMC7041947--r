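#' Voltage-protocol constructors
#'
#' `stepProtocol` builds the classic step series (hold, test step, return to
#' hold) with one sweep per level; `rampProtocol` a hold / optional
#' depolarizing step / voltage ramp; `tailProtocol` the prepulse-tail
#' protocol used for activation curves (hold, variable prepulse,
#' fixed repolarization).
#'
#' @param levels step-series test potentials, mV (one sweep each).
#' @param holdV holding potential, mV.
#' @param preDur,stepDur,postDur,holdDur,prepulseDur,tailDur,rampDur segment
#'   durations, ms.
#' @param vFrom,vTo ramp start/end potentials, mV.
#' @param preV optional step potential inserted before the ramp, mV.
#' @param prepulses prepulse potentials, mV (one sweep each).
#' @param tailV repolarization potential, mV.
#' @param rateKHz sampling rate, kHz.
#' @return A [VoltageProtocol-class].
#' @examples
#' stepProtocol(seq(-140, 100, 20))
#' rampProtocol(-100, 100)
#' tailProtocol(seq(-130, 40, 10), tailV = -140)
#' @export
stepProtocol <- function(levels, holdV = -140, preDur = 10, stepDur = 100,
                         postDur = 50, rateKHz = 10) {
  seg <- data.frame(kind = c("hold", "step", "hold"),
                    vStart = c(holdV, levels[1], holdV),
                    vEnd = c(holdV, levels[1], holdV),
                    duration = c(preDur, stepDur, postDur))
  sw <- data.frame(sweep = seq_along(levels), segment = 2L,
                   vStart = levels, vEnd = levels)
  new("VoltageProtocol", segments = seg, holdingV = holdV,
      sampleRateKHz = rateKHz, sweepTable = sw)
}

#' @rdname stepProtocol
#' @export
rampProtocol <- function(vFrom = -100, vTo = 100, rampDur = 200,
                         holdV = -140, preV = NULL, preDur = 10,
                         postDur = 20, rateKHz = 10) {
  seg <- data.frame(kind = "hold", vStart = holdV, vEnd = holdV,
                    duration = preDur)
  if (!is.null(preV))
    seg <- rbind(seg, data.frame(kind = "step", vStart = preV, vEnd = preV,
                                 duration = preDur))
  seg <- rbind(seg,
               data.frame(kind = "ramp", vStart = vFrom, vEnd = vTo,
                          duration = rampDur),
               data.frame(kind = "hold", vStart = holdV, vEnd = holdV,
                          duration = postDur))
  new("VoltageProtocol", segments = seg, holdingV = holdV,
      sampleRateKHz = rateKHz,
      sweepTable = data.frame(sweep = integer(), segment = integer(),
                              vStart = numeric(), vEnd = numeric()))
}

#' @rdname stepProtocol
#' @export
tailProtocol <- function(prepulses = seq(-130, 40, 10), holdDur = 10,
                         prepulseDur = 150, tailV = -140, tailDur = 60,
                         holdV = -140, rateKHz = 10) {
  seg <- data.frame(kind = c("hold", "step", "step"),
                    vStart = c(holdV, prepulses[1], tailV),
                    vEnd = c(holdV, prepulses[1], tailV),
                    duration = c(holdDur, prepulseDur, tailDur))
  sw <- data.frame(sweep = seq_along(prepulses), segment = 2L,
                   vStart = prepulses, vEnd = prepulses)
  new("VoltageProtocol", segments = seg, holdingV = holdV,
      sampleRateKHz = rateKHz, sweepTable = sw)
}

# Per-sweep command vector + segment sample bookkeeping.
.buildCommand <- function(protocol, sweep) {
  seg <- protocol@segments
  sw <- protocol@sweepTable
  if (nrow(sw)) {
    rows <- sw[sw$sweep == sweep, , drop = FALSE]
    for (j in seq_len(nrow(rows))) {
      seg$vStart[rows$segment[j]] <- rows$vStart[j]
      seg$vEnd[rows$segment[j]] <- rows$vEnd[j]
    }
  }
  dt <- 1 / protocol@sampleRateKHz
  nSeg <- pmax(1L, as.integer(round(seg$duration * protocol@sampleRateKHz)))
  cmd <- vector("list", nrow(seg))
  for (i in seq_len(nrow(seg))) {
    cmd[[i]] <- if (seg$kind[i] == "ramp" && nSeg[i] > 1L)
      seq(seg$vStart[i], seg$vEnd[i], length.out = nSeg[i])
    else rep(seg$vStart[i], nSeg[i])
  }
  ends <- cumsum(nSeg)
  seg$startSample <- c(1L, utils::head(ends, -1) + 1L)
  seg$endSample <- ends
  list(command = unlist(cmd), dt = dt, segments = seg)
}

# First-order gate relaxation along a command vector. tau = 0 means the gate
# tracks its steady-state value instantaneously. Each sample reports the gate
# state at the start of its interval (the command switches first, the gate
# relaxes over the following dt), so the first sample after a voltage step
# carries the pre-step gate value -- the idealized "instantaneous tail
# current" convention of tail-current analysis.
.relaxGate <- function(cmd, dt, m0, targetFun, tauUp, tauDown) {
  n <- length(cmd)
  m <- numeric(n)
  target <- targetFun(cmd)
  if (tauUp == 0 && tauDown == 0) return(target)
  prev <- m0
  for (i in seq_len(n)) {
    tau <- if (target[i] >= prev) tauUp else tauDown
    m[i] <- if (tau == 0) target[i] else prev
    prev <- if (tau == 0) target[i] else
      target[i] + (prev - target[i]) * exp(-dt / tau)
  }
  m
}

#' Simulate a whole-cell voltage-clamp recording
#'
#' Generates one [CurrentTrace-class] per sweep of the protocol. Per sample,
#' an activation gate m relaxes toward the Boltzmann steady state
#' m_inf(V) with time constant tauAct when opening and tauDeact when closing
#' (tau = 0 gives instantaneous gating); an optional inactivation gate h
#' relaxes toward 0 above `inactThreshold` (toward 1 below) with tauInact.
#' The current is
#'
#'   I = gScale * block * m * h * ghkCurrent(V) + leakConductance * V + noise
#'
#' where block = 1/(1 + [Ca]out/caBlockIC50) (1 when the phenomenological
#' Ca2+ block is off) and noise is white Gaussian with SD noiseSd, seeded
#' from the channel seed so that identical specifications give identical
#' traces. Capacitive transients are not modelled. A channel whose permeant
#' ions are absent from both solutions yields zero flux with a warning.
#'
#' @param protocol a [VoltageProtocol-class].
#' @param channel a [SimChannelSpec-class].
#' @param pipette,bath [Solution-class] objects.
#' @param constants see [physicalConstants()].
#' @return list of [CurrentTrace-class], one per sweep.
#' @examples
#' ch <- channelPreset("cavmr-g240a")
#' tr <- simulateRecording(rampProtocol(-100, 100),
#'                         ch,
#'                         builtinSolutions("high-Na pipette"),
#'                         builtinSolutions("ca10-nmdg"))
#' length(tr)
#' @export
simulateRecording <- function(protocol, channel, pipette, bath,
                              constants = physicalConstants()) {
  validObject(protocol); validObject(channel)
  perms <- channel@perms
  permIons <- names(perms@ratios)[isPermeantCation(names(perms@ratios)) &
                                    perms@ratios > 0]
  haveFlux <- length(permIons) > 0 &&
    any(concentrationOf(pipette, permIons) +
          concentrationOf(bath, permIons) > 0)
  if (!haveFlux)
    warning("simulateRecording: no permeant ion present on either side; ",
            "channel flux is zero")
  caOut <- concentrationOf(bath, "Ca")
  block <- 1 / (1 + caOut / channel@caBlockIC50)
  sweeps <- if (nrow(protocol@sweepTable))
    sort(unique(protocol@sweepTable$sweep)) else 1L
  mInf <- function(v) boltzmannActivation(v, channel@gating)
  m0 <- mInf(protocol@holdingV)
  withr::with_seed(channel@seed, {
    lapply(sweeps, function(s) {
      bc <- .buildCommand(protocol, s)
      cmd <- bc$command; dt <- bc$dt
      n <- length(cmd)
      m <- .relaxGate(cmd, dt, m0, mInf, channel@tauAct, channel@tauDeact)
      if (is.finite(channel@tauInact)) {
        h0 <- as.numeric(protocol@holdingV <= channel@inactThreshold)
        h <- .relaxGate(cmd, dt, h0,
                        function(v) as.numeric(v <= channel@inactThreshold),
                        channel@tauInact, channel@tauInact)
      } else h <- 1
      flux <- if (haveFlux)
        ghkCurrent(cmd, perms, pipette, bath, constants) else 0
      cur <- channel@gScale * block * m * h * flux +
        channel@leakConductance * cmd
      if (channel@noiseSd > 0)
        cur <- cur + stats::rnorm(n, 0, channel@noiseSd)
      meta <- list(channel = channel@label,
                   pipette = pipette@label, bath = bath@label,
                   seed = channel@seed, sweep = s,
                   holdingV = protocol@holdingV,
                   sampleRateKHz = protocol@sampleRateKHz,
                   segments = bc$segments,
                   testSegment = if (nrow(protocol@sweepTable))
                     protocol@sweepTable$segment[
                       protocol@sweepTable$sweep == s][1] else NA_integer_,
                   leakSubtracted = FALSE)
      new("CurrentTrace", time = dt * (seq_len(n) - 1), commandV = cmd,
          current = cur, metadata = meta)
    })
  })
}

#' Simulate a P/N leak-subtraction family
#'
#' Produces the main sweeps plus `nSub` sub-sweep recordings whose voltage
#' excursions from the holding potential are scaled by 1/nSub (the P/N
#' protocol, delivered at the holding potential), with the channel
#' conductance zeroed in the sub-sweeps (sub-threshold assumption), the same
#' ohmic leak, and fresh noise per sub-sweep.
#'
#' @inheritParams simulateRecording
#' @param nSub number of sub-sweeps (10 for the standard P/10 protocol).
#' @return list with elements `main` (list of [CurrentTrace-class]), `subs`
#'   (list of nSub recordings, each a list of traces parallel to `main`), and
#'   `nSub`.
#' @seealso [pnSubtract()]
#' @export
simulatePNLeakFamily <- function(protocol, channel, pipette, bath, nSub = 10,
                                 constants = physicalConstants()) {
  stopifnot(nSub >= 1)
  main <- simulateRecording(protocol, channel, pipette, bath, constants)
  hv <- protocol@holdingV
  scaleV <- function(v) hv + (v - hv) / nSub
  sub <- protocol
  sub@segments$vStart <- scaleV(sub@segments$vStart)
  sub@segments$vEnd <- scaleV(sub@segments$vEnd)
  if (nrow(sub@sweepTable)) {
    sub@sweepTable$vStart <- scaleV(sub@sweepTable$vStart)
    sub@sweepTable$vEnd <- scaleV(sub@sweepTable$vEnd)
  }
  subCh <- channel
  subCh@gScale <- 0
  subs <- lapply(seq_len(nSub), function(i) {
    subCh@seed <- channel@seed + 7919L * i
    simulateRecording(sub, subCh, pipette, bath, constants)
  })
  list(main = main, subs = subs, nSub = nSub)
}

#' Simulate a mole-fraction bath series
#'
#' Runs the same channel, pipette and protocol over a series of bath
#' compositions with varying Na+/Ca2+ ratio; each trace set is labelled with
#' its calcium mole fraction f_Ca = [Ca]out / ([Ca]out + [Na]out).
#'
#' @inheritParams simulateRecording
#' @param naCaPairs list (or 2-column matrix) of (Na mM, Ca mM) bath pairs.
#' @return named list (one element per pair, name "Na:Ca") of trace lists,
#'   each with attribute `f_Ca`.
#' @examples
#' pairs <- list(c(135, 0), c(108, 18), c(81, 36), c(54, 54), c(27, 82),
#'               c(0, 90))
#' @export
generateMoleFractionSeries <- function(channel, naCaPairs, protocol, pipette,
                                       constants = physicalConstants()) {
  if (is.matrix(naCaPairs))
    naCaPairs <- split(naCaPairs, seq_len(nrow(naCaPairs)))
  stopifnot(all(vapply(naCaPairs, function(p) all(p >= 0), logical(1))))
  out <- lapply(naCaPairs, function(p) {
    na <- p[1]; ca <- p[2]
    bath <- solution(sprintf("molefrac %g:%g", na, ca),
                     c(Na = na, Ca = ca, Cl = na + 2 * ca, HEPES = 10),
                     "bath")
    tr <- simulateRecording(protocol, channel, pipette, bath, constants)
    fCa <- if (na + ca > 0) ca / (ca + na) else NA_real_
    attr(tr, "f_Ca") <- fCa
    tr
  })
  names(out) <- vapply(naCaPairs, function(p) sprintf("%g:%g", p[1], p[2]),
                       character(1))
  out
}

#' Channel presets
#'
#' Ready-made [SimChannelSpec-class] objects encoding the published
#' selectivities and activation midpoints of the two AnclNav-family channels
#' and their filter mutants: the calcium-selective CavMr (P_Ca/P_Na = 218,
#' V1/2 = -51.7 mV; the G240A gate mutant suppresses inactivation), the
#' CavMr-D7M filter mutant (P_Ca/P_Na = 144), the sodium-selective NavPp
#' (P_Ca/P_Na = 0.308, P_K/P_Na = 0.16, V1/2 = -17.11 mV for the T232A gate
#' mutant), and the filter-swap NavPp-Mr (P_Ca/P_Na = 215). Gating time
#' constants are illustrative (no kinetic values are published for these
#' channels): tauAct = 5 ms, tauDeact = 2 ms, tauInact = 100 ms for wild
#' types and Inf (inactivation removed) for the G240A/T232A gate mutants.
#'
#' @param name preset name, one of "cavmr-g240a", "cavmr-wt", "cavmr-d7m",
#'   "cavmr-pp", "navpp-t232a", "navpp-wt", "navpp-mr".
#' @param seed RNG seed stored in the spec.
#' @param noiseSd,leakConductance,gScale overrides.
#' @return A [SimChannelSpec-class].
#' @examples
#' channelPreset("cavmr-g240a")
#' @export
channelPreset <- function(name, seed = 1L, noiseSd = 0, leakConductance = 0,
                          gScale = 1) {
  defs <- list(
    "cavmr-g240a" = list(perms = c(Ca = 218, Sr = 40.6),
                         gating = boltzmannParams(-51.7, 8), tauInact = Inf),
    "cavmr-wt"    = list(perms = c(Ca = 218, Sr = 40.6),
                         gating = boltzmannParams(-51.7, 8), tauInact = 100),
    "cavmr-d7m"   = list(perms = c(Ca = 144, Sr = 20.7),
                         gating = boltzmannParams(-51.7, 8), tauInact = Inf),
    "cavmr-pp"    = list(perms = c(Ca = 13.8, Sr = 24.5, K = 0.95,
                                   Cs = 0.57),
                         gating = boltzmannParams(-51.7, 8), tauInact = Inf),
    "navpp-t232a" = list(perms = c(Ca = 0.308, Sr = 0.38, K = 0.16,
                                   Cs = 0.0052),
                         gating = boltzmannParams(-17.11, 8),
                         tauInact = Inf),
    "navpp-wt"    = list(perms = c(Ca = 0.308, Sr = 0.38, K = 0.16,
                                   Cs = 0.0052),
                         gating = boltzmannParams(-17.11, 8),
                         tauInact = 100),
    "navpp-mr"    = list(perms = c(Ca = 215, Sr = 86.3),
                         gating = boltzmannParams(-51.7, 8), tauInact = Inf))
  if (!name %in% names(defs))
    stop("unknown preset '", name, "'. Available: ",
         paste(names(defs), collapse = ", "))
  d <- defs[[name]]
  simChannelSpec(permeabilitySet(d$perms), d$gating, tauAct = 5, tauDeact = 2,
                 tauInact = d$tauInact, gScale = gScale,
                 leakConductance = leakConductance, noiseSd = noiseSd,
                 seed = seed, label = name)
}
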