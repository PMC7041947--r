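#' @import methods
NULL

#' Ionic solution
#'
#' A named recording solution: a map from ion/solute name to concentration in
#' mM, tagged with its role (pipette = intracellular, bath = extracellular).
#' All components are recorded for provenance, including impermeant species
#' (anions, buffers, NMDG); only permeant cations contribute flux in the GHK
#' model. Looking up a species that is absent from the solution returns 0 mM.
#'
#' @slot label character, solution name.
#' @slot concentrations named numeric, mM per species; all values >= 0.
#' @slot role "pipette" or "bath".
#' @seealso [solution()], [builtinSolutions()], [concentrationOf()]
#' @export
setClass("Solution",
  representation(label = "character", concentrations = "numeric",
                 role = "character"))

setValidity("Solution", function(object) {
  msg <- character()
  conc <- object@concentrations
  if (is.null(names(conc)) || any(!nzchar(names(conc))))
    msg <- c(msg, "all concentrations must be named by species")
  if (anyDuplicated(names(conc)))
    msg <- c(msg, "species names must be unique within a solution")
  if (any(conc < 0))
    msg <- c(msg, "concentrations must be >= 0 mM")
  if (length(object@role) != 1L || !object@role %in% c("pipette", "bath"))
    msg <- c(msg, "role must be 'pipette' or 'bath'")
  if (length(msg)) msg else TRUE
})

#' Relative permeability set
#'
#' Channel permeabilities expressed relative to sodium: the ratios slot maps
#' ion name to P_X/P_Na (dimensionless, >= 0) and always contains Na with
#' value 1; scale is the absolute P_Na in arbitrary flux units.
#'
#' @slot ratios named numeric, P_X/P_Na with ratios["Na"] == 1.
#' @slot scale numeric(1) > 0, absolute P_Na.
#' @seealso [permeabilitySet()]
#' @export
setClass("PermeabilitySet",
  representation(ratios = "numeric", scale = "numeric"))

setValidity("PermeabilitySet", function(object) {
  msg <- character()
  r <- object@ratios
  if (is.null(names(r)) || !"Na" %in% names(r))
    msg <- c(msg, "ratios must be named and include Na")
  else if (abs(r[["Na"]] - 1) > .Machine$double.eps * 4)
    msg <- c(msg, "P_Na/P_Na must equal 1")
  if (any(r < 0)) msg <- c(msg, "permeability ratios must be >= 0")
  if (length(object@scale) != 1L || object@scale <= 0)
    msg <- c(msg, "scale must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Boltzmann activation parameters
#'
#' Steady-state activation is modelled as
#' m_inf(V) = 1 / (1 + exp(-(V - vHalf)/kSlope)); gMax is the conductance
#' scale applied when the curve is used as a fit model.
#'
#' @slot vHalf numeric(1), midpoint potential (mV).
#' @slot kSlope numeric(1) > 0, slope factor (mV).
#' @slot gMax numeric(1) > 0, normalized conductance scale.
#' @seealso [boltzmannParams()], [boltzmannActivation()], [fitBoltzmann()]
#' @export
setClass("BoltzmannParams",
  representation(vHalf = "numeric", kSlope = "numeric", gMax = "numeric"))

setValidity("BoltzmannParams", function(object) {
  msg <- character()
  if (length(object@vHalf) != 1L) msg <- c(msg, "vHalf must be numeric(1)")
  if (length(object@kSlope) != 1L || object@kSlope <= 0)
    msg <- c(msg, "kSlope must be a single positive number (mV)")
  if (length(object@gMax) != 1L || object@gMax <= 0)
    msg <- c(msg, "gMax must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Voltage-clamp command protocol
#'
#' A piecewise command: ordered segments (hold / step / ramp) with start and
#' end potentials and durations, sampled at a fixed rate. Per-sweep variants
#' (e.g. a step series -140 ... +100 mV) are expressed through sweepTable,
#' whose rows override the voltage of one segment for one sweep.
#'
#' @slot segments data.frame with columns kind, vStart, vEnd, duration (ms).
#' @slot holdingV numeric(1), holding potential (mV).
#' @slot sampleRateKHz numeric(1) > 0.
#' @slot sweepTable data.frame with columns sweep, segment, vStart, vEnd.
#' @seealso [stepProtocol()], [rampProtocol()], [tailProtocol()]
#' @export
setClass("VoltageProtocol",
  representation(segments = "data.frame", holdingV = "numeric",
                 sampleRateKHz = "numeric", sweepTable = "data.frame"))

setValidity("VoltageProtocol", function(object) {
  msg <- character()
  seg <- object@segments
  need <- c("kind", "vStart", "vEnd", "duration")
  if (!all(need %in% names(seg)))
    msg <- c(msg, paste("segments must have columns:",
                        paste(need, collapse = ", ")))
  else {
    if (any(!seg$kind %in% c("hold", "step", "ramp")))
      msg <- c(msg, "segment kind must be hold, step or ramp")
    if (any(seg$duration <= 0)) msg <- c(msg, "segment durations must be > 0")
    ramps <- seg$kind == "ramp"
    if (any(ramps & seg$vStart == seg$vEnd))
      msg <- c(msg, "ramp segments must have vStart != vEnd")
  }
  if (length(object@sampleRateKHz) != 1L || object@sampleRateKHz <= 0)
    msg <- c(msg, "sampleRateKHz must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Simulated or recorded current trace (one sweep)
#'
#' Equal-length time (ms), command potential (mV) and current (normalized
#' units) vectors, plus a metadata list (channel label, solution labels,
#' seed, sweep index, segment sample ranges, leak-subtracted flag).
#'
#' @slot time numeric, ms, strictly increasing, uniform spacing.
#' @slot commandV numeric, mV per sample.
#' @slot current numeric per sample.
#' @slot metadata list.
#' @seealso [simulateRecording()], [readTraceCsv()]
#' @export
setClass("CurrentTrace",
  representation(time = "numeric", commandV = "numeric", current = "numeric",
                 metadata = "list"))

setValidity("CurrentTrace", function(object) {
  msg <- character()
  n <- length(object@time)
  if (length(object@commandV) != n || length(object@current) != n)
    msg <- c(msg, "time, commandV and current must have equal length")
  if (n > 1 && any(diff(object@time) <= 0))
    msg <- c(msg, "time must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Simulated channel specification
#'
#' Everything the recording generator needs: relative permeabilities,
#' Boltzmann gating, first-order activation/deactivation/inactivation time
#' constants (ms; tauInact = Inf disables inactivation; taus of 0 mean
#' instantaneous gating), conductance scale, ohmic leak slope, Gaussian
#' noise SD and RNG seed. An optional phenomenological extracellular Ca2+
#' block (conductance factor 1/(1 + [Ca]out/IC50)) is off by default
#' (caBlockIC50 = Inf).
#'
#' @slot label character.
#' @slot perms PermeabilitySet.
#' @slot gating BoltzmannParams.
#' @slot tauAct,tauDeact,tauInact numeric(1) ms (>= 0; Inf allowed for
#'   tauInact).
#' @slot inactThreshold numeric(1) mV, inactivation engages above this.
#' @slot gScale numeric(1) >= 0 conductance multiplier.
#' @slot leakConductance numeric(1) >= 0, leak current per mV.
#' @slot noiseSd numeric(1) >= 0.
#' @slot caBlockIC50 numeric(1) mM, Inf = no block.
#' @slot seed integer(1).
#' @seealso [simChannelSpec()], [channelPreset()]
#' @export
setClass("SimChannelSpec",
  representation(label = "character", perms = "PermeabilitySet",
                 gating = "BoltzmannParams", tauAct = "numeric",
                 tauDeact = "numeric", tauInact = "numeric",
                 inactThreshold = "numeric", gScale = "numeric",
                 leakConductance = "numeric", noiseSd = "numeric",
                 caBlockIC50 = "numeric", seed = "integer"))

setValidity("SimChannelSpec", function(object) {
  msg <- character()
  if (object@tauAct < 0 || object@tauDeact < 0 || object@tauInact <= 0)
    msg <- c(msg, "time constants must be >= 0 (tauInact > 0, Inf allowed)")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@gScale < 0) msg <- c(msg, "gScale must be >= 0")
  if (object@caBlockIC50 <= 0) msg <- c(msg, "caBlockIC50 must be > 0")
  if (length(msg)) msg else TRUE
})

#' Selectivity-filter window
#'
#' The seven pore-loop residues of a homotetrameric channel subunit, with
#' local positions 1-7 and the parent-sequence index of position 1 (e.g. the
#' CavMr filter 183-TLEGWVD-189 has parentOffset 183, so Thr183 is Thr1 and
#' Asp189 is Asp7).
#'
#' @slot residues character(1), exactly 7 one-letter amino-acid codes.
#' @slot parentOffset integer(1), parent index of local position 1.
#' @slot label character(1), channel name.
#' @seealso [filterSequence()], [applyMutation()], [chargeCount()]
#' @export
setClass("FilterSequence",
  representation(residues = "character", parentOffset = "integer",
                 label = "character"))

setValidity("FilterSequence", function(object) {
  msg <- character()
  res <- object@residues
  if (length(res) != 1L || nchar(res) != 7L)
    msg <- c(msg, "residues must be a single 7-character string")
  else {
    aa <- strsplit(res, "")[[1]]
    ok <- aa %in% Biostrings::AA_STANDARD
    if (!all(ok))
      msg <- c(msg, paste0("invalid residue(s): ",
                           paste(unique(aa[!ok]), collapse = ", ")))
  }
  if (length(object@parentOffset) != 1L || is.na(object@parentOffset))
    msg <- c(msg, "parentOffset must be a single integer")
  if (length(msg)) msg else TRUE
})
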