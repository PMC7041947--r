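#' Create a Solution
#'
#' @param label solution name.
#' @param concentrations named numeric vector, mM per species.
#' @param role "pipette" (intracellular) or "bath" (extracellular).
#' @return A [Solution-class] object.
#' @examples
#' solution("high-Na pipette",
#'          c(Na = 150, F = 115, Cl = 35, EGTA = 10, HEPES = 10), "pipette")
#' @export
solution <- function(label, concentrations, role = c("bath", "pipette")) {
  role <- match.arg(role)
  new("Solution", label = as.character(label),
      concentrations = concentrations, role = role)
}

#' Create a PermeabilitySet
#'
#' The Na entry is added (with value 1) if absent; supplying Na != 1 is an
#' error since all ratios are relative to sodium.
#'
#' @param ratios named numeric vector of P_X/P_Na values.
#' @param scale absolute P_Na in arbitrary flux units.
#' @return A [PermeabilitySet-class] object.
#' @examples
#' permeabilitySet(c(Ca = 218))          # CavMr G240A-like selectivity
#' permeabilitySet(c(Ca = 0.308, K = 0.16))
#' @export
permeabilitySet <- function(ratios, scale = 1) {
  if (!"Na" %in% names(ratios)) ratios <- c(Na = 1, ratios)
  new("PermeabilitySet", ratios = ratios, scale = scale)
}

#' Create BoltzmannParams
#'
#' @param vHalf midpoint potential (mV).
#' @param kSlope slope factor (mV), > 0.
#' @param gMax conductance scale, > 0.
#' @return A [BoltzmannParams-class] object.
#' @examples
#' boltzmannParams(vHalf = -51.7, kSlope = 8)
#' @export
boltzmannParams <- function(vHalf, kSlope = 8, gMax = 1) {
  new("BoltzmannParams", vHalf = vHalf, kSlope = kSlope, gMax = gMax)
}

#' Create a SimChannelSpec
#'
#' @param perms a [PermeabilitySet-class] or a named ratio vector.
#' @param gating a [BoltzmannParams-class].
#' @param tauAct,tauDeact activation/deactivation time constants (ms); 0
#'   means instantaneous gating.
#' @param tauInact inactivation time constant (ms); Inf disables.
#' @param inactThreshold potential (mV) above which inactivation engages.
#' @param gScale conductance multiplier.
#' @param leakConductance ohmic leak slope (current units per mV).
#' @param noiseSd Gaussian recording-noise SD (current units).
#' @param caBlockIC50 phenomenological extracellular Ca2+ block IC50 (mM);
#'   Inf = off.
#' @param seed RNG seed for reproducible noise.
#' @param label channel name.
#' @return A [SimChannelSpec-class] object.
#' @examples
#' simChannelSpec(permeabilitySet(c(Ca = 218)),
#'                boltzmannParams(-51.7, 8), label = "CavMr-like")
#' @export
simChannelSpec <- function(perms, gating, tauAct = 5, tauDeact = 2,
                           tauInact = Inf, inactThreshold = -40, gScale = 1,
                           leakConductance = 0, noiseSd = 0,
                           caBlockIC50 = Inf, seed = 1L, label = "channel") {
  if (!is(perms, "PermeabilitySet")) perms <- permeabilitySet(perms)
  new("SimChannelSpec", label = label, perms = perms, gating = gating,
      tauAct = tauAct, tauDeact = tauDeact, tauInact = tauInact,
      inactThreshold = inactThreshold, gScale = gScale,
      leakConductance = leakConductance, noiseSd = noiseSd,
      caBlockIC50 = caBlockIC50, seed = as.integer(seed))
}

#' Create a FilterSequence
#'
#' @param residues 7-character amino-acid string (one-letter codes).
#' @param parentOffset parent-sequence index of local position 1.
#' @param label channel name.
#' @return A [FilterSequence-class] object.
#' @examples
#' filterSequence("TLEGWVD", parentOffset = 183, label = "CavMr")
#' @export
filterSequence <- function(residues, parentOffset = 1L, label = "") {
  new("FilterSequence", residues = toupper(as.character(residues)),
      parentOffset = as.integer(parentOffset), label = label)
}

setMethod("show", "Solution", function(object) {
  conc <- object@concentrations
  cat(sprintf("Solution '%s' (%s): %s\n", object@label, object@role,
              paste(sprintf("%s %g mM", names(conc), conc), collapse = ", ")))
})

setMethod("show", "PermeabilitySet", function(object) {
  r <- object@ratios
  cat("PermeabilitySet (relative to Na):\n")
  for (nm in names(r)) cat(sprintf("  P_%s/P_Na = %g\n", nm, r[[nm]]))
  cat(sprintf("  absolute scale = %g\n", object@scale))
})

setMethod("show", "BoltzmannParams", function(object) {
  cat(sprintf("Boltzmann activation: V1/2 = %.4g mV, k = %.4g mV, Gmax = %g\n",
              object@vHalf, object@kSlope, object@gMax))
})

setMethod("show", "VoltageProtocol", function(object) {
  cat(sprintf("VoltageProtocol: %d segment(s), hold %g mV, %g kHz, %d sweep(s)\n",
              nrow(object@segments), object@holdingV, object@sampleRateKHz,
              max(1L, length(unique(object@sweepTable$sweep)))))
  print(object@segments)
})

setMethod("show", "CurrentTrace", function(object) {
  cat(sprintf("CurrentTrace: %d samples, %g-%g ms, sweep %s\n",
              length(object@time), min(object@time), max(object@time),
              as.character(object@metadata$sweep %||% NA)))
})

setMethod("show", "SimChannelSpec", function(object) {
  cat(sprintf("SimChannelSpec '%s'\n", object@label))
  show(object@perms)
  show(object@gating)
  cat(sprintf("  tau act/deact/inact = %g/%g/%g ms; leak %g/mV; noise sd %g\n",
              object@tauAct, object@tauDeact, object@tauInact,
              object@leakConductance, object@noiseSd))
})

setMethod("show", "FilterSequence", function(object) {
  cat(sprintf("FilterSequence %s: %d-%s-%d (positions 1-7)\n",
              if (nzchar(object@label)) object@label else "<unnamed>",
              object@parentOffset, object@residues, object@parentOffset + 6L))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
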