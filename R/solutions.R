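#' Physical constants
#'
#' Faraday constant, gas constant, and absolute temperature used throughout
#' the GHK and Nernst computations. The default temperature of 298.1 K
#' (~25 degC) matches the recording conditions the analysis assumes;
#' activities are identified with concentrations (no ionic-strength
#' correction).
#'
#' @param temperatureK absolute temperature in kelvin.
#' @return list with elements F (C/mol), R (J/mol/K), T (K).
#' @examples
#' physicalConstants()            # T = 298.1 K
#' physicalConstants(310)         # body temperature
#' @export
physicalConstants <- function(temperatureK = 298.1) {
  stopifnot(is.numeric(temperatureK), length(temperatureK) == 1L,
            temperatureK > 0)
  list(F = 96485.33212, R = 8.31446261815324, T = temperatureK)
}

# Species registry. Permeant cations are the mono/divalent metal ions; NMDG
# is a large organic cation treated as impermeant, anions and buffers carry
# no flux. Unknown species default to impermeant with valence 0.
.ionTable <- data.frame(
  name     = c("Na", "K", "Cs", "Li", "Rb", "Ca", "Sr", "Ba", "Mg",
               "NMDG", "Cl", "F", "EGTA", "HEPES", "glucose", "ATP"),
  valence  = c(1, 1, 1, 1, 1, 2, 2, 2, 2, 1, -1, -1, 0, 0, 0, 0),
  permeant = c(rep(TRUE, 9), rep(FALSE, 7)),
  stringsAsFactors = FALSE)

#' Ion species properties
#'
#' @param ion species name(s).
#' @return `ionValence`: signed integer charge (0 for neutral/unknown
#'   species); `isPermeantCation`: logical, TRUE for the mono- and divalent
#'   metal cations that carry flux in the GHK model (NMDG, anions and buffers
#'   are impermeant).
#' @examples
#' ionValence(c("Na", "Ca", "Cl", "NMDG"))
#' isPermeantCation(c("Na", "NMDG"))
#' @export
ionValence <- function(ion) {
  idx <- match(ion, .ionTable$name)
  v <- ifelse(is.na(idx), 0, .ionTable$valence[idx])
  names(v) <- ion
  v
}

#' @rdname ionValence
#' @export
isPermeantCation <- function(ion) {
  idx <- match(ion, .ionTable$name)
  p <- !is.na(idx) & .ionTable$permeant[idx]
  names(p) <- ion
  p
}

#' Nernst equilibrium potential
#'
#' E = (RT/zF) ln(c_out/c_in), in mV. Antisymmetric under swapping the two
#' concentrations.
#'
#' @param ion ion name (its valence is looked up) or a signed integer
#'   valence.
#' @param cOut,cIn outside/inside concentrations (mM), both > 0.
#' @param constants see [physicalConstants()].
#' @return numeric, potential in mV.
#' @examples
#' nernstPotential("Na", 150, 15)   # ~ +59 mV
#' nernstPotential("Ca", 20, 2)     # ~ +29.6 mV, one decade for z = 2
#' @export
nernstPotential <- function(ion, cOut, cIn, constants = physicalConstants()) {
  z <- if (is.numeric(ion)) ion else unname(ionValence(ion))
  if (z == 0)
    stop("nernstPotential: species '", ion, "' has zero valence")
  if (any(cOut <= 0) || any(cIn <= 0))
    stop("nernstPotential: concentrations for '",
         if (is.numeric(ion)) paste0("z=", ion) else ion,
         "' must be > 0 (got cOut = ", cOut, ", cIn = ", cIn, ")")
  1000 * constants$R * constants$T / (z * constants$F) * log(cOut / cIn)
}

#' Nernst slope per concentration decade
#'
#' RT ln(10) / (zF), in mV per tenfold concentration change: ~59.2 mV/decade
#' for monovalent and ~29.6 mV/decade for divalent cations at 298.1 K. This
#' is the theoretical comparator for reversal-potential vs concentration
#' regressions of a perfectly selective channel.
#'
#' @param valence signed integer charge, nonzero.
#' @param constants see [physicalConstants()].
#' @return numeric, mV/decade.
#' @examples
#' nernstSlopePerDecade(2)   # ~29.6, the divalent prediction
#' @export
nernstSlopePerDecade <- function(valence, constants = physicalConstants()) {
  if (any(valence == 0)) stop("nernstSlopePerDecade: valence must be nonzero")
  1000 * constants$R * constants$T * log(10) / (valence * constants$F)
}

#' Catalogue of recording solutions
#'
#' Every named pipette and bath recipe used by the analyses this package
#' supports, with per-species concentrations in mM. Includes the high-Na /
#' high-K / high-Cs pipettes (115 mM fluoride + 35 mM chloride salt), the
#' NMDG-based Ca2+ series (4, 10, 20 mM), the 100 mM Ca2+/Sr2+ baths, the
#' K+/Cs+ baths (150 mM + 2 mM Ca2+), the mixed NavPp-style baths, the
#' NaCl/CaCl2 mole-fraction series (135/0, 108/18, 81/36, 54/54, 27/82,
#' 0/90), the Ca2+-free bath (135 NaCl + 1 EGTA), and the step-series I-V
#' baths.
#'
#' @param label optional solution name; if missing the whole catalogue (a
#'   named list of [Solution-class] objects) is returned. An unknown label is
#'   an error that lists the available names.
#' @return A [Solution-class] or a named list of them.
#' @examples
#' builtinSolutions("high-Na pipette")
#' names(builtinSolutions())
#' @export
builtinSolutions <- function(label) {
  sol <- function(lab, conc, role) solution(lab, conc, role)
  cat <- list(
    # pipettes
    "high-Na pipette" = sol("high-Na pipette",
      c(Na = 150, F = 115, Cl = 35, EGTA = 10, HEPES = 10), "pipette"),
    "high-K pipette" = sol("high-K pipette",
      c(K = 150, F = 115, Cl = 35, EGTA = 10, HEPES = 10), "pipette"),
    "high-Cs pipette" = sol("high-Cs pipette",
      c(Cs = 150, F = 115, Cl = 35, EGTA = 10, HEPES = 10), "pipette"),
    "low-Na pipette" = sol("low-Na pipette",
      c(Cs = 140, Na = 10, F = 140, Cl = 10, EGTA = 10, HEPES = 10),
      "pipette"),
    "IV pipette" = sol("IV pipette",  # 75 NaF + 40 CsF + 35 CsCl
      c(Na = 75, Cs = 75, F = 115, Cl = 35, EGTA = 10, HEPES = 10),
      "pipette"),
    "CHO pipette" = sol("CHO pipette",  # 130 KCl, 5 Na2-ATP, 3 EGTA, 0.1 Ca, 4 Mg
      c(K = 130, Na = 10, Cl = 138.2, Ca = 0.1, Mg = 4, EGTA = 3,
        HEPES = 10, ATP = 5), "pipette"),
    # NMDG-background Ca2+ series for bi-ionic measurements
    "ca4-nmdg" = sol("ca4-nmdg",
      c(NMDG = 144, Ca = 4, Cl = 152, HEPES = 10), "bath"),
    "ca10-nmdg" = sol("ca10-nmdg",
      c(NMDG = 135, Ca = 10, Cl = 155, HEPES = 10), "bath"),
    "ca20-nmdg" = sol("ca20-nmdg",
      c(NMDG = 120, Ca = 20, Cl = 160, HEPES = 10), "bath"),
    "ca40-nmdg" = sol("ca40-nmdg",
      c(NMDG = 90, Ca = 40, Cl = 170, HEPES = 10), "bath"),
    # divalent / monovalent test baths
    "ca100" = sol("ca100",
      c(Ca = 100, Cl = 200, HEPES = 10, glucose = 10), "bath"),
    "sr100" = sol("sr100",
      c(Sr = 100, Cl = 200, HEPES = 10, glucose = 10), "bath"),
    "k150-ca2" = sol("k150-ca2",
      c(K = 150, Ca = 2, Cl = 154, HEPES = 10, glucose = 10), "bath"),
    "cs150-ca2" = sol("cs150-ca2",
      c(Cs = 150, Ca = 2, Cl = 154, HEPES = 10, glucose = 10), "bath"),
    # mixed baths for modestly selective (NavPp-style) channels
    "navpp-mixed-ca" = sol("navpp-mixed-ca",
      c(NMDG = 50, Na = 40, Ca = 40, Cl = 170, HEPES = 10), "bath"),
    "navpp-mixed-sr" = sol("navpp-mixed-sr",
      c(NMDG = 50, Na = 40, Sr = 40, Cl = 170, HEPES = 10), "bath"),
    "navpp-cs-na" = sol("navpp-cs-na",
      c(NMDG = 110, Na = 40, Ca = 3, Cl = 156, HEPES = 10), "bath"),
    # step-series I-V baths
    "na150" = sol("na150", c(Na = 150, Cl = 150, HEPES = 10), "bath"),
    "na75-nmdg75" = sol("na75-nmdg75",
      c(Na = 75, NMDG = 75, Cl = 150, HEPES = 10), "bath"),
    "na75-ca50" = sol("na75-ca50",
      c(Na = 75, Ca = 50, Cl = 175, HEPES = 10), "bath"),
    "ca50-nmdg75" = sol("ca50-nmdg75",
      c(Ca = 50, NMDG = 75, Cl = 175, HEPES = 10), "bath"),
    # Ca2+ block baths
    "ca-block-1.5" = sol("ca-block-1.5",
      c(Na = 30, NMDG = 120, Ca = 1.5, Cl = 153, HEPES = 10, glucose = 10),
      "bath"),
    "ca-block-10" = sol("ca-block-10",
      c(Na = 30, NMDG = 105, Ca = 10, Cl = 155, HEPES = 10, glucose = 10),
      "bath"),
    # mole-fraction NaCl/CaCl2 series (CHO recordings)
    "mole-fraction 135:0" = sol("mole-fraction 135:0",
      c(Na = 135, Ca = 0, Cl = 135, HEPES = 10), "bath"),
    "mole-fraction 108:18" = sol("mole-fraction 108:18",
      c(Na = 108, Ca = 18, Cl = 144, HEPES = 10), "bath"),
    "mole-fraction 81:36" = sol("mole-fraction 81:36",
      c(Na = 81, Ca = 36, Cl = 153, HEPES = 10), "bath"),
    "mole-fraction 54:54" = sol("mole-fraction 54:54",
      c(Na = 54, Ca = 54, Cl = 162, HEPES = 10), "bath"),
    "mole-fraction 27:82" = sol("mole-fraction 27:82",
      c(Na = 27, Ca = 82, Cl = 191, HEPES = 10), "bath"),
    "mole-fraction 0:90" = sol("mole-fraction 0:90",
      c(Na = 0, Ca = 90, Cl = 180, HEPES = 10), "bath"),
    # Ca-free control and the sparse three-point series
    "ca-free" = sol("ca-free",
      c(Na = 135, Ca = 0, Cl = 135, EGTA = 1, HEPES = 10), "bath"),
    "fig-series 0:90" = sol("fig-series 0:90",
      c(Na = 0, Ca = 90, Cl = 180, HEPES = 10), "bath"),
    "fig-series 133.7:0.9" = sol("fig-series 133.7:0.9",
      c(Na = 133.7, Ca = 0.9, Cl = 135.5, HEPES = 10), "bath"),
    "fig-series 135:0" = sol("fig-series 135:0",
      c(Na = 135, Ca = 0, Cl = 135, EGTA = 1, HEPES = 10), "bath"))
  if (missing(label)) return(cat)
  if (!label %in% names(cat))
    stop("unknown solution label '", label, "'. Available: ",
         paste(names(cat), collapse = ", "))
  cat[[label]]
}

#' Tabulate the solution catalogue
#'
#' @return data.frame with one row per (solution, species) pair: label, role,
#'   species, mM.
#' @examples
#' head(solutionTable())
#' @export
solutionTable <- function() {
  cat <- builtinSolutions()
  do.call(rbind, lapply(cat, function(s) {
    data.frame(label = s@label, role = s@role,
               species = names(s@concentrations),
               mM = unname(s@concentrations), row.names = NULL)
  }))
}
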