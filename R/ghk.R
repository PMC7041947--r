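#' GHK membrane current
#'
#' Constant-field (Goldman-Hodgkin-Katz) current density summed over the
#' permeant cations of a permeability set, for mixed mono/divalent solutions:
#'
#'   I = sum_X  P_X z^2 (F^2 V / RT) ([X]in - [X]out e^(-zVF/RT)) /
#'       (1 - e^(-zVF/RT))
#'
#' Outward current is positive and membrane potential is inside minus
#' outside. The removable singularity at V = 0 is handled by a series
#' expansion for |zVF/RT| < 1e-4 (limit I(0) = sum P_X z F ([X]in - [X]out)).
#' The result is strictly increasing in V for nonnegative permeabilities and
#' concentrations, which guarantees a unique reversal potential.
#'
#' @param V membrane potential(s), mV.
#' @param perms a [PermeabilitySet-class] (or named ratio vector).
#' @param pipette,bath [Solution-class] objects; pipette = inside, bath =
#'   outside.
#' @param constants see [physicalConstants()].
#' @return numeric, current density in arbitrary units (scaled by
#'   `perms@scale`), outward positive.
#' @examples
#' pip <- solution("sym", c(Na = 150), "pipette")
#' bat <- solution("sym", c(Na = 150), "bath")
#' ghkCurrent(0, permeabilitySet(c()), pip, bat)  # 0 at equilibrium
#' @export
ghkCurrent <- function(V, perms, pipette, bath,
                       constants = physicalConstants()) {
  if (!is(perms, "PermeabilitySet")) perms <- permeabilitySet(perms)
  ratios <- perms@ratios
  ions <- names(ratios)[isPermeantCation(names(ratios)) & ratios > 0]
  cin <- concentrationOf(pipette, ions)
  cout <- concentrationOf(bath, ions)
  if (length(ions) == 0L || all(cin + cout == 0))
    stop("ghkCurrent: no permeant ion has nonzero concentration on either side")
  FF <- constants$F; RT <- constants$R * constants$T
  out <- numeric(length(V))
  for (k in seq_along(ions)) {
    z <- unname(ionValence(ions[k]))
    P <- ratios[[ions[k]]] * perms@scale
    u <- z * (V / 1000) * FF / RT
    term <- numeric(length(V))
    small <- abs(u) < 1e-4
    if (any(small)) {
      us <- u[small]
      N <- cin[k] - cout[k] * exp(-us)
      # I = P z F * u N / (1 - e^-u); u/(1-e^-u) = 1 + u/2 + u^2/12 + O(u^4)
      term[small] <- P * z * FF * N * (1 + us / 2 + us^2 / 12)
    }
    if (any(!small)) {
      ub <- u[!small]
      term[!small] <- P * z^2 * (FF^2 * (V[!small] / 1000) / RT) *
        (cin[k] - cout[k] * exp(-ub)) / (1 - exp(-ub))
    }
    out <- out + term
  }
  out
}

#' Reversal potential of the GHK model
#'
#' Solves the zero-current condition I(E_rev) = 0 on [-200, +200] mV by
#' bracketed root-finding ([stats::uniroot]). Because the GHK current is
#' strictly increasing in V, the root is unique when it exists; if the
#' current does not change sign on the bracket, an error reporting the
#' end-point currents is raised.
#'
#' @inheritParams ghkCurrent
#' @param bracket search interval in mV.
#' @param tol root tolerance in mV.
#' @return list with elements `E_rev` (mV), `bracket`, `iterations`,
#'   `residual` (current at the root).
#' @examples
#' pip <- builtinSolutions("high-Na pipette")
#' bat <- builtinSolutions("ca10-nmdg")
#' reversalPotential(permeabilitySet(c(Ca = 218)), pip, bat)$E_rev
#' @export
reversalPotential <- function(perms, pipette, bath,
                              constants = physicalConstants(),
                              bracket = c(-200, 200), tol = 1e-9) {
  f <- function(v) ghkCurrent(v, perms, pipette, bath, constants)
  flo <- f(bracket[1]); fhi <- f(bracket[2])
  if (sign(flo) == sign(fhi))
    stop(sprintf(paste0("reversalPotential: no reversal in [%g, %g] mV ",
                        "(end-point currents %g and %g)"),
                 bracket[1], bracket[2], flo, fhi))
  r <- stats::uniroot(f, interval = bracket, f.lower = flo, f.upper = fhi,
                      tol = tol)
  list(E_rev = r$root, bracket = bracket, iterations = r$iter,
       residual = f(r$root))
}

#' P_Ca/P_Na from a bi-ionic reversal potential
#'
#' The zero-current GHK expression for a divalent/monovalent pair:
#'
#'   P_Ca/P_Na = -([Na]in - [Na]out a)(1 - a^2) /
#'               (4 ([Ca]in - [Ca]out a^2)(1 - a)),  a = e^(-E_rev F/RT).
#'
#' Implemented with the exact factorization (1 - a^2)/(1 - a) = 1 + a, which
#' removes the E_rev = 0 singularity analytically (the factor tends to 2).
#' The same expression applies to any divalent test ion (Sr2+): pass its
#' concentrations as the `caIn`/`caOut` arguments.
#'
#' @param eRev reversal potential, mV.
#' @param naIn,naOut internal/external Na+ (mM).
#' @param caIn,caOut internal/external divalent ion (mM).
#' @param constants see [physicalConstants()].
#' @return numeric, P_Ca/P_Na (dimensionless).
#' @examples
#' # balanced-flux limit: E_rev = 0, 100 Na in vs 50 Ca out -> exactly 1
#' pcaPnaFromErev(0, naIn = 100, naOut = 0, caIn = 0, caOut = 50)
#' @export
pcaPnaFromErev <- function(eRev, naIn, naOut, caIn, caOut,
                           constants = physicalConstants()) {
  if (anyNA(eRev)) return(NA_real_)
  u <- (eRev / 1000) * constants$F / (constants$R * constants$T)
  a <- exp(-u)
  den <- 4 * (caIn - caOut * a^2)
  if (any(abs(den) < .Machine$double.eps * 16 * max(1, caIn, caOut)))
    stop("pcaPnaFromErev: degenerate condition ([Ca]in = [Ca]out e^(-2uE)); ",
         "the divalent flux term vanishes at this reversal potential")
  -(naIn - naOut * a) * (1 + a) / den
}

#' P_M/P_Na for a monovalent test ion from a three-ion reversal potential
#'
#' Solves the three-ion (Na+, test monovalent M+, Ca2+) GHK zero-current
#' condition for the monovalent selectivity, given an already-known
#' P_Ca/P_Na:
#'
#'   P_M/P_Na = [ -4 (P_Ca/P_Na) ([Ca]in - [Ca]out a^2)/(1 + a)
#'                - ([Na]in - [Na]out a) ] / ([M]in - [M]out a)
#'
#' with a = e^(-E_rev F/RT). This grouping is re-derived from the zero-current
#' condition sum of per-ion GHK flux terms (see the methods vignette for the
#' derivation); the common factor (1 - a) of all three terms cancels, and the
#' divalent term keeps its z^2 = 4 prefactor and e^(-2u) exponent so that the
#' expression is the exact algebraic inverse of [ghkCurrent()]'s zero-current
#' condition. With the Ca2+ terms absent and Na+ only inside / M+ only
#' outside it reduces to the classic bi-ionic formula [Na]in e^(uE)/[M]out.
#'
#' @inheritParams pcaPnaFromErev
#' @param pcaPna known P_Ca/P_Na (dimensionless).
#' @param mIn,mOut internal/external test monovalent ion (mM).
#' @return numeric, P_M/P_Na (dimensionless).
#' @examples
#' # two-ion reduction: no Ca anywhere, Na inside only, K outside only
#' cst <- physicalConstants()
#' e <- 10
#' pmPnaFromErev(e, pcaPna = 0, naIn = 150, naOut = 0, caIn = 0, caOut = 0,
#'               mIn = 0, mOut = 150)
#' 150 * exp(e / 1000 * cst$F / (cst$R * cst$T)) / 150  # same value
#' @export
pmPnaFromErev <- function(eRev, pcaPna, naIn, naOut, caIn, caOut, mIn, mOut,
                          constants = physicalConstants()) {
  if (anyNA(eRev)) return(NA_real_)
  u <- (eRev / 1000) * constants$F / (constants$R * constants$T)
  a <- exp(-u)
  mTerm <- mIn - mOut * a
  if (abs(mTerm) < .Machine$double.eps * 16 * max(1, mIn, mOut))
    stop("pmPnaFromErev: degenerate condition ([M]in = [M]out e^(-uE)); ",
         "the monovalent test-ion flux term vanishes")
  (-4 * pcaPna * (caIn - caOut * a^2) / (1 + a) - (naIn - naOut * a)) / mTerm
}
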