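---
title: "Quantifying ion selectivity and gating of prokaryotic channels with ionperm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ion selectivity and gating of prokaryotic channels with ionperm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionperm)
```

## The scientific problem

Homotetrameric prokaryotic voltage-gated channels (the BacNav family and
its ancestor-like relatives such as the calcium-selective CavMr from
*Meiothermus ruber* and the sodium-selective NavPp from *Plesiocystis
pacifica*) are the minimal systems in which cation selectivity can be
dissected residue by residue. The quantity of interest is the relative
permeability P~X~/P~Na~ of a test cation X, inferred from the reversal
potential E~rev~ of whole-cell currents recorded under controlled ionic
gradients; the voltage dependence of activation is summarized by the
midpoint V~1/2~ of a Boltzmann fit to tail-current amplitudes. `ionperm`
implements this entire inference chain, together with a synthetic
recording generator so that every stage can be validated end to end
against known ground truth.

## The permeation model

Each permeant cation X (valence z, internal and external concentrations
in mM) contributes a Goldman-Hodgkin-Katz (constant-field) flux

$$ I_X(V) \;=\; P_X\, z^2 \frac{F^2 V}{RT}\,
   \frac{[X]_\mathrm{in} - [X]_\mathrm{out}\, e^{-zVF/RT}}
        {1 - e^{-zVF/RT}}, $$

with outward current positive and membrane potential defined inside
minus outside. Activities are identified with concentrations, as is
conventional for this analysis; anions, buffers and NMDG are treated as
impermeant. The total current is the sum over permeant ions, which is
strictly increasing in V, so the zero-current (reversal) potential is
unique and is found by bracketed root-finding on [-200, +200] mV
(`reversalPotential()`, tolerance 1e-9 mV).

Setting the two-ion (Na^+^ inside, Ca^2+^ outside) sum to zero and
solving for the permeability ratio gives

$$ \frac{P_\mathrm{Ca}}{P_\mathrm{Na}} =
   -\frac{([\mathrm{Na}]_\mathrm{in} - [\mathrm{Na}]_\mathrm{out}a)
          (1 - a^2)}
         {4([\mathrm{Ca}]_\mathrm{in} - [\mathrm{Ca}]_\mathrm{out}a^2)
          (1 - a)}, \qquad a = e^{-E_\mathrm{rev}F/RT}, $$

implemented in `pcaPnaFromErev()` with the factorization
$(1-a^2)/(1-a) = 1+a$, which removes the $E_\mathrm{rev}=0$ singularity
exactly (the factor tends to 2). The same expression serves Sr^2+^.

For a third, monovalent test ion M the zero-current condition over
{Na^+^, M^+^, Ca^2+^} is solved for P~M~/P~Na~ given a known
P~Ca~/P~Na~. Dividing the three-ion sum by the common factor $(1-a)$:

$$ \frac{P_M}{P_\mathrm{Na}} =
   \frac{-\dfrac{4\,(P_\mathrm{Ca}/P_\mathrm{Na})
         ([\mathrm{Ca}]_\mathrm{in} - [\mathrm{Ca}]_\mathrm{out}a^2)}{1+a}
         \;-\;([\mathrm{Na}]_\mathrm{in} - [\mathrm{Na}]_\mathrm{out}a)}
        {[M]_\mathrm{in} - [M]_\mathrm{out}a}. $$

This grouping was re-derived from the per-ion flux sum rather than
transcribed (plain-text renderings of the formula are typographically
ambiguous); the derivation above is one line: each monovalent term
carries $(\cdot)/(1-a)$ and the divalent term
$4(\cdot)/(1-a^2) = 4(\cdot)/[(1-a)(1+a)]$. With the Ca^2+^ terms
absent and Na^+^ only inside, M^+^ only outside, it reduces to the
classic bi-ionic formula $[\mathrm{Na}]_\mathrm{in}e^{uE}/[M]_\mathrm{out}$
(asserted in the test suite). Because the inverse expressions use the
same $z^2 = 4$ prefactor and $e^{-2u}$ exponents as the forward model,
solve-then-substitute round trips are exact to solver precision; this is
the package's primary correctness surface and is what the acceptance
script exercises with the published ratios (218 and 144 for CavMr and
its D7M filter mutant, 0.308 and 0.16 for NavPp T232A, 215 for the
NavPp-Mr filter swap).

Physical constants default to F = 96485.33212 C/mol,
R = 8.31446 J/mol/K and T = 298.1 K (the recording temperature this
analysis assumes; override via `physicalConstants()`). At this
temperature the Nernst slope RT ln10/zF is ~59.1 mV/decade for
monovalent and ~29.6 mV/decade for divalent cations
(`nernstSlopePerDecade()`), the theoretical comparator for
reversal-vs-concentration regressions (`erevConcentrationSlope()`).

## Gating model and tail-current analysis

Steady-state activation is a two-state Boltzmann,
$m_\infty(V) = 1/(1 + e^{-(V - V_{1/2})/k})$. The slope factor k is not
constrained by the published analyses, so the simulator default is
k = 8 mV, a typical BacNav value; fits always treat k as free, and none
of the recovery results depend on the choice.

`extractTailAmplitudes()` measures, for each prepulse sweep, the signed
peak deviation of the tail current from its post-decay baseline (the
mean of the final 10% of the repolarization segment). Signed rather
than absolute deviations matter when tails are recorded at a potential
where the steady open fraction is nonzero (NavPp tails at -60 mV):
prepulses below that level produce small opposite-sign deviations, and
taking magnitudes would fold the activation curve over. Peak-minus-
baseline is exact for the simulator's mono-exponential tails; no
exponential back-extrapolation is attempted.

`fitBoltzmann()` fits
$G/G_\mathrm{max}(V) = b + (G_\mathrm{max}-b)/(1+e^{-(V-V_{1/2})/k})$
by Levenberg-Marquardt (`minpack.lm::nls.lm`), with a free floor b by
default. The floor absorbs the baseline offset that a nonzero steady
open fraction at the tail potential leaves in the normalized curve;
without it the fitted midpoint carries a bias of order
$k \cdot m_\infty(V_\mathrm{tail})$ (about 0.1 mV for the NavPp
configuration), while the floor-including family contains the true
curve and recovers the midpoint to machine precision. `fixFloor = TRUE`
restores the classic 3-parameter fit. Initialization is deterministic
(midpoint from linear interpolation of the half-maximum crossing,
k = 8 mV, scale and floor from the data range), so repeated fits are
identical. Normalization is by the largest-magnitude amplitude, making
the maximum point exactly 1; an external reference G~max~ can be
supplied instead when curves recorded under several bath conditions are
all expressed relative to one condition's maximum.

## The synthetic recording generator

`simulateRecording()` produces idealized whole-cell sweeps:

* piecewise command protocols (hold/step/ramp segments with per-sweep
  overrides) via `stepProtocol()`, `rampProtocol()`, `tailProtocol()`;
* an activation gate relaxing mono-exponentially toward
  $m_\infty(V)$ with `tauAct` (5 ms default) when opening and
  `tauDeact` (2 ms) when closing; `tau = 0` means instantaneous gating;
* an optional inactivation gate relaxing toward 0 above
  `inactThreshold` with `tauInact` (Inf, i.e. disabled, for the
  G240A/T232A-style gate-mutant presets; 100 ms for wild types). These
  time constants are illustrative: no kinetic values are published for
  these channels, and no analysis in the package depends on them;
* GHK permeation from the channel's `PermeabilitySet` and the pipette
  and bath solutions; ohmic leak `leakConductance * V`; white Gaussian
  noise with SD `noiseSd`, seeded from the channel spec so identical
  specifications give identical traces;
* a phenomenological extracellular Ca^2+^ block (conductance factor
  $1/(1+[\mathrm{Ca}]_\mathrm{out}/\mathrm{IC}_{50})$), off by default:
  it lets users emulate the Ca^2+^-inhibited NavPp phenotype
  qualitatively without claiming a mechanism.

Each sample reports the gate state at the start of its interval: the
command switches first and the gate relaxes over the following sample
period. The first sample after a repolarization step therefore carries
the prepulse's gate value — the idealized instantaneous tail current —
which is what makes tail amplitudes exactly proportional to
$m_\infty(V_\mathrm{pre}) - m_\infty(V_\mathrm{tail})$ and midpoint
recovery exact rather than accurate only to one sample interval.

What the generator does **not** emulate: capacitive transients
(cancellation is assumed already performed), series-resistance voltage
errors, 1/f or line noise, multi-ion pore behaviour (anomalous
mole-fraction effects are impossible in a single-site GHK model, by
design), and Markov-state gating. Passing recovery tests therefore
demonstrates the correctness of the analysis chain on data satisfying
the model's assumptions, not robustness to every artifact of real
recordings.

`simulatePNLeakFamily()` produces the P/N leak-subtraction family: n
sub-sweeps whose excursions from the holding potential are scaled by
1/n (P/10 by default, delivered at -140 mV), with channel conductance
zeroed (sub-threshold assumption) and fresh noise. `pnSubtract()`
estimates the leak as sum(subs) minus (n-1) times the standing holding
current (taken from the sub-sweeps' own holding segments) and removes
it exactly for an ohmic leak. A consequence worth knowing: subtraction
*adds* noise — the corrected trace has noise SD
$\sigma\sqrt{1+n}$, not less — which the test suite verifies by Monte
Carlo against the variance algebra.

## Solutions and presets

`builtinSolutions()` catalogues the recording solutions this kind of
study uses, with integer-mM per-species totals (e.g. the high-Na^+^
pipette, 115 mM NaF + 35 mM NaCl = 150 mM Na^+^; the NMDG-background
Ca^2+^ series at 4, 10 and 20 mM; the NaCl/CaCl~2~ mole-fraction series
135/0 through 0/90). Two mole-fraction series coexist in the catalogue
(the six-point CHO series and the sparse three-point series including
the 133.7:0.9 composition); both are catalogued verbatim and no attempt
is made to reconcile their differing totals. `channelPreset()` encodes
the published selectivities and midpoints of CavMr (G240A and D7M),
NavPp (T232A) and the NavPp-Mr filter swap.

## The analysis pipeline

The full chain is: simulate (or read) sweeps, P/N-subtract, extract
E~rev~ from the ramp, convert to a per-cell permeability ratio, and
aggregate as mean ± SEM with n (`permeabilityTable()`; ratios are
computed per cell and then averaged, matching the per-cell-n convention
of published tables, not ratio-of-mean-E~rev~). Monovalent ratios
measured against Ca^2+^ (K^+^ pipette vs Ca^2+^ bath, the convention
for highly Ca^2+^-selective channels) are computed with the two-ion
expression and inverted, and the row is footnoted.

Reversal extraction (`extractErevFromRamp()`) interpolates the command
voltage at the zero-current sign change — exact for clean traces, and
the ramp is linear in time, so command-voltage interpolation and time
interpolation coincide. For noisy traces the sample-level sign-change
count is essentially never exactly one (noise flips signs wherever the
true current is near zero), so two tools are provided: a `vWindow`
restricting the search to the voltage range where the channel conducts,
and `method = "linfit"`, which fits a local least-squares line to the
raw samples within ±4 mV of the smoothed minimum-|I| point and returns
its zero. `runPipeline()` uses the exact crossing for noiseless runs
and linfit otherwise. The ±4 mV default trades noise averaging (tens of
samples at usual sampling rates) against local curvature of the I-V
relation; it is configurable.

`moleFractionSummary()` normalizes peak inward currents across a bath
series (maximum = 1) and issues a monotonicity verdict: an anomalous
mole-fraction effect is declared only if an interior composition sits
below both neighbours by more than a tolerance, which defaults to twice
the estimated noise SD of the normalized amplitudes (zero for noiseless
traces) so that the qualitative claim is testable.

## Filter-motif bookkeeping

`FilterSequence` objects carry the seven pore-loop residues with local
1-7 numbering and the parent offset (CavMr: 183-TLEGWVD-189, so Thr183
is Thr1 and Asp189 is Asp7). Mutant nomenclature (`applyMutation()`)
uses local numbering by default; full-protein codes are accepted only
with `numbering = "parent"`, because mixing the two conventions
silently is the classic source of off-by-window errors.
`chargeCount()` counts aspartates and total acidic residues (D + E) per
subunit and per tetramer — reproducing, for example, net charges of 8
for the CavMr assembly versus 12 for CavAb-type engineered filters —
and accepts four distinct filters for heteromeric (mammalian-Cav-like)
assemblies. Only D and E are counted as charged: no positively charged
residues occur in these filters, and histidine is left neutral.
`frequencyMatrix()` tabulates per-position amino-acid frequencies
across a filter set. The package does not build alignments or trees;
parent sequences come in via FASTA (`readFilterFasta()`) with an
explicit window offset.

## Numerical choices

* GHK flux at |zVF/RT| < 1e-4 switches to the series
  $u/(1-e^{-u}) = 1 + u/2 + u^2/12 + O(u^4)$, avoiding catastrophic
  cancellation at the removable V = 0 singularity; the two branches
  agree to better than 1e-9 of the current scale at the boundary
  (tested).
* The inverse expressions use the exact factorization by $(1+a)$
  instead of a numeric threshold around E~rev~ = 0.
* Degenerate conditions (vanishing divalent or test-ion flux terms at
  the measured E~rev~) raise errors naming the vanishing term rather
  than returning infinities.
* Root-finding is plain `uniroot` on a guaranteed sign change;
  monotonicity of the GHK sum makes bracketing sufficient.

## Problem sizes

The test suite and acceptance script run on deliberately compact
problems: tail protocols with 19 prepulses at 10 kHz sampling
(~220 ms sweeps), ramps of 200-250 ms, P/10 families of 11 sweeps,
20-instance random round-trip and recovery sweeps, and Monte Carlo
studies of 25-100 seeds for the noise-sensitivity checks. These sizes
keep the full validation in the minutes range on one core while leaving
every estimator's behaviour (bias, spread, convergence) measurable.

## Known limitations

* Concentrations stand in for activities; no ionic-strength or
  junction-potential corrections (deliberate, for fidelity to the
  standard analysis).
* The single-site GHK model cannot produce anomalous mole-fraction
  effects or Ca^2+^ block; the block is available only as a
  phenomenological conductance factor.
* Mixed divalents (Ca^2+^ and Sr^2+^ simultaneously) are supported by
  the forward model, but the inverse expressions treat one divalent at
  a time, as the published analyses do.
* Gating kinetics in the presets are illustrative, not fitted to data.
* The averaged activation curve is fitted (the convention of the
  analyses this package follows); per-cell fitting can be done by
  calling `fitBoltzmann()` per cell and averaging parameters, but it is
  not the default path.

## A compact worked example

```{r example, eval = FALSE}
pip <- builtinSolutions("high-Na pipette")
bath <- builtinSolutions("ca10-nmdg")

# forward model at the published CavMr selectivity, then invert
er <- reversalPotential(permeabilitySet(c(Ca = 218)), pip, bath)
pcaPnaFromErev(er$E_rev, 150, 0, 0, 10)   # -> 218

# tail-current pipeline at the published NavPp midpoint
ch <- channelPreset("navpp-t232a")
tr <- simulateRecording(tailProtocol(seq(-140, 40, 10), tailV = -60),
                        ch, pip, builtinSolutions("na150"))
fit <- fitBoltzmann(activationCurve(extractTailAmplitudes(tr, -60)))
vHalf(fit$params)                          # -> -17.11
```
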