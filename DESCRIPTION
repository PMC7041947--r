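Package: ionperm
Title: GHK Permeability and Gating Analysis for Prokaryotic Voltage-Gated Channels
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the ion selectivity and voltage-dependent
    gating of homotetrameric prokaryotic channels (BacNav-family channels such
    as the calcium-selective CavMr and the sodium-selective NavPp) from
    whole-cell voltage-clamp recordings. Implements the
    Goldman-Hodgkin-Katz (GHK) flux model for mixed monovalent/divalent
    solutions, bi-ionic reversal-potential solving, the zero-current
    expressions that convert reversal potentials into permeability ratios
    (P_Ca/P_Na, P_M/P_Na), Boltzmann activation analysis of deactivation tail
    currents, P/N leak subtraction, Nernst-slope regression, mole-fraction
    summaries, and selectivity-filter sequence bookkeeping (local 1-7
    numbering, mutant nomenclature, charge accounting, per-position frequency
    matrices). A synthetic whole-cell recording generator reproduces the
    voltage protocols and solution series used in this kind of study so that
    every analysis stage can be exercised and validated without laboratory
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    Biostrings,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
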