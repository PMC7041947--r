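test_that("GHK current vanishes at equilibrium and matches the V = 0 limit", {
  pip <- solution("symNa", c(Na = 150), "pipette")
  bat <- solution("symNa", c(Na = 150), "bath")
  expect_equal(ghkCurrent(0, permeabilitySet(c()), pip, bat), 0)

  # L'Hopital limit at V = 0: I -> P z F ([X]in - [X]out), derived by hand
  cst <- physicalConstants()
  pip2 <- solution("na", c(Na = 150), "pipette")
  bat2 <- solution("na", c(Na = 15), "bath")
  expect_equal(ghkCurrent(0, permeabilitySet(c()), pip2, bat2),
               1 * 1 * cst$F * (150 - 15), tolerance = 1e-12)
  bat3 <- solution("ca", c(Ca = 10), "bath")
  pip3 <- solution("ca", c(Ca = 2), "pipette")
  expect_equal(ghkCurrent(0, permeabilitySet(c(Ca = 1)), pip3, bat3),
               1 * 2 * cst$F * (2 - 10) + 1 * cst$F * 0, tolerance = 1e-9)

  expect_error(
    ghkCurrent(0, permeabilitySet(c()), solution("e", c(NMDG = 150), "pipette"),
               solution("e", c(Cl = 150), "bath")),
    "no permeant ion")
})

test_that("GHK current is continuous across the small-voltage series branch", {
  pip <- builtinSolutions("high-Na pipette")
  bat <- builtinSolutions("navpp-mixed-ca")
  ps <- permeabilitySet(c(Ca = 0.308))
  cst <- physicalConstants()
  vThresh <- 1e-4 * 1000 * cst$R * cst$T / cst$F  # |u| = 1e-4 boundary, mV
  iBelow <- ghkCurrent(vThresh * 0.999999, ps, pip, bat)
  iAbove <- ghkCurrent(vThresh * 1.000001, ps, pip, bat)
  scale <- abs(ghkCurrent(50, ps, pip, bat))
  expect_lt(abs(iAbove - iBelow) / scale, 1e-9)
})

test_that("GHK current is strictly increasing in V (unique reversal)", {
  set.seed(42)
  for (i in 1:10) {
    ps <- permeabilitySet(c(Ca = runif(1, 0.01, 300),
                            K = runif(1, 0, 2), Sr = runif(1, 0, 50)))
    pip <- solution("p", c(Na = runif(1, 50, 200), K = runif(1, 0, 50)),
                    "pipette")
    bat <- solution("b", c(Ca = runif(1, 1, 100), Na = runif(1, 0, 100),
                           Sr = runif(1, 0, 50)), "bath")
    v <- seq(-150, 150, by = 1)
    expect_true(all(diff(ghkCurrent(v, ps, pip, bat)) > 0))
  }
})

test_that("reversal potential reduces to Nernst for a single permeant ion", {
  pip <- solution("p", c(Na = 150), "pipette")
  bat <- solution("b", c(Na = 15), "bath")
  r <- reversalPotential(permeabilitySet(c()), pip, bat)
  expect_equal(r$E_rev, nernstPotential("Na", 15, 150), tolerance = 1e-6)
  expect_lt(abs(r$residual), 1e-4 * abs(ghkCurrent(50, permeabilitySet(c()),
                                                   pip, bat)))
})

test_that("bi-ionic reversal matches a brute-force fine-grid scan", {
  pip <- builtinSolutions("high-Na pipette")
  bat <- builtinSolutions("ca10-nmdg")
  ps <- permeabilitySet(c(Ca = 218))
  r <- reversalPotential(ps, pip, bat)
  # independent oracle: locate the sign change on a 0.001-mV grid
  v <- seq(40, 60, by = 0.001)
  i <- ghkCurrent(v, ps, pip, bat)
  k <- which(i[-length(i)] < 0 & i[-1] >= 0)
  expect_length(k, 1)
  expect_lt(abs(r$E_rev - v[k]), 0.001)
})

test_that("reversal potential increases with external Ca2+", {
  ps <- permeabilitySet(c(Ca = 218))
  pip <- builtinSolutions("high-Na pipette")
  e <- vapply(c("ca4-nmdg", "ca10-nmdg", "ca20-nmdg"), function(lab)
    reversalPotential(ps, pip, builtinSolutions(lab))$E_rev, numeric(1))
  expect_true(all(diff(e) > 0))
})

test_that("reversal solver reports a missing bracket", {
  pip <- solution("p", c(Na = 150), "pipette")
  bat <- solution("b", c(Na = 15), "bath")
  expect_error(reversalPotential(permeabilitySet(c()), pip, bat,
                                 bracket = c(100, 200)),
               "no reversal in \\[100, 200\\]")
})

test_that("divalent ratio expression has the exact balanced-flux limit", {
  # E_rev -> 0 with 100 Na in, 50 Ca out: -(100)(2) / (4 (-50)) = 1 exactly
  expect_equal(pcaPnaFromErev(0, 100, 0, 0, 50), 1)
  expect_error(pcaPnaFromErev(0, 100, 0, 0, 0), "degenerate")
})

test_that("divalent round trip recovers the generating ratio", {
  pip <- builtinSolutions("high-Na pipette")
  set.seed(7)
  for (i in 1:15) {
    truth <- 10^runif(1, -1, 2.7)  # 0.1 .. ~500
    bat <- builtinSolutions(sample(c("ca4-nmdg", "ca10-nmdg", "ca20-nmdg",
                                     "ca100"), 1))
    e <- reversalPotential(permeabilitySet(c(Ca = truth)), pip, bat)$E_rev
    rec <- pcaPnaFromErev(e, concentrationOf(pip, "Na"),
                          concentrationOf(bat, "Na"), 0,
                          concentrationOf(bat, "Ca"))
    expect_lt(abs(rec - truth) / truth, 1e-6)
  }
})

test_that("three-ion expression reduces, round-trips, and detects P_M = 0", {
  cst <- physicalConstants()
  # two-ion reduction: no Ca, Na inside only, M outside only
  e <- 12.3
  u <- e / 1000 * cst$F / (cst$R * cst$T)
  expect_equal(pmPnaFromErev(e, 0, 150, 0, 0, 0, 0, 150),
               150 * exp(u) / 150, tolerance = 1e-12)

  # round trip with all three ions present
  pip <- builtinSolutions("high-Na pipette")
  bat <- builtinSolutions("k150-ca2")
  set.seed(5)
  for (i in 1:10) {
    pca <- runif(1, 0.05, 5); pk <- runif(1, 0.01, 2)
    er <- reversalPotential(permeabilitySet(c(Ca = pca, K = pk)), pip, bat)
    rec <- pmPnaFromErev(er$E_rev, pca, 150, 0, 0, 2, 0, 150)
    expect_lt(abs(rec - pk) / pk, 1e-6)
  }

  # P_M = 0 in the forward model comes back as 0
  erf <- reversalPotential(permeabilitySet(c(Ca = 0.5)), pip, bat)
  expect_lt(abs(pmPnaFromErev(erf$E_rev, 0.5, 150, 0, 0, 2, 0, 150)), 1e-8)

  expect_error(pmPnaFromErev(0, 0.3, 150, 0, 0, 2, 0, 0), "degenerate")
})
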