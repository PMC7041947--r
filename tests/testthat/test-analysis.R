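test_that("P/N subtraction removes a synthetic linear leak", {
  proto <- rampProtocol(-100, 100)
  ch <- channelPreset("cavmr-g240a", leakConductance = 1)
  ch@tauAct <- 0; ch@tauDeact <- 0
  fam <- simulatePNLeakFamily(proto, ch, highNa, ca10)
  corrected <- pnSubtract(fam$main, fam$subs)[[1]]
  expect_true(traceMetadata(corrected)$leakSubtracted)

  # corrected trace equals the pure channel current
  chP <- channelPreset("cavmr-g240a"); chP@tauAct <- 0; chP@tauDeact <- 0
  pure <- simulateRecording(proto, chP, highNa, ca10)[[1]]
  scale <- max(abs(traceCurrent(pure)))
  expect_lt(max(abs(traceCurrent(corrected) - traceCurrent(pure))) / scale,
            1e-12)

  # leak-only family: residual leak slope of the corrected ramp is ~0
  ch0 <- channelPreset("cavmr-g240a", leakConductance = 1, gScale = 0)
  fam0 <- simulatePNLeakFamily(proto, ch0, highNa, ca10)
  cor0 <- pnSubtract(fam0$main, fam0$subs)[[1]]
  seg <- traceMetadata(cor0)$segments
  idx <- seg$startSample[seg$kind == "ramp"]:seg$endSample[seg$kind == "ramp"]
  slope <- stats::coef(stats::lm(traceCurrent(cor0)[idx] ~
                                   traceCommand(cor0)[idx]))[2]
  expect_lt(abs(slope), 1e-6)  # vs the injected 1 unit/mV

  # shape mismatch is caught
  short <- simulatePNLeakFamily(stepProtocol(0), ch0, highNa, ca10)
  expect_error(pnSubtract(fam0$main, short$subs), "length")
})

test_that("ramp reversal extraction matches the solver and flags bad windows", {
  ch <- channelPreset("cavmr-g240a"); ch@tauAct <- 0; ch@tauDeact <- 0
  tr <- simulateRecording(rampProtocol(-100, 100), ch, highNa, ca10)[[1]]
  expect_lt(abs(extractErevFromRamp(tr) -
                  reversalPotential(ch@perms, highNa, ca10)$E_rev), 0.1)

  # all-positive window: no crossing
  up <- makeStepTrace(0, 1, holdI = 1)
  up@metadata$segments$kind[2] <- "ramp"
  expect_error(extractErevFromRamp(up, rampSegment = 2), "found 0")

  # smoothing shrinks the spread of the estimate under noise: hand-built
  # linear ramp current with a known crossing at -10 mV
  mkRamp <- function(noise) {
    n <- 2001L
    v <- seq(-100, 100, length.out = n)
    i <- 5 * (v + 10) + rnorm(n, 0, noise)
    seg <- data.frame(kind = "ramp", vStart = -100, vEnd = 100,
                      duration = n / 10, startSample = 1L, endSample = n)
    new("CurrentTrace", time = 0.1 * (seq_len(n) - 1), commandV = v,
        current = i, metadata = list(sweep = 1L, segments = seg))
  }
  withr::local_seed(1)
  est <- function(width) replicate(100, {
    tryCatch(extractErevFromRamp(mkRamp(1), rampSegment = 1,
                                 smoothing = width),
             error = function(e) NA_real_)
  })
  eNarrow <- est(5); eWide <- est(51)
  expect_lt(stats::sd(eWide, na.rm = TRUE), stats::sd(eNarrow, na.rm = TRUE))
})

test_that("I-V curves normalize to their reference sweep", {
  ch <- channelPreset("cavmr-g240a")
  tr <- simulateRecording(stepProtocol(seq(-60, 20, 20)), ch, highNa,
                          builtinSolutions("na75-ca50"))
  iv <- buildIVCurve(tr, measure = "peak", normalizationRef = 0)
  expect_equal(iv$normalized[iv$V == 0], 1)
  ivs <- buildIVCurve(tr, measure = "peak", normalizationRef = 0,
                      convention = "signed")
  expect_equal(abs(ivs$normalized[ivs$V == 0]), 1)
  expect_error(buildIVCurve(tr, normalizationRef = 5), "reference")

  # larger inward currents in the high-Ca than the high-Na bath at -20 mV
  ivCa <- buildIVCurve(simulateRecording(stepProtocol(-20), ch, highNa,
                                         builtinSolutions("ca50-nmdg75")))
  ivNa <- buildIVCurve(simulateRecording(stepProtocol(-20), ch, highNa,
                                         builtinSolutions("na150")))
  expect_lt(ivCa$I, 0)
  expect_gt(abs(ivCa$I), abs(ivNa$I))

  # symmetric Na through an always-open Na channel reverses at 0 mV
  sym <- simChannelSpec(permeabilitySet(c()), boltzmannParams(-300, 8),
                        tauAct = 0, tauDeact = 0)
  pipS <- solution("s", c(Na = 150), "pipette")
  batS <- solution("s", c(Na = 150), "bath")
  ivSym <- buildIVCurve(simulateRecording(stepProtocol(c(-20, 0, 20)), sym,
                                          pipS, batS), measure = "steady")
  expect_lt(ivSym$I[ivSym$V == -20], 0)
  expect_equal(ivSym$I[ivSym$V == 0], 0)
  expect_gt(ivSym$I[ivSym$V == 20], 0)
})

test_that("permeability tables aggregate per-cell ratios with exact mean/SEM", {
  # 7 synthetic cells at P_Ca/P_Na = 218 with 1-mV reversal jitter
  withr::local_seed(14)
  eTrue <- reversalPotential(permeabilitySet(c(Ca = 218)), highNa, ca10)$E_rev
  rec <- data.frame(cell = 1:7, channel = "cavmr-g240a",
                    ratio = "P_Ca/P_Na", eRev = eTrue + rnorm(7, 0, 1),
                    pipette = "high-Na pipette", bath = "ca10-nmdg")
  tab <- permeabilityTable(rec)
  expect_equal(tab$n, 7)
  expect_lt(abs(tab$mean - 218) / 218, 0.10)

  # aggregation agrees with an independent one-pass oracle to 1e-12
  vals <- attr(tab, "perCell")[[1]]
  oracle <- onePassMeanSem(vals)
  expect_equal(tab$mean, oracle$mean, tolerance = 1e-12)
  expect_equal(tab$sem, oracle$sem, tolerance = 1e-12)

  # single noiseless cell: exact round trip, SEM 0, flagged
  one <- data.frame(cell = 1, channel = "x", ratio = "P_Ca/P_Na",
                    eRev = eTrue, pipette = "high-Na pipette",
                    bath = "ca10-nmdg")
  t1 <- permeabilityTable(one)
  expect_equal(t1$mean, 218, tolerance = 1e-6)
  expect_equal(t1$sem, 0)
  expect_match(t1$footnote, "single cell")

  # bookkeeping: one row per distinct (channel, ratio) pair
  both <- rbind(rec, transform(rec, channel = "navpp-t232a"))
  expect_equal(nrow(permeabilityTable(both)), 2)

  # monovalent rows need an accompanying P_Ca/P_Na
  km <- data.frame(cell = 1, channel = "n", ratio = "P_K/P_Na", eRev = -10,
                   pipette = "high-Na pipette", bath = "k150-ca2")
  expect_error(permeabilityTable(km), "pcaPna")
})

test_that("vs-Ca ratios are inverted and footnoted", {
  # K+ pipette against a Ca2+ bath: the two-ion expression gives P_Ca/P_K,
  # reported as P_K/P_Ca
  truth <- 1 / 0.0036   # P_Ca/P_K of a highly Ca-selective channel
  pipK <- builtinSolutions("high-K pipette")
  eK <- local({
    ps <- new("PermeabilitySet", ratios = c(Na = 1, K = 1, Ca = truth),
              scale = 1)
    reversalPotential(ps, pipK, ca10)$E_rev
  })
  rec <- data.frame(cell = 1, channel = "cavmr", ratio = "P_K/P_Ca",
                    eRev = eK, pipette = "high-K pipette", bath = "ca10-nmdg")
  tab <- permeabilityTable(rec)
  expect_equal(tab$mean, 0.0036, tolerance = 1e-6)
  expect_match(tab$footnote, "vs Ca")
})

test_that("reversal-vs-concentration slopes approach the Nernst prediction", {
  # near-perfect Ca selectivity: slope within 1% of RT ln10 / 2F
  ps <- permeabilitySet(c(Ca = 1e6))
  conc <- c(4, 10, 20)
  labs <- c("ca4-nmdg", "ca10-nmdg", "ca20-nmdg")
  e <- vapply(labs, function(l)
    reversalPotential(ps, highNa, builtinSolutions(l))$E_rev, numeric(1))
  fit <- erevConcentrationSlope(conc, e)
  expect_lt(abs(fit$slope - nernstSlopePerDecade(2)) / nernstSlopePerDecade(2),
            0.01)

  # exact line: r^2 = 1; subset selection honoured
  conc2 <- c(4, 10, 20, 40)
  e2 <- 30 * log10(conc2) + 5
  f2 <- erevConcentrationSlope(conc2, e2)
  expect_equal(f2$rSquared, 1)
  expect_equal(f2$slope, 30)
  f3 <- erevConcentrationSlope(conc2, e2, include = c(4, 10, 20))
  expect_equal(f3$includedConcentrations, c(4, 10, 20))
  expect_error(erevConcentrationSlope(4, 10), ">= 2")
})

test_that("mole-fraction monotonicity verdicts respond to constructed dips", {
  pairs <- list(c(135, 0), c(108, 18), c(81, 36), c(54, 54), c(27, 82),
                c(0, 90))
  mf <- generateMoleFractionSeries(channelPreset("cavmr-g240a"), pairs,
                                   stepProtocol(-20), highNa)
  s <- moleFractionSummary(mf, -20)
  expect_true(s$monotonic)
  expect_equal(max(s$table$normalized), 1)
  expect_equal(s$table$f_Ca,
               c(0, 18 / 126, 36 / 117, 0.5, 82 / 109, 1))

  # hand-built series with an interior dip of 3x the tolerance
  tol <- 0.05
  mk <- function(fCa, amp) {
    tr <- list(makeStepTrace(-20, -amp))
    attr(tr, "f_Ca") <- fCa
    tr
  }
  dipSeries <- list(mk(0, 0.6), mk(0.33, 0.6 - 3 * tol), mk(0.66, 0.8),
                    mk(1, 1))
  sd <- moleFractionSummary(dipSeries, -20, tolerance = tol)
  expect_false(sd$monotonic)
  expect_error(moleFractionSummary(dipSeries[1:2]), ">= 3")
})

test_that("noiseless end-to-end pipeline recovers random ground-truth ratios", {
  withr::local_seed(8)
  proto <- rampProtocol(-150, 100, rampDur = 250)
  for (i in 1:20) {
    truth <- 10^runif(1, -1, log10(500))
    ch <- simChannelSpec(permeabilitySet(c(Ca = truth)),
                         boltzmannParams(-51.7, 8), tauAct = 0, tauDeact = 0,
                         leakConductance = 0.3e9, seed = i)
    fam <- simulatePNLeakFamily(proto, ch, highNa, ca10)
    corr <- pnSubtract(fam$main, fam$subs)[[1]]
    e <- extractErevFromRamp(corr)
    rec <- pcaPnaFromErev(e, 150, 0, 0, 10)
    expect_lt(abs(rec - truth) / truth, 0.05)
  }
})

test_that("end-to-end recovery tolerates recording noise", {
  withr::local_seed(21)
  proto <- rampProtocol(-150, 100, rampDur = 250)
  truth <- 218
  errs <- vapply(1:25, function(s) {
    ch <- simChannelSpec(permeabilitySet(c(Ca = truth)),
                         boltzmannParams(-51.7, 8), tauAct = 0, tauDeact = 0,
                         leakConductance = 0.3e9, noiseSd = 1e6, seed = s)
    fam <- simulatePNLeakFamily(proto, ch, highNa, ca10)
    corr <- pnSubtract(fam$main, fam$subs)[[1]]
    e <- tryCatch(extractErevFromRamp(corr, smoothing = 25,
                                      vWindow = c(-51.7 - 16, 100)),
                  error = function(e) NA_real_)
    abs(pcaPnaFromErev(e, 150, 0, 0, 10) - truth) / truth
  }, numeric(1))
  expect_lt(median(errs, na.rm = TRUE), 0.25)
  expect_gt(mean(is.finite(errs)), 0.8)
})
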