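# Shared fixtures: solutions and a synthetic flat-current trace builder used
# by analysis tests that need hand-built sweeps.

highNa <- builtinSolutions("high-Na pipette")
ca10 <- builtinSolutions("ca10-nmdg")

# A minimal hold/step/hold sweep with constant current during the step,
# carrying the same metadata layout the simulator produces.
makeStepTrace <- function(stepV, stepI, holdV = -140, holdI = 0,
                          nHold = 20L, nStep = 50L, rateKHz = 10) {
  dt <- 1 / rateKHz
  cmd <- c(rep(holdV, nHold), rep(stepV, nStep), rep(holdV, nHold))
  cur <- c(rep(holdI, nHold), rep(stepI, nStep), rep(holdI, nHold))
  n <- length(cmd)
  seg <- data.frame(kind = c("hold", "step", "hold"),
                    vStart = c(holdV, stepV, holdV),
                    vEnd = c(holdV, stepV, holdV),
                    duration = c(nHold, nStep, nHold) * dt,
                    startSample = c(1L, nHold + 1L, nHold + nStep + 1L),
                    endSample = c(nHold, nHold + nStep, n))
  new("CurrentTrace", time = dt * (seq_len(n) - 1), commandV = cmd,
      current = cur,
      metadata = list(sweep = 1L, segments = seg, testSegment = 2L,
                      holdingV = holdV, sampleRateKHz = rateKHz))
}

# one-pass mean/SEM oracle, independent of stats::sd
onePassMeanSem <- function(x) {
  n <- length(x)
  s <- 0; ss <- 0
  for (v in x) { s <- s + v; ss <- ss + v * v }
  m <- s / n
  var <- if (n > 1) (ss - n * m * m) / (n - 1) else NA_real_
  list(mean = m, sem = if (n > 1) sqrt(var / n) else 0, n = n)
}
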