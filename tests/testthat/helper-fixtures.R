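# shared fixtures built in code

# a PhiTrace with prescribed pH samples and a minimal event log
makePhiTrace <- function(time, ph, events = NULL, solutions = NULL) {
  if (is.null(events)) {
    events <- data.frame(time_s = 0, solution_id = "base",
                         stringsAsFactors = FALSE)
    solutions <- list(base = solutionSpec())
  }
  flags <- character(length(ph))
  flags[!is.na(ph) & (ph < 5.5 | ph > 8.5)] <- "out_of_physiological_range"
  new("PhiTrace", time = as.numeric(time), phI = as.numeric(ph),
      flags = flags, events = events, solutions = solutions)
}

# protocol phases without going through segmentation
makePhases <- function(baseline = c(0, 300), nh4On = c(300, 900),
                       recovery = c(960, 1800), nadirPH = 6.5,
                       nadirTime = recovery[1]) {
  new("ProtocolPhases", baseline = baseline, nh4On = nh4On,
      recovery = recovery, nadirTime = nadirTime, nadirPH = nadirPH)
}

# the transport-silent buffering-measurement scenario: Na+-free bath,
# no background load, no carrier flux; only NH3/NH4+ chemistry moves pH
bufferingMeasurementSim <- function(betaITrue = 12, nh4clMM = 10,
                                    noiseSD = 0, seed = 1) {
  p <- transporterParams(vNHE = 0, vNBC = 0, jLoad = 0, kNH4 = 0,
                         betaITrue = betaITrue)
  proto <- prepulseProtocol(co2 = FALSE, nh4S = 300, washS = 0, postS = 300,
                            nh4clMM = nh4clMM)
  simulatePrepulseTrace(p, proto, noiseSD = noiseSD, seed = seed,
                        phInit = 7.1)
}

expect_rel_error <- function(est, truth, tol) {
  expect_lt(abs(est - truth) / abs(truth), tol)
}
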