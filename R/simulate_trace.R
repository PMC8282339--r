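#' Default synthetic ratio-to-pH calibration
#'
#' The fixed linear calibration used by the simulator to emit ratios and by
#' round-trip tests to recover pH: `pH = 1.0 * ratio + 5.5` over ratios
#' 0.5-3.0 (pH 6.0-8.5).
#'
#' @return a [CalibrationCurve-class].
#' @export
defaultCalibration <- function() {
  new("CalibrationCurve", slope = 1.0, intercept = 5.5,
      fitRange = c(0.5, 3.0), rSquared = 1.0)
}

#' Build an NH4+-prepulse protocol
#'
#' Event log and solution dictionary for the canonical quantitative
#' prepulse: baseline bath, NH4Cl epoch, a Na+-free and nominally
#' CO2/HCO3--free washout (the ammonium pool discharges its full acid load
#' with acid extrusion disabled), then Na+ (and, for the CO2/HCO3-
#' condition, CO2/HCO3-) readmission for the recovery phase. Setting
#' `washS = 0` gives the classic immediate washout into the baseline bath;
#' `naFreeRecovery = TRUE` keeps the recovery bath Na+-free as well.
#'
#' @param baselineS,nh4S,washS,postS phase durations, seconds.
#' @param nh4clMM NH4Cl concentration during the epoch, mM.
#' @param co2 logical, CO2/HCO3--buffered baseline/epoch/recovery solutions
#'   (22 mM HCO3-) or nominally CO2/HCO3--free throughout.
#' @param naFreeRecovery logical, Na+-free recovery bath.
#' @param phO bath pH.
#' @return list with `events` (data.frame `time_s`, `solution_id`),
#'   `solutions` (named list of [SolutionSpec-class]), `totalS`.
#' @export
prepulseProtocol <- function(baselineS = 300, nh4S = 300, washS = 180,
                             postS = 900, nh4clMM = 12, co2 = TRUE,
                             naFreeRecovery = FALSE, phO = 7.4) {
  base <- solutionSpec(co2Present = co2, phO = phO)
  nh4 <- solutionSpec(co2Present = co2, nh4clMM = nh4clMM, phO = phO)
  rec <- solutionSpec(naPresent = !naFreeRecovery, co2Present = co2,
                      phO = phO)
  if (washS > 0) {
    wash <- solutionSpec(naPresent = FALSE, co2Present = FALSE, phO = phO)
    events <- data.frame(
      time_s = c(0, baselineS, baselineS + nh4S, baselineS + nh4S + washS),
      solution_id = c("base", "nh4", "wash", "rec"),
      stringsAsFactors = FALSE)
    sols <- list(base = base, nh4 = nh4, wash = wash, rec = rec)
  } else {
    events <- data.frame(
      time_s = c(0, baselineS, baselineS + nh4S),
      solution_id = c("base", "nh4", "rec"),
      stringsAsFactors = FALSE)
    sols <- list(base = base, nh4 = nh4, rec = rec)
  }
  list(events = events, solutions = sols,
       totalS = baselineS + nh4S + washS + postS)
}

# logistic (Hill-like) transporter activation, 1 at acidic pH, 0 alkaline
.activation <- function(ph, half, hill) 1 / (1 + 10^(hill * (ph - half)))

# net transporter acid extrusion (mM/min) for a bath composition
.netFlux <- function(ph, params, naPresent, co2Present) {
  jnhe <- params@vNHE * .activation(ph, params@phHalfNHE, params@hillNHE)
  jnbc <- params@vNBC * .activation(ph, params@phHalfNBC, params@hillNBC)
  jnhe * naPresent + jnbc * naPresent * co2Present - params@jLoad
}

#' Simulate an NH4+-prepulse trace with known ground truth
#'
#' Integrates a two-state ODE for intracellular pH and the total
#' intracellular ammonium pool. NH3 equilibrates across the membrane at
#' rate `pNH3`; carrier-mediated NH4+ influx runs at `kNH4 * [NH4+]_o`
#' while bath ammonium is present and K+-channel-mediated NH4+ efflux at
#' `kNH4out * [NH4+]_i` drains the pool once bath ammonium is removed;
#' intracellular NH3/NH4+ speciation is at equilibrium. Proton balance couples these fluxes and the pH-activated
#' transporter fluxes to pH through the total buffering capacity
#' (intrinsic + CO2/HCO3- when present + the ammonium pool's own
#' buffering). The emitted trace is the inverse-calibrated ratio plus
#' Gaussian noise.
#'
#' @param params a [TransporterParams-class].
#' @param protocol a protocol list from [prepulseProtocol()].
#' @param calibration a [CalibrationCurve-class] used to emit ratios.
#' @param noiseSD Gaussian noise SD on the ratio (default 0.005).
#' @param dtS sampling cadence, seconds (default 5).
#' @param seed integer RNG seed (fixed seed gives bit-identical output).
#' @param phInit initial pH_i; `NULL` solves the baseline steady state.
#' @param constants a [BufferConstants-class].
#' @return list with `trace` ([RatioTrace-class]), `truth` (list holding
#'   `phi` the noise-free pH at the sample times, `fluxFunction(ph,
#'   naPresent, co2Present)` the true net acid extrusion in mM/min,
#'   `params`, `nadirTime`, `nadirPH`).
#' @export
simulatePrepulseTrace <- function(params, protocol = prepulseProtocol(),
                                  calibration = defaultCalibration(),
                                  noiseSD = 0.005, dtS = 5, seed = 1,
                                  phInit = NULL,
                                  constants = bufferConstants()) {
  stopifnot(is(params, "TransporterParams"))
  ev <- protocol$events
  sols <- protocol$solutions
  co2MM <- dissolvedCO2(0.05, constants)
  ln10 <- log(10)

  sol0 <- sols[[ev$solution_id[1]]]
  if (is.null(phInit)) {
    fl <- function(p) .netFlux(p, params, sol0@naPresent, sol0@co2Present)
    phInit <- if (fl(6.0) > 0 && fl(7.8) < 0)
      stats::uniroot(fl, c(6.0, 7.8), tol = 1e-10)$root else 7.2
  }

  deriv <- function(t, y, parms) {
    ph <- y[1]; N <- max(y[2], 0)
    sol <- parms$sol
    spec <- nh3Nh4Speciation(sol@phO, sol@nh4clMM, constants)
    f <- 1 / (1 + 10^(ph - constants@pkNH4))    # intracellular NH4+ fraction
    nh3i <- N * (1 - f)
    phi3 <- params@pNH3 * (spec["nh3"] - nh3i) / 60
    phi4 <- if (sol@nh4clMM > 0) params@kNH4 * spec["nh4"] / 60 else 0
    phi4out <- if (sol@nh4clMM > 0) 0 else params@kNH4out * f * N / 60
    jnet <- .netFlux(ph, params, sol@naPresent, sol@co2Present) / 60
    betaEff <- params@betaITrue +
      (if (sol@co2Present) 2.3 * co2MM * 10^(ph - constants@pkCO2) else 0) +
      ln10 * N * f * (1 - f)
    dph <- (jnet + f * phi3 - (1 - f) * phi4 + (1 - f) * phi4out) / betaEff
    dN <- phi3 + phi4 - phi4out
    list(c(unname(dph), unname(dN)))
  }

  times <- seq(0, protocol$totalS, by = dtS)
  segBounds <- c(ev$time_s, protocol$totalS)
  y <- c(phInit, 0)
  out <- NULL
  for (k in seq_len(nrow(ev))) {
    t0 <- segBounds[k]; t1 <- segBounds[k + 1]
    if (t1 <= t0) next
    segT <- unique(c(t0, times[times > t0 & times <= t1], t1))
    o <- deSolve::lsoda(y, segT, deriv,
                        parms = list(sol = sols[[ev$solution_id[k]]]),
                        rtol = 1e-8, atol = 1e-8, hmax = 1)
    if (attr(o, "istate")[1] < 0)
      stop("simulation error: integration failed")
    y <- as.numeric(o[nrow(o), 2:3])
    keep <- o[, 1] %in% times & o[, 1] > t0 | (k == 1 & o[, 1] == 0)
    out <- rbind(out, o[keep, , drop = FALSE])
  }
  out <- out[!duplicated(out[, 1]), , drop = FALSE]
  phTrue <- out[, 2]
  tOut <- out[, 1]

  set.seed(seed)
  ratioClean <- (phTrue - calibration@intercept) / calibration@slope
  ratio <- ratioClean + rnorm(length(ratioClean), 0, noiseSD)
  f440 <- rep(1, length(ratio))

  trace <- ratioTrace(tOut, f440 = f440, f495 = ratio,
                      events = ev, solutions = sols)
  sw <- tryCatch(.findNH4Switches(ev, sols), error = function(e) NULL)
  nadirI <- if (is.null(sw)) NA_integer_ else {
    washIdx <- tOut >= ev$time_s[sw$off]
    which(washIdx)[which.min(phTrue[washIdx])]
  }
  truth <- list(
    phi = phTrue,
    time = tOut,
    fluxFunction = function(ph, naPresent = TRUE, co2Present = TRUE)
      .netFlux(ph, params, naPresent, co2Present),
    params = params,
    nadirTime = if (is.na(nadirI)) NA_real_ else tOut[nadirI],
    nadirPH = if (is.na(nadirI)) NA_real_ else phTrue[nadirI])
  list(trace = trace, truth = truth)
}
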