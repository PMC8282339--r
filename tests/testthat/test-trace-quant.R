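test_that("calibration fitting: two-point line, collinearity, degeneracy", {
  cal <- fitCalibration(data.frame(ratio = c(1, 2), ph = c(6.5, 7.5)))
  expect_equal(cal@slope, 1.0)
  expect_equal(cal@intercept, 5.5)
  cal3 <- fitCalibration(data.frame(ratio = c(1, 2, 3), ph = c(6, 7, 8)))
  expect_equal(cal3@rSquared, 1.0)
  expect_error(fitCalibration(data.frame(ratio = c(1, 1), ph = c(6, 7))),
               "calibration error")
  expect_error(fitCalibration(data.frame(ratio = 1, ph = 6.5)),
               "at least 2")
  expect_warning(fitCalibration(data.frame(ratio = c(1, 2, 3),
                                           ph = c(6, 7, 6.5))),
                 "not monotone")
})

test_that("ratio-to-pH conversion flags but keeps unusual samples", {
  cal <- fitCalibration(data.frame(ratio = c(1, 2), ph = c(6.5, 7.5)))
  tr <- ratioTrace(c(0, 5, 10), f440 = c(1, 1, -1),
                   f495 = c(1.5, 5, 1.5))
  phi <- ratioToPH(tr, cal)
  expect_equal(phI(phi)[1], 7.0)           # midpoint of the two-point line
  expect_equal(phi@flags[2], "out_of_physiological_range") # ratio 5 -> pH 10.5
  expect_equal(phi@flags[3], "invalid_f440")
  expect_true(is.na(phI(phi)[3]))

  # constant ratio -> constant pH
  trc <- ratioTrace(seq(0, 50, 5), f440 = rep(2, 11), f495 = rep(3, 11))
  expect_equal(unique(phI(ratioToPH(trc, cal))), 1.5 + 5.5)

  # simulator round trip recovers the true pH within the noise SD
  sim <- simulatePrepulseTrace(transporterParams(), noiseSD = 0.003,
                               seed = 9)
  phi <- ratioToPH(sim$trace, defaultCalibration())
  expect_lt(max(abs(phI(phi) - sim$truth$phi)), 5 * 0.003)
  expect_lt(sd(phI(phi) - sim$truth$phi), 1.5 * 0.003)
})

test_that("protocol segmentation maps events and finds the nadir", {
  sols <- list(base = solutionSpec(co2Present = FALSE),
               nh4 = solutionSpec(co2Present = FALSE, nh4clMM = 10),
               rec = solutionSpec(co2Present = FALSE))
  ev <- data.frame(time_s = c(0, 300, 900),
                   solution_id = c("base", "nh4", "rec"),
                   stringsAsFactors = FALSE)
  t <- seq(0, 1800, 5)
  ph <- ifelse(t < 300, 7.2,
        ifelse(t < 900, 7.6,
               6.6 + pmin((t - 900) / 600, 1) * 0.6))
  phases <- segmentProtocol(makePhiTrace(t, ph, ev, sols))
  expect_equal(phases@baseline, c(0, 300))
  expect_equal(phases@nh4On, c(300, 900))
  expect_equal(phases@recovery[1], phases@nadirTime)
  expect_equal(phases@nadirPH, 6.6)

  # monotone rising pH after washout: no nadir
  phUp <- ifelse(t < 300, 7.2, ifelse(t < 900, 7.6, 7.6 + (t - 900) * 1e-4))
  expect_error(segmentProtocol(makePhiTrace(t, phUp, ev, sols)),
               "segmentation error")

  # simulated trace: detected nadir within one sample of the truth
  sim <- simulatePrepulseTrace(transporterParams(), noiseSD = 0, seed = 2)
  phases <- segmentProtocol(ratioToPH(sim$trace, defaultCalibration()))
  expect_lte(abs(phases@nadirTime - sim$truth$nadirTime), 5)
})

test_that("steady-state pH_i with drift QC", {
  t <- seq(0, 200, 5)
  ss <- steadyStatePH(makePhiTrace(t, rep(7.2, length(t))), c(0, 120))
  expect_equal(unname(ss["ph"]), 7.2)
  expect_equal(unname(ss["steady"]), 1)

  drift <- steadyStatePH(makePhiTrace(t, 7.2 + 0.05 * t / 200), c(0, 200))
  expect_equal(unname(drift["steady"]), 0)   # 0.05 pH drift is flagged

  expect_error(steadyStatePH(makePhiTrace(t, rep(7.2, length(t))),
                             c(0, 20)), ">= 30 s")

  sim <- simulatePrepulseTrace(transporterParams(), noiseSD = 0.005,
                               seed = 5)
  phi <- ratioToPH(sim$trace, defaultCalibration())
  ss <- steadyStatePH(phi, c(120, 290))
  truthBase <- mean(sim$truth$phi[sim$truth$time >= 120 &
                                    sim$truth$time <= 290])
  n <- sum(sim$truth$time >= 120 & sim$truth$time <= 290)
  expect_lt(abs(ss["ph"] - truthBase), 4 * 0.005 / sqrt(n))
})

test_that("intrinsic buffering estimation from NH4Cl steps", {
  # washout-step arithmetic oracle: 20 mM NH4+_i dropping to 0 over a
  # 0.4 pH step gives 50 mM/pH; construct a trace realizing it
  sols <- list(base = solutionSpec(co2Present = FALSE),
               nh4 = solutionSpec(co2Present = FALSE, nh4clMM = 10),
               rec = solutionSpec(co2Present = FALSE))
  ev <- data.frame(time_s = c(0, 300, 900),
                   solution_id = c("base", "nh4", "rec"),
                   stringsAsFactors = FALSE)
  nh3o <- unname(nh3Nh4Speciation(7.4, 10)["nh3"])
  phPre <- 7.2
  nh4Pre <- intracellularNH4(phPre, nh3o)
  phPost <- phPre - nh4Pre / 50              # beta = 50 by construction
  t <- seq(0, 1800, 5)
  ph <- ifelse(t < 300, 7.1, ifelse(t < 900, phPre,
         ifelse(t < 1000, phPost, phPost + (t - 1000) * 2e-4)))
  trace <- makePhiTrace(t, ph, ev, sols)
  phases <- segmentProtocol(trace)
  est <- estimateBetaIntrinsic(trace, phases, sols$nh4, step = "washout")
  expect_equal(est, 50, tolerance = 1e-6)

  # a CO2/HCO3--containing solution is rejected
  expect_error(estimateBetaIntrinsic(trace, phases, solutionSpec()),
               "CO2/HCO3")

  # |delta pH| below the resolvability threshold
  phFlat <- ifelse(t < 300, 7.19, ifelse(t < 900, 7.2,
             ifelse(t < 1000, 7.15, 7.15 + (t - 1000) * 1e-5)))
  trFlat <- makePhiTrace(t, phFlat, ev, sols)
  expect_error(estimateBetaIntrinsic(trFlat, segmentProtocol(trFlat),
                                     sols$nh4, step = "washout"),
               "below threshold")

  # simulator oracle: known beta_i = 25 recovered within 10% from a
  # standard CO2/HCO3--free prepulse
  sim <- simulatePrepulseTrace(transporterParams(betaITrue = 25),
                               prepulseProtocol(co2 = FALSE), noiseSD = 0,
                               seed = 3)
  phi <- ratioToPH(sim$trace, defaultCalibration())
  est <- estimateBetaIntrinsic(phi, segmentProtocol(phi),
                               sim$trace@solutions$nh4)
  expect_rel_error(est, 25, 0.10)
})

test_that("flux curve arithmetic and the acid-range rule", {
  # constant beta_total 40: pH 6.50 -> 6.52 over one 30-s window = 1.6 mM/min
  sols <- list(base = solutionSpec(co2Present = FALSE),
               nh4 = solutionSpec(co2Present = FALSE, nh4clMM = 10),
               rec = solutionSpec(co2Present = FALSE))
  ev <- data.frame(time_s = c(0, 300, 900),
                   solution_id = c("base", "nh4", "rec"),
                   stringsAsFactors = FALSE)
  t <- seq(0, 1230, 5)
  ph <- ifelse(t < 300, 7.2, ifelse(t < 900, 7.5,
         ifelse(t < 1200, 6.5 + (t - 900) * 0.02 / 30, 6.7)))
  trace <- makePhiTrace(t, ph, ev, sols)
  phases <- segmentProtocol(trace)
  fc <- fluxCurve(trace, phases, bufferingModel(40, co2Present = FALSE,
                                                co2MM = 0))
  expect_equal(fc@intervals$j_mM_per_min[1], 40 * 0.02 * 2, tolerance = 1e-9)

  # nadir 6.45: rule not triggered, nothing omitted
  ph2 <- ifelse(t < 300, 7.2, ifelse(t < 900, 7.5,
          pmin(6.45 + (t - 900) * 0.001, 7.1)))
  tr2 <- makePhiTrace(t, ph2, ev, sols)
  fc2 <- fluxCurve(tr2, segmentProtocol(tr2),
                   bufferingModel(40, co2Present = FALSE, co2MM = 0))
  expect_false(fc2@excludedPrefix)
  expect_gte(min(fc2@intervals$mean_ph_i), 6.45)

  # nadir 6.0: windows entirely below 6.4 are omitted, span preserved
  ph3 <- ifelse(t < 300, 7.2, ifelse(t < 900, 7.5,
          pmin(6.0 + (t - 900) * 0.002, 7.1)))
  tr3 <- makePhiTrace(t, ph3, ev, sols)
  fc3 <- fluxCurve(tr3, segmentProtocol(tr3),
                   bufferingModel(40, co2Present = FALSE, co2MM = 0))
  expect_true(fc3@excludedPrefix)
  expect_true(all(fc3@intervals$max_ph_i >= 6.4))
  expect_gte(diff(range(fc3@intervals$mean_ph_i)), 0.1)

  # recovery shorter than one window
  phShort <- ifelse(t < 300, 7.2, ifelse(t < 900, 7.5, 6.5))
  trS <- makePhiTrace(t[t <= 915], phShort[t <= 915], ev, sols)
  expect_error(fluxCurve(trS, segmentProtocol(trS),
                         bufferingModel(40, co2Present = FALSE, co2MM = 0)),
               "flux error")
})

test_that("flux at the 6.5-6.6 range: in-range mean, interpolation, missing", {
  mk <- function(df) new("FluxCurve",
                         intervals = transform(df, t_start = 0, t_end = 30,
                                               max_ph_i = mean_ph_i),
                         condition = "with_co2")
  one <- mk(data.frame(mean_ph_i = c(6.45, 6.55, 6.65),
                       j_mM_per_min = c(2, 1.5, 1)))
  expect_equal(fluxAtRange(one), 1.5)

  # no in-range window: linear interpolation at the midpoint 6.55
  # between (6.40, 2.0) and (6.70, 0.8) -> 2.0 + 0.5 * (0.8 - 2.0) = 1.4
  two <- mk(data.frame(mean_ph_i = c(6.40, 6.70), j_mM_per_min = c(2, 0.8)))
  expect_equal(fluxAtRange(two), 1.4)

  high <- mk(data.frame(mean_ph_i = c(6.8, 7.0), j_mM_per_min = c(2, 1)))
  res <- fluxAtRange(high)
  expect_true(is.na(res))
  expect_match(attr(res, "reason"), "not bracketed")
})

test_that("QC gate excludes insufficient acidification", {
  t <- seq(0, 400, 5)
  trace <- makePhiTrace(t, rep(7.2, length(t)))
  ph0 <- makePhases(baseline = c(0, 300), nh4On = c(300, 310),
                    recovery = c(320, 400))
  g1 <- qcGate(trace, makePhases(nadirPH = 6.6, baseline = c(0, 300),
                                 nh4On = c(300, 310), recovery = c(320, 400)))
  expect_true(g1$included)
  g2 <- qcGate(trace, makePhases(nadirPH = 7.0, baseline = c(0, 300),
                                 nh4On = c(300, 310), recovery = c(320, 400)))
  expect_false(g2$included)
  expect_match(g2$reason, "insufficient")
  g3 <- qcGate(trace, makePhases(nadirPH = 7.19, baseline = c(0, 300),
                                 nh4On = c(300, 310), recovery = c(320, 400)),
               minAcidification = 0)
  expect_true(g3$included)
})

test_that("CO2/HCO3--dependent components and NBC monotonicity", {
  mkM <- function(cond, ph, j) new("PhiMetrics", condition = cond,
                                   steadyStatePH = ph, steadyStateSD = 0.005,
                                   baselinePH = ph, nadirPH = 6.3,
                                   betaIntrinsic = 12,
                                   betaSource = "estimated", jAtRange = j)
  same <- co2DependentComponents(mkM("with_co2", 7.3, 10),
                                 mkM("without_co2", 7.3, 10))
  expect_equal(unname(same), c(0, 0))
  expect_error(co2DependentComponents(mkM("without_co2", 7.3, 10),
                                      mkM("with_co2", 7.3, 10)), "with_co2")

  analyzePair <- function(p) {
    aW <- analyzeTrace(simulatePrepulseTrace(
      p, prepulseProtocol(co2 = TRUE), noiseSD = 0)$trace,
      defaultCalibration())
    aF <- analyzeTrace(simulatePrepulseTrace(
      p, prepulseProtocol(co2 = FALSE), noiseSD = 0)$trace,
      defaultCalibration())
    co2DependentComponents(aW$metrics, aF$metrics)
  }

  # NBC-active: delta_j matches the true NBC flux at pH 6.55 within 10%
  p <- transporterParams(vNBC = 8)
  d <- analyzePair(p)
  trueNBC <- 8 * pHflux:::.activation(6.55, 7.0, 3)
  expect_rel_error(unname(d["delta_j"]), trueNBC, 0.10)
  expect_gt(unname(d["delta_ph"]), 0)

  # NBC-null: delta_j within the noiseless tolerance of zero
  d0 <- analyzePair(transporterParams(vNBC = 0))
  expect_lt(abs(d0["delta_j"]), 0.5)

  # increasing V_NBC strictly increases the estimated delta_j
  dj <- vapply(c(2, 6, 10), function(v)
    unname(analyzePair(transporterParams(vNBC = v))["delta_j"]), numeric(1))
  expect_true(all(diff(dj) > 0))
})

test_that("window invariance: halved sampling rate changes J by < 2%", {
  p <- transporterParams()
  j <- vapply(c(5, 10), function(dt) {
    sim <- simulatePrepulseTrace(p, prepulseProtocol(co2 = TRUE),
                                 noiseSD = 0, dtS = dt)
    jAtRange(analyzeTrace(sim$trace, defaultCalibration())$metrics)
  }, numeric(1))
  expect_lt(abs(j[2] - j[1]) / j[1], 0.02)
})
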