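#' Fit a linear ratio-to-pH calibration
#'
#' Least-squares fit of `pH = slope * ratio + intercept` to high-[K+]/
#' nigericin calibration points. A non-monotone point set is accepted with
#' a warning; duplicate ratios mapping to different pH values are an error.
#'
#' @param points data.frame (or 2-column matrix) with columns `ratio`, `ph`.
#' @return a [CalibrationCurve-class].
#' @export
fitCalibration <- function(points) {
  points <- as.data.frame(points)
  if (!all(c("ratio", "ph") %in% names(points)))
    stop("calibration points need columns 'ratio' and 'ph'")
  if (nrow(points) < 2)
    stop("calibration error: need at least 2 points")
  if (sd(points$ratio) == 0)
    stop("calibration error: zero variance in ratios")
  if (anyDuplicated(points$ratio)) {
    dup <- points[duplicated(points$ratio) |
                    duplicated(points$ratio, fromLast = TRUE), ]
    if (any(tapply(dup$ph, dup$ratio, function(x) length(unique(x))) > 1))
      stop("calibration error: duplicate ratios with different pH")
  }
  ord <- order(points$ratio)
  dph <- diff(points$ph[ord])
  if (any(dph > 0) && any(dph < 0))
    warning("calibration points are not monotone in ratio")
  fit <- lm(ph ~ ratio, data = points)
  r2 <- if (sd(points$ph) == 0) 1 else summary(fit)$r.squared
  new("CalibrationCurve",
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      fitRange = range(points$ratio), rSquared = r2)
}

#' Convert a ratio trace to a calibrated pH trace
#'
#' Applies `pH_i(t) = slope * (F495/F440) + intercept`. Samples whose ratio
#' falls outside the calibration fit range are flagged `"extrapolated"`
#' (not dropped); samples with `F440 <= 0` are flagged `"invalid_f440"` and
#' get NA pH; calibrated pH outside [5.5, 8.5] is flagged
#' `"out_of_physiological_range"`.
#'
#' @param trace a [RatioTrace-class].
#' @param curve a [CalibrationCurve-class].
#' @return a [PhiTrace-class].
#' @export
ratioToPH <- function(trace, curve) {
  stopifnot(is(trace, "RatioTrace"), is(curve, "CalibrationCurve"))
  bad440 <- trace@f440 <= 0
  ratio <- ifelse(bad440, NA_real_, trace@f495 / trace@f440)
  ph <- curve@slope * ratio + curve@intercept
  flags <- character(length(ph))
  flags[!bad440 & (ratio < curve@fitRange[1] | ratio > curve@fitRange[2])] <-
    "extrapolated"
  flags[!is.na(ph) & (ph < 5.5 | ph > 8.5)] <- "out_of_physiological_range"
  flags[bad440] <- "invalid_f440"
  new("PhiTrace", time = trace@time, phI = ph, flags = flags,
      events = trace@events, solutions = trace@solutions)
}

## internal: first event index whose solution contains/loses NH4Cl
.findNH4Switches <- function(events, solutions) {
  has <- vapply(events$solution_id,
                function(id) solutions[[id]]@nh4clMM > 0, logical(1))
  on <- which(has & !c(FALSE, utils::head(has, -1)))[1]
  if (is.na(on)) stop("protocol error: no NH4Cl-on event found")
  off <- which(!has & seq_along(has) > on)[1]
  if (is.na(off)) stop("protocol error: no NH4Cl washout event found")
  list(on = on, off = off)
}

#' Segment an NH4+-prepulse trace into protocol phases
#'
#' Baseline is the window before NH4Cl addition; the NH4Cl epoch runs from
#' addition to washout; the acid nadir is the pH_i minimum after washout;
#' recovery runs from the nadir until pH_i plateaus (slope below
#' `plateauTol` pH/s over 60 s) or the next solution switch, whichever
#' comes first.
#'
#' @param trace a [PhiTrace-class] carrying its event log.
#' @param plateauTol plateau slope tolerance, pH/s (default 1e-4).
#' @param minDip minimum post-washout acidification below the pH at washout
#'   for a nadir to be accepted (default 0.02 pH).
#' @return a [ProtocolPhases-class].
#' @export
segmentProtocol <- function(trace, plateauTol = 1e-4, minDip = 0.02) {
  stopifnot(is(trace, "PhiTrace"))
  ev <- trace@events
  sw <- .findNH4Switches(ev, trace@solutions)
  tOn <- ev$time_s[sw$on]; tOff <- ev$time_s[sw$off]

  post <- which(trace@time >= tOff & !is.na(trace@phI))
  if (length(post) < 3) stop("segmentation error: no post-washout samples")
  pre <- which(trace@time < tOff & !is.na(trace@phI))
  phRef <- if (length(pre)) trace@phI[pre[length(pre)]] else
    trace@phI[post[1]]
  iNadir <- post[which.min(trace@phI[post])]
  if (phRef - trace@phI[iNadir] < minDip)
    stop("segmentation error: no post-washout acidification nadir")
  tNadir <- trace@time[iNadir]

  # optional windows: Na+-free wash and CO2 switch between washout and
  # the next solution change
  naFree <- NULL; co2Switch <- NULL
  washSol <- trace@solutions[[ev$solution_id[sw$off]]]
  tAfterOff <- ev$time_s[ev$time_s > tOff]
  tReadmit <- if (length(tAfterOff)) min(tAfterOff) else max(trace@time)
  if (!washSol@naPresent) naFree <- c(tOff, tReadmit)
  preSol <- trace@solutions[[ev$solution_id[sw$on]]]
  if (washSol@co2Present != preSol@co2Present) co2Switch <- c(tOff, tReadmit)

  # when the apparent nadir sits within a few samples of a following
  # solution switch (readmission), recovery begins at that switch: the
  # residual decline belongs to the washout phase
  dt <- stats::median(diff(trace@time))
  tNext <- ev$time_s[ev$time_s > tNadir]
  if (length(tNext) && min(tNext) - tNadir <= 3 * dt) {
    tNadir <- min(tNext)
    after <- post[trace@time[post] >= tNadir]
    iNadir <- after[1]
    tNadir <- trace@time[iNadir]
  }

  # recovery endpoint: plateau (trailing 60 s slope below tol) or the next
  # solution event after the nadir, or the end of the trace
  tNext <- ev$time_s[ev$time_s > tNadir]
  tEndMax <- if (length(tNext)) min(tNext) else max(trace@time)
  rec <- which(trace@time >= tNadir & trace@time <= tEndMax &
                 !is.na(trace@phI))
  tEnd <- tEndMax
  if (length(rec) >= 3) {
    tt <- trace@time[rec]; pp <- trace@phI[rec]
    for (k in seq_along(tt)) {
      w <- tt >= tt[k] - 60 & tt <= tt[k]
      if (sum(w) >= 3 && tt[k] - tNadir >= 60) {
        sl <- coef(lm(pp[w] ~ tt[w]))[2]
        if (abs(sl) < plateauTol) { tEnd <- tt[k]; break }
      }
    }
  }
  new("ProtocolPhases",
      baseline = c(min(trace@time), tOn), nh4On = c(tOn, tOff),
      recovery = c(tNadir, tEnd), nadirTime = tNadir,
      nadirPH = trace@phI[iNadir], naFree = naFree, co2Switch = co2Switch)
}

#' Steady-state baseline pH_i
#'
#' Mean pH_i over a baseline window, with the window SD reported for QC; a
#' drifting window (SD above `driftSD`) is flagged non-steady.
#'
#' @param trace a [PhiTrace-class].
#' @param window `c(t0, t1)` seconds, within the baseline phase, >= 30 s.
#' @param driftSD SD threshold for the non-steady flag (default 0.01 pH).
#' @return named numeric `c(ph, sd, steady)` (`steady` is 1/0).
#' @export
steadyStatePH <- function(trace, window, driftSD = 0.01) {
  stopifnot(is(trace, "PhiTrace"), length(window) == 2)
  if (diff(window) < 30) stop("steady-state window must span >= 30 s")
  i <- trace@time >= window[1] & trace@time <= window[2] & !is.na(trace@phI)
  if (sum(i) < 2) stop("steady-state window contains < 2 samples")
  m <- mean(trace@phI[i]); s <- sd(trace@phI[i])
  c(ph = m, sd = s, steady = as.numeric(s <= driftSD))
}

#' Estimate intrinsic buffering capacity from a CO2/HCO3--free prepulse
#'
#' Uses the pH_i step on NH4Cl addition (default) or washout together with
#' the NH3-equilibration relation to compute `Delta[NH4+]_i`, and returns
#' `|Delta[NH4+]_i / Delta pH_i|`. Addition step: baseline steady state ->
#' alkaline peak within the NH4Cl epoch. Washout step: pH_i at the end of
#' the epoch -> acid nadir.
#'
#' @param trace a [PhiTrace-class] from a CO2/HCO3--free experiment.
#' @param phases a [ProtocolPhases-class].
#' @param solution the NH4Cl-containing [SolutionSpec-class].
#' @param constants a [BufferConstants-class].
#' @param step "addition" or "washout".
#' @param minDeltaPH resolvability threshold on |Delta pH| (default 0.1).
#' @return intrinsic buffering capacity, mM per pH unit.
#' @export
estimateBetaIntrinsic <- function(trace, phases, solution,
                                  constants = bufferConstants(),
                                  step = c("addition", "washout"),
                                  minDeltaPH = 0.1) {
  step <- match.arg(step)
  stopifnot(is(trace, "PhiTrace"), is(phases, "ProtocolPhases"),
            is(solution, "SolutionSpec"))
  if (solution@co2Present)
    stop("beta_i estimation requires CO2/HCO3--free conditions")
  if (solution@nh4clMM <= 0) stop("solution must contain NH4Cl")
  nh3o <- nh3Nh4Speciation(solution@phO, solution@nh4clMM, constants)["nh3"]

  epoch <- trace@time >= phases@nh4On[1] & trace@time < phases@nh4On[2] &
    !is.na(trace@phI)
  if (!any(epoch)) stop("no samples within the NH4Cl epoch")

  if (step == "addition") {
    base <- steadyStatePH(trace,
                          c(max(phases@baseline[1], phases@baseline[2] - 60),
                            phases@baseline[2]))
    phPre <- base["ph"]
    phPost <- max(trace@phI[epoch])
    nh4Pre <- 0
    nh4Post <- intracellularNH4(phPost, nh3o, constants)
  } else {
    tail60 <- trace@time >= phases@nh4On[2] - 60 & epoch
    phPre <- mean(trace@phI[tail60])
    phPost <- phases@nadirPH
    nh4Pre <- intracellularNH4(phPre, nh3o, constants)
    nh4Post <- 0
  }
  dph <- phPost - phPre
  if (abs(dph) < minDeltaPH)
    stop(sprintf("estimation error: |Delta pH| = %.3f below threshold %.3f",
                 abs(dph), minDeltaPH))
  unname(betaIntrinsicFromStep(nh4Post - nh4Pre, dph))
}

#' Net acid extrusion flux curve over the recovery phase
#'
#' Splits the recovery phase into consecutive non-overlapping windows
#' (default 30 s), fits a least-squares slope of pH_i against time in each
#' window, and computes `J = beta_total(mean pH_i) * rate` in mM/min.
#'
#' Acid-range rule: when the nadir lies below pH_i 6.4, windows lying
#' entirely below 6.4 are omitted, provided the remaining analyzed span is
#' at least 0.1 pH; otherwise the most alkaline omitted windows are
#' retained until the 0.1 pH span is preserved.
#'
#' @param trace a [PhiTrace-class].
#' @param phases a [ProtocolPhases-class].
#' @param buffering a [BufferingModel-class].
#' @param constants a [BufferConstants-class].
#' @param windowS interval length, seconds (default 30).
#' @param acidCutoff pH_i below which windows are candidates for omission
#'   (default 6.4).
#' @param minSpan minimum analyzed pH span preserved by the rule (default 0.1).
#' @param rateEstimator "ls" (least squares, default) or "theil-sen".
#' @return a [FluxCurve-class].
#' @export
fluxCurve <- function(trace, phases, buffering,
                      constants = bufferConstants(), windowS = 30,
                      acidCutoff = 6.4, minSpan = 0.1,
                      rateEstimator = c("ls", "theil-sen")) {
  rateEstimator <- match.arg(rateEstimator)
  stopifnot(is(trace, "PhiTrace"), is(phases, "ProtocolPhases"),
            is(buffering, "BufferingModel"))
  t0 <- phases@recovery[1]; t1 <- phases@recovery[2]
  if (t1 - t0 < windowS)
    stop("flux error: recovery phase shorter than one window")

  starts <- seq(t0, t1 - windowS, by = windowS)
  rows <- lapply(starts, function(ws) {
    we <- min(ws + windowS, t1)
    i <- trace@time >= ws & trace@time <= we & !is.na(trace@phI)
    if (sum(i) < 3) return(NULL)
    tt <- trace@time[i]; pp <- trace@phI[i]
    slope <- if (rateEstimator == "ls") {
      unname(coef(lm(pp ~ tt))[2])
    } else {
      ij <- utils::combn(length(tt), 2)
      stats::median((pp[ij[2, ]] - pp[ij[1, ]]) / (tt[ij[2, ]] - tt[ij[1, ]]))
    }
    mph <- mean(pp)
    data.frame(mean_ph_i = mph,
               j_mM_per_min = betaTotal(mph, buffering, constants) * slope * 60,
               t_start = ws, t_end = we, max_ph_i = max(pp))
  })
  intervals <- do.call(rbind, rows)
  if (is.null(intervals) || !nrow(intervals))
    stop("flux error: no analyzable recovery windows")

  excluded <- FALSE; reason <- ""
  if (phases@nadirPH < acidCutoff) {
    # a window is "below" the cutoff when it lies entirely below it;
    # windows straddling the cutoff stay in the analyzed set
    drop <- intervals$max_ph_i < acidCutoff
    if (any(drop)) {
      keep <- intervals[!drop, , drop = FALSE]
      spanOf <- function(df) if (nrow(df)) diff(range(df$mean_ph_i)) else 0
      if (spanOf(keep) >= minSpan) {
        intervals <- keep
        excluded <- TRUE
        reason <- sprintf("nadir %.3f < %.1f: omitted %d acidic window(s)",
                          phases@nadirPH, acidCutoff, sum(drop))
      } else {
        # retain the most alkaline omitted windows until span >= minSpan
        om <- intervals[drop, , drop = FALSE]
        om <- om[order(om$mean_ph_i, decreasing = TRUE), , drop = FALSE]
        k <- 0
        while (spanOf(rbind(keep, om[seq_len(k), , drop = FALSE])) < minSpan &&
               k < nrow(om)) k <- k + 1
        kept <- rbind(keep, om[seq_len(k), , drop = FALSE])
        if (k < nrow(om)) {
          excluded <- TRUE
          reason <- sprintf(
            "nadir %.3f < %.1f: omitted %d window(s), retained %d to keep span >= %.2f",
            phases@nadirPH, acidCutoff, nrow(om) - k, k, minSpan)
        }
        intervals <- kept[order(kept$t_start), , drop = FALSE]
      }
    }
  }
  rownames(intervals) <- NULL
  new("FluxCurve", intervals = intervals,
      condition = if (buffering@co2Present) "with_co2" else "without_co2",
      excludedPrefix = excluded, exclusionReason = reason)
}

#' Net acid extrusion at a pH_i range
#'
#' Mean J over the windows whose mean pH_i lies in the closed range
#' (default 6.5-6.6). With no in-range window, J is linearly interpolated
#' at the range midpoint between the nearest bracketing windows; when the
#' range is not bracketed the result is `NA` with a `reason` attribute.
#'
#' @param curve a [FluxCurve-class].
#' @param range closed pH_i range, default `c(6.5, 6.6)`.
#' @return J in mM/min, or NA with attribute `reason`.
#' @export
fluxAtRange <- function(curve, range = c(6.5, 6.6)) {
  stopifnot(is(curve, "FluxCurve"))
  iv <- curve@intervals
  if (!nrow(iv)) stop("empty flux curve")
  inR <- iv$mean_ph_i >= range[1] & iv$mean_ph_i <= range[2]
  if (any(inR)) return(mean(iv$j_mM_per_min[inR]))
  below <- iv[iv$mean_ph_i < range[1], , drop = FALSE]
  above <- iv[iv$mean_ph_i > range[2], , drop = FALSE]
  if (!nrow(below) || !nrow(above)) {
    out <- NA_real_
    attr(out, "reason") <- "range not bracketed by analyzed windows"
    return(out)
  }
  lo <- below[which.max(below$mean_ph_i), ]
  hi <- above[which.min(above$mean_ph_i), ]
  mid <- mean(range)
  lo$j_mM_per_min + (hi$j_mM_per_min - lo$j_mM_per_min) *
    (mid - lo$mean_ph_i) / (hi$mean_ph_i - lo$mean_ph_i)
}

#' QC gate on prepulse acidification depth
#'
#' A specimen is excluded when the NH4+-prepulse produced insufficient
#' acidification: `baseline pH_i - nadir pH_i < minAcidification`.
#'
#' @param trace a [PhiTrace-class].
#' @param phases a [ProtocolPhases-class].
#' @param minAcidification minimum required acidification, pH units
#'   (default 0.3).
#' @return list with `included` (logical) and `reason`.
#' @export
qcGate <- function(trace, phases, minAcidification = 0.3) {
  base <- steadyStatePH(trace,
                        c(max(phases@baseline[1], phases@baseline[2] - 60),
                          phases@baseline[2]))
  depth <- base["ph"] - phases@nadirPH
  if (depth < minAcidification) {
    list(included = FALSE,
         reason = sprintf("insufficient acidification: %.3f < %.3f pH",
                          depth, minAcidification))
  } else {
    list(included = TRUE, reason = "")
  }
}

#' Full per-trace analysis to PhiMetrics
#'
#' Calibrates, segments, QC-gates and quantifies one trace for one
#' condition: steady-state pH_i, intrinsic buffering (estimated from the
#' trace under CO2/HCO3--free conditions, otherwise the supplied cohort
#' default, flagged), the flux curve, and J at pH_i 6.5-6.6.
#'
#' @param trace a [RatioTrace-class].
#' @param calibration a [CalibrationCurve-class].
#' @param constants a [BufferConstants-class].
#' @param betaIntrinsicDefault cohort-level intrinsic buffering used when
#'   the condition is CO2/HCO3--containing (mM/pH).
#' @param co2MM dissolved CO2 for the with-CO2 buffering model, mM.
#' @param windowS flux window, seconds.
#' @param minAcidification QC threshold, pH units.
#' @param fluxRange pH_i range for the scalar flux readout.
#' @return list with elements `metrics` ([PhiMetrics-class]), `phases`,
#'   `fluxCurve`, `phiTrace`.
#' @export
analyzeTrace <- function(trace, calibration, constants = bufferConstants(),
                         betaIntrinsicDefault = 12, co2MM = dissolvedCO2(0.05),
                         windowS = 30, minAcidification = 0.3,
                         fluxRange = c(6.5, 6.6)) {
  phi <- ratioToPH(trace, calibration)
  phases <- segmentProtocol(phi)
  sol <- trace@solutions[[trace@events$solution_id[1]]]
  nh4sol <- trace@solutions[[
    trace@events$solution_id[.findNH4Switches(trace@events,
                                              trace@solutions)$on]]]
  co2 <- sol@co2Present
  base <- steadyStatePH(phi,
                        c(max(phases@baseline[1], phases@baseline[2] - 60),
                          phases@baseline[2]))
  gate <- qcGate(phi, phases, minAcidification)

  betaSource <- "cohort_default"
  betaI <- betaIntrinsicDefault
  if (!co2) {
    betaI <- tryCatch(
      estimateBetaIntrinsic(phi, phases, nh4sol, constants),
      error = function(e) NA_real_)
    if (is.na(betaI)) { betaI <- betaIntrinsicDefault } else {
      betaSource <- "estimated"
    }
  }

  fc <- NULL; j <- NA_real_
  if (gate$included) {
    model <- bufferingModel(betaI, co2MM = co2MM, co2Present = co2)
    fc <- fluxCurve(phi, phases, model, constants, windowS = windowS)
    j <- fluxAtRange(fc, fluxRange)
  }
  metrics <- new("PhiMetrics",
    condition = if (co2) "with_co2" else "without_co2",
    steadyStatePH = unname(base["ph"]), steadyStateSD = unname(base["sd"]),
    baselinePH = unname(base["ph"]), nadirPH = phases@nadirPH,
    betaIntrinsic = betaI, betaSource = betaSource,
    jAtRange = as.numeric(j),
    qcStatus = if (gate$included) "included" else "excluded",
    qcReason = gate$reason)
  list(metrics = metrics, phases = phases, fluxCurve = fc, phiTrace = phi)
}

#' CO2/HCO3--dependent components of pH_i regulation
#'
#' Differences between the with- and without-CO2/HCO3- conditions of the
#' same specimen: `delta_ph` in steady-state pH_i and `delta_j` in net acid
#' extrusion at pH_i 6.5-6.6. Negative deltas are permitted and reported.
#'
#' @param metricsWith,metricsWithout [PhiMetrics-class] objects from the
#'   two conditions of one specimen.
#' @return named numeric `c(delta_ph, delta_j)`.
#' @export
co2DependentComponents <- function(metricsWith, metricsWithout) {
  stopifnot(is(metricsWith, "PhiMetrics"), is(metricsWithout, "PhiMetrics"))
  if (metricsWith@condition != "with_co2" ||
      metricsWithout@condition != "without_co2")
    stop("need one with_co2 and one without_co2 PhiMetrics, in that order")
  c(delta_ph = metricsWith@steadyStatePH - metricsWithout@steadyStatePH,
    delta_j = metricsWith@jAtRange - metricsWithout@jAtRange)
}
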