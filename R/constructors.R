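#' @describeIn BufferConstants-class constructor with conventional defaults.
#' @param pkCO2,co2Solubility,pkNH4,barometricPressure,waterVaporPressure see slots.
#' @export
bufferConstants <- function(pkCO2 = 6.1, co2Solubility = 0.0307, pkNH4 = 9.03,
                            barometricPressure = 760, waterVaporPressure = 47) {
  new("BufferConstants", pkCO2 = pkCO2, co2Solubility = co2Solubility,
      pkNH4 = pkNH4, barometricPressure = barometricPressure,
      waterVaporPressure = waterVaporPressure)
}

#' @describeIn SolutionSpec-class constructor. The default is the standard
#'   CO2/HCO3--buffered bath (22 mM HCO3-, pH 7.40).
#' @param naPresent,co2Present,nh4clMM,hco3MM,phO,highKNigericin see slots.
#' @export
solutionSpec <- function(naPresent = TRUE, co2Present = TRUE, nh4clMM = 0,
                         hco3MM = if (co2Present) 22 else 0, phO = 7.4,
                         highKNigericin = FALSE) {
  new("SolutionSpec", naPresent = naPresent, co2Present = co2Present,
      nh4clMM = nh4clMM, hco3MM = hco3MM, phO = phO,
      highKNigericin = highKNigericin)
}

#' @describeIn BufferingModel-class constructor.
#' @param betaIntrinsic,co2MM,co2Present see slots.
#' @export
bufferingModel <- function(betaIntrinsic, co2MM = 1.095, co2Present = TRUE) {
  new("BufferingModel", betaIntrinsic = betaIntrinsic, co2MM = co2MM,
      co2Present = co2Present)
}

#' @describeIn RatioTrace-class constructor.
#' @param time,f440,f495 numeric vectors of equal length.
#' @param events data.frame with columns `time_s`, `solution_id`.
#' @param solutions named list of [SolutionSpec-class] objects.
#' @export
ratioTrace <- function(time, f440, f495,
                       events = data.frame(time_s = numeric(),
                                           solution_id = character()),
                       solutions = list()) {
  new("RatioTrace", time = as.numeric(time), f440 = as.numeric(f440),
      f495 = as.numeric(f495), events = events, solutions = solutions)
}

#' @describeIn TransporterParams-class constructor; defaults reproduce the
#'   qualitative NH4+-prepulse trace morphology of carcinoma organoids.
#' @param vNHE,vNBC,phHalfNHE,phHalfNBC,hillNHE,hillNBC,jLoad,pNH3,kNH4,kNH4out,betaITrue see slots.
#' @export
transporterParams <- function(vNHE = 10, vNBC = 8, phHalfNHE = 6.8,
                              phHalfNBC = 7.0, hillNHE = 3, hillNBC = 3,
                              jLoad = 1, pNH3 = 800, kNH4 = 0.075,
                              kNH4out = 1, betaITrue = 12) {
  new("TransporterParams", vNHE = vNHE, vNBC = vNBC, phHalfNHE = phHalfNHE,
      phHalfNBC = phHalfNBC, hillNHE = hillNHE, hillNBC = hillNBC,
      jLoad = jLoad, pNH3 = pNH3, kNH4 = kNH4, kNH4out = kNH4out,
      betaITrue = betaITrue)
}

#' @describeIn StratificationRule-class constructor with the published
#'   defaults (0.5/-0.5, fallback 0.3/-0.3 when a group has < 10 deaths).
#' @param zHigh,zLow,fallbackHigh,fallbackLow,minDeaths see slots.
#' @export
stratificationRule <- function(zHigh = 0.5, zLow = -0.5, fallbackHigh = 0.3,
                               fallbackLow = -0.3, minDeaths = 10) {
  new("StratificationRule", zHigh = zHigh, zLow = zLow,
      fallbackHigh = fallbackHigh, fallbackLow = fallbackLow,
      minDeaths = minDeaths)
}

#' Construct an ExpressionStudy
#'
#' Wraps a gene x sample matrix plus per-sample survival annotations in a
#' [SummarizedExperiment::SummarizedExperiment-class]-derived container.
#'
#' @param matrix numeric gene x sample matrix (rownames = gene symbols,
#'   colnames = unique sample ids).
#' @param dataset character/factor of dataset ids per sample.
#' @param time,event survival time (>= 0) and status (0/1) per sample.
#' @param subtype optional molecular subtype per sample.
#' @return an [ExpressionStudy-class].
#' @export
expressionStudy <- function(matrix, dataset, time, event, subtype = NULL) {
  cd <- S4Vectors::DataFrame(dataset = as.character(dataset),
                             time = as.numeric(time),
                             event = as.integer(event),
                             row.names = colnames(matrix))
  if (!is.null(subtype)) cd$subtype <- as.character(subtype)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = matrix), colData = cd)
  new("ExpressionStudy", se)
}

## ---- accessors ------------------------------------------------------------

#' Accessors for pHflux objects
#'
#' @param object a pHflux S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("phI", function(object) standardGeneric("phI"))

#' @rdname accessors
#' @export
setMethod("phI", "PhiTrace", function(object) object@phI)

#' @rdname accessors
#' @export
setGeneric("traceTime", function(object) standardGeneric("traceTime"))

#' @rdname accessors
#' @export
setMethod("traceTime", "PhiTrace", function(object) object@time)

#' @rdname accessors
#' @export
setMethod("traceTime", "RatioTrace", function(object) object@time)

#' @rdname accessors
#' @export
setGeneric("fluxIntervals", function(object) standardGeneric("fluxIntervals"))

#' @rdname accessors
#' @export
setMethod("fluxIntervals", "FluxCurve", function(object) object@intervals)

#' @rdname accessors
#' @export
setGeneric("qcStatus", function(object) standardGeneric("qcStatus"))

#' @rdname accessors
#' @export
setMethod("qcStatus", "PhiMetrics", function(object)
  c(status = object@qcStatus, reason = object@qcReason))

#' @rdname accessors
#' @export
setGeneric("jAtRange", function(object) standardGeneric("jAtRange"))

#' @rdname accessors
#' @export
setMethod("jAtRange", "PhiMetrics", function(object) object@jAtRange)

#' @rdname accessors
#' @export
setGeneric("steadyStatePHi", function(object) standardGeneric("steadyStatePHi"))

#' @rdname accessors
#' @export
setMethod("steadyStatePHi", "PhiMetrics", function(object) object@steadyStatePH)

#' @rdname accessors
#' @export
setGeneric("betaIntrinsicValue",
           function(object) standardGeneric("betaIntrinsicValue"))

#' @rdname accessors
#' @export
setMethod("betaIntrinsicValue", "PhiMetrics",
          function(object) object@betaIntrinsic)

#' @rdname accessors
#' @export
setGeneric("hazardRatioValue",
           function(object) standardGeneric("hazardRatioValue"))

#' @rdname accessors
#' @export
setMethod("hazardRatioValue", "SurvivalResult",
          function(object) object@hazardRatio)

#' @rdname accessors
#' @export
setGeneric("kmTable", function(object) standardGeneric("kmTable"))

#' @rdname accessors
#' @export
setMethod("kmTable", "SurvivalResult", function(object) object@km)

## ---- show methods ---------------------------------------------------------

setMethod("show", "BufferConstants", function(object) {
  cat("BufferConstants: pK(CO2/HCO3-) =", object@pkCO2,
      "| pK(NH4+/NH3) =", object@pkNH4,
      "| sCO2 =", object@co2Solubility, "mM/mmHg\n")
})

setMethod("show", "SolutionSpec", function(object) {
  cat(sprintf(
    "SolutionSpec: Na+ %s | CO2/HCO3- %s (%.0f mM HCO3-) | NH4Cl %.1f mM | pH_o %.2f%s\n",
    if (object@naPresent) "present" else "absent",
    if (object@co2Present) "present" else "absent",
    object@hco3MM, object@nh4clMM, object@phO,
    if (object@highKNigericin) " | high-K+/nigericin" else ""))
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf(
    "CalibrationCurve: pH = %.4f x ratio + %.4f (R^2 = %.4f, ratios %.3f-%.3f)\n",
    object@slope, object@intercept, object@rSquared,
    object@fitRange[1], object@fitRange[2]))
})

setMethod("show", "RatioTrace", function(object) {
  cat(sprintf("RatioTrace: %d samples over %.0f s, %d solution events\n",
              length(object@time), diff(range(object@time)),
              nrow(object@events)))
})

setMethod("show", "PhiTrace", function(object) {
  cat(sprintf("PhiTrace: %d samples, pH_i %.2f-%.2f, %d flagged\n",
              length(object@time), min(object@phI), max(object@phI),
              sum(nzchar(object@flags))))
})

setMethod("show", "ProtocolPhases", function(object) {
  cat(sprintf(
    "ProtocolPhases: baseline [%.0f, %.0f) | NH4+ [%.0f, %.0f) | nadir %.3f @ %.0f s | recovery [%.0f, %.0f]\n",
    object@baseline[1], object@baseline[2], object@nh4On[1], object@nh4On[2],
    object@nadirPH, object@nadirTime, object@recovery[1], object@recovery[2]))
})

setMethod("show", "FluxCurve", function(object) {
  cat(sprintf("FluxCurve (%s): %d intervals, pH_i %.3f-%.3f%s\n",
              object@condition, nrow(object@intervals),
              min(object@intervals$mean_ph_i), max(object@intervals$mean_ph_i),
              if (object@excludedPrefix)
                paste0(" [acid prefix omitted: ", object@exclusionReason, "]")
              else ""))
})

setMethod("show", "PhiMetrics", function(object) {
  cat(sprintf(
    "PhiMetrics (%s): steady-state pH_i %.3f | beta_i %.1f mM/pH (%s) | J(6.5-6.6) %s mM/min | QC %s%s\n",
    object@condition, object@steadyStatePH, object@betaIntrinsic,
    object@betaSource,
    if (is.na(object@jAtRange)) "NA" else sprintf("%.2f", object@jAtRange),
    object@qcStatus,
    if (nzchar(object@qcReason)) paste0(" (", object@qcReason, ")") else ""))
})

setMethod("show", "TransporterParams", function(object) {
  cat(sprintf(
    "TransporterParams: vNHE %.1f, vNBC %.1f mM/min | pH50 %.2f/%.2f | jLoad %.1f | beta_i %.1f mM/pH\n",
    object@vNHE, object@vNBC, object@phHalfNHE, object@phHalfNBC,
    object@jLoad, object@betaITrue))
})

setMethod("show", "StratificationRule", function(object) {
  cat(sprintf(
    "StratificationRule: z > %.2f vs z < %.2f (fallback %.2f/%.2f when a group has < %d deaths)\n",
    object@zHigh, object@zLow, object@fallbackHigh, object@fallbackLow,
    object@minDeaths))
})

setMethod("show", "SurvivalResult", function(object) {
  cat(sprintf(
    "SurvivalResult: n = %s | deaths = %s\n  log-rank chi2 = %.3f (p = %.3g) | Wilcoxon chi2 = %.3f (p = %.3g)\n  HR = %.3f [%.3f, %.3f]\n",
    paste(object@groupSizes, collapse = "/"),
    paste(object@groupDeaths, collapse = "/"),
    object@logrank["chi2"], object@logrank["p"],
    object@wilcoxon["chi2"], object@wilcoxon["p"],
    object@hazardRatio["hr"], object@hazardRatio["lower"],
    object@hazardRatio["upper"]))
})
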