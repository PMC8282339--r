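#' @import methods
#' @importFrom stats sd lm coef qnorm pnorm pchisq pt qt setNames aggregate
#'   complete.cases rnorm runif rbinom rexp rmultinom cor pf anova
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Physico-chemical constants for acid-base calculations
#'
#' Holds the apparent dissociation constants and gas parameters used by the
#' Henderson-Hasselbalch based helpers. Defaults are conventional values for
#' mammalian cytosol at 37 degrees C: pK(CO2/HCO3-) = 6.1, CO2 solubility
#' 0.0307 mM/mmHg, pK(NH4+/NH3) = 9.03, barometric pressure 760 mmHg, water
#' vapor pressure 47 mmHg. All are overridable.
#'
#' @slot pkCO2 apparent pK of the CO2/HCO3- buffer pair (dimensionless).
#' @slot co2Solubility CO2 solubility in mM per mmHg.
#' @slot pkNH4 pK of the NH4+/NH3 pair (dimensionless).
#' @slot barometricPressure barometric pressure in mmHg.
#' @slot waterVaporPressure water vapor pressure at 37 degrees C in mmHg.
#' @export
setClass("BufferConstants",
  representation(
    pkCO2 = "numeric", co2Solubility = "numeric", pkNH4 = "numeric",
    barometricPressure = "numeric", waterVaporPressure = "numeric"
  ),
  prototype(
    pkCO2 = 6.1, co2Solubility = 0.0307, pkNH4 = 9.03,
    barometricPressure = 760, waterVaporPressure = 47
  )
)

setValidity("BufferConstants", function(object) {
  v <- c(object@pkCO2, object@co2Solubility, object@pkNH4,
         object@barometricPressure, object@waterVaporPressure)
  if (any(!is.finite(v)) || any(v <= 0))
    return("all constants must be finite and strictly positive")
  if (object@pkCO2 >= object@pkNH4)
    return("pkCO2 must be smaller than pkNH4")
  TRUE
})

#' Bath solution composition
#'
#' Describes one experimental bath: presence of Na+, presence of the
#' CO2/HCO3- buffer, NH4Cl and HCO3- concentrations (mM), bath pH, and
#' whether the solution is a high-[K+]/nigericin calibration solution.
#'
#' @slot naPresent logical, Na+ present (absent = NMDG+ substitution).
#' @slot co2Present logical, CO2/HCO3- buffer present.
#' @slot nh4clMM NH4Cl concentration, mM.
#' @slot hco3MM HCO3- concentration, mM (0 when co2Present is FALSE).
#' @slot phO bath pH.
#' @slot highKNigericin logical, calibration solution.
#' @export
setClass("SolutionSpec",
  representation(
    naPresent = "logical", co2Present = "logical", nh4clMM = "numeric",
    hco3MM = "numeric", phO = "numeric", highKNigericin = "logical"
  ),
  prototype(
    naPresent = TRUE, co2Present = TRUE, nh4clMM = 0, hco3MM = 22,
    phO = 7.4, highKNigericin = FALSE
  )
)

setValidity("SolutionSpec", function(object) {
  if (object@nh4clMM < 0) return("nh4clMM must be >= 0")
  if (object@hco3MM < 0) return("hco3MM must be >= 0")
  if (!object@co2Present && object@hco3MM != 0)
    return("hco3MM must be 0 when co2Present is FALSE")
  TRUE
})

#' Intracellular buffering model
#'
#' Intrinsic (non-CO2/HCO3-) buffering capacity plus the dissolved CO2
#' concentration that sets the open-system CO2/HCO3- contribution
#' 2.3 x [HCO3-]i at any pHi.
#'
#' @slot betaIntrinsic intrinsic buffering capacity, mM per pH unit.
#' @slot co2MM dissolved CO2, mM.
#' @slot co2Present logical, whether the CO2/HCO3- term applies.
#' @export
setClass("BufferingModel",
  representation(betaIntrinsic = "numeric", co2MM = "numeric",
                 co2Present = "logical"),
  prototype(betaIntrinsic = 12, co2MM = 1.095, co2Present = TRUE)
)

setValidity("BufferingModel", function(object) {
  if (object@betaIntrinsic < 0) return("betaIntrinsic must be >= 0")
  if (object@co2MM < 0) return("co2MM must be >= 0")
  TRUE
})

#' Linear ratio-to-pH calibration
#'
#' @slot slope pH per ratio unit (non-zero).
#' @slot intercept pH units.
#' @slot fitRange range of ratios covered by the calibration points.
#' @slot rSquared coefficient of determination of the fit.
#' @export
setClass("CalibrationCurve",
  representation(slope = "numeric", intercept = "numeric",
                 fitRange = "numeric", rSquared = "numeric"))

setValidity("CalibrationCurve", function(object) {
  if (object@slope == 0) return("slope must be non-zero")
  if (length(object@fitRange) != 2 || diff(object@fitRange) <= 0)
    return("fitRange must be a non-degenerate (min, max) pair")
  TRUE
})

#' Background-subtracted ratiometric fluorescence trace
#'
#' Raw dual-excitation trace with the solution-switch event log and the
#' dictionary of bath compositions the events refer to.
#'
#' @slot time sample times, seconds, strictly increasing.
#' @slot f440,f495 background-subtracted fluorescence intensities.
#' @slot events data.frame with columns `time_s`, `solution_id`.
#' @slot solutions named list of [SolutionSpec-class] objects.
#' @export
setClass("RatioTrace",
  representation(time = "numeric", f440 = "numeric", f495 = "numeric",
                 events = "data.frame", solutions = "list"))

setValidity("RatioTrace", function(object) {
  n <- length(object@time)
  if (length(object@f440) != n || length(object@f495) != n)
    return("time, f440 and f495 must have equal length")
  if (n > 1 && any(diff(object@time) <= 0))
    return("time must be strictly increasing")
  if (!all(c("time_s", "solution_id") %in% names(object@events)))
    return("events must have columns time_s and solution_id")
  miss <- setdiff(object@events$solution_id, names(object@solutions))
  if (length(miss))
    return(paste("events reference undefined solutions:",
                 paste(miss, collapse = ", ")))
  TRUE
})

#' Calibrated intracellular pH trace
#'
#' @slot time sample times, seconds.
#' @slot phI calibrated intracellular pH.
#' @slot flags per-sample character flags ("" = clean; "extrapolated",
#'   "invalid_f440", "out_of_physiological_range").
#' @slot events,solutions carried over from the source [RatioTrace-class].
#' @export
setClass("PhiTrace",
  representation(time = "numeric", phI = "numeric", flags = "character",
                 events = "data.frame", solutions = "list"))

setValidity("PhiTrace", function(object) {
  n <- length(object@time)
  if (length(object@phI) != n || length(object@flags) != n)
    return("time, phI and flags must have equal length")
  if (n > 1 && any(diff(object@time) <= 0))
    return("time must be strictly increasing")
  bad <- object@phI < 5.5 | object@phI > 8.5
  if (any(bad & object@flags == "", na.rm = TRUE))
    return("pH outside [5.5, 8.5] must be flagged")
  TRUE
})

#' Segmented NH4+-prepulse protocol phases
#'
#' Windows are `c(t_start, t_end)` in seconds; optional windows are NULL.
#'
#' @slot baseline,nh4On,recovery protocol windows, seconds.
#' @slot nadirTime,nadirPH time and pH of the post-washout acid nadir.
#' @slot naFree,co2Switch optional windows.
#' @export
setClass("ProtocolPhases",
  representation(baseline = "numeric", nh4On = "numeric",
                 recovery = "numeric", nadirTime = "numeric",
                 nadirPH = "numeric", naFree = "numericOrNULL",
                 co2Switch = "numericOrNULL"),
  prototype(naFree = NULL, co2Switch = NULL))

setValidity("ProtocolPhases", function(object) {
  for (w in list(object@baseline, object@nh4On, object@recovery))
    if (length(w) != 2 || w[2] < w[1]) return("phase windows must be (t0, t1) with t1 >= t0")
  if (object@baseline[2] > object@nh4On[1] + 1e-9)
    return("baseline must precede the NH4Cl epoch")
  if (object@nh4On[2] > object@recovery[1] + 1e-9)
    return("the NH4Cl epoch must precede recovery")
  TRUE
})

#' Net acid extrusion flux curve
#'
#' Per-interval net acid extrusion J (mM/min) against the mean pHi of the
#' interval, for one experimental condition.
#'
#' @slot intervals data.frame with columns `mean_ph_i`, `j_mM_per_min`,
#'   `t_start`, `t_end`.
#' @slot condition "with_co2" or "without_co2".
#' @slot excludedPrefix logical, whether the acid-range rule removed the
#'   most acidic windows.
#' @slot exclusionReason reason string ("" when nothing was excluded).
#' @export
setClass("FluxCurve",
  representation(intervals = "data.frame", condition = "character",
                 excludedPrefix = "logical", exclusionReason = "character"),
  prototype(excludedPrefix = FALSE, exclusionReason = ""))

setValidity("FluxCurve", function(object) {
  need <- c("mean_ph_i", "j_mM_per_min", "t_start", "t_end")
  if (!all(need %in% names(object@intervals)))
    return(paste("intervals must have columns:", paste(need, collapse = ", ")))
  TRUE
})

#' Per-specimen, per-condition pH metrics
#'
#' @slot condition "with_co2" or "without_co2".
#' @slot steadyStatePH mean baseline pHi.
#' @slot steadyStateSD baseline pHi standard deviation (QC).
#' @slot baselinePH,nadirPH baseline and acid-nadir pHi.
#' @slot betaIntrinsic estimated (or supplied) intrinsic buffering, mM/pH.
#' @slot betaSource "estimated" or "cohort_default".
#' @slot jAtRange net acid extrusion at pHi 6.5-6.6, mM/min (NA = missing).
#' @slot qcStatus "included" or "excluded".
#' @slot qcReason reason for exclusion ("" when included).
#' @export
setClass("PhiMetrics",
  representation(condition = "character", steadyStatePH = "numeric",
                 steadyStateSD = "numeric", baselinePH = "numeric",
                 nadirPH = "numeric", betaIntrinsic = "numeric",
                 betaSource = "character", jAtRange = "numeric",
                 qcStatus = "character", qcReason = "character"),
  prototype(qcStatus = "included", qcReason = "", betaSource = "estimated"))

setValidity("PhiMetrics", function(object) {
  if (!object@qcStatus %in% c("included", "excluded"))
    return("qcStatus must be 'included' or 'excluded'")
  if (object@qcStatus == "excluded" && !nzchar(object@qcReason))
    return("excluded records must carry a reason")
  TRUE
})

#' Transporter and membrane parameters of the prepulse simulator
#'
#' Mechanistic ground-truth parameters: maximal Na+/H+-exchange-like and
#' Na+,HCO3--cotransport-like fluxes with logistic (Hill-like) pH
#' activation, a constant background acid load, NH3 and NH4+ membrane
#' transfer rates, and the true intrinsic buffering capacity.
#'
#' @slot vNHE,vNBC maximal transporter fluxes, mM/min.
#' @slot phHalfNHE,phHalfNBC half-activation pHi.
#' @slot hillNHE,hillNBC activation steepness (dimensionless).
#' @slot jLoad background cellular acid load, mM/min.
#' @slot pNH3 NH3 membrane equilibration rate, 1/min.
#' @slot kNH4 carrier-mediated NH4+ influx rate constant, 1/min.
#' @slot kNH4out K+-channel-mediated NH4+ efflux rate constant applied when
#'   bath ammonium is absent, 1/min.
#' @slot betaITrue true intrinsic buffering capacity, mM/pH.
#' @export
setClass("TransporterParams",
  representation(vNHE = "numeric", vNBC = "numeric", phHalfNHE = "numeric",
                 phHalfNBC = "numeric", hillNHE = "numeric",
                 hillNBC = "numeric", jLoad = "numeric", pNH3 = "numeric",
                 kNH4 = "numeric", kNH4out = "numeric",
                 betaITrue = "numeric"),
  prototype(vNHE = 10, vNBC = 8, phHalfNHE = 6.8, phHalfNBC = 7.0,
            hillNHE = 3, hillNBC = 3, jLoad = 1, pNH3 = 800,
            kNH4 = 0.075, kNH4out = 1, betaITrue = 12))

setValidity("TransporterParams", function(object) {
  rates <- c(object@vNHE, object@vNBC, object@jLoad, object@pNH3,
             object@kNH4, object@kNH4out, object@betaITrue)
  if (any(rates < 0)) return("all rates must be >= 0")
  halves <- c(object@phHalfNHE, object@phHalfNBC)
  if (any(halves < 6.0 | halves > 7.6))
    return("phHalf values must lie in [6.0, 7.6]")
  TRUE
})

#' z-score stratification rule for survival analysis
#'
#' High/low expression groups are z > zHigh and z < zLow; when either group
#' holds fewer than minDeaths deaths, the fallback thresholds are used.
#'
#' @slot zHigh,zLow primary thresholds (default 0.5 / -0.5).
#' @slot fallbackHigh,fallbackLow fallback thresholds (default 0.3 / -0.3).
#' @slot minDeaths minimum deaths per group (default 10).
#' @export
setClass("StratificationRule",
  representation(zHigh = "numeric", zLow = "numeric", fallbackHigh = "numeric",
                 fallbackLow = "numeric", minDeaths = "numeric"),
  prototype(zHigh = 0.5, zLow = -0.5, fallbackHigh = 0.3,
            fallbackLow = -0.3, minDeaths = 10))

setValidity("StratificationRule", function(object) {
  if (!(object@zLow < 0 && 0 < object@zHigh))
    return("need zLow < 0 < zHigh")
  if (abs(object@fallbackHigh) >= abs(object@zHigh) ||
      abs(object@fallbackLow) >= abs(object@zLow))
    return("fallback magnitudes must be smaller than primary magnitudes")
  TRUE
})

#' Multi-dataset expression study with survival annotations
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] whose colData must
#' carry `dataset` (factor/character), `time` (>= 0) and `event` (0/1)
#' columns; an optional `subtype` column holds assigned molecular subtypes.
#'
#' @export
setClass("ExpressionStudy", contains = "SummarizedExperiment")

setValidity("ExpressionStudy", function(object) {
  cd <- SummarizedExperiment::colData(object)
  need <- c("dataset", "time", "event")
  if (!all(need %in% names(cd)))
    return("colData must contain dataset, time and event")
  if (anyDuplicated(colnames(object)))
    return("sample ids must be unique across the combined study")
  if (any(cd$time < 0, na.rm = TRUE)) return("survival times must be >= 0")
  if (!all(cd$event %in% c(0, 1, NA))) return("event must be 0/1")
  TRUE
})

#' Result of a two-group (or k-group) survival comparison
#'
#' @slot km data.frame Kaplan-Meier curves (group, time, n_risk, n_event,
#'   n_censor, surv).
#' @slot logrank named numeric `c(chi2, df, p)` for the Mantel-Cox test.
#' @slot wilcoxon named numeric `c(chi2, df, p)` for Gehan-Breslow-Wilcoxon.
#' @slot hazardRatio named numeric `c(hr, lower, upper)` (Mantel-Haenszel;
#'   reference = low-expression group).
#' @slot thresholds named numeric, z thresholds actually applied.
#' @slot groupSizes,groupDeaths named integer vectors per group.
#' @export
setClass("SurvivalResult",
  representation(km = "data.frame", logrank = "numeric", wilcoxon = "numeric",
                 hazardRatio = "numeric", thresholds = "numeric",
                 groupSizes = "integer", groupDeaths = "integer"))

setValidity("SurvivalResult", function(object) {
  if (length(object@hazardRatio) &&
      any(object@hazardRatio <= 0, na.rm = TRUE))
    return("hazard ratio and its CI must be positive")
  TRUE
})
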