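#' Specification of a synthetic clinicopathological cohort
#'
#' Defaults emulate the published 110-patient breast cancer cohort:
#' covariate frequencies (histological type, malignancy grade, ER and HER2
#' status), age and tumor-size distributions, and binomial outcome models
#' for elevated Ki67 index and axillary lymph node metastasis with
#' configurable effect sizes. Effect defaults are the adjusted odds ratios
#' of the source cohort: OR 3.12 per 0.1 pH of CO2/HCO3--dependent steady-
#' state pH_i elevation for Ki67; OR 1.54 per 10 mM/min Na+,HCO3-
#' cotransport, OR 1.72 per NBCn1 IHC step and OR 0.60 per NHE1 IHC step
#' for node metastasis.
#'
#' @param nPatients number of patients.
#' @param histologyFreq,gradeFreq named frequency vectors (must sum to 1).
#' @param erPosFreq,her2PosFreq,ki67HighFreq,nodePosFreq marginal
#'   frequencies of ER positivity, HER2 positivity and the two outcomes.
#' @param orKi67PerPH odds ratio on Ki67-high per 1 pH unit of
#'   CO2/HCO3--dependent steady-state pH_i rise (default `3.12^10`, i.e.
#'   3.12 per 0.1 pH).
#' @param orNodePerFlux odds ratio on node metastasis per 1 mM/min of
#'   Na+,HCO3- cotransport capacity (default `1.54^0.1`, i.e. 1.54 per
#'   10 mM/min).
#' @param orNodePerNBCn1,orNodePerNHE1 odds ratios per single IHC score
#'   step (defaults 1.72 and 0.60).
#' @param deltaPhiMean,deltaPhiSD distribution of the CO2/HCO3--dependent
#'   steady-state pH_i component, pH units.
#' @param nbcFluxMean,nbcFluxSD,nheFluxMean,nheFluxSD distributions of the
#'   transport capacities at pH_i 6.5-6.6, mM/min.
#' @param noiseSD measurement noise added to the pH metrics.
#' @return a validated spec (list) for [simulateCohort()].
#' @export
cohortSpec <- function(nPatients = 110,
                       histologyFreq = c(ductal = 0.84, lobular = 0.09,
                                         mucinous = 0.05, other = 0.02),
                       gradeFreq = c(I = 0.28, II = 0.47, III = 0.20,
                                     ungraded = 0.05),
                       erPosFreq = 0.90, her2PosFreq = 0.14,
                       ki67HighFreq = 0.25, nodePosFreq = 0.37,
                       orKi67PerPH = 3.12^10,
                       orNodePerFlux = 1.54^0.1,
                       orNodePerNBCn1 = 1.72, orNodePerNHE1 = 0.60,
                       deltaPhiMean = 0.15, deltaPhiSD = 0.10,
                       nbcFluxMean = 12, nbcFluxSD = 6,
                       nheFluxMean = 8, nheFluxSD = 4,
                       noiseSD = 0.02) {
  spec <- as.list(environment())
  for (f in list(histologyFreq, gradeFreq))
    if (abs(sum(f) - 1) > 1e-8)
      stop("spec error: covariate frequencies must sum to 1")
  if (nPatients < 0) stop("spec error: nPatients must be >= 0")
  if (any(c(deltaPhiSD, nbcFluxSD, nheFluxSD, noiseSD) < 0))
    stop("spec error: SDs must be >= 0")
  structure(spec, class = "cohortSpec")
}

# intercept such that mean plogis(b0 + lp) hits the target marginal rate
.solveIntercept <- function(lp, target) {
  stats::uniroot(function(b0) mean(stats::plogis(b0 + lp)) - target,
                 c(-30, 30), tol = 1e-10)$root
}

# latent continuous value -> 6-level IHC score via standard-normal breaks
.ihcScore <- function(latent) {
  z <- (latent - mean(latent)) / sd(latent)
  as.integer(cut(z, breaks = c(-Inf, qnorm(c(0.08, 0.25, 0.5, 0.75, 0.92)),
                               Inf))) - 1L
}

#' Simulate a clinicopathological cohort with known ground truth
#'
#' Samples covariates from the spec's frequency tables, draws transport
#' capacities and CO2/HCO3--dependent pH_i components, derives 6-level IHC
#' scores from noisy versions of the transporter capacities, and draws the
#' two binary outcomes from the binomial logistic models whose
#' coefficients the spec states. Intercepts are calibrated so the marginal
#' outcome frequencies match the spec. All ground truth (linear
#' predictors, generating coefficients) is returned alongside.
#'
#' @param spec a [cohortSpec()].
#' @param seed integer RNG seed.
#' @param traces number of patients (from the top of the table) for which
#'   paired +/-CO2/HCO3- ratio traces are also simulated (default 0).
#' @return list with `patients` (data.frame, one row per patient),
#'   `truth` (generating coefficients and linear predictors) and, when
#'   requested, `traces` (per patient: list with `with_co2`, `without_co2`
#'   simulations from [simulatePrepulseTrace()]).
#' @export
simulateCohort <- function(spec = cohortSpec(), seed = 1, traces = 0) {
  stopifnot(inherits(spec, "cohortSpec"))
  set.seed(seed)
  n <- spec$nPatients
  if (n == 0) {
    return(list(patients = data.frame(), truth = list(spec = spec)))
  }

  histology <- factor(sample(names(spec$histologyFreq), n, replace = TRUE,
                             prob = spec$histologyFreq),
                      levels = names(spec$histologyFreq))
  grade <- factor(sample(names(spec$gradeFreq), n, replace = TRUE,
                         prob = spec$gradeFreq),
                  levels = names(spec$gradeFreq))
  erGroup <- factor(ifelse(runif(n) < spec$erPosFreq, "ER_positive",
                           "ER_negative"),
                    levels = c("ER_positive", "ER_negative"))
  her2 <- factor(ifelse(runif(n) < spec$her2PosFreq, "overexpressed",
                        "normal"),
                 levels = c("normal", "overexpressed"))
  investigator <- factor(sample(c("inv1", "inv2"), n, replace = TRUE))
  age <- pmin(pmax(round(rnorm(n, 64.5, 13)), 30), 92)
  tumorSize <- round(exp(rnorm(n, log(18), 0.45)))

  nbcFlux <- pmax(rnorm(n, spec$nbcFluxMean, spec$nbcFluxSD), 0)
  nheFlux <- pmax(rnorm(n, spec$nheFluxMean, spec$nheFluxSD), 0)
  deltaPhi <- rnorm(n, spec$deltaPhiMean, spec$deltaPhiSD)

  nbcn1Score <- .ihcScore(nbcFlux + rnorm(n, 0, spec$nbcFluxSD / 2))
  nhe1Score <- .ihcScore(nheFlux + rnorm(n, 0, spec$nheFluxSD / 2))

  phWithout <- 7.05 + 0.005 * (nheFlux - spec$nheFluxMean) +
    rnorm(n, 0, spec$noiseSD)
  phWith <- phWithout + deltaPhi + rnorm(n, 0, spec$noiseSD)
  jWithout <- nheFlux + rnorm(n, 0, spec$noiseSD * 10)
  jWith <- nheFlux + nbcFlux + rnorm(n, 0, spec$noiseSD * 10)

  # outcomes are generated from the *recorded* covariates (the measured
  # delta pH and flux values), matching the observational models fitted on
  # the resulting table
  deltaPhiMeas <- phWith - phWithout
  nbcFluxMeas <- jWith - jWithout
  bKi67 <- log(spec$orKi67PerPH)
  lpKi67 <- bKi67 * deltaPhiMeas
  b0Ki67 <- .solveIntercept(lpKi67, spec$ki67HighFreq)
  ki67High <- rbinom(n, 1, stats::plogis(b0Ki67 + lpKi67))

  bNode <- c(flux = log(spec$orNodePerFlux), nbcn1 = log(spec$orNodePerNBCn1),
             nhe1 = log(spec$orNodePerNHE1))
  lpNode <- bNode["flux"] * nbcFluxMeas + bNode["nbcn1"] * nbcn1Score +
    bNode["nhe1"] * nhe1Score
  b0Node <- .solveIntercept(lpNode, spec$nodePosFreq)
  nodePos <- rbinom(n, 1, stats::plogis(b0Node + lpNode))

  patients <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    age = age, tumor_size_mm = tumorSize, histology = histology,
    grade = grade, er_group = erGroup, her2 = her2,
    investigator = investigator,
    nhe1_score = nhe1Score, nbcn1_score = nbcn1Score,
    steady_ph_with_co2 = phWith, steady_ph_without_co2 = phWithout,
    delta_phi = phWith - phWithout,
    j_with_co2 = jWith, j_without_co2 = jWithout,
    nbc_flux = jWith - jWithout,
    ki67_group = factor(ifelse(ki67High == 1, "high", "low"),
                        levels = c("low", "high")),
    node_status = factor(ifelse(nodePos == 1, "positive", "negative"),
                         levels = c("negative", "positive")),
    stringsAsFactors = FALSE)

  out <- list(patients = patients,
              truth = list(spec = spec,
                           ki67 = c(intercept = b0Ki67, slope = bKi67),
                           node = c(intercept = b0Node, bNode),
                           nbcFluxTrue = nbcFlux, nheFluxTrue = nheFlux,
                           deltaPhiTrue = deltaPhi))
  if (traces > 0) {
    act655 <- function(half) .activation(6.55, half, 3)
    out$traces <- lapply(seq_len(min(traces, n)), function(i) {
      p <- transporterParams(vNHE = nheFlux[i] / act655(6.8),
                             vNBC = nbcFlux[i] / act655(7.0))
      list(with_co2 = simulatePrepulseTrace(
             p, prepulseProtocol(co2 = TRUE), seed = seed * 1000 + 2 * i),
           without_co2 = simulatePrepulseTrace(
             p, prepulseProtocol(co2 = FALSE), seed = seed * 1000 + 2 * i + 1))
    })
    names(out$traces) <- patients$patient_id[seq_along(out$traces)]
  }
  out
}
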