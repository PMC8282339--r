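#' Dissolved CO2 concentration from the gas fraction
#'
#' Applies Henry's law: `sCO2 * fCO2 * (Pbar - PH2O)`, i.e. the CO2
#' solubility times the partial pressure of CO2 in humidified gas.
#'
#' @param fractionCO2 CO2 fraction of the aeration gas, in `[0, 1]`
#'   (0.05 for 5% CO2/balance air).
#' @param constants a [BufferConstants-class].
#' @return dissolved CO2, mM.
#' @export
#' @examples
#' dissolvedCO2(0.05) # about 1.095 mM for 5% CO2 at 760 mmHg, 37 C
dissolvedCO2 <- function(fractionCO2, constants = bufferConstants()) {
  if (any(fractionCO2 < 0 | fractionCO2 > 1))
    stop("fractionCO2 must lie in [0, 1]")
  constants@co2Solubility * fractionCO2 *
    (constants@barometricPressure - constants@waterVaporPressure)
}

#' Bicarbonate concentration at a given pH
#'
#' Henderson-Hasselbalch: `[HCO3-] = [CO2] * 10^(pH - pK)`. Strictly
#' increasing in pH.
#'
#' @param ph pH.
#' @param co2MM dissolved CO2, mM (>= 0).
#' @param constants a [BufferConstants-class].
#' @return `[HCO3-]`, mM.
#' @export
bicarbonateFromPH <- function(ph, co2MM, constants = bufferConstants()) {
  if (any(co2MM < 0)) stop("co2MM must be >= 0")
  co2MM * 10^(ph - constants@pkCO2)
}

#' NH3/NH4+ speciation of total ammonium
#'
#' Splits a total ammonium concentration into NH3 and NH4+ using
#' `[NH4+]/[NH3] = 10^(pK - pH)`; the two components sum to the total.
#'
#' @param ph pH.
#' @param totalMM total ammonium (NH3 + NH4+), mM (>= 0).
#' @param constants a [BufferConstants-class].
#' @return named numeric `c(nh3, nh4)` in mM (a 2-column matrix for
#'   vector input).
#' @export
nh3Nh4Speciation <- function(ph, totalMM, constants = bufferConstants()) {
  if (any(totalMM < 0)) stop("totalMM must be >= 0")
  ratio <- 10^(constants@pkNH4 - ph) # NH4+/NH3
  nh3 <- unname(totalMM / (1 + ratio))
  nh4 <- unname(totalMM - nh3)
  if (length(nh3) == 1L) c(nh3 = nh3, nh4 = nh4) else cbind(nh3 = nh3, nh4 = nh4)
}

#' Intracellular NH4+ under NH3 membrane equilibration
#'
#' Model assumption: NH3 equilibrates freely across the plasma membrane, so
#' `[NH3]_i = [NH3]_o` and `[NH4+]_i = [NH3]_o * 10^(pK - pH_i)`. This is
#' the relation used to convert the pH step on NH4Cl addition or washout
#' into an intracellular ammonium load. The result grows as the cell
#' acidifies, since more of the equilibrated NH3 becomes protonated.
#'
#' @param phI intracellular pH.
#' @param nh3oMM extracellular NH3, mM (>= 0).
#' @param constants a [BufferConstants-class].
#' @return `[NH4+]_i`, mM.
#' @export
intracellularNH4 <- function(phI, nh3oMM, constants = bufferConstants()) {
  if (any(nh3oMM < 0)) stop("nh3oMM must be >= 0")
  nh3oMM * 10^(constants@pkNH4 - phI)
}

#' Intrinsic buffering capacity from an NH4Cl step
#'
#' `beta = |Delta[NH4+]_i / Delta pH_i|`, the change in intracellular
#' ammonium divided by the pH step it produced, measured under
#' CO2/HCO3--free conditions. The absolute value makes addition and
#' washout steps give the same magnitude.
#'
#' @param deltaNH4MM change in `[NH4+]_i`, mM.
#' @param deltaPH change in pH_i (non-zero).
#' @return buffering capacity, mM per pH unit.
#' @export
betaIntrinsicFromStep <- function(deltaNH4MM, deltaPH) {
  if (any(deltaPH == 0))
    stop("degenerate input: deltaPH must be non-zero")
  abs(deltaNH4MM / deltaPH)
}

#' CO2/HCO3- buffering capacity
#'
#' Open-system CO2/HCO3- contribution `2.3 * [HCO3-]_i`, with `[HCO3-]_i`
#' from the Henderson-Hasselbalch relation at the given pH_i.
#'
#' @param phI intracellular pH.
#' @param co2MM dissolved CO2, mM (>= 0).
#' @param constants a [BufferConstants-class].
#' @return buffering capacity, mM per pH unit.
#' @export
betaBicarbonate <- function(phI, co2MM, constants = bufferConstants()) {
  2.3 * bicarbonateFromPH(phI, co2MM, constants)
}

#' Total intracellular buffering capacity
#'
#' Intrinsic buffering plus, when the CO2/HCO3- buffer is present, the
#' pH-dependent `2.3 * [HCO3-]_i` term.
#'
#' @param phI intracellular pH.
#' @param model a [BufferingModel-class].
#' @param constants a [BufferConstants-class].
#' @return buffering capacity, mM per pH unit.
#' @export
betaTotal <- function(phI, model, constants = bufferConstants()) {
  stopifnot(is(model, "BufferingModel"))
  b <- rep(model@betaIntrinsic, length(phI))
  if (model@co2Present)
    b <- b + betaBicarbonate(phI, model@co2MM, constants)
  b
}
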