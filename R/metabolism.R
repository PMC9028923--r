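#' Glycolytic flux
#'
#' Rate of conversion of glucose to glucose-6-phosphate, the rate-limiting
#' glycolytic step.  Modeled as a small basal flux plus a glucokinase-like
#' Hill term (Hill coefficient ~1.7, half-saturation 7.5 mM), so the flux is
#' non-negative, strictly increasing and saturates at `jg6p_vmax`.
#'
#' @param G plasma glucose concentration (mM), scalar or vector, `>= 0`.
#' @param params an [alphaParams()] set.
#' @return Flux in model units (same length as `G`).
#' @examples
#' glycolyticFlux(c(0, 1, 6, 10))
#' @export
glycolyticFlux <- function(G, params = alphaParams()) {
  if (any(!is.finite(G)) || any(G < 0)) stop("glucose concentration must be finite and >= 0")
  m <- params$metabolism
  m$jg6p_basal + (m$jg6p_vmax - m$jg6p_basal) * G^m$jg6p_h / (m$jg6p_k^m$jg6p_h + G^m$jg6p_h)
}

#' Lactate production flux
#'
#' Each glucose-6-phosphate yields two pyruvate; a fraction `pL` of the
#' pyruvate (and the accompanying NADH) is diverted to lactate, reflecting the
#' alpha cell's high lactate dehydrogenase expression: `Jlac = 2 pL JG6P`.
#'
#' @param pL fraction of pyruvate diverted to lactate, in `[0, 1]`.
#' @param JG6P glycolytic flux (model units), `>= 0`.
#' @return Lactate flux in model units.
#' @examples
#' lactateFlux(0.5, 1) # 1
#' @export
lactateFlux <- function(pL, JG6P) {
  if (any(pL < 0) || any(pL > 1)) stop("pL must lie in [0, 1]")
  if (any(JG6P < 0)) stop("JG6P must be >= 0")
  2 * pL * JG6P
}

#' CO2 production flux from the respiratory-quotient split
#'
#' Total CO2 production is the sum of a glucose-oxidation part (respiratory
#' quotient 1, so `JCO2_G = JO2_G`) and an FFA-oxidation part (respiratory
#' quotient 0.7, so `JCO2_FFA = 0.7 (JO2 - JO2_G)`).  Writing CO2 production
#' in terms of oxygen consumption lets the net oxygen-consumption rate stand
#' in for the FFA supply as the model input.
#'
#' @param JO2 net oxygen-consumption rate (model units).
#' @param JO2_G oxygen consumption due to glucose oxidation; `0 <= JO2_G <= JO2`.
#' @param rq_ffa respiratory quotient of FFA oxidation (default 0.7).
#' @return A list with `JCO2`, `JCO2_G` and `JCO2_FFA` (`JCO2` is their exact sum).
#' @examples
#' co2Flux(1, 0)$JCO2 # 0.7: pure FFA oxidation
#' @export
co2Flux <- function(JO2, JO2_G, rq_ffa = 0.7) {
  if (any(JO2_G < 0) || any(JO2_G > JO2))
    stop("JO2_G must lie in [0, JO2]")
  co2_g <- JO2_G
  co2_ffa <- rq_ffa * (JO2 - JO2_G)
  list(JCO2 = co2_g + co2_ffa, JCO2_G = co2_g, JCO2_FFA = co2_ffa)
}

# Oxidative glucose flux: pyruvate oxidation capacity saturates at low
# glycolytic flux; the marginal flux at higher glucose is diverted to lactate.
oxidativeGlucoseFlux <- function(JG6P, params) {
  m <- params$metabolism
  m$jo2g_max * JG6P / (m$jo2g_k + JG6P)
}

#' Relative ATP concentration
#'
#' Dimensionless ATP level, affine in the ATP-producing fluxes (glycolytic
#' plus oxidative-glucose, on top of a constant FFA-fuelled oxidative
#' baseline) and normalized to its value at zero glucose, so `atpLevel(0)` is
#' exactly 1.  Monotone non-decreasing and saturating in glucose, and
#' independent of the amino-acid level.  The flux weights are calibrated so
#' the rise between 1 mM and 6 mM glucose is 20%.
#'
#' @inheritParams glycolyticFlux
#' @return Relative ATP (same length as `G`).
#' @examples
#' atpLevel(6) / atpLevel(1) # 1.20
#' @export
atpLevel <- function(G, params = alphaParams()) {
  m <- params$metabolism
  raw <- function(g) {
    j <- glycolyticFlux(g, params)
    m$atp_c0 + m$atp_w_gly * j + m$atp_w_ox * oxidativeGlucoseFlux(j, params)
  }
  raw(G) / raw(0)
}

#' K(ATP)-channel conductance
#'
#' Couples metabolism to membrane electrical activity: a strictly decreasing
#' Hill function of the relative ATP concentration, anchored so the
#' conductance equals `gkatp_max` at the zero-glucose ATP level (ATP = 1).
#'
#' @param ATP relative ATP concentration (dimensionless, `>= 0`).
#' @inheritParams glycolyticFlux
#' @return Conductance in nS.
#' @examples
#' katpConductance(atpLevel(c(1, 6))) # decreasing
#' @export
katpConductance <- function(ATP, params = alphaParams()) {
  if (any(ATP < 0)) stop("ATP must be >= 0")
  m <- params$metabolism
  hill <- function(a) 1 / (1 + (a / m$gkatp_k)^m$gkatp_h)
  m$gkatp_max * hill(ATP) / hill(1)
}

#' Metabolic state at a stimulus condition
#'
#' Evaluates the full metabolic component at one or more glucose levels:
#' glycolytic, lactate and CO2 fluxes (with the glucose/FFA split), oxygen
#' consumption from glucose oxidation, relative ATP and K(ATP) conductance.
#' Metabolic outputs do not depend on the amino-acid level.
#'
#' @inheritParams glycolyticFlux
#' @return A data.frame with columns `G`, `JG6P`, `pL`, `Jlac`, `JCO2`,
#'   `JCO2_G`, `JCO2_FFA`, `JO2`, `JO2_G`, `ATP`, `gKATP`.
#' @examples
#' metabolicState(c(0, 1, 6, 10))
#' @export
metabolicState <- function(G, params = alphaParams()) {
  m <- params$metabolism
  jg6p <- glycolyticFlux(G, params)
  jlac <- lactateFlux(m$pl, jg6p)
  jo2g <- oxidativeGlucoseFlux(jg6p, params)
  co2 <- co2Flux(m$jo2, jo2g, m$rq_ffa)
  atp <- atpLevel(G, params)
  data.frame(
    G = G, JG6P = jg6p, pL = m$pl, Jlac = jlac,
    JCO2 = co2$JCO2, JCO2_G = co2$JCO2_G, JCO2_FFA = co2$JCO2_FFA,
    JO2 = m$jo2, JO2_G = jo2g,
    ATP = atp, gKATP = katpConductance(atp, params)
  )
}
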