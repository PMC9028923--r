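#' Steady-state cAMP of the sAC chain
#'
#' Absolute steady-state cAMP concentration produced by the bicarbonate/sAC
#' pathway.  Lactic-acid production perturbs the Henderson-Hasselbalch
#' equilibrium: the relative bicarbonate level falls with the acid load
#' (lactate flux per unit CO2 buffer), sAC activity follows bicarbonate with
#' Michaelis-Menten kinetics, and phosphodiesterase hydrolysis balances
#' production, giving `cAMP = V_sAC(HCO3) / k_PDE`.
#'
#' @param Jlac lactate production flux (model units, `>= 0`).
#' @param JCO2 CO2 production flux (model units, `> 0`).
#' @param params an [alphaParams()] set.
#' @return Steady-state cAMP in model concentration units.
#' @export
sacCampSteadyState <- function(Jlac, JCO2, params = alphaParams()) {
  if (any(Jlac < 0) || any(JCO2 <= 0)) stop("fluxes must satisfy Jlac >= 0, JCO2 > 0")
  s <- params$signaling
  hco3 <- 1 / (1 + (Jlac / (s$hco3_q * JCO2))^s$hco3_h)
  s$sac_vmax * hco3 / (s$sac_km + hco3) / s$kpde
}

# Extremes of the sAC chain: zero acid load gives cAMPmax, a saturating acid
# load abolishes the bicarbonate drive (cAMPmin = 0 for the default chain).
campExtremes <- function(params = alphaParams()) {
  s <- params$signaling
  list(
    cAMPmax = s$sac_vmax * 1 / (s$sac_km + 1) / s$kpde,
    cAMPmin = 0
  )
}

#' Relative sAC-derived cAMP
#'
#' Maps the steady-state cAMP of the sAC chain onto `[0, 1]` via
#' `(cAMP - cAMPmin) / (cAMPmax - cAMPmin)`, where the extremes are the
#' asymptotic range of the chain (zero versus saturating acid load).  The
#' result is monotone non-increasing in the lactate flux and independent of
#' the amino-acid level, because amino acids do not enter the metabolic
#' component.
#'
#' @inheritParams sacCampSteadyState
#' @return `fcAMP_sAC` in `[0, 1]`.
#' @examples
#' m <- metabolicState(c(0, 10))
#' sacCampFraction(m$Jlac, m$JCO2) # falls with glucose
#' @export
sacCampFraction <- function(Jlac, JCO2, params = alphaParams()) {
  ex <- campExtremes(params)
  camp <- sacCampSteadyState(Jlac, JCO2, params)
  f <- (camp - ex$cAMPmin) / (ex$cAMPmax - ex$cAMPmin)
  pmin(pmax(f, 0), 1)
}

#' Autocrine tmAC-derived relative cAMP
#'
#' Glucagon co-secreted into the interstitial space binds the cell's own
#' glucagon receptors and stimulates transmembrane adenylyl cyclases.  The
#' interstitial glucagon level is proxied by the intrinsic relative secretion
#' `RGS_intrinsic`, and the fold-stimulation follows a Hill response.  With
#' the default `"percent"` interpretation of the maximal stimulation `f0`,
#'
#' `fcAMP_tmAC = 1 + (f0/100) RGS^n / (k^n + RGS^n)`
#'
#' which is 1 with no autocrine signal, rises monotonically, reaches
#' `1 + f0/200` (1.875 at defaults) at `RGS = k`, and saturates at
#' `1 + f0/100` (2.75 at defaults).  `tmac_form = "literal"` multiplies the
#' Hill term by a further factor of `RGS` and uses `f0` unscaled.
#'
#' @param RGS_intrinsic intrinsic relative glucagon secretion (`>= 0`).
#' @param params an [alphaParams()] set.
#' @return `fcAMP_tmAC`, dimensionless.
#' @examples
#' tmacCampFraction(c(0, 2.8, 100)) # 1, 1.875, ~2.75
#' @export
tmacCampFraction <- function(RGS_intrinsic, params = alphaParams()) {
  if (any(!is.finite(RGS_intrinsic)) || any(RGS_intrinsic < 0))
    stop("RGS_intrinsic must be finite and >= 0")
  s <- params$signaling
  hill <- RGS_intrinsic^s$n / (s$k^s$n + RGS_intrinsic^s$n)
  switch(s$tmac_form,
    percent = 1 + s$f0 / 100 * hill,
    literal = 1 + s$f0 * hill * RGS_intrinsic
  )
}

#' Net relative cAMP
#'
#' Combines the intrinsic (sAC) and extrinsic (autocrine tmAC) relative cAMP
#' with fixed 75%/25% weights:
#' `fcAMP = 0.75 fcAMP_sAC + 0.25 fcAMP_tmAC`.
#'
#' @param fcAMP_sAC relative sAC-derived cAMP in `[0, 1]`.
#' @param fcAMP_tmAC relative tmAC-derived cAMP (`>= 0`).
#' @param params an [alphaParams()] set.
#' @return A list with `fcAMP_intrinsic`, `fcAMP_extrinsic` and their sum `fcAMP`.
#' @examples
#' netCamp(1, 2.75)$fcAMP # 1.4375
#' @export
netCamp <- function(fcAMP_sAC, fcAMP_tmAC, params = alphaParams()) {
  s <- params$signaling
  intr <- s$w_intrinsic * fcAMP_sAC
  extr <- s$w_extrinsic * fcAMP_tmAC
  list(fcAMP_intrinsic = intr, fcAMP_extrinsic = extr, fcAMP = intr + extr)
}

#' cAMP state at a stimulus condition (intrinsic pathway)
#'
#' Convenience wrapper: evaluates the metabolic component and the sAC chain at
#' the given glucose levels.  The autocrine tmAC part requires the secretion
#' pipeline and is added by [rgsNet()].
#'
#' @param G plasma glucose (mM), scalar or vector.
#' @param params an [alphaParams()] set.
#' @return A data.frame with `G`, `cAMP`, `cAMPmin`, `cAMPmax`, `fcAMP_sAC`.
#' @export
campState <- function(G, params = alphaParams()) {
  m <- metabolicState(G, params)
  ex <- campExtremes(params)
  data.frame(
    G = G,
    cAMP = sacCampSteadyState(m$Jlac, m$JCO2, params),
    cAMPmin = ex$cAMPmin, cAMPmax = ex$cAMPmax,
    fcAMP_sAC = sacCampFraction(m$Jlac, m$JCO2, params)
  )
}
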