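#' Direct cAMP effect on glucagon secretion
#'
#' `fcAMP_GS = 1 - kcAMP_GS (1 - fcAMP)`: equal to 1 at full cAMP, 0.5 with no
#' cAMP (default coefficient 0.5), and above 1 when tmAC stimulation pushes
#' `fcAMP` beyond 1.
#'
#' @param fcAMP net relative cAMP (`>= 0`).
#' @param params an [alphaParams()] set.
#' @return Dimensionless factor.
#' @examples
#' campSecretionFactor(c(0, 1, 1.4)) # 0.5, 1.0, 1.2
#' @export
campSecretionFactor <- function(fcAMP, params = alphaParams()) {
  1 - params$secretion$kcamp_gs * (1 - fcAMP)
}

hillCurve <- function(x, km, n) x^n / (km^n + x^n)

# Channel-resolved secretion drives from a stationary trace: the microdomain
# calcium at L- and P/Q-type channels follows the instantaneous (modulated)
# channel current; exocytosis responds through steep saturating functions and
# is then time-averaged over the analysis window.
secretionComponents <- function(trace, params) {
  sc <- params$secretion
  w <- analysisWindow(trace)
  ca_l <- pmax(0, -sc$beta_md * w$ICaL_mod)
  ca_pq <- pmax(0, -sc$beta_md * w$ICaPQ_mod)
  list(
    GSL = sc$w_l * mean(hillCurve(ca_l, sc$km_l, sc$n_l)),
    GSPQ = sc$w_pq * mean(hillCurve(ca_pq, sc$km_pq, sc$n_pq)),
    GSm = sc$w_m * mean(hillCurve(w$Cac, sc$km_c, sc$n_c))
  )
}

#' Glucagon secretion rate at given modulation inputs
#'
#' Simulates a stationary membrane trace at the given K(ATP) conductance,
#' cAMP and amino-acid level, converts the channel-resolved calcium signals
#' into the three secretion components (L-type and P/Q-type microdomain
#' pathways and a bulk cytosolic pathway) and assembles the net rate
#' `GS = fcAMP_GS (GSL + GSPQ + GSm)`.
#'
#' @inheritParams simulateTrace
#' @return A list with `GS`, `GSL`, `GSPQ`, `GSm`, `fcAMP_GS` and the
#'   oscillation metrics of the underlying trace.
#' @export
glucagonSecretion <- function(gKATP, fcAMP, fAA, params = alphaParams()) {
  tr <- simulateTrace(gKATP, fcAMP, fAA, params)
  comp <- secretionComponents(tr, params)
  fgs <- campSecretionFactor(fcAMP, params)
  c(list(GS = fgs * (comp$GSL + comp$GSPQ + comp$GSm), fcAMP_GS = fgs),
    comp,
    list(metrics = oscillationMetrics(tr, params$solver$prominence)))
}

#' Relative glucagon secretion
#'
#' `RGS = GS / GSnorm`, where `GSnorm` is the secretion rate in the absence of
#' glucose and extrinsic stimuli (see [gsNorm()]).
#'
#' @param GS absolute secretion rate (model units).
#' @param GSnorm normalization constant (`> 0`).
#' @return Dimensionless RGS.
#' @export
rgs <- function(GS, GSnorm) {
  if (!is.finite(GSnorm) || GSnorm <= 0)
    stop("GSnorm must be positive; check the parameter calibration")
  GS / GSnorm
}

# Cache of GSnorm keyed by parameter hash: every condition of a sweep shares
# the same normalization run.
.gsNormCache <- new.env(parent = emptyenv())

#' Secretion normalization constant
#'
#' Glucagon secretion at zero glucose with intrinsic (sAC-derived) cAMP only
#' and no amino-acid stimulus.  By construction the intrinsic relative
#' secretion at that reference condition equals 1.  The value is cached per
#' parameter set.
#'
#' @param params an [alphaParams()] set.
#' @return `GSnorm` (model secretion units).
#' @export
gsNorm <- function(params = alphaParams()) {
  key <- paramHash(params)
  if (!is.null(.gsNormCache[[key]])) return(.gsNormCache[[key]])
  met <- metabolicState(0, params)
  f_sac <- sacCampFraction(met$Jlac, met$JCO2, params)
  fc_intr <- params$signaling$w_intrinsic * f_sac
  gs <- glucagonSecretion(met$gKATP, fc_intr, fAA = 0, params)$GS
  .gsNormCache[[key]] <- gs
  gs
}

#' Net relative glucagon secretion at a stimulus condition
#'
#' Runs the full feed-forward chain at one `(G, fAA)` condition:
#' metabolism gives `gKATP` and the lactate/CO2 fluxes; the sAC chain gives
#' `fcAMP_sAC`; an intrinsic-only secretion pass (extrinsic cAMP set to zero)
#' gives `RGS_intrinsic`, the proxy for interstitial glucagon; the autocrine
#' Hill response converts it to `fcAMP_tmAC`; the weighted sum gives the net
#' `fcAMP`; and a final secretion pass gives `RGS_net`.  The loop is evaluated
#' once, feed-forward — no fixed-point iteration.
#'
#' @param G plasma glucose concentration (mM, scalar).
#' @param fAA relative amino-acid level (scalar).
#' @param params an [alphaParams()] set.
#' @return A one-row data.frame with the metabolic, signaling and secretion
#'   fields (`G`, `fAA`, `gKATP`, `ATP`, `fcAMP_sAC`, `RGS_intrinsic`,
#'   `fcAMP_tmAC`, `fcAMP_intrinsic`, `fcAMP_extrinsic`, `fcAMP`, `GSL`,
#'   `GSPQ`, `GSm`, `GS`, `fcAMP_GS`, `RGS_net`).
#' @examples
#' \donttest{
#' rgsNet(1, 0)
#' }
#' @export
rgsNet <- function(G, fAA, params = alphaParams()) {
  stopifnot(length(G) == 1, length(fAA) == 1)
  met <- metabolicState(G, params)
  f_sac <- sacCampFraction(met$Jlac, met$JCO2, params)
  gnorm <- gsNorm(params)

  # intrinsic pass: extrinsic cAMP contribution set to zero
  fc_intr <- params$signaling$w_intrinsic * f_sac
  gs_intr <- glucagonSecretion(met$gKATP, fc_intr, fAA, params)
  rgs_intr <- rgs(gs_intr$GS, gnorm)

  # autocrine feedback and final pass
  f_tmac <- tmacCampFraction(rgs_intr, params)
  cam <- netCamp(f_sac, f_tmac, params)
  gs_net <- glucagonSecretion(met$gKATP, cam$fcAMP, fAA, params)

  data.frame(
    G = G, fAA = fAA,
    gKATP = met$gKATP, ATP = met$ATP,
    fcAMP_sAC = f_sac, RGS_intrinsic = rgs_intr, fcAMP_tmAC = f_tmac,
    fcAMP_intrinsic = cam$fcAMP_intrinsic,
    fcAMP_extrinsic = cam$fcAMP_extrinsic,
    fcAMP = cam$fcAMP,
    GSL = gs_net$GSL, GSPQ = gs_net$GSPQ, GSm = gs_net$GSm,
    GS = gs_net$GS, fcAMP_GS = gs_net$fcAMP_GS,
    RGS_net = rgs(gs_net$GS, gnorm)
  )
}
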