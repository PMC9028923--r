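#' cAMP modulation factor for calcium currents
#'
#' Indirect effect of cAMP on the voltage-gated calcium currents:
#' `fcAMP_Ca = 1 - kcAMP_Ca (1 - fcAMP)`.  Equal to 1 at full cAMP and
#' `1 - kcAMP_Ca` (0.8 at the default coefficient 0.2) with no cAMP; values of
#' `fcAMP` above 1 (tmAC stimulation) potentiate the currents.
#'
#' @param fcAMP net relative cAMP (`>= 0`).
#' @param params an [alphaParams()] set.
#' @return Dimensionless factor.
#' @examples
#' campCaFactor(c(0, 0.5, 1)) # 0.8, 0.9, 1.0
#' @export
campCaFactor <- function(fcAMP, params = alphaParams()) {
  1 - params$membrane$kcamp_ca * (1 - fcAMP)
}

#' Amino-acid (iGluR) modulation factors
#'
#' Glutamate binding to AMPA/kainate-type ionotropic glutamate receptors opens
#' cation channels permeable to Na+, K+ and Ca2+.  The whole-cell effect is
#' modeled as linear scalings of the respective current families:
#' `fAA_X = 1 + kAA_X fAA` with coefficients 0.4 (Na), 0.2 (K) and 0.16 (Ca),
#' reflecting the dominant Na+ permeability of the receptors.  Negative `fAA`
#' (hypoaminoacidemia) is allowed down to the bound keeping all factors
#' positive.
#'
#' @param fAA relative amino-acid level (0 = fasting, 1 = protein-rich meal).
#' @param params an [alphaParams()] set.
#' @return A list with `fAA_Na`, `fAA_K`, `fAA_Ca`.
#' @examples
#' aaFactors(1) # 1.4, 1.2, 1.16
#' @export
aaFactors <- function(fAA, params = alphaParams()) {
  mb <- params$membrane
  kmax <- max(mb$kaa_na, mb$kaa_k, mb$kaa_ca)
  if (any(fAA <= -1 / kmax))
    stop("fAA must exceed ", round(-1 / kmax, 3), " to keep all current factors positive")
  list(
    fAA_Na = 1 + mb$kaa_na * fAA,
    fAA_K  = 1 + mb$kaa_k * fAA,
    fAA_Ca = 1 + mb$kaa_ca * fAA
  )
}

#' Leak current
#'
#' Ohmic leak `IL = gL (V - VL)` with a constant conductance (the leak is not
#' tied to the K(ATP) conductance).
#'
#' @param V membrane potential (mV).
#' @param params an [alphaParams()] set.
#' @return Current in pA.
#' @export
leakCurrent <- function(V, params = alphaParams()) {
  params$membrane$gl * (V - params$membrane$vl)
}

# Flat parameter vector for the compiled model; order must match the enum in
# src/alphacell.c.
membraneParVector <- function(params, gKATP, fcAMP, fAA) {
  mb <- params$membrane
  f <- aaFactors(fAA, params)
  c(
    cm = mb$cm,
    gna = mb$gna, vna = mb$vna, vm_na = mb$vm_na, sm_na = mb$sm_na,
    vh_na = mb$vh_na, sh_na = mb$sh_na, tauh_na = mb$tauh_na,
    gcal = mb$gcal, vca = mb$vca, vm_cal = mb$vm_cal, sm_cal = mb$sm_cal,
    gcapq = mb$gcapq, vm_capq = mb$vm_capq, sm_capq = mb$sm_capq,
    gcat = mb$gcat, vm_cat = mb$vm_cat, sm_cat = mb$sm_cat,
    vh_cat = mb$vh_cat, sh_cat = mb$sh_cat, tauh_cat = mb$tauh_cat,
    gkdr = mb$gkdr, vk = mb$vk, vn_kdr = mb$vn_kdr, sn_kdr = mb$sn_kdr,
    taun_kdr = mb$taun_kdr,
    gka = mb$gka, va_ka = mb$va_ka, sa_ka = mb$sa_ka,
    vh_ka = mb$vh_ka, sh_ka = mb$sh_ka, tauh_ka = mb$tauh_ka,
    gkatp = gKATP, gl = mb$gl, vl = mb$vl, gsoc = mb$gsoc, vsoc = mb$vsoc,
    kin = mb$ca_kin, kout = mb$ca_kout, ca0 = mb$ca_rest,
    fca = campCaFactor(fcAMP, params) * f$fAA_Ca,
    fna = f$fAA_Na,
    fk = f$fAA_K
  )
}

# Fixed deterministic initial state (resting values near -55 mV).
membraneInitialState <- function() {
  c(V = -55, hNa = 0.7, n = 0.02, hCaT = 0.45, hKA = 0.1, Cac = 0.08)
}

#' Membrane right-hand side (reference R implementation)
#'
#' Time derivatives of the membrane state for given modulation factors.  This
#' is an exact R transcription of the compiled model used by
#' [simulateTrace()]; it is exported for inspection and testing (e.g. the
#' identity-reduction property: at `fAA = 0`, `fcAMP = 1` all modulation
#' factors are exactly 1 and every current equals its unmodulated value).
#'
#' @param t time (ms; unused, the system is autonomous).
#' @param state named numeric vector `(V, hNa, n, hCaT, hKA, Cac)`.
#' @param gKATP K(ATP) conductance (nS).
#' @param fcAMP net relative cAMP.
#' @param fAA relative amino-acid level.
#' @param params an [alphaParams()] set.
#' @return A list: derivatives vector, then a named vector of the six summed
#'   currents (`INa_AA`, `ICa_AA`, `IK_AA`, `IKATP`, `IL`, `ISOC`) and the
#'   modulated per-channel calcium currents (`ICaL_mod`, `ICaPQ_mod`,
#'   `ICaT_mod`), matching the compiled model's outputs.
#' @export
membraneRhs <- function(t, state, gKATP, fcAMP, fAA, params = alphaParams()) {
  p <- membraneParVector(params, gKATP, fcAMP, fAA)
  if (any(!is.finite(state))) stop("non-finite membrane state")
  v <- state[["V"]]; hna <- state[["hNa"]]; n <- state[["n"]]
  hcat <- state[["hCaT"]]; hka <- state[["hKA"]]; cac <- state[["Cac"]]
  act <- function(v, vh, s) 1 / (1 + exp((vh - v) / s))
  inact <- function(v, vh, s) 1 / (1 + exp((v - vh) / s))

  mna <- act(v, p[["vm_na"]], p[["sm_na"]])
  mcal <- act(v, p[["vm_cal"]], p[["sm_cal"]])
  mcapq <- act(v, p[["vm_capq"]], p[["sm_capq"]])
  mcat <- act(v, p[["vm_cat"]], p[["sm_cat"]])
  aka <- act(v, p[["va_ka"]], p[["sa_ka"]])

  ina <- p[["gna"]] * mna^3 * hna * (v - p[["vna"]])
  ical <- p[["gcal"]] * mcal^2 * (v - p[["vca"]])
  icapq <- p[["gcapq"]] * mcapq^2 * (v - p[["vca"]])
  icat <- p[["gcat"]] * mcat^3 * hcat * (v - p[["vca"]])
  ikdr <- p[["gkdr"]] * n^4 * (v - p[["vk"]])
  ika <- p[["gka"]] * aka * hka * (v - p[["vk"]])
  ikatp <- p[["gkatp"]] * (v - p[["vk"]])
  il <- p[["gl"]] * (v - p[["vl"]])
  isoc <- p[["gsoc"]] * (v - p[["vsoc"]])

  ina_aa <- p[["fna"]] * ina
  ik_aa <- p[["fk"]] * (ikdr + ika)
  ica_aa <- p[["fca"]] * (ical + icat + icapq)

  dv <- -(ina_aa + ica_aa + ik_aa + ikatp + il + isoc) / p[["cm"]]
  dhna <- (inact(v, p[["vh_na"]], p[["sh_na"]]) - hna) / p[["tauh_na"]]
  dn <- (act(v, p[["vn_kdr"]], p[["sn_kdr"]]) - n) / p[["taun_kdr"]]
  dhcat <- (inact(v, p[["vh_cat"]], p[["sh_cat"]]) - hcat) / p[["tauh_cat"]]
  dhka <- (inact(v, p[["vh_ka"]], p[["sh_ka"]]) - hka) / p[["tauh_ka"]]
  dcac <- -p[["kin"]] * ica_aa - p[["kout"]] * (cac - p[["ca0"]])

  list(
    c(dv, dhna, dn, dhcat, dhka, dcac),
    c(INa_AA = ina_aa, ICa_AA = ica_aa, IK_AA = ik_aa, IKATP = ikatp,
      IL = il, ISOC = isoc,
      ICaL_mod = p[["fca"]] * ical, ICaPQ_mod = p[["fca"]] * icapq,
      ICaT_mod = p[["fca"]] * icat)
  )
}

#' Simulate a membrane-potential trace
#'
#' Integrates the membrane model with lsoda (relative tolerance 1e-8,
#' absolute 1e-10 by default) from a fixed resting state, with output
#' resampled on a regular 0.05 ms grid.  Deterministic: identical inputs give
#' identical traces.
#'
#' @param gKATP K(ATP) conductance (nS), from the metabolic component.
#' @param fcAMP net relative cAMP.
#' @param fAA relative amino-acid level.
#' @param params an [alphaParams()] set.
#' @param duration total simulated time (ms); must exceed the transient
#'   discard window `params$solver$t_transient`.
#' @return A data.frame of class `alphaTrace` with columns `time` (ms), the
#'   six state variables and the instantaneous currents (pA).  Attributes:
#'   `condition` (gKATP, fcAMP, fAA), `transient` (ms) and `paramHash`.
#' @examples
#' \donttest{
#' tr <- simulateTrace(gKATP = 0.3, fcAMP = 1, fAA = 0, duration = 2000)
#' oscillationMetrics(tr)
#' }
#' @export
simulateTrace <- function(gKATP, fcAMP, fAA, params = alphaParams(),
                          duration = params$solver$t_transient + params$solver$t_window) {
  sol <- params$solver
  if (duration <= sol$t_transient)
    stop("duration must exceed the transient discard window (",
         sol$t_transient, " ms)")
  pv <- membraneParVector(params, gKATP, fcAMP, fAA)
  times <- seq(0, duration, by = sol$dt)
  outnames <- c("INa_AA", "ICa_AA", "IK_AA", "IKATP", "IL", "ISOC",
                "ICaL_mod", "ICaPQ_mod", "ICaT_mod")
  out <- try(deSolve::ode(
    y = membraneInitialState(), times = times, func = "alphacell_deriv",
    parms = pv, dllname = "alphacell", initfunc = "alphacell_init",
    nout = length(outnames), outnames = outnames,
    method = "lsoda", rtol = sol$rtol, atol = sol$atol, maxsteps = 50000
  ), silent = TRUE)
  cond <- sprintf("gKATP=%.4g, fcAMP=%.4g, fAA=%.4g", gKATP, fcAMP, fAA)
  if (inherits(out, "try-error"))
    stop("membrane integration failed at condition (", cond, "): ",
         attr(out, "condition")$message)
  if (attr(out, "istate")[1] < 0)
    stop("membrane integration did not converge at condition (", cond, ")")
  tr <- as.data.frame(out)
  names(tr)[1] <- "time"
  structure(tr,
            condition = c(gKATP = gKATP, fcAMP = fcAMP, fAA = fAA),
            transient = sol$t_transient,
            paramHash = paramHash(params),
            class = c("alphaTrace", "data.frame"))
}

# Rows of a trace after discarding the initial transient.
analysisWindow <- function(trace) {
  trans <- attr(trace, "transient")
  if (is.null(trans)) trans <- 0
  trace[trace$time >= trans, , drop = FALSE]
}

# Local maxima/minima indices of a regularly sampled signal (flat segments
# are collapsed by dropping zero slopes).
localExtrema <- function(x) {
  s <- sign(diff(x))
  keep <- which(s != 0)
  s2 <- s[keep]
  if (length(s2) < 2) return(list(max = integer(0), min = integer(0)))
  turn <- diff(s2)
  list(max = keep[which(turn == -2) + 1L], min = keep[which(turn == 2) + 1L])
}

#' Oscillation metrics of a membrane-potential trace
#'
#' Detects spikes as local maxima whose prominence (height above the deeper of
#' the two adjacent troughs) exceeds a threshold (default 2 mV), after
#' discarding the initial transient.  Amplitude is the mean peak-to-preceding-
#' trough excursion over detected spikes; frequency is the spike count divided
#' by the analysis window.  A trace without detectable spikes returns the
#' residual peak-to-peak fluctuation as amplitude, frequency 0 and
#' `spiking = FALSE`.
#'
#' @param trace an `alphaTrace` from [simulateTrace()] (or any data.frame with
#'   `time` in ms and `V` in mV).
#' @param prominence minimal spike prominence (mV); defaults to the solver
#'   setting used to build the trace.
#' @return A list with `amplitude` (mV), `frequency` (Hz), `mean_V` (mV),
#'   `n_spikes` and `spiking`.
#' @export
oscillationMetrics <- function(trace, prominence = NULL) {
  if (is.null(prominence)) {
    prominence <- attr(trace, "prominence")
    if (is.null(prominence)) prominence <- 2
  }
  w <- analysisWindow(trace)
  if (nrow(w) < 5) stop("trace too short for metric extraction")
  v <- w$V
  tt <- w$time
  ex <- localExtrema(v)
  window_s <- (tt[length(tt)] - tt[1]) / 1000
  # pair each maximum with the nearest preceding trough (falling back to the
  # following trough for a peak at the window edge)
  amps <- numeric(0)
  for (i in ex$max) {
    prev_min <- ex$min[ex$min < i]
    next_min <- ex$min[ex$min > i]
    if (!length(prev_min) && !length(next_min)) next
    left <- if (length(prev_min)) v[max(prev_min)] else v[min(next_min)]
    right <- if (length(next_min)) v[min(next_min)] else left
    prom <- v[i] - max(left, right)
    if (prom >= prominence) amps <- c(amps, v[i] - left)
  }
  if (length(amps) == 0) {
    return(list(amplitude = diff(range(v)), frequency = 0,
                mean_V = mean(v), n_spikes = 0L, spiking = FALSE))
  }
  list(amplitude = mean(amps),
       frequency = length(amps) / window_s,
       mean_V = mean(v),
       n_spikes = length(amps),
       spiking = TRUE)
}
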