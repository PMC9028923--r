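#' Default model parameters
#'
#' Returns the full calibrated parameter set as a nested list with one element
#' per model component (`metabolism`, `signaling`, `membrane`, `secretion`,
#' `solver`).  Individual entries can be overridden through `...` using nested
#' lists, e.g. `alphaParams(signaling = list(f0 = 150))`.
#'
#' Fixed literature values: the cAMP and amino-acid current-modulation
#' coefficients `kcamp_ca = 0.2`, `kcamp_gs = 0.5`, `kaa_na = 0.4`,
#' `kaa_k = 0.2`, `kaa_ca = 0.16`, the leak conductance `gl = 0.25` nS and the
#' autocrine tmAC response parameters `f0 = 175` (percent), `k = 2.8`,
#' `n = 8`.  The remaining metabolic, signaling and membrane constants are
#' calibrated defaults; see the methods vignette for how each was fixed.
#'
#' @param ... nested named lists overriding individual entries, keyed by
#'   component (see Details).
#' @return A named list of class `alphaParams`.
#' @examples
#' p <- alphaParams()
#' p$membrane$kaa_na
#' p2 <- alphaParams(membrane = list(gkatp_max = 0.25))
#' @export
alphaParams <- function(...) {
  p <- list(
    metabolism = list(
      # glycolysis: glucokinase-like Hill + small basal flux (model flux units)
      jg6p_basal = 0.02,
      jg6p_vmax  = 1.0,
      jg6p_k     = 7.5,   # mM, half-saturation
      jg6p_h     = 1.7,   # Hill coefficient
      pl         = 0.8,   # fraction of pyruvate diverted to lactate
      jo2        = 1.0,   # net O2 consumption (FFA-supply proxy), flux units
      # oxidative glucose flux saturates at low glycolytic flux (limited
      # pyruvate oxidation capacity; surplus glycolytic flux goes to lactate)
      jo2g_max   = 0.6,
      jo2g_k     = 0.03,
      rq_ffa     = 0.7,   # respiratory quotient of FFA oxidation
      # relative ATP: affine in glycolytic + oxidative-glucose flux.
      # atp_w_ox solves ATP(6 mM)/ATP(1 mM) = 1.20 given the other constants.
      atp_c0     = 1.0,
      atp_w_gly  = 0.26,
      atp_w_ox   = 1.00247877480662,  # weight on jo2_g; see scripts/calibrate.R
      # K(ATP) conductance: decreasing Hill in relative ATP, anchored so that
      # gKATP equals gkatp_max at the zero-glucose ATP level (ATP = 1).
      gkatp_max  = 0.17257,    # nS, conductance at G = 0
      gkatp_k    = 1.148316,   # relative-ATP half point
      gkatp_h    = 5.2312173
    ),
    signaling = list(
      # steady-state sAC chain: acid load (lactate per CO2 buffer) lowers
      # bicarbonate, bicarbonate drives sAC, PDEs hydrolyse cAMP.
      hco3_q   = 1.15,  # acid-load scale: HCO3 = 1/(1 + (Jlac/(q JCO2))^h)
      hco3_h   = 2,
      sac_km   = 2.0,   # bicarbonate half-activation of sAC (relative units)
      sac_vmax = 3.0,   # maximal sAC rate (concentration/time, model units)
      kpde     = 1.0,   # lumped PDE3B/PDE4 hydrolysis rate constant
      w_intrinsic = 0.75,  # weight of sAC-derived cAMP in the net signal
      w_extrinsic = 0.25,  # weight of tmAC-derived cAMP
      f0 = 175,  # maximal tmAC stimulation, percent above baseline
      k  = 2.8,  # RGS_intrinsic at half-activation
      n  = 8,    # Hill coefficient of the autocrine response
      tmac_form = "percent"  # "percent" (default) or "literal"
    ),
    membrane = list(
      cm = 5,          # pF
      # voltage-gated Na
      gna = 8, vna = 60, vm_na = -32, sm_na = 5,
      vh_na = -45, sh_na = 4, tauh_na = 6,
      # L-type Ca
      gcal = 0.7, vca = 65, vm_cal = -25, sm_cal = 6,
      # P/Q-type Ca (broad, high-threshold activation; drives exocytosis)
      gcapq = 0.6, vm_capq = 5, sm_capq = 9,
      # T-type Ca (pacemaker window current)
      gcat = 0.4, vm_cat = -45, sm_cat = 5,
      vh_cat = -48, sh_cat = 6, tauh_cat = 15,
      # delayed-rectifier K
      gkdr = 2.5, vk = -75, vn_kdr = -25, sn_kdr = 8, taun_kdr = 3,
      # A-type K
      gka = 1.0, va_ka = -45, sa_ka = 10,
      vh_ka = -68, sh_ka = 6, tauh_ka = 20,
      # leak and store-operated currents
      gl = 0.25, vl = -30, gsoc = 0.03, vsoc = 0,
      # bulk cytosolic calcium balance
      ca_kin = 3e-4,   # uM per pA ms
      ca_kout = 0.01,  # 1/ms
      ca_rest = 0.06,  # uM
      # modulation coefficients (fixed)
      kcamp_ca = 0.2, kaa_na = 0.4, kaa_k = 0.2, kaa_ca = 0.16
    ),
    secretion = list(
      kcamp_gs = 0.5,  # direct cAMP effect on exocytosis (fixed)
      # microdomain calcium per unit (modulated) single-channel-type current
      beta_md = 1.0,   # uM per pA
      # saturating exocytosis drives per calcium signal
      km_l = 40, n_l = 1,              # L-type microdomain (shallow)
      km_pq = 39.39, n_pq = 1.0945533, # P/Q-type microdomain
      km_c = 0.50471, n_c = 6,         # bulk cytosolic pathway (steep)
      w_l = 0.00278, w_pq = 1.0, w_m = 0.0025098331  # weights (P/Q dominant)
    ),
    solver = list(
      rtol = 1e-8, atol = 1e-10,
      dt = 0.05,           # ms, fixed-step output resampling
      t_transient = 1000,  # ms discarded before analysis
      t_window = 4000,     # ms analysis window
      prominence = 2       # mV, spike-detection prominence threshold
    )
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad))
      stop("unknown parameter group(s): ", paste(bad, collapse = ", "))
    for (grp in names(over)) {
      stopifnot(is.list(over[[grp]]))
      unknown <- setdiff(names(over[[grp]]), names(p[[grp]]))
      if (length(unknown))
        stop("unknown ", grp, " parameter(s): ", paste(unknown, collapse = ", "))
      p[[grp]] <- modifyList(p[[grp]], over[[grp]])
    }
  }
  class(p) <- "alphaParams"
  validateParams(p)
  p
}

validateParams <- function(p) {
  m <- p$metabolism
  if (m$pl < 0 || m$pl > 1) stop("pl must lie in [0, 1]")
  if (m$jo2 <= 0) stop("jo2 must be positive")
  if (m$jo2g_max > m$jo2) stop("jo2g_max cannot exceed jo2")
  s <- p$signaling
  if (s$f0 <= 0 || s$k <= 0 || s$n < 1)
    stop("tmAC parameters require f0 > 0, k > 0, n >= 1")
  if (abs(s$w_intrinsic + s$w_extrinsic - 1) > 1e-12)
    stop("intrinsic and extrinsic cAMP weights must sum to 1")
  if (!s$tmac_form %in% c("percent", "literal"))
    stop("tmac_form must be 'percent' or 'literal'")
  mb <- p$membrane
  if (mb$cm <= 0) stop("membrane capacitance must be positive")
  cond <- c(mb$gna, mb$gcal, mb$gcapq, mb$gcat, mb$gkdr, mb$gka, mb$gl, mb$gsoc)
  if (any(cond < 0)) stop("conductances must be non-negative")
  invisible(p)
}

#' @export
print.alphaParams <- function(x, ...) {
  cat("alphacell parameter set (hash ", paramHash(x), ")\n", sep = "")
  for (grp in names(x)) {
    v <- unlist(x[[grp]])
    cat("  ", grp, ": ", paste0(names(v), "=", v, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Parameter-set hash
#'
#' Short stable hash of a parameter set, recorded as provenance metadata in
#' sweep outputs so results can be pinned to the calibrated defaults.
#'
#' @param params an [alphaParams()] list.
#' @return A character scalar.
#' @export
paramHash <- function(params) {
  substr(rlang::hash(unclass(params)), 1, 12)
}

#' Read a model configuration file
#'
#' Reads a YAML configuration with any of the sections `metabolism`,
#' `signaling`, `membrane`, `secretion`, `solver` and `sweep`.  Parameter
#' entries override the calibrated defaults; the optional `sweep` section
#' (fields `glucose`, `faa`) is returned alongside for use with [runSweep()].
#'
#' @param path path to a YAML file.
#' @return A list with elements `params` (an `alphaParams` set) and `sweep`
#'   (a [sweepSpec()] or `NULL`).
#' @export
readAlphaConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  sweep <- NULL
  if (!is.null(cfg$sweep)) {
    sweep <- sweepSpec(glucose = cfg$sweep$glucose, faa = cfg$sweep$faa)
    cfg$sweep <- NULL
  }
  params <- do.call(alphaParams, cfg)
  list(params = params, sweep = sweep)
}

#' Write a model configuration file
#'
#' @param params an [alphaParams()] set.
#' @param path output path.
#' @param sweep optional [sweepSpec()] stored under a `sweep` section.
#' @return `path`, invisibly.
#' @export
writeAlphaConfig <- function(params, path, sweep = NULL) {
  cfg <- unclass(params)
  if (!is.null(sweep)) cfg$sweep <- list(glucose = sweep$glucose, faa = sweep$faa)
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}
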