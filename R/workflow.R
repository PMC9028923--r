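#' Sweep specification
#'
#' Defines the stimulus grid for [runSweep()].  Defaults reproduce the
#' standard analysis conditions: glucose 0-10 mM in 0.5 mM steps at low,
#' medium and high amino-acid levels.
#'
#' @param glucose numeric vector of glucose concentrations (mM, `>= 0`).
#' @param faa numeric vector of relative amino-acid levels.
#' @return A list of class `sweepSpec`.
#' @export
sweepSpec <- function(glucose = seq(0, 10, by = 0.5), faa = c(0, 0.5, 1)) {
  if (!length(glucose) || !length(faa)) stop("grids must be non-empty")
  if (any(glucose < 0)) stop("glucose values must be >= 0")
  structure(list(glucose = sort(unique(glucose)), faa = sort(unique(faa))),
            class = "sweepSpec")
}

#' Run a dose-response sweep
#'
#' Evaluates the full secretion pipeline ([rgsNet()]) on every `(G, fAA)`
#' combination of the spec and appends `RGS_norm`, the net RGS normalized to
#' its value at the `(G = 0, fAA = 0)` reference (the conventional display
#' normalization for dose-response curves; the reference row is added to the
#' computation if the grid does not contain it).
#'
#' @param spec a [sweepSpec()].
#' @param params an [alphaParams()] set.
#' @param quiet suppress per-condition progress messages.
#' @return A data.frame of class `alphaSweep`, one row per condition, with a
#'   `paramHash` attribute as provenance metadata.
#' @examples
#' \donttest{
#' sw <- runSweep(sweepSpec(glucose = c(1, 6), faa = c(0, 1)))
#' }
#' @export
runSweep <- function(spec = sweepSpec(), params = alphaParams(), quiet = TRUE) {
  stopifnot(inherits(spec, "sweepSpec"))
  grid <- expand.grid(G = spec$glucose, fAA = spec$faa,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid$G[i]; a <- grid$fAA[i]
    if (!quiet) message(sprintf("condition %d/%d: G=%.2f mM, fAA=%.2f",
                                i, nrow(grid), g, a))
    rows[[i]] <- tryCatch(rgsNet(g, a, params), error = function(e)
      stop("sweep failed at (G=", g, ", fAA=", a, "): ",
           conditionMessage(e), call. = FALSE))
  }
  out <- do.call(rbind, rows)
  ref <- out$RGS_net[out$G == 0 & out$fAA == 0]
  if (!length(ref)) ref <- rgsNet(0, 0, params)$RGS_net
  out$RGS_norm <- out$RGS_net / ref
  structure(out, paramHash = paramHash(params),
            normalization = "RGS_net at (G=0, fAA=0)",
            class = c("alphaSweep", "data.frame"))
}

#' Amino-acid fold changes of net secretion
#'
#' Per-glucose ratio of net RGS at the high versus low amino-acid level, plus
#' the extreme-state ratio: the maximum of the high-AA curve over the grid
#' divided by the minimum of the low-AA curve.
#'
#' @param sweep an `alphaSweep` from [runSweep()].
#' @param at glucose values (mM) at which to report fold changes; default
#'   `c(1, 6)`.
#' @param faa_low,faa_high amino-acid levels to compare (defaults 0 and 1).
#' @return A list of class `alphaFoldChange` with `per_g` (data.frame `G`,
#'   `fold`), `extreme` (scalar) and `paramHash`.
#' @export
foldChanges <- function(sweep, at = c(1, 6), faa_low = 0, faa_high = 1) {
  lo <- sweep[sweep$fAA == faa_low, ]
  hi <- sweep[sweep$fAA == faa_high, ]
  if (!nrow(lo) || !nrow(hi))
    stop("sweep lacks fAA levels ", faa_low, " and/or ", faa_high)
  missing_g <- setdiff(at, intersect(lo$G, hi$G))
  if (length(missing_g))
    stop("sweep lacks required glucose value(s): ",
         paste(missing_g, collapse = ", "))
  folds <- vapply(at, function(g)
    hi$RGS_net[hi$G == g] / lo$RGS_net[lo$G == g], numeric(1))
  structure(list(
    per_g = data.frame(G = at, fold = folds),
    extreme = max(hi$RGS_net) / min(lo$RGS_net),
    paramHash = attr(sweep, "paramHash")
  ), class = "alphaFoldChange")
}

#' @export
print.alphaFoldChange <- function(x, ...) {
  cat("Amino-acid fold change of net relative glucagon secretion\n")
  for (i in seq_len(nrow(x$per_g)))
    cat(sprintf("  G = %4.1f mM: %.2f-fold\n", x$per_g$G[i], x$per_g$fold[i]))
  cat(sprintf("  extreme ratio (max high-AA / min low-AA): %.2f\n", x$extreme))
  if (!is.null(x$paramHash)) cat("  parameter hash:", x$paramHash, "\n")
  invisible(x)
}

#' Stacked cAMP decomposition
#'
#' Per-condition intrinsic (sAC-derived) and extrinsic (tmAC-derived)
#' contributions to the net relative cAMP, for stacked-area display.  The sAC
#' column is identical across amino-acid levels at every glucose value.
#'
#' @param sweep an `alphaSweep` from [runSweep()].
#' @return A data.frame with `G`, `fAA`, `fcAMP_sAC`, `fcAMP_tmAC`,
#'   `fcAMP_intrinsic`, `fcAMP_extrinsic`, `fcAMP`.
#' @export
campDecomposition <- function(sweep) {
  cols <- c("G", "fAA", "fcAMP_sAC", "fcAMP_tmAC",
            "fcAMP_intrinsic", "fcAMP_extrinsic", "fcAMP")
  stopifnot(all(cols %in% names(sweep)))
  out <- as.data.frame(sweep)[, cols]
  attr(out, "paramHash") <- attr(sweep, "paramHash")
  out
}

#' Compare membrane-potential traces across conditions
#'
#' Simulates the membrane at each `(G, fAA)` condition (with intrinsic-plus-
#' autocrine cAMP resolved by the full pipeline) and tabulates the oscillation
#' metrics, plus qualitative change flags between consecutive conditions.
#'
#' @param conditions a data.frame with columns `G` and `fAA` (>= 2 rows).
#' @param params an [alphaParams()] set.
#' @param keep_traces return the simulated traces as an attribute.
#' @return A data.frame with `G`, `fAA`, `amplitude`, `frequency`, `mean_V`,
#'   `n_spikes`, `spiking`, and for rows after the first the flags
#'   `amplitude_change` and `frequency_change` (`"increases"`, `"decreases"`
#'   or `"unchanged"` relative to the previous row).
#' @export
compareTraces <- function(conditions, params = alphaParams(),
                          keep_traces = FALSE) {
  stopifnot(is.data.frame(conditions), nrow(conditions) >= 2,
            all(c("G", "fAA") %in% names(conditions)))
  traces <- list()
  rows <- lapply(seq_len(nrow(conditions)), function(i) {
    g <- conditions$G[i]; a <- conditions$fAA[i]
    res <- rgsNet(g, a, params)
    tr <- simulateTrace(res$gKATP, res$fcAMP, a, params)
    if (keep_traces) traces[[i]] <<- tr
    m <- oscillationMetrics(tr, params$solver$prominence)
    data.frame(G = g, fAA = a, amplitude = m$amplitude,
               frequency = m$frequency, mean_V = m$mean_V,
               n_spikes = m$n_spikes, spiking = m$spiking)
  })
  out <- do.call(rbind, rows)
  flag <- function(d) ifelse(abs(d) < 1e-9, "unchanged",
                             ifelse(d > 0, "increases", "decreases"))
  out$amplitude_change <- c(NA, flag(diff(out$amplitude)))
  out$frequency_change <- c(NA, flag(diff(out$frequency)))
  if (keep_traces) attr(out, "traces") <- traces
  attr(out, "paramHash") <- paramHash(params)
  out
}

#' Write a result table as CSV with provenance header
#'
#' Writes the table with a leading comment line recording the parameter-set
#' hash, so outputs can be pinned to the calibrated defaults.
#'
#' @param x a data.frame (e.g. an `alphaSweep` or trace).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeResultCsv <- function(x, path) {
  hash <- attr(x, "paramHash")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(hash)) writeLines(paste0("# paramHash: ", hash), con)
  write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}
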