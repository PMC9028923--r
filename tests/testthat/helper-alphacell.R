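# Shared test helpers: short simulations keep property tests fast while the
# acceptance suite uses the full default window.

# Trace with a shortened transient/window, for tests that only need a few
# hundred milliseconds of stationary behavior.
shortTrace <- function(gKATP, fcAMP, fAA, params = alphaParams(),
                       transient = 500, window = 1500) {
  params$solver$t_transient <- transient
  params$solver$t_window <- window
  simulateTrace(gKATP, fcAMP, fAA, params, duration = transient + window)
}

# Direct transcriptions of the closed-form relations, kept deliberately
# separate from the package implementations so tests compare two routes.
oracle <- list(
  lactate = function(pL, j) 2 * pL * j,
  co2 = function(jo2, jo2g) jo2g + 0.7 * (jo2 - jo2g),
  camp_ca = function(f, k = 0.2) 1 - k * (1 - f),
  aa_na = function(f, k = 0.4) 1 + k * f,
  aa_k = function(f, k = 0.2) 1 + k * f,
  aa_ca = function(f, k = 0.16) 1 + k * f,
  camp_gs = function(f, k = 0.5) 1 - k * (1 - f),
  tmac = function(r, f0 = 175, k = 2.8, n = 8)
    1 + f0 / 100 * (r^n / (k^n + r^n))
)
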