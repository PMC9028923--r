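test_that("cAMP and amino-acid modulation factors match their closed forms", {
  expect_equal(campCaFactor(c(0, 0.5, 1)), c(0.8, 0.9, 1.0))
  f <- aaFactors(1)
  expect_equal(unlist(f), c(fAA_Na = 1.4, fAA_K = 1.2, fAA_Ca = 1.16))
  expect_equal(unlist(aaFactors(0.5)), c(fAA_Na = 1.2, fAA_K = 1.1, fAA_Ca = 1.08))
  expect_equal(unlist(aaFactors(0)), c(fAA_Na = 1, fAA_K = 1, fAA_Ca = 1))
  expect_error(aaFactors(-2.5), "fAA")
  # oracle agreement on random inputs, including hypo/hyperaminoacidemia
  x <- runif(100, -1, 2)
  expect_identical(aaFactors(x)$fAA_Na, oracle$aa_na(x))
  expect_identical(aaFactors(x)$fAA_K, oracle$aa_k(x))
  expect_identical(aaFactors(x)$fAA_Ca, oracle$aa_ca(x))
  y <- runif(100, 0, 2)
  expect_identical(campCaFactor(y), oracle$camp_ca(y))
})

test_that("leak current is ohmic around its reversal potential", {
  p <- alphaParams()
  expect_equal(leakCurrent(p$membrane$vl, p), 0)
  expect_equal(leakCurrent(p$membrane$vl + 10, p), 2.5)  # gL = 0.25 nS
  v1 <- runif(20, -80, 0); v2 <- runif(20, -80, 0)
  expect_equal(leakCurrent(v1, p) - leakCurrent(v2, p),
               p$membrane$gl * (v1 - v2))
})

test_that("membrane derivative equals the scaled sum of currents", {
  p <- alphaParams()
  st <- c(V = -45, hNa = 0.5, n = 0.1, hCaT = 0.3, hKA = 0.2, Cac = 0.1)
  r <- membraneRhs(0, st, gKATP = 0.15, fcAMP = 0.9, fAA = 0.5, p)
  cur <- r[[2]]
  total <- sum(cur[c("INa_AA", "ICa_AA", "IK_AA", "IKATP", "IL", "ISOC")])
  expect_equal(r[[1]][1], -total / p$membrane$cm, tolerance = 1e-12)
  # the summed calcium current equals its channel-resolved parts
  expect_equal(cur[["ICa_AA"]],
               cur[["ICaL_mod"]] + cur[["ICaPQ_mod"]] + cur[["ICaT_mod"]])
})

test_that("modulation factors of one leave every current bitwise unchanged", {
  # fAA = 0 and fcAMP = 1 give identity factors; compare against a parameter
  # set whose modulation coefficients are zero so the factors are identities
  # by construction even at nonzero fAA and fcAMP != 1.
  p <- alphaParams()
  p0 <- alphaParams(membrane = list(kcamp_ca = 0, kaa_na = 0, kaa_k = 0,
                                    kaa_ca = 0))
  st <- c(V = -38, hNa = 0.4, n = 0.15, hCaT = 0.25, hKA = 0.3, Cac = 0.12)
  a <- membraneRhs(0, st, 0.12, fcAMP = 1, fAA = 0, p)
  b <- membraneRhs(0, st, 0.12, fcAMP = 0.3, fAA = 0.8, p0)
  expect_identical(a[[1]], b[[1]])
  expect_identical(a[[2]], b[[2]])
})

test_that("compiled model matches the R right-hand side along a trajectory", {
  p <- alphaParams()
  tr <- shortTrace(0.15, 1, 0.5, p, transient = 200, window = 300)
  idx <- seq(1, nrow(tr), by = 997)
  for (i in idx) {
    st <- unlist(tr[i, c("V", "hNa", "n", "hCaT", "hKA", "Cac")])
    r <- membraneRhs(0, st, 0.15, 1, 0.5, p)
    expect_equal(unname(r[[2]]["INa_AA"]), tr$INa_AA[i], tolerance = 1e-8)
    expect_equal(unname(r[[2]]["ICa_AA"]), tr$ICa_AA[i], tolerance = 1e-8)
    expect_equal(unname(r[[2]]["IKATP"]), tr$IKATP[i], tolerance = 1e-8)
  }
})

test_that("gating variables stay in [0, 1] from randomized initial states", {
  p <- alphaParams()
  set.seed(1)
  for (i in 1:4) {
    y0 <- membraneInitialState()
    y0["V"] <- runif(1, -70, -20)
    y0[c("hNa", "n", "hCaT", "hKA")] <- runif(4)
    pv <- alphacell:::membraneParVector(p, 0.12, 1, 0)
    out <- deSolve::ode(y0, seq(0, 500, 0.1), "alphacell_deriv", pv,
                        dllname = "alphacell", initfunc = "alphacell_init",
                        nout = 9, method = "lsoda",
                        rtol = 1e-8, atol = 1e-10)
    g <- out[, c("hNa", "n", "hCaT", "hKA")]
    expect_true(all(g >= -1e-9 & g <= 1 + 1e-9))
    expect_true(all(out[, "Cac"] >= 0))
  }
})

test_that("trace simulation is deterministic", {
  p <- alphaParams()
  a <- shortTrace(0.12, 1, 0, p)
  b <- shortTrace(0.12, 1, 0, p)
  expect_identical(a$V, b$V)
  expect_identical(a$Cac, b$Cac)
})

test_that("oscillation metrics recover closed-form signals", {
  # pure sinusoid: amplitude 2A, frequency 1/T
  t <- seq(0, 2000, 0.5)
  A <- 7; T_ms <- 200
  tr <- data.frame(time = t, V = -40 + A * sin(2 * pi * t / T_ms))
  attr(tr, "transient") <- 0
  m <- oscillationMetrics(tr, prominence = 2)
  expect_equal(m$amplitude, 2 * A, tolerance = 1e-3)
  expect_equal(m$frequency, 1000 / T_ms, tolerance = 0.12)
  # constant trace: no spikes, frequency zero
  flat <- data.frame(time = t, V = rep(-50, length(t)))
  attr(flat, "transient") <- 0
  mf <- oscillationMetrics(flat, prominence = 2)
  expect_false(mf$spiking)
  expect_equal(mf$frequency, 0)
  expect_equal(mf$amplitude, 0)
  # sawtooth with known period, peak count by brute force
  period <- 250
  saw <- data.frame(time = t, V = -60 + 20 * ((t %% period) / period))
  attr(saw, "transient") <- 0
  ms <- oscillationMetrics(saw, prominence = 2)
  expect_equal(ms$frequency, 1000 / period, tolerance = 0.15)
})
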