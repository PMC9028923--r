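test_that("glycolytic flux is basal at zero glucose, saturating and monotone", {
  p <- alphaParams()
  expect_equal(glycolyticFlux(0, p), p$metabolism$jg6p_basal)
  expect_equal(glycolyticFlux(1e6, p), p$metabolism$jg6p_vmax, tolerance = 1e-3)
  expect_gt(glycolyticFlux(6, p), glycolyticFlux(1, p))
  g <- sort(runif(50, 0, 12))
  expect_true(all(diff(glycolyticFlux(g, p)) >= 0))
  expect_error(glycolyticFlux(-1), "glucose")
})

test_that("lactate flux follows the pyruvate split", {
  expect_equal(lactateFlux(0.5, 1.0), 1.0)
  expect_equal(lactateFlux(0, 3.7), 0)
  expect_equal(lactateFlux(0.8, 0.3), 0.48)
  expect_error(lactateFlux(1.2, 1), "pL")
  expect_error(lactateFlux(0.5, -1), "JG6P")
})

test_that("CO2 flux respects the respiratory-quotient split exactly", {
  expect_equal(co2Flux(1, 1)$JCO2, 1.0)   # pure glucose oxidation, RQ = 1
  expect_equal(co2Flux(1, 0)$JCO2, 0.7)   # pure FFA oxidation, RQ = 0.7
  expect_equal(co2Flux(2, 1)$JCO2, 1.7)
  # additivity holds exactly for random inputs
  for (i in 1:25) {
    jo2 <- runif(1, 0.1, 5); jo2g <- runif(1, 0, jo2)
    f <- co2Flux(jo2, jo2g)
    expect_identical(f$JCO2, f$JCO2_G + f$JCO2_FFA)
  }
  expect_error(co2Flux(1, 1.5), "JO2")
})

test_that("relative ATP is normalized, monotone and rises 20% from 1 to 6 mM", {
  p <- alphaParams()
  expect_equal(atpLevel(0, p), 1.0)
  expect_equal(atpLevel(6, p) / atpLevel(1, p), 1.20, tolerance = 1e-9)
  g <- sort(runif(60, 0, 12))
  expect_true(all(diff(atpLevel(g, p)) >= 0))
})

test_that("K(ATP) conductance is anchored, positive and strictly decreasing", {
  p <- alphaParams()
  expect_equal(katpConductance(1, p), p$metabolism$gkatp_max)
  a <- sort(runif(50, 0.5, 2))
  gk <- katpConductance(a, p)
  expect_true(all(gk > 0))
  expect_true(all(diff(gk) < 0))
  expect_gt(katpConductance(atpLevel(1, p), p), katpConductance(atpLevel(6, p), p))
  # continuity at a representative point
  expect_equal(katpConductance(1.2, p), katpConductance(1.2 + 1e-9, p),
               tolerance = 1e-6)
})

test_that("metabolic state satisfies its internal constraints on a grid", {
  p <- alphaParams()
  m <- metabolicState(seq(0, 10, 0.5), p)
  expect_true(all(m$JG6P >= 0 & m$Jlac >= 0 & m$JCO2 >= 0))
  expect_identical(m$JCO2, m$JCO2_G + m$JCO2_FFA)
  expect_true(all(m$JO2_G <= m$JO2))
  expect_true(all(m$pL >= 0 & m$pL <= 1))
  expect_true(all(diff(m$ATP) >= 0))
  expect_true(all(diff(m$gKATP) <= 0))
})
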