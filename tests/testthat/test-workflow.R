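test_that("sweep specification validates its grids", {
  sp <- sweepSpec(glucose = c(6, 1, 1), faa = c(1, 0))
  expect_equal(sp$glucose, c(1, 6))
  expect_equal(sp$faa, c(0, 1))
  expect_error(sweepSpec(glucose = numeric(0)), "non-empty")
  expect_error(sweepSpec(glucose = c(-1, 2)), ">= 0")
})

test_that("a small sweep is finite, normalized and ordered in fAA", {
  p <- alphaParams()
  sw <- runSweep(sweepSpec(glucose = c(0, 1, 6), faa = c(0, 1)), p)
  expect_equal(nrow(sw), 6)
  expect_true(all(is.finite(sw$RGS_net)))
  expect_equal(sw$RGS_norm[sw$G == 0 & sw$fAA == 0], 1)
  # high-AA curve pointwise above low-AA curve
  expect_true(all(sw$RGS_net[sw$fAA == 1] > sw$RGS_net[sw$fAA == 0]))
  expect_type(attr(sw, "paramHash"), "character")
})

test_that("fold changes report per-glucose and extreme-state ratios", {
  p <- alphaParams()
  sw <- runSweep(sweepSpec(glucose = c(0, 1, 6), faa = c(0, 1)), p)
  fc <- foldChanges(sw, at = c(1, 6))
  expect_equal(fc$per_g$fold[1],
               sw$RGS_net[sw$G == 1 & sw$fAA == 1] /
               sw$RGS_net[sw$G == 1 & sw$fAA == 0])
  expect_equal(fc$extreme,
               max(sw$RGS_net[sw$fAA == 1]) / min(sw$RGS_net[sw$fAA == 0]))
  expect_error(foldChanges(sw, at = c(1, 3)), "glucose value")
  expect_error(foldChanges(sw, faa_high = 0.5), "fAA")
})

test_that("cAMP decomposition sums row-wise and has an fAA-invariant sAC column", {
  p <- alphaParams()
  sw <- runSweep(sweepSpec(glucose = c(0, 6), faa = c(0, 1)), p)
  d <- campDecomposition(sw)
  expect_equal(d$fcAMP_intrinsic + d$fcAMP_extrinsic, d$fcAMP)
  for (g in unique(d$G)) {
    s <- d$fcAMP_sAC[d$G == g]
    expect_identical(s[1], s[2])  # sAC part independent of amino acids
  }
})

test_that("sweeps are reproducible and CSV output carries provenance", {
  p <- alphaParams()
  sp <- sweepSpec(glucose = c(1, 6), faa = 0)
  a <- runSweep(sp, p); b <- runSweep(sp, p)
  expect_identical(as.data.frame(a), as.data.frame(b))
  f <- tempfile(fileext = ".csv")
  writeResultCsv(a, f)
  lines <- readLines(f)
  expect_match(lines[1], "^# paramHash: [0-9a-f]+$")
  got <- read.csv(f, comment.char = "#")
  expect_equal(got$RGS_net, a$RGS_net, tolerance = 1e-12)
  unlink(f)
})

test_that("configuration files round-trip and override defaults", {
  p <- alphaParams()
  f <- tempfile(fileext = ".yaml")
  writeAlphaConfig(alphaParams(signaling = list(f0 = 150)), f,
                   sweep = sweepSpec(glucose = c(1, 6), faa = 0))
  cfg <- readAlphaConfig(f)
  expect_equal(cfg$params$signaling$f0, 150)
  expect_equal(cfg$sweep$glucose, c(1, 6))
  expect_equal(unclass(cfg$params),
               unclass(alphaParams(signaling = list(f0 = 150))),
               tolerance = 1e-12)
  unlink(f)
  # shipped scenario files parse
  smoke <- readAlphaConfig(system.file("extdata", "smoke.yaml",
                                       package = "alphacell"))
  expect_equal(smoke$sweep$glucose, c(1, 6))
  expect_identical(paramHash(smoke$params), paramHash(p))
})

test_that("unknown parameter names are rejected", {
  expect_error(alphaParams(signaling = list(nope = 1)), "unknown signaling")
  expect_error(alphaParams(bogus = list(a = 1)), "unknown parameter group")
})
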