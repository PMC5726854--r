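# Two-state fast-exchange algebra and the ribosome binding-site census.

test_that("effective diffusion interpolates between the pure states", {
  expect_identical(effectiveDiffusion(1, 10, 0.04), 10)
  expect_identical(effectiveDiffusion(0, 10, 0.04), 0.04)
  # strongly bound probe: the E. coli +25 GFP regime
  expect_equal(effectiveDiffusion(0.01004, 10, 0.04), 0.14,
               tolerance = 1e-3)
  expect_error(effectiveDiffusion(1.2, 10, 0.04), "fFree")
  expect_error(effectiveDiffusion(0.5, 1, 2), "dFree")
})

test_that("free fraction inverts the two-state relation (printed regimes)", {
  # Hfx. volcanii +25: dEff 1.9 with dFree 10 -> bound fraction 0.81
  f <- freeFraction(1.9, 10, 0.04)
  expect_equal(round(1 - as.numeric(f), 2), 0.81)
  # E. coli +25: dEff 0.14 -> bound fraction 0.99
  f2 <- freeFraction(0.14, 10, 0.04)
  expect_equal(round(1 - as.numeric(f2), 2), 0.99)
  expect_identical(as.numeric(freeFraction(10, 10, 0.04)), 1)
  expect_error(freeFraction(1, 5, 5), "exceed")
})

test_that("out-of-range dEff is clamped and flagged, not an error", {
  f <- freeFraction(c(11, 5, 0.01), 10, 0.04)
  expect_equal(as.numeric(f), c(1, (5 - 0.04) / 9.96, 0))
  expect_identical(attr(f, "clamped"), c(TRUE, FALSE, TRUE))
})

test_that("Kd and bound fraction round-trip and match printed values", {
  expect_equal(kdFromBoundFraction(0.99, 660), 6.7, tolerance = 0.01)
  expect_identical(kdFromBoundFraction(0.5, 660), 660)
  # direct arithmetic from the unrounded Hfx. volcanii bound fraction
  expect_equal(kdFromBoundFraction(0.8133, 660), 151.5, tolerance = 1e-3)
  expect_identical(boundFraction(0, 100), 1)
  expect_identical(boundFraction(660, 660), 0.5)
  expect_equal(boundFraction(6.7, 660), 0.99, tolerance = 1e-3)
  expect_error(kdFromBoundFraction(1, 660), "strictly inside")
  expect_error(kdFromBoundFraction(0, 660), "strictly inside")
  expect_error(boundFraction(0, 0), "both")
})

test_that("algebra round trips hold to 1e-12 and are monotone", {
  f <- seq(0, 1, by = 0.05)
  back <- vapply(f, function(fi) {
    as.numeric(freeFraction(effectiveDiffusion(fi, 10, 0.04), 10, 0.04))
  }, numeric(1))
  expect_equal(back, f, tolerance = 1e-12)
  fb <- seq(0.05, 0.95, by = 0.05)
  back2 <- vapply(fb, function(fi) {
    boundFraction(kdFromBoundFraction(fi, 660), 660)
  }, numeric(1))
  expect_equal(back2, fb, tolerance = 1e-12)
  expect_true(all(diff(effectiveDiffusion(f, 10, 0.04)) > 0))
  expect_true(all(diff(boundFraction(c(1, 10, 100, 1000), 660)) < 0))
})

test_that("Gaussian-convolution variances compose to the effective D", {
  withr::with_seed(1, {
    for (k in 1:20) {
      f <- runif(1)
      dF <- runif(1, 1, 20)
      dB <- runif(1, 0, 1)
      dt <- runif(1, 1e-3, 1)
      sf2 <- 2 * dF * f * dt
      sg2 <- 2 * dB * (1 - f) * dt
      expect_equal(sf2 + sg2,
                   2 * effectiveDiffusion(f, dF, dB) * dt,
                   tolerance = 1e-12)
    }
  })
})

test_that("twoStateDiffusion object validates its identity", {
  ts <- twoStateDiffusion(0.187, 10, 0.04)
  expect_s4_class(ts, "TwoStateDiffusion")
  expect_equal(ts@dEff, 0.187 * 10 + 0.813 * 0.04, tolerance = 1e-12)
  expect_error(new("TwoStateDiffusion", dFree = 10, dBound = 0.04,
                   fFree = 0.5, dEff = 3), "dEff")
})

test_that("site census reproduces the published census arithmetic", {
  g <- estimateSites(20, 0.5, 3.5, 10)
  expect_equal(g@sphereArea, 1260)           # pi*20^2 at 3 s.f.
  expect_equal(g@rnaArea, 630)
  expect_equal(g@probeCrossSection, 9.6)     # pi*1.75^2 at 2 s.f.
  expect_identical(g@nSites, 66L)            # 630/9.6 = 65.625
  expect_equal(g@siteConc, 660)
})

test_that("site census degenerate geometries", {
  # probe as large as the ribosome: area ratio ~4
  g <- estimateSites(20, 1, 20, 10)
  expect_identical(g@nSites, 4L)
  g0 <- estimateSites(20, 0, 3.5, 10)
  expect_identical(g0@nSites, 0L)
  expect_identical(g0@siteConc, 0)
  expect_error(estimateSites(-1, 0.5, 3.5), "diameters")
  expect_error(estimateSites(20, 1.5, 3.5), "rnaSurfaceFraction")
})
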