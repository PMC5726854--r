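# Screened electrostatic binding model, Kd <-> free energy, and the fits.

test_that("binding free energy limits and direct evaluation", {
  p <- ionicBindingParams(-20400, -28900, 1.53)
  expect_equal(bindingFreeEnergy(0, p), -20400 - 28900)   # full screening off
  expect_equal(bindingFreeEnergy(1e6, p), -20400, tolerance = 1e-6)
  # at the E. coli ionic strength the model reproduces RT*ln(Kd)
  expect_equal(bindingFreeEnergy(0.2, p), dgFromKd(6.7e-6, 293),
               tolerance = 2e-3)
  expect_equal(bindingFreeEnergy(0.2, p) / 1000, -29.0, tolerance = 0.01)
  expect_error(bindingFreeEnergy(-0.1, p), "ionicStrength")
  # c1 -> 0: no screening at any ionic strength
  p0 <- ionicBindingParams(-20400, -28900, 1e-12)
  expect_equal(bindingFreeEnergy(c(0.01, 0.5, 3), p0),
               rep(-49300, 3), tolerance = 1e-6)
})

test_that("Kd <-> Delta-G conversions round-trip at 1 M standard state", {
  expect_identical(kdFromDg(0, 293), 1)
  expect_equal(dgFromKd(6.7e-6, 293), -2.90e4, tolerance = 2e-3)
  dgs <- c(-30000, -10000, 0, 5000)
  expect_equal(dgFromKd(kdFromDg(dgs, 293), 293), dgs, tolerance = 1e-12)
  expect_error(dgFromKd(-1), "kd")
  expect_error(kdFromDg(0, -3), "temperature")
})

test_that("ionic fit on the printed Kd triple recovers the printed params", {
  fit <- fitIonic(KD_TRIPLE$ionicStrength, KD_TRIPLE$kd, 293)
  expect_equal(fit@dgNio, -20400, tolerance = 0.02)
  expect_equal(fit@dgIo0, -28900, tolerance = 0.02)
  expect_equal(fit@c1, 1.53, tolerance = 0.02)
  # three points: the fit interpolates (residuals < 1 J/mol each)
  expect_lt(fit@rss, 1)
})

test_that("ionic fit recovers exact synthetic parameters to 1e-6", {
  withr::with_seed(99, {
    for (k in 1:50) {
      dgNio <- runif(1, -30e3, -10e3)
      dgIo0 <- runif(1, -40e3, -5e3)
      c1 <- runif(1, 0.5, 3)
      truth <- ionicBindingParams(dgNio, dgIo0, c1)
      I <- sort(runif(5, 0.05, 3))
      kd <- kdFromDg(bindingFreeEnergy(I, truth), 293)
      fit <- fitIonic(I, kd, 293)
      expect_equal(fit@dgNio, dgNio, tolerance = 1e-6)
      expect_equal(fit@dgIo0, dgIo0, tolerance = 1e-6)
      expect_equal(fit@c1, c1, tolerance = 1e-6)
    }
  })
})

test_that("ionic fit rejects degenerate inputs", {
  expect_error(fitIonic(c(0.2, 0.8), c(1e-6, 2e-6)), "under-determined")
  expect_error(fitIonic(c(0.2, 0.2, 0.8), c(1e-6, 1e-6, 2e-6)), "distinct")
  expect_error(fitIonic(c(0.2, 0.8, 2.1), c(-1e-6, 1e-6, 2e-6)), "> 0")
})

test_that("dEff(charge) saturates at the pure-state coefficients", {
  p <- chargeModelParams(-20400, -1156, 1.53)
  cst <- p@constants
  # very negative probe: no binding -> dFree
  expect_equal(deffOfCharge(-200, p), cst$dFree, tolerance = 1e-6)
  # very positive probe: saturated binding -> dBound
  expect_equal(deffOfCharge(200, p), cst$dBound, tolerance = 1e-6)
  q <- seq(-30, 25, by = 1)
  d <- deffOfCharge(q, p)
  expect_true(all(d >= cst$dBound & d <= cst$dFree))
  expect_true(all(diff(d) <= 0))  # dgPc < 0: monotone non-increasing
})

test_that("dEff(charge) is exactly the composition of the four relations", {
  p <- chargeModelParams(-18000, -900, 1.2,
                         chargeModelConstants(ionicStrength = 0.5))
  cst <- p@constants
  for (q in c(-30, -7, 0, 7, 15, 25)) {
    w <- exp(-p@c1 * sqrt(cst$ionicStrength)) /
      (1 + p@c1 * sqrt(cst$ionicStrength))
    dgB <- p@dgNio + p@dgPc * q * w
    kdM <- kdFromDg(dgB, cst$temperature)
    fb <- boundFraction(kdM * 1e6, cst$siteConc * 1e6)  # uM on both sides
    expect_equal(deffOfCharge(q, p),
                 effectiveDiffusion(1 - fb, cst$dFree, cst$dBound),
                 tolerance = 1e-12)
  }
})

test_that("charge-model fit recovers identifiable parameters", {
  truth <- chargeModelParams(-20400, -1156, 1.53)
  q <- c(-30, -7, 0, 7, 11, 15, 25)
  d <- deffOfCharge(q, truth)
  # single ionic strength, c1 fixed: both free energies recovered
  fit <- fitChargeModel(q, d, truth@constants, c1 = 1.53)
  expect_equal(fit@dgNio, -20400, tolerance = 1e-4)
  expect_equal(fit@dgPc, -1156, tolerance = 1e-4)
  expect_false(fit@boundary)
  # c1 free at one ionic strength: only dgNio and dgPc*screen(c1) are
  # identifiable (dgPc and c1 trade off along a ridge)
  fit3 <- fitChargeModel(q, d, truth@constants)
  screen <- function(c1, I) exp(-c1 * sqrt(I)) / (1 + c1 * sqrt(I))
  expect_equal(fit3@dgNio, -20400, tolerance = 1e-3)
  expect_equal(fit3@dgPc * screen(fit3@c1, 0.2),
               -1156 * screen(1.53, 0.2), tolerance = 1e-3)
  expect_lt(fit3@rss, 1e-8)
})

test_that("pooling ionic strengths makes all three parameters identifiable", {
  qs <- rep(c(-30, -7, 0, 7, 15, 25), 3)
  Is <- rep(c(0.2, 0.8, 2.1), each = 6)
  cst <- chargeModelConstants(ionicStrength = Is)
  d <- numeric(length(qs))
  for (i in seq_along(qs)) {
    pI <- chargeModelParams(-20400, -1156, 1.53,
                            chargeModelConstants(ionicStrength = Is[i]))
    d[i] <- deffOfCharge(qs[i], pI)
  }
  fit <- fitChargeModel(qs, d, cst)
  expect_equal(fit@dgNio, -20400, tolerance = 1e-4)
  expect_equal(fit@dgPc, -1156, tolerance = 1e-4)
  expect_equal(fit@c1, 1.53, tolerance = 1e-4)
})

test_that("fitted charge model beats single-parameter perturbations", {
  # printed E. coli probe charges and representative mean D values
  q <- c(-31.1, -8.2, -1.3, 9.5, 23.5)
  d <- c(10, 10, 8.6, 2.7, 0.14)
  fit <- fitChargeModel(q, d, chargeModelConstants(), c1 = 1.53)
  rssOf <- function(dgNio, dgPc) {
    p <- chargeModelParams(dgNio, dgPc, 1.53, chargeModelConstants())
    sum((log10(deffOfCharge(q, p)) - log10(d))^2)
  }
  for (fac in c(0.9, 1.1)) {
    expect_lt(fit@rss, rssOf(fit@dgNio * fac, fit@dgPc))
    expect_lt(fit@rss, rssOf(fit@dgNio, fit@dgPc * fac))
  }
})

test_that("no-binding data drive the fit to a flagged boundary solution", {
  q <- c(-30, -10, 5, 25)
  fit <- fitChargeModel(q, rep(10, 4), chargeModelConstants(), c1 = 1.53)
  expect_true(fit@boundary)
  expect_equal(deffOfCharge(q, fit), rep(10, 4), tolerance = 1e-4)
})

test_that("charge-model fit rejects under-determined input", {
  expect_error(fitChargeModel(c(-1, 0, 1), c(1, 2, 3)), "under-determined")
  expect_error(fitChargeModel(1:4, c(1, 2, 3, -1)), "> 0")
})
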