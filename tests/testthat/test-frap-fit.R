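# FRAP diffusion-coefficient fitting: round trips, identifiability, I/O.

test_that("noiseless round trip recovers D to well under 1%", {
  stack <- generateFrapStack(dTrue = 10, noiseSd = 0, seed = 1)
  fit <- fitFrap(stack)
  expect_true(fit@converged)
  expect_true(fit@identifiable)
  expect_equal(diffusionCoef(fit), 10, tolerance = 0.01)
  expect_gte(fit@rss, 0)
  expect_identical(dim(fit@profileFit), dim(intensities(stack)))
})

test_that("slow-probe regime with 2% noise recovers D within 5%", {
  # 0.14 um^2/s is the slowest effective coefficient observed in vivo
  acq <- frapAcquisition(0.14)
  stack <- generateFrapStack(dTrue = 0.14, nPixels = acq$nPixels,
                             nFrames = acq$nFrames,
                             frameInterval = acq$frameInterval,
                             noiseSd = 0.02, seed = 7)
  fit <- fitFrap(stack)
  expect_equal(diffusionCoef(fit), 0.14, tolerance = 0.05)
})

test_that("fit is deterministic for fixed input", {
  stack <- generateFrapStack(dTrue = 2, noiseSd = 0.02, seed = 3)
  expect_identical(diffusionCoef(fitFrap(stack)),
                   diffusionCoef(fitFrap(stack)))
})

test_that("pre-equilibrated (flat) stacks are flagged non-identifiable", {
  x <- seq(0.1, 3, by = 0.375)
  times <- seq(0, by = 0.004, length.out = 20)
  withr::with_seed(5, {
    flat <- matrix(1 + rnorm(20 * length(x), sd = 0.02), 20, length(x))
  })
  fit <- fitFrap(lineProfileStack(x, times, pmax(flat, 0)))
  expect_false(fit@identifiable)
  expect_true(is.na(diffusionCoef(fit)))
  # noiseless flat stack too
  fit0 <- fitFrap(lineProfileStack(x, times, matrix(1, 20, length(x))))
  expect_false(fit0@identifiable)
})

test_that("normalization removes a genuine illumination gradient", {
  acq <- frapAcquisition(5)
  st <- generateFrapStack(dTrue = 5, nPixels = acq$nPixels,
                          nFrames = acq$nFrames,
                          frameInterval = acq$frameInterval,
                          noiseSd = 0.02, seed = 11)
  g <- 1 + 0.4 * positions(st) / max(positions(st))
  st2 <- lineProfileStack(positions(st), frameTimes(st),
                          sweep(intensities(st), 2, g, "*"),
                          nPrebleach = 3L,
                          prebleachProfile = prebleachProfile(st) * g)
  expect_equal(diffusionCoef(fitFrap(st2)), 5, tolerance = 0.05)
})

test_that("grid refinement changes fitted D by < 0.5%", {
  mk <- function(nPixels, frameInterval) {
    generateFrapStack(dTrue = 3, nPixels = nPixels, nFrames = 50,
                      frameInterval = frameInterval, noiseSd = 0, seed = 1)
  }
  dCoarse <- diffusionCoef(fitFrap(mk(8, 0.008)))
  dFine <- diffusionCoef(fitFrap(mk(16, 0.004)))
  expect_lt(abs(dFine / dCoarse - 1), 0.005)
})

test_that("stack CSV round trip preserves data and feeds the fit", {
  stack <- generateFrapStack(dTrue = 8, noiseSd = 0.01, seed = 9)
  path <- file.path(withr::local_tempdir(), "stack.csv")
  writeLineProfileStack(stack, path)
  back <- readLineProfileStack(path, nPrebleach = 3L)
  expect_equal(positions(back), positions(stack), tolerance = 1e-12)
  expect_equal(frameTimes(back), frameTimes(stack), tolerance = 1e-12)
  expect_equal(intensities(back), intensities(stack), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(prebleachProfile(back), prebleachProfile(stack),
               tolerance = 1e-9)
  expect_equal(diffusionCoef(fitFrap(back)), diffusionCoef(fitFrap(stack)),
               tolerance = 1e-6)
})

test_that("degenerate fit inputs are rejected", {
  stack <- generateFrapStack(dTrue = 1, noiseSd = 0, seed = 1, nFrames = 3)
  expect_error(fitFrap(stack, dBounds = c(0, 50)), "dBounds")
  expect_error(fitFrap(stack, dBounds = c(5, 1)), "dBounds")
  x <- seq(0, 3, by = 0.375)
  two <- lineProfileStack(x, c(0, 0.004),
                          matrix(runif(2 * length(x)), 2, length(x)))
  expect_error(fitFrap(two), "3 frames")
})
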