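test_that("angular error is exactly zero against the phantom's own ground truth", {
  ph <- simulateFibers(simulationConfig(volumeShape = c(64L, 64L, 64L),
                                        nFibersRange = c(4, 7),
                                        diameterRangeVox = c(4, 8),
                                        rngSeed = 2L))
  sk <- skeletonMask(skeletonize3D(phantomVolume(ph)))
  co <- which(sk, arr.ind = TRUE)
  lab <- phantomLabels(ph)[co]
  fib <- fiberTable(ph)
  m <- match(lab, fib$label)
  keep <- !is.na(m)
  est <- new("OrientationField", coords = co[keep, , drop = FALSE],
             thetaDeg = fib$theta_deg[m[keep]], phiDeg = fib$phi_deg[m[keep]],
             windowVox = 32, gradientSigmaVox = 1, diagnostics = list())
  e <- angularError(est, ph)
  expect_identical(e$mean_azimuth_err_deg, 0)
  expect_identical(e$mean_elevation_err_deg, 0)
})

test_that("azimuth error is wraparound-aware across the +-90 seam", {
  ph <- tinyPhantom(-89, 10)
  est <- orientationFieldAt(cbind(4L, 4L, 4L), 89, 10)
  e <- angularError(est, ph)
  expect_equal(e$mean_azimuth_err_deg, 2)
  expect_error(angularError(
    orientationFieldAt(matrix(integer(), 0, 3), 0, 0), ph), "empty")
})

test_that("a single-window sweep equals a direct error computation and warns on oversized windows", {
  ph <- simulateFibers(alignedConfig(64, c(4, 7), seed = 14,
                                     diameter = c(4, 9)))
  sw <- windowSweep(ph, windows = c(32))
  sk <- skeletonize3D(phantomVolume(ph))
  est <- estimateTensorOrientation(phantomVolume(ph) + 0, sk, 32)
  direct <- angularError(est, ph)
  expect_equal(sw$mean_azimuth_err_deg, direct$mean_azimuth_err_deg)
  expect_equal(sw$n_points, direct$n_points)
  expect_warning(sw2 <- windowSweep(ph, windows = c(32, 128)), "skipping")
  expect_identical(nrow(sw2), 1L)
})

test_that("the zero-noise sweep row matches the clean-phantom error", {
  ph <- simulateFibers(alignedConfig(64, c(4, 7), seed = 15,
                                     diameter = c(4, 9)))
  ns <- noiseSweep(ph, sigmas = 0, sigmaSmooth = 0, rngSeed = 1L)
  sk <- skeletonize3D(phantomVolume(ph))
  est <- estimateTensorOrientation(phantomVolume(ph) + 0, sk, 32)
  direct <- angularError(est, ph)
  expect_equal(ns$mean_azimuth_err_deg, direct$mean_azimuth_err_deg,
               tolerance = 1e-9)
  expect_false(ns$flagged)
})

test_that("the angular-range scan recovers single fibers on a coarse smoke grid", {
  scan <- angularRangeScan(stepDeg = 45, windowVox = 32, side = 64,
                           diameterVox = 9)
  expect_identical(nrow(scan), 5L * 3L)
  expect_true(all(scan$n_points > 0))
  expect_true(all(scan$max_axis_err_deg <= 5))
  best <- scan[scan$theta_deg == 0 & scan$phi_deg == 0, ]
  expect_lt(best$max_axis_err_deg, 1)
})
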