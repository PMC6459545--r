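test_that("ray casting recovers an analytic cylinder diameter within one voxel", {
  vol <- centeredCylinder(64, 0, 90, 12, 48) # along z (phi = 90)
  co <- cbind(32L, 32L, 17:47) # exact axial voxels, interior
  orient <- orientationFieldAt(co, 0, 90)
  dm <- estimateDiameter(vol, orient, nRays = 16, stepVox = 0.5)
  expect_identical(nrow(dm@coords), nrow(co))
  expect_lt(abs(mean(dm@diameterVox) - 12), 1)
  expect_false(any(dm@censored))
})

test_that("a one-voxel line reports the minimal diameter", {
  v <- array(FALSE, dim = c(32, 32, 32))
  v[8:24, 16, 16] <- TRUE
  orient <- orientationFieldAt(cbind(10:22, 16L, 16L), 0, 0)
  dm <- estimateDiameter(v, orient)
  expect_true(all(abs(dm@diameterVox - 1) <= 0.5))
})

test_that("diameter estimates are scale-equivariant and rotation-robust", {
  est <- function(theta, phi, d) {
    vol <- centeredCylinder(72, theta, phi, d, 52)
    sk <- skeletonize3D(vol)
    o <- estimateTensorOrientation(vol + 0, sk, 32)
    mean(estimateDiameter(vol, o)@diameterVox)
  }
  d8 <- est(0, 0, 8)
  d16 <- est(0, 0, 16)
  expect_lt(abs(d16 - 2 * d8), 1)
  vals <- c(est(0, 0, 10), est(45, 30, 10), est(27, 15, 10))
  expect_lt(max(vals) - min(vals), 1)
})

test_that("skeleton voxels off the foreground are skipped with a diagnostic", {
  v <- array(FALSE, dim = c(24, 24, 24))
  v[6:18, 10:14, 10:14] <- TRUE
  co <- rbind(cbind(12L, 12L, 12L), cbind(2L, 2L, 2L)) # second is background
  dm <- estimateDiameter(v, orientationFieldAt(co, 0, 0))
  expect_identical(nrow(dm@coords), 1L)
  expect_identical(dm@diagnostics$nOffForeground, 1L)
})

test_that("a giant blob is censored at the marching limit", {
  v <- array(TRUE, dim = c(40, 40, 40))
  dm <- estimateDiameter(v, orientationFieldAt(cbind(20L, 20L, 20L), 0, 0),
                         maxMarchVox = 5)
  expect_true(all(dm@censored))
  expect_equal(unname(dm@diameterVox), 10, tolerance = 1e-9)
})

test_that("phantom diameters match ground truth within a voxel and the EDT oracle within 1.5", {
  ph <- simulateFibers(simulationConfig(volumeShape = c(96L, 96L, 96L),
                                        nFibersRange = c(6, 10),
                                        diameterRangeVox = c(4, 12),
                                        rngSeed = 17L))
  vol <- phantomVolume(ph) > 0
  sk <- skeletonize3D(vol)
  o <- estimateTensorOrientation(vol + 0, sk, 32)
  dm <- estimateDiameter(vol, o)
  tab <- diameterTable(dm)
  lab <- phantomLabels(ph)[as.matrix(tab[, c("x", "y", "z")])]
  truth <- fiberTable(ph)$diameter_vox[match(lab, fiberTable(ph)$label)]
  expect_lt(mean(abs(tab$diameter_vox - truth)), 1)
  edt <- oracleEDT(vol)
  oracle <- 2 * edt[as.matrix(tab[, c("x", "y", "z")])]
  expect_lt(mean(abs(tab$diameter_vox - oracle)), 1.5)
})
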