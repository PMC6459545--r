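test_that("vector/angle conversion follows the spherical convention and canonical flip", {
  expect_equal(unname(vectorToAngles(c(1, 0, 0))), c(0, 0))
  expect_equal(unname(vectorToAngles(c(0, 0, 1))), c(0, 90))
  # the aligned-dataset direction, negated: the flip restores (27, 15)
  v <- -c(cos(15 * pi / 180) * cos(27 * pi / 180),
          cos(15 * pi / 180) * sin(27 * pi / 180),
          sin(15 * pi / 180))
  expect_equal(unname(vectorToAngles(v)), c(27, 15), tolerance = 1e-9)
  expect_error(vectorToAngles(c(0, 0, 0)), "zero")
})

test_that("angles -> vector -> angles round-trips on a grid, with v and -v identical", {
  grid <- expand.grid(theta = seq(-85, 90, by = 12.5), phi = seq(0, 90, by = 10))
  v <- anglesToVector(grid$theta, grid$phi)
  back <- vectorToAngles(v)
  # azimuth is degenerate at the pole phi = 90
  offPole <- grid$phi < 90
  expect_equal(back[offPole, 1], grid$theta[offPole], tolerance = 1e-9)
  expect_equal(back[, 2], grid$phi, tolerance = 1e-9)
  expect_equal(vectorToAngles(-v), back, tolerance = 1e-12)
})

test_that("tensor orientation recovers a noiseless axis-aligned cylinder to 2 degrees", {
  vol <- centeredCylinder(96, 0, 0, 9, 72)
  sk <- skeletonize3D(vol)
  est <- estimateTensorOrientation(vol + 0, sk, windowVox = 32)
  tab <- orientationTable(est)
  interior <- abs(tab$x - 48.5) <= (36 - 16) # away from the fiber ends
  expect_gt(sum(interior), 10)
  expect_lt(max(pmin(abs(tab$theta_deg[interior]),
                     180 - abs(tab$theta_deg[interior]))), 2)
  expect_lt(max(abs(tab$phi_deg[interior])), 2)
})

test_that("tensor estimates are equivariant under a 90-degree rotation about Z", {
  vol <- centeredCylinder(80, 30, 0, 7, 56)
  rotZ <- function(a) {
    b <- aperm(a, c(2, 1, 3))
    b[rev(seq_len(dim(b)[1])), , , drop = FALSE]
  }
  est1 <- estimateTensorOrientation(vol + 0, skeletonize3D(vol), 32)
  vol2 <- rotZ(vol)
  est2 <- estimateTensorOrientation(vol2 + 0, skeletonize3D(vol2), 32)
  med1 <- stats::median(est1@thetaDeg)
  med2 <- stats::median(est2@thetaDeg)
  shift <- abs(med1 - med2)
  expect_lt(abs(pmin(shift, 180 - shift) - 90), 0.5)
  expect_lt(abs(stats::median(est1@phiDeg) - stats::median(est2@phiDeg)), 0.5)
})

test_that("tensor estimator recovers analytic cylinders across a coarse angular grid", {
  grid <- expand.grid(theta = seq(-90, 90, by = 30), phi = seq(0, 90, by = 30))
  for (i in seq_len(nrow(grid))) {
    vol <- centeredCylinder(64, grid$theta[i], grid$phi[i], 9, 48)
    est <- estimateTensorOrientation(vol + 0, skeletonize3D(vol), 32)
    err <- fibramorph:::.axisAngle(est@thetaDeg, est@phiDeg,
                                   grid$theta[i], grid$phi[i])
    expect_lt(max(err), 3,
              label = sprintf("axis error at theta=%g phi=%g",
                              grid$theta[i], grid$phi[i]))
  }
})

test_that("a flat volume yields no orientation entries, only diagnostics", {
  v <- array(0, dim = c(24, 24, 24))
  sk <- array(FALSE, dim = dim(v)); sk[12, 12, 12] <- TRUE
  est <- estimateTensorOrientation(v, sk, windowVox = 8)
  expect_identical(nrow(est@coords), 0L)
  expect_identical(est@diagnostics$nFlat, 1L)
})

test_that("Fourier orientation finds stripe directions and flags isotropy", {
  r0 <- estimateFourierOrientation(stripeImage(128, 0))
  expect_lt(abs(r0$theta_deg), 1)
  expect_gt(r0$anisotropy, 0.9)
  r35 <- estimateFourierOrientation(stripeImage(128, 35))
  expect_lt(abs(r35$theta_deg - 35), 2)
  set.seed(99)
  aniso <- replicate(20, {
    estimateFourierOrientation(matrix(rnorm(128 * 128), 128, 128))$anisotropy
  })
  expect_lt(max(aniso), 0.1)
  set.seed(100)
  expect_false(estimateFourierOrientation(
    matrix(rnorm(128 * 128), 128, 128))$reliable)
  expect_error(estimateFourierOrientation(matrix(1, 32, 32)), "constant")
})
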