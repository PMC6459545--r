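test_that("aligned configuration fixes every fiber's angles and the phantom is consistent", {
  cfg <- alignedConfig(64, c(4, 8), seed = 11)
  ph <- simulateFibers(cfg)
  fib <- fiberTable(ph)
  expect_gt(nrow(fib), 0)
  expect_true(all(abs(fib$theta_deg - 27) < 1e-9))
  expect_true(all(abs(fib$phi_deg - 15) < 1e-9))
  expect_true(validObject(ph))
  # direction slot is the unit vector implied by the angles
  d <- as.matrix(fib[, c("dir_x", "dir_y", "dir_z")])
  expect_equal(sqrt(rowSums(d^2)), rep(1, nrow(fib)), tolerance = 1e-9)
  expect_equal(unname(vectorToAngles(d)[, 1]), fib$theta_deg, tolerance = 1e-9)
})

test_that("a zero-fiber stop rule yields an empty phantom and a degenerate config only warns", {
  cfg <- simulationConfig(volumeShape = c(32L, 32L, 32L),
                          stopRule = "max_fibers", stopParam = 0)
  ph <- suppressWarnings(simulateFibers(cfg))
  expect_identical(nrow(fiberTable(ph)), 0L)
  expect_true(all(phantomVolume(ph) == 0))
  # diameter larger than the volume: all candidates rejected, warning not error
  bad <- simulationConfig(volumeShape = c(32L, 32L, 32L),
                          diameterRangeVox = c(64, 64),
                          maxFailedAttempts = 5)
  expect_warning(ph2 <- simulateFibers(bad), "no fibers")
  expect_identical(nrow(fiberTable(ph2)), 0L)
})

test_that("invalid ranges are rejected at construction", {
  expect_error(simulationConfig(azimuthRangeDeg = c(45, -45)), "lo <= hi")
  expect_error(simulationConfig(elevationRangeDeg = c(0, 120)), "within")
  expect_error(simulationConfig(diameterRangeVox = c(0.5, 3)), "within")
})

test_that("rasterization matches the exhaustive point-to-segment oracle", {
  shape <- c(48L, 48L, 48L)
  center <- c(24.3, 23.7, 24.1)
  for (ang in list(c(0, 0), c(27, 15), c(-60, 50))) {
    dir <- as.numeric(anglesToVector(ang[1], ang[2]))
    got <- fibramorph:::.cylinderVoxels(shape, center, dir, 4.5, 15)
    want <- oracleCylinderMask(shape, center, dir, 4.5, 15)
    mask <- array(FALSE, shape)
    mask[got$coords] <- TRUE
    expect_identical(mask, want, label = paste("angles", ang[1], ang[2]))
  }
  # analytic volume check: radius 4.5, length 100 cylinder along x
  vol <- centeredCylinder(128, 0, 0, 9, 100)
  expect_lt(abs(sum(vol) - pi * 4.5^2 * 100) / (pi * 4.5^2 * 100), 0.1)
})

test_that("phantom generation is bit-reproducible from the seed", {
  cfg <- alignedConfig(48, c(3, 5), seed = 42, diameter = c(3, 6))
  ph1 <- simulateFibers(cfg)
  ph2 <- simulateFibers(cfg)
  expect_identical(phantomLabels(ph1), phantomLabels(ph2))
  expect_identical(fiberTable(ph1), fiberTable(ph2))
  cfg3 <- alignedConfig(48, c(3, 5), seed = 43, diameter = c(3, 6))
  expect_false(identical(phantomLabels(ph1),
                         phantomLabels(simulateFibers(cfg3))))
})

test_that("non-intersecting fibers keep at least the configured gap", {
  cfg <- simulationConfig(volumeShape = c(72L, 72L, 72L),
                          nFibersRange = c(6, 10),
                          diameterRangeVox = c(3, 8),
                          gapRangeVox = c(3, 3), rngSeed = 5L)
  ph <- simulateFibers(cfg)
  lab <- phantomLabels(ph)
  ids <- sort(unique(lab[lab > 0]))
  expect_gt(length(ids), 1)
  for (i in ids) {
    dist2i <- oracleEDT(array(lab != i, dim = dim(lab))) # distance to fiber i
    others <- dist2i[lab > 0 & lab != i]
    expect_gte(min(others), 3)
  }
})

test_that("ground-truth direction agrees with the voxel cloud's principal axis", {
  cfg <- simulationConfig(volumeShape = c(96L, 96L, 96L),
                          nFibersRange = c(5, 8),
                          diameterRangeVox = c(3, 5),
                          lengthFractionRange = c(0.6, 0.8), rngSeed = 9L)
  ph <- simulateFibers(cfg)
  fib <- fiberTable(ph)
  lab <- phantomLabels(ph)
  long <- fib[fib$length_vox >= 10 * fib$diameter_vox, ]
  expect_gt(nrow(long), 0)
  for (i in seq_len(nrow(long))) {
    co <- which(lab == long$label[i], arr.ind = TRUE)
    ev <- eigen(stats::cov(co), symmetric = TRUE)$vectors[, 1]
    dirTrue <- as.numeric(long[i, c("dir_x", "dir_y", "dir_z")])
    angle <- acos(min(1, abs(sum(ev * dirTrue)))) * 180 / pi
    expect_lt(angle, 3)
  }
})

test_that("sampled fiber parameters respect their ranges and look uniform", {
  cfg <- simulationConfig(volumeShape = c(64L, 64L, 64L),
                          nFibersRange = c(250, 250),
                          azimuthRangeDeg = c(-80, 80),
                          elevationRangeDeg = c(5, 85),
                          diameterRangeVox = c(3, 8),
                          allowIntersections = TRUE,
                          maxFailedAttempts = 10000, rngSeed = 21L)
  ph <- simulateFibers(cfg)
  fib <- fiberTable(ph)
  expect_gte(nrow(fib), 200)
  expect_true(all(fib$diameter_vox >= 3 & fib$diameter_vox <= 8))
  expect_true(all(fib$theta_deg >= -80 & fib$theta_deg <= 80))
  expect_true(all(fib$phi_deg >= 5 & fib$phi_deg <= 85))
  suppressWarnings({
    expect_gt(stats::ks.test(fib$diameter_vox, "punif", 3, 8)$p.value, 0.01)
    expect_gt(stats::ks.test(fib$theta_deg, "punif", -80, 80)$p.value, 0.01)
    expect_gt(stats::ks.test(fib$phi_deg, "punif", 5, 85)$p.value, 0.01)
  })
})

test_that("contamination applies noise then smoothing, reproducibly", {
  v <- array(0, dim = c(24, 24, 24))
  expect_identical(contaminateVolume(v, 0, 0), v)
  expect_error(contaminateVolume(v, -1, 0), ">= 0")
  # CLT bound on the sample sd of 64^3 iid N(0,1) draws
  z <- array(0, dim = c(64, 64, 64))
  n1 <- contaminateVolume(z, 1.0, 0, rngSeed = 7L)
  expect_gt(stats::sd(n1), 0.98)
  expect_lt(stats::sd(n1), 1.02)
  expect_identical(n1, contaminateVolume(z, 1.0, 0, rngSeed = 7L))
  # smoothing shrinks white-noise variance
  n2 <- contaminateVolume(z, 1.0, 1.0, rngSeed = 7L)
  expect_lt(stats::sd(n2), 0.3)
})
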