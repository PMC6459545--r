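test_that("porosity is exact voxel counting with a conservation identity", {
  z <- array(0L, dim = c(10, 10, 10))
  expect_equal(calcPorosity(z)$porosity, 1.0)
  expect_equal(calcPorosity(z + 1L)$porosity, 0.0)
  v <- z; v[seq_len(100)] <- 1L
  res <- calcPorosity(v)
  expect_equal(unname(res$perMaterial["1"]), 0.1)
  expect_equal(res$porosity, 0.9)
  # multi-material conservation
  set.seed(8)
  m <- array(sample(0:4, 6^3, replace = TRUE), dim = c(6, 6, 6))
  r <- calcPorosity(m)
  expect_equal(r$porosity + sum(r$perMaterial), 1, tolerance = 1e-12)
  expect_error(calcPorosity(array(-1L, dim = c(4, 4, 4))), "non-negative")
})

test_that("object counting honours voxel connectivity semantics", {
  expect_identical(nrow(objectCounter(array(FALSE, dim = c(8, 8, 8)))), 0L)
  v <- array(FALSE, dim = c(8, 8, 8))
  v[3, 3, 3] <- TRUE; v[4, 4, 4] <- TRUE # corner-touching pair
  expect_identical(nrow(objectCounter(v, connectivity = 26)), 1L)
  t26 <- objectCounter(v, connectivity = 26)
  expect_identical(t26$voxel_count, 2L)
  t6 <- objectCounter(v, connectivity = 6)
  expect_identical(t6$voxel_count, c(1L, 1L))
})

test_that("sphere morphometrics match a brute-force rasterization oracle", {
  shape <- c(48L, 48L, 48L)
  centers <- rbind(c(12, 12, 12), c(34, 14, 30), c(20, 36, 38))
  v <- array(FALSE, dim = shape)
  co <- as.matrix(expand.grid(x = 1:48, y = 1:48, z = 1:48))
  counts <- integer(3)
  for (i in 1:3) {
    d2 <- rowSums(sweep(co, 2, centers[i, ])^2)
    inside <- d2 <= 16 # radius 4
    counts[i] <- sum(inside)
    v[co[inside, , drop = FALSE]] <- TRUE
  }
  tab <- objectCounter(v, connectivity = 26)
  expect_identical(nrow(tab), 3L)
  expect_setequal(tab$voxel_count, counts)
  expect_equal(sum(tab$voxel_count), sum(v)) # conservation
  expect_equal(tab$equivalent_diameter_vox,
               (6 * tab$voxel_count / pi)^(1 / 3))
  # centroids recover the sphere centres
  got <- tab[order(tab$centroid_x), c("centroid_x", "centroid_y", "centroid_z")]
  want <- centers[order(centers[, 1]), ]
  expect_equal(unname(as.matrix(got)), want, tolerance = 0.01)
})

test_that("component count equals the number of generated objects at scale", {
  # grid of 600 disjoint small spheres (radius 2, comfortably separated)
  v <- array(FALSE, dim = c(90L, 90L, 60L))
  off <- as.matrix(expand.grid(x = seq(5, 86, by = 9),
                               y = seq(5, 86, by = 9),
                               z = seq(5, 55, by = 9)))
  n <- nrow(off)
  ball <- as.matrix(expand.grid(dx = -2:2, dy = -2:2, dz = -2:2))
  ball <- ball[rowSums(ball^2) <= 4, ]
  for (i in seq_len(n)) v[sweep(ball, 2, off[i, ], "+")] <- TRUE
  expect_gte(n, 500)
  expect_identical(nrow(objectCounter(v, connectivity = 26)), n)
  # and a phantom's label volume has exactly one component per fiber
  ph <- simulateFibers(simulationConfig(volumeShape = c(64L, 64L, 64L),
                                        nFibersRange = c(5, 8),
                                        diameterRangeVox = c(3, 6),
                                        rngSeed = 31L))
  expect_identical(nrow(objectCounter(phantomVolume(ph) > 0, 26)),
                   nrow(fiberTable(ph)))
})

test_that("pre-labeled volumes are measured as-is", {
  v <- array(0L, dim = c(10, 10, 10))
  v[2:3, 2:3, 2:3] <- 5L
  v[8, 8, 8] <- 9L
  tab <- objectCounter(v)
  expect_identical(tab$label, c(5L, 9L))
  expect_identical(tab$voxel_count, c(8L, 1L))
})
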