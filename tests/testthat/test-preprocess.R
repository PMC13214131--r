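# Harmonization chain: sanitization, resampling, shape standardization,
# normalization, body masking, cropping, augmentation.

test_that("sanitize replaces exactly the non-finite voxels by zero", {
  g <- array(rnorm(27), c(3, 3, 3))
  v0 <- sanitizeVolume(CTVolume(g))
  expect_identical(gridData(v0), g)
  g[1, 1, 1] <- NaN
  g[2, 2, 2] <- Inf
  v <- sanitizeVolume(CTVolume(g))
  expect_identical(gridData(v)[1, 1, 1], 0)
  expect_identical(gridData(v)[2, 2, 2], 0)
  expect_identical(gridData(v)[-c(1, 14)], g[-c(1, 14)])
  allnan <- sanitizeVolume(CTVolume(array(NaN, c(2, 2, 2))))
  expect_identical(gridData(allnan), array(0, c(2, 2, 2)))
})

test_that("isotropic resampling follows the shape arithmetic and preserves constants", {
  v <- CTVolume(array(rnorm(64 * 16 * 16), c(64, 16, 16)), spacing = c(0.5, 1, 1))
  r <- resampleIsotropic(v, 1.0)
  expect_identical(dim(gridData(r)), c(32L, 16L, 16L))
  expect_identical(voxelSpacing(r), c(1, 1, 1))
  # identity resample
  same <- resampleIsotropic(CTVolume(gridData(v), spacing = c(1, 1, 1)), 1.0)
  expect_equal(gridData(same), gridData(v), tolerance = 1e-12)
  # constants survive any resampling
  const <- CTVolume(array(7, c(10, 12, 14)), spacing = c(0.7, 1.3, 2))
  rc <- resampleIsotropic(const, 1.0)
  expect_true(all(abs(gridData(rc) - 7) < 1e-12))
  expect_error(resampleIsotropic(v, 0), "positive")
})

test_that("label resampling is nearest-neighbour and never grows the label set", {
  g <- array(0L, c(10, 10, 10))
  g[3:5, 3:5, 3:5] <- 2L
  m <- SinusLabels(g, spacing = c(0.5, 0.5, 0.5))
  r <- resampleIsotropic(m, 1.0)
  expect_true(all(gridData(r) %in% c(0L, 2L)))
  expect_identical(dim(gridData(r)), c(5L, 5L, 5L))
})

test_that("shape standardization crops and pads per the index contract", {
  ramp <- array(seq_len(12^3), c(12, 12, 12))
  v <- standardizeShape(CTVolume(ramp), c(8, 8, 8))
  # 12 -> 8 keeps 0-based half-open [2, 10) on every axis
  expect_identical(gridData(v), ramp[3:10, 3:10, 3:10])
  small <- array(1.0, c(5, 5, 5))
  p <- standardizeShape(CTVolume(small), c(8, 8, 8))
  expect_identical(dim(gridData(p)), c(8L, 8L, 8L))
  expect_true(all(gridData(p)[2:6, 2:6, 2:6] == 1))   # pad 1 low / 2 high
  expect_true(all(gridData(p)[c(1, 7, 8), , ] == 0))
  ident <- standardizeShape(CTVolume(small), c(5, 5, 5))
  expect_identical(gridData(ident), small)
})

test_that("min-max normalization clips to the window and maps it onto [0, 1]", {
  v <- CTVolume(array(c(-1000, 500, 2000, 5000, -2000, 0),
                      c(6, 1, 1)))
  n <- normalizeMinMax(v, c(-1000, 2000))
  expect_equal(as.vector(gridData(n))[1:4], c(0, 0.5, 1, 1))
  expect_equal(as.vector(gridData(n))[5], 0)  # below lo clips to 0
  expect_identical(intensityDomain(n), "normalized")
  expect_error(normalizeMinMax(v, c(10, 10)), "lo < hi")
})

test_that("body mask keeps the largest component and fills internal cavities", {
  allbone <- CTVolume(array(500, c(6, 6, 6)))
  expect_true(all(bodyMask(allbone)))
  # two disjoint blobs: only the larger survives (component counting oracle)
  g <- array(-1000, c(12, 12, 12))
  g[2:7, 2:7, 2:7] <- 100
  g[10:11, 10:11, 10:11] <- 100
  bm <- bodyMask(CTVolume(g))
  expect_true(all(bm[2:7, 2:7, 2:7]))
  expect_false(any(bm[10:11, 10:11, 10:11]))
  # phantom: labeled cavity voxels lie inside the hole-filled mask, matching
  # an independent border flood-fill oracle
  s <- generatePhantom(tiny_spec(seed = 21))
  bm2 <- bodyMask(phantomVolume(s))
  lab <- gridData(phantomLabels(s))
  expect_true(all(bm2[lab > 0]))
  thr <- gridData(phantomVolume(s)) >= -500
  outside <- flood_fill_outside(thr)
  expect_true(all(bm2 == !outside))
  expect_error(bodyMask(CTVolume(array(-1000, c(3, 3, 3)))), "empty body mask")
})

test_that("mask-guided cropping obeys bounding-box arithmetic with clamping", {
  g <- array(rnorm(1000), c(10, 10, 10))
  m <- array(0L, c(10, 10, 10))
  m[] <- 1L
  full <- maskGuidedCrop(CTVolume(g), m, 0L)
  expect_identical(dim(gridData(full$volume)), c(10L, 10L, 10L))
  m2 <- array(0L, c(10, 10, 10))
  m2[5, 5, 5] <- 1L
  cr <- maskGuidedCrop(CTVolume(g), m2, 2L)
  expect_identical(dim(gridData(cr$volume)), c(5L, 5L, 5L))
  big <- maskGuidedCrop(CTVolume(g), m2, 50L)
  expect_identical(dim(gridData(big$volume)), c(10L, 10L, 10L))
  expect_error(maskGuidedCrop(CTVolume(g), array(0L, c(10, 10, 10))), "empty")
})

test_that("intensity augmentation is seeded, identity at unit ranges, and follows the power law", {
  v <- CTVolume(array(runif(64), c(4, 4, 4)), domain = "normalized")
  id <- augmentIntensity(v, c(1, 1), c(1, 1), seed = 1)
  expect_equal(gridData(id), gridData(v), tolerance = 1e-15)
  a1 <- augmentIntensity(v, c(0.8, 1.2), c(0.9, 1.1), seed = 7)
  a2 <- augmentIntensity(v, c(0.8, 1.2), c(0.9, 1.1), seed = 7)
  expect_identical(gridData(a1), gridData(a2))
  g2 <- augmentIntensity(CTVolume(array(0.5, c(2, 2, 2)), domain = "normalized"),
                         c(2, 2), c(1, 1), seed = 1)
  expect_equal(as.vector(gridData(g2)), rep(0.25, 8))
  expect_error(augmentIntensity(v, c(-1, 1), c(1, 1), 1), "positive")
  expect_error(augmentIntensity(CTVolume(array(0, c(2, 2, 2))), seed = 1),
               "normalized")
})

test_that("the full chain maps random phantoms to the target shape in [0, 1] without growing labels", {
  set.seed(33)
  for (i in 1:3) {
    sp <- tiny_spec(noiseSdHu = runif(1, 0, 15), blurSigmaVox = runif(1, 0, 1),
                    intensityShiftHu = runif(1, -40, 40),
                    cavityScale = runif(1, 0.9, 1.1), seed = i)
    s <- generatePhantom(sp)
    pp <- preprocessVolume(phantomVolume(s), phantomLabels(s),
                           targetShape = c(40L, 40L, 40L))
    expect_identical(dim(gridData(pp$volume)), c(40L, 40L, 40L))
    expect_true(min(gridData(pp$volume)) >= 0 && max(gridData(pp$volume)) <= 1)
    expect_true(all(unique(gridData(pp$labels)) %in%
                    unique(gridData(phantomLabels(s)))))
  }
})

test_that("resample round trip of a smooth volume has small interpolation error", {
  ax <- seq(0, 2 * pi, length.out = 24)
  g <- outer(outer(sin(ax), cos(ax), "+"), sin(ax / 2), "+") / 3
  v <- CTVolume(g, spacing = c(1, 1, 1))
  up <- resampleIsotropic(v, 0.5)
  back <- resampleIsotropic(up, 1.0)
  expect_identical(dim(gridData(back)), dim(g))
  expect_lt(mean(abs(gridData(back) - g)), 0.02)
})
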