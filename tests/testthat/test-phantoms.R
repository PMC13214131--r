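# Phantom generator: geometry, anomalies, determinism, cohort contract.

test_that("anomaly 'none' yields an empty anomaly mask and seeded generation is bit-identical", {
  s1 <- generatePhantom(tiny_spec(seed = 11))
  s2 <- generatePhantom(tiny_spec(seed = 11))
  expect_identical(sum(anomalyMask(s1) != 0), 0L)
  expect_identical(gridData(phantomVolume(s1)), gridData(phantomVolume(s2)))
  expect_identical(gridData(phantomLabels(s1)), gridData(phantomLabels(s2)))
  expect_identical(anomalyMask(s1), anomalyMask(s2))
})

test_that("label values stay in 0..4 and every compartment is present bilaterally", {
  s <- generatePhantom(phantomSpec(seed = 3))
  lab <- gridData(phantomLabels(s))
  expect_true(all(lab %in% 0:4))
  expect_setequal(sort(unique(lab[lab > 0])), 1:4)
  # each label must occupy two disconnected components (left/right),
  # except the ethmoid whose sub-cells multiply the count
  d <- dim(lab)
  for (k in c(1, 3, 4)) {
    comp <- sinusct:::labelComponents6(as.integer(lab == k), as.integer(d))
    expect_identical(max(comp), 2L)
  }
})

test_that("noiseless cavity voxel count matches a brute-force voxelization oracle within 15%", {
  spec <- phantomSpec(noiseSdHu = 0, blurSigmaVox = 0)
  s <- generatePhantom(spec)
  lab <- gridData(phantomLabels(s))
  d <- spec@gridShape
  # independent oracle: count voxel centers inside any cavity ellipsoid,
  # rebuilt from the generator's stated relative geometry
  cav <- sinusct:::cavity_table(spec@cavityScale)
  xs <- (seq_len(d[1]) - 0.5) / d[1]
  ys <- (seq_len(d[2]) - 0.5) / d[2]
  zs <- (seq_len(d[3]) - 0.5) / d[3]
  inside <- array(FALSE, d)
  for (i in seq_len(nrow(cav))) {
    rho2 <- outer(outer(((xs - cav$cx[i]) / cav$rx[i])^2,
                        ((ys - cav$cy[i]) / cav$ry[i])^2, "+"),
                  ((zs - cav$cz[i]) / cav$rz[i])^2, "+")
    inside <- inside | (rho2 <= 1)
  }
  oracle_count <- sum(inside)
  impl_count <- sum(lab > 0)
  expect_lt(abs(impl_count - oracle_count) / oracle_count, 0.15)
})

test_that("total opacification at strength 1 sets the affected cavity exactly to fluid HU (pre-noise)", {
  spec <- phantomSpec(anomaly = "total_opacification", anomalyStrength = 1,
                      noiseSdHu = 0, blurSigmaVox = 0, seed = 5)
  s <- generatePhantom(spec)
  am <- anomalyMask(s)
  expect_gt(sum(am), 0)
  vals <- gridData(phantomVolume(s))[am == 1]
  expect_identical(unique(vals), spec@huFluid)
})

test_that("every anomaly voxel lies inside or on the wall shell of a cavity", {
  for (a in c("wall_thickening", "partial_opacification",
              "total_opacification", "asymmetry")) {
    spec <- phantomSpec(anomaly = a, anomalyStrength = 0.6, seed = 9)
    s <- generatePhantom(spec)
    am <- anomalyMask(s)
    expect_gt(sum(am), 0)
    # reference: noiseless normal phantom of identical geometry; anomaly
    # voxels must have been cavity air there
    norm <- generatePhantom(phantomSpec(anomaly = "none", seed = 9))
    lab0 <- gridData(phantomLabels(norm))
    expect_true(all(lab0[am == 1] > 0))
  }
})

test_that("increasing noise strictly increases the deviation from the noiseless volume", {
  base <- gridData(phantomVolume(generatePhantom(tiny_spec(seed = 2))))
  sds <- vapply(c(2, 6, 12), function(ns) {
    g <- gridData(phantomVolume(generatePhantom(tiny_spec(noiseSdHu = ns, seed = 2))))
    sd(g - base)
  }, numeric(1))
  expect_true(all(diff(sds) > 0))
})

test_that("oversized cavities raise a sizing error naming the cavity", {
  expect_error(generatePhantom(phantomSpec(cavityScale = 4)),
               "cavity '.*' exceeds the grid bounds")
})

test_that("cohort manifests honor the anomaly fraction and are seed-reproducible", {
  d1 <- file.path(tempdir(), "coh1")
  d2 <- file.path(tempdir(), "coh2")
  m0 <- generateCohort(10, tiny_spec(), 0, d1, seed = 4)
  expect_identical(nrow(m0), 10L)
  expect_true(all(m0$anomaly == "none"))
  unlink(d1, recursive = TRUE)
  m1 <- generateCohort(10, tiny_spec(), 0.5, d1, seed = 4)
  m2 <- generateCohort(10, tiny_spec(), 0.5, d2, seed = 4)
  expect_identical(sum(m1$anomaly != "none"), 5L)
  expect_identical(m1$anomaly, m2$anomaly)
  expect_identical(m1$noise_sd_hu, m2$noise_sd_hu)
  expect_identical(m1$cavity_scale, m2$cavity_scale)
  # written files exist and round-trip
  expect_true(all(file.exists(m1$volume)))
  v <- readVolume(m1$volume[1])
  expect_identical(dim(gridData(v)), c(32L, 32L, 32L))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("unwritable output directories raise an I/O error", {
  expect_error(generateCohort(2, tiny_spec(), 0, "/proc/definitely/not/writable"),
               "cannot create output directory")
})
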