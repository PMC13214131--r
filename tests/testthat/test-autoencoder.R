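# Autoencoder: shapes, losses, training guards, residual semantics.

test_that("the autoencoder reconstructs at the input shape with a seeded init", {
  cfg <- caeConfig(inShape = c(32, 32, 32), encFilters = c(8, 16, 32),
                   latentDim = 64)
  m1 <- buildCAE(cfg, seed = 3)
  m2 <- buildCAE(cfg, seed = 3)
  expect_identical(m1$params, m2$params)
  v <- CTVolume(array(runif(32^3), c(32, 32, 32)), domain = "normalized")
  out <- residualMap(m1, v)
  expect_identical(dim(gridData(out$reconstruction)), c(32L, 32L, 32L))
  expect_identical(length(out$latent), 64L)
  expect_error(caeConfig(inShape = c(30, 32, 32)), "divisible")
  expect_error(caeConfig(encFilters = c(8, 8, 16)), "increasing")
})

test_that("reconstruction losses match their closed forms", {
  a <- array(1, c(2, 2, 2)); b <- array(0, c(2, 2, 2))
  expect_equal(reconLoss(a, a, "L1"), 0)
  expect_equal(reconLoss(a, a, "L2"), 0)
  expect_equal(reconLoss(a, b, "L1"), 1)
  expect_equal(reconLoss(a, b, "L2"), 1)
  x <- array(c(0.2, 0.8), c(2, 1, 1))
  xh <- array(c(0.5, 0.5), c(2, 1, 1))
  expect_equal(reconLoss(x, xh, "L1"), 0.3)
  expect_equal(reconLoss(x, xh, "L2"), 0.09)
  expect_error(reconLoss(a, array(0, c(2, 2, 1))), "shape mismatch")
})

test_that("training refuses anomalous samples, is seeded and makes progress", {
  cfg <- tiny_cae_config()
  bad <- generateCohortSamples(2, tiny_spec(), 1, seed = 5)
  expect_error(caeTrainingSet(bad, cfg), "normal samples only")
  normals <- generateCohortSamples(4, tiny_spec(), 0, seed = 6)
  vols <- caeTrainingSet(normals, cfg)
  m <- buildCAE(cfg, 1)
  t1 <- trainCAE(m, vols, epochs = 8, seed = 2)
  expect_lt(tail(t1$history, 1), t1$history[1])
  t2 <- trainCAE(m, vols, epochs = 8, seed = 2)
  expect_equal(t1$history, t2$history, tolerance = 1e-6)
  expect_error(trainCAE(m, list()), "empty")
})

test_that("a CAE trained on constant volumes reconstructs a held-out constant volume", {
  cfg <- tiny_cae_config()
  m <- buildCAE(cfg, 4)
  vols <- lapply(1:4, function(i)
    CTVolume(array(0.5, c(8, 8, 8)), domain = "normalized"))
  m <- trainCAE(m, vols, epochs = 60, seed = 1)
  held <- CTVolume(array(0.5, c(8, 8, 8)), domain = "normalized")
  out <- residualMap(m, held)
  expect_lt(reconLoss(gridData(held), gridData(out$reconstruction), "L1"), 0.01)
})

test_that("residual maps are the exact absolute difference and non-negative", {
  cfg <- tiny_cae_config()
  m <- buildCAE(cfg, 4)
  v <- CTVolume(array(runif(512), c(8, 8, 8)), domain = "normalized")
  out <- residualMap(m, v)
  expect_equal(gridData(out$residual),
               abs(gridData(v) - gridData(out$reconstruction)),
               tolerance = 1e-15)
  expect_true(min(gridData(out$residual)) >= 0)
  # reconstruction bounded in [0, 1] => L2 loss bounded by 1 for normalized x
  expect_lte(reconLoss(gridData(v), gridData(out$reconstruction), "L2"), 1)
  expect_error(residualMap(m, CTVolume(array(0.1, c(16, 16, 16)),
                                       domain = "normalized")),
               "shape")
})

test_that("anomaly contrast follows the mean-ratio definition with degenerate flags", {
  r <- array(0.5, c(4, 4, 4))
  am <- array(0L, c(4, 4, 4)); am[1:8] <- 1L
  ref <- array(0L, c(4, 4, 4)); ref[33:64] <- 1L
  expect_equal(anomalyContrast(r, am, ref), 1)
  r2 <- array(0, c(4, 4, 4)); r2[am == 1] <- 0.4; r2[ref == 1] <- 0.1
  expect_equal(anomalyContrast(r2, am, ref), 4)
  r3 <- array(0, c(4, 4, 4)); r3[am == 1] <- 1
  expect_identical(anomalyContrast(r3, am, ref), Inf)
  expect_error(anomalyContrast(r, am * 0L, ref), "empty anomaly")
  expect_error(anomalyContrast(r, am, ref * 0L), "empty reference")
})

test_that("sinus-region alignment crops around the labels and normalizes", {
  s <- generatePhantom(tiny_spec(seed = 31))
  cfg <- caeConfig(inShape = c(16, 16, 16), encFilters = c(4, 6, 8),
                   latentDim = 16)
  pp <- caePrepareSample(s, cfg)
  expect_identical(dim(gridData(pp$volume)), c(16L, 16L, 16L))
  expect_identical(intensityDomain(pp$volume), "normalized")
  expect_gt(sum(gridData(pp$labels) > 0), 0)
  # the sinus region fills a much larger share of the crop than of the head
  frac_crop <- mean(gridData(pp$labels) > 0)
  frac_head <- mean(gridData(phantomLabels(s)) > 0)
  expect_gt(frac_crop, 2 * frac_head)
})
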