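# Fused three-channel input, pretext targets, extractor training, embeddings.

make_fused <- function(seed = 1, dims = c(16L, 16L, 16L), variant = "full") {
  set.seed(seed)
  v <- CTVolume(array(runif(prod(dims)), dims), domain = "normalized")
  lg <- array(0L, dims)
  lg[3:6, 3:6, 3:6] <- 1L; lg[9:12, 3:6, 3:6] <- 2L
  lg[3:6, 9:12, 9:12] <- 3L; lg[9:12, 9:12, 9:12] <- 4L
  m <- SinusLabels(lg)
  r <- ResidualMap(array(runif(prod(dims), 0, 0.5), dims))
  list(v = v, m = m, r = r,
       f = assembleInput(v, m, r, variant))
}

test_that("channel assembly scales labels, bounds residuals and zeroes ablated channels", {
  fx <- make_fused()
  dat <- fx$f@data
  lab <- as.numeric(gridData(fx$m))
  expect_equal(dat[lab == 4, 2], rep(1, sum(lab == 4)))
  expect_equal(dat[lab == 0, 2], rep(0, sum(lab == 0)))
  expect_true(all(dat >= 0 & dat <= 1))
  f_nr <- assembleInput(fx$v, fx$m, fx$r, "no_residual")
  expect_true(all(f_nr@data[, 3] == 0))
  f_nm <- assembleInput(fx$v, fx$m, fx$r, "no_mask")
  expect_true(all(f_nm@data[, 2] == 0))
  # constant residual scales to a constant channel
  rc <- ResidualMap(array(0.2, dim(gridData(fx$v))))
  fc <- assembleInput(fx$v, fx$m, rc)
  expect_identical(length(unique(fc@data[, 3])), 1L)
  bad <- ResidualMap(array(0.1, c(8, 8, 8)))
  expect_error(assembleInput(fx$v, fx$m, bad), "aligned")
})

test_that("pretext targets are exact per-sinus residual means", {
  fx <- make_fused()
  z <- ResidualMap(array(0, dim(gridData(fx$v))))
  expect_equal(pretextTargets(fx$m, z), rep(0, 4))
  cst <- ResidualMap(array(0.2, dim(gridData(fx$v))))
  expect_equal(pretextTargets(fx$m, cst), rep(0.2, 4))
  crafted <- array(0, dim(gridData(fx$v)))
  lab <- gridData(fx$m)
  for (k in 1:4) crafted[lab == k] <- k / 10
  expect_equal(pretextTargets(fx$m, ResidualMap(crafted)),
               c(0.1, 0.2, 0.3, 0.4))
  # absent label contributes 0
  lab2 <- lab; lab2[lab2 == 2L] <- 0L
  expect_equal(pretextTargets(SinusLabels(lab2), ResidualMap(crafted))[2], 0)
})

test_that("the extractor emits fixed-length embeddings, deterministic in eval mode only", {
  fx <- make_fused()
  m <- buildExtractor(convFilters = c(4, 6, 8), embedLen = 64, seed = 2)
  e1 <- extractEmbedding(m, fx$f)
  e2 <- extractEmbedding(m, fx$f)
  expect_identical(length(e1), 64L)
  expect_true(all(is.finite(e1)))
  expect_identical(e1, e2)
  ns <- asNamespace("sinusct")
  set.seed(1); tr1 <- ns$fus_forward(m, fx$f, train = TRUE)$embedding
  set.seed(2); tr2 <- ns$fus_forward(m, fx$f, train = TRUE)$embedding
  expect_false(identical(tr1, tr2))   # dropout draws differ
})

test_that("pretext training makes seeded progress and fits the degenerate zero case", {
  set.seed(4)
  data <- lapply(1:6, function(i) {
    fx <- make_fused(seed = i)
    list(input = fx$f, target = pretextTargets(fx$m, fx$r))
  })
  m <- buildExtractor(convFilters = c(4, 6, 8), embedLen = 16, seed = 3)
  t1 <- trainExtractor(m, data, epochs = 4, seed = 5)
  expect_lt(tail(t1$history, 1), t1$history[1])
  t2 <- trainExtractor(m, data, epochs = 4, seed = 5)
  expect_equal(t1$history, t2$history, tolerance = 1e-6)
  # zero targets with a zero-initialized head: loss 0 from epoch 0
  m0 <- m
  m0$params$head$W[] <- 0
  m0$params$head$b[] <- 0
  dz <- lapply(data, function(d) list(input = d$input, target = rep(0, 4)))
  t3 <- trainExtractor(m0, dz, epochs = 1, seed = 5)
  expect_equal(t3$history[1], 0)
  expect_error(trainExtractor(m, list()), "empty")
})

test_that("structurally different phantoms embed at nonzero distance", {
  cfgc <- caeConfig(inShape = c(16, 16, 16), encFilters = c(4, 6, 8),
                    latentDim = 16)
  s1 <- generatePhantom(tiny_spec(seed = 41))
  s2 <- generatePhantom(tiny_spec(anomaly = "total_opacification",
                                  anomalyStrength = 1, seed = 41))
  m <- buildExtractor(convFilters = c(4, 6, 8), embedLen = 32, seed = 6)
  emb <- lapply(list(s1, s2), function(s) {
    pp <- caePrepareSample(s, cfgc)
    r <- ResidualMap(array(0.1, c(16, 16, 16)))
    extractEmbedding(m, assembleInput(pp$volume, pp$labels, r))
  })
  expect_gt(sqrt(sum((emb[[1]] - emb[[2]])^2)), 0)
})

test_that("the silhouette score separates well-separated groups and is symmetric in sign", {
  set.seed(7)
  a <- matrix(rnorm(40, 0), ncol = 4)
  b <- matrix(rnorm(40, 8), ncol = 4)
  s <- embeddingSilhouette(rbind(a, b), rep(c("x", "y"), each = 10))
  expect_gt(s, 0.8)
  mixed <- embeddingSilhouette(rbind(a, a * 1.0000001),
                               rep(c("x", "y"), each = 10))
  expect_lt(mixed, 0.2)
  expect_error(embeddingSilhouette(a, rep("x", 10)), "two groups")
})
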