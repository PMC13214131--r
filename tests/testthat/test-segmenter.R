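# Segmenter: construction, loss, training behaviour, prediction contracts.

test_that("builds are seed-deterministic and ablation variants shrink the graph", {
  cfg <- tiny_seg_config()
  m1 <- buildSegmenter(cfg, seed = 5)
  m2 <- buildSegmenter(cfg, seed = 5)
  expect_identical(m1$params, m2$params)
  m3 <- buildSegmenter(cfg, seed = 6)
  expect_false(identical(m1$params, m3$params))
  full <- countParameters(buildSegmenter(segConfig(), 1))
  cnn <- countParameters(buildSegmenter(segConfig(variant = "cnn_only"), 1))
  trf <- countParameters(buildSegmenter(segConfig(variant = "transformer_only"), 1))
  expect_lt(cnn, full)
  expect_lt(trf, full)
})

test_that("invalid configurations are rejected", {
  expect_error(segConfig(inShape = c(40, 40, 40), window = 3),
               "not a multiple|must be even")
  expect_error(segConfig(embedDim = 10, heads = c(3, 3, 3, 3)), "divisible")
  expect_error(segConfig(numClasses = 1), "numClasses")
})

test_that("composite loss matches its closed forms and worked fixture", {
  # single voxel, 2 classes, probs (0.5, 0.5), target class 1 -> CE = ln 2
  pr <- array(c(0.5, 0.5), c(2, 1, 1, 1))
  cl <- compositeLoss(pr, array(1L, c(1, 1, 1)), diceWeight = 0, ceWeight = 1)
  expect_equal(cl$ce, log(2))
  # one-hot probabilities: Dice component exactly 0 (up to smoothing)
  g <- array(c(0L, 1L), c(2, 1, 1))
  ph <- array(0, c(2, 2, 1, 1))
  ph[1, 1, 1, 1] <- 1; ph[2, 2, 1, 1] <- 1
  cl2 <- compositeLoss(ph, g, diceWeight = 1, ceWeight = 0)
  expect_lt(cl2$dice, 1e-5)
  # 2x1x1 worked case evaluated independently from the formula
  p1 <- c(0.7, 0.3); p2 <- c(0.2, 0.8)   # two voxels, two classes
  probs <- array(c(p1, p2), c(2, 2, 1, 1))
  tgt <- array(c(0L, 1L), c(2, 1, 1))
  sm <- 1e-5
  dice_fg <- (2 * 0.8 + sm) / ((0.3 + 0.8) + 1 + sm)
  expected <- 0.5 * (1 - dice_fg) + 0.5 * (-(log(0.7) + log(0.8)) / 2)
  got <- compositeLoss(probs, tgt, 0.5, 0.5)
  expect_equal(got$loss, expected, tolerance = 1e-12)
  expect_error(compositeLoss(probs, array(5L, c(2, 1, 1))), "exceed")
  expect_error(compositeLoss(probs, tgt, 0, 0), "> 0")
})

test_that("loss gradient on logits matches finite differences", {
  ns <- asNamespace("sinusct")
  set.seed(8)
  logits <- matrix(rnorm(20 * 3), ncol = 3)
  tgt <- sample(0:2, 20, replace = TRUE)
  lg <- ns$seg_loss_grad(logits, tgt, 0.5, 0.5)
  for (idx in list(c(3, 1), c(11, 2), c(20, 3))) {
    eps <- 1e-6
    l1 <- logits; l1[idx[1], idx[2]] <- l1[idx[1], idx[2]] + eps
    l2 <- logits; l2[idx[1], idx[2]] <- l2[idx[1], idx[2]] - eps
    num <- (ns$seg_loss_grad(l1, tgt)$loss - ns$seg_loss_grad(l2, tgt)$loss) / (2 * eps)
    expect_equal(lg$dlogits[idx[1], idx[2]], num, tolerance = 1e-6)
  }
})

test_that("whole-model parameter gradients match finite differences", {
  ns <- asNamespace("sinusct")
  set.seed(12)
  cfg <- tiny_seg_config()
  m <- buildSegmenter(cfg, seed = 5)
  x <- matrix(runif(16^3), ncol = 1)
  tgt <- sample(0:2, 16^3, replace = TRUE)
  fwd <- ns$seg_forward(m, x)
  lg <- ns$seg_loss_grad(fwd$logits, tgt)
  gr <- ns$seg_backward(m, fwd, lg$dlogits)
  leaves <- list(
    list(\(p) p$embed$W, \(p, v) { p$embed$W <- v; p }, gr$embed$W),
    list(\(p) p$stage[[3]]$conv$c1$W, \(p, v) { p$stage[[3]]$conv$c1$W <- v; p },
         gr$stage[[3]]$conv$c1$W),
    list(\(p) p$dec[[2]]$conv$W, \(p, v) { p$dec[[2]]$conv$W <- v; p },
         gr$dec[[2]]$conv$W),
    list(\(p) p$final$head$W, \(p, v) { p$final$head$W <- v; p }, gr$final$head$W))
  for (lf in leaves) {
    p0 <- lf[[1]](m$params)
    j <- which.max(abs(lf[[3]]))
    eps <- 1e-5
    ev <- function(v) {
      mm <- m; mm$params <- lf[[2]](m$params, v)
      ns$seg_loss_grad(ns$seg_forward(mm, x)$logits, tgt)$loss
    }
    p1 <- p0; p1[j] <- p1[j] + eps
    p2 <- p0; p2[j] <- p2[j] - eps
    expect_equal(lf[[3]][j], (ev(p1) - ev(p2)) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("short seeded training reduces the loss deterministically and honors pseudo-label weights", {
  cfg <- small_seg_config()
  samples <- generateCohortSamples(4, tiny_spec(), 0, seed = 91)
  ts <- segTrainingSet(samples, cfg)
  m <- buildSegmenter(cfg, seed = 2)
  t1 <- trainSegmenter(m, ts, trainOpts(lr = 1e-3, epochs = 2, batchSize = 2,
                                        seed = 3))
  expect_lt(tail(t1$history, 1), t1$history[1])
  t2 <- trainSegmenter(m, ts, trainOpts(lr = 1e-3, epochs = 2, batchSize = 2,
                                        seed = 3))
  expect_equal(t1$history, t2$history, tolerance = 1e-6)
  # pseudo-only manifest at weight zero contributes no gradient
  ts_pseudo <- segTrainingSet(samples, cfg, pseudo = TRUE)
  t3 <- trainSegmenter(m, ts_pseudo,
                       trainOpts(lr = 1e-3, epochs = 1, batchSize = 2,
                                 pseudoLabelWeight = 0, seed = 3))
  expect_identical(t3$params, m$params)
  expect_error(trainSegmenter(m, list(), trainOpts()), "empty")
})

test_that("predictions are valid probability fields with deterministic eval-mode argmax", {
  cfg <- tiny_seg_config()
  m <- buildSegmenter(cfg, seed = 5)
  v <- CTVolume(array(runif(16^3), c(16, 16, 16)), domain = "normalized")
  pr1 <- predictMask(m, v)
  pr2 <- predictMask(m, v)
  expect_identical(predictionProbs(pr1), predictionProbs(pr2))
  sums <- apply(predictionProbs(pr1), c(2, 3, 4), sum)
  expect_lt(max(abs(sums - 1)), 1e-5)
  # labels are the argmax with ties toward the lowest class
  K <- dim(predictionProbs(pr1))[1]
  mflat <- t(matrix(predictionProbs(pr1), nrow = K))
  expect_identical(as.vector(gridData(predictionLabels(pr1))),
                   max.col(mflat, ties.method = "first") - 1L)
  tie <- array(1 / 3, c(3, 2, 2, 2))
  tp <- sinusct:::seg_prediction_from_probs(tie, c(1, 1, 1))
  expect_true(all(gridData(predictionLabels(tp)) == 0L))
  expect_error(predictMask(m, CTVolume(array(0, c(16, 16, 16)), domain = "HU")),
               "normalized")
})

test_that("sliding-window inference covers volumes larger than the patch", {
  cfg <- tiny_seg_config()
  m <- buildSegmenter(cfg, seed = 5)
  v <- CTVolume(array(runif(24 * 16 * 16), c(24, 16, 16)), domain = "normalized")
  pr <- predictMask(m, v)
  expect_identical(dim(predictionProbs(pr)), c(3L, 24L, 16L, 16L))
  sums <- apply(predictionProbs(pr), c(2, 3, 4), sum)
  expect_lt(max(abs(sums - 1)), 1e-5)
})
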