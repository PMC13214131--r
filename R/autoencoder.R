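# Self-supervised 3D convolutional autoencoder.
#
# Trained only on structurally normal sinus regions, the CAE learns the
# manifold of healthy morphology; at inference the voxel-wise absolute
# difference between an input and its reconstruction (the residual map)
# highlights structural deviation. Encoder: three stride-2 conv blocks into a
# dense bottleneck; decoder mirrors with transposed convolutions and a
# logistic output squashing onto [0, 1].

#' Autoencoder configuration
#'
#' The full-scale profile is 64-cube inputs, encoder filters (32, 64, 128)
#' and a 256-dimensional latent; the CPU-scale default used in tests is a
#' 32-cube input with filters (16, 32, 64) and a 128-dimensional latent.
#' Training minimizes a voxel-wise L2 reconstruction loss by default; L1 is
#' selectable (`reconLoss = "L1"`) since both appear in common practice.
#'
#' @param inShape Input shape; every axis must be divisible by 8 (three
#'   stride-2 stages).
#' @param encFilters Strictly increasing integer triple.
#' @param latentDim Bottleneck dimension (>= 1).
#' @param reconLoss `"L2"` (default) or `"L1"`.
#' @return A `caeConfig` list.
#' @export
caeConfig <- function(inShape = c(32L, 32L, 32L), encFilters = c(16L, 32L, 64L),
                      latentDim = 128L, reconLoss = c("L2", "L1")) {
  reconLoss <- match.arg(reconLoss)
  inShape <- as.integer(inShape)
  if (any(inShape %% 8L != 0L))
    stop("inShape must be divisible by 2^3 for the three encoder stages")
  encFilters <- as.integer(encFilters)
  if (length(encFilters) != 3L || any(diff(encFilters) <= 0))
    stop("encFilters must be three strictly increasing values")
  if (latentDim < 1L) stop("latentDim must be >= 1")
  structure(list(inShape = inShape, encFilters = encFilters,
                 latentDim = as.integer(latentDim), reconLoss = reconLoss),
            class = "caeConfig")
}

#' Full-scale autoencoder configuration
#' @return A `caeConfig` with 64-cube input, filters (32,64,128), latent 256.
#' @export
caeConfigFull <- function() {
  caeConfig(inShape = c(64L, 64L, 64L), encFilters = c(32L, 64L, 128L),
            latentDim = 256L)
}

#' Build a convolutional autoencoder
#'
#' @param cfg A [caeConfig()].
#' @param seed Integer seed for the parameter draw.
#' @return Model handle of class `sinusCAE`.
#' @export
buildCAE <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "caeConfig"))
  set.seed(deriveSeed(seed, 202L))
  f <- cfg$encFilters
  bdims <- cfg$inShape %/% 8L
  nb <- prod(bdims) * f[3]
  p <- list(
    e1 = init_conv(3L, 1L, f[1]),
    e2 = init_conv(3L, f[1], f[2]),
    e3 = init_conv(3L, f[2], f[3]),
    to_latent = init_dense(nb, cfg$latentDim, sd = sqrt(1 / nb)),
    from_latent = init_dense(cfg$latentDim, nb, sd = sqrt(1 / cfg$latentDim)),
    d3 = init_convT(2L, f[3], f[2]),
    d2 = init_convT(2L, f[2], f[1]),
    d1 = init_convT(2L, f[1], 1L, gain = 1)
  )
  structure(list(config = cfg, params = p), class = "sinusCAE")
}

cae_forward <- function(model, x) {
  cfg <- model$config
  p <- model$params
  d0 <- cfg$inShape
  c1 <- conv3d_f(x, d0, p$e1, 3L, 2L); r1 <- relu_f(c1$y)
  c2 <- conv3d_f(r1, c1$odims, p$e2, 3L, 2L); r2 <- relu_f(c2$y)
  c3 <- conv3d_f(r2, c2$odims, p$e3, 3L, 2L); r3 <- relu_f(c3$y)
  flat <- matrix(as.vector(r3), nrow = 1L)
  z <- dense_f(flat, p$to_latent)      # linear latent code
  fl2 <- dense_f(z, p$from_latent)
  fr <- relu_f(fl2)
  b <- matrix(as.vector(fr), nrow = prod(c3$odims), ncol = cfg$encFilters[3])
  u3 <- convT3d_f(b, c3$odims, p$d3); ur3 <- relu_f(u3$y)
  u2 <- convT3d_f(ur3, c2$odims, p$d2); ur2 <- relu_f(u2$y)
  u1 <- convT3d_f(ur2, c1$odims, p$d1)
  xhat <- sigmoid_f(u1$y)
  list(xhat = xhat, z = as.numeric(z),
       tape = list(x = x, c1 = c1, r1 = r1, c2 = c2, r2 = r2, c3 = c3,
                   r3 = r3, flat = flat, z = z, fl2 = fl2, fr = fr,
                   b = b, u3 = u3, ur3 = ur3, u2 = u2, ur2 = ur2, xhat = xhat))
}

cae_backward <- function(model, fwd, dxhat) {
  cfg <- model$config
  p <- model$params
  tp <- fwd$tape
  g <- list()
  du1 <- sigmoid_b(dxhat, tp$xhat)
  b1 <- convT3d_b(du1, tp$ur2, tp$c1$odims, p$d1); g$d1 <- b1$grads
  dur2 <- relu_b(b1$dx, tp$u2$y)
  b2 <- convT3d_b(dur2, tp$ur3, tp$c2$odims, p$d2); g$d2 <- b2$grads
  dur3 <- relu_b(b2$dx, tp$u3$y)
  b3 <- convT3d_b(dur3, tp$b, tp$c3$odims, p$d3); g$d3 <- b3$grads
  dfr <- matrix(as.vector(b3$dx), nrow = 1L)
  dfl2 <- relu_b(dfr, tp$fl2)
  bf <- dense_b(dfl2, tp$z, p$from_latent); g$from_latent <- bf$grads
  bt <- dense_b(bf$dx, tp$flat, p$to_latent); g$to_latent <- bt$grads
  dr3 <- matrix(as.vector(bt$dx), nrow = nrow(tp$r3), ncol = ncol(tp$r3))
  dc3 <- relu_b(dr3, tp$c3$y)
  be3 <- conv3d_b(dc3, tp$r2, tp$c2$odims, p$e3, 3L, 2L); g$e3 <- be3$grads
  dc2 <- relu_b(be3$dx, tp$c2$y)
  be2 <- conv3d_b(dc2, tp$r1, tp$c1$odims, p$e2, 3L, 2L); g$e2 <- be2$grads
  dc1 <- relu_b(be2$dx, tp$c1$y)
  be1 <- conv3d_b(dc1, tp$x, cfg$inShape, p$e1, 3L, 2L); g$e1 <- be1$grads
  g[c("e1", "e2", "e3", "to_latent", "from_latent", "d3", "d2", "d1")]
}

#' Voxel-wise reconstruction loss
#'
#' L1 is the mean absolute voxel difference; L2 the mean squared difference.
#' Both are non-negative and zero iff the volumes are identical.
#'
#' @param x,xhat [CTVolume]s or numeric arrays of identical shape.
#' @param kind `"L1"` or `"L2"`.
#' @return Scalar loss.
#' @export
reconLoss <- function(x, xhat, kind = c("L2", "L1")) {
  kind <- match.arg(kind)
  gx <- if (is(x, "CTVolume")) gridData(x) else x
  gy <- if (is(xhat, "CTVolume")) gridData(xhat) else xhat
  if (!identical(dim(gx), dim(gy))) stop("shape mismatch between x and xhat")
  d <- gx - gy
  if (kind == "L1") mean(abs(d)) else mean(d * d)
}

# Tight bounding box of the labeled sinus voxels, dilated and clamped.
sinus_bbox <- function(lab, marginVox = 2L) {
  d <- dim(lab)
  idx <- which(lab != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("sample has no labeled sinus voxels to crop to")
  list(lo = pmax(apply(idx, 2L, min) - marginVox, 1L),
       hi = pmin(apply(idx, 2L, max) + marginVox, d))
}

#' Align a phantom's sinus region to the autoencoder input shape
#'
#' Crops the volume, labels and anomaly mask identically to the bounding box
#' of the labeled sinuses (with margin), resamples the crop onto the CAE
#' input grid (trilinear for intensities, nearest for masks) and normalizes
#' the volume. Resampling onto a common grid spatially aligns the sinus
#' anatomy across subjects, which the reconstruction objective needs; the
#' CAE sees sinus regions, not whole heads.
#'
#' @param sample A [PhantomSample-class], or a list with elements `volume`
#'   ([CTVolume] in HU), `labels` ([SinusLabels]) and optionally `anomaly`
#'   (binary array).
#' @param cfg A [caeConfig()].
#' @param marginVox Bounding-box margin in voxels.
#' @return List with `volume` (normalized [CTVolume]), `labels`
#'   ([SinusLabels]) and `anomaly` (binary array), all at `cfg$inShape`.
#' @export
caePrepareSample <- function(sample, cfg, marginVox = 2L) {
  if (is(sample, "PhantomSample")) {
    vol <- phantomVolume(sample)
    labs <- phantomLabels(sample)
    anom <- anomalyMask(sample)
  } else {
    vol <- sample$volume
    labs <- sample$labels
    anom <- sample$anomaly
    if (is.null(anom)) anom <- array(0L, dim = dim(gridData(vol)))
  }
  lab <- gridData(labs)
  bb <- sinus_bbox(lab, marginVox)
  lo <- bb$lo
  hi <- bb$hi
  cr <- function(a) a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sp <- voxelSpacing(vol)
  cshape <- hi - lo + 1L
  scale <- cshape / cfg$inShape
  gv <- resample_grid(cr(gridData(vol)), cfg$inShape, scale, "trilinear")
  gm <- resample_grid(cr(lab), cfg$inShape, scale, "nearest")
  ga <- resample_grid(cr(anom), cfg$inShape, scale, "nearest")
  v <- CTVolume(gv, spacing = sp * scale)
  list(volume = normalizeMinMax(v),
       labels = SinusLabels(gm, spacing = sp * scale),
       anomaly = array(as.integer(ga), dim = cfg$inShape))
}

#' Prepare a normal-only CAE training set
#'
#' Refuses anomalous samples: the autoencoder must learn the healthy manifold
#' only. Each sample is cropped to its sinus bounding box, shaped to the CAE
#' input and normalized.
#'
#' @param samples List of [PhantomSample-class] objects, all with
#'   `anomaly == "none"`.
#' @param cfg A [caeConfig()].
#' @return List of normalized [CTVolume]s.
#' @export
caeTrainingSet <- function(samples, cfg) {
  bad <- vapply(samples, function(s) phantomSpecOf(s)@anomaly != "none",
                logical(1))
  if (any(bad))
    stop(sprintf(
      "CAE training requires structurally normal samples only; %d anomalous sample(s) in manifest",
      sum(bad)))
  lapply(samples, function(s) caePrepareSample(s, cfg)$volume)
}

#' Train the autoencoder
#'
#' Adam at an initial learning rate of 1e-3 with batch size 4 and a step-wise
#' x0.1 learning-rate decay every 50 epochs (all configurable); the loss is
#' the configured voxel-wise reconstruction loss. Seeded-deterministic.
#'
#' @param model A `sinusCAE` from [buildCAE()].
#' @param volumes List of normalized [CTVolume]s at the model's input shape
#'   (see [caeTrainingSet()]).
#' @param epochs Training epochs.
#' @param lr Initial learning rate.
#' @param batchSize Gradient-accumulation batch size.
#' @param decayEvery,decayFactor Step-decay schedule.
#' @param seed Integer seed.
#' @return Trained model with `history` (per-epoch mean loss).
#' @export
trainCAE <- function(model, volumes, epochs = 100L, lr = 1e-3, batchSize = 4L,
                     decayEvery = 50L, decayFactor = 0.1, seed = 1L) {
  if (length(volumes) == 0) stop("empty training manifest")
  cfg <- model$config
  params <- model$params
  state <- adamw_init(params)
  kind <- cfg$reconLoss
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    lrE <- step_decay_lr(lr, ep, decayEvery, decayFactor)
    set.seed(deriveSeed(seed, 3000L, ep))
    ord <- sample.int(length(volumes))
    losses <- numeric(0)
    acc <- NULL; nacc <- 0; bi <- 0L
    for (ii in seq_along(ord)) {
      x <- matrix(as.numeric(gridData(volumes[[ord[ii]]])), ncol = 1L)
      fwd <- cae_forward(list(config = cfg, params = params), x)
      d <- fwd$xhat - x
      n <- length(x)
      if (kind == "L2") {
        losses <- c(losses, mean(d * d))
        dxhat <- 2 * d / n
      } else {
        losses <- c(losses, mean(abs(d)))
        dxhat <- sign(d) / n
      }
      gr <- cae_backward(list(config = cfg, params = params), fwd, dxhat)
      acc <- add_grads(acc, gr); nacc <- nacc + 1; bi <- bi + 1L
      if (bi == batchSize || ii == length(ord)) {
        st <- adamw_step(params, scale_grads(acc, 1 / nacc), state,
                         lr = lrE, decay = 0)
        params <- st$params; state <- st$state
        acc <- NULL; nacc <- 0; bi <- 0L
      }
    }
    history[ep] <- mean(losses)
  }
  model$params <- params
  model$history <- history
  model
}

#' Reconstruction, residual map and latent code
#'
#' Runs a normalized volume through the trained autoencoder and returns the
#' reconstruction, the voxel-wise absolute residual `r = |x - xhat|` and the
#' latent embedding, together.
#'
#' @param model A trained `sinusCAE`.
#' @param v Normalized [CTVolume] at the model's input shape.
#' @return List with `reconstruction` ([CTVolume]), `residual`
#'   ([ResidualMap-class]) and `latent` (numeric vector).
#' @export
residualMap <- function(model, v) {
  cfg <- model$config
  g <- gridData(v)
  if (!identical(dim(g), cfg$inShape))
    stop("volume shape does not match the autoencoder input shape")
  if (intensityDomain(v) != "normalized")
    stop("residualMap expects a normalized volume")
  x <- matrix(as.numeric(g), ncol = 1L)
  fwd <- cae_forward(model, x)
  rec <- array(fwd$xhat, dim = cfg$inShape)
  res <- abs(g - rec)
  list(reconstruction = CTVolume(rec, spacing = voxelSpacing(v),
                                 domain = "normalized"),
       residual = ResidualMap(res, spacing = voxelSpacing(v)),
       latent = fwd$z)
}

#' Residual contrast between anomalous and reference sinus tissue
#'
#' Ratio of the mean residual inside the anomaly region to the mean residual
#' over reference voxels (labeled sinus voxels outside the anomaly). A
#' constant residual map gives 1; values well above 1 indicate that the
#' autoencoder reconstructs the anomalous region poorly, i.e. localizes the
#' deviation.
#'
#' @param r A [ResidualMap-class] or numeric array.
#' @param anomaly Binary array marking anomalous voxels.
#' @param reference Binary array of reference voxels.
#' @return The ratio; `Inf` when the reference mean is exactly zero.
#' @export
anomalyContrast <- function(r, anomaly, reference) {
  rg <- if (is(r, "ResidualMap")) gridData(r) else r
  if (!identical(dim(rg), dim(anomaly)) || !identical(dim(rg), dim(reference)))
    stop("masks are not aligned with the residual map")
  if (!any(anomaly != 0)) stop("empty anomaly mask")
  if (!any(reference != 0)) stop("empty reference mask")
  ma <- mean(rg[anomaly != 0])
  mr <- mean(rg[reference != 0])
  if (mr == 0) return(Inf)
  ma / mr
}
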