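# Segmentation-guided structural embeddings.
#
# A three-channel 3D CNN consumes the normalized CT volume, the segmentation
# mask (single channel, labels/4) and the autoencoder residual map, and
# produces a compact structural embedding via conv+max-pool stages, global
# average pooling and a dense layer with dropout. The network is trained
# self-supervised: it regresses the per-sinus mean residual (pretext
# targets), which forces attention onto sinus regions and their deviations
# without any pathology labels.

#' Three-channel fused model input
#'
#' @slot data Voxels-by-3 matrix: column 1 normalized CT, column 2 mask
#'   channel (labels/4), column 3 residual channel (clipped at its 99th
#'   percentile and scaled to \[0, 1\]).
#' @slot dims Integer length-3 spatial extent.
#' @slot spacing Numeric length-3 voxel spacing in mm.
#' @export
setClass("FusedInput",
  representation(data = "matrix", dims = "integer", spacing = "numeric"),
  validity = function(object) {
    if (ncol(object@data) != 3L) return("data must have 3 channels")
    if (nrow(object@data) != prod(object@dims)) return("data/dims mismatch")
    if (min(object@data) < -1e-9 || max(object@data) > 1 + 1e-9)
      return("channel values must lie in [0, 1]")
    TRUE
  })

setMethod("show", "FusedInput", function(object) {
  cat(sprintf("FusedInput %dx%dx%d voxels x 3 channels\n",
              object@dims[1], object@dims[2], object@dims[3]))
})

#' Assemble the three-channel fused input
#'
#' Channel 0 is the normalized CT volume, channel 1 the label mask scaled to
#' \[0, 1\] (labels 0..4 map to 0, 0.25, 0.5, 0.75, 1), channel 2 the
#' residual map clipped at its 99th percentile and scaled to \[0, 1\].
#' Ablation variants zero the corresponding channel while keeping shape.
#'
#' @param v Normalized [CTVolume].
#' @param m [SinusLabels] aligned with `v`.
#' @param r [ResidualMap-class] aligned with `v`.
#' @param variant `"full"`, `"no_residual"` or `"no_mask"`.
#' @return A [FusedInput-class].
#' @export
assembleInput <- function(v, m, r, variant = c("full", "no_residual", "no_mask")) {
  variant <- match.arg(variant)
  gv <- gridData(v)
  gm <- gridData(m)
  gr <- gridData(r)
  if (!identical(dim(gv), dim(gm)) || !identical(dim(gv), dim(gr)))
    stop("volume, mask and residual map are not geometrically aligned")
  if (intensityDomain(v) != "normalized")
    stop("fused input requires a normalized volume")
  rc <- as.numeric(gr)
  q <- stats::quantile(rc, 0.99, type = 7)
  rc <- if (q > 0) pmin(rc, q) / q else rc * 0
  mc <- as.numeric(gm) / 4
  if (variant == "no_residual") rc <- rc * 0
  if (variant == "no_mask") mc <- mc * 0
  new("FusedInput", data = cbind(as.numeric(gv), mc, rc),
      dims = as.integer(dim(gv)), spacing = as.numeric(voxelSpacing(v)))
}

#' Prepare a whole-volume fusion record from a phantom and a trained CAE
#'
#' The fused three-channel input pairs the residual map with the *whole*
#' preprocessed head volume: the autoencoder reconstructs the aligned sinus
#' crop (see [caePrepareSample()]), and the resulting residual map is
#' resampled back into the crop's position on the full grid (zero outside
#' the sinus bounding box). Returns everything the fusion and explanation
#' stages need on one common geometry.
#'
#' @param sample A [PhantomSample-class], or a list with `volume` (HU
#'   [CTVolume]), `labels` ([SinusLabels]) and optionally `anomaly`.
#' @param cae A trained `sinusCAE`.
#' @param marginVox Bounding-box margin used for the CAE crop.
#' @return List with `volume` (normalized whole [CTVolume]), `labels`,
#'   `residual` (whole-grid [ResidualMap-class]), `anomaly` (whole-grid
#'   binary array) and `latent` (the CAE code).
#' @export
fusionPrepareSample <- function(sample, cae, marginVox = 2L) {
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
  crop <- caePrepareSample(sample, cae$config, marginVox)
  rm_ <- residualMap(cae, crop$volume)
  lab <- gridData(labs)
  bb <- sinus_bbox(lab, marginVox)
  cshape <- bb$hi - bb$lo + 1L
  res_crop <- resample_grid(gridData(rm_$residual), cshape,
                            cae$config$inShape / cshape, "trilinear")
  whole <- array(0, dim(lab))
  whole[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3]] <- res_crop
  nv <- if (intensityDomain(vol) == "HU")
    normalizeMinMax(sanitizeVolume(vol)) else vol
  list(volume = nv, labels = labs,
       residual = ResidualMap(whole, spacing = voxelSpacing(vol)),
       anomaly = anom, latent = rm_$latent)
}

#' Per-sinus mean-residual pretext targets
#'
#' Entry c is the mean residual over voxels with label c (1..4), or 0 when
#' the label is absent. These label-free targets supervise the feature
#' extractor's pretext regression.
#'
#' @param m [SinusLabels].
#' @param r [ResidualMap-class] aligned with `m`.
#' @return Numeric length-4 vector.
#' @export
pretextTargets <- function(m, r) {
  gm <- gridData(m)
  gr <- if (is(r, "ResidualMap")) gridData(r) else r
  if (!identical(dim(gm), dim(gr))) stop("mask and residual are misaligned")
  vapply(1:4, function(k) {
    sel <- gm == k
    if (any(sel)) mean(gr[sel]) else 0
  }, numeric(1))
}

#' Build the structural feature extractor
#'
#' Three conv(3x3x3)+max-pool stages, global average pooling, a dense
#' embedding layer with dropout, and a 4-unit pretext regression head.
#'
#' @param channels Input channels (3).
#' @param convFilters Integer triple of conv widths; (32, 64, 128) at full
#'   scale. The CPU-scale default (6, 12, 24) is deliberately narrow: with
#'   little spare capacity the network cannot learn anatomy shortcuts and
#'   its features stay focused on the residual and mask channels, which
#'   both the saliency maps and the embeddings inherit.
#' @param embedLen Embedding length (64).
#' @param dropout Dropout rate on the embedding layer during training.
#' @param actL1 L1 penalty weight on the final conv layer's activations
#'   during training; sparsifies the feature maps so that activation (and
#'   hence Grad-CAM mass) concentrates where the pretext signal lives.
#' @param seed Integer seed for the parameter draw.
#' @return Model handle of class `sinusExtractor`.
#' @export
buildExtractor <- function(channels = 3L, convFilters = c(6L, 12L, 24L),
                           embedLen = 64L, dropout = 0.3, actL1 = 1e-3,
                           seed = 1L) {
  set.seed(deriveSeed(seed, 303L))
  f <- as.integer(convFilters)
  p <- list(c1 = init_conv(3L, channels, f[1]),
            c2 = init_conv(3L, f[1], f[2]),
            c3 = init_conv(3L, f[2], f[3]),
            emb = init_dense(f[3], as.integer(embedLen)),
            head = init_dense(as.integer(embedLen), 4L, sd = 0.02))
  structure(list(params = p,
                 config = list(channels = as.integer(channels),
                               convFilters = f, embedLen = as.integer(embedLen),
                               dropout = dropout, actL1 = actL1)),
            class = "sinusExtractor")
}

fus_forward <- function(model, f, train = FALSE) {
  p <- model$params
  cfg <- model$config
  d0 <- f@dims
  x <- f@data
  c1 <- conv3d_f(x, d0, p$c1, 3L, 1L); r1 <- relu_f(c1$y)
  p1 <- maxpool3d_fwd(r1, c1$odims, 2L); d1 <- c1$odims %/% 2L
  c2 <- conv3d_f(p1$y, d1, p$c2, 3L, 1L); r2 <- relu_f(c2$y)
  p2 <- maxpool3d_fwd(r2, d1, 2L); d2 <- d1 %/% 2L
  c3 <- conv3d_f(p2$y, d2, p$c3, 3L, 1L); r3 <- relu_f(c3$y)
  p3 <- maxpool3d_fwd(r3, d2, 2L); d3 <- d2 %/% 2L
  gap <- matrix(colMeans(p3$y), nrow = 1L)
  e_pre <- dense_f(gap, p$emb)
  e <- relu_f(e_pre)
  if (train && cfg$dropout > 0) {
    keep <- (runif(length(e)) >= cfg$dropout) / (1 - cfg$dropout)
    e_drop <- e * keep
  } else {
    keep <- NULL
    e_drop <- e
  }
  pretext <- dense_f(e_drop, p$head)
  list(embedding = as.numeric(e_drop), pretext = as.numeric(pretext),
       tape = list(x = x, d0 = d0, c1 = c1, r1 = r1, p1 = p1, d1 = d1,
                   c2 = c2, r2 = r2, p2 = p2, d2 = d2, c3 = c3, r3 = r3,
                   p3 = p3, d3 = d3, gap = gap, e_pre = e_pre, e = e,
                   keep = keep, e_drop = e_drop))
}

# Backward from a pretext-output gradient. When `to_conv3_only` is TRUE,
# stops at the final conv layer's post-relu activations and returns that
# gradient (Grad-CAM needs it); otherwise returns all parameter gradients.
# act_l1 adds the gradient of an L1 activation penalty on that layer.
fus_backward <- function(model, fwd, dpretext, to_conv3_only = FALSE,
                         act_l1 = 0) {
  p <- model$params
  tp <- fwd$tape
  g <- list()
  dp <- matrix(dpretext, nrow = 1L)
  hb <- dense_b(dp, matrix(tp$e_drop, nrow = 1L), p$head)
  g$head <- hb$grads
  de <- hb$dx
  if (!is.null(tp$keep)) de <- de * tp$keep
  de_pre <- relu_b(de, tp$e_pre)
  eb <- dense_b(de_pre, tp$gap, p$emb)
  g$emb <- eb$grads
  n3 <- nrow(tp$p3$y)
  dgap <- matrix(rep(as.numeric(eb$dx), each = n3) / n3, nrow = n3)
  dr3 <- maxpool3d_bwd(dgap, tp$p3$idx, nrow(tp$r3))
  if (to_conv3_only) return(dr3)
  if (act_l1 > 0) dr3 <- dr3 + act_l1 * (tp$r3 > 0) / length(tp$r3)
  dc3 <- relu_b(dr3, tp$c3$y)
  b3 <- conv3d_b(dc3, tp$p2$y, tp$d2, p$c3, 3L, 1L); g$c3 <- b3$grads
  dr2 <- maxpool3d_bwd(b3$dx, tp$p2$idx, nrow(tp$r2))
  dc2 <- relu_b(dr2, tp$c2$y)
  b2 <- conv3d_b(dc2, tp$p1$y, tp$d1, p$c2, 3L, 1L); g$c2 <- b2$grads
  dr1 <- maxpool3d_bwd(b2$dx, tp$p1$idx, nrow(tp$r1))
  dc1 <- relu_b(dr1, tp$c1$y)
  b1 <- conv3d_b(dc1, tp$x, tp$d0, p$c1, 3L, 1L); g$c1 <- b1$grads
  g[c("c1", "c2", "c3", "emb", "head")]
}

#' Train the feature extractor on the pretext regression
#'
#' Minimizes the mean squared error between the pretext head and the
#' per-sinus mean-residual targets (see [pretextTargets()]); Adam, seeded
#' dropout, deterministic given the seed.
#'
#' @param model A `sinusExtractor` from [buildExtractor()].
#' @param trainSet List of `list(input = FusedInput, target = numeric(4))`.
#' @param epochs Training epochs.
#' @param lr Learning rate.
#' @param batchSize Gradient-accumulation batch size.
#' @param weightDecay Decoupled (AdamW-style) weight decay.
#' @param seed Integer seed.
#' @return Trained model with `history`.
#' @export
trainExtractor <- function(model, trainSet, epochs = 20L, lr = 1e-3,
                           batchSize = 4L, weightDecay = 0, seed = 1L) {
  if (length(trainSet) == 0) stop("empty training manifest")
  params <- model$params
  state <- adamw_init(params)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    set.seed(deriveSeed(seed, 4000L, ep))
    ord <- sample.int(length(trainSet))
    losses <- numeric(0)
    acc <- NULL; nacc <- 0; bi <- 0L
    for (ii in seq_along(ord)) {
      rec <- trainSet[[ord[ii]]]
      fwd <- fus_forward(list(params = params, config = model$config),
                         rec$input, train = TRUE)
      diff <- fwd$pretext - rec$target
      lam <- model$config$actL1
      if (is.null(lam)) lam <- 0
      losses <- c(losses, mean(diff^2))   # history tracks the pretext MSE
      gr <- fus_backward(list(params = params, config = model$config), fwd,
                         2 * diff / length(diff), act_l1 = lam)
      acc <- add_grads(acc, gr); nacc <- nacc + 1; bi <- bi + 1L
      if (bi == batchSize || ii == length(ord)) {
        st <- adamw_step(params, scale_grads(acc, 1 / nacc), state,
                         lr = lr, decay = weightDecay)
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

#' Structural embedding of a fused input
#'
#' Deterministic eval-mode forward pass (dropout disabled).
#'
#' @param model A `sinusExtractor`.
#' @param f A [FusedInput-class].
#' @return Numeric embedding vector of the configured length.
#' @export
extractEmbedding <- function(model, f) {
  if (nrow(f@data) %% 1L != 0)
    stop("invalid fused input")
  fus_forward(model, f, train = FALSE)$embedding
}

#' Mean silhouette width of grouped embeddings
#'
#' Euclidean silhouette over a two-group (or k-group) labeling; positive
#' values mean inter-group distances exceed intra-group distances.
#'
#' @param x Numeric matrix, one embedding per row.
#' @param groups Group labels, one per row (at least two groups).
#' @return Mean silhouette width in \[-1, 1\].
#' @export
embeddingSilhouette <- function(x, groups) {
  x <- as.matrix(x)
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  D <- as.matrix(stats::dist(x))
  s <- vapply(seq_len(nrow(x)), function(i) {
    own <- groups == groups[i]
    a <- if (sum(own) > 1) mean(D[i, own & seq_len(nrow(x)) != i]) else 0
    b <- min(vapply(setdiff(levels(groups), as.character(groups[i])),
                    function(g) mean(D[i, groups == g]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Pretext predictions of a fused input (eval mode)
#' @param model A `sinusExtractor`.
#' @param f A [FusedInput-class].
#' @return Numeric length-4 vector of predicted per-sinus mean residuals.
#' @export
predictPretext <- function(model, f) {
  fus_forward(model, f, train = FALSE)$pretext
}
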