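# Hybrid CNN-transformer multi-class 3D segmenter.
#
# Encoder: strided patch embedding, then four stages; stage i holds
# depths[i] shifted-window attention blocks (pre-norm, alternating shift 0
# and window/2) interleaved with one residual 3x3x3 conv block under group
# normalization, then strided downsampling. Stage channels double per stage
# from embedDim; convFilters[i] is the internal width of stage i's residual
# conv block. Decoder mirrors the encoder with transposed convolutions and
# stage-wise skip connections. Ablation variants: cnn_only removes the
# attention blocks, transformer_only removes the interleaved conv blocks.

#' Segmenter configuration
#'
#' The `"desk"` profile (default) is a CPU-scale model used throughout the
#' tests; [segConfigFull()] carries the full-scale hyperparameters
#' (96-cube patches, heads (3,6,12,24), depths (2,2,6,2), window 7,
#' conv filter ladder (32,64,128,256)).
#'
#' @param inShape Input patch shape (voxels).
#' @param numClasses Number of classes including background (>= 2).
#' @param embedDim Channel width after patch embedding; stage i has
#'   `embedDim * 2^(i-1)` channels, which `heads[i]` must divide.
#' @param depths Integer quadruple: attention blocks per stage.
#' @param heads Integer quadruple: attention heads per stage.
#' @param window Attention window extent (scalar or length 3).
#' @param convFilters Integer quadruple: internal widths of the residual
#'   conv blocks.
#' @param variant `"full"`, `"cnn_only"` or `"transformer_only"`.
#' @param groupnormGroups Maximum group count for group normalization.
#' @param mlpRatio Hidden-width multiplier of the attention-block MLPs.
#' @return A `segConfig` list.
#' @export
segConfig <- function(inShape = c(48L, 48L, 48L), numClasses = 5L,
                      embedDim = 24L, depths = c(1L, 1L, 2L, 1L),
                      heads = c(1L, 2L, 4L, 8L), window = 3L,
                      convFilters = c(12L, 16L, 24L, 32L),
                      variant = c("full", "cnn_only", "transformer_only"),
                      groupnormGroups = 8L, mlpRatio = 2) {
  variant <- match.arg(variant)
  if (length(window) == 1L) window <- rep(window, 3L)
  cfg <- list(inShape = as.integer(inShape), numClasses = as.integer(numClasses),
              embedDim = as.integer(embedDim), depths = as.integer(depths),
              heads = as.integer(heads), window = as.integer(window),
              convFilters = as.integer(convFilters), variant = variant,
              groupnormGroups = as.integer(groupnormGroups),
              mlpRatio = mlpRatio)
  ch <- cfg$embedDim * 2L^(0:3)
  if (cfg$numClasses < 2L) stop("numClasses must be >= 2")
  if (any(cfg$window < 1L)) stop("window entries must be >= 1")
  if (any(ch %% cfg$heads != 0L))
    stop("embedDim * 2^(stage-1) must be divisible by heads at every stage")
  dims <- cfg$inShape
  if (any(dims %% 2L != 0L)) stop("inShape must be even for patch embedding")
  for (i in 1:4) {
    dims <- if (i == 1L) cfg$inShape %/% 2L else dims %/% 2L
    if (i < 4L && any(dims %% 2L != 0L))
      stop(sprintf("stage %d grid (%s) must be even for downsampling",
                   i, paste(dims, collapse = "x")))
    if (cfg$variant != "cnn_only" && any(dims %% cfg$window != 0L))
      stop(sprintf(
        "stage %d grid (%s) is not a multiple of the attention window (%s)",
        i, paste(dims, collapse = "x"), paste(cfg$window, collapse = "x")))
  }
  class(cfg) <- "segConfig"
  cfg
}

#' Full-scale segmenter configuration
#'
#' All full-scale hyperparameters in one place: 96-cube input
#' patches, heads (3,6,12,24) over depths (2,2,6,2), 7x7x7 windows and the
#' (32,64,128,256) conv-filter ladder. Training at this scale needs GPU-class
#' resources; it exists as a named profile, not a test default.
#' @return A `segConfig` list.
#' @export
segConfigFull <- function() {
  segConfig(inShape = c(96L, 96L, 96L), embedDim = 96L,
            depths = c(2L, 2L, 6L, 2L), heads = c(3L, 6L, 12L, 24L),
            window = 7L, convFilters = c(32L, 64L, 128L, 256L),
            groupnormGroups = 8L, mlpRatio = 4)
}

gn_groups <- function(C, gmax) {
  g <- min(gmax, C)
  while (C %% g != 0L) g <- g - 1L
  g
}

seg_stage_channels <- function(cfg) cfg$embedDim * 2L^(0:3)

#' Build a segmenter model
#'
#' Initializes all parameters deterministically from `seed` (He init for
#' convolutions, truncated-scale normal for attention projections).
#'
#' @param cfg A [segConfig()].
#' @param seed Integer seed for the parameter draw.
#' @return Model handle of class `sinusSegmenter`.
#' @export
buildSegmenter <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "segConfig"))
  set.seed(deriveSeed(seed, 101L))
  ch <- seg_stage_channels(cfg)
  p <- list()
  p$embed <- init_conv(3L, 1L, ch[1])
  p$embed_ln <- init_norm(ch[1])
  p$stage <- vector("list", 4L)
  for (i in 1:4) {
    st <- list()
    if (cfg$variant != "cnn_only" && cfg$depths[i] > 0) {
      st$attn <- lapply(seq_len(cfg$depths[i]), function(b) {
        C <- ch[i]
        list(ln1 = init_norm(C), attn = init_attn(C),
             ln2 = init_norm(C),
             mlp1 = init_dense(C, round(cfg$mlpRatio * C)),
             mlp2 = init_dense(round(cfg$mlpRatio * C), C, sd = 0.02))
      })
    }
    if (cfg$variant != "transformer_only") {
      f <- cfg$convFilters[i]
      st$conv <- list(c1 = init_conv(3L, ch[i], f),
                      gn1 = init_norm(f),
                      c2 = init_conv(3L, f, ch[i]),
                      gn2 = init_norm(ch[i]))
    }
    p$stage[[i]] <- st
  }
  p$down <- lapply(1:3, function(i) init_conv(3L, ch[i], ch[i + 1]))
  p$dec <- lapply(3:1, function(j) {
    list(up = init_convT(2L, ch[j + 1], ch[j]),
         conv = init_conv(3L, ch[j], ch[j]),
         gn = init_norm(ch[j]))
  })
  cf <- max(8L, cfg$numClasses)
  p$final <- list(up = init_convT(2L, ch[1], cf),
                  gn = init_norm(cf),
                  head = init_conv(1L, cf, cfg$numClasses))
  # prior-logit bias: start the head at realistic class frequencies so the
  # rare foreground classes do not collapse under the cross-entropy term
  K <- cfg$numClasses
  fg_prior <- 0.02
  p$final$head$b <- log(c(1 - (K - 1L) * fg_prior, rep(fg_prior, K - 1L)))
  structure(list(config = cfg, params = p), class = "sinusSegmenter")
}

#' Number of trainable parameters of a model handle
#' @param model A model handle (`sinusSegmenter`, `sinusCAE`, `sinusExtractor`).
#' @return Integer parameter count.
#' @export
countParameters <- function(model) {
  n <- 0L
  rec <- function(p) {
    if (is.list(p)) lapply(p, rec) else n <<- n + length(p)
    invisible(NULL)
  }
  rec(model$params)
  n
}

attn_block_f <- function(x, dims, bp, win, shift, heads) {
  l1 <- layernorm_f(x, bp$ln1)
  at <- win_attn_f(l1$y, dims, bp$attn, win, shift, heads)
  x1 <- x + at$y
  l2 <- layernorm_f(x1, bp$ln2)
  h_pre <- dense_f(l2$y, bp$mlp1)
  h <- gelu_f(h_pre)
  m2 <- dense_f(h, bp$mlp2)
  y <- x1 + m2
  list(y = y, l1 = l1, at = at, x1 = x1, l2 = l2, h_pre = h_pre, h = h)
}

attn_block_b <- function(dy, cache, bp) {
  g <- list()
  d2 <- dense_b(dy, cache$h, bp$mlp2)
  g$mlp2 <- d2$grads
  dh_pre <- gelu_b(d2$dx, cache$h_pre)
  d1 <- dense_b(dh_pre, cache$l2$y, bp$mlp1)
  g$mlp1 <- d1$grads
  l2b <- layernorm_b(d1$dx, cache$l2, bp$ln2)
  g$ln2 <- l2b$grads
  dx1 <- dy + l2b$dx
  ab <- win_attn_b(dx1, cache$at, bp$attn)
  g$attn <- ab$grads
  l1b <- layernorm_b(ab$dx, cache$l1, bp$ln1)
  g$ln1 <- l1b$grads
  dx <- dx1 + l1b$dx
  list(dx = dx, grads = g[c("ln1", "attn", "ln2", "mlp1", "mlp2")])
}

conv_block_f <- function(x, dims, bp, groups) {
  c1 <- conv3d_f(x, dims, bp$c1, 3L, 1L)
  g1 <- groupnorm_f(c1$y, bp$gn1, gn_groups(ncol(c1$y), groups))
  r1 <- relu_f(g1$y)
  c2 <- conv3d_f(r1, dims, bp$c2, 3L, 1L)
  g2 <- groupnorm_f(c2$y, bp$gn2, gn_groups(ncol(c2$y), groups))
  pre <- x + g2$y
  y <- relu_f(pre)
  list(y = y, x = x, c1y = c1$y, g1 = g1, r1 = r1, g2 = g2, pre = pre)
}

conv_block_b <- function(dy, cache, bp, dims, groups) {
  dpre <- relu_b(dy, cache$pre)
  g2b <- groupnorm_b(dpre, cache$g2, bp$gn2, gn_groups(length(bp$gn2$gamma), groups))
  c2b <- conv3d_b(g2b$dx, cache$r1, dims, bp$c2, 3L, 1L)
  dr1 <- relu_b(c2b$dx, cache$g1$y)
  g1b <- groupnorm_b(dr1, cache$g1, bp$gn1, gn_groups(length(bp$gn1$gamma), groups))
  c1b <- conv3d_b(g1b$dx, cache$x, dims, bp$c1, 3L, 1L)
  dx <- dpre + c1b$dx
  list(dx = dx, grads = list(c1 = c1b$grads, gn1 = g1b$grads,
                             c2 = c2b$grads, gn2 = g2b$grads))
}

seg_forward <- function(model, x) {
  cfg <- model$config
  p <- model$params
  ch <- seg_stage_channels(cfg)
  tape <- list()
  dims <- cfg$inShape
  pe <- conv3d_f(x, dims, p$embed, 3L, 2L)
  tape$embed <- list(x = x, dims = dims)
  dims <- pe$odims
  ln <- layernorm_f(pe$y, p$embed_ln)
  tape$embed_ln <- ln
  h <- ln$y
  skips <- vector("list", 4L)
  sdims <- vector("list", 4L)
  tape$stage <- vector("list", 4L)
  for (i in 1:4) {
    st <- list()
    if (!is.null(p$stage[[i]]$attn)) {
      st$attn <- vector("list", length(p$stage[[i]]$attn))
      for (b in seq_along(p$stage[[i]]$attn)) {
        shift <- if (b %% 2L == 0L) cfg$window %/% 2L else c(0L, 0L, 0L)
        ab <- attn_block_f(h, dims, p$stage[[i]]$attn[[b]], cfg$window,
                           shift, cfg$heads[i])
        st$attn[[b]] <- ab
        h <- ab$y
      }
    }
    if (!is.null(p$stage[[i]]$conv)) {
      cb <- conv_block_f(h, dims, p$stage[[i]]$conv, cfg$groupnormGroups)
      st$conv <- cb
      h <- cb$y
    }
    skips[[i]] <- h
    sdims[[i]] <- dims
    tape$stage[[i]] <- st
    if (i < 4L) {
      dcv <- conv3d_f(h, dims, p$down[[i]], 3L, 2L)
      tape$down[[i]] <- list(x = h, dims = dims)
      h <- dcv$y
      dims <- dcv$odims
    }
  }
  tape$dec <- vector("list", 3L)
  for (d in 1:3) {
    j <- 4L - d                       # decode into stage j's resolution
    up <- convT3d_f(h, dims, p$dec[[d]]$up, 2L, 2L)
    tape$dec[[d]]$up_x <- h
    tape$dec[[d]]$up_dims <- dims
    dims <- up$odims
    sum_x <- up$y + skips[[j]]        # additive stage-wise skip connection
    cv <- conv3d_f(sum_x, dims, p$dec[[d]]$conv, 3L, 1L)
    gn <- groupnorm_f(cv$y, p$dec[[d]]$gn,
                      gn_groups(ncol(cv$y), cfg$groupnormGroups))
    h <- relu_f(gn$y)
    tape$dec[[d]]$sum_x <- sum_x
    tape$dec[[d]]$gn <- gn
    tape$dec[[d]]$dims <- dims
  }
  fup <- convT3d_f(h, dims, p$final$up, 2L, 2L)
  tape$final$up_x <- h
  tape$final$up_dims <- dims
  dims <- fup$odims
  fgn <- groupnorm_f(fup$y, p$final$gn,
                     gn_groups(ncol(fup$y), cfg$groupnormGroups))
  fr <- relu_f(fgn$y)
  logits <- conv3d_f(fr, dims, p$final$head, 1L, 1L, 0L)$y
  tape$final$fgn <- fgn
  tape$final$fr <- fr
  tape$final$dims <- dims
  list(logits = logits, tape = tape, skip_dims = sdims)
}

seg_backward <- function(model, fwd, dlogits) {
  cfg <- model$config
  p <- model$params
  tape <- fwd$tape
  g <- list()
  dims <- tape$final$dims
  hb <- conv3d_b(dlogits, tape$final$fr, dims, p$final$head, 1L, 1L, 0L)
  g$final$head <- hb$grads
  dfr <- relu_b(hb$dx, tape$final$fgn$y)
  gnb <- groupnorm_b(dfr, tape$final$fgn, p$final$gn,
                     gn_groups(length(p$final$gn$gamma), cfg$groupnormGroups))
  g$final$gn <- gnb$grads
  upb <- convT3d_b(gnb$dx, tape$final$up_x, tape$final$up_dims, p$final$up, 2L, 2L)
  g$final$up <- upb$grads
  dh <- upb$dx
  dskips <- vector("list", 4L)
  g$dec <- vector("list", 3L)
  for (d in 3:1) {
    j <- 4L - d
    dims <- tape$dec[[d]]$dims
    dfr <- relu_b(dh, tape$dec[[d]]$gn$y)
    gnb <- groupnorm_b(dfr, tape$dec[[d]]$gn, p$dec[[d]]$gn,
                       gn_groups(length(p$dec[[d]]$gn$gamma), cfg$groupnormGroups))
    cvb <- conv3d_b(gnb$dx, tape$dec[[d]]$sum_x, dims, p$dec[[d]]$conv, 3L, 1L)
    dskips[[j]] <- cvb$dx
    upb <- convT3d_b(cvb$dx, tape$dec[[d]]$up_x, tape$dec[[d]]$up_dims,
                     p$dec[[d]]$up, 2L, 2L)
    g$dec[[d]] <- list(up = upb$grads, conv = cvb$grads, gn = gnb$grads)
    dh <- upb$dx
  }
  # dh now flows into stage 4's output; add decoder skip gradients stagewise
  g$stage <- vector("list", 4L)
  g$down <- vector("list", 3L)
  for (i in 4:1) {
    dims <- fwd$skip_dims[[i]]
    if (i < 4L) {
      dnb <- conv3d_b(dh, tape$down[[i]]$x, tape$down[[i]]$dims,
                      p$down[[i]], 3L, 2L)
      g$down[[i]] <- dnb$grads
      dh <- dnb$dx
    }
    if (!is.null(dskips[[i]])) dh <- dh + dskips[[i]]
    if (!is.null(p$stage[[i]]$conv)) {
      cb <- conv_block_b(dh, tape$stage[[i]]$conv, p$stage[[i]]$conv, dims,
                         cfg$groupnormGroups)
      g$stage[[i]]$conv <- cb$grads
      dh <- cb$dx
    }
    if (!is.null(p$stage[[i]]$attn)) {
      nb <- length(p$stage[[i]]$attn)
      g$stage[[i]]$attn <- vector("list", nb)
      for (b in nb:1) {
        ab <- attn_block_b(dh, tape$stage[[i]]$attn[[b]], p$stage[[i]]$attn[[b]])
        g$stage[[i]]$attn[[b]] <- ab$grads
        dh <- ab$dx
      }
    }
    if (!is.null(g$stage[[i]])) g$stage[[i]] <- g$stage[[i]][c("attn", "conv")[
      c(!is.null(g$stage[[i]]$attn), !is.null(g$stage[[i]]$conv))]]
  }
  lnb <- layernorm_b(dh, tape$embed_ln, p$embed_ln)
  g$embed_ln <- lnb$grads
  peb <- conv3d_b(lnb$dx, tape$embed$x, tape$embed$dims, p$embed, 3L, 2L)
  g$embed <- peb$grads
  g[c("embed", "embed_ln", "stage", "down", "dec", "final")]
}

# ---- loss ------------------------------------------------------------------

DICE_SMOOTH <- 1e-5

# Loss and logit gradient for one sample. target: 0-based integer vector.
seg_loss_grad <- function(logits, target, diceWeight = 0.5, ceWeight = 0.5) {
  N <- nrow(logits)
  K <- ncol(logits)
  if (any(target >= K)) stop("target labels exceed the class count")
  pr <- softmax_rows(logits)
  ti <- cbind(seq_len(N), target + 1L)
  ce <- -mean(log(pmax(pr[ti], 1e-300)))
  G <- matrix(0, N, K)
  G[ti] <- 1
  fg <- 2:K
  num <- 2 * colSums(pr[, fg, drop = FALSE] * G[, fg, drop = FALSE]) + DICE_SMOOTH
  den <- colSums(pr[, fg, drop = FALSE]) + colSums(G[, fg, drop = FALSE]) + DICE_SMOOTH
  dice <- num / den
  dice_loss <- 1 - mean(dice)
  loss <- diceWeight * dice_loss + ceWeight * ce
  # dL/dp then chain through softmax
  dLdp <- matrix(0, N, K)
  for (c in fg) {
    cc <- c - 1L
    dLdp[, c] <- -diceWeight / (K - 1) *
      (2 * G[, c] * den[cc] - num[cc]) / den[cc]^2
  }
  dz_dice <- pr * (dLdp - rowSums(dLdp * pr))
  dz_ce <- ceWeight * (pr - G) / N
  list(loss = loss, ce = ce, dice_loss = dice_loss, dlogits = dz_ce + dz_dice)
}

#' Composite Dice + cross-entropy loss
#'
#' `diceWeight * (1 - mean soft Dice over foreground classes) +
#' ceWeight * mean voxel-wise cross-entropy`, evaluated on per-voxel class
#' probabilities. Soft Dice uses a smoothing constant of 1e-5 in numerator
#' and denominator. Zero iff the probabilities are exactly one-hot on the
#' target.
#'
#' @param probs Class-first 4D array (class x H x W x D) of per-voxel
#'   probabilities, or an N x K matrix.
#' @param target A [SinusLabels] or integer array of labels in
#'   `0..(K-1)`, aligned with `probs`.
#' @param diceWeight,ceWeight Non-negative weights; default equal (0.5/0.5).
#' @return Named list `loss`, `dice`, `ce` (the weighted total and the two
#'   unweighted components).
#' @export
compositeLoss <- function(probs, target, diceWeight = 0.5, ceWeight = 0.5) {
  if (diceWeight + ceWeight <= 0) stop("diceWeight + ceWeight must be > 0")
  tg <- if (is(target, "SinusLabels")) gridData(target) else target
  if (is.array(probs) && length(dim(probs)) == 4L) {
    K <- dim(probs)[1]
    pr <- t(matrix(probs, nrow = K))
  } else {
    pr <- as.matrix(probs)
    K <- ncol(pr)
  }
  tv <- as.integer(as.vector(tg))
  if (length(tv) != nrow(pr)) stop("probability grid and target are misaligned")
  if (any(tv >= K)) stop("target labels exceed the class count")
  N <- nrow(pr)
  ti <- cbind(seq_len(N), tv + 1L)
  ce <- -mean(log(pmax(pr[ti], 1e-300)))
  G <- matrix(0, N, K)
  G[ti] <- 1
  fg <- 2:K
  num <- 2 * colSums(pr[, fg, drop = FALSE] * G[, fg, drop = FALSE]) + DICE_SMOOTH
  den <- colSums(pr[, fg, drop = FALSE]) + colSums(G[, fg, drop = FALSE]) + DICE_SMOOTH
  dice_loss <- 1 - mean(num / den)
  list(loss = diceWeight * dice_loss + ceWeight * ce,
       dice = dice_loss, ce = ce)
}

# ---- training --------------------------------------------------------------

#' Segmentation training options
#'
#' Defaults are the full-scale recipe: AdamW at 1e-4 under cosine annealing,
#' batch size 2, equal Dice/CE weights. The CPU-scale runs in the tests pass
#' a larger learning rate and few epochs.
#'
#' @param lr Base learning rate.
#' @param schedule `"cosine"` or `"constant"`.
#' @param batchSize Gradient-accumulation batch size.
#' @param epochs Training epochs.
#' @param diceWeight,ceWeight Loss weights (sum must be positive).
#' @param pseudoLabelWeight Loss weight in \[0, 1\] applied to samples
#'   flagged as pseudo-labeled.
#' @param weightDecay AdamW decoupled weight decay.
#' @param augment Apply intensity-only augmentation during training.
#' @param seed Integer seed controlling ordering, augmentation and dropout.
#' @return A `trainOpts` list.
#' @export
trainOpts <- function(lr = 1e-4, schedule = c("cosine", "constant"),
                      batchSize = 2L, epochs = 200L, diceWeight = 0.5,
                      ceWeight = 0.5, pseudoLabelWeight = 0.5,
                      weightDecay = 0.01, augment = TRUE, seed = 1L) {
  schedule <- match.arg(schedule)
  if (diceWeight + ceWeight <= 0) stop("diceWeight + ceWeight must be > 0")
  if (pseudoLabelWeight < 0 || pseudoLabelWeight > 1)
    stop("pseudoLabelWeight must lie in [0, 1]")
  structure(list(lr = lr, schedule = schedule, batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs), diceWeight = diceWeight,
                 ceWeight = ceWeight, pseudoLabelWeight = pseudoLabelWeight,
                 weightDecay = weightDecay, augment = augment,
                 seed = as.integer(seed)), class = "trainOpts")
}

#' Prepare phantom samples for segmentation training
#'
#' Runs the standard preprocessing chain on each [PhantomSample-class] and
#' pairs the normalized volume with its ground-truth labels.
#'
#' @param samples List of [PhantomSample-class] objects.
#' @param cfg The [segConfig()] the samples must match.
#' @param pseudo Logical vector (recycled) flagging pseudo-labeled samples.
#' @return List of `list(volume, labels, pseudo)` training records.
#' @export
segTrainingSet <- function(samples, cfg, pseudo = FALSE) {
  pseudo <- rep_len(pseudo, length(samples))
  lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    pp <- preprocessVolume(phantomVolume(s), phantomLabels(s),
                           targetSpacingMm = voxelSpacing(phantomVolume(s))[1],
                           targetShape = cfg$inShape)
    list(volume = pp$volume, labels = pp$labels, pseudo = pseudo[i])
  })
}

#' Train a segmenter
#'
#' Deterministic given the seed (up to floating-point reduction order).
#' Applies intensity-only augmentation, accumulates gradients over
#' `batchSize` samples, steps AdamW under the configured schedule, and
#' down-weights pseudo-labeled samples by `pseudoLabelWeight`.
#'
#' @param model A `sinusSegmenter` from [buildSegmenter()].
#' @param trainSet List of records from [segTrainingSet()].
#' @param opts A [trainOpts()].
#' @return The trained model with a `history` element (per-epoch mean loss).
#' @export
trainSegmenter <- function(model, trainSet, opts = trainOpts()) {
  if (length(trainSet) == 0) stop("empty training manifest")
  cfg <- model$config
  params <- model$params
  state <- adamw_init(params)
  history <- numeric(opts$epochs)
  for (ep in seq_len(opts$epochs)) {
    lr <- if (opts$schedule == "cosine")
      cosine_lr(opts$lr, ep, opts$epochs) else opts$lr
    set.seed(deriveSeed(opts$seed, 1000L, ep))
    ord <- sample.int(length(trainSet))
    ep_losses <- numeric(0)
    bi <- 0L
    acc <- NULL
    acc_w <- 0
    for (ii in seq_along(ord)) {
      rec <- trainSet[[ord[ii]]]
      v <- rec$volume
      if (opts$augment)
        v <- augmentIntensity(v, seed = deriveSeed(opts$seed, 2000L, ep, ord[ii]))
      x <- matrix(as.numeric(gridData(v)), ncol = 1L)
      tgt <- as.integer(as.vector(gridData(rec$labels)))
      w <- if (isTRUE(rec$pseudo)) opts$pseudoLabelWeight else 1
      fwd <- seg_forward(list(config = cfg, params = params), x)
      lg <- seg_loss_grad(fwd$logits, tgt, opts$diceWeight, opts$ceWeight)
      ep_losses <- c(ep_losses, w * lg$loss)
      if (w > 0) {
        gr <- seg_backward(list(config = cfg, params = params), fwd,
                           lg$dlogits * w)
        acc <- add_grads(acc, gr)
        acc_w <- acc_w + 1
      }
      bi <- bi + 1L
      if (bi == opts$batchSize || ii == length(ord)) {
        if (!is.null(acc)) {
          st <- adamw_step(params, scale_grads(acc, 1 / max(acc_w, 1)), state,
                           lr = lr, decay = opts$weightDecay)
          params <- st$params
          state <- st$state
        }
        bi <- 0L
        acc <- NULL
        acc_w <- 0
      }
    }
    history[ep] <- mean(ep_losses)
  }
  model$params <- params
  model$history <- history
  model
}

# ---- prediction ------------------------------------------------------------

#' Per-voxel class probabilities and argmax labels
#'
#' @slot probs Class-first 4D array (class x H x W x D); per-voxel
#'   probabilities sum to 1.
#' @slot labels [SinusLabels] holding the per-voxel argmax (ties broken
#'   toward the lowest class index).
#' @export
setClass("SegPrediction",
  representation(probs = "array", labels = "SinusLabels"),
  validity = function(object) {
    if (length(dim(object@probs)) != 4L) return("probs must be class-first 4D")
    TRUE
  })

#' Predict a multi-class sinus mask
#'
#' Inference on a normalized volume. Inputs larger than the model's patch
#' shape are covered by sliding-window tiles with 50% overlap and
#' mean-blended probabilities; smaller inputs are zero-padded then cropped
#' back.
#'
#' @param model A trained `sinusSegmenter`.
#' @param v A normalized [CTVolume].
#' @return A [SegPrediction-class].
#' @export
predictMask <- function(model, v) {
  if (intensityDomain(v) != "normalized")
    stop("predictMask expects a normalized volume")
  cfg <- model$config
  d <- dim(gridData(v))
  ts <- cfg$inShape
  if (any(d < ts)) {
    vp <- standardizeShape(v, pmax(d, ts))
    pred <- predictMask(model, vp)
    dp <- dim(gridData(v))
    lo <- (pmax(d, ts) - d) %/% 2L
    pr <- pred@probs[, lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]),
                     lo[3] + seq_len(d[3]), drop = FALSE]
    return(seg_prediction_from_probs(pr, voxelSpacing(v)))
  }
  starts <- lapply(1:3, function(a) {
    if (d[a] == ts[a]) return(1L)
    s <- unique(c(seq(1L, d[a] - ts[a] + 1L, by = max(ts[a] %/% 2L, 1L)),
                  d[a] - ts[a] + 1L))
    s
  })
  K <- cfg$numClasses
  acc <- array(0, c(K, d))
  cnt <- array(0, d)
  g <- gridData(v)
  for (sx in starts[[1]]) for (sy in starts[[2]]) for (sz in starts[[3]]) {
    ix <- sx:(sx + ts[1] - 1L); iy <- sy:(sy + ts[2] - 1L); iz <- sz:(sz + ts[3] - 1L)
    x <- matrix(as.numeric(g[ix, iy, iz]), ncol = 1L)
    logits <- seg_forward(model, x)$logits
    pr <- softmax_rows(logits)
    tile <- array(t(pr), c(K, ts))
    acc[, ix, iy, iz] <- acc[, ix, iy, iz] + tile
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
  }
  for (k in seq_len(K)) acc[k, , , ] <- acc[k, , , ] / cnt
  seg_prediction_from_probs(acc, voxelSpacing(v))
}

seg_prediction_from_probs <- function(probs, spacing) {
  K <- dim(probs)[1]
  d <- dim(probs)[-1]
  m <- t(matrix(probs, nrow = K))
  lab <- max.col(m, ties.method = "first") - 1L
  new("SegPrediction", probs = probs,
      labels = SinusLabels(array(lab, dim = d), spacing = spacing))
}

#' @rdname predictMask
#' @param object,x A `SegPrediction`.
#' @export
setMethod("show", "SegPrediction", function(object) {
  d <- dim(object@probs)
  cat(sprintf("SegPrediction %d classes over %dx%dx%d voxels\n",
              d[1], d[2], d[3], d[4]))
})

#' Accessors for SegPrediction
#' @param x A [SegPrediction-class].
#' @return `predictionProbs()` the class-first 4D probability array;
#'   `predictionLabels()` the argmax [SinusLabels].
#' @export
predictionProbs <- function(x) x@probs
#' @rdname predictionProbs
#' @export
predictionLabels <- function(x) x@labels
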