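# Harmonization chain applied identically to real and synthetic volumes:
# sanitize -> isotropic resample -> shape standardization -> HU windowing,
# plus threshold-based body masking, mask-guided cropping and intensity-only
# augmentation. Coordinates are 0-based half-open index ranges in (x,y,z)
# NIfTI voxel order throughout.

#' Replace non-finite voxels by zero
#'
#' @param v A [CTVolume].
#' @return The volume with every NaN/Inf voxel set to 0; finite voxels are
#'   untouched.
#' @export
sanitizeVolume <- function(v) {
  g <- gridData(v)
  g[!is.finite(g)] <- 0
  CTVolume(g, spacing = voxelSpacing(v), domain = intensityDomain(v))
}

# Generic grid resampler. in-coordinate of output voxel i (0-based) is
# (i + 0.5) * scale - 0.5 per axis; trilinear or nearest gather with edge
# clamping.
resample_grid <- function(grid, outShape, scale, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  d <- dim(grid)
  ax <- lapply(1:3, function(a) (seq_len(outShape[a]) - 0.5) * scale[a] - 0.5)
  if (method == "nearest") {
    idx <- lapply(1:3, function(a) pmin(pmax(round(ax[[a]]), 0), d[a] - 1) + 1)
    return(grid[idx[[1]], idx[[2]], idx[[3]], drop = FALSE])
  }
  lo <- lapply(1:3, function(a) pmin(pmax(floor(ax[[a]]), 0), d[a] - 1))
  fr <- lapply(1:3, function(a) pmin(pmax(ax[[a]] - lo[[a]], 0), 1))
  hi <- lapply(1:3, function(a) pmin(lo[[a]] + 1, d[a] - 1))
  n <- prod(outShape)
  ex <- function(v, axis) {
    switch(axis,
           rep(v, times = outShape[2] * outShape[3]),
           rep(rep(v, each = outShape[1]), times = outShape[3]),
           rep(v, each = outShape[1] * outShape[2]))
  }
  out <- numeric(n)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ix <- ex((if (cx) hi[[1]] else lo[[1]]) + 1, 1)
    iy <- ex((if (cy) hi[[2]] else lo[[2]]) + 1, 2)
    iz <- ex((if (cz) hi[[3]] else lo[[3]]) + 1, 3)
    wx <- ex(if (cx) fr[[1]] else 1 - fr[[1]], 1)
    wy <- ex(if (cy) fr[[2]] else 1 - fr[[2]], 2)
    wz <- ex(if (cz) fr[[3]] else 1 - fr[[3]], 3)
    out <- out + wx * wy * wz * grid[cbind(ix, iy, iz)]
  }
  array(out, dim = outShape)
}

#' Resample a volume or label mask to isotropic spacing
#'
#' Output shape is `round(inputShape * inputSpacing / target)` per axis.
#' Intensities are interpolated trilinearly; labels by nearest neighbour, so
#' the label set never grows.
#'
#' @param x A [CTVolume] or [SinusLabels].
#' @param targetSpacingMm Positive target voxel edge length in mm.
#' @return Same kind as `x`, at spacing `(t, t, t)`.
#' @export
resampleIsotropic <- function(x, targetSpacingMm = 1.0) {
  if (targetSpacingMm <= 0) stop("target spacing must be positive")
  sp <- voxelSpacing(x)
  d <- dim(gridData(x))
  outShape <- pmax(as.integer(round(d * sp / targetSpacingMm)), 1L)
  scale <- targetSpacingMm / sp
  if (is(x, "SinusLabels")) {
    g <- resample_grid(gridData(x), outShape, scale, "nearest")
    SinusLabels(g, spacing = rep(targetSpacingMm, 3))
  } else {
    g <- resample_grid(gridData(x), outShape, scale, "trilinear")
    CTVolume(g, spacing = rep(targetSpacingMm, 3), domain = intensityDomain(x))
  }
}

#' Standardize grid shape by center-cropping and symmetric zero-padding
#'
#' Oversized axes are center-cropped (the extra voxel of an odd difference is
#' removed from the high side); undersized axes are zero-padded symmetrically
#' (the extra voxel goes on the high side).
#'
#' @param x A [CTVolume] or [SinusLabels].
#' @param targetShape Integer length-3.
#' @return Same kind as `x` with grid dimensions `targetShape`.
#' @export
standardizeShape <- function(x, targetShape) {
  g <- std_shape_core(gridData(x), targetShape,
                      fill = if (is(x, "SinusLabels")) 0L else 0)
  if (is(x, "SinusLabels")) SinusLabels(g, spacing = voxelSpacing(x))
  else CTVolume(g, spacing = voxelSpacing(x), domain = intensityDomain(x))
}

std_shape_core <- function(g, targetShape, fill = 0) {
  d <- dim(g)
  t <- as.integer(targetShape)
  # crop phase
  sel <- lapply(1:3, function(a) {
    if (d[a] > t[a]) {
      lo <- (d[a] - t[a]) %/% 2L
      (lo + 1L):(lo + t[a])
    } else seq_len(d[a])
  })
  g <- g[sel[[1]], sel[[2]], sel[[3]], drop = FALSE]
  d <- dim(g)
  # pad phase
  if (any(d < t)) {
    out <- array(fill, dim = t)
    lo <- (t - d) %/% 2L
    out[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]), lo[3] + seq_len(d[3])] <- g
    g <- out
  }
  g
}

#' Min-max normalize a HU volume into \[0, 1\]
#'
#' Values are clipped to the window and mapped affinely to \[0, 1\]. The
#' default fixed window (-1000, 2000) HU covers air through dense bone and is
#' deliberately not per-volume: per-volume extremes are scanner artifacts and
#' a fixed window keeps intensity meaning comparable across scanners.
#'
#' @param v A [CTVolume] in HU.
#' @param huWindow Numeric pair `(lo, hi)` with `lo < hi`.
#' @return A normalized [CTVolume].
#' @export
normalizeMinMax <- function(v, huWindow = c(-1000, 2000)) {
  if (intensityDomain(v) != "HU") stop("normalizeMinMax expects a HU volume")
  if (huWindow[1] >= huWindow[2]) stop("hu window must satisfy lo < hi")
  g <- gridData(v)
  g <- pmin(pmax(g, huWindow[1]), huWindow[2])
  g <- (g - huWindow[1]) / (huWindow[2] - huWindow[1])
  CTVolume(array(g, dim = dim(gridData(v))), spacing = voxelSpacing(v),
           domain = "normalized")
}

fill_holes6 <- function(mask) {
  d <- dim(mask)
  comp <- labelComponents6(as.integer(!mask), as.integer(d))
  comp <- array(comp, dim = d)
  border_ids <- unique(c(comp[1, , ], comp[d[1], , ], comp[, 1, ],
                         comp[, d[2], ], comp[, , 1], comp[, , d[3]]))
  border_ids <- setdiff(border_ids, 0L)
  hole <- comp > 0 & !(comp %in% border_ids)
  mask | hole
}

#' Threshold-based body mask
#'
#' Returns the largest 6-connected component of voxels at or above the
#' threshold with interior holes filled, so air cavities inside the head stay
#' inside the mask. The default -500 HU separates osseous/soft tissue from
#' the air background.
#'
#' @param v A [CTVolume] in HU.
#' @param thresholdHu Threshold in HU.
#' @return Logical 3D array.
#' @export
bodyMask <- function(v, thresholdHu = -500) {
  if (intensityDomain(v) != "HU") stop("bodyMask expects a HU volume")
  g <- gridData(v)
  fg <- g >= thresholdHu
  if (!any(fg)) stop("no voxel at or above the threshold; empty body mask")
  comp <- labelComponents6(as.integer(fg), as.integer(dim(g)))
  tab <- tabulate(comp)
  keep <- array(comp == which.max(tab), dim = dim(g))
  fill_holes6(keep)
}

#' Crop a volume and mask to the mask's bounding box
#'
#' Crops both inputs identically to the tight bounding box of the nonzero
#' mask voxels, dilated by `marginVox` and clamped to the grid.
#'
#' @param v A [CTVolume].
#' @param m A [SinusLabels] or a binary/logical 3D array aligned with `v`.
#' @param marginVox Non-negative integer margin.
#' @return List with elements `volume` and `mask` (same kind as `m`).
#' @export
maskGuidedCrop <- function(v, m, marginVox = 0L) {
  mg <- if (is(m, "SinusLabels")) gridData(m) else m
  if (!any(mg != 0)) stop("mask is empty; nothing to crop to")
  d <- dim(mg)
  idx <- which(mg != 0, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2L, min) - marginVox, 1L)
  hi <- pmin(apply(idx, 2L, max) + marginVox, d)
  gv <- gridData(v)[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  gm <- mg[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  vol <- CTVolume(gv, spacing = voxelSpacing(v), domain = intensityDomain(v))
  mask <- if (is(m, "SinusLabels")) SinusLabels(gm, spacing = voxelSpacing(v)) else gm
  list(volume = vol, mask = mask)
}

#' Intensity-only augmentation
#'
#' Applies `x -> clip(x^gamma * s, 0, 1)` with gamma and s drawn uniformly
#' from the given ranges. Geometry is untouched; paired masks must never be
#' modified by augmentation.
#'
#' @param v A normalized [CTVolume].
#' @param gammaRange Positive pair for the gamma draw.
#' @param scaleRange Pair for the multiplicative rescale draw.
#' @param seed Integer seed; the same seed reproduces the same draw.
#' @return Augmented normalized [CTVolume].
#' @export
augmentIntensity <- function(v, gammaRange = c(0.8, 1.25),
                             scaleRange = c(0.9, 1.1), seed = 1L) {
  if (intensityDomain(v) != "normalized")
    stop("augmentIntensity expects a normalized volume")
  if (any(gammaRange <= 0)) stop("gamma range must be positive")
  set.seed(seed)
  gam <- runif(1, gammaRange[1], gammaRange[2])
  s <- runif(1, scaleRange[1], scaleRange[2])
  g <- pmin(pmax(gridData(v)^gam * s, 0), 1)
  CTVolume(g, spacing = voxelSpacing(v), domain = "normalized")
}

#' Standard preprocessing chain
#'
#' sanitize -> isotropic resample -> shape standardization -> min-max
#' normalization, the harmonization applied before any model sees a volume.
#'
#' @param v A [CTVolume] in HU.
#' @param m Optional [SinusLabels] processed with the matching geometric ops.
#' @param targetSpacingMm Isotropic target spacing.
#' @param targetShape Final grid shape.
#' @param huWindow Normalization window.
#' @return List with `volume` (normalized) and, if given, `labels`.
#' @export
preprocessVolume <- function(v, m = NULL, targetSpacingMm = 1.0,
                             targetShape = c(48L, 48L, 48L),
                             huWindow = c(-1000, 2000)) {
  v <- sanitizeVolume(v)
  v <- resampleIsotropic(v, targetSpacingMm)
  v <- standardizeShape(v, targetShape)
  v <- normalizeMinMax(v, huWindow)
  out <- list(volume = v)
  if (!is.null(m)) {
    m <- resampleIsotropic(m, targetSpacingMm)
    m <- standardizeShape(m, targetShape)
    out$labels <- m
  }
  out
}
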