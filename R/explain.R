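# Grad-CAM over the feature extractor's final convolutional layer.
#
# Channel weights are the spatial means of the gradient of a scalar target
# (a pretext output) with respect to the final conv activations; the CAM is
# the rectified weighted channel sum, trilinearly upsampled to the input
# geometry and min-max normalized.

#' Grad-CAM saliency map for a fused input
#'
#' The scalar target defaults to the sum of the four per-sinus pretext
#' outputs, yielding aggregate saliency over all sinus compartments;
#' `"max"` selects the output with the maximal predicted value (the
#' class-discriminative analog for a network without a classifier), and an
#' explicit sinus index 1..4 selects that pretext output alone. Dropout is
#' disabled. An identically-zero map (zero gradient) is passed through
#' unnormalized.
#'
#' @param model A trained `sinusExtractor` (see [buildExtractor()]).
#' @param f A [FusedInput-class].
#' @param target `"sum"`, `"max"`, or an integer sinus index in 1..4.
#' @return A [CAMMap-class] on the input geometry.
#' @export
gradCam <- function(model, f, target = "sum") {
  fwd <- fus_forward(model, f, train = FALSE)
  if (identical(target, "sum")) {
    dp <- rep(1, 4)
  } else if (identical(target, "max")) {
    dp <- numeric(4)
    dp[which.max(fwd$pretext)] <- 1
  } else {
    ti <- as.integer(target)
    if (ti < 1L || ti > 4L) stop("target index out of range (1..4)")
    dp <- numeric(4)
    dp[ti] <- 1
  }
  dA <- fus_backward(model, fwd, dp, to_conv3_only = TRUE)
  A <- fwd$tape$r3                     # final conv layer, post-activation
  d_feat <- fwd$tape$d2                # conv3 runs at the pre-pool3 grid
  CAMMap(cam_core(A, dA, d_feat, f@dims), spacing = f@spacing)
}

# Grad-CAM arithmetic: channel weights = spatial gradient means, rectified
# weighted channel sum, trilinear upsampling, per-map min-max normalization
# (identically-zero maps pass through).
cam_core <- function(A, dA, d_feat, d_out) {
  w <- colMeans(dA)
  cam <- as.numeric(A %*% w)
  cam[cam < 0] <- 0
  up <- resample_grid(array(cam, dim = d_feat), d_out, d_feat / d_out,
                      "trilinear")
  mx <- max(up)
  if (mx > 0) {
    mn <- min(up)
    up <- if (mx > mn) (up - mn) / (mx - mn) else up / mx
  }
  up
}

#' Fraction of CAM mass inside a region
#'
#' @param cam A [CAMMap-class] or numeric array with non-negative values.
#' @param region Binary array aligned with the CAM.
#' @return `sum(cam[region]) / sum(cam)`, in \[0, 1\].
#' @export
camMassFraction <- function(cam, region) {
  g <- if (is(cam, "CAMMap")) gridData(cam) else cam
  if (!identical(dim(g), dim(region))) stop("region not aligned with CAM")
  tot <- sum(g)
  if (tot <= 0) stop("CAM has zero total mass; fraction undefined")
  sum(g[region != 0]) / tot
}
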