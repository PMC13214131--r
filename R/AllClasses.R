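#' @useDynLib sinusct, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rnorm runif quantile sd setNames
#' @importFrom utils head tail write.table read.table
NULL

SINUS_LABEL_NAMES <- c(`1` = "maxillary", `2` = "ethmoid",
                       `3` = "frontal", `4` = "sphenoid")

#' Named sinus compartment labels
#'
#' Integer labels used throughout the package for the four paired paranasal
#' sinus compartments. Label 0 is background.
#'
#' @return Named character vector mapping label integers ("1".."4") to
#'   compartment names.
#' @export
sinusLabelNames <- function() SINUS_LABEL_NAMES

#' 3D CT volume with voxel spacing
#'
#' An S4 container for a dense 3D scalar grid with per-axis voxel spacing in
#' millimetres. Intensities are either calibrated Hounsfield units
#' (`domain = "HU"`) or min-max normalized to \[0, 1\]
#' (`domain = "normalized"`).
#'
#' @slot grid 3D numeric array (x, y, z voxel order).
#' @slot spacing Numeric length-3, voxel edge lengths in mm, all positive.
#' @slot domain `"HU"` or `"normalized"`.
#' @export
setClass("CTVolume",
  representation(grid = "array", spacing = "numeric", domain = "character"),
  validity = function(object) {
    if (length(dim(object@grid)) != 3L) return("grid must be a 3D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      return("spacing must be 3 positive finite values")
    if (!object@domain %in% c("HU", "normalized"))
      return("domain must be 'HU' or 'normalized'")
    if (object@domain == "normalized") {
      rng <- range(object@grid)
      if (any(!is.finite(rng)) || rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
        return("normalized volumes must lie in [0, 1]")
    }
    TRUE
  })

#' Multi-class sinus label mask
#'
#' Integer-valued 3D grid geometrically aligned with a [CTVolume]. Values are
#' 0 (background), 1 (maxillary), 2 (ethmoid), 3 (frontal), 4 (sphenoid).
#'
#' @slot grid 3D integer-valued array.
#' @slot spacing Numeric length-3 voxel spacing in mm.
#' @export
setClass("SinusLabels",
  representation(grid = "array", spacing = "numeric"),
  validity = function(object) {
    if (length(dim(object@grid)) != 3L) return("grid must be a 3D array")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be 3 positive values")
    vals <- unique(as.vector(object@grid))
    if (any(!vals %in% 0:4))
      return(sprintf("unexpected label values: %s",
                     paste(setdiff(vals, 0:4), collapse = ", ")))
    TRUE
  })

#' Autoencoder reconstruction residual map
#'
#' Voxel-wise absolute difference `|x - xhat|` between a normalized volume and
#' its autoencoder reconstruction; non-negative, same geometry as the source.
#'
#' @slot grid 3D non-negative numeric array.
#' @slot spacing Numeric length-3 voxel spacing in mm.
#' @export
setClass("ResidualMap",
  representation(grid = "array", spacing = "numeric"),
  validity = function(object) {
    if (length(dim(object@grid)) != 3L) return("grid must be a 3D array")
    if (min(object@grid) < -1e-12) return("residual values must be >= 0")
    TRUE
  })

#' Grad-CAM saliency map
#'
#' Rectified, gradient-weighted activation map min-max normalized to \[0, 1\]
#' (an identically-zero map is passed through unchanged), upsampled to the
#' geometry of the model input.
#'
#' @slot grid 3D numeric array in \[0, 1\].
#' @slot spacing Numeric length-3 voxel spacing in mm.
#' @export
setClass("CAMMap",
  representation(grid = "array", spacing = "numeric"),
  validity = function(object) {
    rng <- range(object@grid)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) return("CAM values must lie in [0, 1]")
    TRUE
  })

ANOMALY_KINDS <- c("none", "wall_thickening", "partial_opacification",
                   "total_opacification", "asymmetry")

#' Specification of a synthetic sinus CT phantom
#'
#' Parameters of the procedural phantom generator: grid geometry, tissue
#' intensities in Hounsfield units, cavity scaling, ethmoid subdivision,
#' scanner-emulating corruption (noise, blur, global intensity shift) and an
#' optional structural anomaly.
#'
#' @slot gridShape Integer length-3, all entries >= 16.
#' @slot spacingMm Numeric length-3, positive.
#' @slot huAir,huSoft,huBone,huFluid Tissue intensities (HU); must satisfy
#'   air < fluid < soft < bone.
#' @slot cavityScale Positive multiplier on all cavity radii.
#' @slot ethmoidCells Integer >= 1; number of ethmoid sub-cells per side.
#' @slot noiseSdHu Additive Gaussian noise SD (HU), >= 0.
#' @slot blurSigmaVox Gaussian blur sigma (voxels), >= 0.
#' @slot intensityShiftHu Global additive intensity shift (HU).
#' @slot anomaly One of `"none"`, `"wall_thickening"`,
#'   `"partial_opacification"`, `"total_opacification"`, `"asymmetry"`.
#' @slot anomalyStrength Real in \[0, 1\].
#' @slot seed Integer seed; generation is bit-reproducible given the spec.
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", spacingMm = "numeric",
                 huAir = "numeric", huSoft = "numeric", huBone = "numeric",
                 huFluid = "numeric", cavityScale = "numeric",
                 ethmoidCells = "integer", noiseSdHu = "numeric",
                 blurSigmaVox = "numeric", intensityShiftHu = "numeric",
                 anomaly = "character", anomalyStrength = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (length(object@gridShape) != 3L || any(object@gridShape < 16L))
      return("gridShape entries must be >= 16")
    if (any(object@spacingMm <= 0)) return("spacingMm entries must be > 0")
    if (!(object@huAir < object@huFluid && object@huFluid < object@huSoft &&
          object@huSoft < object@huBone))
      return("tissue intensities must satisfy air < fluid < soft < bone")
    if (object@cavityScale <= 0) return("cavityScale must be > 0")
    if (object@ethmoidCells < 1L) return("ethmoidCells must be >= 1")
    if (object@noiseSdHu < 0 || object@blurSigmaVox < 0)
      return("noiseSdHu and blurSigmaVox must be >= 0")
    if (!object@anomaly %in% ANOMALY_KINDS)
      return(sprintf("anomaly must be one of: %s",
                     paste(ANOMALY_KINDS, collapse = ", ")))
    if (object@anomalyStrength < 0 || object@anomalyStrength > 1)
      return("anomalyStrength must lie in [0, 1]")
    TRUE
  })

#' A generated phantom with ground truth
#'
#' @slot volume [CTVolume] in HU.
#' @slot labels [SinusLabels] aligned with the volume.
#' @slot anomalyMask Binary 3D array; all-zero iff the spec's anomaly is
#'   `"none"`; nonzero voxels lie inside or on the wall shell of a cavity.
#' @slot spec The generating [PhantomSpec].
#' @export
setClass("PhantomSample",
  representation(volume = "CTVolume", labels = "SinusLabels",
                 anomalyMask = "array", spec = "PhantomSpec"),
  validity = function(object) {
    if (!identical(dim(object@volume@grid), dim(object@labels@grid)))
      return("labels not aligned with volume")
    if (!identical(dim(object@volume@grid), dim(object@anomalyMask)))
      return("anomalyMask not aligned with volume")
    if (object@spec@anomaly == "none" && any(object@anomalyMask != 0))
      return("anomalyMask must be empty when anomaly is 'none'")
    TRUE
  })

# ---- constructors ----------------------------------------------------------

#' Create a CT volume
#'
#' @param grid 3D numeric array.
#' @param spacing Voxel spacing in mm (length 3 or scalar).
#' @param domain `"HU"` (default) or `"normalized"`.
#' @return A [CTVolume-class] object.
#' @export
CTVolume <- function(grid, spacing = c(1, 1, 1), domain = "HU") {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("CTVolume", grid = grid, spacing = as.numeric(spacing), domain = domain)
}

#' Create a sinus label mask
#'
#' @param grid 3D integer-valued array with values in 0..4.
#' @param spacing Voxel spacing in mm.
#' @return A [SinusLabels-class] object.
#' @export
SinusLabels <- function(grid, spacing = c(1, 1, 1)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  storage.mode(grid) <- "integer"
  new("SinusLabels", grid = grid, spacing = as.numeric(spacing))
}

#' @rdname ResidualMap-class
#' @param grid 3D non-negative numeric array.
#' @param spacing Voxel spacing in mm.
#' @export
ResidualMap <- function(grid, spacing = c(1, 1, 1)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("ResidualMap", grid = grid, spacing = as.numeric(spacing))
}

#' @rdname CAMMap-class
#' @param grid 3D numeric array in \[0, 1\].
#' @param spacing Voxel spacing in mm.
#' @export
CAMMap <- function(grid, spacing = c(1, 1, 1)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("CAMMap", grid = grid, spacing = as.numeric(spacing))
}

#' Create a phantom specification
#'
#' Default tissue intensities follow typical CT calibration: air -1000 HU,
#' fluid 30 HU, soft tissue 40 HU, cancellous/cortical bone 700 HU.
#'
#' @param gridShape Integer length-3 (voxels), entries >= 16.
#' @param spacingMm Voxel spacing in mm.
#' @param huAir,huSoft,huBone,huFluid Tissue intensities in HU.
#' @param cavityScale Relative cavity radius multiplier.
#' @param ethmoidCells Number of ethmoid sub-cells per side (>= 1).
#' @param noiseSdHu Gaussian noise SD in HU.
#' @param blurSigmaVox Gaussian blur sigma in voxels.
#' @param intensityShiftHu Global additive shift in HU.
#' @param anomaly Anomaly kind (see [PhantomSpec-class]).
#' @param anomalyStrength Real in \[0, 1\].
#' @param seed Integer seed.
#' @return A [PhantomSpec-class] object.
#' @export
phantomSpec <- function(gridShape = c(48L, 48L, 48L), spacingMm = c(1, 1, 1),
                        huAir = -1000, huSoft = 40, huBone = 700, huFluid = 30,
                        cavityScale = 1, ethmoidCells = 3L, noiseSdHu = 0,
                        blurSigmaVox = 0, intensityShiftHu = 0,
                        anomaly = "none", anomalyStrength = 0.5, seed = 1L) {
  if (length(spacingMm) == 1L) spacingMm <- rep(spacingMm, 3L)
  new("PhantomSpec", gridShape = as.integer(gridShape),
      spacingMm = as.numeric(spacingMm), huAir = huAir, huSoft = huSoft,
      huBone = huBone, huFluid = huFluid, cavityScale = cavityScale,
      ethmoidCells = as.integer(ethmoidCells), noiseSdHu = noiseSdHu,
      blurSigmaVox = blurSigmaVox, intensityShiftHu = intensityShiftHu,
      anomaly = anomaly, anomalyStrength = anomalyStrength,
      seed = as.integer(seed))
}

# ---- generics and accessors ------------------------------------------------

#' Extract the raw voxel grid
#' @param x A volume-like object.
#' @return The underlying 3D array.
#' @export
setGeneric("gridData", function(x) standardGeneric("gridData"))

#' Extract the voxel spacing in mm
#' @param x A volume-like object.
#' @return Numeric length-3.
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' Intensity domain of a volume
#' @param x A [CTVolume].
#' @return `"HU"` or `"normalized"`.
#' @export
setGeneric("intensityDomain", function(x) standardGeneric("intensityDomain"))

#' @rdname gridData
#' @export
setMethod("gridData", "CTVolume", function(x) x@grid)
#' @rdname gridData
#' @export
setMethod("gridData", "SinusLabels", function(x) x@grid)
#' @rdname gridData
#' @export
setMethod("gridData", "ResidualMap", function(x) x@grid)
#' @rdname gridData
#' @export
setMethod("gridData", "CAMMap", function(x) x@grid)

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "CTVolume", function(x) x@spacing)
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "SinusLabels", function(x) x@spacing)
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "ResidualMap", function(x) x@spacing)
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "CAMMap", function(x) x@spacing)

#' @rdname intensityDomain
#' @export
setMethod("intensityDomain", "CTVolume", function(x) x@domain)

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@grid)
  cat(sprintf("CTVolume %dx%dx%d voxels, spacing %.3gx%.3gx%.3g mm, %s [%.4g, %.4g]\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3], object@domain,
              min(object@grid), max(object@grid)))
})

setMethod("show", "SinusLabels", function(object) {
  d <- dim(object@grid)
  tab <- table(factor(object@grid[object@grid > 0], levels = 1:4))
  cat(sprintf("SinusLabels %dx%dx%d voxels; foreground voxels: %s\n",
              d[1], d[2], d[3],
              paste(sprintf("%s=%d", SINUS_LABEL_NAMES, as.integer(tab)),
                    collapse = ", ")))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec %dx%dx%d @ %.3g mm | anomaly=%s (strength %.2f) | noise %.3g HU, blur %.3g vox, shift %.3g HU | seed %d\n",
    object@gridShape[1], object@gridShape[2], object@gridShape[3],
    object@spacingMm[1], object@anomaly, object@anomalyStrength,
    object@noiseSdHu, object@blurSigmaVox, object@intensityShiftHu,
    object@seed))
})

setMethod("show", "PhantomSample", function(object) {
  cat("PhantomSample:\n  ")
  show(object@volume)
  cat("  ")
  show(object@labels)
  cat(sprintf("  anomaly: %s (%d voxels)\n", object@spec@anomaly,
              sum(object@anomalyMask != 0)))
})

#' @rdname gridData
#' @export
setMethod("gridData", "PhantomSample", function(x) x@volume@grid)

#' Access phantom sample components
#'
#' @param x A [PhantomSample-class].
#' @return `phantomVolume()` the [CTVolume]; `phantomLabels()` the
#'   [SinusLabels]; `anomalyMask()` the binary anomaly array;
#'   `phantomSpecOf()` the generating [PhantomSpec].
#' @export
phantomVolume <- function(x) x@volume
#' @rdname phantomVolume
#' @export
phantomLabels <- function(x) x@labels
#' @rdname phantomVolume
#' @export
anomalyMask <- function(x) x@anomalyMask
#' @rdname phantomVolume
#' @export
phantomSpecOf <- function(x) x@spec
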