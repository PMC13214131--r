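# NIfTI round-trip helpers. Spacing is carried in the pixdim header field.

#' Read / write volumes and label masks as NIfTI
#'
#' Round-trips preserve grid values bit-exactly (float64 for volumes, int16
#' for masks) and voxel spacing to well below 1e-6 mm.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param domain Intensity domain to stamp on the volume read back.
#' @return `readVolume()` a [CTVolume]; `readMask()` a [SinusLabels].
#' @export
readVolume <- function(path, domain = "HU") {
  img <- RNifti::readNifti(path)
  sp <- attr(img, "pixdim")[1:3]
  CTVolume(array(as.numeric(img), dim = dim(img)), spacing = sp,
           domain = domain)
}

#' @rdname readVolume
#' @param v A [CTVolume] to write.
#' @export
writeVolume <- function(v, path) {
  g <- gridData(v)
  attr(g, "pixdim") <- voxelSpacing(v)
  RNifti::writeNifti(RNifti::asNifti(g, datatype = "double"), path)
  invisible(path)
}

#' @rdname readVolume
#' @export
readMask <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- attr(img, "pixdim")[1:3]
  g <- array(as.integer(img), dim = dim(img))
  bad <- setdiff(unique(as.vector(g)), 0:4)
  if (length(bad) > 0) {
    warning(sprintf("mask %s contains unexpected labels: %s; clamping to 0",
                    path, paste(bad, collapse = ", ")))
    g[!(g %in% 0:4)] <- 0L
  }
  SinusLabels(g, spacing = sp)
}

#' @rdname readVolume
#' @param m A [SinusLabels] to write.
#' @export
writeMask <- function(m, path) {
  g <- gridData(m)
  attr(g, "pixdim") <- voxelSpacing(m)
  RNifti::writeNifti(RNifti::asNifti(g, datatype = "int16"), path)
  invisible(path)
}

write_binary_nifti <- function(arr, spacing, path) {
  g <- array(as.integer(arr != 0), dim = dim(arr))
  attr(g, "pixdim") <- spacing
  RNifti::writeNifti(RNifti::asNifti(g, datatype = "int16"), path)
  invisible(path)
}
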