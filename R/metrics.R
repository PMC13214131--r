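# Segmentation evaluation: overlap metrics and the 95th-percentile Hausdorff
# distance in millimetres, computed per class in 3D.

#' Binary overlap metrics
#'
#' Dice, Jaccard, precision and recall from confusion counts. When both masks
#' are empty all four are defined as 1; when exactly one is empty, Dice and
#' Jaccard are 0 and the undefined ratio is reported as 0.
#'
#' @param pred,gt Binary/logical 3D arrays of identical shape.
#' @return Named list with `dice`, `jaccard`, `precision`, `recall`.
#' @export
overlapMetrics <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt))) stop("shape mismatch between pred and gt")
  p <- pred != 0
  g <- gt != 0
  np <- sum(p)
  ng <- sum(g)
  if (np == 0 && ng == 0)
    return(list(dice = 1, jaccard = 1, precision = 1, recall = 1))
  tp <- sum(p & g)
  list(dice = 2 * tp / (np + ng),
       jaccard = tp / (np + ng - tp),
       precision = if (np > 0) tp / np else 0,
       recall = if (ng > 0) tp / ng else 0)
}

# Surface voxels: mask voxels with at least one 6-neighbour (face adjacency)
# outside the mask; the grid border counts as outside. Returns 0-based voxel
# coordinates, one row per surface voxel.
surface_voxels <- function(mask) {
  m <- mask != 0
  d <- dim(m)
  shift_out <- function(off, axis) {
    # neighbour value with out-of-bounds treated as FALSE (outside)
    out <- array(FALSE, d)
    idx_src <- seq_len(d[axis]) + off
    ok <- idx_src >= 1 & idx_src <= d[axis]
    dst <- which(ok)
    src <- idx_src[ok]
    if (axis == 1) out[dst, , ] <- m[src, , ]
    if (axis == 2) out[, dst, ] <- m[, src, ]
    if (axis == 3) out[, , dst] <- m[, , src]
    out
  }
  exposed <- array(FALSE, d)
  for (axis in 1:3) for (off in c(-1L, 1L))
    exposed <- exposed | !shift_out(off, axis)
  which(m & exposed, arr.ind = TRUE) - 1L
}

#' 95th-percentile Hausdorff distance in mm
#'
#' Surface voxels are mask voxels with a face neighbour outside the mask
#' (grid border counts as outside). Directed distances are Euclidean mm
#' distances from each surface voxel of one mask to the nearest surface voxel
#' of the other; HD95 is the 95th percentile (linear interpolation between
#' order statistics) of the pooled bidirectional distance multiset, hence
#' symmetric by construction.
#'
#' @param pred,gt Binary/logical 3D arrays of identical shape.
#' @param spacingMm Voxel spacing in mm (length 3 or scalar).
#' @return HD95 in mm, or `NA` with a `"reason"` attribute when a mask is
#'   empty.
#' @export
hd95 <- function(pred, gt, spacingMm = c(1, 1, 1)) {
  if (!identical(dim(pred), dim(gt))) stop("shape mismatch between pred and gt")
  if (length(spacingMm) == 1L) spacingMm <- rep(spacingMm, 3L)
  if (!any(pred != 0) || !any(gt != 0)) {
    out <- NA_real_
    attr(out, "reason") <- "empty mask: surface distance undefined"
    return(out)
  }
  sp <- surface_voxels(pred)
  sg <- surface_voxels(gt)
  d_pg <- minSurfaceDists(sp, sg, as.numeric(spacingMm))
  d_gp <- minSurfaceDists(sg, sp, as.numeric(spacingMm))
  unname(stats::quantile(c(d_pg, d_gp), probs = 0.95, type = 7))
}

#' Per-class segmentation evaluation
#'
#' Binarizes each foreground class of the predicted and ground-truth label
#' masks and reports Dice, Jaccard, precision, recall and HD95 (mm) per
#' class plus means over classes (HD95 mean over defined values only).
#'
#' @param pred,gt [SinusLabels] of identical geometry.
#' @param spacingMm Voxel spacing override; defaults to the ground truth's.
#' @return List with `per_class` (data.frame, one row per foreground class)
#'   and `mean` (named numeric over the foreground classes).
#' @export
evaluateSegmentation <- function(pred, gt, spacingMm = NULL) {
  pg <- gridData(pred)
  gg <- gridData(gt)
  if (!identical(dim(pg), dim(gg))) stop("prediction and ground truth misaligned")
  if (is.null(spacingMm)) spacingMm <- voxelSpacing(gt)
  labs <- 1:4
  present <- union(unique(pg[pg > 0]), unique(gg[gg > 0]))
  if (length(present) > 0 && !any(present %in% labs))
    stop("label sets share no foreground class in 1..4")
  rows <- lapply(labs, function(k) {
    om <- overlapMetrics(pg == k, gg == k)
    h <- hd95(pg == k, gg == k, spacingMm)
    data.frame(label = k, name = unname(SINUS_LABEL_NAMES[as.character(k)]),
               dice = om$dice, jaccard = om$jaccard, precision = om$precision,
               recall = om$recall, hd95_mm = as.numeric(h),
               stringsAsFactors = FALSE)
  })
  per_class <- do.call(rbind, rows)
  means <- c(dice = mean(per_class$dice), jaccard = mean(per_class$jaccard),
             precision = mean(per_class$precision),
             recall = mean(per_class$recall),
             hd95_mm = mean(per_class$hd95_mm, na.rm = TRUE))
  list(per_class = per_class, mean = means)
}

#' Aggregate per-subject evaluation reports
#'
#' Cohort-level mean and standard deviation of Dice and HD95 per class,
#' mirroring the usual per-sinus reporting layout.
#'
#' @param reports List of results from [evaluateSegmentation()].
#' @return data.frame with one row per sinus class.
#' @export
aggregateEvalReports <- function(reports) {
  stopifnot(length(reports) > 0)
  labs <- 1:4
  rows <- lapply(labs, function(k) {
    dice <- vapply(reports, function(r) r$per_class$dice[r$per_class$label == k],
                   numeric(1))
    h <- vapply(reports, function(r) r$per_class$hd95_mm[r$per_class$label == k],
                numeric(1))
    data.frame(label = k, name = unname(SINUS_LABEL_NAMES[as.character(k)]),
               dice_mean = mean(dice), dice_sd = sd(dice),
               hd95_mean = mean(h, na.rm = TRUE),
               hd95_sd = sd(h, na.rm = TRUE),
               n = length(reports), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
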