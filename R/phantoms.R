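# Procedural sinus CT phantoms.
#
# A head-shaped soft-tissue/bone ellipsoid on an air background carries four
# bilateral pairs of air-filled cavities with thin bony walls, mimicking the
# maxillary, ethmoid, frontal and sphenoid sinuses. The ethmoid analog is
# subdivided into small cells by 1-voxel bone septa. Cavity geometry uses
# fixed, anatomically inspired relative centers (maxillary lateral-inferior,
# ethmoid paramedian-central, frontal superior, sphenoid posterior-central)
# so the ground truth is exactly reproducible.

# Relative cavity geometry: centers/radii as fractions of the grid extent per
# axis; x is mirrored for the two sides.
cavity_table <- function(cavityScale = 1) {
  base <- data.frame(
    name   = c("maxillary", "ethmoid", "frontal", "sphenoid"),
    label  = 1:4,
    dx     = c(0.200, 0.070, 0.090, 0.075),  # lateral offset from midline
    cy     = c(0.420, 0.400, 0.380, 0.620),
    cz     = c(0.380, 0.520, 0.700, 0.480),
    rx     = c(0.100, 0.055, 0.070, 0.055),
    ry     = c(0.110, 0.100, 0.050, 0.080),
    rz     = c(0.110, 0.080, 0.070, 0.060),
    stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(c(-1, 1), function(side) {
    d <- base
    d$cx <- 0.5 + side * d$dx
    d$side <- if (side < 0) "left" else "right"
    d
  }))
  out$rx <- out$rx * cavityScale
  out$ry <- out$ry * cavityScale
  out$rz <- out$rz * cavityScale
  out$id <- paste(out$name, out$side, sep = "_")
  out
}

# Normalized ellipsoid radius field for one cavity over the voxel-center grid.
cavity_rho <- function(coords, cx, cy, cz, rx, ry, rz) {
  ax <- ((coords$x - cx) / rx)^2
  ay <- ((coords$y - cy) / ry)^2
  az <- ((coords$z - cz) / rz)^2
  sqrt(outer(outer(ax, ay, "+"), az, "+"))
}

# Separable Gaussian blur, sigma in voxels; kernel truncated at 3 sigma.
gauss_blur3 <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w <- w / sum(w)
  d <- dim(arr)
  shift_axis <- function(a, off, axis) {
    # replicate-padding shift along one axis
    idx <- pmin(pmax(seq_len(d[axis]) + off, 1L), d[axis])
    switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
           a[, , idx, drop = FALSE])
  }
  for (axis in 1:3) {
    out <- array(0, d)
    for (t in seq_along(w)) out <- out + w[t] * shift_axis(arr, t - r - 1L, axis)
    arr <- out
  }
  arr
}

#' Generate a synthetic sinus CT phantom
#'
#' Deterministically renders the phantom described by `spec`: a head-shaped
#' soft-tissue ellipsoid with a bone shell on an air background, four
#' bilateral air-filled cavity pairs (labels 1-4) with thin bony walls, the
#' ethmoid subdivided into cells by 1-voxel septa, an optional structural
#' anomaly affecting one randomly chosen (seeded) cavity, and finally
#' Gaussian blur, Gaussian noise and a global intensity shift emulating
#' scanner variability.
#'
#' @param spec A [PhantomSpec-class].
#' @return A [PhantomSample-class] with the HU volume, label mask, binary
#'   anomaly ground-truth mask and the generating spec.
#' @examples
#' s <- generatePhantom(phantomSpec(gridShape = c(32, 32, 32)))
#' table(gridData(phantomLabels(s)))
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  d <- spec@gridShape
  coords <- list(x = (seq_len(d[1]) - 0.5) / d[1],
                 y = (seq_len(d[2]) - 0.5) / d[2],
                 z = (seq_len(d[3]) - 0.5) / d[3])
  cav <- cavity_table(spec@cavityScale)

  # bounds check: cavity plus wall must stay inside the unit cube
  wall_frac <- 1.5 / (pmin(cav$rx, cav$ry, cav$rz) * mean(d))  # ~1.5 voxels
  for (i in seq_len(nrow(cav))) {
    wf <- 1 + wall_frac[i]
    lo <- c(cav$cx[i] - cav$rx[i] * wf, cav$cy[i] - cav$ry[i] * wf,
            cav$cz[i] - cav$rz[i] * wf)
    hi <- c(cav$cx[i] + cav$rx[i] * wf, cav$cy[i] + cav$ry[i] * wf,
            cav$cz[i] + cav$rz[i] * wf)
    if (any(lo < 0) || any(hi > 1))
      stop(sprintf("cavity '%s' exceeds the grid bounds at cavityScale %.3g",
                   cav$id[i], spec@cavityScale))
  }

  # head: outer soft tissue, bone shell, inner soft tissue
  hx <- ((coords$x - 0.5) / 0.44)^2
  hy <- ((coords$y - 0.5) / 0.46)^2
  hz <- ((coords$z - 0.5) / 0.46)^2
  head_r <- sqrt(outer(outer(hx, hy, "+"), hz, "+"))
  vol <- array(spec@huAir, dim = d)
  vol[head_r <= 1] <- spec@huSoft
  vol[head_r > 0.80 & head_r <= 0.93] <- spec@huBone

  # cavities: assign by smallest normalized radius so labels never overlap
  rho <- array(Inf, dim = d)
  which_cav <- array(0L, dim = d)
  for (i in seq_len(nrow(cav))) {
    ri <- cavity_rho(coords, cav$cx[i], cav$cy[i], cav$cz[i],
                     cav$rx[i], cav$ry[i], cav$rz[i])
    closer <- ri < rho
    rho[closer] <- ri[closer]
    which_cav[closer] <- i
  }
  labels <- array(0L, dim = d)
  inside <- rho <= 1
  labels[inside] <- cav$label[which_cav[inside]]
  vol[inside] <- spec@huAir
  wall <- rho > 1 & rho <= 1 + wall_frac[pmax(which_cav, 1L)]
  vol[wall & !inside] <- spec@huBone

  # ethmoid septations: 1-voxel bone walls along y, per side
  if (spec@ethmoidCells > 1L) {
    yvox <- rep(rep(seq_len(d[2]) - 0.5, each = d[1]), times = d[3])
    for (i in which(cav$name == "ethmoid")) {
      sel_cav <- which_cav == i & inside
      for (q in seq_len(spec@ethmoidCells - 1L)) {
        ysep <- (cav$cy[i] - cav$ry[i] + 2 * cav$ry[i] * q / spec@ethmoidCells) * d[2]
        sep <- sel_cav & array(abs(yvox - ysep) <= 0.5, dim = d)
        vol[sep] <- spec@huBone
        labels[sep] <- 0L
      }
    }
  }

  # anomaly in one randomly chosen cavity instance
  amask <- array(0L, dim = d)
  if (spec@anomaly != "none") {
    set.seed(deriveSeed(spec@seed, 17L))
    i <- sample.int(nrow(cav), 1L)
    sel <- which_cav == i
    rho_i <- cavity_rho(coords, cav$cx[i], cav$cy[i], cav$cz[i],
                        cav$rx[i], cav$ry[i], cav$rz[i])
    in_i <- sel & rho_i <= 1 & labels == cav$label[i]
    st <- spec@anomalyStrength
    if (spec@anomaly == "wall_thickening") {
      rind <- in_i & rho_i > 1 - 0.5 * st
      vol[rind] <- spec@huSoft
      amask[rind] <- 1L
    } else if (spec@anomaly == "partial_opacification") {
      zvox <- array(rep(seq_len(d[3]) - 0.5, each = d[1] * d[2]), dim = d)
      zz <- zvox[in_i]
      if (length(zz) > 0 && st > 0) {
        zcut <- stats::quantile(zz, probs = st, type = 7)
        fill <- in_i & zvox <= zcut
        vol[fill] <- spec@huFluid
        amask[fill] <- 1L
      }
    } else if (spec@anomaly == "total_opacification") {
      vol[in_i] <- spec@huFluid
      amask[in_i] <- 1L
    } else if (spec@anomaly == "asymmetry") {
      shrink <- max(1 - st, 1e-6)
      rho_s <- rho_i / shrink
      gone <- in_i & rho_s > 1
      vol[gone] <- spec@huBone
      labels[gone] <- 0L
      amask[gone] <- 1L
    }
  }

  # scanner emulation: blur, then noise, then global shift
  if (spec@blurSigmaVox > 0) vol <- gauss_blur3(vol, spec@blurSigmaVox)
  if (spec@noiseSdHu > 0) {
    set.seed(deriveSeed(spec@seed, 29L))
    vol <- vol + array(rnorm(prod(d), sd = spec@noiseSdHu), dim = d)
  }
  vol <- vol + spec@intensityShiftHu

  new("PhantomSample",
      volume = CTVolume(vol, spacing = spec@spacingMm, domain = "HU"),
      labels = SinusLabels(labels, spacing = spec@spacingMm),
      anomalyMask = amask, spec = spec)
}

# Per-sample jittered specs for a cohort; pure function of (n, baseSpec,
# anomalyFraction, seed). Scanner-style jitter: noise U[3,10] HU, blur
# U[0.3,0.9] voxels, shift U[-25,25] HU; subject-style jitter: cavityScale
# multiplied by U[0.92,1.08]. round(anomalyFraction*n) randomly placed
# samples carry a randomly chosen anomaly with strength U[0.3,1].
cohortSpecs <- function(n, baseSpec, anomalyFraction = 0, seed = 1L) {
  stopifnot(n >= 1)
  set.seed(deriveSeed(seed, 3L))
  n_anom <- round(anomalyFraction * n)
  anom_rows <- if (n_anom > 0) sort(sample.int(n, n_anom)) else integer(0)
  kinds <- setdiff(ANOMALY_KINDS, "none")
  lapply(seq_len(n), function(i) {
    set.seed(deriveSeed(seed, 5L, i))
    sp <- baseSpec
    sp@noiseSdHu <- runif(1, 3, 10)
    sp@blurSigmaVox <- runif(1, 0.3, 0.9)
    sp@intensityShiftHu <- runif(1, -25, 25)
    sp@cavityScale <- baseSpec@cavityScale * runif(1, 0.92, 1.08)
    if (i %in% anom_rows) {
      sp@anomaly <- sample(kinds, 1L)
      sp@anomalyStrength <- runif(1, 0.3, 1)
    } else {
      sp@anomaly <- "none"
    }
    sp@seed <- deriveSeed(seed, 11L, i)
    sp
  })
}

#' Generate a phantom cohort on disk
#'
#' Renders `n` jittered phantoms (see [generatePhantom()]) and writes, per
#' sample, `vol_<id>.nii.gz`, `lab_<id>.nii.gz` and `anom_<id>.nii.gz`
#' together with a JSON-lines manifest (`manifest.jsonl`) and a tab-delimited
#' table (`manifest.tsv`) recording file paths, spec values and anomaly
#' status. Per-sample noise/blur/shift are drawn from scanner-emulating
#' ranges and `round(anomalyFraction * n)` samples carry a randomly chosen
#' anomaly; everything is a deterministic function of `seed`.
#'
#' @param n Number of phantoms (>= 1).
#' @param baseSpec Template [PhantomSpec-class].
#' @param anomalyFraction Fraction of anomalous samples in \[0, 1\].
#' @param outDir Output directory (created if missing).
#' @param seed Integer seed controlling all jitter and anomaly placement.
#' @return The manifest as a data.frame (invisibly written to disk).
#' @export
generateCohort <- function(n, baseSpec = phantomSpec(), anomalyFraction = 0,
                           outDir, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create output directory '%s'", outDir))
  specs <- cohortSpecs(n, baseSpec, anomalyFraction, seed)
  rows <- lapply(seq_len(n), function(i) {
    sp <- specs[[i]]
    smp <- generatePhantom(sp)
    id <- sprintf("s%03d", i)
    pv <- file.path(outDir, sprintf("vol_%s.nii.gz", id))
    pl <- file.path(outDir, sprintf("lab_%s.nii.gz", id))
    pa <- file.path(outDir, sprintf("anom_%s.nii.gz", id))
    writeVolume(phantomVolume(smp), pv)
    writeMask(phantomLabels(smp), pl)
    write_binary_nifti(anomalyMask(smp), sp@spacingMm, pa)
    data.frame(id = id, volume = pv, labels = pl, anomaly_mask = pa,
               anomaly = sp@anomaly,
               anomaly_strength = if (sp@anomaly == "none") 0 else sp@anomalyStrength,
               noise_sd_hu = sp@noiseSdHu, blur_sigma_vox = sp@blurSigmaVox,
               intensity_shift_hu = sp@intensityShiftHu,
               cavity_scale = sp@cavityScale, seed = sp@seed,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  jsonl <- vapply(seq_len(nrow(manifest)), function(i) {
    as.character(jsonlite::toJSON(as.list(manifest[i, ]), auto_unbox = TRUE,
                                  digits = NA))
  }, character(1))
  writeLines(jsonl, file.path(outDir, "manifest.jsonl"))
  write.table(manifest, file.path(outDir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Generate a phantom cohort in memory
#'
#' Same jitter and anomaly placement as [generateCohort()] but returns the
#' rendered [PhantomSample-class] objects directly without touching disk.
#'
#' @inheritParams generateCohort
#' @return List of `n` [PhantomSample-class] objects.
#' @export
generateCohortSamples <- function(n, baseSpec = phantomSpec(),
                                  anomalyFraction = 0, seed = 1L) {
  lapply(cohortSpecs(n, baseSpec, anomalyFraction, seed), generatePhantom)
}
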