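# End-to-end orchestration: generate/preprocess -> segment -> CAE residual ->
# fuse/embed -> Grad-CAM -> evaluate, with provenance logging. Each stage
# consumes the previous stage's outputs; one global seed deterministically
# derives per-stage seeds.

#' Pipeline run configuration
#'
#' The `"desk"` profile is the CPU-scale configuration used throughout the
#' tests; `"full"` swaps in the full-scale model configurations and training
#' recipes (GPU-scale; provided for completeness, not exercised by tests).
#'
#' @param outDir Run directory (created on execution).
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param profile `"desk"` or `"full"`.
#' @param nSegTrain,nSegTest Segmentation cohort sizes.
#' @param nCaeTrain Normal-only autoencoder cohort size.
#' @param nAnomTest Anomalous evaluation cohort size.
#' @param anomalyFraction Anomalous fraction of the segmentation cohorts.
#' @param segVariant,fusionVariant Ablation switches (see [segConfig()] and
#'   [assembleInput()]); together with `segEpochs = 0` style overrides these
#'   express the ablation matrix purely via configuration.
#' @param segEpochs,segLr,segBatch Segmenter training budget.
#' @param caeEpochs Autoencoder training budget.
#' @param nFusTrain Size of the dedicated (all-anomalous) feature-extractor
#'   training cohort (75% anomalous).
#' @param fusEpochs Feature-extractor training budget.
#' @return A `runConfig` list.
#' @export
runConfig <- function(outDir = tempfile("sinusct_run_"), seed = 1L,
                      profile = c("desk", "full"),
                      nSegTrain = 32L, nSegTest = 8L, nCaeTrain = 16L,
                      nAnomTest = 16L, anomalyFraction = 0.25,
                      segVariant = "full", fusionVariant = "full",
                      segEpochs = NULL, segLr = NULL, segBatch = NULL,
                      caeEpochs = NULL, nFusTrain = 32L, fusEpochs = 60L) {
  profile <- match.arg(profile)
  desk <- profile == "desk"
  cfg <- list(
    outDir = outDir, seed = as.integer(seed), profile = profile,
    nSegTrain = nSegTrain, nSegTest = nSegTest, nCaeTrain = nCaeTrain,
    nAnomTest = nAnomTest, anomalyFraction = anomalyFraction,
    segConfig = if (desk) segConfig(variant = segVariant) else
      segConfig(inShape = c(96L, 96L, 96L), embedDim = 96L,
                depths = c(2L, 2L, 6L, 2L), heads = c(3L, 6L, 12L, 24L),
                window = 7L, convFilters = c(32L, 64L, 128L, 256L),
                mlpRatio = 4, variant = segVariant),
    segOpts = trainOpts(
      lr = if (is.null(segLr)) (if (desk) 3e-3 else 1e-4) else segLr,
      schedule = if (desk) "constant" else "cosine",
      epochs = if (is.null(segEpochs)) (if (desk) 13L else 200L) else segEpochs,
      batchSize = if (is.null(segBatch)) (if (desk) 1L else 2L) else segBatch,
      seed = deriveSeed(seed, 21L)),
    caeConfig = if (desk) caeConfig() else caeConfigFull(),
    caeEpochs = if (is.null(caeEpochs)) (if (desk) 100L else 200L) else caeEpochs,
    nFusTrain = as.integer(nFusTrain),
    fusEpochs = fusEpochs,
    fusionVariant = fusionVariant,
    phantomShape = if (desk) c(48L, 48L, 48L) else c(96L, 96L, 96L))
  class(cfg) <- "runConfig"
  cfg
}

md5_of <- function(paths) {
  h <- tools::md5sum(paths[file.exists(paths)])
  lapply(names(h), function(p) list(path = p, md5 = unname(h[p])))
}

stage_logger <- function(path) {
  function(stage, seed, t0, outputs = character(0)) {
    line <- jsonlite::toJSON(list(
      stage = stage, seed = seed,
      wall_s = round(as.numeric(proc.time()[3] - t0), 3),
      outputs = md5_of(outputs)), auto_unbox = TRUE)
    cat(as.character(line), "\n", sep = "", file = path, append = TRUE)
  }
}

#' Run the full analysis pipeline
#'
#' Executes generate -> preprocess/train segmenter -> evaluate -> train CAE
#' -> residual/anomaly contrast -> fuse/embed -> Grad-CAM, writing all
#' artifacts plus a structured JSON-lines log (stage, wall time, output
#' hashes) and a summary to the run directory. Any stage failure aborts with
#' the stage name. Deterministic given the config seed.
#'
#' @param cfg A [runConfig()].
#' @return Invisibly, a list with the run directory, evaluation report,
#'   anomaly contrasts, CAM statistics, embedding silhouette and summary.
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "runConfig"))
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(cfg$outDir)) stop("cannot create run directory")
  logf <- stage_logger(file.path(cfg$outDir, "log.jsonl"))
  run_stage <- function(name, seed, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    logf(name, seed, t0, if (is.character(out$files)) out$files else character(0))
    out
  }
  base <- phantomSpec(gridShape = cfg$phantomShape)

  g <- run_stage("generate", cfg$seed, {
    dd <- file.path(cfg$outDir, "data")
    m_tr <- generateCohort(cfg$nSegTrain, base, cfg$anomalyFraction,
                           file.path(dd, "seg_train"), deriveSeed(cfg$seed, 1L))
    m_te <- generateCohort(cfg$nSegTest, base, cfg$anomalyFraction,
                           file.path(dd, "seg_test"), deriveSeed(cfg$seed, 2L))
    m_cae <- generateCohort(cfg$nCaeTrain, base, 0,
                            file.path(dd, "cae_train"), deriveSeed(cfg$seed, 3L))
    m_an <- generateCohort(cfg$nAnomTest, base, 1,
                           file.path(dd, "anom_test"), deriveSeed(cfg$seed, 4L))
    list(train = m_tr, test = m_te, cae = m_cae, anom = m_an,
         files = c(file.path(dd, "seg_train", "manifest.tsv"),
                   file.path(dd, "seg_test", "manifest.tsv"),
                   file.path(dd, "cae_train", "manifest.tsv"),
                   file.path(dd, "anom_test", "manifest.tsv")))
  })

  load_rec <- function(row) {
    list(volume = readVolume(row$volume), labels = readMask(row$labels),
         anomaly = gridData(readMask(row$anomaly_mask)))
  }

  seg <- run_stage("train_segmenter", cfg$segOpts$seed, {
    recs <- lapply(seq_len(nrow(g$train)), function(i) {
      r <- load_rec(g$train[i, ])
      pp <- preprocessVolume(r$volume, r$labels,
                             targetShape = cfg$segConfig$inShape)
      list(volume = pp$volume, labels = pp$labels, pseudo = FALSE)
    })
    model <- buildSegmenter(cfg$segConfig, seed = deriveSeed(cfg$seed, 31L))
    model <- trainSegmenter(model, recs, cfg$segOpts)
    ck <- file.path(cfg$outDir, "segmenter.rds")
    saveRDS(model, ck)
    list(model = model, files = ck)
  })

  ev <- run_stage("evaluate_segmentation", cfg$seed, {
    reports <- list()
    preds <- list()
    for (i in seq_len(nrow(g$test))) {
      r <- load_rec(g$test[i, ])
      pp <- preprocessVolume(r$volume, r$labels,
                             targetShape = cfg$segConfig$inShape)
      pred <- predictMask(seg$model, pp$volume)
      preds[[i]] <- list(pred = pred, rec = r, pp = pp)
      reports[[i]] <- evaluateSegmentation(predictionLabels(pred), pp$labels)
      writeMask(predictionLabels(pred),
                file.path(cfg$outDir, sprintf("pred_%s.nii.gz", g$test$id[i])))
    }
    agg <- aggregateEvalReports(reports)
    per_subj <- do.call(rbind, lapply(seq_along(reports), function(i) {
      d <- reports[[i]]$per_class
      d$id <- g$test$id[i]
      d
    }))
    f1 <- file.path(cfg$outDir, "eval_per_subject.tsv")
    f2 <- file.path(cfg$outDir, "eval_aggregate.tsv")
    write.table(per_subj, f1, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(agg, f2, sep = "\t", quote = FALSE, row.names = FALSE)
    list(reports = reports, aggregate = agg, preds = preds, files = c(f1, f2))
  })

  cae <- run_stage("train_cae", cfg$seed, {
    vols <- lapply(seq_len(nrow(g$cae)), function(i) {
      r <- load_rec(g$cae[i, ])
      caePrepareSample(r, cfg$caeConfig)$volume
    })
    model <- buildCAE(cfg$caeConfig, seed = deriveSeed(cfg$seed, 41L))
    model <- trainCAE(model, vols, epochs = cfg$caeEpochs,
                      seed = deriveSeed(cfg$seed, 42L))
    ck <- file.path(cfg$outDir, "cae.rds")
    saveRDS(model, ck)
    list(model = model, files = ck)
  })

  an <- run_stage("anomaly_residuals", cfg$seed, {
    rows <- lapply(seq_len(nrow(g$anom)), function(i) {
      r <- load_rec(g$anom[i, ])
      pp <- caePrepareSample(r, cfg$caeConfig)
      rm <- residualMap(cae$model, pp$volume)
      writeVolume(CTVolume(gridData(rm$residual), voxelSpacing(rm$residual)),
                  file.path(cfg$outDir, sprintf("residual_%s.nii.gz", g$anom$id[i])))
      am <- pp$anomaly
      ref <- (gridData(pp$labels) > 0) & (am == 0)
      ctr <- if (any(am != 0) && any(ref))
        anomalyContrast(rm$residual, am, ref) else NA_real_
      list(pp = pp, residual = rm$residual, contrast = ctr)
    })
    contrasts <- vapply(rows, function(x) x$contrast, numeric(1))
    f <- file.path(cfg$outDir, "anomaly_contrast.tsv")
    write.table(data.frame(id = g$anom$id, anomaly = g$anom$anomaly,
                           strength = g$anom$anomaly_strength,
                           contrast = contrasts),
                f, sep = "\t", quote = FALSE, row.names = FALSE)
    list(rows = rows, contrasts = contrasts, files = f)
  })

  fus <- run_stage("train_extractor", cfg$seed, {
    # dedicated anomaly-rich cohort: strong per-sinus pretext variance
    m_fus <- generateCohort(cfg$nFusTrain, base, 0.75,
                            file.path(cfg$outDir, "data", "fusion_train"),
                            deriveSeed(cfg$seed, 5L))
    tr <- lapply(seq_len(nrow(m_fus)), function(i) {
      r <- load_rec(m_fus[i, ])
      pp <- caePrepareSample(r, cfg$caeConfig)
      rm <- residualMap(cae$model, pp$volume)
      list(input = assembleInput(pp$volume, pp$labels, rm$residual,
                                 cfg$fusionVariant),
           target = pretextTargets(pp$labels, rm$residual))
    })
    model <- buildExtractor(seed = deriveSeed(cfg$seed, 51L))
    model <- trainExtractor(model, tr, epochs = cfg$fusEpochs, lr = 3e-3,
                            seed = deriveSeed(cfg$seed, 52L))
    ck <- file.path(cfg$outDir, "extractor.rds")
    saveRDS(model, ck)
    list(model = model, train_inputs = tr, files = ck)
  })

  emb <- run_stage("embeddings", cfg$seed, {
    make_emb <- function(manifest) {
      t(vapply(seq_len(nrow(manifest)), function(i) {
        r <- load_rec(manifest[i, ])
        pp <- caePrepareSample(r, cfg$caeConfig)
        rm <- residualMap(cae$model, pp$volume)
        fi <- assembleInput(pp$volume, pp$labels, rm$residual, cfg$fusionVariant)
        extractEmbedding(fus$model, fi)
      }, numeric(fus$model$config$embedLen)))
    }
    E_norm <- make_emb(g$cae)          # normal cohort
    E_anom <- make_emb(g$anom)         # anomalous cohort
    E <- rbind(E_norm, E_anom)
    groups <- c(rep("normal", nrow(E_norm)), rep("anomalous", nrow(E_anom)))
    sil <- embeddingSilhouette(E, groups)
    f <- file.path(cfg$outDir, "embeddings.tsv")
    write.table(data.frame(id = c(g$cae$id, g$anom$id), group = groups,
                           round(E, 6)),
                f, sep = "\t", quote = FALSE, row.names = FALSE)
    list(silhouette = sil, files = f)
  })

  cam <- run_stage("grad_cam", cfg$seed, {
    fr <- vapply(seq_along(an$rows)[seq_len(min(length(an$rows), 16L))],
                 function(i) {
      row <- an$rows[[i]]
      fi <- assembleInput(row$pp$volume, row$pp$labels, row$residual,
                          cfg$fusionVariant)
      cm <- gradCam(fus$model, fi)
      writeVolume(CTVolume(gridData(cm), voxelSpacing(cm)),
                  file.path(cfg$outDir, sprintf("cam_%s.nii.gz", g$anom$id[i])))
      region <- gridData(row$pp$labels) > 0
      c(camMassFraction(cm, region), mean(region))
    }, numeric(2))
    f <- file.path(cfg$outDir, "cam_fractions.tsv")
    write.table(data.frame(id = g$anom$id[seq_len(ncol(fr))],
                           cam_fraction = fr[1, ], volume_fraction = fr[2, ]),
                f, sep = "\t", quote = FALSE, row.names = FALSE)
    list(fractions = fr[1, ], volume_fractions = fr[2, ], files = f)
  })

  summary <- list(
    profile = cfg$profile, seed = cfg$seed,
    mean_foreground_dice = mean(vapply(ev$reports,
      function(r) mean(r$per_class$dice), numeric(1))),
    dice_per_class = stats::setNames(ev$aggregate$dice_mean, ev$aggregate$name),
    hd95_per_class = stats::setNames(ev$aggregate$hd95_mean, ev$aggregate$name),
    median_anomaly_contrast = stats::median(an$contrasts, na.rm = TRUE),
    median_cam_fraction = stats::median(cam$fractions),
    mean_sinus_volume_fraction = mean(cam$volume_fractions),
    embedding_silhouette = emb$silhouette)
  jsonlite::write_json(summary, file.path(cfg$outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(runDir = cfg$outDir, summary = summary,
                 evaluation = ev$aggregate, contrasts = an$contrasts,
                 camFractions = cam$fractions, silhouette = emb$silhouette,
                 segmenter = seg$model, cae = cae$model, extractor = fus$model))
}
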