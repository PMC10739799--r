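# Pipeline wiring: simulate -> preprocess -> train -> predict -> evaluate
# -> analyze, driven by one YAML config with a single global seed. Every
# stage reads only its own config block, writes plain artifacts (TIFF/PNG/
# CSV/JSON) under the output root, and derives all randomness from the
# global seed, so reruns with the same config reproduce the simulate/
# evaluate/analyze artifacts bit-identically.

PIPELINE_STAGES <- c("simulate", "preprocess", "train", "predict",
                     "evaluate", "analyze")

#' Default pipeline configuration
#'
#' A scaled-down end-to-end run on synthetic scenes, suitable for a single
#' CPU. Any block can be overridden by the YAML config.
#' @return nested configuration list.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    out = "gobletseg-run",
    scene = list(widthPx = 96L, heightPx = 96L, umPerPx = 0.5,
                 targetDensity = 1500, nScenes = 8L, nCases = 4L,
                 clusterProb = 0.2, vesselCount = 1L, artifactRate = 10,
                 mosaic = NULL),
    preprocess = list(clahe = TRUE, clipLimit = 0.01, grid = c(4L, 4L)),
    model = list(arch = "dcau", depth = 2L, baseChannels = 8L,
                 textureKernelLen = 7L),
    train = list(epochs = 8L, lr = 1e-3, decayEvery = 20L,
                 decayFactor = 0.5, earlyStopPatience = 10L,
                 batchSize = 2L, kFolds = 4L),
    loss = list(diceWeight = 0.7, focalWeight = 0.3),
    analysis = list(threshold = 0.5, minAreaPx = 5)
  )
}

mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(override[[nm]]))
      mergeConfig(base[[nm]], override[[nm]]) else override[[nm]]
  }
  base
}

configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

sceneParamsFromConfig <- function(sc, seed) {
  keep <- intersect(names(sc), names(formals(sceneParams)))
  do.call(sceneParams, c(sc[keep], list(seed = seed)))
}

pipelinePaths <- function(out) {
  list(scenes = file.path(out, "scenes"), prep = file.path(out, "prep"),
       model = file.path(out, "model"), probs = file.path(out, "probs"),
       report = file.path(out, "report"), analysis = file.path(out, "analysis"))
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order. `simulate` writes
#' synthetic scenes (16-bit TIFF + 0/255 PNG masks + generator-truth CSV);
#' `preprocess` applies CLAHE; `train` fits the configured model on a
#' case-grouped split; `predict` writes probability maps; `evaluate`
#' compares predictions with the ground truth (per-tile metrics, pooled
#' metrics, PR curve) -- when no predictions exist it wires the ground
#' truth through as a perfect oracle, a pipeline self-check that must yield
#' Dice 1; `analyze` extracts regions, densities and (for mosaic layouts) a
#' density map. A provenance record (config, hash, seed, package version)
#' is written alongside the artifacts.
#'
#' @param config a YAML file path or a nested list (see
#'   [defaultRunConfig()]); unspecified fields take the defaults.
#' @param stages subset of `simulate`, `preprocess`, `train`, `predict`,
#'   `evaluate`, `analyze`.
#' @param seed optional override of the config's global seed.
#' @return invisibly, a list with the output root and per-stage summaries.
#' @export
runPipeline <- function(config = list(), stages = PIPELINE_STAGES,
                        seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "),
         "; valid stages are ", paste(PIPELINE_STAGES, collapse = ", "))
  cfg <- mergeConfig(defaultRunConfig(), config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  out <- cfg$out
  pp <- pipelinePaths(out)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(config = cfg, configHash = configHash(cfg), seed = cfg$seed,
         package = as.character(utils::packageVersion("gobletseg"))),
    file.path(out, "provenance.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  res <- list(out = out)

  nScenes <- cfg$scene$nScenes
  caseOf <- function(i) ((i - 1L) %% cfg$scene$nCases) + 1L

  if ("simulate" %in% stages) {
    dir.create(pp$scenes, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(cfg$scene$mosaic)) {
      mz <- cfg$scene$mosaic
      params <- sceneParamsFromConfig(cfg$scene, cfg$seed)
      mo <- generateMosaic(mz$rows, mz$cols, cfg$scene$targetDensity, params)
      saveRDS(mo, file.path(pp$scenes, "mosaic.rds"))
      for (k in seq_along(mosaicScenes(mo)))
        writeScene(mosaicScenes(mo)[[k]], pp$scenes, sprintf("tile%03d", k))
      res$simulate <- list(n = length(mosaicScenes(mo)), mosaic = TRUE)
    } else {
      for (i in seq_len(nScenes)) {
        p <- sceneParamsFromConfig(cfg$scene, cfg$seed + i)
        writeScene(generateScene(p), pp$scenes, sprintf("tile%03d", i))
      }
      res$simulate <- list(n = nScenes, mosaic = FALSE)
    }
  }

  loadScenes <- function(dir = pp$scenes) {
    imgs <- sort(list.files(dir, pattern = "_image\\.tif$", full.names = TRUE))
    if (!length(imgs)) stop("no scenes under ", dir,
                            "; run the simulate stage first")
    lapply(imgs, function(f) {
      pre <- sub("_image\\.tif$", "", f)
      list(image = readTile(f, umPerPx = cfg$scene$umPerPx),
           mask = readMaskPng(paste0(pre, "_mask.png")),
           name = basename(pre))
    })
  }

  if ("preprocess" %in% stages) {
    dir.create(pp$prep, recursive = TRUE, showWarnings = FALSE)
    sc <- loadScenes()
    for (s in sc) {
      t <- if (isTRUE(cfg$preprocess$clahe))
        applyClahe(s$image, cfg$preprocess$clipLimit,
                   unlist(cfg$preprocess$grid)) else s$image
      tiff::writeTIFF(pixels(t) / (2^bitDepth(t) - 1),
                      file.path(pp$prep, paste0(s$name, "_image.tif")),
                      bits.per.sample = 16L)
      writeMaskPng(s$mask, file.path(pp$prep, paste0(s$name, "_mask.png")))
    }
    res$preprocess <- list(n = length(sc), clahe = isTRUE(cfg$preprocess$clahe))
  }

  tileDir <- function() if (dir.exists(pp$prep) &&
                            length(list.files(pp$prep))) pp$prep else pp$scenes

  if ("train" %in% stages) {
    dir.create(pp$model, recursive = TRUE, showWarnings = FALSE)
    sc <- loadScenes(tileDir())
    dataset <- lapply(seq_along(sc), function(i)
      c(sc[[i]], list(case = caseOf(i))))
    mcfg <- modelConfig(cfg$model$depth, cfg$model$baseChannels,
                        cfg$model$textureKernelLen,
                        useResidual = !identical(cfg$model$arch, "unet"))
    tcfg <- do.call(trainConfig, c(cfg$train, list(seed = cfg$seed)))
    lcfg <- do.call(lossConfig, cfg$loss)
    fa <- makeGroupFolds(vapply(dataset, function(s) s$case, integer(1)),
                         tcfg$kFolds, cfg$seed)
    vi <- fa$tileFold == 1L
    model <- if (identical(cfg$model$arch, "unet"))
      buildUnetBaseline(mcfg, seed = cfg$seed)
    else buildDcauNet(mcfg, seed = cfg$seed)
    fit <- trainModel(model, dataset[!vi], dataset[vi], tcfg, lcfg,
                      loss = if (identical(cfg$model$arch, "unet")) "bce"
                             else "combined")
    saveModel(fit$model, file.path(pp$model, "checkpoint.rds"))
    write.csv(fit$history, file.path(pp$model, "history.csv"),
              row.names = FALSE)
    res$train <- list(valDice = fit$model$bestValDice,
                      epochs = nrow(fit$history))
  }

  if ("predict" %in% stages) {
    dir.create(pp$probs, recursive = TRUE, showWarnings = FALSE)
    ck <- file.path(pp$model, "checkpoint.rds")
    if (!file.exists(ck)) stop("no checkpoint at ", ck,
                               "; run the train stage first")
    model <- loadModel(ck)
    sc <- loadScenes(tileDir())
    for (s in sc) {
      pr <- predictProb(model, s$image)
      tiff::writeTIFF(pr, file.path(pp$probs, paste0(s$name, "_prob.tif")),
                      bits.per.sample = 32L)
    }
    res$predict <- list(n = length(sc))
  }

  loadProbs <- function(sc) {
    lapply(sc, function(s) {
      f <- file.path(pp$probs, paste0(s$name, "_prob.tif"))
      if (file.exists(f)) {
        p <- tiff::readTIFF(f)
        if (length(dim(p)) == 3L) p <- p[, , 1]
        p
      } else NULL
    })
  }

  if ("evaluate" %in% stages) {
    dir.create(pp$report, recursive = TRUE, showWarnings = FALSE)
    sc <- loadScenes(tileDir())
    probs <- loadProbs(sc)
    oracle <- all(vapply(probs, is.null, logical(1)))
    if (oracle)
      probs <- lapply(sc, function(s) s$mask + 0)
    th <- cfg$analysis$threshold
    per <- do.call(rbind, lapply(seq_along(sc), function(i) {
      m <- metricsFromCounts(confusionCounts(binarizeProb(probs[[i]], th),
                                             sc[[i]]$mask))
      cbind(tile = sc[[i]]$name, m)
    }))
    pooledP <- unlist(probs)
    pooledG <- unlist(lapply(sc, function(s) s$mask))
    pr <- prCurve(matrix(pooledP, ncol = 1), matrix(pooledG, ncol = 1))
    write.csv(per, file.path(pp$report, "metrics_per_tile.csv"),
              row.names = FALSE)
    write.csv(pr$curve, file.path(pp$report, "pr_curve.csv"),
              row.names = FALSE)
    pooled <- metricsFromCounts(confusionCounts(
      binarizeProb(matrix(pooledP, ncol = 1), th),
      matrix(pooledG, ncol = 1)))
    summary <- c(as.list(pooled), ap = pr$ap, oracle = oracle)
    jsonlite::write_json(summary, file.path(pp$report, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    res$evaluate <- summary
  }

  if ("analyze" %in% stages) {
    dir.create(pp$analysis, recursive = TRUE, showWarnings = FALSE)
    sc <- loadScenes(tileDir())
    probs <- loadProbs(sc)
    th <- cfg$analysis$threshold
    minA <- cfg$analysis$minAreaPx
    regAll <- NULL
    dens <- data.frame(tile = character(0), density = numeric(0))
    for (i in seq_along(sc)) {
      m <- if (is.null(probs[[i]])) sc[[i]]$mask
           else binarizeProb(probs[[i]], th)
      reg <- extractRegions(m, cfg$scene$umPerPx, minA)
      if (nrow(reg)) regAll <- rbind(regAll, cbind(tile = sc[[i]]$name, reg))
      area <- tileAreaMm2(ncol(m), nrow(m), cfg$scene$umPerPx)
      dens[nrow(dens) + 1L, ] <- list(sc[[i]]$name, gcDensity(reg, area))
    }
    write.csv(regAll, file.path(pp$analysis, "regions.csv"),
              row.names = FALSE)
    write.csv(dens, file.path(pp$analysis, "densities.csv"),
              row.names = FALSE)
    mosf <- file.path(pp$scenes, "mosaic.rds")
    if (file.exists(mosf)) {
      mo <- readRDS(mosf)
      dm <- densityMap(mo, if (all(vapply(probs, is.null, logical(1))))
        NULL else probs, th, minA)
      write.csv(densities(dm), file.path(pp$analysis, "density_map.csv"),
                row.names = FALSE)
      renderDensityOverlay(dm, mo, file.path(pp$analysis,
                                             "density_overlay.png"))
    }
    res$analyze <- list(nRegions = if (is.null(regAll)) 0L else nrow(regAll),
                        meanDensity = mean(dens$density))
  }
  invisible(res)
}
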