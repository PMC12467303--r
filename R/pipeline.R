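#' Default end-to-end run configuration
#'
#' Nested configuration for [runPipeline()]. Every default matches the
#' documented study conditions where one exists (QC thresholds, CP10K +
#' log1p, 2000 HVGs, Dirichlet alpha 1.0, 2000 cells per pseudo-bulk
#' sample, 5000/500 train/test split, T = 1000 linear schedule from 1e-4
#' to 0.02, the standard architecture, AdamW at 1e-4 with cosine annealing
#' over 150 epochs and patience 20). A single global \code{seed} fans out
#' to per-stage sub-seeds (reference, simulation, one per model training,
#' one per model inference) via a documented integer derivation, so stages
#' are independently reproducible.
#'
#' @param seed global seed.
#' @param outDir output directory for artifacts.
#' @return nested configuration list of class \code{RunConfig}.
#' @export
defaultRunConfig <- function(seed = 42L, outDir = tempfile("diffdeconv_run_")) {
  structure(list(
    seed = as.integer(seed),
    outDir = outDir,
    reference = list(
      source = "synthetic",          # "synthetic", "tenx" or "dense"
      path = NULL,                   # triplet dir / counts TSV
      annotationFile = NULL,
      orientation = "cellsByGenes",
      synthetic = list(nTypes = 5L, nGenes = 300L, cellsPerType = 100L,
                       nMarkersPerType = 10L, markerFold = 20,
                       baseMean = 5, nbDispersion = 0.1,
                       librarySizeCV = 0.2, overlapFrac = 0)
    ),
    preprocess = list(
      qc = list(minGenes = 200L, maxGenes = 5000L, maxMitoFrac = 0.20,
                minCellsPerGene = 3L),
      hvg = list(nTop = 2000L, minMean = 0.0125, maxMean = 3,
                 minDisp = 0.5, nBins = 20L)
    ),
    simulation = list(alpha = 1.0, nCells = 2000L, nTrain = 5000L,
                      nTest = 500L, latentTruth = FALSE),
    schedule = list(nSteps = 1000L, betaStart = 1e-4, betaEnd = 0.02),
    model = list(dModel = 128L, nHeads = 4L, nLayers = 3L, dFF = 256L,
                 dropout = 0.1, mlpHidden = c(256L, 256L)),
    training = list(lr = 1e-4, weightDecay = 0.01, epochs = 150L,
                    batchSize = 64L, etaMin = 1e-6, earlyStopPatience = 20L,
                    valFraction = 0.1),
    inference = list(nDraws = 1L),
    models = "diffformer",           # any of "diffformer", "diffmlp", "nnls"
    evaluation = list(overallRMSEMode = "meanPerSample")
  ), class = "RunConfig")
}

# Merge a user config into the defaults, rejecting unknown keys at every
# nesting level so typos fail loudly instead of silently using a default.
mergeRunConfig <- function(user, defaults = defaultRunConfig()) {
  mergeLevel <- function(u, d, path) {
    if (!is.list(u) || !is.list(d)) return(u)
    unknown <- setdiff(names(u), names(d))
    if (length(unknown))
      stop(sprintf("unknown config key(s) at %s: %s", path,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    for (nm in names(u)) {
      d[[nm]] <- if (is.list(d[[nm]]) && is.list(u[[nm]]))
        mergeLevel(u[[nm]], d[[nm]], paste0(path, "$", nm)) else u[[nm]]
    }
    d
  }
  out <- mergeLevel(unclass(user), unclass(defaults), "config")
  class(out) <- "RunConfig"
  out
}

logEvent <- function(logPath, stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
  cat(jsonlite::toJSON(list(stage = stage, message = msg), auto_unbox = TRUE),
      "\n", sep = "", file = logPath, append = TRUE)
}

#' Run the full simulate / train / infer / evaluate pipeline
#'
#' Orchestrates reference construction (synthetic or from files), atlas
#' preprocessing, pseudo-bulk dataset simulation, training and inference
#' for each requested model, and evaluation against the held-out test
#' split. Writes the dataset, checkpoints, prediction CSVs, a JSON report
#' and a provenance record under \code{config$outDir}; a rerun with the
#' same config reproduces the report byte for byte.
#'
#' @param config a partial configuration merged over
#'   [defaultRunConfig()] (a plain list is accepted).
#' @return invisibly, a list with the evaluation reports per model, any
#'   paired test, and the artifact paths.
#' @export
runPipeline <- function(config = list()) {
  cfg <- mergeRunConfig(config)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(cfg$outDir, "events.jsonl")
  if (file.exists(logPath)) file.remove(logPath)

  stageFail <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }

  ## reference
  raw <- stageFail("reference", {
    src <- cfg$reference$source
    if (src == "synthetic") {
      sc <- do.call(synthRefConfig,
                    c(cfg$reference$synthetic,
                      list(seed = deriveSeed(cfg$seed, 100L))))
      simulateReference(sc)
    } else if (src == "tenx") {
      if (is.null(cfg$reference$annotationFile))
        readReference10x(cfg$reference$path)
      else readReference10x(cfg$reference$path, cfg$reference$annotationFile)
    } else if (src == "dense") {
      readReferenceDense(cfg$reference$path, cfg$reference$annotationFile,
                         cfg$reference$orientation)
    } else stop(sprintf("unknown reference source '%s'", src))
  })
  logEvent(logPath, "reference", sprintf("%d cells x %d genes",
                                         nrow(raw@counts), ncol(raw@counts)))

  ## atlas
  atlas <- stageFail("atlas",
    buildAtlas(raw, qc = cfg$preprocess$qc, hvg = cfg$preprocess$hvg))
  logEvent(logPath, "atlas", sprintf("%d cells x %d HVGs, K=%d",
                                     nrow(atlas@lognorm), ncol(atlas@lognorm),
                                     nTypes(atlas)))

  ## dataset
  ds <- stageFail("simulate", {
    sim <- do.call(simulationConfig,
                   c(cfg$simulation, list(seed = deriveSeed(cfg$seed, 101L))))
    generateDataset(atlas, sim)
  })
  writeDataset(ds$train, file.path(cfg$outDir, "dataset_train"))
  writeDataset(ds$test, file.path(cfg$outDir, "dataset_test"))
  logEvent(logPath, "simulate", sprintf("%d train / %d test samples",
                                        nrow(ds$train@bulk), nrow(ds$test@bulk)))

  schedule <- do.call(makeSchedule, cfg$schedule)
  pTrue <- ds$test@props
  colnames(pTrue) <- ds$test@typeNames
  reports <- list(); rmseBy <- list(); paths <- list()

  for (mi in seq_along(cfg$models)) {
    kind <- cfg$models[mi]
    pred <- if (kind == "nnls") {
      stageFail("nnls", {
        ctr <- typeCentroids(atlas)
        t(apply(ds$test@bulk, 1, nnlsDeconvolve, centroids = ctr))
      })
    } else {
      fit <- stageFail(paste0("train_", kind), {
        mc <- do.call(denoiserConfig,
                      c(list(K = nTypes(atlas), G = ncol(atlas@lognorm),
                             tMax = schedule@nSteps), cfg$model))
        tc <- do.call(trainingConfig,
                      c(cfg$training,
                        list(seed = deriveSeed(cfg$seed, 200L + mi))))
        trainModel(kind, ds$train, tc, schedule, modelConfig = mc)
      })
      ckpt <- file.path(cfg$outDir, paste0(kind, ".ckpt.rds"))
      saveCheckpoint(fit$model, ckpt, typeNames = atlas@typeNames,
                     hvgIds = atlas@hvgIds, seed = cfg$seed)
      paths[[paste0(kind, "_checkpoint")]] <- ckpt
      logEvent(logPath, paste0("train_", kind),
               sprintf("best epoch %d (%s)", fit$bestEpoch, fit$stopReason))
      stageFail(paste0("infer_", kind),
        inferProportions(fit$model, ds$test@bulk, schedule,
                         seed = deriveSeed(cfg$seed, 300L + mi),
                         nDraws = cfg$inference$nDraws))
    }
    colnames(pred) <- ds$test@typeNames
    predPath <- file.path(cfg$outDir, paste0("predictions_", kind, ".csv"))
    writeProportionsCSV(pred, predPath)
    paths[[paste0(kind, "_predictions")]] <- predPath
    rep <- evaluateProportions(pTrue, pred,
                               overallRMSEMode = cfg$evaluation$overallRMSEMode)
    reports[[kind]] <- rep
    rmseBy[[kind]] <- rep@perSampleRMSE
    logEvent(logPath, paste0("evaluate_", kind),
             sprintf("mean RMSE %.4f, overall PCC %.4f",
                     rep@overallRMSE, rep@overallPCC))
  }

  paired <- NULL
  if (length(rmseBy) >= 2) {
    nms <- names(rmseBy)[1:2]
    paired <- pairedRMSETest(rmseBy[[nms[1]]], rmseBy[[nms[2]]], methods = nms)
  }

  reportJSON <- list(
    models = lapply(reports, reportToList),
    pairedTest = if (is.null(paired)) NULL else pairedTestToList(paired)
  )
  reportPath <- file.path(cfg$outDir, "report.json")
  jsonlite::write_json(reportJSON, reportPath, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  jsonlite::write_json(
    list(config = unclass(cfg), package = "DiffDeconv",
         version = as.character(utils::packageVersion("DiffDeconv")),
         seedDerivation = "deriveSeed(seed, idx) = (seed*7919 + idx*104729) mod (2^31-1); idx: 100 reference, 101 simulation, 200+i training, 300+i inference"),
    file.path(cfg$outDir, "provenance.json"), auto_unbox = TRUE, null = "null",
    pretty = TRUE)
  paths$report <- reportPath

  invisible(list(reports = reports, pairedTest = paired, paths = paths,
                 config = cfg))
}
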