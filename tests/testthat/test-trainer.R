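test_that("training config guards reject invalid values", {
  expect_error(trainingConfig(earlyStopPatience = 0L), "earlyStopPatience")
  expect_error(trainingConfig(valFraction = 0.8), "valFraction")
  expect_error(trainingConfig(lr = -1), "lr")
  expect_error(trainingConfig(epochs = 10L, earlyStopPatience = 20L),
               "patience")
})

test_that("cosine schedule hits both endpoints in closed form", {
  cfg <- trainingConfig(lr = 1e-4, epochs = 150L, tMaxLR = 150L, etaMin = 1e-6)
  expect_equal(cosineLR(1L, cfg), 1e-4)
  expect_equal(cosineLR(150L, cfg), 1e-6)
  expect_equal(cosineLR(200L, cfg), 1e-6)   # beyond the horizon: floor
  mid <- cosineLR(75L, cfg)
  expect_true(mid < 1e-4 && mid > 1e-6)
  # midpoint of the cosine: epoch (1 + tMax)/2 gives the arithmetic mean
  cfg2 <- trainingConfig(lr = 2e-3, epochs = 101L, tMaxLR = 101L, etaMin = 2e-5)
  expect_equal(cosineLR(51L, cfg2), (2e-3 + 2e-5) / 2, tolerance = 1e-12)
})

test_that("training is reproducible and learns on a tiny problem", {
  atlas <- makeTestAtlas(seed = 41L)
  ds <- generateDataset(atlas, simulationConfig(nTrain = 120L, nTest = 10L,
                                                nCells = 300L, seed = 42L))
  sch <- makeSchedule(50L)
  mc <- denoiserConfig(K = 3L, G = ncol(lognorm(atlas)), dModel = 32L,
                       nHeads = 2L, nLayers = 1L, dFF = 32L, dropout = 0.1,
                       mlpHidden = c(32L), tMax = 50L)
  tc <- trainingConfig(lr = 2e-3, epochs = 8L, tMaxLR = 8L, etaMin = 2e-5,
                       earlyStopPatience = 8L, batchSize = 32L, seed = 7L)
  f1 <- trainModel("diffmlp", ds$train, tc, sch, modelConfig = mc)
  f2 <- trainModel("diffmlp", ds$train, tc, sch, modelConfig = mc)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$model@params, f2$model@params)
  expect_lt(min(f1$trace$valLoss), f1$trace$valLoss[1])
  expect_equal(f1$trace$lr[1], 2e-3)
})

test_that("early stopping reports the best (earliest) epoch", {
  atlas <- makeTestAtlas(seed = 43L)
  ds <- generateDataset(atlas, simulationConfig(nTrain = 60L, nTest = 5L,
                                                nCells = 100L, seed = 2L))
  sch <- makeSchedule(20L)
  mc <- denoiserConfig(K = 3L, G = ncol(lognorm(atlas)), dModel = 8L,
                       nHeads = 2L, nLayers = 1L, dFF = 8L, dropout = 0,
                       mlpHidden = c(8L), tMax = 20L)
  tc <- trainingConfig(lr = 1e-3, epochs = 30L, tMaxLR = 30L, etaMin = 1e-5,
                       earlyStopPatience = 3L, batchSize = 32L, seed = 5L)
  fit <- trainModel("diffmlp", ds$train, tc, sch, modelConfig = mc)
  ran <- nrow(fit$trace)
  expect_equal(fit$bestEpoch, which.min(fit$trace$valLoss))
  if (ran < 30L) {
    expect_match(fit$stopReason, "early stop")
    expect_equal(ran, fit$bestEpoch + 3L)
  }
})

test_that("inference is seed-deterministic, simplex-valid and row-stable", {
  atlas <- makeTestAtlas(seed = 44L)
  sch <- makeSchedule(30L)
  mc <- denoiserConfig(K = 3L, G = ncol(lognorm(atlas)), dModel = 8L,
                       nHeads = 2L, nLayers = 1L, dFF = 8L, dropout = 0,
                       mlpHidden = c(8L), tMax = 30L)
  model <- diffMLP(mc, seed = 3L)
  bulk <- matrix(rnorm(5 * ncol(lognorm(atlas))), 5)
  p1 <- inferProportions(model, bulk, sch, seed = 11L)
  p2 <- inferProportions(model, bulk, sch, seed = 11L)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0))
  expect_equal(rowSums(p1), rep(1, 5), tolerance = 1e-12)
  # per-row sub-seeds: a row's result is unchanged by rows after it
  p3 <- inferProportions(model, bulk[1:2, , drop = FALSE], sch, seed = 11L)
  expect_equal(p3, p1[1:2, ], tolerance = 1e-8)
  # empty input
  expect_equal(nrow(inferProportions(model, bulk[0, , drop = FALSE], sch)), 0L)
})

test_that("checkpoint gene-order mismatch is refused with the genes named", {
  mc <- denoiserConfig(K = 3L, G = 4L, dModel = 8L, nHeads = 2L,
                       nLayers = 1L, dFF = 8L, mlpHidden = c(8L), tMax = 10L)
  model <- diffMLP(mc, seed = 1L)
  path <- tempfile(fileext = ".rds")
  saveCheckpoint(model, path, typeNames = c("a", "b", "c"),
                 hvgIds = c("g1", "g2", "g3", "g4"), seed = 1L)
  loaded <- loadCheckpoint(path)
  sch <- makeSchedule(10L)
  bulk <- matrix(rnorm(4), 1)
  expect_error(inferProportions(loaded, bulk, sch,
                                geneIds = c("g2", "g1", "g3", "g4")),
               "g2")
  expect_silent(inferProportions(loaded, bulk, sch,
                                 geneIds = c("g1", "g2", "g3", "g4")))
})

test_that("a trained model beats its untrained initialisation clearly", {
  atlas <- makeTestAtlas(nTypes = 3L, nGenes = 60L, cellsPerType = 50L,
                         seed = 45L)
  ds <- generateDataset(atlas, simulationConfig(nTrain = 400L, nTest = 40L,
                                                nCells = 500L, seed = 9L))
  sch <- makeSchedule(100L)
  mc <- denoiserConfig(K = 3L, G = ncol(lognorm(atlas)), dModel = 32L,
                       nHeads = 2L, nLayers = 1L, dFF = 32L, dropout = 0.1,
                       mlpHidden = c(64L), tMax = 100L)
  tc <- trainingConfig(lr = 2e-3, epochs = 15L, tMaxLR = 15L, etaMin = 2e-5,
                       earlyStopPatience = 15L, seed = 21L)
  fit <- trainModel("diffmlp", ds$train, tc, sch, modelConfig = mc)
  fresh <- diffMLP(mc, seed = 77L)
  pT <- trueProps(ds$test)
  rmseTrained <- mean(perSampleRMSE(pT,
    inferProportions(fit$model, bulkMatrix(ds$test), sch, seed = 1L)))
  rmseFresh <- mean(perSampleRMSE(pT,
    inferProportions(fresh, bulkMatrix(ds$test), sch, seed = 1L)))
  expect_lt(rmseTrained * 2, rmseFresh)
})
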