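#' Training configuration
#'
#' Defaults follow the stated optimisation recipe: AdamW (decoupled weight
#' decay) with learning rate 1e-4, weight decay 0.01, betas (0.9, 0.999),
#' eps 1e-8; cosine learning-rate annealing to eta_min = 1e-6 over
#' T_max = 150 epochs; batch size 64; 150 epochs with early-stopping
#' patience 20 on validation loss; seed 42.
#'
#' @param lr initial learning rate.
#' @param weightDecay decoupled weight-decay coefficient.
#' @param adamBetas length-2 numeric, Adam moment decay rates.
#' @param adamEps Adam denominator epsilon.
#' @param epochs maximum training epochs.
#' @param batchSize minibatch size.
#' @param tMaxLR cosine annealing horizon in epochs (defaults to
#'   \code{epochs}).
#' @param etaMin final learning rate of the cosine schedule.
#' @param earlyStopPatience epochs without validation improvement before
#'   stopping (>= 1).
#' @param valFraction fraction of the training samples held out for
#'   validation, in (0, 0.5].
#' @param gradClip optional gradient-norm clip; NULL (default) disables.
#' @param seed integer seed fixing the split, batching, noise draws,
#'   dropout and weight initialisation.
#' @return configuration list of class \code{TrainingConfig}.
#' @export
trainingConfig <- function(lr = 1e-4, weightDecay = 0.01,
                           adamBetas = c(0.9, 0.999), adamEps = 1e-8,
                           epochs = 150L, batchSize = 64L, tMaxLR = epochs,
                           etaMin = 1e-6, earlyStopPatience = 20L,
                           valFraction = 0.1, gradClip = NULL, seed = 42L) {
  checkPositiveScalar(lr, "lr")
  stopIfNot(weightDecay >= 0, "'weightDecay' must be >= 0")
  checkCountScalar(epochs, "epochs")
  checkCountScalar(batchSize, "batchSize")
  checkCountScalar(tMaxLR, "tMaxLR")
  checkCountScalar(earlyStopPatience, "earlyStopPatience", 1L)
  stopIfNot(earlyStopPatience <= epochs, "patience must be <= epochs")
  stopIfNot(valFraction > 0 && valFraction <= 0.5,
            "'valFraction' must lie in (0, 0.5]")
  stopIfNot(etaMin > 0 && etaMin <= lr, "need 0 < etaMin <= lr")
  structure(list(lr = lr, weightDecay = weightDecay, adamBetas = adamBetas,
                 adamEps = adamEps, epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize),
                 tMaxLR = as.integer(tMaxLR), etaMin = etaMin,
                 earlyStopPatience = as.integer(earlyStopPatience),
                 valFraction = valFraction, gradClip = gradClip,
                 seed = as.integer(seed)),
            class = "TrainingConfig")
}

#' Cosine-annealed learning rate at a given epoch
#'
#' Closed form with exact endpoints: epoch 1 returns \code{lr}, epoch
#' \code{tMaxLR} returns \code{etaMin}; epochs beyond the horizon stay at
#' \code{etaMin}.
#'
#' @param epoch 1-based epoch index.
#' @param config a [trainingConfig()] list.
#' @return learning rate for that epoch.
#' @export
cosineLR <- function(epoch, config) {
  if (config$tMaxLR <= 1L || epoch >= config$tMaxLR) {
    if (epoch >= config$tMaxLR) return(config$etaMin)
    return(config$lr)
  }
  frac <- (epoch - 1) / (config$tMaxLR - 1)
  config$etaMin + 0.5 * (config$lr - config$etaMin) * (1 + cos(pi * frac))
}

#' Train a denoiser on a pseudo-bulk dataset
#'
#' Seeded training loop for the diffusion noise-prediction objective.
#' Per batch: timesteps are drawn uniformly from \code{1..nSteps}, standard
#' normal noise is injected via the closed-form forward process, and the
#' mean squared error between true and predicted noise is minimised with
#' AdamW under cosine learning-rate annealing. A seeded shuffle holds out
#' \code{valFraction} of the samples for validation; training stops early
#' when the validation loss has not improved for
#' \code{earlyStopPatience} epochs, and the parameters with the lowest
#' validation loss (ties to the earlier epoch) are returned.
#'
#' @param kind "diffformer" or "diffmlp".
#' @param train a [PseudoBulkDataset-class] of training samples.
#' @param config a [trainingConfig()] list.
#' @param schedule a [NoiseSchedule-class] object.
#' @param modelConfig optional [denoiserConfig()]; defaults to the standard
#'   architecture sized to the dataset, with \code{tMax} set to the
#'   schedule length.
#' @param verbose if TRUE, log one line per epoch to stderr.
#' @return list with the trained \code{model} and a \code{trace}
#'   data.frame (epoch, trainLoss, valLoss, lr), plus \code{bestEpoch} and
#'   \code{stopReason}.
#' @export
trainModel <- function(kind = c("diffformer", "diffmlp"), train,
                       config = trainingConfig(), schedule = makeSchedule(),
                       modelConfig = NULL, verbose = FALSE) {
  kind <- match.arg(kind)
  stopIfNot(methods::is(train, "PseudoBulkDataset"),
            "'train' must be a PseudoBulkDataset")
  stopIfNot(inherits(config, "TrainingConfig"),
            "'config' must come from trainingConfig()")
  N <- nrow(train@bulk)
  stopIfNot(N >= 4, "need at least 4 training samples")
  K <- ncol(train@props); G <- ncol(train@bulk)
  if (is.null(modelConfig))
    modelConfig <- denoiserConfig(K = K, G = G, tMax = schedule@nSteps)
  stopIfNot(modelConfig$K == K && modelConfig$G == G,
            "modelConfig dims must match the dataset")

  model <- if (kind == "diffformer") diffFormer(modelConfig, seed = config$seed)
           else diffMLP(modelConfig, seed = config$seed)

  withSeed(deriveSeed(config$seed, 1L), {
    idx <- sample.int(N)
    nVal <- max(1L, floor(config$valFraction * N))
    valIdx <- idx[seq_len(nVal)]
    trIdx <- idx[(nVal + 1L):N]
    xVal <- train@props[valIdx, , drop = FALSE]
    cVal <- train@bulk[valIdx, , drop = FALSE]
    xTr <- train@props[trIdx, , drop = FALSE]
    cTr <- train@bulk[trIdx, , drop = FALSE]
    nTr <- nrow(xTr)
    Tn <- schedule@nSteps

    state <- adamwInit(model@params)
    best <- list(loss = Inf, params = model@params, epoch = 0L)
    trace <- data.frame(epoch = integer(), trainLoss = numeric(),
                        valLoss = numeric(), lr = numeric())
    sinceBest <- 0L
    stopReason <- "max epochs reached"

    # fixed validation batch noise for a comparable loss across epochs
    valT <- sample.int(Tn, nrow(xVal), replace = TRUE)
    valEps <- matrix(rnorm(length(xVal)), nrow(xVal), K)
    valXt <- forwardNoise(xVal, valT, valEps, schedule)

    for (epoch in seq_len(config$epochs)) {
      lrEpoch <- cosineLR(epoch, config)
      ord <- sample.int(nTr)
      losses <- numeric()
      for (start in seq(1L, nTr, by = config$batchSize)) {
        rows <- ord[start:min(start + config$batchSize - 1L, nTr)]
        B <- length(rows)
        x0 <- xTr[rows, , drop = FALSE]
        cb <- cTr[rows, , drop = FALSE]
        tb <- sample.int(Tn, B, replace = TRUE)
        eps <- matrix(rnorm(B * K), B, K)
        xt <- forwardNoise(x0, tb, eps, schedule)
        fwd <- denoiserFwd(model, xt, tb, cb, training = TRUE)
        loss <- mean((eps - fwd$eps)^2)
        if (!is.finite(loss))
          stop(sprintf("non-finite loss at epoch %d, batch starting %d",
                       epoch, start), call. = FALSE)
        losses <- c(losses, loss)
        grads <- denoiserBwd(model, fwd$cache, 2 * (fwd$eps - eps) / (B * K))
        if (!is.null(config$gradClip)) {
          gn <- sqrt(sumParams(grads, function(x) x^2))
          if (gn > config$gradClip)
            grads <- mapParams(grads, grads, function(g, .) g * config$gradClip / gn)
        }
        upd <- adamwStep(model@params, grads, state, lr = lrEpoch,
                         weightDecay = config$weightDecay,
                         betas = config$adamBetas, eps = config$adamEps)
        model@params <- upd$params
        state <- upd$state
      }
      valPred <- denoiserFwd(model, valXt, valT, cVal, training = FALSE)$eps
      valLoss <- mean((valEps - valPred)^2)
      trace <- rbind(trace, data.frame(epoch = epoch,
                                       trainLoss = mean(losses),
                                       valLoss = valLoss, lr = lrEpoch))
      if (verbose)
        message(sprintf("epoch %3d  train %.5f  val %.5f  lr %.2e",
                        epoch, mean(losses), valLoss, lrEpoch))
      if (valLoss < best$loss) {
        best <- list(loss = valLoss, params = model@params, epoch = epoch)
        sinceBest <- 0L
      } else {
        sinceBest <- sinceBest + 1L
        if (sinceBest >= config$earlyStopPatience) {
          stopReason <- sprintf("early stop at epoch %d (patience %d)",
                                epoch, config$earlyStopPatience)
          break
        }
      }
    }
    model@params <- best$params
    list(model = model, trace = trace, bestEpoch = best$epoch,
         stopReason = stopReason)
  })
}

#' Infer proportions for a matrix of bulk profiles
#'
#' Runs conditional ancestral sampling for each bulk sample with a
#' per-row derived sub-seed: every row's noise sequence comes from its own
#' seeded stream, so its result does not depend on which other rows are in
#' the matrix. The reverse process itself is evaluated batched across rows
#' for speed.
#'
#' @param model a trained denoiser model.
#' @param bulk N x G numeric matrix of bulk profiles in the model's gene
#'   order (checked against \code{hvgIds} when \code{geneIds} given).
#' @param schedule the [NoiseSchedule-class] used in training.
#' @param seed integer base seed for the sampling randomness.
#' @param nDraws draws averaged per sample (see [ddpmSample()]).
#' @param geneIds optional column gene ids; verified against the model
#'   checkpoint's \code{hvgIds} attribute when both are present.
#' @return N x K matrix of simplex-valid proportion vectors.
#' @export
inferProportions <- function(model, bulk, schedule, seed = 42L, nDraws = 1L,
                             geneIds = NULL) {
  if (is.vector(bulk)) bulk <- matrix(bulk, nrow = 1)
  stopIfNot(ncol(bulk) == model@config$G,
            "bulk gene dimension does not match the model")
  ckptGenes <- attr(model, "hvgIds")
  if (!is.null(geneIds) && !is.null(ckptGenes) &&
      !identical(as.character(geneIds), as.character(ckptGenes))) {
    bad <- which(as.character(geneIds) != as.character(ckptGenes))
    stop(sprintf("bulk gene order does not match checkpoint; first mismatches: %s",
                 paste(head(geneIds[bad], 3), collapse = ", ")), call. = FALSE)
  }
  K <- model@config$K
  N <- nrow(bulk)
  if (N == 0L) return(matrix(numeric(0), 0L, K))
  Tn <- schedule@nSteps
  out <- matrix(NA_real_, N, K)
  for (d in seq_len(nDraws)) {
    # per-row noise streams: each row consumes rnorm in the same order as
    # a single-sample ancestral pass (x_T first, then z at t = T..2)
    noise <- lapply(seq_len(N), function(i)
      withSeed(deriveSeed(deriveSeed(seed, i), d),
               matrix(rnorm(Tn * K), Tn, K)))
    x <- do.call(rbind, lapply(noise, function(nz) nz[1, ]))
    for (t in Tn:1) {
      epsHat <- predictNoise(model, x, rep(t, N), bulk, training = FALSE)
      if (!all(is.finite(epsHat)))
        stop(sprintf("non-finite values in reverse process at timestep %d", t),
             call. = FALSE)
      b <- schedule@beta[t]; a <- schedule@alpha[t]; ab <- schedule@alphaBar[t]
      x <- (x - (b / sqrt(1 - ab)) * epsHat) / sqrt(a)
      if (t > 1L) {
        z <- do.call(rbind, lapply(noise, function(nz) nz[Tn - t + 2L, ]))
        x <- x + sqrt(b) * z
      }
    }
    out <- if (d == 1L) x else out + x
  }
  out <- out / nDraws
  t(apply(out, 1, projectToSimplex))
}
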