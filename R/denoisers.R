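#' Denoiser architecture configuration
#'
#' Hyperparameters of the Transformer denoiser (and the shared embedding
#' dimensions reused by the MLP ablation): model dimension 128, 4 attention
#' heads, 3 pre-norm encoder layers, feed-forward dimension 256, dropout
#' 0.1 on attention weights and feed-forward activations, GELU activations.
#'
#' @param K proportion-vector dimension (number of cell types, >= 2).
#' @param G bulk-profile dimension (number of genes).
#' @param dModel token embedding dimension; must be divisible by
#'   \code{nHeads}.
#' @param nHeads number of attention heads.
#' @param nLayers number of encoder layers.
#' @param dFF feed-forward hidden dimension.
#' @param dropout dropout rate in [0, 1).
#' @param mlpHidden hidden-layer widths of the MLP ablation denoiser.
#' @param tMax timestep normaliser: the scalar timestep enters its
#'   embedding as t / tMax. Set to the diffusion schedule length.
#' @return configuration list of class \code{DenoiserConfig}.
#' @export
denoiserConfig <- function(K, G, dModel = 128L, nHeads = 4L, nLayers = 3L,
                           dFF = 256L, dropout = 0.1,
                           mlpHidden = c(256L, 256L), tMax = 1000L) {
  checkCountScalar(K, "K", 2L)
  checkCountScalar(G, "G")
  checkCountScalar(dModel, "dModel")
  checkCountScalar(nHeads, "nHeads")
  checkCountScalar(nLayers, "nLayers")
  checkCountScalar(dFF, "dFF")
  checkCountScalar(tMax, "tMax")
  stopIfNot(dModel %% nHeads == 0, "dModel must be divisible by nHeads")
  stopIfNot(is.numeric(dropout) && dropout >= 0 && dropout < 1,
            "dropout must lie in [0, 1)")
  stopIfNot(all(mlpHidden >= 1), "mlpHidden widths must be positive")
  structure(list(K = as.integer(K), G = as.integer(G),
                 dModel = as.integer(dModel), nHeads = as.integer(nHeads),
                 nLayers = as.integer(nLayers), dFF = as.integer(dFF),
                 dropout = dropout, mlpHidden = as.integer(mlpHidden),
                 tMax = as.integer(tMax)),
            class = "DenoiserConfig")
}

#' Transformer token-fusion denoiser
#'
#' The three inputs (noisy proportion vector, scaled timestep, bulk
#' profile) are affinely embedded into a shared d-dimensional space,
#' learnable positional embeddings are added, and the resulting 3-token
#' sequence \code{[proportion, time, bulk]} runs through a pre-norm
#' Transformer encoder (softmax attention, GELU feed-forward). The first
#' token's output, after a final layer normalisation, is projected to K
#' with no output activation so the full noise range is reachable.
#'
#' @slot config a \code{DenoiserConfig} list.
#' @slot params nested list of trainable parameters.
#' @export
setClass("DiffFormer", representation(config = "list", params = "list"))

#' MLP concatenation-fusion denoiser (ablation baseline)
#'
#' Same per-modality affine embeddings as the Transformer denoiser, but
#' the three embedded vectors are simply concatenated and passed through
#' a GELU MLP; no attention, no positional information. Shares every other
#' hyperparameter with [DiffFormer-class] so the comparison isolates the
#' fusion mechanism.
#'
#' @slot config a \code{DenoiserConfig} list.
#' @slot params nested list of trainable parameters.
#' @export
setClass("DiffMLP", representation(config = "list", params = "list"))

#' Construct denoiser models with seeded initialisation
#'
#' Weights are drawn from zero-mean normals scaled by 1/sqrt(fan-in)
#' (positional embeddings from N(0, 0.02^2)); biases and layer-norm
#' offsets start at zero, layer-norm gains at one.
#'
#' @param config a configuration from [denoiserConfig()].
#' @param seed integer seed for the initialisation draws.
#' @return A [DiffFormer-class] or [DiffMLP-class] object.
#' @export
diffFormer <- function(config, seed = 42L) {
  stopIfNot(inherits(config, "DenoiserConfig"),
            "'config' must come from denoiserConfig()")
  d <- config$dModel
  withSeed(seed, {
    params <- list(
      Wp = initMatrix(config$K, d, 1 / sqrt(config$K)), bp = rep(0, d),
      Wt = initMatrix(1, d, 1), bt = rep(0, d),
      Wc = initMatrix(config$G, d, 1 / sqrt(config$G)), bc = rep(0, d),
      pos = initMatrix(3, d, 0.02),
      layers = lapply(seq_len(config$nLayers),
                      function(i) initEncoderLayer(d, config$dFF)),
      lnFg = rep(1, d), lnFb = rep(0, d),
      Wout = initMatrix(d, config$K, 1 / sqrt(d)), bout = rep(0, config$K)
    )
    methods::new("DiffFormer", config = unclass(config), params = params)
  })
}

#' @rdname diffFormer
#' @export
diffMLP <- function(config, seed = 42L) {
  stopIfNot(inherits(config, "DenoiserConfig"),
            "'config' must come from denoiserConfig()")
  d <- config$dModel
  withSeed(seed, {
    widths <- c(3L * d, config$mlpHidden)
    hidden <- lapply(seq_along(config$mlpHidden), function(i) {
      list(W = initMatrix(widths[i], widths[i + 1], 1 / sqrt(widths[i])),
           b = rep(0, widths[i + 1]))
    })
    params <- list(
      Wp = initMatrix(config$K, d, 1 / sqrt(config$K)), bp = rep(0, d),
      Wt = initMatrix(1, d, 1), bt = rep(0, d),
      Wc = initMatrix(config$G, d, 1 / sqrt(config$G)), bc = rep(0, d),
      hidden = hidden,
      Wout = initMatrix(widths[length(widths)], config$K,
                        1 / sqrt(widths[length(widths)])),
      bout = rep(0, config$K)
    )
    methods::new("DiffMLP", config = unclass(config), params = params)
  })
}

# Shared per-modality embeddings. t is scaled to t/tMax before its affine
# 1 -> d embedding; raw timesteps in the hundreds destabilise training.
embedInputs <- function(prm, cfg, xt, t, cond) {
  stopIfNot(ncol(xt) == cfg$K, "xt must have K columns")
  stopIfNot(ncol(cond) == cfg$G, "cond must have G columns")
  tScaled <- matrix(rep_len(t, nrow(xt)) / cfg$tMax, ncol = 1)
  list(P = linFwd(xt, prm$Wp, prm$bp),
       Tk = linFwd(tScaled, prm$Wt, prm$bt),
       C = linFwd(cond, prm$Wc, prm$bc),
       tScaled = tScaled)
}

diffFormerFwd <- function(model, xt, t, cond, training = FALSE) {
  cfg <- model@config; prm <- model@params
  emb <- embedInputs(prm, cfg, xt, t, cond)
  B <- nrow(xt)
  X <- list(sweep(emb$P, 2, prm$pos[1, ], "+"),
            sweep(emb$Tk, 2, prm$pos[2, ], "+"),
            sweep(emb$C, 2, prm$pos[3, ], "+"))
  layerCaches <- vector("list", cfg$nLayers)
  for (l in seq_len(cfg$nLayers)) {
    out <- encoderLayerFwd(X, prm$layers[[l]], cfg$nHeads, cfg$dropout, training)
    layerCaches[[l]] <- out$cache
    X <- out$Y
  }
  lnF <- lnFwd(X[[1]], prm$lnFg, prm$lnFb)
  eps <- linFwd(lnF$y, prm$Wout, prm$bout)
  if (!all(is.finite(eps)))
    stop("non-finite denoiser output", call. = FALSE)
  list(eps = eps,
       cache = list(emb = emb, xt = xt, cond = cond, layers = layerCaches,
                    lnF = lnF, Xlast1 = X[[1]]))
}

diffFormerBwd <- function(model, cache, dEps) {
  cfg <- model@config; prm <- model@params
  g <- zerosLike(prm)
  lo <- linBwd(cache$lnF$y, prm$Wout, dEps)
  g$Wout <- lo$dW; g$bout <- lo$db
  lnb <- lnBwd(cache$lnF, prm$lnFg, lo$dx)
  g$lnFg <- lnb$dg; g$lnFb <- lnb$db
  B <- nrow(dEps); d <- cfg$dModel
  dX <- list(lnb$dx, matrix(0, B, d), matrix(0, B, d))
  for (l in rev(seq_len(cfg$nLayers))) {
    bwd <- encoderLayerBwd(dX, prm$layers[[l]], cache$layers[[l]], cfg$nHeads)
    g$layers[[l]] <- bwd$grads
    dX <- bwd$dX
  }
  for (i in 1:3) g$pos[i, ] <- colSums(dX[[i]])
  lp <- linBwd(cache$xt, prm$Wp, dX[[1]])
  lt <- linBwd(cache$emb$tScaled, prm$Wt, dX[[2]])
  lc <- linBwd(cache$cond, prm$Wc, dX[[3]])
  g$Wp <- lp$dW; g$bp <- lp$db
  g$Wt <- lt$dW; g$bt <- lt$db
  g$Wc <- lc$dW; g$bc <- lc$db
  g
}

diffMLPFwd <- function(model, xt, t, cond, training = FALSE) {
  cfg <- model@config; prm <- model@params
  emb <- embedInputs(prm, cfg, xt, t, cond)
  h <- cbind(emb$P, emb$Tk, emb$C)
  acts <- list()
  for (i in seq_along(prm$hidden)) {
    pre <- linFwd(h, prm$hidden[[i]]$W, prm$hidden[[i]]$b)
    act <- geluFwd(pre)
    dr <- dropoutFwd(act, cfg$dropout, training)
    acts[[i]] <- list(input = h, pre = pre, mask = dr$mask)
    h <- dr$y
  }
  eps <- linFwd(h, prm$Wout, prm$bout)
  if (!all(is.finite(eps)))
    stop("non-finite denoiser output", call. = FALSE)
  list(eps = eps, cache = list(emb = emb, xt = xt, cond = cond, acts = acts,
                               last = h))
}

diffMLPBwd <- function(model, cache, dEps) {
  prm <- model@params
  g <- zerosLike(prm)
  lo <- linBwd(cache$last, prm$Wout, dEps)
  g$Wout <- lo$dW; g$bout <- lo$db
  dh <- lo$dx
  for (i in rev(seq_along(prm$hidden))) {
    a <- cache$acts[[i]]
    dAct <- dropoutBwd(a$mask, dh)
    dPre <- geluBwd(a$pre, dAct)
    lb <- linBwd(a$input, prm$hidden[[i]]$W, dPre)
    g$hidden[[i]]$W <- lb$dW; g$hidden[[i]]$b <- lb$db
    dh <- lb$dx
  }
  d <- model@config$dModel
  dP <- dh[, 1:d, drop = FALSE]
  dT <- dh[, (d + 1):(2 * d), drop = FALSE]
  dC <- dh[, (2 * d + 1):(3 * d), drop = FALSE]
  lp <- linBwd(cache$xt, prm$Wp, dP)
  lt <- linBwd(cache$emb$tScaled, prm$Wt, dT)
  lc <- linBwd(cache$cond, prm$Wc, dC)
  g$Wp <- lp$dW; g$bp <- lp$db
  g$Wt <- lt$dW; g$bt <- lt$db
  g$Wc <- lc$dW; g$bc <- lc$db
  g
}

denoiserFwd <- function(model, xt, t, cond, training = FALSE) {
  if (methods::is(model, "DiffFormer")) diffFormerFwd(model, xt, t, cond, training)
  else diffMLPFwd(model, xt, t, cond, training)
}

denoiserBwd <- function(model, cache, dEps) {
  if (methods::is(model, "DiffFormer")) diffFormerBwd(model, cache, dEps)
  else diffMLPBwd(model, cache, dEps)
}

#' @describeIn predictNoise Transformer denoiser forward pass.
#' @export
setMethod("predictNoise", "DiffFormer", function(model, xt, t, cond,
                                                 training = FALSE) {
  if (is.vector(xt)) xt <- matrix(xt, nrow = 1)
  if (is.vector(cond)) cond <- matrix(cond, nrow = 1)
  diffFormerFwd(model, xt, t, cond, training)$eps
})

#' @describeIn predictNoise MLP denoiser forward pass.
#' @export
setMethod("predictNoise", "DiffMLP", function(model, xt, t, cond,
                                              training = FALSE) {
  if (is.vector(xt)) xt <- matrix(xt, nrow = 1)
  if (is.vector(cond)) cond <- matrix(cond, nrow = 1)
  diffMLPFwd(model, xt, t, cond, training)$eps
})

#' @describeIn nParams parameter count of the Transformer denoiser.
#' @export
setMethod("nParams", "DiffFormer", function(model) countParams(model@params))

#' @describeIn nParams parameter count of the MLP denoiser.
#' @export
setMethod("nParams", "DiffMLP", function(model) countParams(model@params))

setMethod("show", "DiffFormer", function(object) {
  cfg <- object@config
  cat(sprintf("DiffFormer denoiser: K=%d, G=%d, d=%d, heads=%d, layers=%d, %d parameters\n",
              cfg$K, cfg$G, cfg$dModel, cfg$nHeads, cfg$nLayers,
              countParams(object@params)))
})

setMethod("show", "DiffMLP", function(object) {
  cfg <- object@config
  cat(sprintf("DiffMLP denoiser: K=%d, G=%d, d=%d, hidden=[%s], %d parameters\n",
              cfg$K, cfg$G, cfg$dModel,
              paste(cfg$mlpHidden, collapse = ", "),
              countParams(object@params)))
})
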