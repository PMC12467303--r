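# Compact neural-network core used by the denoiser models: dense layers,
# layer normalisation, GELU, dropout, softmax attention over the fixed
# 3-token sequence, and the matching analytic backward passes. Written in
# base-R matrix code; batches are plain B x d matrices, tokens a list of 3
# such matrices. Every backward function was validated against finite
# differences (see tests).

linFwd <- function(x, W, b) x %*% W + matrix(b, nrow(x), length(b), byrow = TRUE)

linBwd <- function(x, W, dy) {
  list(dx = dy %*% t(W), dW = crossprod(x, dy), db = colSums(dy))
}

lnFwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  y <- sweep(xhat, 2, g, "*")
  y <- sweep(y, 2, b, "+")
  list(y = y, xhat = xhat, inv = inv)
}

lnBwd <- function(cache, g, dy) {
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- sweep(dy, 2, g, "*")
  dx <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = dg, db = db)
}

geluFwd <- function(x) x * pnorm(x)

geluBwd <- function(x, dy) dy * (pnorm(x) + x * dnorm(x))

# Inverted dropout; returns the mask so the backward pass can reuse it.
# Consumes RNG only when active.
dropoutFwd <- function(x, p, training) {
  if (!training || p <= 0) return(list(y = x, mask = NULL))
  mask <- matrix((runif(length(x)) >= p) / (1 - p), nrow(x), ncol(x))
  list(y = x * mask, mask = mask)
}

dropoutBwd <- function(mask, dy) if (is.null(mask)) dy else dy * mask

rowSoftmax <- function(s) {
  m <- apply(s, 1, max)
  e <- exp(s - m)
  e / rowSums(e)
}

initMatrix <- function(nr, nc, scale) matrix(rnorm(nr * nc, sd = scale), nr, nc)

zerosLike <- function(p) {
  if (is.list(p)) lapply(p, zerosLike)
  else if (is.matrix(p)) matrix(0, nrow(p), ncol(p))
  else numeric(length(p))
}

# Elementwise recursion over two identically-shaped nested parameter lists.
mapParams <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- mapParams(a[[i]], b[[i]], f)
    out
  } else f(a, b)
}

sumParams <- function(p, f = identity) {
  if (is.list(p)) sum(vapply(p, sumParams, numeric(1), f = f)) else sum(f(p))
}

countParams <- function(p) {
  if (is.list(p)) sum(vapply(p, countParams, numeric(1))) else length(p)
}

## ---- Transformer encoder over the fixed [proportion, time, bulk] tokens ----

initEncoderLayer <- function(d, dff) {
  s <- 1 / sqrt(d)
  list(
    ln1g = rep(1, d), ln1b = rep(0, d),
    Wq = initMatrix(d, d, s), bq = rep(0, d),
    Wk = initMatrix(d, d, s), bk = rep(0, d),
    Wv = initMatrix(d, d, s), bv = rep(0, d),
    Wo = initMatrix(d, d, s), bo = rep(0, d),
    ln2g = rep(1, d), ln2b = rep(0, d),
    W1 = initMatrix(d, dff, s), b1 = rep(0, dff),
    W2 = initMatrix(dff, d, 1 / sqrt(dff)), b2 = rep(0, d)
  )
}

# Pre-norm encoder layer forward over a list of 3 tokens. Dropout is applied
# to the attention weights and to the feed-forward hidden activations.
encoderLayerFwd <- function(X, prm, nHeads, dropout, training) {
  d <- ncol(X[[1]]); dh <- d / nHeads; B <- nrow(X[[1]])
  N <- Q <- K <- V <- vector("list", 3)
  ln1c <- vector("list", 3)
  for (i in 1:3) {
    c1 <- lnFwd(X[[i]], prm$ln1g, prm$ln1b)
    ln1c[[i]] <- c1; N[[i]] <- c1$y
    Q[[i]] <- linFwd(N[[i]], prm$Wq, prm$bq)
    K[[i]] <- linFwd(N[[i]], prm$Wk, prm$bk)
    V[[i]] <- linFwd(N[[i]], prm$Wv, prm$bv)
  }
  A <- vector("list", 3)       # A[[i]][[h]]: B x 3 post-dropout weights
  Amask <- vector("list", 3)
  O <- vector("list", 3)
  for (i in 1:3) {
    A[[i]] <- Amask[[i]] <- vector("list", nHeads)
    Oi <- matrix(0, B, d)
    for (h in seq_len(nHeads)) {
      idx <- ((h - 1) * dh + 1):(h * dh)
      s <- sapply(1:3, function(j)
        rowSums(Q[[i]][, idx, drop = FALSE] * K[[j]][, idx, drop = FALSE]))
      if (B == 1L) s <- matrix(s, nrow = 1)
      a <- rowSoftmax(s / sqrt(dh))
      dr <- dropoutFwd(a, dropout, training)
      A[[i]][[h]] <- list(pre = a, post = dr$y)
      Amask[[i]][h] <- list(dr$mask)
      Oh <- dr$y[, 1] * V[[1]][, idx, drop = FALSE] +
            dr$y[, 2] * V[[2]][, idx, drop = FALSE] +
            dr$y[, 3] * V[[3]][, idx, drop = FALSE]
      Oi[, idx] <- Oh
    }
    O[[i]] <- Oi
  }
  X1 <- H <- Hpre <- ffnIn <- ln2c <- Fout <- vector("list", 3)
  Hmask <- vector("list", 3)
  for (i in 1:3) {
    att <- linFwd(O[[i]], prm$Wo, prm$bo)
    X1[[i]] <- X[[i]] + att
    c2 <- lnFwd(X1[[i]], prm$ln2g, prm$ln2b)
    ln2c[[i]] <- c2
    ffnIn[[i]] <- c2$y
    Hpre[[i]] <- linFwd(c2$y, prm$W1, prm$b1)
    g <- geluFwd(Hpre[[i]])
    dr <- dropoutFwd(g, dropout, training)
    H[[i]] <- dr$y; Hmask[i] <- list(dr$mask)
    Fout[[i]] <- linFwd(H[[i]], prm$W2, prm$b2)
  }
  Y <- lapply(1:3, function(i) X1[[i]] + Fout[[i]])
  list(Y = Y, cache = list(X = X, N = N, Q = Q, K = K, V = V, A = A,
                           Amask = Amask, O = O, X1 = X1, ln1c = ln1c,
                           ln2c = ln2c, ffnIn = ffnIn, Hpre = Hpre, H = H,
                           Hmask = Hmask))
}

encoderLayerBwd <- function(dY, prm, cache, nHeads) {
  d <- ncol(dY[[1]]); dh <- d / nHeads; B <- nrow(dY[[1]])
  g <- zerosLike(prm)
  dX1 <- vector("list", 3)
  # FFN branch (residual: dY flows to both X1 and the FFN path)
  for (i in 1:3) {
    l2 <- linBwd(cache$H[[i]], prm$W2, dY[[i]])
    g$W2 <- g$W2 + l2$dW; g$b2 <- g$b2 + l2$db
    dH <- dropoutBwd(cache$Hmask[[i]], l2$dx)
    dHpre <- geluBwd(cache$Hpre[[i]], dH)
    l1 <- linBwd(cache$ffnIn[[i]], prm$W1, dHpre)
    g$W1 <- g$W1 + l1$dW; g$b1 <- g$b1 + l1$db
    ln2 <- lnBwd(cache$ln2c[[i]], prm$ln2g, l1$dx)
    g$ln2g <- g$ln2g + ln2$dg; g$ln2b <- g$ln2b + ln2$db
    dX1[[i]] <- dY[[i]] + ln2$dx
  }
  # Attention branch
  dN <- lapply(1:3, function(i) matrix(0, B, d))
  dQ <- lapply(1:3, function(i) matrix(0, B, d))
  dK <- lapply(1:3, function(i) matrix(0, B, d))
  dV <- lapply(1:3, function(i) matrix(0, B, d))
  dX <- vector("list", 3)
  for (i in 1:3) {
    lo <- linBwd(cache$O[[i]], prm$Wo, dX1[[i]])
    g$Wo <- g$Wo + lo$dW; g$bo <- g$bo + lo$db
    dO <- lo$dx
    for (h in seq_len(nHeads)) {
      idx <- ((h - 1) * dh + 1):(h * dh)
      dOh <- dO[, idx, drop = FALSE]
      aPost <- cache$A[[i]][[h]]$post
      aPre <- cache$A[[i]][[h]]$pre
      dApost <- sapply(1:3, function(j)
        rowSums(dOh * cache$V[[j]][, idx, drop = FALSE]))
      if (B == 1L) dApost <- matrix(dApost, nrow = 1)
      for (j in 1:3)
        dV[[j]][, idx] <- dV[[j]][, idx, drop = FALSE] + aPost[, j] * dOh
      dApre <- dropoutBwd(cache$Amask[[i]][[h]], dApost)
      ds <- aPre * (dApre - rowSums(aPre * dApre))   # softmax backward
      ds <- ds / sqrt(dh)
      for (j in 1:3) {
        dQ[[i]][, idx] <- dQ[[i]][, idx, drop = FALSE] +
          ds[, j] * cache$K[[j]][, idx, drop = FALSE]
        dK[[j]][, idx] <- dK[[j]][, idx, drop = FALSE] +
          ds[, j] * cache$Q[[i]][, idx, drop = FALSE]
      }
    }
  }
  for (i in 1:3) {
    lq <- linBwd(cache$N[[i]], prm$Wq, dQ[[i]])
    lk <- linBwd(cache$N[[i]], prm$Wk, dK[[i]])
    lv <- linBwd(cache$N[[i]], prm$Wv, dV[[i]])
    g$Wq <- g$Wq + lq$dW; g$bq <- g$bq + lq$db
    g$Wk <- g$Wk + lk$dW; g$bk <- g$bk + lk$db
    g$Wv <- g$Wv + lv$dW; g$bv <- g$bv + lv$db
    dN[[i]] <- lq$dx + lk$dx + lv$dx
    ln1 <- lnBwd(cache$ln1c[[i]], prm$ln1g, dN[[i]])
    g$ln1g <- g$ln1g + ln1$dg; g$ln1b <- g$ln1b + ln1$db
    dX[[i]] <- dX1[[i]] + ln1$dx   # residual into the layer input
  }
  list(dX = dX, grads = g)
}

## ---- AdamW (decoupled weight decay) on nested parameter lists ----

adamwInit <- function(params) list(m = zerosLike(params), v = zerosLike(params),
                                   step = 0L)

adamwStep <- function(params, grads, state, lr, weightDecay = 0.01,
                      betas = c(0.9, 0.999), eps = 1e-8) {
  state$step <- state$step + 1L
  b1 <- betas[1]; b2 <- betas[2]; s <- state$step
  state$m <- mapParams(state$m, grads, function(m, g) b1 * m + (1 - b1) * g)
  state$v <- mapParams(state$v, grads, function(v, g) b2 * v + (1 - b2) * g^2)
  bc1 <- 1 - b1^s; bc2 <- 1 - b2^s
  upd <- mapParams(state$m, state$v,
                   function(m, v) (m / bc1) / (sqrt(v / bc2) + eps))
  params <- mapParams(params, upd,
                      function(p, u) p - lr * u - lr * weightDecay * p)
  list(params = params, state = state)
}
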