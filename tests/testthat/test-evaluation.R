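test_that("per-sample RMSE matches hand computations", {
  pT <- rbind(c(0.5, 0.3, 0.2), c(1, 0, 0))
  expect_equal(perSampleRMSE(pT, pT), c(0, 0))
  pP <- rbind(c(0.4, 0.4, 0.2), c(0, 1, 0))
  expect_equal(perSampleRMSE(pT, pP),
               c(sqrt((0.01 + 0.01 + 0) / 3), sqrt(2 / 3)),
               tolerance = 1e-10)
  two <- rbind(c(1, 0), c(0, 1))
  expect_equal(perSampleRMSE(two, two[2:1, ]), c(1, 1))
  expect_error(perSampleRMSE(pT, pT[, 1:2]), "identical shape")
})

test_that("per-type PCC handles constants as explicit undefined markers", {
  set.seed(1)
  pT <- matrix(runif(20), 5, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  expect_equal(unname(perTypePCC(pT, pT)), rep(1, 4))
  # affine transform with positive slope keeps correlation 1
  expect_equal(unname(perTypePCC(pT, 2 * pT + 0.3)), rep(1, 4),
               tolerance = 1e-12)
  pP <- pT; pP[, 2] <- 0.25
  pcc <- perTypePCC(pT, pP)
  expect_true(is.na(pcc[["b"]]))
  expect_false(anyNA(pcc[c("a", "c", "d")]))
  expect_error(perTypePCC(pT[1, , drop = FALSE], pP[1, , drop = FALSE]),
               "at least 2")
})

test_that("overall PCC is the flattened-vector correlation", {
  pT <- matrix(c(0.1, 0.9, 0.4, 0.6), 2, 2, byrow = TRUE)
  pP <- matrix(c(0.2, 0.8, 0.5, 0.5), 2, 2, byrow = TRUE)
  a <- c(0.1, 0.9, 0.4, 0.6); b <- c(0.2, 0.8, 0.5, 0.5)
  # hand-computed Pearson correlation of the two 4-vectors
  hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(overallPCC(pT, pP), hand, tolerance = 1e-12)
  expect_equal(overallPCC(pT, pT), 1)
  # cross-check against a naive two-loop implementation on random input
  set.seed(2)
  for (r in 1:5) {
    x <- matrix(runif(15), 5, 3); y <- matrix(runif(15), 5, 3)
    flatX <- numeric(0); flatY <- numeric(0)
    for (i in 1:5) for (j in 1:3) {
      flatX <- c(flatX, x[i, j]); flatY <- c(flatY, y[i, j])
    }
    expect_equal(overallPCC(x, y), cor(flatX, flatY), tolerance = 1e-12)
  }
})

test_that("paired t-test matches the textbook formula on a hand example", {
  a <- c(0.10, 0.12, 0.08, 0.15, 0.11)
  b <- c(0.12, 0.15, 0.09, 0.16, 0.15)
  res <- pairedRMSETest(a, b, c("A", "B"))
  d <- a - b
  tHand <- mean(d) / (sd(d) / sqrt(5))
  pHand <- 2 * pt(-abs(tHand), df = 4)
  expect_equal(res@t, tHand, tolerance = 1e-10)
  expect_equal(res@p, pHand, tolerance = 1e-10)
  expect_equal(res@cohensD, mean(d) / sd(d), tolerance = 1e-12)
  # sign convention: a better than b => negative mean difference and d < 0
  expect_lt(res@meanDiff, 0)
  expect_lt(res@cohensD, 0)
})

test_that("paired t-test degenerate cases are reported, not crashed", {
  x <- c(0.1, 0.2, 0.3)
  same <- pairedRMSETest(x, x)
  expect_equal(same@t, 0)
  expect_equal(same@p, 1)
  const <- pairedRMSETest(x + 0.05, x)
  expect_true(is.na(const@t))
  expect_true(is.na(const@p))
  expect_equal(const@meanDiff, 0.05)
})

test_that("parametric p agrees with a permutation test on small data", {
  set.seed(33)
  n <- 12
  a <- runif(n, 0.05, 0.15)
  b <- a + rnorm(n, 0.03, 0.02)  # b consistently worse
  res <- pairedRMSETest(a, b)
  d <- a - b
  nPerm <- 20000
  tObs <- abs(mean(d) / (sd(d) / sqrt(n)))
  tPerm <- replicate(nPerm, {
    signs <- sample(c(-1, 1), n, replace = TRUE)
    ds <- d * signs
    abs(mean(ds) / (sd(ds) / sqrt(n)))
  })
  pPerm <- mean(tPerm >= tObs)
  se <- sqrt(pPerm * (1 - pPerm) / nPerm)
  expect_lt(abs(res@p - pPerm), max(4 * se, 0.01))
})

test_that("stability summary follows the linear-interpolation convention", {
  s <- stabilitySummary(c(1, 2, 3, 4))
  expect_equal(unname(s), c(1.75, 2.5, 3.25, 1.5))
  expect_equal(stabilitySummary(rep(0.3, 6))[["iqr"]], 0)
  set.seed(3)
  x <- runif(50)
  expect_equal(stabilitySummary(x), stabilitySummary(sample(x)))
  expect_error(stabilitySummary(c(1, 2, 3)), "at least 4")
})

test_that("NNLS deconvolution matches closed-form least squares", {
  # orthogonal centroids: projection is solvable by hand
  ctr <- rbind(c(2, 0, 0, 0), c(0, 3, 0, 0))
  rownames(ctr) <- c("x", "y")
  bulk <- c(4, 3, 0, 0)  # = 2*row1 + 1*row2
  w <- nnlsDeconvolve(bulk, ctr)
  expect_equal(unname(w), c(2, 1) / 3, tolerance = 1e-10)
  # single centroid -> one-hot
  one <- nnlsDeconvolve(ctr[1, ], ctr)
  expect_equal(unname(one), c(1, 0))
  # general 2x2 via normal equations (both coefficients positive)
  A <- rbind(c(1, 2, 0.5), c(0.3, 1, 2))
  target <- 0.7 * A[1, ] + 0.3 * A[2, ]
  coefs <- solve(A %*% t(A), A %*% target)
  expect_equal(unname(nnlsDeconvolve(target, A)),
               as.numeric(coefs / sum(coefs)), tolerance = 1e-10)
})

test_that("evaluateProportions bundles metrics consistently", {
  set.seed(4)
  pT <- t(apply(matrix(rexp(40), 10, 4), 1, function(r) r / sum(r)))
  colnames(pT) <- paste0("t", 1:4)
  pP <- pT + matrix(rnorm(40, 0, 0.01), 10, 4)
  rep <- evaluateProportions(pT, pP)
  expect_equal(rep@perSampleRMSE, perSampleRMSE(pT, pP))
  expect_equal(rep@overallRMSE, mean(rep@perSampleRMSE))
  expect_equal(rep@overallPCC, overallPCC(pT, pP))
  expect_length(rep@failedTypes, 0)
  flat <- evaluateProportions(pT, pP, overallRMSEMode = "flattened")
  expect_equal(flat@overallRMSE, sqrt(mean((pT - pP)^2)))
  # a constant predicted column is reported as a failed type
  pBad <- pP; pBad[, 2] <- 0.25
  expect_equal(evaluateProportions(pT, pBad)@failedTypes, "t2")
})
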