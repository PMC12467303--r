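#' Per-sample root-mean-square error of proportion estimates
#'
#' Row i is \code{sqrt(mean((pTrue[i,] - pPred[i,])^2))} over the K
#' cell-type components.
#'
#' @param pTrue,pPred N x K matrices of true and predicted proportions
#'   with matching sample and type order.
#' @return numeric vector of length N, non-negative.
#' @export
perSampleRMSE <- function(pTrue, pPred) {
  stopIfNot(is.matrix(pTrue) && is.matrix(pPred) &&
              all(dim(pTrue) == dim(pPred)),
            "pTrue and pPred must be matrices of identical shape")
  sqrt(rowMeans((pTrue - pPred)^2))
}

#' Per-cell-type Pearson correlation across samples
#'
#' Column-wise correlation between truth and prediction. A column whose
#' truth or prediction has zero variance yields NA (an explicit undefined
#' marker, not an error) — the "model produced no variable prediction for
#' this type" failure mode.
#'
#' @inheritParams perSampleRMSE
#' @return named numeric vector of length K with NA for undefined entries
#'   (named when \code{pTrue} has column names).
#' @export
perTypePCC <- function(pTrue, pPred) {
  stopIfNot(is.matrix(pTrue) && is.matrix(pPred) &&
              all(dim(pTrue) == dim(pPred)),
            "pTrue and pPred must be matrices of identical shape")
  stopIfNot(nrow(pTrue) >= 2, "need at least 2 samples for correlations")
  out <- vapply(seq_len(ncol(pTrue)), function(k) {
    a <- pTrue[, k]; b <- pPred[, k]
    if (sd(a) == 0 || sd(b) == 0) NA_real_ else cor(a, b)
  }, numeric(1))
  names(out) <- colnames(pTrue)
  out
}

#' Overall Pearson correlation on flattened proportion matrices
#'
#' Both matrices are flattened row-major (sample by sample) into single
#' N*K vectors and correlated — a holistic score distinct from averaging
#' per-type correlations.
#'
#' @inheritParams perSampleRMSE
#' @return scalar correlation, NA when either flattened vector is constant.
#' @export
overallPCC <- function(pTrue, pPred) {
  stopIfNot(is.matrix(pTrue) && is.matrix(pPred) &&
              all(dim(pTrue) == dim(pPred)),
            "pTrue and pPred must be matrices of identical shape")
  stopIfNot(length(pTrue) >= 2, "need at least 2 values")
  a <- as.vector(t(pTrue))  # row-major flattening
  b <- as.vector(t(pPred))
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

#' Paired t-test on per-sample RMSE of two methods
#'
#' Two-tailed paired t-test on differences \code{d_i = rmseA_i - rmseB_i}
#' with the classical Student-t reference (n - 1 df), plus the paired
#' Cohen's d effect size \code{mean(d)/sd(d)} (sample sd). Negative d
#' means method a had the lower error. Zero-variance differences give an
#' undefined (NA) t, p and d rather than an error.
#'
#' @param rmseA,rmseB equal-length per-sample error vectors in the same
#'   sample order.
#' @param methods length-2 character labels for the two methods.
#' @return A [PairedTestResult-class] object.
#' @export
pairedRMSETest <- function(rmseA, rmseB, methods = c("a", "b")) {
  stopIfNot(length(rmseA) == length(rmseB), "vectors must have equal length")
  n <- length(rmseA)
  stopIfNot(n >= 2, "need at least 2 paired samples")
  d <- rmseA - rmseB
  m <- mean(d); s <- sd(d)
  if (s <= abs(m) * 1e-12 || (m == 0 && s == 0)) {
    # effectively constant differences: t undefined unless all-zero
    if (m == 0)
      return(methods::new("PairedTestResult", methods = methods, meanDiff = 0,
                          t = 0, p = 1, cohensD = 0, n = as.integer(n)))
    return(methods::new("PairedTestResult", methods = methods,
                        meanDiff = m, t = NA_real_, p = NA_real_,
                        cohensD = NA_real_, n = as.integer(n)))
  }
  tt <- t.test(rmseA, rmseB, paired = TRUE)
  methods::new("PairedTestResult", methods = methods, meanDiff = mean(d),
               t = unname(tt$statistic), p = tt$p.value,
               cohensD = mean(d) / sd(d), n = as.integer(n))
}

#' Quartile summary of an error distribution
#'
#' Median, first and third quartiles and the interquartile range, using
#' the linear-interpolation quantile convention (R type 7).
#'
#' @param x numeric vector of per-sample errors, length >= 4.
#' @return named numeric vector (q1, median, q3, iqr).
#' @export
stabilitySummary <- function(x) {
  stopIfNot(is.numeric(x) && length(x) >= 4, "need at least 4 samples")
  q <- quantile(x, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(q1 = q[1], median = q[2], q3 = q[3], iqr = q[3] - q[1])
}

#' Non-negative least squares linear deconvolution baseline
#'
#' Fits the bulk profile as a non-negative combination of the cell-type
#' centroid profiles and renormalises the coefficients to sum to one.
#' Serves as the linear sanity baseline and as the oracle on noiseless
#' centroid mixtures.
#'
#' @param bulk numeric vector of length G.
#' @param centroids K x G signature matrix (rows = types), e.g. from
#'   [typeCentroids()].
#' @return proportion vector of length K (named by centroid row names).
#' @export
nnlsDeconvolve <- function(bulk, centroids) {
  stopIfNot(is.matrix(centroids) && length(bulk) == ncol(centroids),
            "'centroids' must be K x G with G matching 'bulk'")
  fit <- pracma::lsqnonneg(t(centroids), as.numeric(bulk))
  w <- fit$x
  if (sum(w) <= 0) {
    warning("NNLS returned the all-zero solution; falling back to uniform")
    w <- rep(1, nrow(centroids))
  }
  stats::setNames(w / sum(w), rownames(centroids))
}

#' Full accuracy report for a prediction matrix
#'
#' Bundles per-sample RMSE, per-type and overall Pearson correlation, the
#' overall RMSE (mean of per-sample RMSE by default, or the RMSE over the
#' flattened matrices) and the RMSE interquartile range.
#'
#' @inheritParams perSampleRMSE
#' @param overallRMSEMode "meanPerSample" (default) or "flattened".
#' @return An [EvalReport-class] object.
#' @export
evaluateProportions <- function(pTrue, pPred,
                                overallRMSEMode = c("meanPerSample", "flattened")) {
  overallRMSEMode <- match.arg(overallRMSEMode)
  rmse <- perSampleRMSE(pTrue, pPred)
  pcc <- perTypePCC(pTrue, pPred)
  failed <- if (is.null(names(pcc))) as.character(which(is.na(pcc)))
            else names(pcc)[is.na(pcc)]
  ormse <- if (overallRMSEMode == "meanPerSample") mean(rmse)
           else sqrt(mean((pTrue - pPred)^2))
  iqr <- if (length(rmse) >= 4) unname(stabilitySummary(rmse)["iqr"]) else NA_real_
  methods::new("EvalReport", perSampleRMSE = rmse, perTypePCC = pcc,
               overallPCC = overallPCC(pTrue, pPred), overallRMSE = ormse,
               rmseIQR = iqr, failedTypes = failed)
}
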