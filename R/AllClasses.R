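#' @import methods
#' @importFrom stats cor quantile rnorm runif rnbinom rlnorm rmultinom rgamma
#'   sd t.test pt var setNames dnorm pnorm
#' @importFrom utils write.table read.table head
NULL

#' Raw single-cell counts with per-cell type annotations
#'
#' Thin container for an unprocessed single-cell RNA-seq counts matrix
#' (cells x genes, non-negative integers), the gene identifiers and one
#' cell-type label per cell. Mitochondrial genes are recognised downstream
#' by the conventional "MT-"/"mt-" gene-name prefix.
#'
#' @slot counts cells x genes matrix (base matrix or \code{Matrix} sparse
#'   matrix) of non-negative counts.
#' @slot geneIds character vector, one id per column of \code{counts}.
#' @slot cellTypes character vector, one label per row of \code{counts}.
#' @export
setClass("RawCounts",
  representation(counts = "ANY", geneIds = "character", cellTypes = "character"),
  validity = function(object) {
    msg <- character()
    if (!(is.matrix(object@counts) || methods::is(object@counts, "Matrix")))
      msg <- c(msg, "counts must be a base matrix or a Matrix sparse matrix")
    else {
      if (nrow(object@counts) == 0L || ncol(object@counts) == 0L)
        msg <- c(msg, "counts must be non-empty")
      if (length(object@geneIds) != ncol(object@counts))
        msg <- c(msg, "length(geneIds) must equal ncol(counts)")
      if (length(object@cellTypes) != nrow(object@counts))
        msg <- c(msg, "length(cellTypes) must equal nrow(counts)")
      mn <- suppressWarnings(min(object@counts))
      if (is.finite(mn) && mn < 0) msg <- c(msg, "counts must be non-negative")
    }
    if (anyDuplicated(object@geneIds)) msg <- c(msg, "geneIds must be unique")
    if (length(msg)) msg else TRUE
  }
)

#' Processed single-cell reference atlas
#'
#' The processed reference used for pseudo-bulk simulation and as the
#' conditioning signature space: CP10K + log1p normalised expression
#' restricted to the selected highly variable genes, with per-cell type
#' labels. \code{typeNames} is sorted lexicographically so the index of a
#' proportion vector component is reproducible across runs.
#'
#' @slot lognorm cells x G numeric matrix (log1p of CP10K), G = number of
#'   retained highly variable genes.
#' @slot hvgIds ordered character vector of the selected gene ids
#'   (selection rank order).
#' @slot cellTypes character vector, one label per row of \code{lognorm}.
#' @slot typeNames sorted character vector of the K unique cell types.
#' @export
setClass("ReferenceAtlas",
  representation(lognorm = "matrix", hvgIds = "character",
                 cellTypes = "character", typeNames = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@hvgIds) != ncol(object@lognorm))
      msg <- c(msg, "length(hvgIds) must equal ncol(lognorm)")
    if (length(object@cellTypes) != nrow(object@lognorm))
      msg <- c(msg, "length(cellTypes) must equal nrow(lognorm)")
    if (any(object@lognorm < 0)) msg <- c(msg, "lognorm must be non-negative")
    if (length(object@typeNames) < 2L)
      msg <- c(msg, "atlas needs at least 2 cell types")
    if (!all(object@cellTypes %in% object@typeNames))
      msg <- c(msg, "every cellTypes entry must be in typeNames")
    if (is.unsorted(object@typeNames))
      msg <- c(msg, "typeNames must be sorted lexicographically")
    if (length(msg)) msg else TRUE
  }
)

#' Linear diffusion noise schedule
#'
#' Per-timestep noise variances beta_t of the forward diffusion, the
#' signal-retention factors alpha_t = 1 - beta_t, and their cumulative
#' products alphaBar_t. Timesteps are 1-based: element \code{t} of each
#' vector corresponds to diffusion step t in 1..nSteps.
#'
#' @slot nSteps integer number of diffusion timesteps T.
#' @slot beta numeric vector length T, strictly inside (0, 1).
#' @slot alpha numeric vector, 1 - beta.
#' @slot alphaBar numeric vector, cumprod(alpha); strictly decreasing.
#' @export
setClass("NoiseSchedule",
  representation(nSteps = "integer", beta = "numeric", alpha = "numeric",
                 alphaBar = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@nSteps < 1L) msg <- c(msg, "nSteps must be >= 1")
    if (length(object@beta) != object@nSteps ||
        length(object@alpha) != object@nSteps ||
        length(object@alphaBar) != object@nSteps)
      msg <- c(msg, "beta/alpha/alphaBar must all have length nSteps")
    if (any(object@beta <= 0) || any(object@beta >= 1))
      msg <- c(msg, "beta must lie strictly in (0, 1)")
    if (any(diff(object@beta) < 0))
      msg <- c(msg, "beta must be non-decreasing")
    if (any(diff(object@alphaBar) >= 0))
      msg <- c(msg, "alphaBar must be strictly decreasing")
    if (object@alphaBar[object@nSteps] <= 0 || object@alphaBar[object@nSteps] >= 1)
      msg <- c(msg, "alphaBar_T must lie in (0, 1)")
    if (length(msg)) msg else TRUE
  }
)

#' Pseudo-bulk dataset with ground-truth proportions
#'
#' A set of simulated bulk profiles paired with the realized cell-type
#' fractions they were mixed from, in the gene/type coordinate system of
#' the atlas that generated them.
#'
#' @slot bulk N x G numeric matrix of mean log-normalised expression.
#' @slot props N x K numeric matrix; each row is on the probability simplex.
#' @slot typeNames character length K (column order of \code{props}).
#' @slot hvgIds character length G (column order of \code{bulk}).
#' @slot config list; the simulation configuration used (provenance).
#' @export
setClass("PseudoBulkDataset",
  representation(bulk = "matrix", props = "matrix", typeNames = "character",
                 hvgIds = "character", config = "list"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@bulk) != nrow(object@props))
      msg <- c(msg, "bulk and props must have one row per sample")
    if (ncol(object@props) != length(object@typeNames))
      msg <- c(msg, "props columns must match typeNames")
    if (ncol(object@bulk) != length(object@hvgIds))
      msg <- c(msg, "bulk columns must match hvgIds")
    if (nrow(object@props) > 0) {
      if (any(object@props < 0)) msg <- c(msg, "proportions must be non-negative")
      if (any(abs(rowSums(object@props) - 1) > 1e-9))
        msg <- c(msg, "each proportion row must sum to 1 (tol 1e-9)")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Deconvolution accuracy report
#'
#' Per-sample RMSE, per-type Pearson correlation (NA marks a cell type for
#' which a constant prediction or truth made the correlation undefined),
#' the overall flattened-matrix correlation, and error-distribution
#' stability summaries.
#'
#' @slot perSampleRMSE numeric length N.
#' @slot perTypePCC named numeric length K; NA marks undefined entries.
#' @slot overallPCC numeric scalar (NA if undefined).
#' @slot overallRMSE numeric scalar; mean of per-sample RMSE by default.
#' @slot rmseIQR numeric scalar; interquartile range of per-sample RMSE.
#' @slot failedTypes character; names of types with undefined correlation.
#' @export
setClass("EvalReport",
  representation(perSampleRMSE = "numeric", perTypePCC = "numeric",
                 overallPCC = "numeric", overallRMSE = "numeric",
                 rmseIQR = "numeric", failedTypes = "character"),
  validity = function(object) {
    msg <- character()
    if (any(object@perSampleRMSE < 0)) msg <- c(msg, "RMSE must be >= 0")
    pcc <- object@perTypePCC[!is.na(object@perTypePCC)]
    if (length(pcc) && any(pcc < -1 - 1e-12 | pcc > 1 + 1e-12))
      msg <- c(msg, "defined PCC entries must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
  }
)

#' Paired t-test comparison of two methods' per-sample errors
#'
#' @slot methods character length 2, the (a, b) method labels.
#' @slot meanDiff mean of the paired differences a - b.
#' @slot t t statistic (NA when the differences have zero variance).
#' @slot p two-tailed p-value from Student-t with n - 1 df (NA if undefined).
#' @slot cohensD mean(d)/sd(d) with the sample (n - 1) standard deviation;
#'   negative when method a has the lower error.
#' @slot n number of paired samples.
#' @export
setClass("PairedTestResult",
  representation(methods = "character", meanDiff = "numeric", t = "numeric",
                 p = "numeric", cohensD = "numeric", n = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@n < 2L) msg <- c(msg, "n must be >= 2")
    if (!is.na(object@p) && (object@p < 0 || object@p > 1))
      msg <- c(msg, "p must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "RawCounts", function(object) {
  cat("RawCounts:", nrow(object@counts), "cells x", ncol(object@counts),
      "genes;", length(unique(object@cellTypes)), "cell types\n")
})

setMethod("show", "ReferenceAtlas", function(object) {
  cat("ReferenceAtlas:", nrow(object@lognorm), "cells x",
      ncol(object@lognorm), "HVGs; K =", length(object@typeNames),
      "types:", paste(object@typeNames, collapse = ", "), "\n")
})

setMethod("show", "NoiseSchedule", function(object) {
  cat(sprintf("NoiseSchedule: T = %d, beta in [%g, %g], alphaBar_T = %.4g\n",
              object@nSteps, object@beta[1], object@beta[object@nSteps],
              object@alphaBar[object@nSteps]))
})

setMethod("show", "PseudoBulkDataset", function(object) {
  cat("PseudoBulkDataset:", nrow(object@bulk), "samples x",
      ncol(object@bulk), "genes; K =", length(object@typeNames), "\n")
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: mean RMSE %.4f (IQR %.4f), overall PCC %s\n",
              object@overallRMSE, object@rmseIQR,
              ifelse(is.na(object@overallPCC), "NA",
                     sprintf("%.4f", object@overallPCC))))
  cat("  per-type PCC:\n")
  print(round(object@perTypePCC, 4))
  if (length(object@failedTypes))
    cat("  undefined for:", paste(object@failedTypes, collapse = ", "), "\n")
})

setMethod("show", "PairedTestResult", function(object) {
  cat(sprintf(
    "Paired RMSE test %s vs %s: mean diff %.4g, t = %s, p = %s, d = %s (n = %d)\n",
    object@methods[1], object@methods[2], object@meanDiff,
    format(object@t, digits = 4), format(object@p, digits = 4),
    format(object@cohensD, digits = 4), object@n))
})
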