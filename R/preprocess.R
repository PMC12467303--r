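#' Construct a RawCounts object
#'
#' @param counts cells x genes matrix of non-negative counts (base matrix
#'   or sparse \code{Matrix}).
#' @param geneIds character vector of gene identifiers (columns).
#' @param cellTypes character vector of per-cell type labels (rows).
#' @return A validated [RawCounts-class] object.
#' @examples
#' rc <- RawCounts(matrix(1:4, 2, 2), c("g1", "g2"), c("A", "B"))
#' @export
RawCounts <- function(counts, geneIds, cellTypes) {
  methods::new("RawCounts", counts = counts, geneIds = as.character(geneIds),
               cellTypes = as.character(cellTypes))
}

#' Flag mitochondrial genes by name prefix
#'
#' Standard convention: gene ids starting with "MT-" or "mt-" are treated
#' as mitochondrially encoded.
#'
#' @param geneIds character vector of gene identifiers.
#' @return logical vector, TRUE for mitochondrial genes.
#' @export
mitoFlags <- function(geneIds) {
  startsWith(geneIds, "MT-") | startsWith(geneIds, "mt-")
}

#' Quality-control filtering of cells and genes
#'
#' Removes low-quality cells (too few or too many detected genes, or a
#' mitochondrial count fraction above \code{maxMitoFrac}), then removes
#' genes expressed in fewer than \code{minCellsPerGene} of the retained
#' cells. Cell filters run first so gene prevalence is computed on the
#' surviving cells.
#'
#' @param raw a [RawCounts-class] object.
#' @param minGenes minimum number of detected (non-zero) genes per cell.
#' @param maxGenes maximum number of detected genes per cell.
#' @param maxMitoFrac maximum allowed mitochondrial count fraction.
#' @param minCellsPerGene genes detected in fewer retained cells are dropped.
#' @return A filtered [RawCounts-class] object.
#' @export
qcFilter <- function(raw, minGenes = 200L, maxGenes = 5000L,
                     maxMitoFrac = 0.20, minCellsPerGene = 3L) {
  stopIfNot(methods::is(raw, "RawCounts"), "'raw' must be a RawCounts object")
  cm <- raw@counts
  detected <- if (methods::is(cm, "Matrix")) Matrix::rowSums(cm > 0) else rowSums(cm > 0)
  total <- if (methods::is(cm, "Matrix")) Matrix::rowSums(cm) else rowSums(cm)
  mito <- mitoFlags(raw@geneIds)
  mitoCounts <- if (any(mito)) {
    sub <- cm[, mito, drop = FALSE]
    if (methods::is(sub, "Matrix")) Matrix::rowSums(sub) else rowSums(sub)
  } else rep(0, nrow(cm))
  mitoFrac <- ifelse(total > 0, mitoCounts / total, 0)
  keepCell <- detected >= minGenes & detected <= maxGenes & mitoFrac <= maxMitoFrac
  if (!any(keepCell)) stop("empty after QC: no cell passed the filters", call. = FALSE)
  cm <- cm[keepCell, , drop = FALSE]
  prevalence <- if (methods::is(cm, "Matrix")) Matrix::colSums(cm > 0) else colSums(cm > 0)
  keepGene <- prevalence >= minCellsPerGene
  if (!any(keepGene)) stop("empty after QC: no gene passed the filters", call. = FALSE)
  RawCounts(cm[, keepGene, drop = FALSE], raw@geneIds[keepGene],
            raw@cellTypes[keepCell])
}

#' CP10K + log1p normalisation
#'
#' Scales each cell's counts to sum to 10,000 (counts per 10K), then
#' applies \code{log1p} elementwise.
#'
#' @param raw a [RawCounts-class] object; every cell must have a positive
#'   total count.
#' @return dense numeric matrix (cells x genes) of log-normalised values,
#'   with \code{geneIds} as column names.
#' @export
normalizeCP10kLog1p <- function(raw) {
  stopIfNot(methods::is(raw, "RawCounts"), "'raw' must be a RawCounts object")
  cm <- asMatrixDense(raw@counts)
  total <- rowSums(cm)
  bad <- which(total <= 0)
  if (length(bad))
    stop(sprintf("cell(s) with zero total count cannot be normalised: row %s",
                 paste(head(bad, 5), collapse = ", ")), call. = FALSE)
  out <- log1p(cm * (1e4 / total))
  dimnames(out) <- list(NULL, raw@geneIds)
  out
}

#' Dispersion-based highly variable gene selection
#'
#' Per-gene mean and dispersion (variance / mean) are computed on the
#' \code{expm1} (CP10K) scale. Log dispersions are z-scored within
#' \code{nBins} equal-frequency bins of log1p mean expression; genes inside
#' the \code{[minMean, maxMean]} log-mean window with normalised dispersion
#' >= \code{minDisp} are ranked by normalised dispersion (ties broken by
#' gene id) and the top \code{nTop} returned.
#'
#' @param lognorm cells x genes matrix from [normalizeCP10kLog1p()] with
#'   gene ids as column names.
#' @param nTop number of genes to select.
#' @param minMean,maxMean window on log1p of the mean CP10K expression.
#' @param minDisp cutoff on the bin-normalised dispersion.
#' @param nBins number of equal-frequency mean bins for normalisation.
#' @return character vector of selected gene ids in rank order. If fewer
#'   genes pass the window than \code{nTop}, all passers are returned with
#'   a warning.
#' @export
selectHvgs <- function(lognorm, nTop = 2000L, minMean = 0.0125, maxMean = 3,
                       minDisp = 0.5, nBins = 20L) {
  stopIfNot(is.matrix(lognorm) && !is.null(colnames(lognorm)),
            "'lognorm' must be a matrix with gene ids as column names")
  checkCountScalar(nTop, "nTop")
  x <- expm1(lognorm)
  mu <- colMeans(x)
  v <- apply(x, 2, var)
  disp <- ifelse(mu > 0, v / mu, 0)
  meanLog <- log1p(mu)
  dispLog <- ifelse(disp > 0, log(disp), NA_real_)

  # equal-frequency binning of the mean, z-score dispersions within bins
  nBins <- max(1L, min(as.integer(nBins), length(mu)))
  br <- unique(quantile(meanLog, probs = seq(0, 1, length.out = nBins + 1),
                        type = 7, names = FALSE))
  bin <- if (length(br) > 2)
    cut(meanLog, breaks = br, include.lowest = TRUE, labels = FALSE)
  else rep(1L, length(meanLog))
  dispNorm <- rep(0, length(disp))
  for (b in unique(bin)) {
    idx <- which(bin == b)
    dl <- dispLog[idx]
    ok <- !is.na(dl)
    if (sum(ok) >= 2 && sd(dl[ok]) > 0) {
      z <- (dl - mean(dl[ok])) / sd(dl[ok])
      dispNorm[idx] <- ifelse(is.na(z), -Inf, z)
    } else {
      dispNorm[idx] <- ifelse(ok, 0, -Inf)
    }
  }

  pass <- meanLog > minMean & meanLog < maxMean & dispNorm >= minDisp &
    is.finite(dispNorm)
  ids <- colnames(lognorm)[pass]
  ord <- order(-dispNorm[pass], colnames(lognorm)[pass], method = "radix")
  ids <- ids[ord]
  if (length(ids) < nTop) {
    warning(sprintf("only %d genes passed the HVG window (requested %d); returning all passers",
                    length(ids), nTop))
    return(ids)
  }
  ids[seq_len(nTop)]
}

#' Build a processed reference atlas from raw counts
#'
#' Runs the fixed preprocessing pipeline: QC filtering, CP10K + log1p
#' normalisation, highly variable gene selection, and column subsetting to
#' the selected genes. \code{typeNames} is the lexicographically sorted set
#' of surviving cell types, fixing the proportion-vector index order.
#'
#' @param raw a [RawCounts-class] object.
#' @param qc named list overriding [qcFilter()] arguments.
#' @param hvg named list overriding [selectHvgs()] arguments
#'   (e.g. \code{list(nTop = 5000)} for batch-shifted validation targets).
#' @param requireAllTypes if TRUE (default), error when QC removes every
#'   cell of some input type; if FALSE, K is silently reduced.
#' @return A [ReferenceAtlas-class] object.
#' @export
buildAtlas <- function(raw, qc = list(), hvg = list(), requireAllTypes = TRUE) {
  filtered <- do.call(qcFilter, c(list(raw = raw), qc))
  if (requireAllTypes) {
    lost <- setdiff(unique(raw@cellTypes), unique(filtered@cellTypes))
    if (length(lost))
      stop(sprintf("cell type(s) entirely removed by QC: %s",
                   paste(lost, collapse = ", ")), call. = FALSE)
  }
  ln <- normalizeCP10kLog1p(filtered)
  ids <- do.call(selectHvgs, c(list(lognorm = ln), hvg))
  if (!length(ids)) stop("HVG selection returned no genes", call. = FALSE)
  methods::new("ReferenceAtlas",
               lognorm = unname(ln[, ids, drop = FALSE]),
               hvgIds = ids,
               cellTypes = filtered@cellTypes,
               typeNames = sort(unique(filtered@cellTypes), method = "radix"))
}
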