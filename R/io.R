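# Readers and writers for the on-disk formats: matrix-market reference
# triplets (10x v2 dialect), dense TSV fallbacks, plain-text atlas and
# dataset containers (TSV matrices + JSON metadata), RDS model
# checkpoints, and JSON reports.

#' Read a 10x-style matrix-market reference triplet
#'
#' Expects \code{matrix.mtx} (genes x cells, 1-based indices per the
#' standard), \code{genes.tsv} (gene id in the first column),
#' \code{barcodes.tsv}, and a two-column annotation TSV
#' (barcode, cell type) covering every barcode.
#'
#' @param dir directory containing the triplet.
#' @param annotationFile path to the barcode/type TSV (default
#'   \code{annotations.tsv} inside \code{dir}).
#' @return A [RawCounts-class] object (cells x genes).
#' @export
readReference10x <- function(dir, annotationFile = file.path(dir, "annotations.tsv")) {
  mtx <- file.path(dir, "matrix.mtx")
  genesF <- file.path(dir, "genes.tsv")
  bcF <- file.path(dir, "barcodes.tsv")
  for (f in c(mtx, genesF, bcF, annotationFile))
    stopIfNot(file.exists(f), sprintf("missing input file: %s", f))
  m <- Matrix::t(Matrix::readMM(mtx))  # -> cells x genes
  genes <- read.table(genesF, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)[, 1]
  barcodes <- read.table(bcF, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)[, 1]
  ann <- read.table(annotationFile, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE, col.names = c("barcode", "type"))
  stopIfNot(length(genes) == ncol(m), "genes.tsv length does not match matrix")
  stopIfNot(length(barcodes) == nrow(m), "barcodes.tsv length does not match matrix")
  types <- ann$type[match(barcodes, ann$barcode)]
  stopIfNot(!anyNA(types), "annotation file does not cover every barcode")
  RawCounts(m, genes, types)
}

#' Write a RawCounts object as a 10x-style triplet
#'
#' @param raw a [RawCounts-class] object.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeReference10x <- function(raw, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  barcodes <- sprintf("cell%05d", seq_along(raw@cellTypes))
  sp <- methods::as(methods::as(Matrix::Matrix(Matrix::t(raw@counts), sparse = TRUE),
                                "generalMatrix"), "TsparseMatrix")
  Matrix::writeMM(sp, file.path(dir, "matrix.mtx"))
  write.table(data.frame(raw@geneIds, raw@geneIds),
              file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeLines(barcodes, file.path(dir, "barcodes.tsv"))
  write.table(data.frame(barcodes, raw@cellTypes),
              file.path(dir, "annotations.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Read a dense TSV counts table as a reference
#'
#' Fallback for references shipped as a dense table. Orientation is
#' explicit: \code{"cellsByGenes"} (rows = cells) or \code{"genesByCells"}.
#'
#' @param countsFile TSV with row and column names.
#' @param annotationFile two-column TSV (cell id, type).
#' @param orientation table orientation, see Details.
#' @return A [RawCounts-class] object.
#' @export
readReferenceDense <- function(countsFile, annotationFile,
                               orientation = c("cellsByGenes", "genesByCells")) {
  orientation <- match.arg(orientation)
  tab <- as.matrix(read.table(countsFile, sep = "\t", header = TRUE,
                              row.names = 1, check.names = FALSE))
  if (orientation == "genesByCells") tab <- t(tab)
  ann <- read.table(annotationFile, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE, col.names = c("cell", "type"))
  types <- ann$type[match(rownames(tab), ann$cell)]
  stopIfNot(!anyNA(types), "annotation file does not cover every cell")
  RawCounts(tab, colnames(tab), types)
}

#' Serialise / restore a reference atlas
#'
#' Plain-text directory container: \code{lognorm.tsv} (cells x HVGs,
#' gene ids as header), \code{cells.tsv} (per-cell type labels) and
#' \code{meta.json} (hvg order, type names).
#'
#' @param atlas a [ReferenceAtlas-class] object.
#' @param dir container directory.
#' @return \code{writeAtlas}: \code{dir} invisibly; \code{readAtlas}: the
#'   restored [ReferenceAtlas-class].
#' @export
writeAtlas <- function(atlas, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ln <- atlas@lognorm
  colnames(ln) <- atlas@hvgIds
  write.table(format(ln, digits = 17, trim = TRUE, scientific = TRUE),
              file.path(dir, "lognorm.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(atlas@cellTypes, file.path(dir, "cells.tsv"))
  jsonlite::write_json(list(hvgIds = atlas@hvgIds, typeNames = atlas@typeNames),
                       file.path(dir, "meta.json"))
  invisible(dir)
}

#' @rdname writeAtlas
#' @export
readAtlas <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  ln <- as.matrix(read.table(file.path(dir, "lognorm.tsv"), sep = "\t",
                             header = TRUE, check.names = FALSE))
  methods::new("ReferenceAtlas", lognorm = unname(ln),
               hvgIds = as.character(meta$hvgIds),
               cellTypes = readLines(file.path(dir, "cells.tsv")),
               typeNames = as.character(meta$typeNames))
}

#' Serialise / restore a pseudo-bulk dataset
#'
#' Plain-text directory container: \code{bulk.tsv} (N x G),
#' \code{props.tsv} (N x K, type names as header) and \code{meta.json}
#' (gene order, type names, full simulation config for provenance).
#'
#' @param ds a [PseudoBulkDataset-class] object.
#' @param dir container directory.
#' @return \code{writeDataset}: \code{dir} invisibly; \code{readDataset}:
#'   the restored [PseudoBulkDataset-class].
#' @export
writeDataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bulk <- ds@bulk; colnames(bulk) <- ds@hvgIds
  props <- ds@props; colnames(props) <- ds@typeNames
  write.table(format(bulk, digits = 17, trim = TRUE, scientific = TRUE),
              file.path(dir, "bulk.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(format(props, digits = 17, trim = TRUE, scientific = TRUE),
              file.path(dir, "props.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(hvgIds = ds@hvgIds, typeNames = ds@typeNames,
                            config = ds@config),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname writeDataset
#' @export
readDataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  bulk <- as.matrix(read.table(file.path(dir, "bulk.tsv"), sep = "\t",
                               header = TRUE, check.names = FALSE))
  props <- as.matrix(read.table(file.path(dir, "props.tsv"), sep = "\t",
                                header = TRUE, check.names = FALSE))
  methods::new("PseudoBulkDataset", bulk = unname(bulk), props = unname(props),
               typeNames = as.character(meta$typeNames),
               hvgIds = as.character(meta$hvgIds),
               config = as.list(meta$config))
}

#' Save / load a trained denoiser checkpoint
#'
#' Single-file container holding the architecture configuration, the
#' trained parameters, and the gene/type coordinate system
#' (\code{hvgIds}, \code{typeNames}) plus the training seed so inference
#' can validate compatibility before running.
#'
#' @param model a [DiffFormer-class] or [DiffMLP-class] object.
#' @param path checkpoint file path.
#' @param typeNames,hvgIds coordinate metadata stored alongside.
#' @param seed the training seed (provenance).
#' @return \code{saveCheckpoint}: \code{path} invisibly;
#'   \code{loadCheckpoint}: the model with \code{typeNames}/\code{hvgIds}
#'   attached as attributes.
#' @export
saveCheckpoint <- function(model, path, typeNames = NULL, hvgIds = NULL,
                           seed = NULL) {
  kind <- if (methods::is(model, "DiffFormer")) "diffformer" else "diffmlp"
  saveRDS(list(kind = kind, config = model@config, params = model@params,
               typeNames = typeNames, hvgIds = hvgIds, seed = seed,
               package = "DiffDeconv",
               version = as.character(utils::packageVersion("DiffDeconv"))),
          path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  cls <- if (identical(ck$kind, "diffformer")) "DiffFormer" else "DiffMLP"
  model <- methods::new(cls, config = ck$config, params = ck$params)
  attr(model, "hvgIds") <- ck$hvgIds
  attr(model, "typeNames") <- ck$typeNames
  attr(model, "seed") <- ck$seed
  model
}

#' Write / read a proportions matrix as CSV
#'
#' CSV schema: header row of cell-type names, one row per sample.
#'
#' @param props N x K matrix.
#' @param path CSV file path.
#' @param typeNames column names to write (defaults to existing colnames).
#' @return \code{writeProportionsCSV}: \code{path} invisibly;
#'   \code{readProportionsCSV}: the matrix.
#' @export
writeProportionsCSV <- function(props, path, typeNames = colnames(props)) {
  out <- as.data.frame(props)
  if (!is.null(typeNames)) colnames(out) <- typeNames
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeProportionsCSV
#' @export
readProportionsCSV <- function(path) {
  as.matrix(utils::read.csv(path, check.names = FALSE))
}

reportToList <- function(report) {
  list(overallRMSE = report@overallRMSE,
       overallPCC = report@overallPCC,
       rmseIQR = report@rmseIQR,
       perTypePCC = as.list(report@perTypePCC),
       failedTypes = report@failedTypes,
       perSampleRMSE = report@perSampleRMSE)
}

pairedTestToList <- function(pt) {
  list(methods = pt@methods, meanDiff = pt@meanDiff, t = pt@t, p = pt@p,
       cohensD = pt@cohensD, n = pt@n)
}
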