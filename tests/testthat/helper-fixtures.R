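# Shared fixtures, all generated in code at test time.

# Small, well-separated synthetic atlas for fast end-to-end checks.
makeTestAtlas <- function(nTypes = 3L, nGenes = 60L, cellsPerType = 30L,
                          markerFold = 20, seed = 101L, ...) {
  rc <- simulateReference(synthRefConfig(
    nTypes = nTypes, nGenes = nGenes, cellsPerType = cellsPerType,
    nMarkersPerType = 5L, markerFold = markerFold, seed = seed, ...))
  suppressWarnings(buildAtlas(rc,
    qc = list(minGenes = 1L, minCellsPerGene = 1L),
    hvg = list(nTop = nGenes, maxMean = Inf)))
}

# Raw counts with hand-set values for QC edge cases.
makeRawCounts <- function(counts, geneIds = NULL, cellTypes = NULL) {
  if (is.null(geneIds)) geneIds <- sprintf("g%03d", seq_len(ncol(counts)))
  if (is.null(cellTypes)) cellTypes <- rep("A", nrow(counts))
  RawCounts(counts, geneIds, cellTypes)
}

# Micro denoiser configuration used for arithmetic oracles.
microConfig <- function(dropout = 0) {
  denoiserConfig(K = 3L, G = 5L, dModel = 4L, nHeads = 1L, nLayers = 1L,
                 dFF = 6L, dropout = dropout, mlpHidden = c(4L), tMax = 10L)
}
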